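#' @importFrom utils read.delim head tail
#' @importFrom stats setNames
NULL

# package-local cache for the configuration table
.electrum_env <- new.env(parent = emptyenv())

# subshells in Madelung (aufbau) filling order; the first 15 (through 6p)
# span exactly 86 electron slots and define the metal-encoding window
.SUBSHELLS <- c("1s", "2s", "2p", "3s", "3p", "4s", "3d", "4p", "5s", "4d",
                "5p", "6s", "4f", "5d", "6p", "7s", "5f", "6d", "7p")
.SUBSHELL_CAP <- c(2, 2, 6, 2, 6, 2, 10, 6, 2, 10, 6, 2, 14, 10, 6, 2, 14, 10, 6)
.N_WINDOW_SUBSHELLS <- 15L
.METAL_BITS <- 86L

#' Metals recognised as complex centres by default
#'
#' The union of the metal sets spanned by the two curated benchmark
#' datasets: the 48 elements of the coordination-number curation (d- and
#' f-block metals plus post-transition metals found as mononuclear complex
#' centres in crystallographic data) together with Pd and Ag, which the
#' oxidation-state subset adds.
#'
#' @return Character vector of 50 element symbols.
#' @export
electrum_metals <- function() {
  c("Bi", "Cd", "Ce", "Cr", "Co", "Cu", "Dy", "Er", "Eu", "Gd", "Ga", "Ge",
    "Au", "Hf", "Ho", "In", "Ir", "Fe", "La", "Pb", "Lu", "Mn", "Hg", "Mo",
    "Nd", "Ni", "Nb", "Os", "Pa", "Pt", "Pr", "Re", "Rh", "Ru", "Sm", "Sc",
    "Ta", "Tc", "Tb", "Tl", "Tm", "Sn", "Ti", "W", "V", "Y", "Zn", "Zr",
    "Pd", "Ag")
}

.config_table <- function() {
  if (is.null(.electrum_env$config)) {
    path <- system.file("extdata", "electron_configurations.tsv",
                        package = "electrum", mustWork = TRUE)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    tab$Z <- as.integer(tab$Z)
    occ <- as.matrix(tab[, .SUBSHELLS])
    storage.mode(occ) <- "integer"
    rownames(occ) <- tab$symbol
    .electrum_env$config <- list(symbols = tab$symbol, Z = tab$Z, occ = occ)
  }
  .electrum_env$config
}

#' Atomic number of an element
#'
#' @param element_symbol Element symbol, e.g. `"Fe"`.
#' @return Integer atomic number.
#' @export
atomic_number <- function(element_symbol) {
  tab <- .config_table()
  i <- match(element_symbol, tab$symbols)
  if (is.na(i)) {
    stop("unsupported element symbol: '", element_symbol, "'", call. = FALSE)
  }
  tab$Z[i]
}

#' Neutral ground-state electron configuration
#'
#' Returns the tabulated neutral-atom ground-state configuration, including
#' the usual aufbau exceptions (Cr, Cu, Nb, Mo, Ru, Rh, Pd, Ag, Pt, Au, ...).
#' Subshells are reported in Madelung filling order 1s, 2s, 2p, ..., 7p.
#'
#' @param element_symbol Element symbol (supported: Z = 1..96).
#' @return An object of class `electron_configuration`: a list with
#'   `element_symbol`, `atomic_number` and `occupancies` (named integer
#'   vector over subshells).
#' @examples
#' ground_state_configuration("Cu")$occupancies[c("3d", "4s")]
#' @export
ground_state_configuration <- function(element_symbol) {
  tab <- .config_table()
  i <- match(element_symbol, tab$symbols)
  if (is.na(i)) {
    stop("unsupported element symbol: '", element_symbol, "'", call. = FALSE)
  }
  structure(list(element_symbol = element_symbol,
                 atomic_number = tab$Z[i],
                 occupancies = setNames(tab$occ[i, ], .SUBSHELLS)),
            class = "electron_configuration")
}

#' @export
print.electron_configuration <- function(x, ...) {
  occ <- x$occupancies[x$occupancies > 0]
  cat(x$element_symbol, " (Z = ", x$atomic_number, "): ",
      paste0(names(occ), occ, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' 86-bit metal electron-configuration encoding
#'
#' Encodes an element's neutral ground-state electron configuration as a
#' binary vector of length 86: one slot per electron over the 15 subshells
#' 1s through 6p in Madelung order, each subshell block filled unarily from
#' its first slot according to the tabulated occupancy. For every element
#' with Z <= 86 the number of set bits equals Z; radon fills the window
#' exactly. Electrons beyond the window (7s/5f/6d, relevant for Z > 86 such
#' as Pa) are dropped with a warning.
#'
#' @param element_symbol Element symbol.
#' @return Integer 0/1 vector of length 86.
#' @examples
#' sum(encode_metal("Fe"))  # 26
#' @export
encode_metal <- function(element_symbol) {
  cfg <- ground_state_configuration(element_symbol)
  occ <- cfg$occupancies
  dropped <- sum(occ[(.N_WINDOW_SUBSHELLS + 1L):length(occ)])
  if (dropped > 0L) {
    warning(sprintf("%s (Z = %d): %d electron(s) beyond the 86-slot window (7s/5f/6d) dropped",
                    element_symbol, cfg$atomic_number, dropped), call. = FALSE)
  }
  bits <- integer(.METAL_BITS)
  offset <- 0L
  for (j in seq_len(.N_WINDOW_SUBSHELLS)) {
    k <- occ[[j]]
    if (k > 0L) bits[offset + seq_len(k)] <- 1L
    offset <- offset + .SUBSHELL_CAP[j]
  }
  bits
}
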