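# Assembly of the full complex fingerprint (folded ligand counts + 86-bit
# metal block) and the two baseline encodings used as controls.

#' Parse a dot-separated component string
#'
#' Splits `"SMILES1.SMILES2.[Metal]"` on dots and classifies each component:
#' a component that parses to a single atom whose element is in `metal_set`
#' is the metal (any position; charge or isotope annotations on it are
#' ignored for encoding, with a notice), everything else is a ligand.
#' Exactly one metal and at least one ligand are required. A metal-set atom
#' embedded in a multi-atom component is a metalloligand and is rejected:
#' only mononuclear complexes are in scope.
#'
#' @param raw Component string, e.g. `"N.N.Cl.Cl.[Pt]"`.
#' @param metal_set Character vector of element symbols treated as complex
#'   centres (default [electrum_metals()]).
#' @return Object of class `complex_input`: list with `raw`, `ligand_smiles`
#'   (character vector) and `metal_symbol`.
#' @export
parse_complex_string <- function(raw, metal_set = electrum_metals()) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("component string must be one non-empty string", call. = FALSE)
  }
  parts <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (any(!nzchar(parts))) {
    stop("SMILES parse error in '", raw, "': empty component", call. = FALSE)
  }
  metal <- character(0)
  ligands <- character(0)
  for (p in parts) {
    mol <- parse_smiles(p)
    is_metal_atom <- mol$atoms$element %in% metal_set
    if (nrow(mol$atoms) == 1L && is_metal_atom) {
      if (mol$atoms$charge != 0L || mol$atoms$hcount != 0L) {
        message("metal component '", p, "': charge/hydrogen annotation ignored for encoding")
      }
      metal <- c(metal, mol$atoms$element)
    } else if (any(is_metal_atom)) {
      stop("metalloligand component '", p,
           "' embeds a metal atom; mononuclear complexes only", call. = FALSE)
    } else {
      ligands <- c(ligands, p)
    }
  }
  if (length(metal) == 0L) {
    stop("missing metal: no single-atom component from the metal set in '", raw, "'",
         call. = FALSE)
  }
  if (length(metal) > 1L) {
    stop("multinuclear complexes unsupported: found metals ",
         paste(metal, collapse = ", "), call. = FALSE)
  }
  if (length(ligands) == 0L) {
    stop("no ligand components in '", raw, "'", call. = FALSE)
  }
  structure(list(raw = raw, ligand_smiles = ligands, metal_symbol = metal),
            class = "complex_input")
}

#' @export
print.complex_input <- function(x, ...) {
  cat("<complex_input> metal ", x$metal_symbol, ", ", length(x$ligand_smiles),
      " ligand(s): ", paste(x$ligand_smiles, collapse = " | "), "\n", sep = "")
  invisible(x)
}

.as_complex_input <- function(input, metal_set = electrum_metals()) {
  if (inherits(input, "complex_input")) input else parse_complex_string(input, metal_set)
}

.ligand_part <- function(input, size, max_radius) {
  counts <- integer(size)
  for (smi in input$ligand_smiles) {
    counts <- counts + .ligand_counts_cached(smi, size, max_radius)
  }
  counts
}

#' Full complex fingerprint: ligands + metal electron configuration
#'
#' The ligand part is the elementwise sum of each ligand's folded circular
#' fingerprint — summation makes the descriptor invariant to ligand order and
#' exactly additive over repeated ligands. The metal part is the 86-bit
#' electron-configuration encoding; at the default ligand size of 512 the
#' combined vector has 598 entries.
#'
#' @param input A component string or a [parse_complex_string()] result.
#' @param size Ligand fingerprint length (default 512).
#' @param max_radius Environment radius in bonds (default 2).
#' @param metal_set Metal symbols accepted as centres.
#' @return Object of class `electrum_fp`: list with `ligand_part` (length
#'   `size`), `metal_part` (length 86), `combined` (length `size + 86`),
#'   `metal_symbol` and `size`.
#' @examples
#' fp <- electrum_fingerprint("N.N.Cl.Cl.[Pt]")
#' length(fp$combined)  # 598
#' @export
electrum_fingerprint <- function(input, size = 512L, max_radius = 2L,
                                 metal_set = electrum_metals()) {
  input <- .as_complex_input(input, metal_set)
  ligand_part <- .ligand_part(input, size, max_radius)
  metal_part <- encode_metal(input$metal_symbol)
  structure(list(ligand_part = ligand_part, metal_part = metal_part,
                 combined = c(ligand_part, metal_part),
                 metal_symbol = input$metal_symbol, size = as.integer(size)),
            class = "electrum_fp")
}

#' @export
print.electrum_fp <- function(x, ...) {
  cat("<electrum_fp> metal ", x$metal_symbol, " (", sum(x$metal_part),
      " electrons encoded), ligand part length ", x$size, " holding ",
      sum(x$ligand_part), " environments; combined length ",
      length(x$combined), "\n", sep = "")
  invisible(x)
}

#' Ligands-only baseline fingerprint
#'
#' The summed ligand count vector with the metal discarded entirely — the
#' metal-blind negative control.
#'
#' @inheritParams electrum_fingerprint
#' @return Integer count vector of length `size`.
#' @export
ligands_only_fingerprint <- function(input, size = 512L, max_radius = 2L,
                                     metal_set = electrum_metals()) {
  input <- .as_complex_input(input, metal_set)
  .ligand_part(input, size, max_radius)
}

#' Atomic-number baseline fingerprint
#'
#' The summed ligand count vector with the metal reduced to a single scalar
#' feature: its (unscaled) atomic number, appended as the trailing entry.
#'
#' @inheritParams electrum_fingerprint
#' @return Numeric vector of length `size + 1`.
#' @export
atomic_fingerprint <- function(input, size = 512L, max_radius = 2L,
                               metal_set = electrum_metals()) {
  input <- .as_complex_input(input, metal_set)
  c(.ligand_part(input, size, max_radius), atomic_number(input$metal_symbol))
}

#' Encode a batch of component strings as a feature matrix
#'
#' @param strings Character vector of component strings.
#' @param variant `"electrum"` (ligands + 86-bit metal block),
#'   `"ligands"` (metal-blind) or `"atomic"` (ligands + atomic number).
#' @inheritParams electrum_fingerprint
#' @param on_error `"stop"` or `"reject"`: with `"reject"`, failing rows are
#'   dropped and reported in the `rejects` attribute (data.frame with `row`,
#'   `input`, `reason`) instead of aborting the batch.
#' @return Numeric matrix, one row per (successfully encoded) complex.
#' @export
fingerprint_matrix <- function(strings, variant = c("electrum", "ligands", "atomic"),
                               size = 512L, max_radius = 2L,
                               metal_set = electrum_metals(),
                               on_error = c("stop", "reject")) {
  variant <- match.arg(variant)
  on_error <- match.arg(on_error)
  fun <- switch(variant,
    electrum = function(s) electrum_fingerprint(s, size, max_radius, metal_set)$combined,
    ligands = function(s) ligands_only_fingerprint(s, size, max_radius, metal_set),
    atomic = function(s) atomic_fingerprint(s, size, max_radius, metal_set))
  rows <- vector("list", length(strings))
  rej_row <- integer(0); rej_in <- character(0); rej_why <- character(0)
  for (i in seq_along(strings)) {
    if (on_error == "stop") {
      rows[[i]] <- fun(strings[i])
    } else {
      rows[[i]] <- tryCatch(fun(strings[i]), error = function(e) {
        rej_row <<- c(rej_row, i); rej_in <<- c(rej_in, strings[i])
        rej_why <<- c(rej_why, conditionMessage(e))
        NULL
      })
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- which(keep)
  attr(mat, "rejects") <- data.frame(row = rej_row, input = rej_in,
                                     reason = rej_why, stringsAsFactors = FALSE)
  mat
}
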