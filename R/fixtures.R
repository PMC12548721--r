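# Synthetic complex generator: assembles mononuclear complexes from a pool
# of small real ligands with declared denticity, emitting both the
# component string (encoder input) and a bonded complex SMILES
# (decomposition input) whose coordination number is the denticity sum by
# construction.

#' Default ligand pool for the synthetic generator
#'
#' Around twenty small, parser-safe real ligands spanning denticities 1-3:
#' halides, aqua, ammine, carbonyl, cyanide, hydroxide, methyl, pyridine,
#' phosphines, acetonitrile, thiocyanate, plus chelates (ethylenediamine,
#' glycolate, an acetylacetonate-like O,O-chelate, 2,2'-bipyridine,
#' diethylenetriamine). `smiles` is the standalone ligand spelling used in
#' component strings; `template` is the same fragment written from its first
#' donor atom with `{r}` markers where secondary donor atoms ring-bond to
#' the metal in the assembled complex SMILES.
#'
#' @return data.frame with columns `name`, `smiles`, `template`, `denticity`.
#' @export
ligand_pool_default <- function() {
  data.frame(
    name = c("aqua", "ammine", "chloro", "bromo", "fluoro", "iodo",
             "carbonyl", "cyanido", "hydroxo", "methyl", "pyridine",
             "phosphine", "trimethylphosphine", "acetonitrile", "thiocyanato",
             "ethylenediamine", "glycolato", "acac", "bipyridine", "dien"),
    smiles = c("O", "N", "Cl", "Br", "F", "I",
               "C#O", "[C-]#N", "[OH-]", "C", "n1ccccc1",
               "P", "P(C)(C)C", "N#CC", "[S-]C#N",
               "NCCN", "OCCO", "OC(C)=CC(C)=O", "n1ccccc1-c2ccccn2",
               "NCCNCCN"),
    template = c("O", "N", "Cl", "Br", "F", "I",
                 "C#O", "[C-]#N", "[OH-]", "C", "n1ccccc1",
                 "P", "P(C)(C)C", "N#CC", "[S-]C#N",
                 "NCCN{r}", "OCCO{r}", "OC(C)=CC(C)=O{r}",
                 "n1ccccc1-c2ccccn2{r}", "NCCN{r}CCN{r}"),
    denticity = c(1L, 1L, 1L, 1L, 1L, 1L,
                  1L, 1L, 1L, 1L, 1L,
                  1L, 1L, 1L, 1L,
                  2L, 2L, 2L, 2L,
                  3L),
    stringsAsFactors = FALSE
  )
}

.COUNTERIONS <- c("[Na+]", "[K+]", "[Cl-]", "[Br-]", "O=S(=O)([O-])[O-]")

.assemble_complex_smiles <- function(metal, templates) {
  ring <- 9L   # ring-closure numbers 10+ (%nn) never collide with templates
  frags <- character(length(templates))
  metal_digits <- ""
  for (i in seq_along(templates)) {
    tpl <- templates[i]
    while (grepl("{r}", tpl, fixed = TRUE)) {
      ring <- ring + 1L
      if (ring > 99L) stop("ring-closure numbers exhausted", call. = FALSE)
      digit <- sprintf("%%%02d", ring)
      tpl <- sub("{r}", digit, tpl, fixed = TRUE)
      metal_digits <- paste0(metal_digits, digit)
    }
    frags[i] <- tpl
  }
  paste0("[", metal, "]", metal_digits,
         paste0("(", frags, ")", collapse = ""))
}

#' Generate a synthetic dataset of mononuclear complexes
#'
#' For each record a metal and a target coordination number are sampled,
#' then ligands are drawn from the pool until their denticities sum to the
#' target. Both a component string and a bonded complex SMILES are emitted;
#' secondary donor atoms of chelating ligands bind the metal through
#' ring-closure bonds, so the metal's graph degree equals the denticity sum
#' exactly. Optionally, charge-balancing counterion fragments are appended
#' to the complex SMILES to exercise counterion stripping.
#'
#' @param n Number of complexes.
#' @param metal_set Metal symbols to sample from.
#' @param ligand_pool A pool data.frame as in [ligand_pool_default()].
#' @param cn_range Integer interval of target coordination numbers
#'   (default 2..6).
#' @param seed Integer seed; regeneration is bit-identical.
#' @param counterion_prob Probability of appending a counterion fragment.
#' @return data.frame of class `electrum_dataset` with columns `id`,
#'   `component_string`, `complex_smiles`, `metal`, `cn`; generator
#'   parameters kept as attributes.
#' @export
generate_complexes <- function(n, metal_set = electrum_metals(),
                               ligand_pool = ligand_pool_default(),
                               cn_range = c(2L, 6L), seed = 1L,
                               counterion_prob = 0.3) {
  stopifnot(n >= 0, nrow(ligand_pool) > 0, length(cn_range) == 2L,
            cn_range[1] >= 1L, cn_range[1] <= cn_range[2])
  set.seed(seed)
  comp <- character(n); full <- character(n)
  metal <- character(n); cn <- integer(n)
  for (i in seq_len(n)) {
    m <- sample(metal_set, 1L)
    target <- sample(seq.int(cn_range[1], cn_range[2]), 1L)
    remaining <- target
    rows <- integer(0)
    while (remaining > 0L) {
      cand <- which(ligand_pool$denticity <= remaining)
      if (length(cand) == 0L) {
        stop("coordination number target ", target,
             " unreachable from pool denticities", call. = FALSE)
      }
      pick <- cand[sample.int(length(cand), 1L)]
      rows <- c(rows, pick)
      remaining <- remaining - ligand_pool$denticity[pick]
    }
    comp[i] <- paste(c(ligand_pool$smiles[rows], paste0("[", m, "]")),
                     collapse = ".")
    smi <- .assemble_complex_smiles(m, ligand_pool$template[rows])
    if (stats::runif(1) < counterion_prob) {
      smi <- paste0(smi, ".", sample(.COUNTERIONS, 1L))
    }
    full[i] <- smi; metal[i] <- m; cn[i] <- target
  }
  out <- data.frame(id = seq_len(n), component_string = comp,
                    complex_smiles = full, metal = metal, cn = cn,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "cn_range") <- cn_range
  class(out) <- c("electrum_dataset", "data.frame")
  out
}

#' Attach a classification label with controllable signal
#'
#' `metal_dependent` labels are a deterministic function of the metal
#' identity alone — atomic-number quantile bins over the dataset's metals —
#' so metal-blind features carry no information about them, while the
#' signal varies smoothly with the electron-configuration encoding;
#' `ligand_dependent` labels derive from the ligand composition (quantile
#' bins of the total heavy-atom count) and ignore the metal; `none` draws
#' labels independently at random.
#'
#' @param dataset An `electrum_dataset` (or compatible data.frame with
#'   `component_string` and `metal` columns).
#' @param mode Label mechanism.
#' @param seed Seed for the `none` mode.
#' @param n_classes Number of label classes (default 3).
#' @return The dataset with an added factor column `label`.
#' @export
inject_signal <- function(dataset, mode = c("metal_dependent",
                                            "ligand_dependent", "none"),
                          seed = 1L, n_classes = 3L) {
  mode <- match.arg(mode)
  qbin <- function(v) {
    breaks <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1L)))
    as.integer(cut(v, breaks, include.lowest = TRUE)) - 1L
  }
  lab <- switch(mode,
    metal_dependent = qbin(vapply(dataset$metal, atomic_number, integer(1))),
    ligand_dependent = qbin(vapply(dataset$component_string, function(s) {
      inp <- parse_complex_string(s)
      sum(vapply(inp$ligand_smiles,
                 function(l) nrow(parse_smiles(l)$atoms), integer(1)))
    }, numeric(1))),
    none = { set.seed(seed); sample.int(n_classes, nrow(dataset), replace = TRUE) - 1L }
  )
  dataset$label <- factor(lab)
  dataset
}
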