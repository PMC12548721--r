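# Curation pipeline for full complex SMILES: counterion stripping, metal
# deletion from the molecular graph, ligand SMILES recovery, coordination
# number and metal-ligand bond descriptors.

#' Decompose a full complex SMILES into metal, ligands and coordination number
#'
#' The string is parsed without valence sanitization. Disconnected fragments
#' that do not contain the metal are dropped as counterions (recorded in the
#' result and reported via a message). The metal atom is then deleted from
#' the molecular graph; every remaining connected component of its fragment
#' becomes one ligand SMILES. The coordination number is the number of
#' metal-incident bonds — a ligand bound through several atoms (chelate or
#' polyhapto) contributes one per bond. Bond order labels of the deleted
#' bonds are recorded per ligand but never consumed by the fingerprint.
#'
#' @param complex_smiles SMILES of the full complex (counterion fragments
#'   allowed as dot-separated components).
#' @param metal_set Metal symbols accepted as centres.
#' @param provenance_id Optional source identifier carried through.
#' @return Object of class `complex_record`: list with `metal_symbol`,
#'   `ligand_smiles`, `coordination_number`, `bond_descriptors` (data.frame
#'   `ligand`, `order`), `counterions`, `n_heavy` (heavy atoms of the
#'   metal-containing fragment) and `provenance_id`.
#' @examples
#' decompose_complex("N[Pt](N)(Cl)Cl")$coordination_number  # 4
#' @export
decompose_complex <- function(complex_smiles, metal_set = electrum_metals(),
                              provenance_id = NULL) {
  mol <- parse_smiles(complex_smiles)
  metal_idx <- which(mol$atoms$element %in% metal_set)
  if (length(metal_idx) == 0L) {
    stop("missing metal: no atom from the metal set in '", complex_smiles, "'",
         call. = FALSE)
  }
  if (length(metal_idx) > 1L) {
    stop("multinuclear complexes unsupported: found ",
         paste(mol$atoms$element[metal_idx], collapse = ", "), " in '",
         complex_smiles, "'", call. = FALSE)
  }
  metal_comp <- mol$atoms$component[metal_idx]

  counterions <- character(0)
  other <- setdiff(unique(mol$atoms$component), metal_comp)
  for (cp in other) {
    frag <- .mol_subset(mol, which(mol$atoms$component == cp))
    counterions <- c(counterions, write_smiles(frag))
  }
  if (length(counterions) > 0) {
    message("dropped ", length(counterions), " counterion/solvent fragment(s): ",
            paste(counterions, collapse = ", "))
  }

  frag_idx <- which(mol$atoms$component == metal_comp)
  incident <- which(mol$bonds$a1 == metal_idx | mol$bonds$a2 == metal_idx)
  cn <- length(incident)
  donor <- ifelse(mol$bonds$a1[incident] == metal_idx,
                  mol$bonds$a2[incident], mol$bonds$a1[incident])
  donor_order <- mol$bonds$order[incident]

  keep <- setdiff(frag_idx, metal_idx)
  ligand_smiles <- character(0)
  bond_ligand <- integer(0)
  if (length(keep) > 0) {
    sub <- .mol_subset(mol, keep)
    remap <- integer(nrow(mol$atoms)); remap[sort(keep)] <- seq_along(keep)
    for (cp in sort(unique(sub$atoms$component))) {
      members <- which(sub$atoms$component == cp)
      ligand_smiles <- c(ligand_smiles, write_smiles(.mol_subset(sub, members)))
    }
    bond_ligand <- sub$atoms$component[remap[donor]]
  }

  structure(list(
    metal_symbol = mol$atoms$element[metal_idx],
    ligand_smiles = ligand_smiles,
    coordination_number = cn,
    bond_descriptors = data.frame(ligand = bond_ligand, order = donor_order,
                                  stringsAsFactors = FALSE),
    counterions = counterions,
    n_heavy = length(frag_idx),
    provenance_id = provenance_id
  ), class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat("<complex_record> metal ", x$metal_symbol, ", CN ", x$coordination_number,
      ", ", length(x$ligand_smiles), " ligand(s): ",
      paste(x$ligand_smiles, collapse = " | "), sep = "")
  if (length(x$counterions) > 0) {
    cat("  [", length(x$counterions), " counterion(s) dropped]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Keep only records whose class label has enough support
#'
#' Mirrors the dataset-curation rule of keeping only label classes with at
#' least `min_count` examples (default 1000) so every class can populate all
#' cross-validation folds. Input order is preserved.
#'
#' @param records A data.frame with a label column, or a list/vector of
#'   records paired with a `labels` vector of equal length.
#' @param min_count Minimum class frequency to survive (default 1000).
#' @param labels Label vector when `records` is not a data.frame; otherwise
#'   the name of the label column (default `"label"`).
#' @return The filtered records, same type as the input.
#' @export
filter_by_class_support <- function(records, min_count = 1000L, labels = "label") {
  stopifnot(min_count >= 1L)
  if (is.data.frame(records)) {
    stopifnot(is.character(labels), labels %in% names(records))
    lab <- records[[labels]]
    keep <- lab %in% names(which(table(lab) >= min_count))
    return(records[keep, , drop = FALSE])
  }
  stopifnot(length(labels) == length(records))
  keep <- labels %in% names(which(table(labels) >= min_count))
  records[keep]
}

#' Build the component string of a decomposed complex
#'
#' Dot-joins the ligand SMILES and appends the bracketed metal symbol,
#' yielding the input format of [parse_complex_string()].
#'
#' @param record A `complex_record`.
#' @return A component string, e.g. `"N.N.Cl.Cl.[Pt]"`.
#' @export
complex_to_component_string <- function(record) {
  stopifnot(inherits(record, "complex_record"))
  paste(c(record$ligand_smiles, paste0("[", record$metal_symbol, "]")),
        collapse = ".")
}
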