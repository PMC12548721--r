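# Circular-substructure hashing and folding for single ligands.
#
# Identifiers follow the Morgan/ECFP iteration: a seed invariant per atom,
# then per-radius updates that hash the sorted (bond, neighbor-identifier)
# multiset, so the result is independent of input atom ordering. The
# concrete integer hash is pinned here (see .ELECTRUM_HASH_VERSION):
# fingerprints are comparable only within one hash version.

.ELECTRUM_HASH_VERSION <- "1"
.HASH_MOD <- 2147483647   # 2^31 - 1; identifiers stay exact in doubles
.HASH_MULT <- 1000003

# order-sensitive polynomial hash of a non-negative integer vector
.hash_vec <- function(x) {
  h <- 17
  for (v in x) h <- (h * .HASH_MULT + (v %% .HASH_MOD)) %% .HASH_MOD
  h
}

.BOND_CODE <- c(single = 1, double = 2, triple = 3, quadruple = 4, aromatic = 5)

#' Enumerate hashed circular atom environments of a ligand
#'
#' For every heavy atom one identifier is emitted at radius 0 (hash of the
#' atom invariants: element, degree, formal charge, attached-hydrogen count,
#' ring membership, aromaticity) and one per larger radius at which the
#' environment still grows, i.e. at which some atom sits at exactly that
#' bond distance. Identifiers at radius r hash the radius, the atom's
#' identifier at r-1 and the sorted (bond, neighbor identifier) pairs, so
#' they depend only on the environment's structure, never on atom order.
#'
#' @param ligand_smiles SMILES of one ligand (or an `electrum_mol`).
#' @param max_radius Maximum environment radius in bonds (default 2).
#' @return data.frame with columns `atom`, `radius`, `identifier`.
#' @examples
#' nrow(enumerate_environments("c1ccccc1"))  # 18: six atoms x radii 0,1,2
#' @export
enumerate_environments <- function(ligand_smiles, max_radius = 2L) {
  stopifnot(max_radius >= 0L)
  mol <- if (inherits(ligand_smiles, "electrum_mol")) ligand_smiles else parse_smiles(ligand_smiles)
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  ids <- vapply(seq_len(n), function(a) {
    .hash_vec(c(mol$atoms$Z[a], mol$atoms$degree[a], mol$atoms$charge[a] + 16L,
                mol$atoms$hcount[a], as.integer(mol$atoms$in_ring[a]),
                as.integer(mol$atoms$aromatic[a])))
  }, numeric(1))

  # BFS eccentricity (capped) decides up to which radius each environment grows
  ecc <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L; queue <- s
    while (length(queue) > 0 && dist[queue[1]] < max_radius) {
      a <- queue[1]; queue <- queue[-1]
      nb <- if (is.null(adj[[a]])) integer(0) else adj[[a]][, 1]
      fresh <- nb[dist[nb] < 0L]
      dist[fresh] <- dist[a] + 1L
      queue <- c(queue, fresh)
    }
    ecc[s] <- max(dist)
  }

  out_atom <- seq_len(n); out_radius <- rep(0L, n); out_id <- ids
  prev <- ids
  for (r in seq_len(max_radius)) {
    cur <- numeric(n)
    for (a in seq_len(n)) {
      nbrs <- adj[[a]]
      if (is.null(nbrs)) {
        cur[a] <- .hash_vec(c(r, prev[a]))
        next
      }
      codes <- .BOND_CODE[mol$bonds$order[nbrs[, 2]]]
      nb_ids <- prev[nbrs[, 1]]
      o <- order(codes, nb_ids)
      cur[a] <- .hash_vec(c(r, prev[a], as.vector(rbind(codes[o], nb_ids[o]))))
    }
    grew <- which(ecc >= r)
    out_atom <- c(out_atom, grew)
    out_radius <- c(out_radius, rep(r, length(grew)))
    out_id <- c(out_id, cur[grew])
    prev <- cur
  }
  data.frame(atom = out_atom, radius = out_radius, identifier = out_id)
}

#' Fold integer identifiers into a fixed-length count vector
#'
#' `counts[i]` is the number of identifiers congruent to `i - 1` modulo
#' `size`; the vector sum always equals the identifier count.
#'
#' @param identifiers Numeric vector of non-negative integer identifiers.
#' @param size Vector length (>= 1).
#' @return Integer count vector of length `size`.
#' @export
fold_identifiers <- function(identifiers, size) {
  stopifnot(length(size) == 1L, size >= 1)
  if (length(identifiers) == 0) return(integer(size))
  if (any(identifiers < 0)) stop("identifiers must be non-negative", call. = FALSE)
  tabulate(identifiers %% size + 1L, nbins = as.integer(size))
}

#' Folded circular-substructure fingerprint of one ligand
#'
#' Enumerates circular environments up to `max_radius` bonds and folds their
#' hashed identifiers modulo `size` into a count vector. Counts (not bits)
#' are retained so that summation over a complex's ligands reflects the
#' cumulative presence of substructures exactly. Stereochemical annotations
#' in the SMILES are ignored: stereoisomeric spellings hash identically.
#'
#' @inheritParams enumerate_environments
#' @param size Fingerprint length; 256, 512 (default) or 1024 in the
#'   benchmark configurations, but any positive length is accepted.
#' @return Object of class `ligand_fp`: list with `counts` (integer vector
#'   of length `size`) and `source_smiles`.
#' @examples
#' sum(ligand_fingerprint("O")$counts)  # 1: a single heavy atom
#' @export
ligand_fingerprint <- function(ligand_smiles, size = 512L, max_radius = 2L) {
  env <- enumerate_environments(ligand_smiles, max_radius)
  smi <- if (inherits(ligand_smiles, "electrum_mol")) ligand_smiles$smiles else ligand_smiles
  structure(list(counts = fold_identifiers(env$identifier, size),
                 source_smiles = smi),
            class = "ligand_fp")
}

#' @export
print.ligand_fp <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("<ligand_fp> '", x$source_smiles, "': length ", length(x$counts),
      ", ", sum(x$counts), " environments in ", nz, " slots\n", sep = "")
  invisible(x)
}

# memoized ligand counts, keyed by (smiles, size, radius); pools of repeated
# ligands dominate batch encoding, so this is the main throughput lever
.ligand_counts_cached <- function(smiles, size, max_radius) {
  key <- paste(smiles, size, max_radius, sep = "\r")
  if (is.null(.electrum_env$fp_cache)) .electrum_env$fp_cache <- new.env(parent = emptyenv())
  hit <- .electrum_env$fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ligand_fingerprint(smiles, size, max_radius)$counts
  .electrum_env$fp_cache[[key]] <- val
  val
}
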