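# Independent oracles used across test files.

# brute-force all-pairs BFS distances on an electrum_mol (no reuse of the
# package's adjacency/eccentricity code paths)
oracle_bfs_distances <- function(mol) {
  n <- nrow(mol$atoms)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (j in seq_len(nrow(mol$bonds))) {
    D[mol$bonds$a1[j], mol$bonds$a2[j]] <- 1
    D[mol$bonds$a2[j], mol$bonds$a1[j]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# expected environment count: one per atom at radius 0 plus one per radius
# r <= max_radius at which some atom sits at exactly distance r
oracle_environment_count <- function(smiles, max_radius = 2L) {
  mol <- parse_smiles(smiles)
  D <- oracle_bfs_distances(mol)
  total <- 0L
  for (a in seq_len(nrow(mol$atoms))) {
    for (r in 0:max_radius) {
      if (r == 0 || any(D[a, ] == r)) total <- total + 1L
    }
  }
  total
}

# heavy-atom count straight off the parser (used for conservation checks)
oracle_heavy_atoms <- function(smiles) nrow(parse_smiles(smiles)$atoms)

# small deterministic fingerprint set for neighbor tests
random_count_matrix <- function(n, d, seed) {
  set.seed(seed)
  matrix(rpois(n * d, lambda = 1.5), nrow = n)
}
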