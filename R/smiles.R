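# Sanitization-free SMILES parsing and writing.
#
# The pipeline must accept organometallic valences that toolkit sanitizers
# reject (e.g. N bonded to Pt plus two hydrogens, bare halide ligands), and
# must survive a lossless round trip through metal deletion. Implicit
# hydrogens on organic-subset atoms are derived from standard default
# valences only; nothing is ever "corrected".

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")
# default valences used for implicit-H perception (smallest value >= bond sum)
.DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)
.BOND_ORDER_NUM <- c(single = 1, double = 2, triple = 3, quadruple = 4, aromatic = 1)

.smiles_error <- function(smiles, msg) {
  stop(sprintf("SMILES parse error in '%s': %s", smiles, msg), call. = FALSE)
}

.parse_bracket <- function(content, smiles) {
  rest <- content
  # isotope (ignored)
  rest <- sub("^[0-9]+", "", rest)
  # element, aromatic lowercase allowed
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|se|as|[bcnops])", rest))
  if (length(m) == 0) .smiles_error(smiles, paste0("no element in bracket [", content, "]"))
  elem_raw <- m
  rest <- substring(rest, nchar(elem_raw) + 1L)
  aromatic <- elem_raw %in% .AROMATIC_ELEMS && elem_raw == tolower(elem_raw)
  element <- if (aromatic) {
    paste0(toupper(substring(elem_raw, 1, 1)), substring(elem_raw, 2))
  } else elem_raw
  # stereo descriptors are parsed and discarded
  rest <- sub("^@{1,2}(TH[12]|AL[12]|SP[1-3]|TB[0-9]{1,2}|OH[0-9]{1,2})?", "", rest)
  hcount <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1) {
    hcount <- if (nchar(hm) == 1) 1L else as.integer(substring(hm, 2))
    rest <- substring(rest, nchar(hm) + 1L)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("^([+-][0-9]+|[+]+|[-]+)", rest))
  if (length(cm) == 1) {
    charge <- if (grepl("[0-9]", cm)) {
      as.integer(cm)
    } else {
      nchar(cm) * (if (substring(cm, 1, 1) == "+") 1L else -1L)
    }
    rest <- substring(rest, nchar(cm) + 1L)
  }
  rest <- sub("^:[0-9]+", "", rest)
  if (nzchar(rest)) .smiles_error(smiles, paste0("unrecognized bracket content [", content, "]"))
  list(element = element, aromatic = aromatic, hcount = hcount, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' A deliberately tolerant parser: no valence sanitization, no aromaticity
#' re-perception, no charge correction. Dot-separated fragments become
#' disconnected components of one graph. Stereochemical annotations
#' (`/`, `\\`, `@`) are accepted and ignored. Implicit hydrogen counts for
#' organic-subset atoms are derived from standard default valences; bracket
#' atoms carry exactly the hydrogen count they declare (default 0).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `electrum_mol`: list with `atoms` (data.frame:
#'   `element`, `Z`, `aromatic`, `charge`, `hcount`, `bracket`, `in_ring`,
#'   `degree`, `component`) and `bonds` (data.frame: `a1`, `a2`, `order`).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("SMILES parse error: input must be one non-empty string", call. = FALSE)
  }
  n <- nchar(smiles)
  elements <- character(0); aromatic <- logical(0); charge <- integer(0)
  hcount <- integer(0); bracket <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- character(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL          # explicit bond symbol awaiting next atom / ring digit
  ring_open <- list()      # digit -> list(atom, bond)
  i <- 1L

  add_atom <- function(element, arom, chg, hc, brk) {
    elements[length(elements) + 1L] <<- element
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hcount[length(hcount) + 1L] <<- hc
    bracket[length(bracket) + 1L] <<- brk
    idx <- length(elements)
    if (!is.na(prev)) {
      ord <- if (!is.null(pending)) pending
             else if (aromatic[prev] && arom) "aromatic" else "single"
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- idx
      bord[length(bord) + 1L] <<- ord
    }
    pending <<- NULL
    prev <<- idx
    idx
  }

  while (i <= n) {
    ch <- substring(smiles, i, i)
    if (ch == "(") {
      if (is.na(prev)) .smiles_error(smiles, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) .smiles_error(smiles, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == ".") {
      if (!is.null(pending)) .smiles_error(smiles, "bond before '.'")
      if (is.na(prev)) .smiles_error(smiles, "empty component")
      prev <- NA_integer_; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- "single"; i <- i + 1L
    } else if (ch == "=") {
      pending <- "double"; i <- i + 1L
    } else if (ch == "#") {
      pending <- "triple"; i <- i + 1L
    } else if (ch == "$") {
      pending <- "quadruple"; i <- i + 1L
    } else if (ch == ":") {
      pending <- "aromatic"; i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        num <- substring(smiles, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", num)) .smiles_error(smiles, "'%' needs two digits")
        i <- i + 3L
      } else {
        num <- ch; i <- i + 1L
      }
      if (is.na(prev)) .smiles_error(smiles, "ring closure with no preceding atom")
      key <- as.character(as.integer(num))
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending)
      } else {
        op <- ring_open[[key]]
        if (op$atom == prev) .smiles_error(smiles, "ring closure to self")
        ord <- if (!is.null(pending)) pending
               else if (!is.null(op$bond)) op$bond
               else if (aromatic[op$atom] && aromatic[prev]) "aromatic" else "single"
        if (!is.null(pending) && !is.null(op$bond) && pending != op$bond) {
          .smiles_error(smiles, paste0("conflicting bond orders on ring closure ", key))
        }
        b1[length(b1) + 1L] <- op$atom; b2[length(b2) + 1L] <- prev
        bord[length(bord) + 1L] <- ord
        ring_open[[key]] <- NULL
      }
      pending <- NULL
    } else if (ch == "[") {
      close <- regexpr("]", substring(smiles, i))
      if (close < 0) .smiles_error(smiles, "unmatched '['")
      info <- .parse_bracket(substring(smiles, i + 1L, i + close - 2L), smiles)
      add_atom(info$element, info$aromatic, info$charge, info$hcount, TRUE)
      i <- i + close
    } else if (grepl("^[A-Z]$", ch)) {
      two <- substring(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, FALSE); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(ch, FALSE, 0L, NA_integer_, FALSE); i <- i + 1L
      } else {
        .smiles_error(smiles, paste0("element '", ch, "' needs brackets"))
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE); i <- i + 1L
    } else {
      .smiles_error(smiles, paste0("unexpected character '", ch, "' at position ", i))
    }
  }
  if (length(stack) > 0) .smiles_error(smiles, "unmatched '('")
  if (length(ring_open) > 0) {
    .smiles_error(smiles, paste0("unclosed ring bond(s): ",
                                 paste(names(ring_open), collapse = ", ")))
  }
  if (length(elements) == 0) .smiles_error(smiles, "no atoms")

  Z <- vapply(elements, function(e) {
    tryCatch(atomic_number(e),
             error = function(err) .smiles_error(smiles, conditionMessage(err)))
  }, integer(1), USE.NAMES = FALSE)

  natom <- length(elements)
  degree <- integer(natom)
  bondsum <- numeric(natom)
  for (j in seq_along(b1)) {
    o <- .BOND_ORDER_NUM[[bord[j]]]
    degree[b1[j]] <- degree[b1[j]] + 1L; degree[b2[j]] <- degree[b2[j]] + 1L
    bondsum[b1[j]] <- bondsum[b1[j]] + o; bondsum[b2[j]] <- bondsum[b2[j]] + o
  }
  # aromatic atoms carry one extra valence unit for the delocalized system
  bondsum <- bondsum + as.numeric(aromatic)
  for (a in seq_len(natom)) {
    if (is.na(hcount[a])) {
      vals <- .DEFAULT_VALENCE[[elements[a]]]
      v <- vals[vals >= bondsum[a]]
      hcount[a] <- if (length(v) == 0) 0L else as.integer(v[1] - bondsum[a])
    }
  }

  mol <- list(
    atoms = data.frame(element = elements, Z = Z, aromatic = aromatic,
                       charge = charge, hcount = hcount, bracket = bracket,
                       degree = degree, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord, stringsAsFactors = FALSE),
    smiles = smiles
  )
  mol$atoms$component <- .mol_components(mol)
  mol$atoms$in_ring <- .mol_ring_atoms(mol)
  class(mol) <- "electrum_mol"
  mol
}

#' @export
print.electrum_mol <- function(x, ...) {
  cat("<electrum_mol> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds, ", max(x$atoms$component), " component(s): ", x$smiles, "\n", sep = "")
  invisible(x)
}

.mol_adjacency <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  for (j in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[j]; b <- mol$bonds$a2[j]
    adj[[a]] <- rbind(adj[[a]], c(b, j))
    adj[[b]] <- rbind(adj[[b]], c(a, j))
  }
  adj
}

.mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      a <- queue[1]; queue <- queue[-1]
      nb <- if (is.null(adj[[a]])) integer(0) else adj[[a]][, 1]
      fresh <- nb[comp[nb] == 0L]
      comp[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  comp
}

# atoms lying on at least one cycle: incident to a non-bridge bond
.mol_ring_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(n))
  adj <- .mol_adjacency(mol)
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nb)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # iterative DFS with explicit stack: (atom, parent-edge, neighbor cursor)
    st_atom <- root; st_edge <- 0L; st_ptr <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(st_atom) > 0) {
      d <- length(st_atom)
      a <- st_atom[d]; pe <- st_edge[d]; ptr <- st_ptr[d]
      nbrs <- adj[[a]]
      if (is.null(nbrs) || ptr > nrow(nbrs)) {
        st_atom <- st_atom[-d]; st_edge <- st_edge[-d]; st_ptr <- st_ptr[-d]
        if (length(st_atom) > 0) {
          p <- st_atom[length(st_atom)]
          low[p] <- min(low[p], low[a])
          if (low[a] > disc[p]) is_bridge[pe] <- TRUE
        }
        next
      }
      st_ptr[d] <- ptr + 1L
      b <- nbrs[ptr, 1]; e <- nbrs[ptr, 2]
      if (e == pe) next
      if (disc[b] != 0L) {
        low[a] <- min(low[a], disc[b])
      } else {
        timer <- timer + 1L; disc[b] <- low[b] <- timer
        st_atom <- c(st_atom, b); st_edge <- c(st_edge, e); st_ptr <- c(st_ptr, 1L)
      }
    }
  }
  in_ring <- logical(n)
  keep <- which(!is_bridge)
  in_ring[mol$bonds$a1[keep]] <- TRUE
  in_ring[mol$bonds$a2[keep]] <- TRUE
  in_ring
}

# subgraph on a set of atom indices, reindexed
.mol_subset <- function(mol, idx) {
  idx <- sort(idx)
  remap <- integer(nrow(mol$atoms)); remap[idx] <- seq_along(idx)
  keep <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
  sub <- list(
    atoms = mol$atoms[idx, , drop = FALSE],
    bonds = data.frame(a1 = remap[mol$bonds$a1[keep]],
                       a2 = remap[mol$bonds$a2[keep]],
                       order = mol$bonds$order[keep], stringsAsFactors = FALSE),
    smiles = NA_character_
  )
  rownames(sub$atoms) <- NULL
  sub$atoms$degree <- tabulate(c(sub$bonds$a1, sub$bonds$a2), nbins = nrow(sub$atoms))
  sub$atoms$component <- .mol_components(sub)
  sub$atoms$in_ring <- .mol_ring_atoms(sub)
  class(sub) <- "electrum_mol"
  sub
}

.bond_symbol <- function(order, arom1, arom2) {
  switch(order,
    single = if (arom1 && arom2) "-" else "",
    aromatic = if (arom1 && arom2) "" else ":",
    double = "=", triple = "#", quadruple = "$",
    stop("unknown bond order: ", order))
}

.atom_token <- function(atoms, a) {
  el <- atoms$element[a]
  sym <- if (atoms$aromatic[a]) tolower(el) else el
  if (!atoms$bracket[a] && atoms$charge[a] == 0L && el %in% .ORGANIC_SUBSET) {
    return(sym)
  }
  h <- atoms$hcount[a]
  hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- atoms$charge[a]
  cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
        else sprintf("%+d", ch)
  paste0("[", sym, hs, cs, "]")
}

#' Write a molecular graph back to SMILES
#'
#' Emits one dot-separated fragment per connected component. Organic-subset
#' atoms without charge that entered as bare symbols are written bare, so
#' their hydrogen count is re-derived on re-parsing (the convention used when
#' ligand SMILES are recovered after metal deletion); bracket atoms keep
#' their explicit hydrogen count and charge.
#'
#' @param mol An `electrum_mol`.
#' @param shuffle If `TRUE`, randomize traversal start and neighbor order
#'   (uses the R RNG), producing an alternative spelling of the same graph —
#'   useful for representation-invariance testing.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, shuffle = FALSE) {
  stopifnot(inherits(mol, "electrum_mol"))
  natom <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  # fix a neighbor order per atom (optionally randomized), shared by the
  # tree-classification pre-pass and the emission pass
  order_of <- lapply(adj, function(nbrs) {
    if (is.null(nbrs)) return(NULL)
    if (shuffle && nrow(nbrs) > 1) nbrs[sample(nrow(nbrs)), , drop = FALSE] else nbrs
  })
  comps <- unique(mol$atoms$component)
  starts <- vapply(comps, function(cp) {
    members <- which(mol$atoms$component == cp)
    if (shuffle) members[sample(length(members), 1)] else members[1]
  }, integer(1))

  # pre-pass: DFS classifying tree vs back (ring-closure) edges
  visited <- logical(natom)
  seen_edge <- logical(nrow(mol$bonds))
  tree_edge <- logical(nrow(mol$bonds))
  prepass <- function(a) {
    visited[a] <<- TRUE
    nbrs <- order_of[[a]]
    if (is.null(nbrs)) return(invisible())
    for (r in seq_len(nrow(nbrs))) {
      b <- nbrs[r, 1]; e <- nbrs[r, 2]
      if (seen_edge[e]) next
      seen_edge[e] <<- TRUE
      if (visited[b]) next else { tree_edge[e] <<- TRUE; prepass(b) }
    }
  }
  for (s in starts) prepass(s)
  back_at <- vector("list", natom)   # atom -> incident back-edge indices
  for (e in which(seen_edge & !tree_edge)) {
    a <- mol$bonds$a1[e]; b <- mol$bonds$a2[e]
    back_at[[a]] <- c(back_at[[a]], e); back_at[[b]] <- c(back_at[[b]], e)
  }

  ring_num <- integer(nrow(mol$bonds))
  counter <- 0L
  ring_token <- function(e, a) {
    first <- ring_num[e] == 0L
    if (first) { counter <<- counter + 1L; ring_num[e] <<- counter }
    num <- ring_num[e]
    digit <- if (num < 10) as.character(num) else sprintf("%%%02d", num)
    sym <- if (first) .bond_symbol(mol$bonds$order[e], mol$atoms$aromatic[mol$bonds$a1[e]],
                                   mol$atoms$aromatic[mol$bonds$a2[e]]) else ""
    paste0(sym, digit)
  }

  emit <- function(a) {
    out <- .atom_token(mol$atoms, a)
    for (e in back_at[[a]]) out <- paste0(out, ring_token(e, a))
    nbrs <- order_of[[a]]
    if (!is.null(nbrs)) {
      kids <- list()
      for (r in seq_len(nrow(nbrs))) {
        b <- nbrs[r, 1]; e <- nbrs[r, 2]
        if (tree_edge[e]) {
          tree_edge[e] <<- FALSE   # each tree edge descends once
          sym <- .bond_symbol(mol$bonds$order[e], mol$atoms$aromatic[a],
                              mol$atoms$aromatic[b])
          kids[[length(kids) + 1L]] <- paste0(sym, emit(b))
        }
      }
      if (length(kids) > 0) {
        if (length(kids) > 1) {
          out <- paste0(out, paste0("(", unlist(kids[-length(kids)]), ")", collapse = ""))
        }
        out <- paste0(out, kids[[length(kids)]])
      }
    }
    out
  }

  paste(vapply(starts, emit, character(1)), collapse = ".")
}
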