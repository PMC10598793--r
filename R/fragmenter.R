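# Molecule breakdown: ring fragments (RFs) and acyclic fragments (AFs).
#
# RF rule: break all bonds between any two acyclic atoms and remove all
# acyclic atoms not directly attached to a ring; an acyclic atom directly
# bonded to ring atoms of more than one ring system is disconnected and
# reattached to each ring system separately (it appears in each of those
# RFs). A ring system is a connected component of the subgraph induced by
# the ring atoms, so fused and spiro rings merge, and two rings joined by a
# direct ring-ring bond (biphenyl) stay one system: only acyclic-acyclic
# bonds are ever broken for RFs.
#
# AF rule: break all bonds between cyclic and acyclic atoms and remove all
# cyclic atoms; AFs are the connected components of the acyclic subgraph.
#
# Valences opened by bond breaking are saturated with implicit hydrogens
# when the fragment graph is re-canonicalized.

.mol_graph <- function(mol) {
  list(
    elem = mol$atoms$elem,
    charge = mol$atoms$charge,
    bonds = cbind(mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  )
}

# Atom index sets of the ring systems (components of the ring-atom-induced
# subgraph), in first-atom order.
.ring_systems <- function(mol) {
  ring <- which(mol$atoms$in_ring)
  if (!length(ring)) return(list())
  b <- mol$bonds[mol$bonds$a1 %in% ring & mol$bonds$a2 %in% ring, , drop = FALSE]
  idx <- integer(mol$hac)
  idx[ring] <- seq_along(ring)
  memb <- .component_membership(length(ring), cbind(idx[b$a1], idx[b$a2]))
  unname(lapply(split(ring, memb), identity))
}

# Fragment graphs without canonicalization: list(rf = list of graphs,
# af = list of graphs). Used internally so canonicalization can be batched
# across many molecules.
.fragment_graphs <- function(mol) {
  g <- .mol_graph(mol)
  ring <- mol$atoms$in_ring
  systems <- .ring_systems(mol)
  nbrs <- function(atoms) {
    b <- mol$bonds
    unique(c(b$a2[b$a1 %in% atoms], b$a1[b$a2 %in% atoms]))
  }
  rf <- lapply(systems, function(S) {
    attach <- setdiff(nbrs(S), which(ring))
    keep <- sort(c(S, attach))
    sub <- .subgraph(g, keep)
    # drop any acyclic-acyclic bond that slipped into the induced subgraph
    # (two retained substituent atoms mutually bonded cannot occur for a
    # single system, but an attach atom of this system never keeps bonds to
    # atoms outside keep by construction of .subgraph)
    acyc <- !ring[keep]
    if (nrow(sub$bonds)) {
      dropb <- acyc[sub$bonds[, 1]] & acyc[sub$bonds[, 2]]
      sub$bonds <- sub$bonds[!dropb, , drop = FALSE]
    }
    sub
  })
  acyclic <- which(!ring)
  af <- list()
  if (length(acyclic)) {
    b <- mol$bonds[mol$bonds$a1 %in% acyclic & mol$bonds$a2 %in% acyclic, , drop = FALSE]
    idx <- integer(mol$hac)
    idx[acyclic] <- seq_along(acyclic)
    memb <- .component_membership(length(acyclic), cbind(idx[b$a1], idx[b$a2]))
    af <- unname(lapply(split(acyclic, memb), function(keep) .subgraph(g, sort(keep))))
  }
  list(rf = rf, af = af)
}

.frag_df <- function(kind, graphs) {
  data.frame(
    kind = rep(kind, length(graphs)),
    smiles = .canon_graphs(graphs),
    hac = vapply(graphs, function(g) length(g$elem), integer(1)),
    stringsAsFactors = FALSE
  )
}

.as_mol <- function(x) {
  if (inherits(x, "molfrag_mol")) x else parse_molecule(x)
}

#' Extract ring fragments (RFs) from a molecule
#'
#' One RF per ring system: all ring atoms of the system plus every acyclic
#' atom directly bonded to a ring atom of that system, with original bond
#' orders; cut valences are hydrogen-saturated. An acyclic atom bonded to
#' ring atoms of k distinct ring systems appears in k RFs. Acyclic molecules
#' yield an empty result.
#'
#' @param mol a `molfrag_mol` or a SMILES string.
#' @return data frame with columns `kind` ("RF"), `smiles` (canonical),
#'   `hac`; zero rows for acyclic molecules. Rows are a multiset: identical
#'   RFs from distinct ring systems are repeated.
#' @examples
#' extract_ring_fragments("COc1ccccc1")$smiles  # "Oc1ccccc1"
#' @export
extract_ring_fragments <- function(mol) {
  mol <- .as_mol(mol)
  .frag_df("RF", .fragment_graphs(mol)$rf)
}

#' Extract acyclic fragments (AFs) from a molecule
#'
#' AFs are the connected components of the subgraph induced by the acyclic
#' (non-ring) atoms, with bond orders preserved inside each component and
#' cut valences hydrogen-saturated. Fully cyclic molecules yield an empty
#' result; duplicates are kept (multiset).
#'
#' @inheritParams extract_ring_fragments
#' @return data frame with columns `kind` ("AF"), `smiles`, `hac`.
#' @examples
#' extract_acyclic_fragments("Cc1ccc(C)cc1")$smiles  # "C", "C"
#' @export
extract_acyclic_fragments <- function(mol) {
  mol <- .as_mol(mol)
  .frag_df("AF", .fragment_graphs(mol)$af)
}

#' Fragment a molecule into RFs and AFs
#'
#' @inheritParams extract_ring_fragments
#' @return list with elements `rf` and `af`, each a fragment data frame as
#'   returned by [extract_ring_fragments()] / [extract_acyclic_fragments()].
#' @examples
#' fragment_molecule("COc1ccccc1")
#' @export
fragment_molecule <- function(mol) {
  mol <- .as_mol(mol)
  fg <- .fragment_graphs(mol)
  list(rf = .frag_df("RF", fg$rf), af = .frag_df("AF", fg$af))
}

#' Fragment a collection of molecules
#'
#' Batch fragmentation with a single canonicalization pass; much faster than
#' calling [fragment_molecule()] per molecule on large collections.
#'
#' @param x character vector of SMILES, a list of `molfrag_mol` objects, or
#'   the result of [parse_molecules()].
#' @param ids optional molecule identifiers (recycled from names or index).
#' @return data frame with columns `molecule_id`, `molecule` (canonical
#'   SMILES), `kind`, `smiles`, `hac`; attribute `skipped` carries the number
#'   of unparsable input records.
#' @export
fragment_collection <- function(x, ids = NULL) {
  skipped <- 0L
  if (is.character(x)) {
    if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
    ok <- nzchar(trimws(x)) & !startsWith(trimws(x), "#")
    ids <- ids[ok]
    mols <- parse_molecules(x)
    skipped <- attr(mols, "skipped")
    if (length(mols) != length(ids)) {
      # recover id alignment by reparsing record-wise on the rare skip path
      src <- trimws(x)[ok]
      keep <- vapply(src, function(s) {
        !is.null(tryCatch(.parse_one(s), molfrag_parse_error = function(e) NULL))
      }, logical(1))
      ids <- ids[keep]
    }
  } else {
    mols <- x
    if (is.null(ids)) ids <- as.character(seq_along(mols))
  }
  fgs <- lapply(mols, .fragment_graphs)
  counts <- vapply(fgs, function(f) c(length(f$rf), length(f$af)), integer(2))
  all_graphs <- unlist(lapply(fgs, function(f) c(f$rf, f$af)), recursive = FALSE)
  smi <- .canon_graphs(all_graphs)
  hac <- vapply(all_graphs, function(g) length(g$elem), integer(1))
  per_mol <- colSums(counts)
  out <- data.frame(
    molecule_id = rep(rep(ids, per_mol), times = 1),
    molecule = rep(vapply(mols, `[[`, character(1), "canonical_smiles"), per_mol),
    kind = unlist(lapply(seq_along(fgs), function(i) {
      c(rep("RF", counts[1, i]), rep("AF", counts[2, i]))
    })),
    smiles = smi,
    hac = hac,
    stringsAsFactors = FALSE
  )
  structure(out, skipped = skipped)
}

# ---- ring statistics --------------------------------------------------------

# Smallest-set-of-smallest-rings sizes by Horton's minimum cycle basis:
# shortest-path candidate cycles through every (vertex, edge) pair, sorted by
# length, kept greedily while linearly independent over GF(2) on the edge
# space, until the cyclomatic number is reached.
.sssr_sizes <- function(na, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(integer(0))
  memb <- .component_membership(na, bonds)
  m <- nb - na + length(unique(memb))
  if (m == 0) return(integer(0))
  adj <- lapply(seq_len(na), function(i) integer(0))
  for (k in seq_len(nb)) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  edge_id <- new.env(hash = TRUE)
  for (k in seq_len(nb)) {
    assign(paste(min(bonds[k, 1:2]), max(bonds[k, 1:2])), k, envir = edge_id)
  }
  eid <- function(a, b) get(paste(min(a, b), max(a, b)), envir = edge_id)
  cand <- list(); clen <- integer(0)
  for (v in seq_len(na)) {
    # BFS tree from v
    dist <- rep(NA_integer_, na); par <- integer(na)
    dist[v] <- 0L; q <- v
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (w in adj[[u]]) if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L; par[w] <- u; q <- c(q, w)
      }
    }
    path <- function(x) { p <- x; while (x != v) { x <- par[x]; p <- c(p, x) }; p }
    for (k in seq_len(nb)) {
      x <- bonds[k, 1]; y <- bonds[k, 2]
      if (is.na(dist[x]) || is.na(dist[y])) next
      if (par[x] == y || par[y] == x) next  # BFS-tree edge: no cycle
      px <- path(x); py <- path(y)
      # paths must meet only at v for a simple candidate cycle
      if (length(intersect(px, py)) != 1L) next
      ev <- logical(nb)
      walk <- c(px, rev(py)[-1])
      for (i in seq_len(length(walk) - 1)) ev[eid(walk[i], walk[i + 1])] <- TRUE
      ev[k] <- TRUE
      cand[[length(cand) + 1]] <- ev
      clen <- c(clen, sum(ev))
    }
  }
  if (!length(cand)) return(integer(0))
  ord <- order(clen)
  basis <- list(); sizes <- integer(0)
  pivots <- integer(0)
  for (i in ord) {
    v <- cand[[i]]
    red <- v
    for (j in seq_along(basis)) {
      if (red[pivots[j]]) red <- xor(red, basis[[j]])
    }
    if (any(red)) {
      basis[[length(basis) + 1]] <- red
      pivots <- c(pivots, which(red)[1])
      sizes <- c(sizes, sum(v))
      if (length(sizes) == m) break
    }
  }
  sizes
}

#' Structural profile of a ring fragment
#'
#' Computes, per RF: the number of rings (cyclomatic number), the largest
#' ring size over a smallest-set-of-smallest-rings decomposition, the number
#' of acyclic atoms (the retained ring-adjacent substituent atoms), and the
#' number of heteroatoms (non-carbon heavy atoms).
#'
#' @param smiles character vector of RF SMILES (or a single `molfrag_mol`).
#' @param scores if `TRUE`, append `sa_score` and `np_score` columns computed
#'   by [fragment_scores()] (requires a Python with RDKit, see that help page).
#' @return data frame with columns `smiles`, `n_rings`, `largest_ring_size`,
#'   `n_acyclic_atoms`, `n_heteroatoms` (plus scores when requested).
#' @examples
#' rf_profile("Cc1ccccc1")
#' @export
rf_profile <- function(smiles, scores = FALSE) {
  mols <- if (inherits(smiles, "molfrag_mol")) list(smiles) else lapply(smiles, parse_molecule)
  rows <- lapply(mols, function(mol) {
    if (!any(mol$atoms$in_ring)) {
      .usage_error(paste0("not a ring fragment (no ring atoms): ", mol$canonical_smiles))
    }
    bonds <- cbind(mol$bonds$a1, mol$bonds$a2)
    data.frame(
      smiles = mol$canonical_smiles,
      n_rings = nrow(mol$bonds) - mol$hac + length(unique(.component_membership(mol$hac, bonds))),
      largest_ring_size = max(.sssr_sizes(mol$hac, bonds)),
      n_acyclic_atoms = sum(!mol$atoms$in_ring),
      n_heteroatoms = sum(mol$atoms$elem != "C"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (scores) out <- cbind(out, fragment_scores(out$smiles)[, c("sa_score", "np_score")])
  out
}

#' Structural profile of an acyclic fragment
#'
#' Computes, per AF: the number of quaternary centers (carbon atoms with four
#' heavy-atom neighbors), triple bonds, heteroatoms, and terminal atoms
#' (heavy atoms with at most one heavy neighbor; a lone atom counts as one
#' terminal atom).
#'
#' @inheritParams rf_profile
#' @return data frame with columns `smiles`, `n_quaternary`, `n_triple_bonds`,
#'   `n_heteroatoms`, `n_terminal_atoms` (plus scores when requested).
#' @examples
#' af_profile("C#N")
#' @export
af_profile <- function(smiles, scores = FALSE) {
  mols <- if (inherits(smiles, "molfrag_mol")) list(smiles) else lapply(smiles, parse_molecule)
  rows <- lapply(mols, function(mol) {
    if (any(mol$atoms$in_ring)) {
      .usage_error(paste0("not an acyclic fragment (has ring atoms): ", mol$canonical_smiles))
    }
    data.frame(
      smiles = mol$canonical_smiles,
      n_quaternary = sum(mol$atoms$elem == "C" & mol$atoms$heavy_nbrs == 4L),
      n_triple_bonds = sum(mol$bonds$order == 3L),
      n_heteroatoms = sum(mol$atoms$elem != "C"),
      n_terminal_atoms = sum(mol$atoms$heavy_nbrs <= 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (scores) out <- cbind(out, fragment_scores(out$smiles)[, c("sa_score", "np_score")])
  out
}
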