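# Independent brute-force fragmentation oracle.
#
# Classifies ring atoms by a per-edge connectivity test (an edge lies on a
# cycle iff its endpoints stay connected after removing it) using a
# hand-rolled BFS, and computes ring systems / acyclic components by direct
# set traversal. No igraph, no sharing of the package's fragmentation code;
# only the molfile emission + OpenBabel canonicalization plumbing is reused
# for fragment identity.

oracle_bfs_reachable <- function(n, edges, from, to, drop_edge = 0L) {
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (k in seq_len(nrow(edges))) {
      if (k == drop_edge) next
      a <- edges[k, 1]; b <- edges[k, 2]
      v <- if (a == u) b else if (b == u) a else next
      if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
    }
  }
  seen[to]
}

oracle_ring_atoms <- function(mol) {
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  ring <- logical(mol$hac)
  for (k in seq_len(nrow(edges))) {
    if (oracle_bfs_reachable(mol$hac, edges, edges[k, 1], edges[k, 2], drop_edge = k)) {
      ring[edges[k, ]] <- TRUE
    }
  }
  ring
}

# connected components of the subgraph induced by `atoms`, as a list of
# atom-index vectors (deterministic order)
oracle_components <- function(atoms, edges) {
  comps <- list()
  left <- atoms
  while (length(left)) {
    seen <- left[1]
    queue <- left[1]
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(edges))) {
        a <- edges[k, 1]; b <- edges[k, 2]
        v <- if (a == u) b else if (b == u) a else next
        if (v %in% atoms && !(v %in% seen)) { seen <- c(seen, v); queue <- c(queue, v) }
      }
    }
    comps[[length(comps) + 1]] <- sort(seen)
    left <- setdiff(left, seen)
  }
  comps
}

# Brute-force RF/AF extraction; returns list(rf = character, af = character)
# of canonical SMILES multisets (sorted).
oracle_fragment <- function(mol) {
  if (is.character(mol)) mol <- molfrag::parse_molecule(mol)
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  ring <- oracle_ring_atoms(mol)
  g <- list(elem = mol$atoms$elem, charge = mol$atoms$charge,
            bonds = cbind(mol$bonds$a1, mol$bonds$a2, mol$bonds$order))
  ring_edges <- edges[ring[edges[, 1]] & ring[edges[, 2]], , drop = FALSE]
  systems <- oracle_components(which(ring), ring_edges)
  rf <- lapply(systems, function(S) {
    adj <- unique(c(edges[edges[, 1] %in% S, 2], edges[edges[, 2] %in% S, 1]))
    attach <- setdiff(adj[!ring[adj]], S)
    keep <- sort(c(S, attach))
    sub <- molfrag:::.subgraph(g, keep)
    acyc <- !ring[keep]
    if (nrow(sub$bonds)) {
      sub$bonds <- sub$bonds[!(acyc[sub$bonds[, 1]] & acyc[sub$bonds[, 2]]), , drop = FALSE]
    }
    sub
  })
  af <- lapply(oracle_components(which(!ring), edges[!ring[edges[, 1]] & !ring[edges[, 2]], , drop = FALSE]),
               function(keep) molfrag:::.subgraph(g, keep))
  list(
    rf = sort(molfrag:::.canon_graphs(rf)),
    af = sort(molfrag:::.canon_graphs(af))
  )
}

# independent SMILES heavy-atom token counter (no molecular parsing):
# bracket atoms count once; organic-subset symbols counted by regex
oracle_smiles_atom_count <- function(smiles) {
  n_bracket <- length(gregexpr("\\[[^]]*\\]", smiles)[[1]])
  if (regexpr("\\[", smiles) < 0) n_bracket <- 0
  rest <- gsub("\\[[^]]*\\]", "", smiles)
  toks <- gregexpr("Cl|Br|[BCNOSPFI]|[bcnops]", rest)[[1]]
  n_org <- if (toks[1] < 0) 0 else length(toks)
  n_bracket + n_org
}
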