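# MinHashed atom-pair fingerprints (MAP4-style) and Jaccard-distance
# screening.
#
# Shingle grammar (documented, package-defined): for every unordered pair of
# heavy atoms (i, j) and every radius r in `radii`, one token
#     envR(i) | d | envR(j)
# where d is the topological (bond count) distance between i and j, envR is
# a canonical serialization of the circular atom environment of radius r
# (sorted neighbor expansion, so it is invariant under input atom order),
# and the two environment strings are ordered lexicographically inside the
# token. Radii {1, 2} correspond to substructure diameters of two and four
# bonds. A single-atom fragment emits its environment tokens paired with
# itself at distance 0. Distances are not capped.
#
# The MinHash uses a 32-bit FNV-1a base hash of the token followed by 256
# universal-hash permutations h_i(x) = (a_i x + b_i) mod (2^31 - 1) with
# (a_i, b_i) drawn from a Park-Miller generator seeded by `seed`; the
# signature stores the 256 minima.

.atom_descriptor <- function(mol) {
  paste0(
    mol$atoms$elem,
    ifelse(mol$atoms$charge == 0, "", sprintf("%+d", mol$atoms$charge)),
    ifelse(mol$atoms$aromatic, "a", ifelse(mol$atoms$in_ring, "r", "-"))
  )
}

.adj_list <- function(mol) {
  adj <- rep(list(integer(0)), mol$hac)
  ords <- rep(list(integer(0)), mol$hac)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
    adj[[a]] <- c(adj[[a]], b); ords[[a]] <- c(ords[[a]], o)
    adj[[b]] <- c(adj[[b]], a); ords[[b]] <- c(ords[[b]], o)
  }
  list(adj = adj, ord = ords)
}

# canonical environment string of radius r around atom i
.env_string <- function(i, r, d0, al, from = 0L) {
  if (r == 0L) return(d0[i])
  nb <- al$adj[[i]]; oo <- al$ord[[i]]
  keep <- nb != from
  nb <- nb[keep]; oo <- oo[keep]
  if (!length(nb)) return(d0[i])
  kids <- vapply(seq_along(nb), function(k) {
    paste0(oo[k], .env_string(nb[k], r - 1L, d0, al, from = i))
  }, character(1))
  paste0(d0[i], "(", paste(sort(kids), collapse = ","), ")")
}

#' Atom-pair shingle set of a fragment
#'
#' Tokenizes a molecule or fragment into the atom-pair shingles used by the
#' MinHash fingerprint (see the package vignette for the token grammar).
#'
#' @param mol a `molfrag_mol` or SMILES string.
#' @param radii integer radii of the circular environments (default `c(1, 2)`,
#'   i.e. substructure diameters up to four bonds).
#' @return character vector (a set: no duplicates) of shingle tokens.
#' @export
atom_pair_shingles <- function(mol, radii = c(1L, 2L)) {
  mol <- .as_mol(mol)
  d0 <- .atom_descriptor(mol)
  al <- .adj_list(mol)
  envs <- lapply(radii, function(r) {
    vapply(seq_len(mol$hac), .env_string, character(1), r = as.integer(r), d0 = d0, al = al)
  })
  if (mol$hac == 1L) {
    toks <- vapply(seq_along(radii), function(k) {
      paste(envs[[k]][1], 0L, envs[[k]][1], sep = "|")
    }, character(1))
    return(unique(toks))
  }
  if (nrow(mol$bonds)) {
    g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2), directed = FALSE)
    if (igraph::vcount(g) < mol$hac) g <- igraph::add_vertices(g, mol$hac - igraph::vcount(g))
    dmat <- igraph::distances(g)
  } else {
    dmat <- matrix(Inf, mol$hac, mol$hac); diag(dmat) <- 0
  }
  toks <- character(0)
  pairs <- utils::combn(mol$hac, 2)
  for (k in seq_along(radii)) {
    e <- envs[[k]]
    ea <- e[pairs[1, ]]; eb <- e[pairs[2, ]]
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    d <- dmat[cbind(pairs[1, ], pairs[2, ])]
    toks <- c(toks, paste(lo, ifelse(is.finite(d), d, "x"), hi, sep = "|"))
  }
  unique(toks)
}

# ---- hashing ----------------------------------------------------------------

.P31 <- 2147483647  # 2^31 - 1

# exact (a * b) mod (2^31 - 1) for 0 <= a, b < 2^31, in doubles
.mulmod31 <- function(a, b) {
  ah <- a %/% 32768; al <- a %% 32768
  (((ah * b) %% .P31) * 32768 + al * b) %% .P31
}

# 32-bit FNV-1a over the UTF-8 bytes of each string
.fnv1a <- function(strings) {
  vapply(strings, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- .xor32(h, b %% 256)
      h <- .mul32(h, 16777619)
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.xor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; map doubles in [0, 2^32) safely
  ai <- as.integer(a %% 65536); ah <- as.integer(a %/% 65536)
  bi <- as.integer(b %% 65536); bh <- as.integer(b %/% 65536)
  bitwXor(ah, bh) * 65536 + bitwXor(ai, bi)
}

.mul32 <- function(a, p) {
  # (a * p) mod 2^32 with p < 2^25
  ah <- a %/% 65536; al <- a %% 65536
  (((ah * p) %% 65536) * 65536 + al * p) %% 4294967296
}

# Park-Miller sequence for permutation parameters, decoupled from R's RNG
.pm_seq <- function(seed, n) {
  x <- (abs(seed) %% (.P31 - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- .mulmod31(16807, x)
    out[i] <- x
  }
  out
}

.minhash_params <- function(dimensions, seed) {
  s <- .pm_seq(seed, 2 * dimensions)
  list(
    a = (s[seq_len(dimensions)] %% (.P31 - 1)) + 1,
    b = s[dimensions + seq_len(dimensions)] %% .P31
  )
}

#' MinHash signature of a shingle set
#'
#' @param shingles character vector of shingle tokens (non-empty).
#' @param dimensions signature length (default 256).
#' @param seed integer seed pinning the hash family; signatures are only
#'   comparable for equal `dimensions` and `seed`.
#' @return object of class `minhash_signature`: list with `values`
#'   (numeric vector of length `dimensions`), `dimensions`, `seed`.
#' @export
minhash_signature <- function(shingles, dimensions = 256L, seed = 42L) {
  shingles <- unique(as.character(shingles))
  if (!length(shingles)) {
    .usage_error("cannot fingerprint an empty shingle set")
  }
  h0 <- .fnv1a(shingles) %% .P31
  par <- .minhash_params(dimensions, seed)
  vals <- vapply(seq_len(dimensions), function(i) {
    min((.mulmod31(par$a[i], h0) + par$b[i]) %% .P31)
  }, numeric(1))
  structure(list(values = vals, dimensions = as.integer(dimensions),
                 seed = as.integer(seed)),
            class = "minhash_signature")
}

#' @export
print.minhash_signature <- function(x, ...) {
  cat("<minhash_signature> dimensions=", x$dimensions, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Estimated Jaccard distance between MinHash signatures
#'
#' `1 - matching positions / dimensions`; an unbiased estimate of the exact
#' Jaccard distance between the underlying shingle sets.
#'
#' @param a,b `minhash_signature` objects with equal dimensions and seed.
#' @return distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  if (!inherits(a, "minhash_signature") || !inherits(b, "minhash_signature")) {
    .usage_error("jaccard_distance expects minhash_signature objects")
  }
  if (a$dimensions != b$dimensions || a$seed != b$seed) {
    .usage_error("signatures differ in dimensions or seed and are not comparable")
  }
  1 - mean(a$values == b$values)
}

#' Exact Jaccard distance between shingle sets
#'
#' `1 - |A intersect B| / |A union B|`; the oracle against which MinHash
#' estimates are validated.
#'
#' @param a,b character vectors (sets) of shingles.
#' @return distance in \[0, 1\].
#' @export
exact_jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Screen candidates against a reference set by MinHash distance
#'
#' Retains every candidate whose estimated Jaccard distance to at least one
#' reference is `<= d_max`. Deterministic for fixed `seed`.
#'
#' @param candidates,references character vectors of fragment SMILES
#'   (references non-empty).
#' @param d_max distance threshold (default 0.6).
#' @param dimensions,radii,seed fingerprint configuration.
#' @return character vector: the retained candidates, with attribute
#'   `screen`, a data frame (`candidate`, `min_distance`,
#'   `nearest_reference`, `retained`) covering all candidates.
#' @export
screen_within <- function(candidates, references, d_max = 0.6,
                          dimensions = 256L, radii = c(1L, 2L), seed = 42L) {
  if (!length(references)) .usage_error("screen_within needs a non-empty reference set")
  if (!(d_max > 0 && d_max <= 1)) .usage_error("d_max must be in (0, 1]")
  sig <- function(smis) lapply(smis, function(s) {
    minhash_signature(atom_pair_shingles(s, radii), dimensions, seed)
  })
  cs <- sig(candidates)
  rs <- sig(references)
  det <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    d <- vapply(rs, jaccard_distance, numeric(1), a = cs[[i]])
    j <- which.min(d)
    data.frame(candidate = candidates[i], min_distance = d[j],
               nearest_reference = references[j],
               retained = d[j] <= d_max, stringsAsFactors = FALSE)
  }))
  structure(candidates[det$retained], screen = det)
}
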