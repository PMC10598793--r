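test_that("shingle sets are canonical and permutation-invariant", {
  expect_setequal(atom_pair_shingles("CCO"), atom_pair_shingles("OCC"))
  expect_setequal(atom_pair_shingles("c1ccccc1"), atom_pair_shingles("C1=CC=CC=C1"))
  for (smi in c("CC(C)CO", "Cc1ccncc1", "O=C1CCCN1")) {
    m <- parse_molecule(smi)
    g <- molfrag:::.mol_graph(m)
    set.seed(11)
    perm <- sample(m$hac); inv <- order(perm)
    pg <- list(elem = g$elem[perm], charge = g$charge[perm],
               bonds = cbind(inv[g$bonds[, 1]], inv[g$bonds[, 2]], g$bonds[, 3]))
    smi_perm <- trimws(sub("\t.*$", "", molfrag:::.ob_convert(
      "SDF", "SMI", molfrag:::.write_v2000(pg))))
    expect_setequal(atom_pair_shingles(smi), atom_pair_shingles(smi_perm))
  }
  # single-atom fragments are fingerprintable via the self-pair token
  expect_length(atom_pair_shingles("O"), 1L)
  expect_match(atom_pair_shingles("O"), "\\|0\\|")
  expect_false(identical(atom_pair_shingles("O"), atom_pair_shingles("N")))
})

test_that("signatures are deterministic, seeded and length-checked", {
  s <- atom_pair_shingles("Cc1ccccc1")
  sig1 <- minhash_signature(s, seed = 42)
  sig2 <- minhash_signature(s, seed = 42)
  expect_equal(sig1, sig2)
  expect_length(sig1$values, 256L)
  sig3 <- minhash_signature(s, seed = 43)
  expect_false(identical(sig1$values, sig3$values))
  expect_error(minhash_signature(character(0)), class = "molfrag_usage_error")
  expect_error(jaccard_distance(sig1, sig3), class = "molfrag_usage_error")
  expect_error(jaccard_distance(sig1, minhash_signature(s, dimensions = 128)),
               class = "molfrag_usage_error")
})

test_that("matching-position fraction estimates Jaccard similarity (binomial bound)", {
  # token sets constructed with exact Jaccard similarity 0.5
  A <- c(sprintf("shared%02d", 1:20), sprintf("onlyA%02d", 1:10))
  B <- c(sprintf("shared%02d", 1:20), sprintf("onlyB%02d", 1:10))
  expect_equal(exact_jaccard_distance(A, B), 0.5)
  d <- jaccard_distance(minhash_signature(A, seed = 42), minhash_signature(B, seed = 42))
  expect_lt(abs(d - 0.5), 3 * sqrt(0.25 / 256))
})

test_that("exact Jaccard distance arithmetic", {
  expect_equal(exact_jaccard_distance(c("a", "b", "c"), c("a", "b", "c")), 0)
  expect_equal(exact_jaccard_distance(c("a", "b"), c("x", "y")), 1)
  expect_equal(exact_jaccard_distance(c("a", "b", "c"), c("a", "b", "d")), 0.5)
})

test_that("the MinHash estimate tracks the exact distance on fragment pairs", {
  pool <- fixture_fragments()
  set.seed(31)
  n <- 60
  i1 <- sample(length(pool), n, replace = TRUE)
  i2 <- sample(length(pool), n, replace = TRUE)
  shingle_cache <- lapply(pool, atom_pair_shingles)
  err <- vapply(seq_len(n), function(k) {
    a <- shingle_cache[[i1[k]]]; b <- shingle_cache[[i2[k]]]
    est <- jaccard_distance(minhash_signature(a, seed = 42),
                            minhash_signature(b, seed = 42))
    abs(est - exact_jaccard_distance(a, b))
  }, numeric(1))
  expect_lte(mean(err), 3 / sqrt(256))
})

test_that("distance axioms hold at the estimator level", {
  sigs <- lapply(c("Cc1ccccc1", "CCO", "c1ccncc1"), function(s) {
    minhash_signature(atom_pair_shingles(s), seed = 42)
  })
  for (s in sigs) expect_equal(jaccard_distance(s, s), 0)
  expect_equal(jaccard_distance(sigs[[1]], sigs[[2]]),
               jaccard_distance(sigs[[2]], sigs[[1]]))
  # disjoint shingle sets sit near distance 1
  expect_gt(jaccard_distance(sigs[[2]], sigs[[3]]), 0.9)
})

test_that("screening retains candidates near at least one reference", {
  refs <- c("Cc1ccccc1", "CCO")
  cands <- c("Cc1ccccc1", "CCCCCCCC", "c1ccc2ccccc2c1")
  kept <- screen_within(cands, refs, d_max = 0.6, seed = 42)
  expect_true("Cc1ccccc1" %in% kept)  # identical to a reference, distance 0
  det <- attr(kept, "screen")
  expect_equal(det$min_distance[det$candidate == "Cc1ccccc1"], 0)
  # d_max = 1 retains everything
  expect_setequal(screen_within(cands, refs, d_max = 1, seed = 42), cands)
  expect_error(screen_within(cands, character(0)), class = "molfrag_usage_error")
})

test_that("screening results are nested as d_max grows", {
  pool <- fixture_fragments()
  cands <- pool[1:20]
  refs <- pool[21:26]
  kept <- lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(d) {
    screen_within(cands, refs, d_max = d, seed = 42)
  })
  for (k in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[k]] %in% kept[[k + 1]]))
  }
})
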