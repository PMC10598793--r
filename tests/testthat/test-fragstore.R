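test_that("occurrence counts distinct molecules, not fragment copies", {
  # p-xylene carries two methyl AFs but counts once
  idx <- build_fragment_index("Cc1ccc(C)cc1", kind = "AF")
  expect_equal(idx$counts, c(C = 1L))
  idx2 <- build_fragment_index(c("Cc1ccccc1", "COc1ccccc1"), kind = "RF")
  expect_setequal(names(idx2$counts), canonical_key(c("Cc1ccccc1", "Oc1ccccc1")))
  expect_true(all(idx2$counts == 1L))
  empty <- build_fragment_index(character(0), kind = "RF")
  expect_equal(empty$n_molecules, 0L)
  expect_length(empty$counts, 0L)
})

test_that("index invariants hold on a generated library", {
  lib <- generate_library(library_spec(60, seed = 5))
  idx <- build_fragment_index(lib$smiles, kind = "AF")
  expect_true(all(idx$counts >= 1L))
  expect_true(all(idx$counts <= idx$n_molecules))
  # singletons equal a brute-force scan over the per-molecule fragment sets
  fr <- fragment_collection(lib$smiles)
  af <- fr[fr$kind == "AF", ]
  per_mol <- tapply(af$smiles, af$molecule_id, unique)
  scan <- table(unlist(per_mol))
  expect_setequal(singletons(idx), names(scan)[scan == 1])
  # singletons and non-singletons partition the key set
  expect_setequal(c(singletons(idx), names(idx$counts)[idx$counts > 1]),
                  names(idx$counts))
})

test_that("indexes merge additively over disjoint molecule shards", {
  lib <- generate_library(library_spec(80, seed = 9))
  s1 <- lib$smiles[1:40]; s2 <- lib$smiles[41:80]
  whole <- build_fragment_index(lib$smiles, kind = "RF")
  merged <- merge_indexes(build_fragment_index(s1, kind = "RF"),
                          build_fragment_index(s2, kind = "RF"))
  expect_equal(merged$n_molecules, whole$n_molecules)
  expect_equal(merged$counts[sort(names(merged$counts))],
               whole$counts[sort(names(whole$counts))])
  expect_error(merge_indexes(whole, build_fragment_index(s1, kind = "AF")),
               class = "molfrag_usage_error")
})

test_that("exclusives are the set difference against all other collections", {
  mk <- function(counts) structure(list(collection_name = "x", kind = "RF",
                                        counts = counts, hac = counts,
                                        n_molecules = 10L, n_skipped = 0L),
                                   class = "fragment_index")
  t <- mk(c(A = 1L, B = 2L, C = 3L))
  expect_setequal(exclusives(t, list(mk(c(D = 1L)), mk(c(E = 2L)))), c("A", "B", "C"))
  expect_length(exclusives(t, list(mk(c(A = 1L, B = 1L, C = 9L)))), 0L)
  o1 <- mk(c(A = 1L)); o2 <- mk(c(B = 5L, Z = 1L))
  expect_setequal(exclusives(t, list(o1, o2)),
                  setdiff(names(t$counts), c(names(o1$counts), names(o2$counts))))
})

test_that("coverage means every fragment of the kind fits the size bound", {
  # one molecule with a 14-atom RF, one with a 6-atom RF
  big_rf <- "C1CCCCCCCCCCCCC1"  # cyclotetradecane, HAC 14
  expect_equal(coverage(c(big_rf, "c1ccccc1"), "RF", 13), 0.5)
  # vacuous truth: no fragments of the kind counts as covered
  expect_equal(coverage("CCC", "RF", 13), 1)
  expect_equal(coverage("c1ccccc1", "AF", 13), 1)
  # "both" restricts RFs and AFs together
  long_tail <- "CCCCCCCCCCCCCCc1ccccc1"  # AF of 14 atoms
  expect_equal(coverage(c(long_tail, "Cc1ccccc1"), "RF", 13), 1)
  expect_equal(coverage(c(long_tail, "Cc1ccccc1"), "both", 13), 0.5)
  # monotone non-decreasing in max_hac
  smis <- fixture_molecules()[1:40]
  cov <- vapply(3:14, function(h) coverage(smis, "both", h), numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("frequency distribution tabulates occurrence values", {
  mk <- function(counts) structure(list(collection_name = "x", kind = "AF",
                                        counts = counts, hac = counts,
                                        n_molecules = 50L, n_skipped = 0L),
                                   class = "fragment_index")
  fd <- frequency_distribution(mk(c(A = 1L, B = 1L, C = 3L)))
  expect_equal(fd, data.frame(occurrence = c(1L, 3L), n_fragments = c(2L, 1L)))
  expect_equal(nrow(frequency_distribution(mk(setNames(integer(0), character(0))))), 0L)
  # histogram over a generated library sums to the number of keys
  idx <- build_fragment_index(generate_library(library_spec(70, seed = 2))$smiles, "AF")
  fd <- frequency_distribution(idx)
  expect_equal(sum(fd$n_fragments), length(idx$counts))
  expect_equal(fd$n_fragments,
               as.integer(table(idx$counts))[match(fd$occurrence, sort(unique(idx$counts)))])
})

test_that("top fragments rank by count with deterministic tie-breaking", {
  mk <- function(counts) structure(list(collection_name = "x", kind = "AF",
                                        counts = counts, hac = counts,
                                        n_molecules = 50L, n_skipped = 0L),
                                   class = "fragment_index")
  expect_equal(top_fragments(mk(c(A = 2L, B = 9L)), 1), "B")
  expect_equal(top_fragments(mk(c(A = 2L, B = 9L)), 0), character(0))
  expect_equal(top_fragments(mk(c(B = 3L, A = 3L, C = 7L)), 3), c("C", "A", "B"))
  idx <- build_fragment_index(generate_library(library_spec(50, seed = 3))$smiles, "AF")
  full <- top_fragments(idx, length(idx$counts))
  ord <- order(-idx$counts, names(idx$counts), method = "radix")
  expect_equal(full, names(idx$counts)[ord])
})

test_that("size histograms count compounds and unique fragments per HAC", {
  h <- size_histograms("c1ccccc1")
  expect_equal(as.integer(h$compounds["6"]), 1L)
  expect_equal(as.integer(h$rf["6"]), 1L)
  expect_length(h$af, 0L)
  smis <- c("Cc1ccccc1", "CCO")
  h2 <- size_histograms(smis, exclusive_af = "CCO")
  expect_equal(sum(h2$compounds), 2L)
  expect_equal(as.integer(h2$rf["7"]), 1L)
  expect_setequal(names(h2$af), c("1", "3"))
  expect_equal(as.integer(h2$eaf["3"]), 1L)
})

test_that("index TSV serialization round-trips, including gzip", {
  idx <- build_fragment_index(c("Cc1ccccc1", "COc1ccccc1", "CCO"),
                              kind = "AF", collection_name = "toy")
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_fragment_index(idx, path)
    back <- read_fragment_index(path)
    expect_equal(back$collection_name, "toy")
    expect_equal(back$kind, "AF")
    expect_equal(back$n_molecules, idx$n_molecules)
    expect_equal(back$counts, idx$counts)
    unlink(path)
  }
})
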