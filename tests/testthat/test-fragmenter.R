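key <- function(s) molfrag::canonical_key(s)

test_that("worked fragmentation examples follow the breakdown rules", {
  expect_equal(nrow(extract_ring_fragments("CCC")), 0L)
  expect_equal(nrow(extract_acyclic_fragments("c1ccccc1")), 0L)

  expect_equal(extract_ring_fragments("Cc1ccccc1")$smiles, key("Cc1ccccc1"))
  # anisole: O is ring-adjacent and retained; methyl is not
  expect_equal(extract_ring_fragments("COc1ccccc1")$smiles, key("Oc1ccccc1"))
  expect_equal(extract_acyclic_fragments("COc1ccccc1")$smiles, key("CO"))
  # p-xylene: two single-carbon AFs (multiset, not a set)
  expect_equal(extract_acyclic_fragments("Cc1ccc(C)cc1")$smiles, c("C", "C"))
  # exocyclic ketone oxygen severed from the ring carbon
  expect_equal(extract_acyclic_fragments("O=C1CCCCC1")$smiles, "O")
  expect_equal(extract_ring_fragments("O=C1CCCCC1")$smiles, key("O=C1CCCCC1"))
  # whole acyclic molecule is one AF
  expect_equal(extract_acyclic_fragments("CCC")$smiles, "CCC")
})

test_that("bridging acyclic atoms are duplicated into every adjacent ring system", {
  rf <- extract_ring_fragments("C(c1ccccc1)c1ccccc1")
  expect_equal(rf$smiles, rep(key("Cc1ccccc1"), 2))
  expect_equal(extract_acyclic_fragments("C(c1ccccc1)c1ccccc1")$smiles, "C")
  # three-way bridge
  rf3 <- extract_ring_fragments("C(C1CC1)(C1CC1)C1CC1")
  expect_equal(rf3$smiles, rep(key("CC1CC1"), 3))
})

test_that("ring systems merge across fused, spiro and direct ring-ring bonds", {
  expect_equal(nrow(extract_ring_fragments("c1ccc2ccccc2c1")), 1L)   # fused
  expect_equal(nrow(extract_ring_fragments("C1CC2(C1)CCC2")), 1L)    # spiro
  # biphenyl: only acyclic-acyclic bonds are broken, so one RF
  rf <- extract_ring_fragments("c1ccc(-c2ccccc2)cc1")
  expect_equal(rf$smiles, key("c1ccc(-c2ccccc2)cc1"))
  expect_equal(rf$hac, 12L)
})

test_that("gefitinib splits into its three RFs and five AFs", {
  gefitinib <- "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1"
  fr <- fragment_molecule(gefitinib)
  expect_equal(nrow(fr$rf), 3L)
  expect_equal(nrow(fr$af), 5L)
  expect_setequal(fr$rf$smiles, key(c(
    "Nc1ncnc2cc(O)c(O)cc12",  # amino-dioxy-quinazoline
    "Nc1ccc(F)c(Cl)c1",       # amino-fluoro-chloro-benzene
    "CN1CCOCC1"               # N-methyl morpholine
  )))
  expect_setequal(fr$af$smiles, key(c("CO", "OCCC", "N", "F", "Cl")))
  # atom conservation: RF ring atoms partition the parent's ring atoms and
  # AF atoms partition the acyclic atoms
  m <- parse_molecule(gefitinib)
  expect_equal(sum(fr$af$hac), sum(!m$atoms$in_ring))  # 9 acyclic atoms
  # 22 ring atoms + 7 (acyclic atom, adjacent ring system) incidences; the
  # bridging NH is counted once per ring system it touches
  expect_equal(sum(fr$rf$hac), 29L)
})

test_that("atom conservation holds across the fixture set", {
  all_mols <- fixture_molecules()
  for (smi in all_mols[seq(1, length(all_mols), by = 37)]) {
    m <- parse_molecule(smi)
    fr <- fragment_molecule(m)
    # AF multiset of heavy atoms == acyclic heavy atoms of parent
    expect_equal(sum(fr$af$hac), sum(!m$atoms$in_ring), info = smi)
    # each RF contributes its ring system's atoms exactly once, plus one
    # entry per (acyclic atom, adjacent ring system) incidence
    ring <- m$atoms$in_ring
    sys <- molfrag:::.ring_systems(m)
    inc <- 0L
    for (S in sys) {
      b <- m$bonds
      nb <- unique(c(b$a2[b$a1 %in% S], b$a1[b$a2 %in% S]))
      inc <- inc + length(setdiff(nb[!ring[nb]], S))
    }
    expect_equal(sum(fr$rf$hac), sum(ring) + inc, info = smi)
    expect_equal(nrow(fr$rf), length(sys), info = smi)
  }
})

test_that("fragmentation is idempotent on its own fragments", {
  for (smi in c("Cc1ccccc1", "O=C1CCCCC1", "CN1CCOCC1", "Nc1ccc(F)c(Cl)c1")) {
    rf <- extract_ring_fragments(smi)$smiles
    for (f in rf) {
      again <- fragment_molecule(f)
      expect_equal(again$rf$smiles, f)
    }
  }
  for (f in c("CCC", "CO", "C#N", "CC(C)C")) {
    again <- fragment_molecule(f)
    expect_equal(nrow(again$rf), 0L)
    expect_equal(again$af$smiles, canonical_key(f))
  }
})

test_that("batch fragmentation matches per-molecule fragmentation", {
  smis <- fixture_molecules()[1:25]
  batch <- fragment_collection(smis)
  for (i in c(1, 7, 19, 25)) {
    one <- fragment_molecule(smis[i])
    got <- batch[batch$molecule_id == as.character(i), ]
    expect_setequal(got$smiles[got$kind == "RF"], one$rf$smiles)
    expect_equal(sort(got$smiles[got$kind == "AF"]), sort(one$af$smiles))
  }
})

test_that("RF profiles report ring counts, sizes and composition", {
  p <- rf_profile(c("c1ccccc1", "Cc1ccccc1", "CN1CCOCC1"))
  expect_equal(p$n_rings, c(1L, 1L, 1L))
  expect_equal(p$largest_ring_size, c(6L, 6L, 6L))
  expect_equal(p$n_acyclic_atoms, c(0L, 1L, 1L))
  expect_equal(p$n_heteroatoms, c(0L, 0L, 2L))
  # fused/bridged/macrocycle ring sizes over an SSSR decomposition
  p2 <- rf_profile(c("c1ccc2ccccc2c1", "C1CC2CCC1C2", "C1CCCCCCC1", "C12CC3CC(C1)CC(C2)C3"))
  expect_equal(p2$n_rings, c(2L, 2L, 1L, 3L))
  expect_equal(p2$largest_ring_size, c(6L, 5L, 8L, 6L))
  expect_error(rf_profile("CCC"), class = "molfrag_usage_error")
})

test_that("AF profiles count quaternary centers, triples, heteroatoms, terminals", {
  p <- af_profile(c("C#N", "CC(C)(C)C", "OCCC", "C"))
  expect_equal(p$n_quaternary, c(0L, 1L, 0L, 0L))
  expect_equal(p$n_triple_bonds, c(1L, 0L, 0L, 0L))
  expect_equal(p$n_heteroatoms, c(1L, 0L, 1L, 0L))
  expect_equal(p$n_terminal_atoms, c(2L, 4L, 2L, 1L))
  # quaternary center counts heavy neighbors regardless of their element
  expect_equal(af_profile("FC(F)(F)F")$n_quaternary, 1L)
  expect_equal(af_profile("FC(F)F")$n_quaternary, 0L)
  expect_error(af_profile("c1ccccc1"), class = "molfrag_usage_error")
})
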