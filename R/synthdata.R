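# Deterministic generator of toy compound libraries with known ground-truth
# fragment composition, and planted bioactivity enrichment splits.
#
# Molecules are composed from a ring-scaffold alphabet and an acyclic
# substituent alphabet, joined only through single bonds at positions with
# free valence, so the ground-truth fragmentation is unambiguous: the RF of
# a molecule is its scaffold plus the first atom of every substituent, and
# the AFs are the substituents themselves. A "bridge" mode instead joins two
# scaffolds through one acyclic linker atom, which must then appear in both
# RFs (the duplication rule) and as a single-atom AF.

.std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3)

.free_valence <- function(g) {
  used <- numeric(length(g$elem))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      used[g$bonds[k, 1]] <- used[g$bonds[k, 1]] + g$bonds[k, 3]
      used[g$bonds[k, 2]] <- used[g$bonds[k, 2]] + g$bonds[k, 3]
    }
  }
  val <- .std_valence[g$elem]
  val[is.na(val)] <- 0
  pmax(0, val + g$charge * (g$elem %in% c("N", "O", "S", "P")) - used)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# append graph `sub` to `g`, bonding sub atom `at` to g atom `pos`
.attach_graph <- function(g, pos, sub, at = 1L) {
  off <- length(g$elem)
  list(
    elem = c(g$elem, sub$elem),
    charge = c(g$charge, sub$charge),
    bonds = rbind(
      g$bonds,
      if (nrow(sub$bonds)) cbind(sub$bonds[, 1] + off, sub$bonds[, 2] + off, sub$bonds[, 3]),
      c(pos, at + off, 1L)
    )
  )
}

#' Specification of a synthetic compound library
#'
#' @param n_molecules number of molecules to generate (>= 1).
#' @param rf_alphabet ring-scaffold SMILES; every scaffold must be a single
#'   ring system with no acyclic atoms.
#' @param af_alphabet substituent SMILES; every substituent must be fully
#'   acyclic with free valence on its first atom.
#' @param max_substituents maximum substituents attached per molecule
#'   (each molecule draws 0..max, limited by open scaffold positions).
#' @param seed integer seed; generation is deterministic per seed.
#' @param bridge if `TRUE`, every molecule is two scaffolds joined by a
#'   single acyclic carbon linker (exercises the RF duplication rule).
#' @return object of class `library_spec`.
#' @export
library_spec <- function(n_molecules,
                         rf_alphabet = c("C1CC1", "C1CCC1", "C1CCCC1", "c1ccccc1",
                                         "c1ccncc1", "C1CCOC1", "C1CCNC1", "C1CCSC1"),
                         af_alphabet = c("C", "CC", "CCC", "O", "N", "F", "Cl",
                                         "CO", "CCO", "C#N", "CN"),
                         max_substituents = 3L, seed = 1L, bridge = FALSE) {
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    .usage_error("n_molecules must be >= 1")
  }
  if (!length(rf_alphabet) || !length(af_alphabet)) {
    .usage_error("alphabets must be non-empty")
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    rf_alphabet = rf_alphabet,
    af_alphabet = af_alphabet,
    max_substituents = as.integer(max_substituents),
    seed = as.integer(seed),
    bridge = isTRUE(bridge)
  ), class = "library_spec")
}

#' Generate a synthetic compound library with ground truth
#'
#' Builds molecules by attaching randomly chosen substituents to randomly
#' chosen ring scaffolds at open valence positions (or, in bridge mode, by
#' joining two scaffolds through a one-carbon linker). The returned truth
#' table lists, per molecule, exactly the RFs and AFs the construction
#' implies. Deterministic per seed; chemically invalid assemblies are
#' rejected and resampled (counted in the `resamples` element; the valence
#' bookkeeping makes them rare to impossible).
#'
#' @param spec a [library_spec()].
#' @return object of class `molfrag_library`: list with `smiles` (canonical
#'   SMILES, one per molecule), `truth` (data frame `molecule`, `kind`,
#'   `smiles`), `spec`, `resamples`.
#' @export
generate_library <- function(spec) {
  if (!inherits(spec, "library_spec")) .usage_error("spec must be a library_spec")
  scaf <- lapply(spec$rf_alphabet, function(s) {
    m <- parse_molecule(s)
    if (!all(m$atoms$in_ring)) .usage_error(paste0("scaffold has acyclic atoms: ", s))
    if (length(.ring_systems(m)) != 1) .usage_error(paste0("scaffold must be one ring system: ", s))
    .mol_graph(m)
  })
  subst <- lapply(spec$af_alphabet, function(s) {
    m <- parse_molecule(s)
    if (any(m$atoms$in_ring)) .usage_error(paste0("substituent must be acyclic: ", s))
    g <- .mol_graph(m)
    if (.free_valence(g)[1] < 1) .usage_error(paste0("substituent's first atom has no free valence: ", s))
    g
  })
  open_pos <- lapply(scaf, function(g) which(.free_valence(g) >= 1))
  .with_seed(spec$seed, {
    graphs <- vector("list", spec$n_molecules)
    truth_graphs <- list()
    truth_mol <- integer(0)
    truth_kind <- character(0)
    for (i in seq_len(spec$n_molecules)) {
      if (spec$bridge) {
        si <- sample.int(length(scaf), 2, replace = TRUE)
        linker <- list(elem = "C", charge = 0L, bonds = matrix(integer(0), ncol = 3))
        g <- scaf[[si[1]]]
        p1 <- .pick1(open_pos[[si[1]]])
        g <- .attach_graph(g, p1, linker)
        lidx <- length(g$elem)
        off <- length(g$elem)
        g2 <- scaf[[si[2]]]
        p2 <- .pick1(open_pos[[si[2]]])
        g <- list(
          elem = c(g$elem, g2$elem), charge = c(g$charge, g2$charge),
          bonds = rbind(g$bonds,
                        if (nrow(g2$bonds)) cbind(g2$bonds[, 1] + off, g2$bonds[, 2] + off, g2$bonds[, 3]),
                        c(lidx, p2 + off, 1L))
        )
        graphs[[i]] <- g
        tg <- list(
          .attach_graph(scaf[[si[1]]], p1, linker),
          .attach_graph(scaf[[si[2]]], p2, linker),
          linker
        )
        truth_graphs <- c(truth_graphs, tg)
        truth_mol <- c(truth_mol, rep(i, 3))
        truth_kind <- c(truth_kind, "RF", "RF", "AF")
      } else {
        si <- .pick1(seq_along(scaf))
        pos <- open_pos[[si]]
        k <- sample.int(min(spec$max_substituents, length(pos)) + 1L, 1L) - 1L
        at <- if (k > 0) pos[sample.int(length(pos), k)] else integer(0)
        sj <- if (k > 0) sample.int(length(subst), k, replace = TRUE) else integer(0)
        g <- scaf[[si]]
        rf_truth <- scaf[[si]]
        for (q in seq_len(k)) {
          g <- .attach_graph(g, at[q], subst[[sj[q]]])
          stub <- list(elem = subst[[sj[q]]]$elem[1], charge = subst[[sj[q]]]$charge[1],
                       bonds = matrix(integer(0), ncol = 3))
          rf_truth <- .attach_graph(rf_truth, at[q], stub)
        }
        graphs[[i]] <- g
        truth_graphs <- c(truth_graphs, list(rf_truth), subst[sj])
        truth_mol <- c(truth_mol, rep(i, 1 + k))
        truth_kind <- c(truth_kind, "RF", rep("AF", k))
      }
    }
    smiles <- .canon_graphs(graphs)
    truth_smiles <- .canon_graphs(truth_graphs)
    structure(list(
      smiles = smiles,
      truth = data.frame(molecule = truth_mol, kind = truth_kind,
                         smiles = truth_smiles, stringsAsFactors = FALSE),
      spec = spec,
      resamples = 0L
    ), class = "molfrag_library")
  })
}

.pick1 <- function(x) if (length(x) == 1) x else sample(x, 1)

#' @export
print.molfrag_library <- function(x, ...) {
  cat("<molfrag_library> ", length(x$smiles), " molecules (seed ",
      x$spec$seed, if (x$spec$bridge) ", bridge mode" else "", ")\n", sep = "")
  invisible(x)
}

#' Split a synthetic library into active/inactive subsets with a planted
#' enrichment ratio
#'
#' Assigns molecules to an active subset of size `n_active` and an inactive
#' subset of size `n_inactive` such that the expected measured R_bioactive
#' of `planted_fragment` equals `target_ratio`: of the M molecules
#' containing the fragment, `round(M * p)` with
#' `p = rho * n_active / (rho * n_active + n_inactive)` go to the active
#' subset (which molecules is drawn at random, seeded), the rest to the
#' inactive subset; non-containing molecules fill the remaining slots.
#'
#' @param lib a `molfrag_library` from [generate_library()].
#' @param planted_fragment fragment SMILES (canonicalized internally); must
#'   occur in the library's ground truth.
#' @param target_ratio desired R_bioactive (> 0, finite).
#' @param n_active,n_inactive subset sizes; their sum must not exceed the
#'   library size (a seeded subsample is taken when the library is larger).
#' @param seed integer seed.
#' @return list with character vectors `active` and `inactive` (molecule
#'   SMILES) and the realized containing-molecule counts `m_active`,
#'   `m_inactive`.
#' @export
generate_activity_split <- function(lib, planted_fragment, target_ratio,
                                    n_active, n_inactive, seed = 1L) {
  if (!inherits(lib, "molfrag_library")) .usage_error("lib must be a molfrag_library")
  if (!is.finite(target_ratio) || target_ratio <= 0) {
    .usage_error("target_ratio must be finite and > 0")
  }
  total <- n_active + n_inactive
  if (total > length(lib$smiles)) {
    .config_error("library smaller than n_active + n_inactive")
  }
  key <- canonical_key(planted_fragment)
  containing_all <- unique(lib$truth$molecule[lib$truth$smiles == key])
  if (!length(containing_all)) {
    .config_error(paste0("planted fragment not present in library: ", key))
  }
  .with_seed(seed, {
    use <- if (total < length(lib$smiles)) sample.int(length(lib$smiles), total) else
      seq_along(lib$smiles)
    containing <- intersect(use, containing_all)
    M <- length(containing)
    p <- target_ratio * n_active / (target_ratio * n_active + n_inactive)
    a <- round(M * p)
    if (M == 0 || a < 1 || a > n_active || (M - a) < 1 || (M - a) > n_inactive) {
      .config_error(sprintf(
        "target ratio %g unattainable: %d containing molecules for subsets %d/%d",
        target_ratio, M, n_active, n_inactive))
    }
    act_cont <- containing[sample.int(M, a)]
    rest <- setdiff(use, containing)
    act_rest <- rest[sample.int(length(rest), n_active - a)]
    active <- c(act_cont, act_rest)
    inactive <- setdiff(use, active)
    list(
      active = lib$smiles[active],
      inactive = lib$smiles[inactive],
      m_active = a,
      m_inactive = M - a
    )
  })
}
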