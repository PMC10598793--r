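#' @importFrom stats setNames
#' @importFrom utils head
NULL

# ---- conditions -------------------------------------------------------------

.parse_error <- function(smiles, reason = "not a valid SMILES") {
  stop(errorCondition(
    sprintf("cannot parse SMILES %s: %s", deparse(substr(smiles, 1, 200)), reason),
    smiles = smiles,
    class = c("molfrag_parse_error", "molfrag_error")
  ))
}

.empty_input <- function() {
  stop(errorCondition(
    "empty input line (skip signal, not a parse error)",
    class = c("molfrag_empty_input", "molfrag_error")
  ))
}

.usage_error <- function(msg) {
  stop(errorCondition(msg, class = c("molfrag_usage_error", "molfrag_error")))
}

.config_error <- function(msg) {
  stop(errorCondition(msg, class = c("molfrag_config_error", "molfrag_error")))
}

# ---- OpenBabel bridge -------------------------------------------------------

.ob_convert <- function(from, to, source) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from = from, to = to, source = source))
  if (is.null(out)) out <- ""
  out
}

# Read the atom/bond/charge blocks of a V2000 molfile (one SDF record).
# Returns list(elem, charge, bonds = matrix[a1, a2, order]).
.read_v2000 <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) return(NULL)
  at <- lines[5:(4 + na)]
  elem <- trimws(substr(at, 32, 34))
  charge <- integer(na)
  bonds <- matrix(integer(0), ncol = 3)
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- cbind(
      as.integer(substr(bl, 1, 3)),
      as.integer(substr(bl, 4, 6)),
      as.integer(substr(bl, 7, 9))
    )
  }
  # formal charges live in M  CHG lines (old-style atom-block codes ignored:
  # OpenBabel always writes M  CHG)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    n <- as.integer(substr(l, 7, 9))
    for (k in seq_len(n)) {
      off <- 10 + (k - 1) * 8
      idx <- as.integer(substr(l, off, off + 3))
      chg <- as.integer(substr(l, off + 4, off + 7))
      charge[idx] <- chg
    }
  }
  list(elem = elem, charge = charge, bonds = bonds)
}

# Emit a V2000 molfile for a bare heavy-atom graph. No coordinates, isotopes
# or stereo fields: OpenBabel re-perceives aromaticity and fills implicit
# hydrogens to standard valence, so cut valences come back H-saturated and
# stereo/isotope annotations of the source are dropped.
.write_v2000 <- function(g) {
  na <- length(g$elem)
  nb <- nrow(g$bonds)
  l <- c(
    "", "  molfrag", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", g$elem)
  )
  if (nb > 0) {
    l <- c(l, sprintf("%3d%3d%3d  0  0  0  0", g$bonds[, 1], g$bonds[, 2], g$bonds[, 3]))
  }
  ch <- which(g$charge != 0L)
  if (length(ch)) {
    # M CHG lines hold at most 8 (index, charge) pairs each
    for (grp in split(ch, ceiling(seq_along(ch) / 8))) {
      l <- c(l, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, g$charge[grp]), collapse = "")
      ))
    }
  }
  paste0(paste(c(l, "M  END", "$$$$"), collapse = "\n"), "\n")
}

# Canonical SMILES for a list of heavy-atom graphs, in one OpenBabel call.
# Package-generated graphs are always convertible; a count mismatch is a bug.
.canon_graphs <- function(graphs) {
  if (!length(graphs)) return(character(0))
  sdf <- paste0(vapply(graphs, .write_v2000, character(1)), collapse = "")
  out <- .ob_convert("SDF", "CAN", sdf)
  smi <- sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]])
  smi <- smi[nzchar(smi)]
  if (length(smi) != length(graphs)) {
    stop("internal error: canonicalization dropped ", length(graphs) - length(smi),
         " of ", length(graphs), " fragment records")
  }
  smi
}

# ---- ring perception --------------------------------------------------------

# An edge lies on a cycle iff it is not a bridge; an atom is a ring atom iff
# it is incident to a non-bridge edge.
.ring_flags <- function(na, bonds) {
  if (nrow(bonds) == 0) {
    return(list(atom = logical(na), bond = logical(0)))
  }
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
  bond_ring <- rep(TRUE, nrow(bonds))
  bond_ring[as.integer(igraph::bridges(g))] <- FALSE
  atom_ring <- logical(na)
  atom_ring[unique(as.vector(bonds[bond_ring, 1:2]))] <- TRUE
  list(atom = atom_ring, bond = bond_ring)
}

# ---- molecule parsing -------------------------------------------------------

.mol2_aromatic <- function(mol2, na) {
  arom <- logical(na)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  b0 <- grep("^@<TRIPOS>BOND", lines)
  if (!length(b0)) return(arom)
  end <- grep("^@<TRIPOS>", lines)
  end <- c(end[end > b0[1]], length(lines) + 1)[1]
  bl <- lines[(b0[1] + 1):(end - 1)]
  bl <- bl[nzchar(trimws(bl))]
  for (l in bl) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (length(f) >= 4 && f[4] == "ar") {
      arom[as.integer(f[2:3])] <- TRUE
    }
  }
  arom
}

.component_membership <- function(na, bonds) {
  if (nrow(bonds) == 0) return(seq_len(na))
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
  igraph::components(g)$membership
}

.subgraph <- function(g, keep) {
  idx <- integer(length(g$elem))
  idx[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep, , drop = FALSE]
  list(
    elem = g$elem[keep],
    charge = g$charge[keep],
    bonds = cbind(idx[b[, 1]], idx[b[, 2]], b[, 3])
  )
}

.finish_molecule <- function(smiles, g, arom) {
  na <- length(g$elem)
  rf <- .ring_flags(na, g$bonds)
  deg <- tabulate(as.vector(g$bonds[, 1:2]), nbins = na)
  canonical <- .canon_graphs(list(g))
  structure(list(
    source_smiles = smiles,
    canonical_smiles = canonical,
    hac = na,
    atoms = data.frame(
      elem = g$elem, charge = g$charge, aromatic = arom,
      in_ring = rf$atom, heavy_nbrs = deg, stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      a1 = g$bonds[, 1], a2 = g$bonds[, 2], order = g$bonds[, 3],
      in_ring = rf$bond
    )
  ), class = "molfrag_mol")
}

.parse_one <- function(smiles) {
  sdf <- .ob_convert("SMI", "SDF", paste0(smiles, "\n"))
  if (!nzchar(sdf)) .parse_error(smiles)
  g <- .read_v2000(strsplit(sdf, "\n", fixed = TRUE)[[1]])
  if (is.null(g)) .parse_error(smiles, "no heavy atoms")
  mol2 <- .ob_convert("SMI", "MOL2", paste0(smiles, "\n"))
  arom <- .mol2_aromatic(mol2, length(g$elem))
  .reduce_and_finish(smiles, g, arom)
}

# Largest-heavy-atom-count component; ties broken by canonical SMILES
# lexicographic order (salt/counter-ion stripping).
.reduce_and_finish <- function(smiles, g, arom) {
  memb <- .component_membership(length(g$elem), g$bonds)
  sizes <- tabulate(memb)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    smi <- .canon_graphs(lapply(best, function(ci) .subgraph(g, which(memb == ci))))
    best <- best[order(smi)[1]]
  }
  keep <- which(memb == best[1])
  .finish_molecule(smiles, .subgraph(g, keep), arom[keep])
}

#' Parse a SMILES string into an annotated molecule
#'
#' Parses one SMILES record with OpenBabel, reduces multi-component records
#' (salts) to the largest component by heavy atom count, strips isotope labels
#' and stereo descriptors, preserves formal charges, and annotates every atom
#' and bond with ring membership (an atom is a ring atom iff it lies on at
#' least one cycle of the molecular graph).
#'
#' @param smiles a single SMILES string.
#' @return An object of class `molfrag_mol` with elements `source_smiles`,
#'   `canonical_smiles`, `hac` (heavy atom count), `atoms` (data frame with
#'   `elem`, `charge`, `aromatic`, `in_ring`, `heavy_nbrs`) and `bonds`
#'   (data frame with `a1`, `a2`, `order`, `in_ring`).
#' @examples
#' m <- parse_molecule("Cc1ccccc1")
#' m$hac
#' sum(m$atoms$in_ring)
#' @export
parse_molecule <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles)) .usage_error("smiles must be a single string")
  if (!nzchar(trimws(smiles))) .empty_input()
  .parse_one(trimws(smiles))
}

#' Parse a vector of SMILES strings
#'
#' Batch variant of [parse_molecule()]. Unparsable records are skipped (with
#' a warning naming them); blank records are skipped silently. The number of
#' skipped records is returned in the `skipped` attribute.
#'
#' @param smiles character vector of SMILES.
#' @return A list of `molfrag_mol` objects with attribute `skipped`.
#' @export
parse_molecules <- function(smiles) {
  smiles <- trimws(as.character(smiles))
  keep <- nzchar(smiles) & !startsWith(smiles, "#")
  src <- smiles[keep]
  if (!length(src)) return(structure(list(), skipped = 0L))
  # fast path: one batched conversion; OpenBabel drops unparsable records,
  # so fall back to per-record parsing when counts disagree
  sdf <- .ob_convert("SMI", "SDF", paste0(paste(src, collapse = "\n"), "\n"))
  recs <- strsplit(sdf, "$$$$\n", fixed = TRUE)[[1]]
  recs <- recs[nzchar(trimws(recs))]
  skipped <- 0L
  if (length(recs) == length(src)) {
    mol2 <- .ob_convert("SMI", "MOL2", paste0(paste(src, collapse = "\n"), "\n"))
    m2 <- strsplit(mol2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
    m2 <- m2[nzchar(trimws(m2))]
    mols <- vector("list", length(src))
    for (i in seq_along(src)) {
      g <- .read_v2000(strsplit(recs[i], "\n", fixed = TRUE)[[1]])
      if (is.null(g)) {
        mols[i] <- list(NULL)
        next
      }
      arom <- if (length(m2) == length(src)) {
        .mol2_aromatic(m2[i], length(g$elem))
      } else {
        logical(length(g$elem))
      }
      mols[[i]] <- .reduce_and_finish(src[i], g, arom)
    }
  } else {
    mols <- lapply(src, function(s) {
      tryCatch(.parse_one(s), molfrag_parse_error = function(e) NULL)
    })
  }
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " unparsable SMILES record(s) skipped: ",
            paste(utils::head(src[bad], 5), collapse = ", "))
    skipped <- sum(bad)
    mols <- mols[!bad]
  }
  structure(mols, skipped = skipped + sum(!keep & nzchar(smiles)))
}

#' Canonical SMILES key
#'
#' Deterministic canonical SMILES usable as a dictionary key: two inputs
#' describing the same molecular graph (any atom order, Kekule or aromatic
#' notation) yield identical keys. Stereochemistry and isotopes are stripped.
#'
#' @param x a `molfrag_mol`, or a character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @examples
#' canonical_key("C(C)O") == canonical_key("OCC")
#' @export
canonical_key <- function(x) {
  if (inherits(x, "molfrag_mol")) return(x$canonical_smiles)
  vapply(as.character(x), function(s) parse_molecule(s)$canonical_smiles,
         character(1), USE.NAMES = FALSE)
}

#' Heavy atom count
#'
#' Number of non-hydrogen atoms of a molecule (after largest-component
#' reduction, as in [parse_molecule()]).
#'
#' @param smiles character vector of SMILES (or a `molfrag_mol`).
#' @return integer vector.
#' @examples
#' heavy_atom_count("c1ccccc1")
#' @export
heavy_atom_count <- function(smiles) {
  if (inherits(smiles, "molfrag_mol")) return(smiles$hac)
  vapply(as.character(smiles), function(s) parse_molecule(s)$hac,
         integer(1), USE.NAMES = FALSE)
}

#' @export
print.molfrag_mol <- function(x, ...) {
  cat("<molfrag_mol> ", x$canonical_smiles, "\n", sep = "")
  cat("  heavy atoms: ", x$hac,
      "  ring atoms: ", sum(x$atoms$in_ring),
      "  bonds: ", nrow(x$bonds), "\n", sep = "")
  invisible(x)
}

#' Read a SMILES file
#'
#' Reads the line format `SMILES` or `SMILES<TAB>ID` (UTF-8). Blank lines and
#' lines starting with `#` are ignored. Gzip-compressed files are read
#' transparently.
#'
#' @param path file path (`.smi` or `.smi.gz`).
#' @return data frame with columns `smiles` and `id` (id `NA` when absent).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) .usage_error(paste0("file not found: ", path))
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}
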