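# Fragment occurrence indexing and collection-level statistics: counts,
# singletons, exclusives, coverage, frequency distributions, top-N lists,
# size histograms. Occurrence of a fragment is the number of DISTINCT
# molecules of the collection containing it (within-molecule duplicates
# count once).

#' Build a fragment occurrence index
#'
#' Fragments every molecule of a collection and counts, per canonical
#' fragment SMILES, the number of distinct molecules containing it.
#' Unparsable records are skipped (warning) and reported in `n_skipped`.
#' Input collections are assumed pre-deduplicated at the molecule level;
#' set `dedupe = TRUE` to deduplicate by canonical key first.
#'
#' @param x character vector of SMILES, a list of `molfrag_mol`, or a
#'   fragment table from [fragment_collection()].
#' @param kind "RF" or "AF".
#' @param collection_name label stored in the index.
#' @param dedupe deduplicate molecules by canonical key before counting.
#' @return object of class `fragment_index`: list with `collection_name`,
#'   `kind`, `counts` (named integer vector, fragment key -> molecule count),
#'   `hac` (named integer vector, fragment key -> heavy atom count),
#'   `n_molecules`, `n_skipped`.
#' @examples
#' idx <- build_fragment_index(c("Cc1ccccc1", "COc1ccccc1"), kind = "RF")
#' idx$counts
#' @export
build_fragment_index <- function(x, kind = c("RF", "AF"), collection_name = "collection",
                                 dedupe = FALSE) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    frags <- x
    n_mol <- length(unique(frags$molecule_id))
    skipped <- attr(x, "skipped")
    if (is.null(skipped)) skipped <- 0L
  } else {
    if (is.character(x)) {
      mols <- parse_molecules(x)
    } else {
      mols <- x
    }
    skipped <- attr(mols, "skipped")
    if (is.null(skipped)) skipped <- 0L
    if (dedupe) {
      keys <- vapply(mols, `[[`, character(1), "canonical_smiles")
      mols <- mols[!duplicated(keys)]
    }
    n_mol <- length(mols)
    frags <- if (n_mol) fragment_collection(mols) else
      data.frame(molecule_id = character(0), kind = character(0),
                 smiles = character(0), hac = integer(0))
  }
  frags <- frags[frags$kind == kind, , drop = FALSE]
  # distinct molecules per fragment
  key <- paste(frags$molecule_id, frags$smiles, sep = "\r")
  frags <- frags[!duplicated(key), , drop = FALSE]
  counts <- table(frags$smiles)
  counts <- setNames(as.integer(counts), names(counts))
  hac <- frags$hac[!duplicated(frags$smiles)]
  names(hac) <- frags$smiles[!duplicated(frags$smiles)]
  structure(list(
    collection_name = collection_name,
    kind = kind,
    counts = counts,
    hac = hac[names(counts)],
    n_molecules = n_mol,
    n_skipped = skipped
  ), class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  cat("<fragment_index> ", x$collection_name, " [", x$kind, "]\n", sep = "")
  cat("  molecules: ", x$n_molecules,
      "  unique fragments: ", length(x$counts),
      "  skipped records: ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

.check_index <- function(x) {
  if (!inherits(x, "fragment_index")) .usage_error("expected a fragment_index")
  x
}

#' Merge fragment indexes of disjoint molecule sets
#'
#' Counts are additive over disjoint molecule sets, so sharded collections
#' can be indexed independently and merged.
#'
#' @param ... `fragment_index` objects of the same kind.
#' @param collection_name label for the merged index.
#' @return merged `fragment_index`.
#' @export
merge_indexes <- function(..., collection_name = "merged") {
  xs <- lapply(list(...), .check_index)
  if (length(unique(vapply(xs, `[[`, character(1), "kind"))) != 1) {
    .usage_error("cannot merge indexes of different fragment kinds")
  }
  counts <- unlist(lapply(xs, `[[`, "counts"))
  counts <- tapply(counts, names(counts), sum)
  counts <- setNames(as.integer(counts), names(counts))
  hac <- unlist(lapply(xs, `[[`, "hac"))
  hac <- hac[!duplicated(names(hac))]
  structure(list(
    collection_name = collection_name,
    kind = xs[[1]]$kind,
    counts = counts,
    hac = hac[names(counts)],
    n_molecules = sum(vapply(xs, `[[`, integer(1), "n_molecules")),
    n_skipped = sum(vapply(xs, `[[`, integer(1), "n_skipped"))
  ), class = "fragment_index")
}

#' Singleton fragments
#'
#' Fragments occurring in exactly one molecule of the collection.
#'
#' @param index a `fragment_index`.
#' @return character vector of fragment keys.
#' @export
singletons <- function(index) {
  index <- .check_index(index)
  names(index$counts)[index$counts == 1L]
}

#' Exclusive fragments
#'
#' Fragments of `target` absent from every comparison index (eRF/eAF).
#'
#' @param target a `fragment_index`.
#' @param others list of comparison `fragment_index` objects (same kind).
#' @return character vector of fragment keys.
#' @export
exclusives <- function(target, others) {
  target <- .check_index(target)
  if (inherits(others, "fragment_index")) others <- list(others)
  for (o in others) {
    o <- .check_index(o)
    if (o$kind != target$kind) .usage_error("exclusives: indexes must share the fragment kind")
  }
  seen <- unique(unlist(lapply(others, function(o) names(o$counts))))
  setdiff(names(target$counts), seen)
}

#' Fraction of molecules covered by small fragments
#'
#' A molecule is covered when EVERY fragment of the selected kind(s) has a
#' heavy atom count of at most `max_hac`; a molecule with no fragments of
#' that kind counts as covered (vacuous truth).
#'
#' @param x SMILES vector, list of `molfrag_mol`, or a fragment table from
#'   [fragment_collection()].
#' @param kind_filter "RF", "AF", or "both".
#' @param max_hac heavy-atom-count threshold (default 13).
#' @return fraction in \[0, 1\].
#' @export
coverage <- function(x, kind_filter = c("both", "RF", "AF"), max_hac = 13) {
  kind_filter <- match.arg(kind_filter)
  if (is.data.frame(x)) {
    frags <- x
    n_mol <- length(unique(frags$molecule_id))
  } else {
    mols <- if (is.character(x)) parse_molecules(x) else x
    n_mol <- length(mols)
    if (!n_mol) return(NaN)
    frags <- fragment_collection(mols)
  }
  if (kind_filter != "both") frags <- frags[frags$kind == kind_filter, , drop = FALSE]
  bad <- unique(frags$molecule_id[frags$hac > max_hac])
  (n_mol - length(bad)) / n_mol
}

#' Occurrence frequency distribution
#'
#' Histogram of fragment occurrence values: how many fragments occur in
#' exactly k molecules, for every realized k.
#'
#' @param index a `fragment_index`.
#' @return data frame with columns `occurrence` and `n_fragments`, sorted by
#'   occurrence; the `n_fragments` column sums to the number of unique
#'   fragment keys.
#' @export
frequency_distribution <- function(index) {
  index <- .check_index(index)
  if (!length(index$counts)) {
    return(data.frame(occurrence = integer(0), n_fragments = integer(0)))
  }
  tab <- table(index$counts)
  data.frame(
    occurrence = as.integer(names(tab)),
    n_fragments = as.integer(tab)
  )
}

#' Most frequent fragments
#'
#' The n highest-occurrence fragments, ties broken by canonical key
#' lexicographic order (deterministic).
#'
#' @param index a `fragment_index`.
#' @param n number of fragments to return.
#' @return character vector of fragment keys, most frequent first.
#' @export
top_fragments <- function(index, n) {
  index <- .check_index(index)
  if (n < 0) .usage_error("n must be >= 0")
  keys <- names(index$counts)
  ord <- order(-index$counts, keys, method = "radix")
  utils::head(keys[ord], n)
}

#' Size histograms of compounds and fragments
#'
#' Per-heavy-atom-count counts of compounds, unique RFs, unique AFs, and
#' (when exclusive fragment sets are supplied) exclusive RFs/AFs.
#'
#' @param x SMILES vector, list of `molfrag_mol`, or fragment table from
#'   [fragment_collection()].
#' @param exclusive_rf,exclusive_af optional character vectors of exclusive
#'   fragment keys (e.g. from [exclusives()]).
#' @return named list of tables keyed by HAC: `compounds`, `rf`, `af`, and
#'   `erf`/`eaf` when exclusive sets are given.
#' @export
size_histograms <- function(x, exclusive_rf = NULL, exclusive_af = NULL) {
  if (is.data.frame(x)) {
    .usage_error("size_histograms needs molecules, not a fragment table")
  }
  mols <- if (is.character(x)) parse_molecules(x) else x
  frags <- if (length(mols)) fragment_collection(mols) else
    data.frame(molecule_id = character(0), kind = character(0),
               smiles = character(0), hac = integer(0))
  htab <- function(h) table(factor(h, levels = sort(unique(h))))
  uniq <- frags[!duplicated(paste(frags$kind, frags$smiles)), , drop = FALSE]
  rf <- uniq[uniq$kind == "RF", , drop = FALSE]
  af <- uniq[uniq$kind == "AF", , drop = FALSE]
  out <- list(
    compounds = htab(vapply(mols, `[[`, integer(1), "hac")),
    rf = htab(rf$hac),
    af = htab(af$hac)
  )
  if (!is.null(exclusive_rf)) out$erf <- htab(rf$hac[rf$smiles %in% exclusive_rf])
  if (!is.null(exclusive_af)) out$eaf <- htab(af$hac[af$smiles %in% exclusive_af])
  out
}

#' Write a fragment index as TSV
#'
#' Two-column TSV (fragment_smiles, count) with a header comment line
#' carrying the collection name, kind, molecule count and skip count; a
#' third column stores the fragment heavy atom count. Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param index a `fragment_index`.
#' @param path output path.
#' @export
write_fragment_index <- function(index, path) {
  index <- .check_index(index)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#collection=%s\tkind=%s\tn_molecules=%d\tn_skipped=%d",
                     index$collection_name, index$kind,
                     index$n_molecules, index$n_skipped), con)
  writeLines("fragment_smiles\tcount\thac", con)
  if (length(index$counts)) {
    writeLines(sprintf("%s\t%d\t%d", names(index$counts),
                       index$counts, index$hac), con)
  }
  invisible(path)
}

#' Read a fragment index written by [write_fragment_index()]
#'
#' @param path input path (gzip transparent).
#' @return a `fragment_index`.
#' @export
read_fragment_index <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) .usage_error("missing index header line")
  kv <- strsplit(strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]], "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, character(1), 1)
  counts <- setNames(as.integer(vapply(parts, `[`, character(1), 2)), keys)
  hac <- setNames(as.integer(vapply(parts, `[`, character(1), 3)), keys)
  structure(list(
    collection_name = unname(meta["collection"]),
    kind = unname(meta["kind"]),
    counts = counts,
    hac = hac,
    n_molecules = as.integer(meta["n_molecules"]),
    n_skipped = as.integer(meta["n_skipped"])
  ), class = "fragment_index")
}
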