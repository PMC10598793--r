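# Bioactivity enrichment of fragments.
#
# For a fragment f with occurrence n_active among N_active active molecules
# and n_inactive among N_inactive inactive molecules:
#   pct_active   = 100 * n_active   / N_active
#   pct_inactive = 100 * n_inactive / N_inactive
#   R_bioactive  = pct_active / pct_inactive
# with 0/positive -> 0 and positive/0 -> +Inf (no pseudocounts: fragments
# exclusive to one subset sit at the extremes and are labeled accordingly).
# Classification: active iff R >= hi (default 4), inactive iff R <= lo
# (default 0.25), nonpreferential otherwise.

#' Compute fragment bioactivity enrichment
#'
#' One record per fragment present in either index; a fragment absent from
#' one side gets count 0 there, giving `r_bioactive` of 0 or `+Inf` (no
#' pseudocounts). Labels are assigned at the thresholds `hi` / `lo`
#' (inclusive bounds).
#'
#' @param active_index,inactive_index `fragment_index` objects of the same
#'   kind built from the active and inactive molecule subsets.
#' @param hi,lo classification thresholds (defaults 4 and 0.25).
#' @return data frame of class `molfrag_enrichment` with columns `fragment`,
#'   `kind`, `n_active`, `n_inactive`, `pct_active`, `pct_inactive`,
#'   `r_bioactive`, `total_occurrence`, `label`.
#' @export
compute_enrichment <- function(active_index, inactive_index, hi = 4, lo = 0.25) {
  active_index <- .check_index(active_index)
  inactive_index <- .check_index(inactive_index)
  if (active_index$kind != inactive_index$kind) {
    .usage_error("enrichment: indexes must share the fragment kind")
  }
  if (active_index$n_molecules == 0 || inactive_index$n_molecules == 0) {
    .config_error("enrichment needs non-empty active and inactive subsets")
  }
  keys <- union(names(active_index$counts), names(inactive_index$counts))
  na <- ifelse(keys %in% names(active_index$counts),
               active_index$counts[keys], 0L)
  ni <- ifelse(keys %in% names(inactive_index$counts),
               inactive_index$counts[keys], 0L)
  pa <- 100 * na / active_index$n_molecules
  pi_ <- 100 * ni / inactive_index$n_molecules
  r <- ifelse(pi_ > 0, pa / pi_, ifelse(pa > 0, Inf, NaN))
  r[pa == 0 & pi_ > 0] <- 0
  rec <- data.frame(
    fragment = keys,
    kind = active_index$kind,
    n_active = as.integer(na),
    n_inactive = as.integer(ni),
    pct_active = pa,
    pct_inactive = pi_,
    r_bioactive = r,
    total_occurrence = as.integer(na + ni),
    stringsAsFactors = FALSE
  )
  rec$label <- .enrichment_label(rec$r_bioactive, hi, lo)
  rownames(rec) <- NULL
  class(rec) <- c("molfrag_enrichment", "data.frame")
  rec
}

.enrichment_label <- function(r, hi, lo) {
  if (!(0 < lo && lo < 1 && 1 < hi)) {
    .usage_error("thresholds must satisfy 0 < lo < 1 < hi")
  }
  ifelse(r >= hi, "active", ifelse(r <= lo, "inactive", "nonpreferential"))
}

#' Partition enrichment records by R_bioactive
#'
#' Relabels the records at the given thresholds and splits them into the
#' three disjoint, exhaustive classes: active (`r >= hi`), inactive
#' (`r <= lo`), nonpreferential (the open complement interval).
#'
#' @param records output of [compute_enrichment()].
#' @param hi,lo thresholds, `0 < lo < 1 < hi`.
#' @return list with character vectors `active`, `nonpreferential`,
#'   `inactive` of fragment keys.
#' @export
partition_enrichment <- function(records, hi = 4, lo = 0.25) {
  lab <- .enrichment_label(records$r_bioactive, hi, lo)
  list(
    active = records$fragment[lab == "active"],
    nonpreferential = records$fragment[lab == "nonpreferential"],
    inactive = records$fragment[lab == "inactive"]
  )
}

#' Volcano-plot coordinates for enrichment records
#'
#' x is `log2(pct_active / pct_inactive)` for fragments occurring in both
#' subsets and the column `side` flags fragments exclusive to one subset:
#' `"left"` when `pct_active = 0` (x is `-Inf`) and `"right"` when
#' `pct_inactive = 0` (x is `+Inf`); such points are conventionally drawn as
#' vertical stacks at the plot edges. y is the total occurrence.
#'
#' @param records output of [compute_enrichment()].
#' @return data frame with columns `fragment`, `x`, `y`, `side`
#'   (`"finite"`, `"left"` or `"right"`).
#' @export
volcano_data <- function(records) {
  x <- log2(records$r_bioactive)
  side <- ifelse(records$pct_active == 0, "left",
                 ifelse(records$pct_inactive == 0, "right", "finite"))
  data.frame(
    fragment = records$fragment,
    x = x,
    y = records$total_occurrence,
    side = side,
    stringsAsFactors = FALSE
  )
}

#' Write enrichment records as TSV
#'
#' Columns: fragment_smiles, kind, n_active, n_inactive, pct_active,
#' pct_inactive, r_bioactive (`inf` / `0` literals allowed), label.
#'
#' @param records output of [compute_enrichment()].
#' @param path output path (gzip when ending in `.gz`).
#' @export
write_enrichment <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines("fragment_smiles\tkind\tn_active\tn_inactive\tpct_active\tpct_inactive\tr_bioactive\tlabel", con)
  rtxt <- ifelse(is.infinite(records$r_bioactive), "inf",
                 format(records$r_bioactive, trim = TRUE, digits = 8))
  writeLines(sprintf("%s\t%s\t%d\t%d\t%g\t%g\t%s\t%s",
                     records$fragment, records$kind, records$n_active,
                     records$n_inactive, records$pct_active,
                     records$pct_inactive, rtxt, records$label), con)
  invisible(path)
}
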