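# SAscore / NPscore via the published RDKit Contrib scorers.
#
# Both scores are fragment-contribution methods whose published data tables
# ship with RDKit; the package calls them through a bundled Python helper
# rather than re-deriving the tables. A missing Python or RDKit raises an
# explicit configuration error -- never silent zeros.

.find_python <- function() {
  p <- getOption("molfrag.python", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  ""
}

#' Synthetic accessibility and natural-product likeness scores
#'
#' Computes, per fragment, the synthetic accessibility score (SAscore, range
#' 1 easy to 10 hard) and the natural-product likeness score (NPscore,
#' typically -5 to 5, higher means more natural-product-like) using the
#' published fragment-contribution scoring methods as implemented in the
#' RDKit Contrib collection. Requires a Python interpreter with RDKit on
#' `PATH` (or set `options(molfrag.python = "/path/to/python")`).
#'
#' @param smiles character vector of fragment SMILES.
#' @return data frame with columns `smiles`, `sa_score`, `np_score`.
#' @export
fragment_scores <- function(smiles) {
  smiles <- as.character(smiles)
  python <- .find_python()
  if (!nzchar(python) || (!file.exists(python) && !nzchar(Sys.which(python)))) {
    .config_error("no Python interpreter found; SAscore/NPscore need Python with RDKit (set options(molfrag.python=...))")
  }
  script <- system.file("python", "score_fragments.py", package = "molfrag")
  if (!nzchar(script)) .config_error("bundled scoring helper not found (package not installed correctly)")
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile))
  writeLines(smiles, infile)
  out <- tryCatch(
    suppressWarnings(
      system2(python, shQuote(script), stdin = infile, stdout = TRUE, stderr = TRUE)
    ),
    error = function(e) structure(character(0), status = 127L)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    .config_error(paste0("fragment scoring failed (SAscore/NPscore need RDKit): ",
                         paste(out, collapse = " | ")))
  }
  out <- out[grepl("\t", out, fixed = TRUE)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  res <- data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    sa_score = as.numeric(vapply(parts, `[`, character(1), 2)),
    np_score = as.numeric(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (nrow(res) != length(smiles)) {
    .config_error("fragment scoring returned an unexpected number of records")
  }
  res
}

#' Score a single fragment
#'
#' Convenience wrapper around [fragment_scores()] returning a two-element
#' numeric vector `c(sa_score, np_score)`.
#'
#' @param smiles one fragment SMILES.
#' @export
score_fragment <- function(smiles) {
  r <- fragment_scores(smiles[1])
  c(sa_score = r$sa_score[1], np_score = r$np_score[1])
}
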