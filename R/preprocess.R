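#' Sparsity-filter configuration
#'
#' Parameters of the Filter stage.  Low-abundance/sparse proteins are removed
#' before log2 transformation and imputation under two rules used by the SFI
#' workflow: (a) the fraction of samples whose abundance is missing or below
#' `intensity_threshold` (default 2^15 = 32768 on the raw scale) reaches
#' `sparse_fraction` (default 0.5); (b) fewer than `min_observations`
#' (default 3) values are observed.  A missing cell counts as below
#' threshold, since it cannot certify abundance above the limit.
#'
#' @param intensity_threshold raw-intensity cutoff, > 0.
#' @param sparse_fraction fraction of samples at/below threshold that
#'   triggers removal, in (0, 1].
#' @param min_observations minimum observed values per protein, >= 0.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(intensity_threshold = 2^15, sparse_fraction = 0.5,
                          min_observations = 3L) {
  if (!is.numeric(intensity_threshold) || intensity_threshold <= 0)
    stop("`intensity_threshold` must be > 0")
  if (!is.numeric(sparse_fraction) || sparse_fraction <= 0 ||
      sparse_fraction > 1)
    stop("`sparse_fraction` must lie in (0, 1]")
  if (!is.numeric(min_observations) || min_observations < 0)
    stop("`min_observations` must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 sparse_fraction = sparse_fraction,
                 min_observations = as.integer(min_observations)),
            class = "filter_config")
}

#' Remove contaminant proteins
#'
#' Drops rows whose accession appears in a contaminant list (e.g. cRAP or
#' the MaxQuant contaminant database).  With `strip_prefix` set (for example
#' `"CON__"`), an accession also matches when the list contains it with the
#' prefix removed, so `CON__P12345` is removed by a list entry `P12345`.
#'
#' @param x an [intensity_matrix()].
#' @param contaminant_ids character vector of contaminant accessions (an
#'   empty vector is a no-op).
#' @param strip_prefix optional prefix stripped from accessions before
#'   matching, in addition to exact matching.
#' @return The filtered [intensity_matrix()]; the removed accessions are
#'   available through [removal_report()].
#' @export
filter_contaminants <- function(x, contaminant_ids = character(0),
                                strip_prefix = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  acc <- rownames(x$values)
  hit <- acc %in% contaminant_ids
  if (!is.null(strip_prefix))
    hit <- hit | sub(paste0("^", strip_prefix), "", acc) %in% contaminant_ids
  out <- intensity_matrix(x$values[!hit, , drop = FALSE], x$scale)
  attr(out, "removed") <- if (any(hit))
    data.frame(accession = acc[hit], rule = "contaminant",
               stringsAsFactors = FALSE)
  else
    data.frame(accession = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  out
}

#' Remove sparse / lowly expressed proteins
#'
#' The Filter stage: on the raw intensity scale, removes protein rows that
#' fail either of the two sparsity rules of [filter_config()].  Both rules
#' are applied by default (union of removals); either can be switched off
#' through `rules`.
#'
#' @param x a raw-scale [intensity_matrix()].
#' @param cfg a [filter_config()].
#' @param rules which rules to apply: `"abundance"` (fraction of samples
#'   missing-or-below-threshold >= `sparse_fraction`) and/or `"min_obs"`
#'   (observed count < `min_observations`).
#' @return The surviving [intensity_matrix()]; removed accessions and the
#'   rule that removed them are available through [removal_report()].
#' @export
filter_sparse <- function(x, cfg = filter_config(),
                          rules = c("abundance", "min_obs")) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!inherits(cfg, "filter_config")) stop("`cfg` must be a filter_config")
  if (x$scale != "raw")
    stop("sparsity filtering operates on the raw intensity scale")
  rules <- match.arg(rules, several.ok = TRUE)
  v <- x$values
  below <- is.na(v) | v < cfg$intensity_threshold
  fail_a <- rowMeans(below) >= cfg$sparse_fraction
  fail_b <- rowSums(!is.na(v)) < cfg$min_observations
  drop <- rep(FALSE, nrow(v))
  if ("abundance" %in% rules) drop <- drop | fail_a
  if ("min_obs" %in% rules) drop <- drop | fail_b
  rule <- ifelse(fail_a & "abundance" %in% rules,
                 ifelse(fail_b & "min_obs" %in% rules, "both", "abundance"),
                 "min_obs")
  out <- intensity_matrix(v[!drop, , drop = FALSE], x$scale)
  attr(out, "removed") <- data.frame(accession = rownames(v)[drop],
                                     rule = rule[drop],
                                     stringsAsFactors = FALSE)
  out
}

#' Report of rows removed by a filter
#'
#' @param x the result of [filter_contaminants()] or [filter_sparse()].
#' @return A data frame with columns `accession` and `rule`.
#' @export
removal_report <- function(x) {
  attr(x, "removed") %||%
    data.frame(accession = character(0), rule = character(0))
}

#' Write a removal report as TSV
#' @param x the result of a filter operation.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(x, path) {
  write.table(removal_report(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize a complete log2 matrix
#'
#' Forces every sample column onto the same empirical distribution (the
#' vector of row-wise means of the column-sorted matrix), with ties broken
#' by average rank.  Normalization is specified after imputation, so the
#' input must be complete.
#'
#' @param x a complete log2-scale [intensity_matrix()].
#' @return The normalized [intensity_matrix()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale != "log2")
    stop("quantile normalization expects log2-scale intensities")
  if (anyNA(x$values))
    stop("matrix contains missing values; impute before normalizing")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  intensity_matrix(v, "log2")
}
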