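#' Capture rate of true significant proteins
#'
#' Percentage of the ground-truth significant set recovered by an observed
#' significant set: `100 * |intersection| / |truth|`.
#'
#' @param truth_sig character vector of truly significant accessions
#'   (non-empty).
#' @param observed_sig character vector of accessions called significant.
#' @return Percentage in \[0, 100\].
#' @export
capture_rate <- function(truth_sig, observed_sig) {
  truth_sig <- unique(truth_sig)
  if (!length(truth_sig)) stop("the ground-truth significant set is empty")
  100 * length(intersect(truth_sig, observed_sig)) / length(truth_sig)
}

#' Bin proteins by number and location of missing values
#'
#' For a two-group design: when only one group has missing values the bin
#' is that group's missing count (`"0"`, `"1"`, `"2"`, `"3"`, ...); when
#' both groups have missing values the bin is `"B3"` if either group is
#' missing all of a size-3 block's values (per-group maximum of 3),
#' otherwise `"B2"`.
#'
#' @param mask logical missingness matrix (see [missing_mask()]).
#' @param g a [sample_groups()] whose contrast groups cover the columns.
#' @return Named character vector of bins, one per protein.
#' @export
bin_missingness <- function(mask, g) {
  stopifnot(is.matrix(mask), inherits(g, "sample_groups"))
  c1 <- rowSums(mask[, intersect(colnames(mask),
                                 group_samples(g, g$contrast[1])),
                     drop = FALSE])
  c2 <- rowSums(mask[, intersect(colnames(mask),
                                 group_samples(g, g$contrast[2])),
                     drop = FALSE])
  both <- c1 > 0 & c2 > 0
  bins <- ifelse(both,
                 ifelse(pmax(c1, c2) >= 3, "B3", "B2"),
                 as.character(pmax(c1, c2)))
  setNames(bins, rownames(mask))
}

#' Merge the top-n proteins of several ranked method tables
#'
#' Takes the union of each method's top `n` proteins by rank, removes
#' duplicates, flags per-method membership, and orders the merged list by
#' each protein's best (minimum) rank across methods.
#'
#' @param tables named list of `mi_combined` tables (see [combine_mi()]).
#' @param n list depth per method (default 10); when `n` exceeds a table's
#'   size the whole table is used, with a warning.
#' @return Data frame: `accession`, `best_rank`, and one logical
#'   `in_<method>` column per table.
#' @export
merge_top <- function(tables, n = 10L) {
  if (!length(tables)) stop("no tables supplied")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("`tables` must be a named list (method -> table)")
  tops <- lapply(tables, function(t) {
    nn <- n
    if (nn > nrow(t)) {
      warning("n = ", n, " exceeds table size ", nrow(t),
              "; using the full table")
      nn <- nrow(t)
    }
    t$accession[order(t$rank)][seq_len(nn)]
  })
  acc <- unique(unlist(tops, use.names = FALSE))
  best <- vapply(acc, function(a) {
    min(vapply(tables, function(t) {
      r <- t$rank[t$accession == a]
      if (length(r)) r else Inf
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(accession = acc, best_rank = unname(best),
                    stringsAsFactors = FALSE)
  for (m in names(tables))
    out[[paste0("in_", m)]] <- acc %in% tops[[m]]
  out[order(out$best_rank, out$accession), , drop = FALSE]
}

#' Spread statistics of selected proteins across methods
#'
#' For each requested protein and each method table, tabulates the mean and
#' SD of logFC and of -log10 q across MI iterations, plus the half-widths
#' of the 95% spread ellipse (1.96 SD per axis).  A protein absent from a
#' table is flagged absent, not an error.
#'
#' @param tables named list of `mi_combined` tables.
#' @param accessions proteins to extract.
#' @return Long-format data frame: `accession`, `method`, `present`,
#'   `logfc_mean`, `logfc_sd`, `neglog10q_mean`, `neglog10q_sd`,
#'   `ellipse_logfc`, `ellipse_neglog10q`.
#' @export
spread_stats <- function(tables, accessions) {
  if (is.null(names(tables))) stop("`tables` must be a named list")
  rows <- list()
  for (m in names(tables)) {
    t <- tables[[m]]
    idx <- match(accessions, t$accession)
    rows[[m]] <- data.frame(
      accession = accessions, method = m, present = !is.na(idx),
      logfc_mean = t$logfc_mean[idx], logfc_sd = t$logfc_sd[idx],
      neglog10q_mean = t$neglog10q_mean[idx],
      neglog10q_sd = t$neglog10q_sd[idx],
      ellipse_logfc = 1.96 * t$logfc_sd[idx],
      ellipse_neglog10q = 1.96 * t$neglog10q_sd[idx],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify proteins against the MNAR censoring threshold
#'
#' Crosses each protein's mean (imputed) expression against the model
#' selector's censoring threshold with its significance call, yielding the
#' four classes `"above_significant"`, `"above_not_significant"`,
#' `"below_significant"`, `"below_not_significant"`.
#'
#' @param combined an `mi_combined` table.
#' @param imputed the complete [intensity_matrix()] whose row means define
#'   "protein expression".
#' @param sel a [model_selector()] result supplying `threshold_log2`.
#' @param alpha significance threshold on the q-value mean.
#' @return Named character vector of classes, one per protein in
#'   `combined`.
#' @export
classify_vs_threshold <- function(combined, imputed, sel, alpha = 0.05) {
  stopifnot(inherits(imputed, "intensity_matrix"))
  expr <- rowMeans(imputed$values)[combined$accession]
  above <- expr >= sel$threshold_log2
  sig <- combined$qmean < alpha
  setNames(paste0(ifelse(above, "above", "below"),
                  ifelse(sig, "_significant", "_not_significant")),
           combined$accession)
}

#' Rate imputation methods by q-value rank on target proteins
#'
#' For each target protein, methods are rated 1 (lowest q-value mean) to M
#' (highest); ties share the mean rating.  Per-method totals are the column
#' sums over targets, and the overall ranking orders the totals ascending.
#' Totals from several experiments can be added with [combine_ratings()].
#'
#' @param tables named list (method -> `mi_combined` table).
#' @param targets character vector of target accessions (non-empty).  A
#'   target absent from a table receives that table's worst possible
#'   q-value (rating last), with a warning.
#' @return An object of class `rank_rating`: list with `ratings` (targets x
#'   methods matrix), `totals`, and `overall` (rank of each method, 1 =
#'   best).
#' @export
rank_rating <- function(tables, targets) {
  if (!length(targets)) stop("`targets` must be non-empty")
  if (is.null(names(tables))) stop("`tables` must be a named list")
  qm <- sapply(names(tables), function(m) {
    t <- tables[[m]]
    q <- t$qmean[match(targets, t$accession)]
    if (anyNA(q))
      warning("target(s) absent from method '", m,
              "': assigned the worst rank")
    ifelse(is.na(q), Inf, q)
  })
  qm <- matrix(qm, nrow = length(targets),
               dimnames = list(targets, names(tables)))
  ratings <- t(apply(qm, 1L, rank, ties.method = "average"))
  ratings <- matrix(ratings, nrow = length(targets),
                    dimnames = dimnames(qm))
  totals <- colSums(ratings)
  structure(list(ratings = ratings, totals = totals,
                 overall = rank(totals, ties.method = "min")),
            class = "rank_rating")
}

#' Sum rank ratings across experiments
#'
#' @param ... `rank_rating` objects over the same methods.
#' @return A `rank_rating` whose totals are the element-wise sums; the
#'   `ratings` field stacks the per-experiment rating matrices.
#' @export
combine_ratings <- function(...) {
  rs <- list(...)
  methods <- names(rs[[1L]]$totals)
  for (r in rs)
    if (!identical(names(r$totals), methods))
      stop("rank ratings cover different method sets")
  totals <- Reduce(`+`, lapply(rs, `[[`, "totals"))
  structure(list(ratings = do.call(rbind, lapply(rs, `[[`, "ratings")),
                 totals = totals,
                 overall = rank(totals, ties.method = "min")),
            class = "rank_rating")
}

#' @export
print.rank_rating <- function(x, ...) {
  cat("<rank_rating> totals (lower is better):\n")
  print(x$totals)
  invisible(x)
}
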