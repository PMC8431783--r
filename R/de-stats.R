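#' Empirical-Bayes variance prior
#'
#' Prior for the moderated t-test: residual variances are shrunk towards a
#' common value `s0sq` with weight `d0` prior degrees of freedom.  `d0 = 0`
#' recovers the classical pooled t-test; `d0 = Inf` fixes every posterior
#' variance at `s0sq`.
#'
#' @param d0 prior degrees of freedom, >= 0 (`Inf` allowed).
#' @param s0sq prior variance, > 0.
#' @return An object of class `eb_prior`.
#' @export
eb_prior <- function(d0, s0sq) {
  if (d0 < 0) stop("`d0` must be >= 0")
  if (s0sq <= 0) stop("`s0sq` must be > 0")
  structure(list(d0 = d0, s0sq = s0sq), class = "eb_prior")
}

row_group_stats <- function(v, cols) {
  sub <- v[, cols, drop = FALSE]
  n <- length(cols)
  mean <- rowMeans(sub)
  var <- rowSums((sub - mean)^2) / (n - 1L)
  list(mean = mean, var = var, n = n)
}

#' Moderated t-test for a two-group comparison
#'
#' Per protein: log fold change (treatment minus reference group mean),
#' pooled residual variance, and a moderated t statistic in which the
#' residual variance is shrunk towards an empirical-Bayes prior fitted
#' across all proteins (scaled inverse-chi-square, estimated with
#' `limma::squeezeVar`).  Two-sided p-values use the total
#' (residual + prior) degrees of freedom, and are also carried through
#' Benjamini-Hochberg adjustment and Storey q-values.
#'
#' @param x a complete log2-scale [intensity_matrix()].
#' @param g a [sample_groups()] with exactly two contrast groups of >= 2
#'   samples each present in the matrix.
#' @param prior optional [eb_prior()] overriding the fitted prior (used for
#'   the `d0 = 0` / `d0 = Inf` limiting cases).
#' @param alpha significance threshold on the q-value (strict `<`).
#' @return A `DETable` data frame: `accession`, `logFC`, `t`, `df_total`,
#'   `p`, `p_adj`, `q`, `significant`.
#' @export
moderated_ttest <- function(x, g, prior = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(g, "sample_groups"))
  if (anyNA(x$values))
    stop("matrix contains missing values; impute before testing")
  if (x$scale != "log2") stop("moderated t-test expects log2 intensities")
  v <- x$values
  trt_cols <- intersect(colnames(v), group_samples(g, g$contrast[1]))
  ref_cols <- intersect(colnames(v), group_samples(g, g$contrast[2]))
  if (length(trt_cols) < 2L || length(ref_cols) < 2L)
    stop("both contrast groups need at least 2 samples in the matrix")
  st <- row_group_stats(v, trt_cols)
  sr <- row_group_stats(v, ref_cols)
  d <- st$n + sr$n - 2L
  logFC <- st$mean - sr$mean
  s2 <- ((st$n - 1L) * st$var + (sr$n - 1L) * sr$var) / d
  if (all(s2 == 0)) stop("all residual variances are zero")
  df_cap <- Inf
  if (is.null(prior)) {
    if (nrow(v) == 1L) {
      warning("single protein: no prior estimable, ordinary t-test used")
      prior <- eb_prior(0, 1)
    } else {
      sq <- limma::squeezeVar(s2, df = d)
      prior <- eb_prior(sq$df.prior, sq$var.prior)
      # with an estimated prior the total df cannot exceed the pooled
      # residual df of the whole dataset
      df_cap <- length(s2) * d
    }
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * prior$s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / st$n + 1 / sr$n))
  t <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, sign(logFC) * Inf))
  df_total <- min(d0 + d, df_cap)
  p <- 2 * pt(-abs(t), df = df_total)
  tab <- data.frame(accession = rownames(v), logFC = logFC, t = t,
                    df_total = df_total,
                    p = p, p_adj = bh_adjust(p),
                    q = suppressWarnings(qvalues(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "prior") <- prior
  decide_significant(tab, alpha)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Estimate the null proportion pi0 (Storey smoother)
#'
#' Evaluates `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over a lambda
#' grid and extrapolates a cubic smoothing spline to the largest lambda;
#' the result is clipped to (0, 1].
#'
#' @param p p-value vector (length >= 10; otherwise returns 1 with a
#'   warning).
#' @param lambda grid of tuning values in (0, 1).
#' @return Scalar estimate of the proportion of true nulls.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) < 10L) {
    warning("fewer than 10 p-values: pi0 set to 1")
    return(1)
  }
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values
#'
#' Converts p-values into q-values: the step-up FDR quantity scaled by the
#' estimated null proportion pi0, so `pi0 = 1` reproduces the
#' Benjamini-Hochberg adjustment exactly.
#'
#' @param p p-value vector in \[0, 1\].
#' @param lambda grid for [estimate_pi0()].
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values in the input order, monotone in p-value rank.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  adj <- bh_adjust(p)
  pi0 <- pi0 %||% estimate_pi0(p, lambda)
  if (pi0 <= 0 || pi0 > 1) stop("`pi0` must lie in (0, 1]")
  pmin(pi0 * adj, 1)
}

#' Call significance on a DE table
#'
#' @param tab a `DETable` (or any data frame with a `q` column).
#' @param alpha threshold; significant means `q < alpha`, strictly.
#' @return The table with its `significant` column (re)computed.
#' @export
decide_significant <- function(tab, alpha = 0.05) {
  if (is.null(tab$q)) stop("table has no `q` column")
  tab$significant <- tab$q < alpha
  tab
}

#' Write a DE table as TSV
#' @param tab a `DETable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
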