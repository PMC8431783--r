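#' Imputation parameter bundle
#'
#' Collects the tunable parameters of the seven imputation strategies so a
#' whole method can be passed around the multiple-imputation engine as one
#' object (see [impute_matrix()]).
#'
#' @param method one of `"knn"`, `"svd"`, `"mle"`, `"mindet"`, `"minprob"`,
#'   `"qrilc"`, `"hybrid"`.
#' @param k_neighbors number of donor rows for kNN (and the kNN half of the
#'   hybrid).  Default 15: with few donors the imputed values (and hence
#'   logFC) are highly variable, so a mid-teens neighbourhood is the
#'   recommended operating point.
#' @param n_components number of eigenproteins for SVD imputation.  Default
#'   6 for the same stability reason (capped at `min(dim)` at run time).
#' @param svd_tol convergence threshold on the relative change of the
#'   imputed cells between SVD iterations (default 0.01).
#' @param mindet_quantile low quantile defining the "smallest detectable
#'   intensity" for MinDet/MinProb (default 0.01).
#' @param minprob_sigma_scale width multiplier of the MinProb Gaussian.
#' @param qrilc_sigma_scale width multiplier of the QRILC truncated normal.
#' @param mle_draw draw imputations from the conditional normal (`TRUE`,
#'   stochastic) or use the conditional mean (`FALSE`, deterministic).
#' @param seed optional RNG seed applied by the individual imputer; leave
#'   `NULL` to use the ambient RNG stream (as the MI engine does).
#' @return An object of class `impute_params`.
#' @export
impute_params <- function(method = c("knn", "svd", "mle", "mindet",
                                     "minprob", "qrilc", "hybrid"),
                          k_neighbors = 15L, n_components = 6L,
                          svd_tol = 0.01, mindet_quantile = 0.01,
                          minprob_sigma_scale = 1, qrilc_sigma_scale = 1,
                          mle_draw = TRUE, seed = NULL) {
  method <- match.arg(method)
  if (k_neighbors < 1L) stop("`k_neighbors` must be >= 1")
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (svd_tol <= 0) stop("`svd_tol` must be > 0")
  if (mindet_quantile <= 0 || mindet_quantile >= 1)
    stop("`mindet_quantile` must lie in (0, 1)")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 n_components = as.integer(n_components), svd_tol = svd_tol,
                 mindet_quantile = mindet_quantile,
                 minprob_sigma_scale = minprob_sigma_scale,
                 qrilc_sigma_scale = qrilc_sigma_scale,
                 mle_draw = isTRUE(mle_draw), seed = seed),
            class = "impute_params")
}

#' MAR/MNAR model selector
#'
#' Flags each protein row for the missing-at-random (1) or left-censored
#' missing-not-at-random (0) imputation path.  The censoring threshold is
#' the quantile of the per-row mean observed log2 intensities at probability
#' equal to the overall missing-value fraction of the matrix: when x% of the
#' cells are missing, the lowest-abundance x% of proteins are treated as
#' left-censored.  `mode = "mar"` or `"mnar"` forces all flags to 1 or 0
#' (the forced-MAR mode used when running a pure MAR method).
#'
#' @param x a log2-scale [intensity_matrix()]; every row must have at least
#'   one observed value (filter first).
#' @param mode `"auto"` (quantile rule), `"mar"`, or `"mnar"`.
#' @return An object of class `model_selector_result` with fields `flags`
#'   (named 0/1 integer vector) and `threshold_log2`.
#' @export
model_selector <- function(x, mode = c("auto", "mar", "mnar")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale != "log2")
    stop("model selector expects log2-scale intensities")
  sel <- selector_impl(x$values, mode, allow_empty_rows = FALSE)
  structure(sel, class = "model_selector_result")
}

# Core selector; rows with zero observed values are only tolerated when
# allow_empty_rows = TRUE (the per-group hybrid), where they are necessarily
# flagged MNAR (a whole-group absence is the archetypal left-censored case).
selector_impl <- function(v, mode, allow_empty_rows) {
  nobs <- rowSums(!is.na(v))
  if (any(nobs == 0L) && !allow_empty_rows)
    stop("row(s) with no observed values: ",
         paste(head(rownames(v)[nobs == 0L], 5L), collapse = ", "),
         " (filter before running the model selector)")
  row_means <- rowMeans(v, na.rm = TRUE)
  miss_frac <- mean(is.na(v))
  threshold <- unname(quantile(row_means[nobs > 0L], probs = miss_frac,
                               names = FALSE))
  flags <- switch(mode,
                  auto = as.integer(row_means >= threshold),
                  mar  = rep(1L, nrow(v)),
                  mnar = rep(0L, nrow(v)))
  flags[nobs == 0L & mode != "mar"] <- 0L
  names(flags) <- rownames(v)
  list(flags = flags, threshold_log2 = threshold, mode = mode)
}

#' @export
print.model_selector_result <- function(x, ...) {
  cat(sprintf("<model_selector_result> mode=%s threshold=%.3f  MAR:%d  MNAR:%d\n",
              x$mode, x$threshold_log2, sum(x$flags == 1L),
              sum(x$flags == 0L)))
  invisible(x)
}

# Pairwise row distances: Euclidean over mutually observed columns, scaled
# by sqrt(total columns / overlap) so rows with different overlap sizes are
# comparable.  Returns Inf where the overlap is empty.
row_distances <- function(v) {
  W <- !is.na(v)
  X0 <- v
  X0[!W] <- 0
  S <- X0^2
  A <- S %*% t(W)              # sum of x_i^2 over columns observed in both
  C <- X0 %*% t(X0)
  O <- W %*% t(W)
  SS <- pmax(A + t(A) - 2 * C, 0)
  d <- sqrt(SS * ncol(v) / O)  # O == 0 -> NaN
  d[!is.finite(d)] <- Inf
  diag(d) <- Inf
  d
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the inverse-distance-weighted average of
#' the `k` most similar protein rows that are observed at that column.
#' Similarity is Euclidean distance over mutually observed columns, scaled
#' by `sqrt(total columns / overlap)`; zero distances receive weight
#' `1/eps`.  When fewer than `k` eligible donors exist the pool size is used
#' (with a warning); a cell with no eligible donor falls back to the row
#' mean (with a warning).
#'
#' @param x a log2-scale [intensity_matrix()].
#' @param k number of neighbours.
#' @param weights `"inverse"` (inverse-distance, default) or `"uniform"`.
#' @param eps floor applied to distances before inversion.
#' @return The complete [intensity_matrix()]; observed cells are untouched.
#' @export
impute_knn <- function(x, k = 15L, weights = c("inverse", "uniform"),
                       eps = 1e-10) {
  stopifnot(inherits(x, "intensity_matrix"))
  weights <- match.arg(weights)
  v <- x$values
  if (!anyNA(v)) return(x)
  if (k < 1L) stop("`k` must be >= 1")
  d <- row_distances(v)
  W <- !is.na(v)
  n_short <- 0L
  n_fallback <- 0L
  for (j in seq_len(ncol(v))) {
    donors <- which(W[, j])
    for (i in which(!W[, j])) {
      dij <- d[i, donors]
      elig <- is.finite(dij)
      if (!any(elig)) {
        mu <- mean(v[i, ], na.rm = TRUE)
        if (is.nan(mu))
          stop("no eligible neighbour and no observed value in row '",
               rownames(v)[i], "'")
        v[i, j] <- mu
        n_fallback <- n_fallback + 1L
        next
      }
      dd <- dij[elig]
      dn <- donors[elig]
      k_use <- min(k, length(dd))
      if (k_use < k) n_short <- n_short + 1L
      sel <- order(dd)[seq_len(k_use)]
      w <- if (weights == "inverse") 1 / pmax(dd[sel], eps)
           else rep(1, k_use)
      v[i, j] <- sum(w * x$values[dn[sel], j]) / sum(w)
    }
  }
  if (n_short > 0L)
    warning("k = ", k, " exceeded the eligible donor pool for ", n_short,
            " cell(s); the pool size was used")
  if (n_fallback > 0L)
    warning(n_fallback,
            " cell(s) had no eligible neighbour; row mean used")
  set_values(x, v)
}

#' Iterative SVD (eigenprotein regression) imputation
#'
#' Missing cells are initialized with row means; then the matrix is
#' repeatedly decomposed into its top `n_components` eigenproteins, each
#' incomplete row is regressed on the eigenprotein basis restricted to its
#' observed columns, and the missing cells are replaced with the fitted
#' values — until the change metric falls below `tol` (default 0.01).
#'
#' @param x a log2-scale [intensity_matrix()]; every row must have at least
#'   one observed value.
#' @param n_components number of eigenproteins (capped at `min(dim)`).
#' @param tol convergence threshold on the change metric.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @param change `"relative"` (root-sum-of-squares change of the imputed
#'   cells divided by the root-sum-of-squares of the matrix, default) or
#'   `"absolute"` (root-sum-of-squares change alone).
#' @return The complete [intensity_matrix()], with the per-iteration change
#'   metric attached as attribute `"trace"`.
#' @export
impute_svd <- function(x, n_components = 6L, tol = 0.01, max_iter = 100L,
                       change = c("relative", "absolute")) {
  stopifnot(inherits(x, "intensity_matrix"))
  change <- match.arg(change)
  v <- x$values
  if (!anyNA(v)) {
    out <- x
    attr(out, "trace") <- numeric(0)
    return(out)
  }
  n_components <- min(as.integer(n_components), nrow(v), ncol(v))
  mask <- is.na(v)
  nobs <- rowSums(!mask)
  if (any(nobs == 0L))
    stop("row(s) with no observed values cannot be SVD-imputed")
  filled <- v
  rmean <- rowMeans(v, na.rm = TRUE)
  filled[mask] <- rmean[row(v)[mask]]
  trace <- numeric(0)
  converged <- FALSE
  incomplete <- which(rowSums(mask) > 0L)
  for (iter in seq_len(max_iter)) {
    dec <- svd(filled, nu = 0L, nv = n_components)
    V <- dec$v
    old_imp <- filled[mask]
    for (i in incomplete) {
      o <- !mask[i, ]
      Vo <- V[o, , drop = FALSE]
      beta <- qr.coef(qr(Vo), v[i, o])
      beta[is.na(beta)] <- 0
      fit <- V[!o, , drop = FALSE] %*% beta
      filled[i, !o] <- fit
    }
    delta <- sqrt(sum((filled[mask] - old_imp)^2))
    metric <- if (change == "relative")
      delta / sqrt(sum(filled^2))
    else delta
    trace <- c(trace, metric)
    if (metric < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("SVD imputation did not converge in ", max_iter,
            " iterations (last change ", signif(metric, 3), ")")
  out <- set_values(x, filled)
  attr(out, "trace") <- trace
  out
}

# Multivariate-normal log-likelihood of the observed entries of each row.
obs_loglik <- function(v, mu, sigma) {
  pat <- apply(!is.na(v), 1L, paste, collapse = "")
  ll <- 0
  for (p in unique(pat)) {
    rows <- which(pat == p)
    o <- !is.na(v[rows[1L], ])
    if (!any(o)) next
    S <- sigma[o, o, drop = FALSE]
    ch <- chol(S)
    xs <- sweep(v[rows, o, drop = FALSE], 2L, mu[o])
    z <- backsolve(ch, t(xs), transpose = TRUE)
    ll <- ll + sum(-0.5 * colSums(z^2)) -
      length(rows) * (sum(log(diag(ch))) + 0.5 * sum(o) * log(2 * pi))
  }
  ll
}

#' Maximum-likelihood (EM) imputation under a multivariate normal
#'
#' Treats protein rows as i.i.d. draws from a multivariate normal over the
#' samples, estimates the mean vector and covariance by
#' expectation-maximization on the observed entries, then fills each row's
#' missing block either with a random draw from the conditional normal
#' given its observed entries (`draw = TRUE`) or with the conditional mean.
#'
#' @param x a log2-scale [intensity_matrix()] with more rows than columns.
#' @param draw stochastic conditional draws (default) or deterministic
#'   conditional means.
#' @param tol EM convergence tolerance on the observed-data log-likelihood.
#' @param max_iter EM iteration cap.
#' @param ridge diagonal regularizer added when the covariance turns
#'   numerically singular (applied with a warning).
#' @param seed optional RNG seed for draw mode.
#' @return The complete [intensity_matrix()]; the fitted parameters are
#'   attached as attribute `"mvn_params"` (fields `mu`, `sigma`).
#' @export
impute_mle <- function(x, draw = TRUE, tol = 1e-4, max_iter = 100L,
                       ridge = 1e-6, seed = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  n <- nrow(v)
  p <- ncol(v)
  if (n <= p)
    stop("MLE imputation needs more rows than columns (", n, " x ", p, ")")
  if (!is.null(seed)) set.seed(seed)
  mask <- is.na(v)
  # init: column means / complete-row covariance (fallback diagonal)
  mu <- colMeans(v, na.rm = TRUE)
  cc <- complete.cases(v)
  sigma <- if (sum(cc) > p) cov(v[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
           else diag(apply(v, 2L, var, na.rm = TRUE), p)
  ridged <- FALSE
  regularize <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < ridge * max(ev)) {
      ridged <<- TRUE
      S <- S + diag(ridge * max(ev, 1), nrow(S))
    }
    S
  }
  sigma <- regularize(sigma)
  if (!anyNA(v)) {
    out <- x
    attr(out, "mvn_params") <- list(mu = mu, sigma = sigma)
    return(out)
  }
  pat <- apply(!mask, 1L, paste, collapse = "")
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    Ex <- v
    Sxx <- matrix(0, p, p)
    for (pt in unique(pat)) {
      rows <- which(pat == pt)
      o <- !mask[rows[1L], ]
      m <- !o
      if (any(m)) {
        Soo <- regularize(sigma[o, o, drop = FALSE])
        B <- sigma[m, o, drop = FALSE] %*% solve(Soo)
        cond_cov <- sigma[m, m, drop = FALSE] -
          B %*% sigma[o, m, drop = FALSE]
        xs <- sweep(v[rows, o, drop = FALSE], 2L, mu[o])
        Ex[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
          xs %*% t(B)
        Sxx[m, m] <- Sxx[m, m] + length(rows) * cond_cov
      }
    }
    mu_new <- colMeans(Ex)
    xc <- sweep(Ex, 2L, mu_new)
    sigma_new <- (crossprod(xc) + Sxx) / n
    sigma_new <- regularize((sigma_new + t(sigma_new)) / 2)
    mu <- mu_new
    sigma <- sigma_new
    ll <- obs_loglik(v, mu, sigma)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (ridged)
    warning("near-singular covariance during EM; ridge regularization applied")
  filled <- v
  for (pt in unique(pat)) {
    rows <- which(pat == pt)
    o <- !mask[rows[1L], ]
    m <- !o
    if (!any(m)) next
    if (any(o)) {
      Soo <- regularize(sigma[o, o, drop = FALSE])
      B <- sigma[m, o, drop = FALSE] %*% solve(Soo)
      cond_cov <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
    } else {
      B <- NULL
      cond_cov <- sigma[m, m, drop = FALSE]
    }
    ch <- chol(regularize((cond_cov + t(cond_cov)) / 2))
    for (i in rows) {
      em <- if (is.null(B)) mu[m]
            else mu[m] + drop(B %*% (v[i, o] - mu[o]))
      filled[i, m] <- if (draw) em + drop(t(ch) %*% rnorm(sum(m))) else em
    }
  }
  out <- set_values(x, filled)
  attr(out, "mvn_params") <- list(mu = mu, sigma = sigma)
  out
}

# Per-sample (or global) low-quantile "smallest detectable intensity".
mindet_centers <- function(v, q, mode) {
  obs_all <- v[!is.na(v)]
  if (length(obs_all) == 0L) stop("matrix has no observed values")
  global <- unname(quantile(obs_all, probs = q, names = FALSE))
  if (mode == "global") return(rep(global, ncol(v)))
  centers <- numeric(ncol(v))
  empty <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    obs <- v[!is.na(v[, j]), j]
    if (length(obs) == 0L) {
      centers[j] <- global
      empty[j] <- TRUE
    } else {
      centers[j] <- unname(quantile(obs, probs = q, names = FALSE))
    }
  }
  if (any(empty))
    warning("column(s) with no observed values fell back to the global ",
            "MinDet quantile: ", paste(colnames(v)[empty], collapse = ", "))
  centers
}

#' Deterministic minimum (MinDet) imputation
#'
#' Replaces every missing cell with the "smallest detectable intensity":
#' the `q`-quantile of the observed values of its sample column (default),
#' or of the whole dataset in global mode.  Fully deterministic — repeated
#' calls are bitwise identical, so the across-iteration spread of any
#' downstream statistic is exactly zero.
#'
#' @param x a log2-scale [intensity_matrix()].
#' @param q low quantile in (0, 1) (default 0.01).
#' @param mode `"sample"` (per column, default) or `"global"`.
#' @return The complete [intensity_matrix()].
#' @export
impute_mindet <- function(x, q = 0.01, mode = c("sample", "global")) {
  stopifnot(inherits(x, "intensity_matrix"))
  mode <- match.arg(mode)
  v <- x$values
  if (!anyNA(v)) return(x)
  centers <- mindet_centers(v, q, mode)
  for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- centers[j]
  set_values(x, v)
}

#' Probabilistic minimum (MinProb) imputation
#'
#' Like MinDet, but each missing cell is a random draw from a Gaussian
#' centred on the MinDet value of its sample, with standard deviation
#' `sigma_scale` times a robust spread estimate (the median of the per-row
#' observed standard deviations).  As `sigma_scale` tends to 0 the output
#' tends to the MinDet output.
#'
#' @inheritParams impute_mindet
#' @param sigma_scale Gaussian width multiplier (default 1).
#' @param seed optional RNG seed.
#' @return The complete [intensity_matrix()].
#' @export
impute_minprob <- function(x, q = 0.01, sigma_scale = 1,
                           mode = c("sample", "global"), seed = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  mode <- match.arg(mode)
  v <- x$values
  if (!anyNA(v)) return(x)
  if (!is.null(seed)) set.seed(seed)
  centers <- mindet_centers(v, q, mode)
  row_sds <- apply(v, 1L, sd, na.rm = TRUE)
  spread <- median(row_sds[rowSums(!is.na(v)) >= 2L], na.rm = TRUE)
  if (!is.finite(spread) || spread == 0) {
    warning("spread estimate is zero/undefined; MinProb draws degenerate ",
            "to the MinDet centers")
    spread <- 0
  }
  for (j in seq_len(ncol(v))) {
    mis <- which(is.na(v[, j]))
    if (length(mis))
      v[mis, j] <- rnorm(length(mis), mean = centers[j],
                         sd = sigma_scale * spread)
  }
  set_values(x, v)
}

# Fit the uncensored normal of one sample column by least squares on
# normal Q-Q points over the probability range (pi + eps, 1 - eps).
qrilc_fit <- function(obs, pi_j, eps = 0.001, n_grid = 100L) {
  pr <- seq(pi_j + eps, 1 - eps, length.out = n_grid)
  xq <- qnorm(pr)
  yq <- unname(quantile(obs, probs = (pr - pi_j) / (1 - pi_j), names = FALSE))
  slope <- cov(xq, yq) / var(xq)
  mu <- mean(yq) - slope * mean(xq)
  if (!is.finite(slope) || slope <= 0) {
    warning("QRILC slope estimate non-positive; falling back to the ",
            "observed standard deviation")
    slope <- sd(obs)
    mu <- mean(obs)
  }
  c(mu = mu, sigma = slope)
}

#' Quantile regression imputation of left-censored data (QRILC)
#'
#' Per sample column: the observed values are treated as the upper
#' (1 - pi) tail of an underlying normal, where pi is the column's missing
#' fraction.  The uncensored mean and standard deviation are estimated by
#' ordinary least squares of the empirical quantiles against standard-normal
#' quantiles over the probability range (pi + 0.001, 0.999); missing cells
#' are then drawn from that normal truncated above at its pi-quantile
#' `mu + sigma * qnorm(pi)`, i.e. from the left-censored tail.
#'
#' @param x a log2-scale [intensity_matrix()]; each column needs at least 4
#'   observed values (otherwise an error, unless `fit_matrix` provides a
#'   fallback).
#' @param sigma_scale truncated-normal width multiplier (default 1).
#' @param seed optional RNG seed.
#' @param eps probability-grid margin.
#' @param n_grid number of grid points for the quantile regression.
#' @param fit_matrix optional numeric matrix with the same columns; when a
#'   column of `x` has fewer than 4 observed values, the censored normal is
#'   fitted from the corresponding column of `fit_matrix` instead (used by
#'   the per-group hybrid, where the MNAR-flagged subset can be small).
#' @return The complete [intensity_matrix()].
#' @export
impute_qrilc <- function(x, sigma_scale = 1, seed = NULL, eps = 0.001,
                         n_grid = 100L, fit_matrix = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (!anyNA(v)) return(x)
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(v))) {
    mis <- which(is.na(v[, j]))
    if (!length(mis)) next
    pi_j <- length(mis) / nrow(v)
    if (pi_j >= 1)
      stop("column '", colnames(v)[j], "' is fully missing")
    obs <- v[-mis, j]
    if (length(obs) < 4L) {
      if (is.null(fit_matrix))
        stop("column '", colnames(v)[j], "' has only ", length(obs),
             " observed value(s); at least 4 are needed for the quantile ",
             "regression")
      fo <- fit_matrix[, j]
      fo <- fo[!is.na(fo)]
      if (length(fo) < 4L)
        stop("fallback fit column '", colnames(v)[j],
             "' also has fewer than 4 observed values")
      warning("column '", colnames(v)[j], "' has fewer than 4 observed ",
              "values in the imputed subset; censored normal fitted from ",
              "the full column")
      fit <- qrilc_fit(fo, mean(is.na(fit_matrix[, j])), eps, n_grid)
    } else {
      fit <- qrilc_fit(obs, pi_j, eps, n_grid)
    }
    mu <- fit[["mu"]]
    sig <- fit[["sigma"]]
    upper <- mu + sig * qnorm(max(pi_j, .Machine$double.eps))
    sd_draw <- sigma_scale * sig
    if (sd_draw <= 0) {
      v[mis, j] <- upper
    } else {
      a <- pnorm((upper - mu) / sd_draw)
      u <- runif(length(mis), 0, a)
      u <- pmax(u, .Machine$double.xmin)
      v[mis, j] <- mu + sd_draw * qnorm(u)
    }
  }
  set_values(x, v)
}

#' Per-group MAR/MNAR hybrid (SFI-hybrid) imputation
#'
#' The workflow's combinatorial strategy: within each treatment group's
#' column block independently, the [model_selector()] flags each protein
#' MAR or MNAR from that block alone; MAR-flagged rows are imputed with kNN
#' (donors restricted to the MAR-flagged subset) and MNAR-flagged rows with
#' QRILC, then the blocks are reassembled.  A row entirely missing within a
#' group — the presence/absence case — is flagged MNAR and drawn from that
#' group's left-censored tail only; its other group is untouched.
#'
#' @param x a log2-scale [intensity_matrix()] restricted to the contrast
#'   samples (see [select_groups()]).
#' @param g a [sample_groups()] covering the matrix columns.
#' @param k neighbours for the kNN half.
#' @param sigma_scale width multiplier for the QRILC half.
#' @param selector_mode passed to the model selector (`"auto"` default).
#' @param seed optional RNG seed.
#' @return The complete [intensity_matrix()], with the per-group selector
#'   results attached as attribute `"selectors"` (a named list).
#' @export
impute_hybrid <- function(x, g, k = 15L, sigma_scale = 1,
                          selector_mode = c("auto", "mar", "mnar"),
                          seed = NULL) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(g, "sample_groups"))
  selector_mode <- match.arg(selector_mode)
  if (x$scale != "log2") stop("hybrid imputation expects log2 intensities")
  if (!is.null(seed)) set.seed(seed)
  v <- x$values
  selectors <- list()
  labs <- unique(g$assignment[colnames(v)])
  for (lab in labs) {
    cols <- intersect(colnames(v), group_samples(g, lab))
    block <- v[, cols, drop = FALSE]
    sel <- withCallingHandlers(
      selector_impl(block, selector_mode, allow_empty_rows = TRUE),
      error = function(e) stop("group '", lab, "': ", conditionMessage(e)))
    selectors[[lab]] <- structure(sel, class = "model_selector_result")
    mar_rows <- which(sel$flags == 1L)
    mnar_rows <- which(sel$flags == 0L)
    tryCatch({
      if (length(mar_rows) && anyNA(block[mar_rows, , drop = FALSE])) {
        sub <- intensity_matrix(block[mar_rows, , drop = FALSE], "log2")
        imp <- impute_knn(sub, k = max(1L, min(k, length(mar_rows) - 1L)))
        block[mar_rows, ] <- imp$values
      }
      if (length(mnar_rows) && anyNA(block[mnar_rows, , drop = FALSE])) {
        sub <- intensity_matrix(block[mnar_rows, , drop = FALSE], "log2")
        imp <- impute_qrilc(sub, sigma_scale = sigma_scale,
                            fit_matrix = block)
        block[mnar_rows, ] <- imp$values
      }
    }, error = function(e) stop("group '", lab, "': ",
                                conditionMessage(e), call. = FALSE))
    v[, cols] <- block
  }
  out <- set_values(x, v)
  attr(out, "selectors") <- selectors
  out
}

#' Impute with a parameter bundle
#'
#' Dispatches to the individual imputer named by `params$method`; this is
#' the entry point the multiple-imputation engine uses.
#'
#' @param x a log2-scale [intensity_matrix()].
#' @param params an [impute_params()].
#' @param g a [sample_groups()]; required for the hybrid method.
#' @return The complete [intensity_matrix()].
#' @export
impute_matrix <- function(x, params, g = NULL) {
  stopifnot(inherits(params, "impute_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  switch(params$method,
    knn     = impute_knn(x, k = params$k_neighbors),
    svd     = impute_svd(x, n_components = params$n_components,
                         tol = params$svd_tol),
    mle     = impute_mle(x, draw = params$mle_draw),
    mindet  = impute_mindet(x, q = params$mindet_quantile),
    minprob = impute_minprob(x, q = params$mindet_quantile,
                             sigma_scale = params$minprob_sigma_scale),
    qrilc   = impute_qrilc(x, sigma_scale = params$qrilc_sigma_scale),
    hybrid  = {
      if (is.null(g))
        stop("hybrid imputation requires a `sample_groups` design")
      impute_hybrid(x, g, k = params$k_neighbors,
                    sigma_scale = params$qrilc_sigma_scale)
    })
}

#' Per-cell imputation provenance table
#'
#' @param before the matrix before imputation.
#' @param after the complete matrix after imputation.
#' @param method method label to record.
#' @return Data frame with one row per cell that was imputed: `accession`,
#'   `sample`, `value`, `method`.
#' @export
provenance_table <- function(before, after, method = "unknown") {
  mask <- missing_mask(before)
  idx <- which(mask, arr.ind = TRUE)
  data.frame(accession = rownames(before$values)[idx[, 1L]],
             sample = colnames(before$values)[idx[, 2L]],
             value = after$values[mask],
             method = method,
             stringsAsFactors = FALSE)
}
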