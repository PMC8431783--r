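#' Multiple-imputation configuration
#'
#' Settings of the multiple-imputation loop: the matrix is imputed,
#' quantile-normalized and tested `m` times (default 25), each iteration
#' with its own RNG seed (`base_seed + i`, so any single iteration can be
#' re-run in isolation).  For kNN and SVD, `vary_k = TRUE` ties the number
#' of neighbours / eigenproteins to the iteration index (iteration 10 uses
#' 10 neighbours or components, capped at the matrix limits), so the loop
#' sweeps the method's own tuning parameter instead of re-drawing noise.
#'
#' @param m number of iterations, >= 1.
#' @param params an [impute_params()] naming the method.
#' @param vary_k vary `k`/`n_components` with the iteration index for
#'   kNN/SVD (default `TRUE`; ignored for other methods).
#' @param base_seed integer base RNG seed; iteration `i` uses
#'   `base_seed + i`.
#' @param alpha significance threshold applied after combination.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(m = 25L, params = impute_params("hybrid"),
                      vary_k = TRUE, base_seed = 1L, alpha = 0.05) {
  if (m < 1L) stop("`m` must be >= 1")
  stopifnot(inherits(params, "impute_params"))
  structure(list(m = as.integer(m), params = params,
                 vary_k = isTRUE(vary_k), base_seed = as.integer(base_seed),
                 alpha = alpha),
            class = "mi_config")
}

#' Run the multiple-imputation loop
#'
#' For each iteration: seed the RNG, impute the matrix with the configured
#' method, quantile-normalize, and run the moderated t-test; the `m`
#' per-iteration DE tables are returned for [combine_mi()].  Any iteration
#' failure aborts with the iteration index and cause.
#'
#' @param x a filtered log2-scale [intensity_matrix()] restricted to the
#'   contrast samples.
#' @param g a [sample_groups()].
#' @param cfg an [mi_config()].
#' @return A list of `m` DE tables, with the per-iteration seeds attached
#'   as attribute `"seeds"`.
#' @export
run_mi <- function(x, g, cfg) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(g, "sample_groups"),
            inherits(cfg, "mi_config"))
  if (x$scale != "log2") stop("run_mi expects log2 intensities")
  seeds <- cfg$base_seed + seq_len(cfg$m)
  tables <- vector("list", cfg$m)
  for (i in seq_len(cfg$m)) {
    p_i <- cfg$params
    if (cfg$vary_k && p_i$method == "knn")
      p_i$k_neighbors <- max(1L, min(i, nrow(x$values) - 1L))
    if (cfg$vary_k && p_i$method == "svd")
      p_i$n_components <- max(1L, min(i, nrow(x$values), ncol(x$values)))
    set.seed(seeds[i])
    tables[[i]] <- tryCatch({
      imputed <- impute_matrix(x, p_i, g)
      normalized <- quantile_normalize(imputed)
      suppressWarnings(moderated_ttest(normalized, g, alpha = cfg$alpha))
    }, error = function(e) {
      stop("MI iteration ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  attr(tables, "seeds") <- seeds
  tables
}

#' Combine multiple-imputation DE tables
#'
#' Across-iteration combination by plain means (the workflow's procedure,
#' deliberately not Rubin's rules): per protein, the mean and sample SD of
#' logFC and of -log10 q, and the mean q-value.  Proteins are ranked
#' ascending by q-value mean (ties broken by accession) and called
#' significant when the q-value mean is strictly below `alpha`.  When the
#' pre-imputation mask and design are supplied, each protein's missingness
#' bin (see [bin_missingness()]) is attached.
#'
#' @param tables list of DE tables sharing one protein index (from
#'   [run_mi()]).
#' @param mask optional pre-imputation logical mask (see [missing_mask()]).
#' @param g optional [sample_groups()], required with `mask`.
#' @param alpha significance threshold on the q-value mean.
#' @return An `mi_combined` data frame sorted by rank: `accession`,
#'   `logfc_mean`, `logfc_sd`, `neglog10q_mean`, `neglog10q_sd`, `qmean`,
#'   `rank`, `significant` and (optionally) `missing_bin`.
#' @export
combine_mi <- function(tables, mask = NULL, g = NULL, alpha = 0.05) {
  if (!length(tables)) stop("no DE tables to combine")
  acc <- tables[[1L]]$accession
  for (t in tables)
    if (!identical(t$accession, acc))
      stop("DE tables do not share the same protein index")
  L <- vapply(tables, function(t) t$logFC, numeric(length(acc)))
  Q <- vapply(tables, function(t) t$q, numeric(length(acc)))
  L <- matrix(L, nrow = length(acc))
  Q <- matrix(Q, nrow = length(acc))
  NQ <- -log10(pmax(Q, .Machine$double.xmin))
  sd0 <- function(m) {
    s <- apply(m, 1L, sd)
    ifelse(is.na(s), 0, s)
  }
  out <- data.frame(accession = acc,
                    logfc_mean = rowMeans(L), logfc_sd = sd0(L),
                    neglog10q_mean = rowMeans(NQ), neglog10q_sd = sd0(NQ),
                    qmean = rowMeans(Q),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(out$qmean, out$accession)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$qmean < alpha
  if (!is.null(mask)) {
    if (is.null(g)) stop("`g` is required to bin missingness")
    bins <- bin_missingness(mask, g)
    out$missing_bin <- bins[out$accession]
  }
  rownames(out) <- NULL
  class(out) <- c("mi_combined", "data.frame")
  out
}

#' Write a combined MI table as TSV
#' @param x an `mi_combined` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mi_combined <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
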