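# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

# log2-scale matrix: protein baselines N(mean, sd), replicate noise, MCAR
# missingness; every row keeps at least one observed value.
make_log2_matrix <- function(n, p = 6L, missing = 0.1, seed = 1L,
                             mean = 20, sd = 2, noise = 0.5) {
  set.seed(seed)
  base <- rnorm(n, mean, sd)
  v <- matrix(rnorm(n * p, mean = base, sd = noise), n, p)
  dimnames(v) <- list(sprintf("P%03d", seq_len(n)), paste0("S", seq_len(p)))
  if (missing > 0) {
    v[sample(n * p, round(missing * n * p))] <- NA
    dead <- which(rowSums(!is.na(v)) == 0L)
    for (i in dead) v[i, 1L] <- rnorm(1, base[i], noise)
  }
  intensity_matrix(v, "log2")
}

make_raw_matrix <- function(n, p = 6L, missing = 0.1, seed = 1L) {
  m <- make_log2_matrix(n, p, missing, seed)
  intensity_matrix(2^m$values, "raw")
}

two_groups <- function(p = 6L, labels = c("trt", "ctl"),
                       samples = paste0("S", seq_len(p))) {
  sample_groups(setNames(rep(labels, each = p / 2), samples),
                contrast = labels)
}

# Independent brute-force kNN oracle: literal nested-loop neighbour search
# with the same distance definition, kept free of the package's vectorized
# path.
brute_knn <- function(v, k, eps = 1e-10) {
  n <- nrow(v)
  p <- ncol(v)
  out <- v
  for (i in seq_len(n)) for (j in seq_len(p)) if (is.na(v[i, j])) {
    ds <- rep(Inf, n)
    for (r in seq_len(n)) if (r != i && !is.na(v[r, j])) {
      sh <- which(!is.na(v[i, ]) & !is.na(v[r, ]))
      if (length(sh))
        ds[r] <- sqrt(sum((v[i, sh] - v[r, sh])^2) * p / length(sh))
    }
    elig <- which(is.finite(ds))
    sel <- elig[order(ds[elig])][seq_len(min(k, length(elig)))]
    w <- 1 / pmax(ds[sel], eps)
    out[i, j] <- sum(w * v[sel, j]) / sum(w)
  }
  out
}

# Hand step-up BH for the dual-route check.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (idx in seq_len(n)) {
    i <- o[idx]
    adj[i] <- min(vapply(idx:n, function(jdx) {
      j <- o[jdx]
      min(p[j] * n / jdx, 1)
    }, numeric(1)))
  }
  adj
}
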