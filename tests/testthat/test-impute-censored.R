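test_that("MinDet replaces missing cells with the per-sample low quantile", {
  v <- rbind(P1 = c(5, NA), P2 = c(7, 10), P3 = c(NA, 12))
  colnames(v) <- c("S1", "S2")
  out <- impute_mindet(intensity_matrix(v, "log2"), q = 0)
  expect_equal(out$values["P3", "S1"], 5)
  expect_equal(out$values["P1", "S2"], 10)

  gl <- impute_mindet(intensity_matrix(v, "log2"), q = 0, mode = "global")
  expect_equal(gl$values["P3", "S1"], 5)
  expect_equal(gl$values["P1", "S2"], 5)
})

test_that("MinDet is bitwise deterministic across repeated calls", {
  m <- make_log2_matrix(40, 6, 0.15, seed = 21)
  a <- impute_mindet(m)
  b <- impute_mindet(m)
  expect_identical(a$values, b$values)
})

test_that("MinProb degenerates to MinDet as sigma_scale tends to zero", {
  m <- make_log2_matrix(40, 6, 0.15, seed = 22)
  md <- impute_mindet(m, q = 0.01)
  mp <- impute_minprob(m, q = 0.01, sigma_scale = 0, seed = 1)
  expect_equal(mp$values, md$values, tolerance = 1e-12)
})

test_that("MinProb draws are centred on the MinDet value", {
  set.seed(23)
  n <- 20000
  v <- cbind(A = rnorm(n, 20, 2), B = rnorm(n, 20, 2))
  rownames(v) <- sprintf("P%05d", seq_len(n))
  mis <- sample(n, 10000)
  v[mis, "B"] <- NA
  m <- intensity_matrix(v, "log2")
  center <- quantile(v[-mis, "B"], 0.01, names = FALSE)
  out <- impute_minprob(m, q = 0.01, sigma_scale = 1, seed = 5)
  draws <- out$values[mis, "B"]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - center), 3 * se)
})

test_that("MinProb honours its seeding contract", {
  m <- make_log2_matrix(30, 6, 0.2, seed = 24)
  mask <- missing_mask(m)
  a <- impute_minprob(m, seed = 7)
  b <- impute_minprob(m, seed = 7)
  c <- impute_minprob(m, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values[mask], c$values[mask]))
  expect_identical(a$values[!mask], m$values[!mask])
})

test_that("QRILC draws stay in the left-censored tail", {
  set.seed(25)
  n <- 400
  v <- matrix(rnorm(n * 3, 20, 2), n, 3,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              paste0("S", 1:3)))
  # censor the lowest 20% of column 1 so the pi-quantile sits below the
  # observed minimum
  cut <- quantile(v[, 1], 0.2)
  mis <- which(v[, 1] < cut)
  v[mis, 1] <- NA
  m <- intensity_matrix(v, "log2")
  out <- impute_qrilc(m, seed = 1)
  expect_true(all(out$values[mis, 1] < min(v[, 1], na.rm = TRUE)))
  # complete columns are untouched
  expect_identical(out$values[, 2], v[, 2])
  expect_identical(out$values[, 3], v[, 3])
})

test_that("QRILC recovers the uncensored normal parameters", {
  fits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    x <- rnorm(1000, 20, 2)
    x[x < quantile(x, 0.2)] <- NA
    v <- cbind(A = x, B = rnorm(1000, 20, 2))
    rownames(v) <- sprintf("P%04d", 1:1000)
    m <- intensity_matrix(v, "log2")
    out <- impute_qrilc(m)
    # recompute the fitted parameters from the observed tail directly
    obs <- x[!is.na(x)]
    pr <- seq(0.2 + 0.001, 0.999, length.out = 100)
    xq <- qnorm(pr)
    yq <- quantile(obs, probs = (pr - 0.2) / 0.8, names = FALSE)
    slope <- cov(xq, yq) / var(xq)
    c(mu = mean(yq) - slope * mean(xq), sigma = slope)
  }, numeric(2))
  expect_lt(abs(mean(fits["mu", ]) - 20) / 20, 0.05)
  expect_lt(abs(mean(fits["sigma", ]) - 2) / 2, 0.05)
})

test_that("QRILC rejects columns with too few observations", {
  v <- rbind(P1 = c(1, 20), P2 = c(NA, 21), P3 = c(2, 22), P4 = c(NA, 23),
             P5 = c(3, 24))
  colnames(v) <- c("S1", "S2")
  expect_error(impute_qrilc(intensity_matrix(v, "log2")), "at least 4")
})

test_that("hybrid with a forced-MAR selector equals per-group kNN", {
  m <- make_log2_matrix(30, 6, 0.1, seed = 26)
  g <- two_groups()
  hy <- suppressWarnings(
    impute_hybrid(m, g, k = 3, selector_mode = "mar", seed = 1))
  manual <- m$values
  for (lab in c("trt", "ctl")) {
    cols <- names(g$assignment)[g$assignment == lab]
    block <- suppressWarnings(
      impute_knn(intensity_matrix(m$values[, cols], "log2"), k = 3))
    manual[, cols] <- block$values
  }
  expect_equal(hy$values, manual)
})

test_that("hybrid imputes MNAR-flagged rows below the censoring threshold", {
  set.seed(27)
  n <- 60
  low <- 49:60  # 12 low-abundance rows, well separated from the rest
  base <- c(rnorm(48, 21, 0.5), rnorm(12, 14, 0.3))
  v <- matrix(rnorm(n * 6, base, 0.3), n, 6,
              dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:6)))
  # 25% missingness in the trt block so the selector's censoring threshold
  # clears the whole low group: each low row and 33 high rows lose one cell
  for (j in seq_along(low)) v[low[j], ((j - 1) %% 3) + 1] <- NA
  for (i in 1:33) v[i, ((i - 1) %% 3) + 1] <- NA
  m <- intensity_matrix(v, "log2")
  g <- two_groups()
  hy <- impute_hybrid(m, g, k = 5, seed = 2)
  sel_trt <- attr(hy, "selectors")[["trt"]]
  expect_true(all(sel_trt$flags[low] == 0L))
  imputed_low <- hy$values[low, 1:3][is.na(v[low, 1:3])]
  expect_true(all(imputed_low < sel_trt$threshold_log2))
  expect_false(anyNA(hy$values))
})

test_that("hybrid keeps per-group isolation for whole-group absences", {
  set.seed(28)
  n <- 40
  v <- matrix(rnorm(n * 6, 20, 1), n, 6,
              dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:6)))
  v[1, 1:3] <- NA  # protein absent from the whole trt group
  m <- intensity_matrix(v, "log2")
  g <- two_groups()
  hy <- suppressWarnings(impute_hybrid(m, g, k = 5, seed = 3))
  expect_false(anyNA(hy$values))
  # untouched where observed, including the full ctl block of row 1
  expect_identical(hy$values[1, 4:6], v[1, 4:6])
  # the absent group is drawn from the trt group's left tail
  expect_true(all(hy$values[1, 1:3] < mean(v[-1, 1:3])))
})
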