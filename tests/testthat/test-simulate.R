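test_that("template simulation draws from per-group observed moments", {
  v <- rbind(P1 = c(10, 10, 10, 20, 21, 22),
             P2 = c(15, NA, NA, 18, 19, 20),
             P3 = c(NA, NA, NA, 25, 26, 27))
  colnames(v) <- paste0("S", 1:6)
  g <- two_groups()
  template <- intensity_matrix(v, "log2")
  sim <- suppressWarnings(
    simulate_from_template(template, g, n_replicates = 3, seed = 1))
  sv <- sim$values
  # degenerate SD: constant observed group reproduces exactly
  expect_true(all(sv["P1", 1:3] == 10))
  # single observed value is replicated with SD 0 (warned)
  expect_warning(simulate_from_template(template, g, 3, seed = 2),
                 "single observed")
  expect_true(all(sv["P2", 1:3] == 15))
  # fully missing group stays fully missing
  expect_true(all(is.na(sv["P3", 1:3])))
  expect_true(all(!is.na(sv["P3", 4:6])))
  expect_identical(unname(attr(sim, "groups")),
                   rep(c("trt", "ctl"), each = 3))
})

test_that("template simulation recovers template moments at scale", {
  template <- make_log2_matrix(300, 6, 0, seed = 61)
  g <- two_groups()
  k <- 40
  sim <- simulate_from_template(template, g, n_replicates = k, seed = 62)
  trt_cols <- grep("^trt", colnames(sim$values))
  mu_t <- rowMeans(template$values[, 1:3])
  sd_t <- apply(template$values[, 1:3], 1L, sd)
  mu_s <- rowMeans(sim$values[, trt_cols])
  z <- (mu_s - mu_t) / (sd_t / sqrt(k))
  expect_gt(mean(abs(z) < 3), 0.95)
  sd_s <- apply(sim$values[, trt_cols], 1L, sd)
  expect_lt(median(abs(sd_s - sd_t) / sd_t), 0.25)
})

test_that("amputation respects mechanisms, proportions, and eligibility", {
  m <- make_log2_matrix(200, 6, 0, seed = 63)
  # identity at 0:0
  out0 <- ampute(m, ampute_config(0, 0))
  expect_identical(out0$matrix$values, m$values)
  expect_true(all(out0$mechanism == "observed"))

  # pure MNAR at proportion 1: every eligible row loses exactly one cell
  set.seed(1)
  out1 <- ampute(m, ampute_config(prop_mar = 0, prop_mnar = 1))
  lost <- rowSums(is.na(out1$matrix$values))
  expect_true(all(lost == 1L))
  masked_vals <- m$values[is.na(out1$matrix$values)]
  kept_vals <- m$values[!is.na(out1$matrix$values)]
  expect_lt(mean(masked_vals), mean(kept_vals))

  # already-missing cells are never re-masked, survivors never change
  m2 <- make_log2_matrix(200, 6, 0.1, seed = 64)
  pre <- missing_mask(m2)
  set.seed(2)
  out2 <- ampute(m2, ampute_config(0.5, 0.5))
  expect_true(all(out2$mechanism[pre] == "missing"))
  post <- missing_mask(out2$matrix)
  expect_identical(out2$matrix$values[!post], m2$values[!post])
  # amputation only touched previously complete rows
  touched <- rowSums(post & !pre) > 0
  expect_true(all(rowSums(pre)[touched] == 0))
})

test_that("a 0.5:0.5 mixture hits its expected missingness and contrasts mechanisms", {
  m <- make_log2_matrix(800, 6, 0, seed = 65)
  set.seed(3)
  out <- ampute(m, ampute_config(0.5, 0.5))
  n_masked_rows <- sum(rowSums(is.na(out$matrix$values)) > 0)
  expected <- 800 * 0.5
  band <- 3 * sqrt(800 * 0.5 * 0.5)
  expect_lt(abs(n_masked_rows - expected), band)
  mnar_vals <- m$values[out$mechanism == "MNAR"]
  mar_vals <- m$values[out$mechanism == "MAR"]
  expect_lt(wilcox.test(mnar_vals, mar_vals,
                        alternative = "less")$p.value, 0.01)
  # mechanism labels reproduce their own semantics
  expect_lt(mean(mnar_vals), mean(m$values))
})

test_that("ground-truth generation is seeded, labelled, and configurable", {
  gt1 <- generate_ground_truth(n_proteins = 100, seed = 5)
  gt2 <- generate_ground_truth(n_proteins = 100, seed = 5)
  expect_identical(gt1$complete$values, gt2$complete$values)
  expect_identical(gt1$amputed$values, gt2$amputed$values)
  expect_identical(gt1$mechanism, gt2$mechanism)
  expect_identical(gt1$truth, gt2$truth)
  expect_identical(gt1$truth$de, gt1$truth$effect != 0)

  gt0 <- generate_ground_truth(n_proteins = 100, frac_de = 0, seed = 6)
  expect_false(any(gt0$truth$de))
  expect_error(generate_ground_truth(n_proteins = 10), ">= 50")
})

test_that("a near-noiseless complete fixture is perfectly separable", {
  gt <- generate_ground_truth(n_proteins = 150, frac_de = 0.2,
                              noise_sd = 0.01,
                              ampute_cfg = ampute_config(0, 0), seed = 7)
  # checked without quantile normalization (which by construction distorts
  # near-noiseless data with large asymmetric effects), and at a stringent
  # threshold, since at q < 0.05 an FDR procedure is expected to admit ~5%
  # false calls
  tab <- suppressWarnings(
    moderated_ttest(gt$complete, gt$groups, alpha = 1e-6))
  called <- tab$accession[tab$significant]
  strong <- gt$truth$accession[abs(gt$truth$effect) > 0.1]
  weak_null <- gt$truth$accession[gt$truth$effect == 0]
  expect_true(all(strong %in% called))
  expect_false(any(weak_null %in% called))
})

test_that("ground-truth bundles round-trip through disk", {
  gt <- generate_ground_truth(n_proteins = 60, seed = 8)
  dir <- withr::local_tempdir()
  write_ground_truth(gt, dir, config = list(seed = 8))
  expect_true(all(file.exists(file.path(dir,
    c("complete.tsv", "amputed.tsv", "truth.tsv", "mechanism.tsv",
      "groups.tsv", "replay.yaml")))))
  back <- read_ground_truth(dir)
  expect_equal(back$complete$values, gt$complete$values)
  expect_equal(back$amputed$values, gt$amputed$values)
  expect_identical(back$mechanism, gt$mechanism)
  expect_equal(back$truth$effect, gt$truth$effect)
  expect_identical(back$groups$contrast, gt$groups$contrast)
})
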