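test_that("capture rate is the recovered percentage of the truth set", {
  truth <- paste0("P", 1:10)
  expect_equal(capture_rate(truth, paste0("P", 1:5)), 50)
  expect_equal(capture_rate(truth, truth), 100)
  expect_equal(capture_rate(truth, paste0("X", 1:4)), 0)
  expect_error(capture_rate(character(0), "P1"), "empty")
  # monotone in the observed set
  expect_lte(capture_rate(truth, paste0("P", 1:3)),
             capture_rate(truth, paste0("P", 1:7)))
})

test_that("missingness bins follow the one-group / both-groups rule", {
  mk <- function(c1, c2) {
    mask <- matrix(FALSE, 1, 6, dimnames = list("P1", paste0("S", 1:6)))
    if (c1 > 0) mask[1, seq_len(c1)] <- TRUE
    if (c2 > 0) mask[1, 3 + seq_len(c2)] <- TRUE
    bin_missingness(mask, two_groups())[["P1"]]
  }
  expect_identical(mk(0, 3), "3")
  expect_identical(mk(2, 1), "B2")
  expect_identical(mk(0, 0), "0")
  expect_identical(mk(1, 0), "1")
  expect_identical(mk(1, 1), "B2")
  expect_identical(mk(3, 2), "B3")

  # bins partition the protein set
  m <- make_log2_matrix(100, 6, 0.2, seed = 71)
  bins <- bin_missingness(missing_mask(m), two_groups())
  expect_length(bins, 100L)
  expect_true(all(bins %in% c("0", "1", "2", "3", "B2", "B3")))
})

mk_combined <- function(acc, q) {
  out <- data.frame(accession = acc, logfc_mean = seq_along(acc),
                    logfc_sd = 0, neglog10q_mean = -log10(q),
                    neglog10q_sd = 0, qmean = q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$qmean, out$accession), ]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$qmean < 0.05
  rownames(out) <- NULL
  out
}

test_that("merge_top unions per-method top lists without duplication", {
  accs <- sprintf("P%02d", 1:30)
  t1 <- mk_combined(accs, seq(0.001, 0.3, length.out = 30))
  same <- merge_top(list(a = t1, b = t1), n = 10)
  expect_identical(nrow(same), 10L)

  t2 <- mk_combined(accs, rev(seq(0.001, 0.3, length.out = 30)))
  disj <- merge_top(list(a = t1, b = t2), n = 10)
  expect_identical(nrow(disj), 20L)

  set.seed(72)
  t3 <- mk_combined(accs, runif(30))
  part <- merge_top(list(a = t1, b = t3), n = 10)
  oracle <- union(t1$accession[t1$rank <= 10], t3$accession[t3$rank <= 10])
  expect_setequal(part$accession, oracle)
  expect_true(all(c("in_a", "in_b") %in% colnames(part)))
  expect_true(!is.unsorted(part$best_rank))

  expect_warning(full <- merge_top(list(a = t1), n = 50), "full table")
  expect_identical(nrow(full), 30L)
})

test_that("spread statistics tabulate per-method means, SDs, and ellipses", {
  t1 <- mk_combined(c("A", "B"), c(0.01, 0.2))
  t1$logfc_mean <- c(2, 1)
  t1$logfc_sd <- c(sqrt(2), 0)
  st <- spread_stats(list(m1 = t1), c("A", "B", "Z"))
  a <- st[st$accession == "A", ]
  expect_equal(a$logfc_mean, 2)
  expect_equal(a$ellipse_logfc, 1.96 * sqrt(2))
  b <- st[st$accession == "B", ]
  expect_equal(b$ellipse_logfc, 0)
  expect_false(st$present[st$accession == "Z"])

  # hand arithmetic for the across-iteration spread itself
  expect_equal(sd(c(1, 3)), sqrt(2))
  expect_equal(mean(c(1, 3)), 2)
})

test_that("threshold classification crosses expression with significance", {
  m <- make_log2_matrix(50, 6, 0.1, seed = 73)
  sel <- model_selector(m)
  imputed <- impute_mindet(m)
  comb <- mk_combined(rownames(m$values), runif(50))
  cls <- classify_vs_threshold(comb, imputed, sel, alpha = 0.05)
  expect_length(cls, 50L)
  expect_true(all(cls %in% c("above_significant", "above_not_significant",
                             "below_significant", "below_not_significant")))
  hi <- comb$accession[comb$qmean < 0.05][1]
  if (!is.na(hi)) {
    expr <- rowMeans(imputed$values)[hi]
    expected <- if (expr >= sel$threshold_log2) "above_significant"
                else "below_significant"
    expect_identical(unname(cls[hi]), expected)
  }
})

test_that("rank rating rates methods per target and sums totals", {
  t_a <- mk_combined(c("X", "Y"), c(0.001, 0.5))
  t_b <- mk_combined(c("X", "Y"), c(0.03, 0.4))
  rr <- rank_rating(list(a = t_a, b = t_b), c("X", "Y"))
  expect_equal(unname(rr$ratings["X", ]), c(1, 2))
  expect_equal(unname(rr$ratings["Y", ]), c(2, 1))
  expect_equal(unname(rr$totals), c(3, 3))

  # three-way tie shares the mean rating
  tt <- mk_combined("X", 0.2)
  rr3 <- rank_rating(list(a = tt, b = tt, c = tt), "X")
  expect_true(all(rr3$ratings == 2))

  # totals are invariant to method order in the input map
  set.seed(74)
  tabs <- setNames(lapply(1:7, function(i)
    mk_combined(sprintf("P%02d", 1:7), runif(7))), paste0("m", 1:7))
  targets <- sprintf("P%02d", 1:7)
  rr7 <- rank_rating(tabs, targets)
  rr7r <- rank_rating(rev(tabs), targets)
  expect_equal(rr7$totals[names(rr7r$totals)], rr7r$totals)

  # brute-force oracle over the 7x7 grid
  brute <- matrix(0, 7, 7, dimnames = list(targets, names(tabs)))
  for (tg in targets) {
    qs <- vapply(tabs, function(t) t$qmean[t$accession == tg], numeric(1))
    brute[tg, ] <- rank(qs, ties.method = "average")
  }
  expect_equal(rr7$ratings, brute)
  expect_equal(rr7$totals, colSums(brute))

  # absent target takes the worst rank, with a warning
  expect_warning(rrm <- rank_rating(list(a = t_a, b = mk_combined("X", 0.9)),
                                    c("X", "Y")), "worst rank")
  expect_equal(unname(rrm$ratings["Y", ]), c(1, 2))

  # summing across experiments
  both <- combine_ratings(rr, rr)
  expect_equal(unname(both$totals), c(6, 6))
  expect_error(rank_rating(list(a = t_a), character(0)), "non-empty")
})
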