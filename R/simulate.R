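#' Simulate replicate data from a template matrix
#'
#' Builds a simulated dataset from a real (template) quantification matrix:
#' for each protein and treatment group, `n_replicates` values are drawn
#' from a normal with that group's observed mean and standard deviation
#' (missing observations excluded).  A group with a single observed value
#' is replicated as-is (SD 0, with a warning); a group with no observed
#' values stays fully missing when `keep_all_missing_groups` is `TRUE`,
#' reproducing the presence/absence rows of real data.
#'
#' @param template a log2-scale [intensity_matrix()].
#' @param g a [sample_groups()] covering the template samples.
#' @param n_replicates simulated replicates per group, >= 2.
#' @param seed optional RNG seed.
#' @param keep_all_missing_groups keep rows whose group is entirely missing
#'   (`TRUE`, default) or drop such rows (`FALSE`).
#' @return A log2-scale [intensity_matrix()] with columns
#'   `<group>_sim<i>`; the simulated design is attached as attribute
#'   `"groups"` (a named group-label vector).
#' @export
simulate_from_template <- function(template, g, n_replicates = 3L,
                                   seed = NULL,
                                   keep_all_missing_groups = TRUE) {
  stopifnot(inherits(template, "intensity_matrix"),
            inherits(g, "sample_groups"))
  if (template$scale != "log2")
    stop("simulation expects a log2-scale template")
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  v <- template$values
  labs <- unique(g$assignment[colnames(v)])
  labs <- labs[!is.na(labs)]
  if (!length(labs)) stop("no template sample is assigned to a group")
  n <- nrow(v)
  blocks <- list()
  assignment <- character(0)
  n_singleton <- 0L
  for (lab in labs) {
    cols <- intersect(colnames(v), group_samples(g, lab))
    if (!length(cols)) stop("group '", lab, "' absent from the template")
    sub <- v[, cols, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, sd, na.rm = TRUE)
    sdv[nobs == 1L] <- 0
    n_singleton <- n_singleton + sum(nobs == 1L)
    block <- matrix(NA_real_, n, n_replicates)
    has <- nobs >= 1L
    block[has, ] <- rnorm(sum(has) * n_replicates,
                          mean = rep(mu[has], n_replicates),
                          sd = rep(sdv[has], n_replicates))
    colnames(block) <- paste0(lab, "_sim", seq_len(n_replicates))
    blocks[[lab]] <- block
    assignment <- c(assignment,
                    setNames(rep(lab, n_replicates), colnames(block)))
  }
  if (n_singleton > 0L)
    warning(n_singleton, " protein-group(s) had a single observed value; ",
            "replicated with SD 0")
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(v)
  if (!keep_all_missing_groups) {
    keep <- rowSums(is.na(out)) == 0L |
      apply(!is.na(out), 1L, function(r) all(tapply(r, assignment, any)))
    out <- out[keep, , drop = FALSE]
  }
  res <- intensity_matrix(out, "log2")
  attr(res, "groups") <- assignment
  res
}

#' Amputation configuration
#'
#' Controls mechanism-driven introduction of missing values into complete
#' rows.  Two amputed copies of the data are built — one under MAR (each
#' candidate row's masking probability is a logistic function of a weighted
#' sum of its remaining observed columns) and one under MNAR (the masking
#' probability is a left-shaped logistic function of the value that would
#' be masked, so low intensities are preferentially lost) — each calibrated
#' so its expected masked-row fraction equals the requested proportion.  A
#' random allocation vector then assigns each candidate row to one
#' mechanism's copy.  The benchmark grid of MAR:MNAR proportions is
#' 0.2:0.2, 0.2:0.8, 0.5:0.5 and 0.8:0.2.
#'
#' @param prop_mar,prop_mnar fraction of a mechanism's allocated rows that
#'   lose a cell, each in \[0, 1\].
#' @param patterns optional list of column-index vectors to mask per
#'   affected row; default: one randomly chosen single column per row.
#' @param mar_weights optional weights on the observed columns of the MAR
#'   score (default: equal weights).
#' @param mar_shape,mnar_shape logistic link shape per mechanism: `"left"`
#'   (low scores preferred), `"right"` (high), `"mid"`, `"tail"`.
#' @param seed optional RNG seed (the allocation seed).
#' @return An object of class `ampute_config`.
#' @export
ampute_config <- function(prop_mar = 0.5, prop_mnar = 0.5, patterns = NULL,
                          mar_weights = NULL, mar_shape = "right",
                          mnar_shape = "left", seed = NULL) {
  for (p in c(prop_mar, prop_mnar))
    if (p < 0 || p > 1) stop("mechanism proportions must lie in [0, 1]")
  shapes <- c("left", "right", "mid", "tail")
  mar_shape <- match.arg(mar_shape, shapes)
  mnar_shape <- match.arg(mnar_shape, shapes)
  structure(list(prop_mar = prop_mar, prop_mnar = prop_mnar,
                 patterns = patterns, mar_weights = mar_weights,
                 mar_shape = mar_shape, mnar_shape = mnar_shape,
                 seed = seed),
            class = "ampute_config")
}

shape_score <- function(z, shape) {
  switch(shape, left = -z, right = z, mid = -abs(z), tail = abs(z))
}

# Calibrate the logistic link shift so the mean masking probability equals
# the requested proportion; returns per-row probabilities.
calibrated_probs <- function(scores, shape, prop) {
  if (prop <= 0) return(rep(0, length(scores)))
  if (prop >= 1) return(rep(1, length(scores)))
  z <- scores
  s <- sd(z)
  z <- if (is.finite(s) && s > 0) (z - mean(z)) / s else rep(0, length(z))
  z <- shape_score(z, shape)
  f <- function(c) mean(plogis(z + c)) - prop
  shift <- uniroot(f, lower = -50, upper = 50, extendInt = "yes")$root
  plogis(z + shift)
}

#' Ampute a matrix under controlled MAR/MNAR mechanisms
#'
#' Introduces missing values into the complete rows of `x` according to an
#' [ampute_config()]; rows that already contain missing cells are excluded
#' from candidacy and never touched.  See [ampute_config()] for the
#' mechanism semantics.
#'
#' @param x an [intensity_matrix()].
#' @param cfg an [ampute_config()].
#' @return A list with `matrix` (the amputed [intensity_matrix()]) and
#'   `mechanism` (a character matrix labelling every cell `"observed"`,
#'   `"MAR"`, `"MNAR"`, or `"missing"` for cells already missing on input).
#' @export
ampute <- function(x, cfg = ampute_config()) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(cfg, "ampute_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  v <- x$values
  mech <- matrix("observed", nrow(v), ncol(v), dimnames = dimnames(v))
  mech[is.na(v)] <- "missing"
  cand <- which(rowSums(is.na(v)) == 0L)
  active <- c(MAR = cfg$prop_mar > 0, MNAR = cfg$prop_mnar > 0)
  if (!any(active))
    return(list(matrix = x, mechanism = mech))
  if (!length(cand))
    stop("no complete rows are eligible for amputation")
  nc <- length(cand)
  # per-candidate pattern: the column(s) that would be masked
  pat_cols <- if (is.null(cfg$patterns)) {
    as.list(sample(ncol(v), nc, replace = TRUE))
  } else {
    for (p in cfg$patterns)
      if (length(p) < 1L || length(p) >= ncol(v))
        stop("each pattern must mask at least 1 and fewer than all columns")
    cfg$patterns[sample(length(cfg$patterns), nc, replace = TRUE)]
  }
  w <- cfg$mar_weights %||% rep(1, ncol(v))
  mar_scores <- vapply(seq_len(nc), function(i) {
    keep <- setdiff(seq_len(ncol(v)), pat_cols[[i]])
    sum(w[keep] * v[cand[i], keep])
  }, numeric(1))
  mnar_scores <- vapply(seq_len(nc), function(i) {
    mean(v[cand[i], pat_cols[[i]]])
  }, numeric(1))
  p_mar <- calibrated_probs(mar_scores, cfg$mar_shape, cfg$prop_mar)
  p_mnar <- calibrated_probs(mnar_scores, cfg$mnar_shape, cfg$prop_mnar)
  # random allocation of candidates among the active mechanisms
  mechs <- names(active)[active]
  alloc <- mechs[sample.int(length(mechs), nc, replace = TRUE)]
  u <- runif(nc)
  masked <- ifelse(alloc == "MAR", u < p_mar, u < p_mnar)
  for (i in which(masked)) {
    cols <- pat_cols[[i]]
    v[cand[i], cols] <- NA_real_
    mech[cand[i], cols] <- alloc[i]
  }
  list(matrix = intensity_matrix(v, x$scale), mechanism = mech)
}

#' Generate a self-contained ground-truth benchmark fixture
#'
#' Builds a complete two-group log2 dataset with known differential
#' expression, then amputes it under controlled mechanisms: baseline
#' protein means are drawn from Normal(20, 2) on the log2 scale (matching
#' typical LFQ intensity magnitudes), a fraction `frac_de` of proteins
#' receive a treatment effect drawn from Normal(0, `effect_size_sd`), and
#' replicate noise is Normal(0, `noise_sd`).
#'
#' @param n_proteins number of proteins, >= 50.
#' @param n_per_group replicates per group (default 3, the typical
#'   label-free design).
#' @param frac_de fraction of proteins carrying a true effect.
#' @param effect_size_sd SD of the true log2 fold changes.
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param ampute_cfg an [ampute_config()] for the missingness mechanisms.
#'   The default (`NULL`) uses a 0.5:0.5 MAR:MNAR mixture whose candidate
#'   patterns are the six single-column masks plus the two whole-group
#'   blocks, so part of the induced missingness is the presence/absence
#'   kind (a protein entirely missing from one treatment group) that
#'   dominates real label-free data.
#' @param seed RNG seed (drives both simulation and amputation).
#' @return An object of class `ground_truth`: list with `complete` and
#'   `amputed` intensity matrices, `mechanism` label matrix, `truth` data
#'   frame (`accession`, `effect`, `de`), and `groups`
#'   (a [sample_groups()], contrast treatment vs control).
#' @export
generate_ground_truth <- function(n_proteins = 1000L, n_per_group = 3L,
                                  frac_de = 0.25, effect_size_sd = 2,
                                  noise_sd = 0.3,
                                  ampute_cfg = NULL, seed = 1L) {
  if (n_proteins < 50L) stop("`n_proteins` must be >= 50")
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2")
  if (frac_de < 0 || frac_de > 1) stop("`frac_de` must lie in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  ampute_cfg <- ampute_cfg %||%
    ampute_config(prop_mar = 0.5, prop_mnar = 0.5,
                  patterns = c(as.list(seq_len(2L * n_per_group)),
                               list(seq_len(n_per_group)),
                               list(n_per_group + seq_len(n_per_group))))
  set.seed(seed)
  acc <- sprintf("P%05d", seq_len(n_proteins))
  base <- rnorm(n_proteins, mean = 20, sd = 2)
  n_de <- round(frac_de * n_proteins)
  effect <- numeric(n_proteins)
  if (n_de > 0L)
    effect[sample.int(n_proteins, n_de)] <- rnorm(n_de, 0, effect_size_sd)
  trt <- matrix(rnorm(n_proteins * n_per_group, mean = base + effect,
                      sd = noise_sd), n_proteins, n_per_group)
  ctl <- matrix(rnorm(n_proteins * n_per_group, mean = base,
                      sd = noise_sd), n_proteins, n_per_group)
  v <- cbind(trt, ctl)
  dimnames(v) <- list(acc, c(paste0("trt_", seq_len(n_per_group)),
                             paste0("ctl_", seq_len(n_per_group))))
  complete <- intensity_matrix(v, "log2")
  groups <- sample_groups(
    setNames(rep(c("trt", "ctl"), each = n_per_group), colnames(v)),
    contrast = c("trt", "ctl"))
  amp <- ampute(complete, ampute_cfg)
  structure(list(complete = complete, amputed = amp$matrix,
                 mechanism = amp$mechanism,
                 truth = data.frame(accession = acc, effect = effect,
                                    de = effect != 0,
                                    stringsAsFactors = FALSE),
                 groups = groups),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d proteins, %d samples, %d true DE, %.1f%% missing after amputation\n",
              nrow(x$complete$values), ncol(x$complete$values),
              sum(x$truth$de), 100 * mean(is.na(x$amputed$values))))
  invisible(x)
}

#' Write a ground-truth bundle as plain-text files
#'
#' Writes the complete and amputed matrices, the truth table, the
#' per-cell mechanism map and the group assignment as TSVs, plus a replay
#' YAML with the generating configuration.
#'
#' @param gt a `ground_truth` object.
#' @param dir output directory (created if needed).
#' @param config optional list recorded in `replay.yaml`.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir, config = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(gt$complete, file.path(dir, "complete.tsv"))
  write_matrix(gt$amputed, file.path(dir, "amputed.tsv"))
  write.table(gt$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mech <- data.frame(accession = rownames(gt$mechanism), gt$mechanism,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mech, file.path(dir, "mechanism.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  grp <- data.frame(sample = names(gt$groups$assignment),
                    group = unname(gt$groups$assignment),
                    stringsAsFactors = FALSE)
  write.table(grp, file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(c(config,
                     list(contrast = as.list(gt$groups$contrast))),
                   file.path(dir, "replay.yaml"))
  invisible(dir)
}

#' Read a ground-truth bundle written by [write_ground_truth()]
#' @param dir bundle directory.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(dir) {
  complete <- read_matrix(file.path(dir, "complete.tsv"), scale = "log2")
  amputed <- read_matrix(file.path(dir, "amputed.tsv"), scale = "log2")
  truth <- read.delim(file.path(dir, "truth.tsv"),
                      stringsAsFactors = FALSE)
  truth$de <- as.logical(truth$de)
  mech_df <- read.delim(file.path(dir, "mechanism.tsv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  mech <- as.matrix(mech_df[, -1L, drop = FALSE])
  rownames(mech) <- mech_df[[1L]]
  grp <- read.delim(file.path(dir, "groups.tsv"),
                    stringsAsFactors = FALSE)
  replay <- yaml::read_yaml(file.path(dir, "replay.yaml"))
  groups <- sample_groups(setNames(grp$group, grp$sample),
                          contrast = unlist(replay$contrast))
  structure(list(complete = complete, amputed = amputed, mechanism = mech,
                 truth = truth, groups = groups),
            class = "ground_truth")
}
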