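#' Load a pipeline configuration
#'
#' Accepts either a YAML/JSON file path or an already-built list and
#' returns the list.  Configurations drive [sfi_run()], [sfi_simulate()]
#' and [sfi_benchmark()]; scalar fields can be overridden from the command
#' line by the `inst/cli/sfi.R` script.
#'
#' @param config path to a YAML (or JSON) file, or a list.
#' @return The configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  config
}

config_groups <- function(cfg) {
  gr <- cfg$groups
  assignment <- if (is.character(gr) && length(gr) == 1L && file.exists(gr)) {
    df <- read.delim(gr, stringsAsFactors = FALSE)
    setNames(df$group, df$sample)
  } else {
    unlist(gr)
  }
  if (is.null(cfg$contrast) || length(cfg$contrast) != 2L)
    stop("config field `contrast` must name (treatment, reference)")
  sample_groups(assignment, contrast = unlist(cfg$contrast))
}

config_params <- function(cfg) {
  method <- cfg$method %||% "hybrid"
  impute_params(
    method = method,
    k_neighbors = cfg$k_neighbors %||% 15L,
    n_components = cfg$n_components %||% 6L,
    svd_tol = cfg$svd_tol %||% 0.01,
    mindet_quantile = cfg$mindet_quantile %||% 0.01,
    minprob_sigma_scale = cfg$minprob_sigma_scale %||% 1,
    qrilc_sigma_scale = cfg$qrilc_sigma_scale %||% 1,
    mle_draw = cfg$mle_draw %||% TRUE)
}

config_mi <- function(cfg, params) {
  mi <- cfg$mi %||% list()
  mi_config(m = mi$m %||% 25L, params = params,
            vary_k = mi$vary_k %||% TRUE,
            base_seed = mi$base_seed %||% cfg$seed %||% 1L,
            alpha = mi$alpha %||% 0.05)
}

write_manifest <- function(dir, cfg, seeds, extra = list()) {
  manifest <- c(list(package = "sfimpute",
                     version = as.character(packageVersion("sfimpute")),
                     seeds = as.list(seeds)),
                extra, list(config = cfg))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
}

#' Run the full SFI differential-expression workflow
#'
#' Executes select -> filter -> multiple imputation (impute -> quantile
#' normalize -> moderated t-test -> q-values) -> combine on a configured
#' input matrix, writing the combined ranked table, per-stage reports and a
#' run manifest (config + seeds + package version) for exact replay.
#'
#' Config fields: `matrix` (path, or an `intensity_matrix` under
#' `matrix_object`), `matrix_scale` (`"raw"` default, or `"log2"` for
#' pre-transformed inputs), `groups` (named sample->group list or TSV path
#' with `sample`/`group` columns), `contrast`, optional `contaminants`
#' (path, one accession per line) and `contaminant_prefix`, optional
#' `filter` (`intensity_threshold`, `sparse_fraction`, `min_observations`),
#' `method` plus method parameters, and `mi` (`m`, `base_seed`, `alpha`,
#' `vary_k`).
#'
#' @param config configuration list or YAML path (see [load_config()]).
#' @param output_dir output directory; overrides `config$output_dir`.
#' @return Invisibly, a list with `combined`, `tables`, `matrix` (the
#'   filtered log2 matrix), `groups` and `output_dir`.
#' @export
sfi_run <- function(config, output_dir = NULL) {
  cfg <- load_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||%
    stop("no output directory configured")
  for (d in c("", "inputs", "iterations", "combined", "evaluation"))
    dir.create(file.path(out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  g <- config_groups(cfg)
  m <- if (!is.null(cfg$matrix_object)) cfg$matrix_object
       else read_matrix(cfg$matrix,
                        missing_tokens = cfg$missing_tokens %||% c("", "NA"),
                        scale = cfg$matrix_scale %||% "raw")
  log <- c(sprintf("input: %d proteins x %d samples", nrow(m$values),
                   ncol(m$values)))
  if (!is.null(cfg$contaminants)) {
    ids <- readLines(cfg$contaminants, warn = FALSE)
    ids <- ids[nzchar(ids)]
    m <- filter_contaminants(m, ids,
                             strip_prefix = cfg$contaminant_prefix)
    write_removal_report(m, file.path(out_dir, "inputs",
                                      "removed_contaminants.tsv"))
    log <- c(log, sprintf("contaminants removed: %d",
                          nrow(removal_report(m))))
  }
  if (m$scale == "raw") {
    fl <- cfg$filter %||% list()
    fcfg <- filter_config(
      intensity_threshold = fl$intensity_threshold %||% 2^15,
      sparse_fraction = fl$sparse_fraction %||% 0.5,
      min_observations = fl$min_observations %||% 3L)
    m <- filter_sparse(m, fcfg)
    write_removal_report(m, file.path(out_dir, "inputs",
                                      "removed_sparse.tsv"))
    log <- c(log, sprintf("sparse rows removed: %d, surviving: %d",
                          nrow(removal_report(m)), nrow(m$values)))
    m <- log2_transform(m)
  }
  m <- select_groups(m, g)
  mask <- missing_mask(m)
  write_matrix(m, file.path(out_dir, "inputs", "selected_log2.tsv"))
  params <- config_params(cfg)
  micfg <- config_mi(cfg, params)
  tables <- run_mi(m, g, micfg)
  if (isTRUE(cfg$archive_iterations)) {
    for (i in seq_along(tables))
      write_detable(tables[[i]],
                    file.path(out_dir, "iterations",
                              sprintf("detable_%03d.tsv", i)))
  }
  combined <- combine_mi(tables, mask = mask, g = g, alpha = micfg$alpha)
  write_mi_combined(combined,
                    file.path(out_dir, "combined", "mi_combined.tsv"))
  writeLines(log, file.path(out_dir, "run.log"))
  write_manifest(out_dir, strip_objects(cfg), attr(tables, "seeds"),
                 list(stage_log = as.list(log)))
  invisible(list(combined = combined, tables = tables, matrix = m,
                 groups = g, output_dir = out_dir))
}

strip_objects <- function(cfg) {
  cfg$matrix_object <- NULL
  cfg
}

#' Generate and write a ground-truth simulation bundle
#'
#' Config fields: either `template` (path to a log2 matrix) with `groups` /
#' `contrast` / `n_replicates`, or generator settings (`n_proteins`,
#' `n_per_group`, `frac_de`, `effect_size_sd`, `noise_sd`); plus `ampute`
#' (`prop_mar`, `prop_mnar`, `mar_shape`, `mnar_shape`), `seed` and
#' `output_dir`.
#'
#' @param config configuration list or YAML path.
#' @param output_dir overrides `config$output_dir`.
#' @return Invisibly, the `ground_truth` object (bundle written to disk).
#' @export
sfi_simulate <- function(config, output_dir = NULL) {
  cfg <- load_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||%
    stop("no output directory configured")
  am <- cfg$ampute %||% list()
  acfg <- ampute_config(prop_mar = am$prop_mar %||% 0.5,
                        prop_mnar = am$prop_mnar %||% 0.5,
                        mar_shape = am$mar_shape %||% "right",
                        mnar_shape = am$mnar_shape %||% "left")
  seed <- cfg$seed %||% 1L
  if (!is.null(cfg$template)) {
    template <- read_matrix(cfg$template, scale = "log2")
    g <- config_groups(cfg)
    set.seed(seed)
    sim <- simulate_from_template(template, g,
                                  n_replicates = cfg$n_replicates %||% 3L)
    amp <- ampute(sim, acfg)
    assignment <- attr(sim, "groups")
    gt <- structure(
      list(complete = sim, amputed = amp$matrix,
           mechanism = amp$mechanism,
           truth = data.frame(accession = rownames(sim$values),
                              effect = NA_real_, de = NA,
                              stringsAsFactors = FALSE),
           groups = sample_groups(assignment, g$contrast)),
      class = "ground_truth")
  } else {
    gt <- generate_ground_truth(
      n_proteins = cfg$n_proteins %||% 1000L,
      n_per_group = cfg$n_per_group %||% 3L,
      frac_de = cfg$frac_de %||% 0.25,
      effect_size_sd = cfg$effect_size_sd %||% 2,
      noise_sd = cfg$noise_sd %||% 0.3,
      ampute_cfg = acfg, seed = seed)
  }
  write_ground_truth(gt, out_dir, config = strip_objects(cfg))
  invisible(gt)
}

#' Benchmark imputation methods against a ground-truth bundle
#'
#' Derives the ground-truth significant set by running the DE pipeline on
#' the bundle's complete matrix (no imputation needed), then runs the full
#' MI pipeline on the amputed matrix with every listed method and computes
#' capture rates, missingness-bin frequencies of each method's top list,
#' and rank ratings over the merged top proteins.  A JSON summary is
#' written for machine comparison.
#'
#' Config fields: `bundle` (directory from [sfi_simulate()]) or
#' `ground_truth` (object), `methods` (character vector), `mi` settings,
#' `top_n` (default 10), `alpha`, `output_dir`.
#'
#' @param config configuration list or YAML path.
#' @param output_dir overrides `config$output_dir` (optional; when absent
#'   nothing is written).
#' @return A list with `truth_sig`, `capture` (named percentages),
#'   `combined` (per-method tables), `bin_freq`, `merged_top`, `rating`
#'   and `summary` (the JSON-ready list).
#' @export
sfi_benchmark <- function(config, output_dir = NULL) {
  cfg <- load_config(config)
  gt <- cfg$ground_truth %||% read_ground_truth(cfg$bundle)
  methods <- unlist(cfg$methods %||%
    c("knn", "svd", "mle", "mindet", "minprob", "qrilc", "hybrid"))
  alpha <- cfg$alpha %||% 0.05
  truth_tab <- suppressWarnings(
    moderated_ttest(quantile_normalize(gt$complete), gt$groups,
                    alpha = alpha))
  truth_sig <- truth_tab$accession[truth_tab$significant]
  mask <- missing_mask(gt$amputed)
  combined <- list()
  capture <- numeric(0)
  for (method in methods) {
    cfg_m <- cfg
    cfg_m$method <- method
    params <- config_params(cfg_m)
    micfg <- config_mi(cfg, params)
    tables <- run_mi(gt$amputed, gt$groups, micfg)
    comb <- combine_mi(tables, mask = mask, g = gt$groups, alpha = alpha)
    combined[[method]] <- comb
    capture[method] <- capture_rate(truth_sig,
                                    comb$accession[comb$significant])
  }
  top_n <- cfg$top_n %||% 10L
  merged <- merge_top(combined, n = top_n)
  rating <- rank_rating(combined, merged$accession)
  bin_freq <- lapply(combined, function(cb) {
    top <- head(cb$accession, min(200L, nrow(cb)))
    as.list(table(bin_missingness(mask, gt$groups)[top]))
  })
  summary <- list(methods = as.list(methods),
                  n_truth_significant = length(truth_sig),
                  capture_rate_pct = as.list(capture),
                  rating_totals = as.list(rating$totals),
                  bin_frequencies_top200 = bin_freq)
  out_dir <- output_dir %||% cfg$output_dir
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "evaluation"), recursive = TRUE,
               showWarnings = FALSE)
    jsonlite::write_json(summary,
                         file.path(out_dir, "evaluation", "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (m in names(combined))
      write_mi_combined(combined[[m]],
                        file.path(out_dir, "evaluation",
                                  paste0("combined_", m, ".tsv")))
  }
  list(truth_sig = truth_sig, capture = capture, combined = combined,
       bin_freq = bin_freq, merged_top = merged, rating = rating,
       summary = summary)
}
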