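#' Protein intensity matrix
#'
#' Lightweight container for a proteins x samples quantification grid as
#' exported by label-free quantification pipelines.  Rows are protein
#' accessions, columns are samples, cells are intensities; missing values are
#' stored as `NA` (never as sentinel zeros, which are ambiguous in MS
#' exports).  The `scale` flag records whether the values are raw intensities
#' or log2-transformed; sparsity filtering operates on the raw scale while
#' every imputation model assumes Gaussian-like log2 intensities.
#'
#' @param values numeric matrix with protein accessions as row names and
#'   sample names as column names.  `NA` marks a missing value.
#' @param scale `"raw"` (all present values must be positive) or `"log2"`.
#' @return An object of class `intensity_matrix` with fields `values` and
#'   `scale`.
#' @examples
#' v <- matrix(2^rnorm(12, 20), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' m <- intensity_matrix(v, "raw")
#' missing_fraction(m)
#' @export
intensity_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L)
      stop("`values` must carry protein accessions as row names")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0L)
      stop("`values` must carry sample names as column names")
    colnames(values) <- character(0)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate protein accession(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample name(s): ", paste(dup, collapse = ", "))
  if (scale == "raw") {
    bad <- !is.na(values) & values <= 0
    if (any(bad))
      stop("raw-scale intensities must be positive; found ", sum(bad),
           " value(s) <= 0")
  }
  structure(list(values = values, scale = scale), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Extract the numeric value grid of an intensity matrix
#' @param x an [intensity_matrix()].
#' @return The numeric matrix (with `NA` at missing cells).
#' @export
intensity_values <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  x$values
}

#' Missingness mask of an intensity matrix
#'
#' @param x an [intensity_matrix()].
#' @return Logical matrix, `TRUE` exactly where a value is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  is.na(x$values)
}

#' Missing-value fraction of an intensity matrix
#'
#' @param x an [intensity_matrix()].
#' @param by `"total"` for a scalar, `"sample"` / `"protein"` for per-column /
#'   per-row fractions.
#' @return Numeric scalar or named vector of fractions in \[0, 1\].
#' @export
missing_fraction <- function(x, by = c("total", "sample", "protein")) {
  by <- match.arg(by)
  m <- missing_mask(x)
  switch(by,
         total   = mean(m),
         sample  = colMeans(m),
         protein = rowMeans(m))
}

is_complete <- function(x) !anyNA(x$values)

#' Sample-to-group design with a pairwise contrast
#'
#' @param assignment named character vector mapping sample name to group
#'   label.
#' @param contrast length-2 character vector `(treatment, reference)`; the
#'   log fold change convention throughout the package is treatment minus
#'   reference.  Both labels must be present in `assignment` with at least
#'   two samples each.
#' @return An object of class `sample_groups`.
#' @examples
#' g <- sample_groups(c(A1 = "HG", A2 = "HG", A3 = "HG",
#'                      B1 = "GD", B2 = "GD", B3 = "GD"),
#'                    contrast = c("GD", "HG"))
#' @export
sample_groups <- function(assignment, contrast) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("`assignment` must be a named vector (sample name -> group label)")
  assignment <- vapply(assignment, as.character, character(1))
  if (length(contrast) != 2L)
    stop("`contrast` must be an ordered pair (treatment, reference)")
  contrast <- as.character(contrast)
  for (lab in contrast) {
    n <- sum(assignment == lab)
    if (n < 2L)
      stop("contrast group '", lab, "' has ", n,
           " sample(s); at least 2 are required")
  }
  structure(list(assignment = assignment, contrast = contrast),
            class = "sample_groups")
}

#' @export
print.sample_groups <- function(x, ...) {
  cat("<sample_groups> contrast:", x$contrast[1], "vs", x$contrast[2], "\n")
  print(table(x$assignment))
  invisible(x)
}

group_samples <- function(g, label) names(g$assignment)[g$assignment == label]

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a wide-format quantification table
#'
#' Reads a delimited text file whose header row holds sample names and whose
#' first column holds protein accessions, as exported by common LFQ tools.
#' Cells matching any of `missing_tokens` become missing values; add `"0"`
#' to the token set for exports that encode absence as zero.
#'
#' @param path path to a TSV (default) or CSV (by extension) file.
#' @param missing_tokens character vector of cell contents to treat as
#'   missing.  Default: empty cell and `"NA"`.
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @param scale scale flag to record, `"raw"` by default.
#' @return An [intensity_matrix()].
#' @export
read_matrix <- function(path, missing_tokens = c("", "NA"), sep = NULL,
                        scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  sep <- sep %||% infer_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expected an accession column plus at least one sample column")
  acc <- df[[1L]]
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stop("duplicate protein accession(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell '", cells[bad[1, 1], bad[1, 2]], "' at row '",
         acc[bad[1, 1]], "', column '", colnames(cells)[bad[1, 2]], "'")
  }
  dimnames(vals) <- list(acc, colnames(cells))
  if (all(is.na(vals)))
    warning("matrix is 100% missing after applying missing tokens")
  intensity_matrix(vals, scale)
}

#' Write an intensity matrix as a wide-format table
#'
#' Inverse of [read_matrix()]: writes accessions in the first column
#' (`accession`), one column per sample, missing cells as `NA`.  Values are
#' formatted with 17 significant digits so that a read/write round trip is
#' lossless.
#'
#' @param x an [intensity_matrix()].
#' @param path output path; `.csv` extension selects comma separation.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  sep <- sep %||% infer_sep(path)
  v <- x$values
  chr <- matrix(formatC(v, digits = 17, format = "g"), nrow(v), ncol(v))
  chr[is.na(v)] <- "NA"
  df <- data.frame(accession = rownames(v), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("accession", colnames(v))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a raw-scale intensity matrix
#'
#' All imputation models in the package assume Gaussian-like log2
#' intensities; raw LFQ intensities are log2-transformed after raw-scale
#' sparsity filtering.  The missingness mask is unchanged.
#'
#' @param x a raw-scale [intensity_matrix()] with all present values > 0.
#' @return The log2-scale matrix.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale == "log2")
    stop("matrix is already on the log2 scale")
  if (any(!is.na(x$values) & x$values <= 0))
    stop("cannot log2-transform non-positive intensities")
  intensity_matrix(log2(x$values), "log2")
}

#' Select and order the columns of a pairwise contrast
#'
#' The Selection stage of the SFI workflow: keeps only the samples belonging
#' to the two contrast groups, ordered treatment block first then reference
#' block (matching the logFC sign convention).  Values and mask are never
#' altered, only column membership and order.
#'
#' @param x an [intensity_matrix()].
#' @param g a [sample_groups()] whose assignment covers the contrast samples.
#' @return The column-subset [intensity_matrix()].
#' @export
select_groups <- function(x, g) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(g, "sample_groups"))
  cols <- character(0)
  for (lab in g$contrast) {
    s <- intersect(colnames(x$values), group_samples(g, lab))
    if (length(s) == 0L)
      stop("contrast group '", lab, "' has no samples in the matrix")
    cols <- c(cols, s)
  }
  intensity_matrix(x$values[, cols, drop = FALSE], x$scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replace the value grid of an intensity matrix, keeping metadata
#' @noRd
set_values <- function(x, values) {
  x$values <- values
  x
}
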