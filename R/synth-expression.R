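#' Expression dataset container
#'
#' Genes x samples matrix of log2 intensities plus a sample sheet mapping
#' each sample to a subject and a timepoint in months (0, 2, 4, 6 in the
#' transplant design; 0 is the pre-transplant baseline).
#'
#' @param mat numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), log2 scale.
#' @param sample_sheet data.frame with columns `sample`, `subject`,
#'   `timepoint`; one row per column of `mat`, in any order.
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(mat, sample_sheet) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  req <- c("sample", "subject", "timepoint")
  if (!all(req %in% names(sample_sheet)))
    stop("sample_sheet needs columns: ", paste(req, collapse = ", "))
  if (is.null(colnames(mat))) stop("matrix must have sample colnames")
  if (is.null(rownames(mat))) stop("matrix must have gene rownames")
  if (!setequal(colnames(mat), sample_sheet$sample))
    stop("sample sheet does not match matrix columns")
  if (any(is.na(sample_sheet$timepoint)))
    stop("missing timepoint labels")
  sample_sheet <- sample_sheet[match(colnames(mat), sample_sheet$sample), ]
  structure(list(matrix = mat, sample_sheet = sample_sheet),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$sample_sheet$timepoint)
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("samples per timepoint (months):",
      paste(sprintf("%s mo: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic 4-timepoint expression dataset
#'
#' Emulates a log2 microarray matrix over the transplant design (0, 2, 4, 6
#' months) with planted differentially expressed gene sets: `core` genes
#' are shifted at all three post-transplant timepoints, `unique2` /
#' `unique4` / `unique6` genes at exactly one. Effect signs alternate
#' up/down within each set.
#'
#' @param n_genes total number of genes.
#' @param n_per_timepoint samples per timepoint.
#' @param n_unique planted set sizes for the three unique sets, length 3
#'   (2, 4, 6 months).
#' @param n_core planted core-set size.
#' @param effect_log2 absolute log2 effect size of planted genes.
#' @param noise_sd within-group Gaussian noise standard deviation (log2
#'   units); 0 gives a noiseless matrix in which empirical fold changes are
#'   exact.
#' @param seed integer RNG seed.
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   list of gene-id character vectors (`unique2`, `unique4`, `unique6`,
#'   `core`, `null`).
#' @export
generate_expression_dataset <- function(n_genes = 2000,
                                        n_per_timepoint = 3,
                                        n_unique = c(30, 30, 30),
                                        n_core = 30,
                                        effect_log2 = 1.5,
                                        noise_sd = 0.5,
                                        seed = 1L) {
  stopifnot(length(n_unique) == 3, n_genes >= sum(n_unique) + n_core)
  if (noise_sd > 0 && effect_log2 > 0 &&
      effect_log2 / (noise_sd * sqrt(2 / n_per_timepoint)) < 3)
    warning("planted effect is small relative to noise at this sample ",
            "size; recovery will be partial")
  set.seed(seed)
  tps <- c(0, 2, 4, 6)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  samples <- as.vector(vapply(tps, function(t)
    sprintf("s%dmo_%02d", t, seq_len(n_per_timepoint)),
    character(n_per_timepoint)))
  sheet <- data.frame(
    sample = samples,
    subject = rep(sprintf("subj%02d", seq_len(n_per_timepoint)),
                  times = length(tps)),
    timepoint = rep(tps, each = n_per_timepoint)
  )
  idx <- seq_len(sum(n_unique) + n_core)
  sets <- split(gene_ids[idx], rep(c("unique2", "unique4", "unique6",
                                     "core"),
                                   c(n_unique, n_core)))
  affected <- list(unique2 = 2, unique4 = 4, unique6 = 6, core = c(2, 4, 6))

  mu <- runif(n_genes, 4, 12)
  mat <- matrix(rep(mu, length(samples)), nrow = n_genes,
                dimnames = list(gene_ids, samples))
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (length(g) == 0) next
    sgn <- rep_len(c(1, -1), length(g))
    cols <- sheet$timepoint %in% affected[[nm]]
    mat[g, cols] <- mat[g, cols] + sgn * effect_log2
  }
  if (noise_sd > 0)
    mat <- mat + matrix(rnorm(length(mat), 0, noise_sd), nrow = n_genes)

  truth <- c(sets[c("unique2", "unique4", "unique6", "core")],
             list(null = setdiff(gene_ids, unlist(sets))))
  list(dataset = expression_dataset(mat, sheet), truth = truth)
}

#' Write / read an expression dataset as TSV
#'
#' The matrix is written genes x samples with an `id` first column; the
#' sample sheet is written alongside as `<path>.samples.tsv` (columns
#' `sample`, `subject`, `timepoint`).
#'
#' @param ds an [expression_dataset()].
#' @param path TSV path for the matrix.
#' @return `read_expression_tsv` returns an [expression_dataset()].
#' @export
write_expression_tsv <- function(ds, path) {
  df <- data.frame(id = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$sample_sheet, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param sample_sheet_path optional explicit sample sheet TSV; defaults to
#'   `<path>.samples.tsv`.
#' @export
read_expression_tsv <- function(path, sample_sheet_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (is.null(sample_sheet_path))
    sample_sheet_path <- paste0(path, ".samples.tsv")
  sheet <- utils::read.delim(sample_sheet_path)
  sheet$timepoint <- as.numeric(sheet$timepoint)
  expression_dataset(mat, sheet)
}

#' Read a GEO series-matrix file
#'
#' Parses the tab-separated block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Timepoint labels are not standardized in
#' series-matrix headers, so a sample sheet must be supplied.
#'
#' @param path series-matrix TSV (uncompressed).
#' @param sample_sheet data.frame with `sample`, `subject`, `timepoint`.
#' @return An [expression_dataset()].
#' @export
read_series_matrix <- function(path, sample_sheet) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("no series_matrix_table block found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  df <- utils::read.delim(text = paste(block, collapse = "\n"),
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- gsub('^"|"$', "", df[[1]])
  colnames(mat) <- gsub('^"|"$', "", colnames(mat))
  expression_dataset(mat, sample_sheet)
}
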