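#' Baseline transform (baseline to median of all samples)
#'
#' Subtracts each gene's median across all samples from that gene's
#' values, the standard baseline transformation applied after RMA
#' normalization. Idempotent up to the median of the centred values being
#' zero.
#'
#' @param ds an [expression_dataset()].
#' @return The transformed [expression_dataset()].
#' @export
baseline_transform <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  med <- apply(ds$matrix, 1, median)
  ds$matrix <- ds$matrix - med
  ds
}

group_stats <- function(mat, f) {
  lv <- sort(unique(f))
  n <- vapply(lv, function(l) sum(f == l), numeric(1))
  means <- vapply(lv, function(l)
    rowMeans(mat[, f == l, drop = FALSE]), numeric(nrow(mat)))
  vars <- vapply(lv, function(l)
    apply(mat[, f == l, drop = FALSE], 1, var), numeric(nrow(mat)))
  list(levels = lv, n = n,
       means = matrix(means, nrow = nrow(mat),
                      dimnames = list(rownames(mat), lv)),
       vars = matrix(vars, nrow = nrow(mat),
                     dimnames = list(rownames(mat), lv)))
}

# signed linear fold change from a log2 difference: positive = up versus
# baseline, negative = down, |fc| = 2^|delta|
signed_fc <- function(delta) ifelse(delta >= 0, 2^delta, -(2^(-delta)))

#' One-way ANOVA differential expression filter
#'
#' Per-gene one-way ANOVA across the four timepoints, Benjamini-Hochberg
#' FDR over all genes, and a fold-change gate. The fold change reported
#' per gene is the largest-magnitude linear fold change of any
#' post-transplant timepoint mean versus the 0-month mean (signed:
#' negative = down-regulated). A gene passes when `|fc| >
#' fc_threshold`, `p < p_threshold` and `fdr < fdr_threshold`.
#'
#' Genes with zero within-group variance get the degenerate-case p-value
#' (0 when the group means differ, 1 otherwise); their count is reported
#' as a message.
#'
#' @param ds an [expression_dataset()] (log2 scale, typically after
#'   [baseline_transform()]).
#' @param fc_threshold linear fold-change gate (default 1.5).
#' @param p_threshold per-gene p-value gate (default 0.01).
#' @param fdr_threshold BH FDR gate (default 0.01).
#' @return data.frame (`de_result`): `gene`, `fc`, `p_value`, `fdr`,
#'   `pass`; thresholds are carried as attributes.
#' @export
anova_de_filter <- function(ds, fc_threshold = 1.5, p_threshold = 0.01,
                            fdr_threshold = 0.01) {
  stopifnot(inherits(ds, "expression_dataset"))
  f <- ds$sample_sheet$timepoint
  if (any(table(f) < 2)) stop("need >= 2 samples per timepoint")
  gs <- group_stats(ds$matrix, f)
  k <- length(gs$levels); N <- sum(gs$n)
  grand <- as.vector(gs$means %*% gs$n) / N
  ssb <- as.vector(((gs$means - grand)^2) %*% gs$n)
  ssw <- as.vector(gs$vars %*% (gs$n - 1))
  fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(fstat, k - 1, N - k, lower.tail = FALSE)
  degen <- ssw == 0
  if (any(degen)) {
    p[degen] <- ifelse(ssb[degen] > 0, 0, 1)
    message(sum(degen), " gene(s) with zero within-group variance; ",
            "degenerate p-value rule applied")
  }
  if (!0 %in% gs$levels) stop("no 0-month baseline samples")
  delta <- gs$means[, as.character(setdiff(gs$levels, 0)), drop = FALSE] -
    gs$means[, "0"]
  pick <- max.col(abs(delta), ties.method = "first")
  dmax <- delta[cbind(seq_len(nrow(delta)), pick)]
  fc <- signed_fc(dmax)
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(ds$matrix), fc = fc, p_value = p,
                    fdr = fdr,
                    pass = abs(fc) > fc_threshold & p < p_threshold &
                      fdr < fdr_threshold,
                    row.names = NULL)
  attr(res, "thresholds") <- c(fc = fc_threshold, p = p_threshold,
                               fdr = fdr_threshold)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Pairwise timepoint comparison against baseline
#'
#' Welch two-sample t-test of one post-transplant timepoint against the
#' 0-month baseline per gene, with the same fold-change / p / FDR gates as
#' [anova_de_filter()]. The FDR gate can be switched off
#' (`use_fdr = FALSE`) to mirror the laxer gate configuration.
#'
#' @param ds an [expression_dataset()].
#' @param timepoint the post-transplant timepoint to compare (months).
#' @param fc_threshold,p_threshold,fdr_threshold gates as in
#'   [anova_de_filter()].
#' @param use_fdr apply the FDR gate (default `TRUE`).
#' @return data.frame (`de_result`) as in [anova_de_filter()]; the passing
#'   gene set is `res$gene[res$pass]`.
#' @export
pairwise_de <- function(ds, timepoint, fc_threshold = 1.5,
                        p_threshold = 0.01, fdr_threshold = 0.01,
                        use_fdr = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  f <- ds$sample_sheet$timepoint
  if (!timepoint %in% f || !0 %in% f)
    stop("both the 0-month baseline and timepoint ", timepoint,
         " must be present")
  m0 <- ds$matrix[, f == 0, drop = FALSE]
  m1 <- ds$matrix[, f == timepoint, drop = FALSE]
  n0 <- ncol(m0); n1 <- ncol(m1)
  if (n0 < 2 || n1 < 2) stop("need >= 2 samples per group")
  mu0 <- rowMeans(m0); mu1 <- rowMeans(m1)
  v0 <- apply(m0, 1, var); v1 <- apply(m1, 1, var)
  se2 <- v0 / n0 + v1 / n1
  delta <- mu1 - mu0
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(delta[degen] != 0, 0, 1)
    message(sum(degen), " gene(s) with zero variance in both groups; ",
            "degenerate p-value rule applied")
  }
  fdr <- p.adjust(p, method = "BH")
  pass <- abs(signed_fc(delta)) > fc_threshold & p < p_threshold
  if (use_fdr) pass <- pass & fdr < fdr_threshold
  res <- data.frame(gene = rownames(ds$matrix), fc = signed_fc(delta),
                    p_value = p, fdr = fdr, pass = pass,
                    row.names = NULL)
  attr(res, "thresholds") <- c(fc = fc_threshold, p = p_threshold,
                               fdr = if (use_fdr) fdr_threshold else NA)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Unique / core partition of pairwise timepoint gene sets
#'
#' Given the gene sets differentially expressed at 2, 4 and 6 months
#' versus baseline, computes the genes unique to each timepoint and the
#' core signature present in all three. The three unique sets and the
#' core are pairwise disjoint by construction.
#'
#' @param s2,s4,s6 character vectors of gene ids (or `de_result` data
#'   frames, from which passing genes are taken).
#' @return A list (`venn_partition`): `S2`, `S4`, `S6`, `unique2`,
#'   `unique4`, `unique6`, `core`, and `region_sizes` (all seven Venn
#'   regions).
#' @export
venn_core <- function(s2, s4, s6) {
  as_set <- function(s)
    if (inherits(s, "de_result")) s$gene[s$pass] else unique(as.character(s))
  s2 <- as_set(s2); s4 <- as_set(s4); s6 <- as_set(s6)
  core <- intersect(intersect(s2, s4), s6)
  u2 <- setdiff(s2, union(s4, s6))
  u4 <- setdiff(s4, union(s2, s6))
  u6 <- setdiff(s6, union(s2, s4))
  structure(list(
    S2 = s2, S4 = s4, S6 = s6,
    unique2 = u2, unique4 = u4, unique6 = u6, core = core,
    region_sizes = c(
      only2 = length(u2), only4 = length(u4), only6 = length(u6),
      s2_s4 = length(setdiff(intersect(s2, s4), s6)),
      s2_s6 = length(setdiff(intersect(s2, s6), s4)),
      s4_s6 = length(setdiff(intersect(s4, s6), s2)),
      core = length(core))
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf(
    "venn_partition: |S2| = %d, |S4| = %d, |S6| = %d\nunique: %d / %d / %d; core: %d\n",
    length(x$S2), length(x$S4), length(x$S6),
    length(x$unique2), length(x$unique4), length(x$unique6),
    length(x$core)))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on a gene subset (typically the
#' DE-filter passes), using 1 - Pearson correlation distance and average
#' linkage by default; both are recorded on the result.
#'
#' @param ds an [expression_dataset()].
#' @param genes optional character vector restricting the matrix.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return A list: `hclust`, `order` (sample ids in dendrogram order),
#'   `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(ds, genes = NULL, distance = "pearson",
                                 linkage = "average") {
  stopifnot(inherits(ds, "expression_dataset"))
  mat <- ds$matrix
  if (!is.null(genes)) mat <- mat[rownames(mat) %in% genes, ,
                                  drop = FALSE]
  if (ncol(mat) < 2) stop("need >= 2 samples")
  d <- if (distance == "pearson") {
    as.dist(1 - cor(mat))
  } else dist(t(mat))
  hc <- hclust(d, method = linkage)
  list(hclust = hc, order = hc$labels[hc$order],
       distance = distance, linkage = linkage)
}

#' Write a sample dendrogram as Newick
#'
#' @param clustering result of [hierarchical_cluster()] (or an `hclust`).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering
        else clustering$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' qPCR relative quantification (delta-delta Ct)
#'
#' `RQ = 2^(-ddCt)` with `dCt = Ct_target - Ct_reference` per sample,
#' averaged per condition, and `ddCt` taken relative to the baseline
#' condition, whose RQ is 1 by construction. Samples missing the
#' reference-gene Ct are excluded with a message.
#'
#' @param ct data.frame with columns `sample`, `condition`, `gene`, `ct`;
#'   the reference gene must have a Ct for every retained sample.
#' @param reference_gene reference (housekeeping) gene id, default
#'   `"GAPDH"`.
#' @param baseline the baseline condition (e.g. `0` months).
#' @return data.frame: `gene`, `condition`, `d_ct`, `dd_ct`, `rq`.
#' @export
relative_quantification <- function(ct, reference_gene = "GAPDH",
                                    baseline) {
  req <- c("sample", "condition", "gene", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  ref <- ct[ct$gene == reference_gene, c("sample", "ct")]
  if (nrow(ref) == 0) stop("reference gene '", reference_gene,
                           "' not in the table")
  names(ref)[2] <- "ct_ref"
  tgt <- ct[ct$gene != reference_gene, ]
  merged <- merge(tgt, ref, by = "sample", all.x = TRUE)
  drop <- is.na(merged$ct_ref)
  if (any(drop)) {
    message("excluding ", length(unique(merged$sample[drop])),
            " sample(s) without a reference Ct")
    merged <- merged[!drop, ]
  }
  merged$d_ct <- merged$ct - merged$ct_ref
  agg <- stats::aggregate(d_ct ~ gene + condition, data = merged,
                          FUN = mean)
  base <- agg[agg$condition == baseline, c("gene", "d_ct")]
  if (nrow(base) == 0) stop("baseline condition '", baseline,
                            "' not present")
  names(base)[2] <- "d_ct_base"
  out <- merge(agg, base, by = "gene")
  out$dd_ct <- out$d_ct - out$d_ct_base
  out$rq <- 2^(-out$dd_ct)
  out[order(out$gene, out$condition),
      c("gene", "condition", "d_ct", "dd_ct", "rq")]
}
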