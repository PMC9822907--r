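make_ds <- function(...)
  suppressWarnings(generate_expression_dataset(...))

test_that("baseline transform centres every gene's median at zero", {
  m <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  sheet <- data.frame(sample = paste0("s", 1:4), subject = "x",
                      timepoint = c(0, 2, 4, 6))
  ds <- baseline_transform(expression_dataset(m, sheet))
  expect_equal(unname(ds$matrix["gA", ]), c(0, 0, 0, 0))
  expect_equal(unname(ds$matrix["gB", ]), c(-1.5, -0.5, 0.5, 1.5))
  # random matrix: all medians zero afterwards; idempotent
  gen <- make_ds(n_genes = 100, n_per_timepoint = 3,
                 n_unique = c(3, 3, 3), n_core = 3, seed = 5L)
  bt <- baseline_transform(gen$dataset)
  expect_true(all(abs(apply(bt$matrix, 1, median)) < 1e-12))
  expect_equal(baseline_transform(bt)$matrix, bt$matrix,
               tolerance = 1e-12)
})

test_that("noiseless DE filter has perfect sensitivity and specificity", {
  gen <- make_ds(n_genes = 400, n_per_timepoint = 3,
                 n_unique = c(10, 10, 10), n_core = 10,
                 effect_log2 = 1, noise_sd = 0, seed = 6L)
  suppressMessages(de <- anova_de_filter(baseline_transform(gen$dataset)))
  planted <- unlist(gen$truth[c("unique2", "unique4", "unique6", "core")])
  hits <- de$gene[de$pass]
  expect_setequal(hits, planted)
})

test_that("the fold-change gate rejects significant sub-threshold genes", {
  # FC 1.4 with near-zero noise: tiny p but |FC| <= 1.5 -> fail
  set.seed(7)
  n <- 6
  tps <- rep(c(0, 2, 4, 6), each = n)
  m <- matrix(rnorm(4 * n * 50, 8, 0.01), nrow = 50)
  m[1, tps > 0] <- m[1, tps > 0] + log2(1.4)
  m[2, tps > 0] <- m[2, tps > 0] + log2(4)
  rownames(m) <- sprintf("g%02d", 1:50)
  colnames(m) <- sprintf("s%02d", seq_len(4 * n))
  ds <- expression_dataset(m, data.frame(sample = colnames(m),
                                         subject = "x",
                                         timepoint = tps))
  de <- anova_de_filter(ds)
  expect_lt(de$p_value[1], 1e-6)
  expect_false(de$pass[1])
  expect_true(de$pass[2])
})

test_that("ANOVA p-values match stats::aov on a small matrix", {
  gen <- make_ds(n_genes = 40, n_per_timepoint = 4,
                 n_unique = c(2, 2, 2), n_core = 2,
                 effect_log2 = 1, noise_sd = 0.5, seed = 8L)
  ds <- gen$dataset
  de <- anova_de_filter(ds)
  tp <- factor(ds$sample_sheet$timepoint)
  for (g in c(1, 7, 25)) {
    fit <- anova(aov(ds$matrix[g, ] ~ tp))
    expect_equal(de$p_value[g], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("pairwise Welch tests match stats::t.test and place planted genes", {
  gen <- make_ds(n_genes = 300, n_per_timepoint = 4,
                 n_unique = c(8, 8, 8), n_core = 8,
                 effect_log2 = 3, noise_sd = 0.2, seed = 9L)
  ds <- baseline_transform(gen$dataset)
  s2 <- pairwise_de(ds, 2)
  tp <- ds$sample_sheet$timepoint
  for (g in c(2, 150)) {
    tt <- t.test(ds$matrix[g, tp == 2], ds$matrix[g, tp == 0])
    expect_equal(s2$p_value[g], tt$p.value, tolerance = 1e-10)
  }
  s4 <- pairwise_de(ds, 4); s6 <- pairwise_de(ds, 6)
  vp <- venn_core(s2, s4, s6)
  # planted core genes appear in all three comparisons
  expect_true(all(gen$truth$core %in% vp$core))
  # planted unique-2mo genes never appear at 4 or 6 months
  expect_false(any(gen$truth$unique2 %in% c(vp$S4, vp$S6)))
  expect_true(all(gen$truth$unique2 %in% vp$unique2))
})

test_that("null matrices respect the FDR gate over repeated draws", {
  passes <- vapply(1:10, function(s) {
    gen <- make_ds(n_genes = 2000, n_per_timepoint = 3,
                   n_unique = c(0, 0, 0), n_core = 0,
                   effect_log2 = 0, noise_sd = 0.5, seed = 400L + s)
    de <- anova_de_filter(baseline_transform(gen$dataset))
    sum(de$pass)
  }, numeric(1))
  # with no planted effects the expected pass count under FDR < 0.01
  # control is a small handful; the mean must stay near zero
  expect_lt(mean(passes), 2)
})

test_that("venn partition set algebra is exact", {
  vp <- venn_core(c("a", "b", "c"), c("b", "c"), c("c"))
  expect_identical(vp$unique2, "a")
  expect_identical(vp$unique4, character(0))
  expect_identical(vp$unique6, character(0))
  expect_identical(vp$core, "c")
  # disjoint sets: core empty, uniques equal the inputs
  vd <- venn_core(c("a"), c("b"), c("d"))
  expect_identical(vd$core, character(0))
  expect_identical(vd$unique2, "a")
  # all seven regions tile the union (brute-force membership check)
  set.seed(10)
  univ <- sprintf("g%03d", 1:200)
  s2 <- sample(univ, 70); s4 <- sample(univ, 60); s6 <- sample(univ, 80)
  vr <- venn_core(s2, s4, s6)
  expect_identical(sum(vr$region_sizes),
                   length(union(union(s2, s4), s6)))
  # unique sets and core are pairwise disjoint
  parts <- list(vr$unique2, vr$unique4, vr$unique6, vr$core)
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(parts[[i]], parts[[j]]), 0)
})

test_that("sample clustering groups timepoint blocks and ignores input order", {
  gen <- make_ds(n_genes = 300, n_per_timepoint = 3,
                 n_unique = c(0, 0, 0), n_core = 60,
                 effect_log2 = 3, noise_sd = 0.2, seed = 11L)
  ds <- baseline_transform(gen$dataset)
  cl <- hierarchical_cluster(ds, genes = gen$truth$core)
  ord_tp <- ds$sample_sheet$timepoint[match(cl$order,
                                            ds$sample_sheet$sample)]
  # baseline samples form one contiguous block (core genes separate
  # 0 months from everything else)
  base_pos <- which(ord_tp == 0)
  expect_identical(diff(range(base_pos)), 2L)
  # permuting columns leaves merge heights unchanged
  perm <- sample(ncol(ds$matrix))
  dsp <- expression_dataset(ds$matrix[, perm],
                            ds$sample_sheet[perm, ])
  clp <- hierarchical_cluster(dsp, genes = gen$truth$core)
  expect_equal(sort(clp$hclust$height), sort(cl$hclust$height),
               tolerance = 1e-12)
  # duplicated sample merges first at distance zero
  m2 <- cbind(ds$matrix, dup = ds$matrix[, 1])
  sheet2 <- rbind(ds$sample_sheet,
                  data.frame(sample = "dup", subject = "x",
                             timepoint = 0))
  cl2 <- hierarchical_cluster(expression_dataset(m2, sheet2))
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)
  # newick export parses back with the same tips
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(ds$matrix))
})

test_that("relative quantification reproduces the hand-computed table", {
  ct <- rbind(
    data.frame(sample = "b1", condition = "0mo", gene = "TGFB1", ct = 25),
    data.frame(sample = "b1", condition = "0mo", gene = "GAPDH", ct = 20),
    data.frame(sample = "t1", condition = "2mo", gene = "TGFB1", ct = 24),
    data.frame(sample = "t1", condition = "2mo", gene = "GAPDH", ct = 20)
  )
  rq <- relative_quantification(ct, "GAPDH", baseline = "0mo")
  expect_equal(rq$rq[rq$condition == "0mo"], 1)
  expect_equal(rq$rq[rq$condition == "2mo"], 2)
  # target tracking the reference gives RQ 1 everywhere
  ct2 <- ct; ct2$ct[ct2$gene == "TGFB1"] <- ct2$ct[ct2$gene == "GAPDH"] + 3
  rq2 <- relative_quantification(ct2, "GAPDH", baseline = "0mo")
  expect_true(all(rq2$rq == 1))
  # missing reference Ct excludes that sample with a message
  ct3 <- ct[-4, ]
  expect_message(rq3 <- relative_quantification(ct3, "GAPDH", "0mo"),
                 "without a reference")
  expect_identical(nrow(rq3), 1L)
})

test_that("series-matrix reader parses the standard block format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    '!Series_title\t"example"',
    "!series_matrix_table_begin",
    paste("ID_REF", "GSM1", "GSM2", "GSM3", "GSM4", sep = "\t"),
    paste('"g1"', "1.5", "2.5", "3.5", "4.5", sep = "\t"),
    paste('"g2"', "5.0", "5.0", "5.0", "5.0", sep = "\t"),
    "!series_matrix_table_end"
  ), path)
  sheet <- data.frame(sample = paste0("GSM", 1:4), subject = "p1",
                      timepoint = c(0, 2, 4, 6))
  ds <- read_series_matrix(path, sheet)
  expect_identical(rownames(ds$matrix), c("g1", "g2"))
  expect_equal(unname(ds$matrix["g1", ]), c(1.5, 2.5, 3.5, 4.5))
})
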