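#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino) and the
#' transformed kurtosis statistic (Anscombe-Glynn) into
#' `K2 = Zs^2 + Zk^2`, chi-squared with 2 degrees of freedom under
#' normality. Requires `n >= 8` (the kurtosis transform is undefined
#' below that).
#'
#' @param x numeric sample.
#' @return A list: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("sample is constant")
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2s <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2s - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  b2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  v_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(v_b2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z_k <- ((1 - 2 / (9 * a)) -
            ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_s^2 + z_k^2
  list(statistic = k2, p_value = pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_s, z_kurt = z_k, n = n)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs test: `G = max|x - mean| / sd` against the critical
#' value derived from the t distribution at significance level `alpha`.
#' At most one observation is flagged per call; a constant sample flags
#' none.
#'
#' @param x numeric sample (`n >= 3`).
#' @param alpha significance level (default 0.05).
#' @return A list: `outlier_index` (`NA` when none), `outlier_value`, `G`,
#'   `critical`, `n`.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("Grubbs' test requires n >= 3")
  s <- sd(x)
  if (s == 0) {
    message("constant sample: no outlier")
    return(list(outlier_index = NA_integer_, outlier_value = NA_real_,
                G = 0, critical = NA_real_, n = n))
  }
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  g <- dev[i] / s
  tcrit <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(outlier_index = if (g > gcrit) i else NA_integer_,
       outlier_value = if (g > gcrit) x[i] else NA_real_,
       G = g, critical = gcrit, n = n)
}

#' Dunn's post-hoc test
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis test, with tie
#' correction; p-values are Bonferroni-adjusted over all pairs.
#'
#' @param values numeric vector.
#' @param groups grouping factor, same length.
#' @return data.frame: `comparison`, `z`, `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  tie <- table(r)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lv <- levels(groups)
  k <- length(lv)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z <- (rbar[i] - rbar[j]) / se
    out <- rbind(out, data.frame(
      comparison = paste(lv[i], "-", lv[j]),
      z = as.numeric(z),
      p_value = 2 * pnorm(abs(z), lower.tail = FALSE)))
  }
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

normality_p <- function(x, alpha) {
  if (length(x) >= 8) {
    list(p = dagostino_pearson(x)$p_value, method = "dagostino_pearson")
  } else {
    list(p = shapiro.test(x)$p.value, method = "shapiro_wilk")
  }
}

#' Assumption-driven test selection and execution
#'
#' The statistical decision tree: D'Agostino-Pearson normality per group
#' (Shapiro-Wilk below n = 8), then variance homogeneity (F test for two
#' groups, Bartlett for more), then the matched test: Student's t /
#' one-way ANOVA with Tukey post-hoc / two-way ANOVA with Tukey when both
#' assumptions hold, otherwise Mann-Whitney U / Kruskal-Wallis with Dunn
#' post-hoc. The full decision trace is recorded on the result.
#'
#' @param groups for designs `"two-group"` and `"one-way"`: a (named) list
#'   of numeric samples, each `n >= 3`. For `"two-way"`: a data.frame with
#'   columns `value`, `timepoint`, `subject`; the tree is evaluated on the
#'   timepoint groups.
#' @param design `"two-group"`, `"one-way"` or `"two-way"`.
#' @param alpha significance level for the assumption checks.
#' @return A `stat_result` list: `test`, `statistic`, `p_value`,
#'   `posthoc` (data.frame or NULL), `trace`.
#' @export
select_and_run_test <- function(groups,
                                design = c("two-group", "one-way",
                                           "two-way"),
                                alpha = 0.05) {
  design <- match.arg(design)
  if (design == "two-way") {
    stopifnot(is.data.frame(groups),
              all(c("value", "timepoint", "subject") %in% names(groups)))
    df <- groups
    glist <- split(df$value, df$timepoint)
  } else {
    stopifnot(is.list(groups), length(groups) >= 2)
    if (design == "two-group" && length(groups) != 2)
      stop("two-group design needs exactly 2 groups")
    glist <- groups
    if (is.null(names(glist)))
      names(glist) <- paste0("g", seq_along(glist))
  }
  ns <- lengths(glist)
  if (any(ns < 3)) stop("every group needs n >= 3 (normality test ",
                        "undefined below that)")
  norm <- lapply(glist, normality_p, alpha = alpha)
  norm_p <- vapply(norm, `[[`, numeric(1), "p")
  normal <- all(norm_p > alpha)
  vt <- list(method = NA_character_, p = NA_real_)
  equal_var <- NA
  if (normal) {
    if (length(glist) == 2) {
      v <- var.test(glist[[1]], glist[[2]])
      vt <- list(method = "f_test", p = v$p.value)
    } else {
      v <- bartlett.test(glist)
      vt <- list(method = "bartlett", p = v$p.value)
    }
    equal_var <- vt$p > alpha
  }
  parametric <- normal && isTRUE(equal_var)
  trace <- list(
    n = as.numeric(ns),
    normality_method = vapply(norm, `[[`, character(1), "method"),
    normality_p = norm_p,
    normal = normal,
    variance_test = vt$method,
    variance_p = vt$p,
    equal_variances = equal_var,
    branch = if (parametric) "parametric" else "nonparametric"
  )

  posthoc <- NULL
  if (parametric) {
    if (design == "two-group") {
      tt <- t.test(glist[[1]], glist[[2]], var.equal = TRUE)
      res <- list(test = "student_t", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else if (design == "one-way") {
      dat <- data.frame(
        value = unlist(glist, use.names = FALSE),
        group = factor(rep(names(glist), ns)))
      fit <- aov(value ~ group, data = dat)
      tab <- anova(fit)
      tk <- TukeyHSD(fit)$group
      posthoc <- data.frame(comparison = rownames(tk),
                            estimate = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL)
      res <- list(test = "one_way_anova_tukey",
                  statistic = tab[["F value"]][1],
                  p_value = tab[["Pr(>F)"]][1])
    } else {
      df$timepoint <- factor(df$timepoint)
      df$subject <- factor(df$subject)
      fit <- aov(value ~ timepoint + subject, data = df)
      tab <- anova(fit)
      tk <- TukeyHSD(fit, which = "timepoint")$timepoint
      posthoc <- data.frame(comparison = rownames(tk),
                            estimate = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL)
      res <- list(test = "two_way_anova_tukey",
                  statistic = tab["timepoint", "F value"],
                  p_value = tab["timepoint", "Pr(>F)"])
    }
  } else {
    if (design == "two-group") {
      wt <- wilcox.test(glist[[1]], glist[[2]])
      res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value)
    } else {
      vals <- unlist(glist, use.names = FALSE)
      grp <- factor(rep(names(glist), ns))
      kw <- kruskal.test(vals, grp)
      posthoc <- dunn_test(vals, grp)
      res <- list(test = "kruskal_wallis_dunn",
                  statistic = unname(kw$statistic),
                  p_value = kw$p.value)
    }
  }
  structure(c(res, list(posthoc = posthoc, trace = trace)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("stat_result: %s, statistic = %.4g, p = %.4g (%s branch)\n",
              x$test, x$statistic, x$p_value, x$trace$branch))
  invisible(x)
}
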