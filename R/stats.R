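## Group descriptives and comparisons used in the per-figure reports.

#' Descriptive statistics of one sample
#'
#' Either mean with standard error, or median with the 25th/75th
#' percentiles (linear interpolation between order statistics — the default
#' R quantile convention, type 7).
#'
#' @param x numeric sample (n >= 1).
#' @param style `"mean_sem"` or `"median_iqr"`.
#' @return named list; with `style = "mean_sem"` and `n = 1` the SEM is
#'   `NA` and `flagged` is TRUE.
#' @examples
#' describeSample(c(1, 2, 3), "mean_sem")      # 2 +/- 0.577
#' describeSample(c(1, 2, 3, 4), "median_iqr") # 2.5 (1.75 - 3.25)
#' @export
describeSample <- function(x, style = c("mean_sem", "median_iqr")) {
  style <- match.arg(style)
  if (length(x) < 1L) stop("sample must contain at least one value")
  if (style == "mean_sem") {
    sem <- if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
    list(style = style, mean = mean(x), sem = sem, n = length(x),
         flagged = length(x) < 2L)
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(style = style, median = q[2L], iqr_low = q[1L], iqr_high = q[3L],
         n = length(x), flagged = FALSE)
  }
}

#' Compare groups with the tests used for the figure panels
#'
#' Two-sided throughout. Designs:
#' * `two_indep`: Mann-Whitney (Wilcoxon rank sum) for two groups;
#' * `k_indep_nonparametric`: Kruskal-Wallis, with pairwise Mann-Whitney
#'   post hoc tests (Bonferroni adjusted);
#' * `k_indep_parametric`: one-way ANOVA, with Newman-Keuls (stepwise
#'   studentized range) or Bonferroni-adjusted pairwise t post hoc tests.
#'
#' Bonferroni adjustment is `min(1, m * p)` exactly. Rank tests on heavily
#' tied data fall back to the normal approximation with tie correction (as
#' implemented by the base tests) and are flagged.
#'
#' @param samples named list of numeric vectors (>= 2 groups).
#' @param design `"two_indep"`, `"k_indep_parametric"` or
#'   `"k_indep_nonparametric"`.
#' @param posthoc `"none"`, `"bonferroni"` or `"newman_keuls"` (parametric
#'   designs only; Bonferroni is the default because Newman-Keuls lacks
#'   strong familywise error control).
#' @param describe descriptive style passed to [describeSample()].
#' @return list of class `ComparisonResult`: `test`, `statistic`, `p_value`,
#'   `posthoc` (data.frame of pairs with raw and adjusted p), `descriptives`
#'   per group, `tied` flag.
#' @examples
#' compareGroups(list(a = 1:10, b = 11:20), design = "two_indep")
#' @export
compareGroups <- function(samples,
                          design = c("two_indep", "k_indep_parametric",
                                     "k_indep_nonparametric"),
                          posthoc = c("bonferroni", "newman_keuls", "none"),
                          describe = c("median_iqr", "mean_sem")) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  describe <- match.arg(describe)
  if (!is.list(samples) || length(samples) < 2L)
    stop("'samples' must be a named list of at least two groups")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("group", seq_along(samples))
  if (design == "two_indep" && length(samples) != 2L)
    stop("'two_indep' requires exactly two groups")

  pooled <- unlist(samples)
  tied <- any(duplicated(pooled))
  allTied <- length(unique(pooled)) == 1L
  if (allTied && design != "k_indep_parametric")
    warning("all values tied; rank test degenerate (tie correction applied)")

  ph <- NULL
  if (design == "two_indep") {
    tst <- suppressWarnings(stats::wilcox.test(samples[[1L]], samples[[2L]],
                                               alternative = "two.sided"))
    testName <- "Mann-Whitney U"
    statistic <- unname(tst$statistic)
    p <- if (allTied) 1 else tst$p.value
  } else if (design == "k_indep_nonparametric") {
    tst <- stats::kruskal.test(samples)
    testName <- "Kruskal-Wallis"
    statistic <- unname(tst$statistic)
    p <- if (allTied) 1 else tst$p.value
    if (posthoc != "none") {
      pairs <- utils::combn(names(samples), 2)
      m <- ncol(pairs)
      ph <- do.call(rbind, lapply(seq_len(m), function(k) {
        a <- pairs[1, k]; b <- pairs[2, k]
        pw <- suppressWarnings(
          stats::wilcox.test(samples[[a]], samples[[b]]))$p.value
        if (!is.finite(pw)) pw <- 1
        data.frame(group1 = a, group2 = b, p_raw = pw,
                   p_adjusted = min(1, m * pw), stringsAsFactors = FALSE)
      }))
    }
  } else {
    values <- unlist(samples)
    group <- factor(rep(names(samples), lengths(samples)))
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1L]]
    testName <- "one-way ANOVA"
    statistic <- an[["F value"]][1L]
    p <- an[["Pr(>F)"]][1L]
    if (posthoc == "bonferroni") {
      pairs <- utils::combn(names(samples), 2)
      m <- ncol(pairs)
      ph <- do.call(rbind, lapply(seq_len(m), function(k) {
        a <- pairs[1, k]; b <- pairs[2, k]
        pw <- stats::t.test(samples[[a]], samples[[b]])$p.value
        data.frame(group1 = a, group2 = b, p_raw = pw,
                   p_adjusted = min(1, m * pw), stringsAsFactors = FALSE)
      }))
    } else if (posthoc == "newman_keuls") {
      ph <- newmanKeuls(samples)
    }
  }

  structure(list(test = testName, statistic = statistic, p_value = p,
                 posthoc = ph,
                 descriptives = lapply(samples, describeSample, style = describe),
                 tied = tied, design = design, posthoc_method = posthoc),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$posthoc)) {
    cat(sprintf("post hoc (%s):\n", x$posthoc_method))
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Newman-Keuls stepwise studentized-range procedure
#'
#' Classical stepwise procedure on the group means: means are ordered, the
#' studentized range statistic `q = diff / sqrt(MSE/2 * (1/n_i + 1/n_j))` is
#' referred to the studentized-range distribution with the span of the
#' comparison as the number of means, and inner comparisons are blocked
#' (declared non-significant without testing) when an enclosing span fails.
#'
#' @param samples named list of numeric vectors.
#' @param alpha significance level used for the blocking logic.
#' @return data.frame with `group1`, `group2`, `span`, `q`, `p_value`
#'   (`NA` when blocked), `significant`.
#' @export
newmanKeuls <- function(samples, alpha = 0.05) {
  k <- length(samples)
  means <- vapply(samples, mean, numeric(1))
  ns <- lengths(samples)
  dfe <- sum(ns) - k
  mse <- sum(vapply(samples, function(x)
    sum((x - mean(x))^2), numeric(1))) / dfe
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  nms <- names(samples)[ord]

  rows <- list()
  blocked <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (blocked[i, j]) {
        rows[[length(rows) + 1L]] <-
          data.frame(group1 = nms[i], group2 = nms[j], span = span,
                     q = NA_real_, p_value = NA_real_, significant = FALSE,
                     stringsAsFactors = FALSE)
        next
      }
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- (means[j] - means[i]) / se
      p <- 1 - stats::ptukey(q, nmeans = span, df = dfe)
      sig <- p < alpha
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = nms[i], group2 = nms[j], span = span, q = q,
                   p_value = p, significant = sig, stringsAsFactors = FALSE)
      if (!sig) {
        ## block all comparisons nested inside a non-significant span
        for (a in i:j) for (b in i:j) if (b > a && (b - a + 1L) < span)
          blocked[a, b] <- TRUE
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
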