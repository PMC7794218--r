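# Statistical decision procedure: normality gate, test selection and the
# two-control significance rule of Gal4/UAS experiments.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness statistic and the Anscombe-Glynn
#' kurtosis statistic into the K-squared omnibus statistic, referred to a
#' chi-squared distribution with 2 degrees of freedom.  Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (K-squared), `p_value`, `z_skew`,
#'   `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample", call. = FALSE)
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness: D'Agostino (1970) transformation to normality
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983) transformation
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - e_b2) / sqrt(var_b2)
  sqb1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1_b2 * (2 / sqb1_b2 + sqrt(1 + 4 / sqb1_b2^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality gate for test selection
#'
#' Each group is tested for normality at `alpha`: with the
#' D'Agostino-Pearson omnibus test when the group has at least
#' `small_n_cut` observations, otherwise with the Shapiro-Wilk test (the
#' small-N branch).  The parametric branch is taken only when every group
#' passes.
#'
#' @param samples List of numeric vectors, one per group (each n >= 3).
#' @param alpha Normality rejection level.
#' @param small_n_cut Group sizes below this use Shapiro-Wilk.
#' @return List with `branch` (`"parametric"` or `"nonparametric"`) and a
#'   data frame `tests` (`group`, `n`, `test`, `p_value`, `normal`).
#' @export
normality_gate <- function(samples, alpha = 0.05, small_n_cut = 8) {
  if (!is.list(samples)) samples <- list(samples)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]]
    n <- sum(is.finite(x))
    if (n < 3) stop(sprintf("group '%s' has n < 3", g), call. = FALSE)
    if (stats::sd(x) == 0) {
      # constant group: cannot be tested; treat as non-normal
      return(data.frame(group = g, n = n, test = "degenerate",
                        p_value = NA_real_, normal = FALSE,
                        stringsAsFactors = FALSE))
    }
    if (n >= small_n_cut) {
      t <- dagostino_pearson(x)
      data.frame(group = g, n = n, test = "dagostino-pearson",
                 p_value = t$p_value, normal = t$p_value >= alpha,
                 stringsAsFactors = FALSE)
    } else {
      t <- stats::shapiro.test(x)
      data.frame(group = g, n = n, test = "shapiro-wilk",
                 p_value = t$p.value, normal = t$p.value >= alpha,
                 stringsAsFactors = FALSE)
    }
  })
  tests <- do.call(rbind, rows)
  list(branch = if (all(tests$normal)) "parametric" else "nonparametric",
       tests = tests)
}

# Dunn's rank-based post hoc comparisons after Kruskal-Wallis, with tie
# correction; returns the unadjusted two-sided p-value for each requested
# pair against the reference group
.dunn_vs_reference <- function(values, groups, reference) {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lvls <- unique(groups)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  others <- setdiff(lvls, reference)
  p <- vapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[[reference]] + 1 / ns[[g]]))
    z <- (rbar[[reference]] - rbar[[g]]) / se
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  stats::setNames(p, others)
}

#' Two-control group comparison
#'
#' Implements the significance rule of Gal4/UAS experiments: the
#' experimental group is compared against both parental controls and an
#' effect is reported as significant only when it differs from both.  The
#' branch is chosen by [normality_gate()] unless supplied: the parametric
#' branch runs a one-way ANOVA with Dunnett-type comparisons of both
#' controls against the test group (single-step adjusted); the
#' non-parametric branch runs Kruskal-Wallis with Dunn's post hoc
#' comparisons (Bonferroni-adjusted over the two control contrasts).
#'
#' @param test,ctrl_gal4,ctrl_uas Numeric samples of the experimental group
#'   and the two parental controls.
#' @param metric Label of the compared metric.
#' @param alpha Significance level.
#' @param branch `"parametric"`, `"nonparametric"`, or `NULL` to gate
#'   automatically.
#' @param labels Group labels, used in output.
#' @return One-row data frame of class `comparison_result` with `metric`,
#'   `test_used`, `p_vs_gal4`, `p_vs_uas`, `significant` (both adjusted
#'   p < alpha), `alpha`, `branch`, `degenerate`.
#' @export
two_control_comparison <- function(test, ctrl_gal4, ctrl_uas,
                                   metric = "metric", alpha = 0.05,
                                   branch = NULL,
                                   labels = c("test", "control_gal4",
                                              "control_uas")) {
  samples <- list(test, ctrl_gal4, ctrl_uas)
  names(samples) <- labels
  if (any(vapply(samples, function(x) sum(is.finite(x)), 0L) < 3))
    stop("each group needs at least 3 finite values", call. = FALSE)
  values <- unlist(samples)
  groups <- factor(rep(labels, vapply(samples, length, 0L)), levels = labels)
  if (stats::sd(values) == 0) {
    out <- data.frame(metric = metric, test_used = "none (degenerate)",
                      p_vs_gal4 = NA_real_, p_vs_uas = NA_real_,
                      significant = FALSE, alpha = alpha,
                      branch = NA_character_, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    class(out) <- c("comparison_result", "data.frame")
    return(out)
  }
  if (is.null(branch)) branch <- normality_gate(samples, alpha)$branch
  branch <- match.arg(branch, c("parametric", "nonparametric"))
  if (branch == "parametric") {
    d <- data.frame(value = values, group = groups)
    fit <- stats::aov(value ~ group, data = d)
    ght <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    p <- summary(ght)$test$pvalues
    # Dunnett with the test group as reference: contrasts are
    # control_gal4 - test and control_uas - test
    p_gal4 <- p[1]
    p_uas <- p[2]
    used <- "one-way ANOVA + Dunnett"
  } else {
    kw <- stats::kruskal.test(values, groups)
    p_raw <- .dunn_vs_reference(values, as.character(groups), labels[1])
    # Bonferroni over the two control contrasts
    p_adj <- stats::setNames(pmin(p_raw * length(p_raw), 1), names(p_raw))
    p_gal4 <- p_adj[[labels[2]]]
    p_uas <- p_adj[[labels[3]]]
    used <- "Kruskal-Wallis + Dunn"
  }
  out <- data.frame(metric = metric, test_used = used,
                    p_vs_gal4 = unname(p_gal4), p_vs_uas = unname(p_uas),
                    significant = p_gal4 < alpha && p_uas < alpha,
                    alpha = alpha, branch = branch, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Two-sample comparison with normality gating
#'
#' For designs with a single comparison (e.g. wild type at two
#' temperatures): Welch's t-test on the parametric branch, Mann-Whitney
#' (Wilcoxon rank-sum) otherwise.
#'
#' @param x,y Numeric samples.
#' @param metric Label of the compared metric.
#' @param alpha Significance level.
#' @param branch `"parametric"`, `"nonparametric"`, or `NULL` to gate.
#' @return One-row data frame with `metric`, `test_used`, `p_value`,
#'   `significant`.
#' @export
two_sample_comparison <- function(x, y, metric = "metric", alpha = 0.05,
                                  branch = NULL) {
  if (sum(is.finite(x)) < 3 || sum(is.finite(y)) < 3)
    stop("each group needs at least 3 finite values", call. = FALSE)
  if (stats::sd(c(x, y)) == 0) {
    return(data.frame(metric = metric, test_used = "none (degenerate)",
                      p_value = NA_real_, significant = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (is.null(branch))
    branch <- normality_gate(list(a = x, b = y), alpha)$branch
  if (branch == "parametric") {
    p <- stats::t.test(x, y)$p.value
    used <- "Welch t-test"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    used <- "Mann-Whitney"
  }
  data.frame(metric = metric, test_used = used, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Combine comparison results into a summary table
#'
#' @param results List of comparison rows from [two_control_comparison()]
#'   (optionally tagged with a `condition` column) or a single such row.
#' @param p_adjust Optional multiple-testing correction applied across the
#'   table's overall verdicts (`"none"`, default, or `"BH"`).
#' @return Data frame with one row per (condition, metric), ordered by
#'   condition then metric.
#' @export
summary_table <- function(results, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (inherits(results, "data.frame")) results <- list(results)
  if (length(results) == 0) stop("no comparisons supplied", call. = FALSE)
  rows <- lapply(results, function(r) {
    if (!"condition" %in% names(r)) r$condition <- "condition1"
    r
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    r[, union(c("condition", "metric"), names(r)), drop = FALSE]
  }))
  out <- out[order(out$condition, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  if (p_adjust == "BH" && all(c("p_vs_gal4", "p_vs_uas") %in% names(out))) {
    pmaxv <- pmax(out$p_vs_gal4, out$p_vs_uas)
    adj <- stats::p.adjust(pmaxv, method = "BH")
    out$p_overall_bh <- adj
    out$significant <- adj < out$alpha
  }
  out
}
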