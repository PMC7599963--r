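# Cohort-level statistics (demographic table tests) and ROI-level
# Spearman correlations with Benjamini-Hochberg correction.
#
# All standard tests are delegated to base R (chisq.test, fisher.test,
# t.test, wilcox.test, kruskal.test, ks.test) and car::leveneTest; the
# only hand-written statistic is the pooled two-sample t from printed
# summaries, which t.test cannot take.

test_result <- function(test, statistic, df, p, groups) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), groups = groups),
            class = "microtract_test")
}

#' @export
print.microtract_test <- function(x, ...) {
  cat(x$test, ": stat = ", signif(x$statistic, 4),
      if (!is.null(x$df) && !all(is.na(x$df)))
        paste0(", df = ", paste(x$df, collapse = ", ")) else "",
      ", p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Contingency-table tests
#'
#' Pearson chi-square (no continuity correction) for r x c count tables;
#' two-sided Fisher exact (sum of hypergeometric probabilities of tables
#' no more likely than the observed one) for 2 x 2 tables.
#'
#' @param counts matrix of non-negative integer counts (categories x
#'   groups).
#' @param test "chisq" or "fisher" (fisher needs a 2 x 2 table).
#' @return a `microtract_test`.
#' @export
contingency_tests <- function(counts, test = c("chisq", "fisher")) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop_validation("need at least a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_validation("zero marginal in contingency table")
  if (test == "chisq") {
    r <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    test_result("chi-square", r$statistic, r$parameter, r$p.value,
                colnames(counts))
  } else {
    if (!all(dim(counts) == c(2L, 2L)))
      stop_validation("Fisher exact test requires a 2 x 2 table")
    r <- stats::fisher.test(counts)
    test_result("fisher-exact", r$estimate, NA, r$p.value, colnames(counts))
  }
}

#' Two-sample tests (t and Mann-Whitney)
#'
#' The t-test is the pooled-variance two-tailed test with
#' df = n_a + n_b - 2, accepting either raw samples or printed summaries
#' `list(mean =, sd =, n =)`. The Mann-Whitney U test needs raw samples;
#' the smaller of the two U values is reported, with the
#' normal approximation (tie-corrected) for n > 20 per group and the
#' exact distribution otherwise.
#'
#' @param a,b numeric vectors, or for `kind = "t"` summary lists.
#' @param kind "t" or "mann_whitney".
#' @return a `microtract_test`.
#' @export
two_sample_tests <- function(a, b, kind = c("t", "mann_whitney")) {
  kind <- match.arg(kind)
  is_summary <- function(x) is.list(x) && all(c("mean", "sd", "n") %in% names(x))
  if (kind == "t") {
    if (is_summary(a) != is_summary(b))
      stop_validation("mix of raw and summary input")
    if (is_summary(a)) {
      n1 <- a$n; n2 <- b$n
      if (n1 < 2 || n2 < 2) stop_validation("need n >= 2 per group")
      sp2 <- ((n1 - 1) * a$sd^2 + (n2 - 1) * b$sd^2) / (n1 + n2 - 2)
      tt <- (a$mean - b$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
      return(test_result("t-pooled", tt, df, 2 * stats::pt(-abs(tt), df),
                         c("a", "b")))
    }
    if (length(a) < 2 || length(b) < 2) stop_validation("need n >= 2 per group")
    if (stats::sd(c(a, b)) == 0)
      return(test_result("t-pooled", 0, length(a) + length(b) - 2, 1,
                         c("a", "b")))
    r <- stats::t.test(a, b, var.equal = TRUE)
    test_result("t-pooled", r$statistic, r$parameter, r$p.value, c("a", "b"))
  } else {
    if (is_summary(a) || is_summary(b))
      stop_validation("Mann-Whitney requires raw samples (rank test)")
    if (length(a) < 2 || length(b) < 2) stop_validation("need n >= 2 per group")
    n1 <- length(a); n2 <- length(b)
    big <- n1 > 20 || n2 > 20
    has_ties <- anyDuplicated(c(a, b)) > 0
    r <- suppressWarnings(stats::wilcox.test(
      a, b, exact = !big && !has_ties, correct = FALSE))
    u1 <- unname(r$statistic)            # U of the first sample
    u <- min(u1, n1 * n2 - u1)
    test_result("mann-whitney", u, NA, r$p.value, c("a", "b"))
  }
}

#' Kruskal-Wallis test across three or more groups
#'
#' Rank-based H statistic with tie correction, chi-square reference with
#' df = groups - 1. All-identical values return H = 0, p = 1.
#'
#' @param samples list of >= 3 numeric vectors (>= 2 values each).
#' @return a `microtract_test`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 3)
    stop_validation("need >= 3 groups (use two_sample_tests for 2)")
  if (any(lengths(samples) < 2)) stop_validation("need >= 2 values per group")
  x <- unlist(samples)
  if (length(unique(x)) == 1L)
    return(test_result("kruskal-wallis", 0, length(samples) - 1, 1,
                       names(samples)))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  r <- stats::kruskal.test(x, g)
  test_result("kruskal-wallis", r$statistic, r$parameter, r$p.value,
              names(samples))
}

#' Normality/homogeneity gate between parametric and rank tests
#'
#' Kolmogorov-Smirnov against a normal with each sample's mean/SD, and
#' Levene's test (center = mean) across groups. If either rejects at
#' `alpha` the rank-based test is chosen. Groups with n < 5 default to
#' rank-based with a warning.
#'
#' @param samples list of numeric vectors (>= 2 groups).
#' @param alpha gate level (0.05).
#' @return list: `choice` ("parametric" or "rank"), `ks_p` (per group),
#'   `levene_p`.
#' @export
normality_homogeneity_gate <- function(samples, alpha = 0.05) {
  if (length(samples) < 2) stop_validation("need >= 2 groups")
  if (any(lengths(samples) < 5)) {
    warning("group with n < 5: defaulting to the rank-based test")
    return(list(choice = "rank", ks_p = rep(NA_real_, length(samples)),
                levene_p = NA_real_))
  }
  if (any(vapply(samples, stats::sd, 0) == 0))
    return(list(choice = "rank", ks_p = rep(NA_real_, length(samples)),
                levene_p = NA_real_))
  ks_p <- vapply(samples, function(x)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                    stats::sd(x)))$p.value, 0)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  lev <- car::leveneTest(unlist(samples) ~ g, center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  choice <- if (any(ks_p < alpha) || levene_p < alpha) "rank" else "parametric"
  list(choice = choice, ks_p = ks_p, levene_p = levene_p)
}

#' ROI-wise Spearman correlations with BH correction
#'
#' Spearman rho (average ranks for ties) between a clinical covariate and
#' each region's mean measure, with Benjamini-Hochberg adjustment across
#' all regions of the family (one family per measure-covariate-group
#' combination).
#'
#' @param roi_means subjects x regions matrix (column names = region
#'   names).
#' @param covariate numeric vector, one value per subject.
#' @param measure measure name recorded in the output.
#' @param covariate_name covariate name recorded in the output.
#' @param alpha significance flag level on adjusted p.
#' @return data.frame of class `correlation_records`: region, measure,
#'   covariate, rho, p, p_adj, n, significant.
#' @export
roi_correlations <- function(roi_means, covariate, measure = "FA",
                             covariate_name = "covariate", alpha = 0.05) {
  roi_means <- as.matrix(roi_means)
  n <- nrow(roi_means)
  if (n < 4) stop_validation("need >= 4 subjects for rank correlation")
  if (length(covariate) != n)
    stop_validation("covariate length does not match subjects")
  if (any(is.na(covariate)))
    stop_validation("covariate must be defined for all included subjects")
  if (stats::sd(covariate) == 0) stop_validation("constant covariate")
  regions <- colnames(roi_means)
  if (is.null(regions)) regions <- paste0("region_", seq_len(ncol(roi_means)))
  rho <- p <- numeric(ncol(roi_means))
  for (j in seq_len(ncol(roi_means))) {
    ct <- suppressWarnings(stats::cor.test(roi_means[, j], covariate,
                                           method = "spearman",
                                           exact = FALSE))
    rho[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(region = regions, measure = measure,
                    covariate = covariate_name, rho = rho, p = p,
                    p_adj = p_adj, n = n, significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_records", "data.frame")
  out
}
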