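# Statistical kernels used by every pipeline stage. Standard tests delegate
# to the corresponding base R routines after validation; the one-sample
# Wilcoxon signed-rank test is implemented here in full because an exact,
# tie-aware two-sided p-value is needed for panel deviation testing.

#' Construct a test result
#'
#' Light container for a test statistic, its two-sided p-value, the method
#' label and the degrees of freedom (or effective sample size). Degenerate
#' inputs yield flagged results rather than errors so that pipelines can
#' continue over thousands of features.
#'
#' @param statistic Numeric test statistic.
#' @param p_value Two-sided p-value in `[0, 1]`.
#' @param method Character method label.
#' @param df_or_n Degrees of freedom or effective n.
#' @param degenerate Logical degeneracy flag.
#' @param extra Optional named list of method-specific extras.
#' @return An object of class `vascage_test`.
#' @export
test_result <- function(statistic, p_value, method, df_or_n = NA_real_,
                        degenerate = FALSE, extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    c(list(statistic = as.numeric(statistic), p_value = as.numeric(p_value),
           method = method, df_or_n = as.numeric(df_or_n),
           degenerate = isTRUE(degenerate)), extra),
    class = "vascage_test"
  )
}

#' @export
print.vascage_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (df/n = %g)%s\n",
              x$method, x$statistic, x$p_value, x$df_or_n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

validate_pvalues <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    stop_named("vascage_invalid_pvalues", "p-values must be a non-empty numeric vector")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    bad <- which(!is.finite(p) | p < 0 | p > 1)
    stop_named("vascage_invalid_pvalues",
               "p-values outside [0,1] or non-finite at positions: %s",
               paste(utils::head(bad, 10), collapse = ", "))
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p-values to q-values controlling the false discovery rate:
#' `q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank(j)`, clipped at 1.
#' Output is aligned with the input and monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  validate_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Per-gene Pearson correlation against age
#'
#' Pearson product-moment correlation of an expression vector against age,
#' with the two-sided p-value from the exact t transform
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom, the
#' ordinary least-squares slope of expression on age, and the mean expression.
#' A constant expression vector is returned flagged degenerate (R undefined)
#' so the caller can exclude the gene with a logged reason; constant age is a
#' validation error because it invalidates the whole cohort.
#'
#' @param x Age vector (years).
#' @param y Expression vector (TPM), same length.
#' @return List with `r`, `p`, `slope`, `mean_y`, `n`, `degenerate`.
#' @export
pearson_age_corr <- function(x, y) {
  if (length(x) != length(y)) {
    stop_named("vascage_length_mismatch", "age and expression lengths differ")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_named("vascage_too_few_samples", "need >= 3 paired observations")
  if (stats::var(x) == 0) {
    stop_named("vascage_constant_age", "age vector is constant; correlation undefined")
  }
  mean_y <- mean(y)
  if (stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, slope = 0, mean_y = mean_y,
                n = n, degenerate = TRUE))
  }
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean_y))
  r <- sxy / sqrt(sxx * sum((y - mean_y)^2))
  r <- max(-1, min(1, r))
  slope <- sxy / sxx
  if (abs(r) == 1) {
    p <- .p_floor
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- floor_p(2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))$p
  }
  list(r = r, p = p, slope = slope, mean_y = mean_y, n = n, degenerate = FALSE)
}

# Exact null distribution of the one-sample signed-rank sum W+ for given
# (possibly tied, midrank) ranks, by generating-function dynamic programming.
# Ranks are doubled so midranks (x.5) become integers; returns P(W+ = s/2)
# over s = 0..sum(2*ranks) as a probability vector indexed from 0.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    idx <- (r + 1):(total + 1)
    g[idx] <- g[idx] + f[idx - r]
    f <- g
  }
  f / sum(f)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetric around `mu0`. Values equal to `mu0`
#' are dropped (classic Wilcoxon zero-handling; see `zero_handling`). The
#' exact two-sided p-value is computed from the exact null distribution of
#' the signed-rank sum — tie-aware via midranks and a generating-function
#' convolution — when the effective n is at most `exact_limit`; otherwise a
#' normal approximation with the usual tie correction is used (no continuity
#' correction). The two-sided p is `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param values Numeric vector.
#' @param mu0 Null location.
#' @param mode `"auto"` (exact when effective n <= `exact_limit`),
#'   `"exact"`, or `"normal"`.
#' @param exact_limit Largest effective n for the exact mode under `"auto"`.
#' @param zero_handling `"drop"` (default) removes values equal to `mu0`.
#' @return A [test_result] carrying the signed-rank sum `W+`, with extras
#'   `median_diff` (median of `values - mu0`) and `n_effective`.
#' @export
wilcoxon_one_sample <- function(values, mu0 = 0,
                                mode = c("auto", "exact", "normal"),
                                exact_limit = 25, zero_handling = "drop") {
  mode <- match.arg(mode)
  stopifnot(identical(zero_handling, "drop"))
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop_named("vascage_empty_input", "no finite values supplied")
  }
  d <- values - mu0
  med <- stats::median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result(NA_real_, 1, "wilcoxon_one_sample", 0, degenerate = TRUE,
                       extra = list(median_diff = med, n_effective = 0)))
  }
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  use_exact <- switch(mode,
    auto = n <= exact_limit,
    exact = TRUE,
    normal = FALSE
  )
  if (use_exact) {
    ranks2 <- as.integer(round(2 * rk))
    f <- signed_rank_null(ranks2)
    s <- as.integer(round(2 * w))
    lower <- sum(f[seq_len(s + 1)])
    upper <- sum(f[(s + 1):length(f)])
    p <- min(1, 2 * min(lower, upper))
    method <- "wilcoxon_one_sample (exact)"
  } else {
    ties <- table(rk)
    mu_w <- n * (n + 1) / 4
    var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (var_w <= 0) {
      return(test_result(w, 1, "wilcoxon_one_sample (normal)", n,
                         degenerate = TRUE,
                         extra = list(median_diff = med, n_effective = n)))
    }
    z <- (w - mu_w) / sqrt(var_w)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    method <- "wilcoxon_one_sample (normal)"
  }
  test_result(w, floor_p(p)$p, method, n,
              extra = list(median_diff = med, n_effective = n))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on `k - 1`
#' degrees of freedom. All-identical observations yield H = 0, p = 1 with a
#' degeneracy flag instead of an error.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty).
#' @return A [test_result].
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(!vapply(groups, length, 1L))) {
    stop_named("vascage_invalid_groups", "need >= 2 non-empty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1) {
    return(test_result(0, 1, "kruskal_wallis", length(groups) - 1, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(x, g)
  test_result(unname(kt$statistic), floor_p(unname(kt$p.value))$p,
              "kruskal_wallis", unname(kt$parameter))
}

validate_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_named("vascage_invalid_table", "2x2 cells must be non-negative integers")
  }
  if (sum(cells) < 1) stop_named("vascage_invalid_table", "grand total must be >= 1")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop_named("vascage_zero_margin", "a zero row or column margin makes the test undefined")
  }
  matrix(cells, nrow = 2, byrow = TRUE)
}

#' Chi-squared test for a 2x2 table
#'
#' Uncorrected by default: `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' compared to a chi-squared distribution with 1 df. With `correction =
#' "yates"` the continuity correction subtracts N/2 from `|ad - bc|` (floored
#' at 0). A warning is logged when any expected count is below 5 and no
#' correction is requested.
#'
#' @param a,b,c,d Cell counts (rows = groups, columns = outcome yes/no).
#' @param correction `"none"` (default) or `"yates"`.
#' @return A [test_result].
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- validate_2x2(a, b, c, d)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (correction == "none" && any(expected < 5)) {
    vg_log("stats_core", "chi_square_2x2: expected count < 5 without continuity correction")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = (correction == "yates")))
  test_result(unname(ct$statistic), floor_p(unname(ct$p.value))$p,
              sprintf("chi_square_2x2 (%s)", correction), unname(ct$parameter))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than the
#' observed table's. Sanity companion to [chi_square_2x2] for small tables.
#'
#' @inheritParams chi_square_2x2
#' @return A [test_result]; the statistic slot carries the odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  tab <- validate_2x2(a, b, c, d)
  ft <- stats::fisher.test(tab)
  test_result(unname(ft$estimate), floor_p(unname(ft$p.value))$p,
              "fisher_exact_2x2", sum(tab))
}

#' Ordinary least squares with coefficient tests
#'
#' Fits `y ~ X` with an automatically added intercept, returning R-squared,
#' coefficient estimates and two-sided t-test p-values. A rank-deficient
#' design raises a named error listing the collinear columns.
#'
#' @param y Numeric response.
#' @param X Numeric matrix or data frame of covariates (named columns).
#' @return List with `r2`, `coefficients`, `coef_p`, `coef_se`, `n`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n != nrow(X)) stop_named("vascage_length_mismatch", "y and X row counts differ")
  if (n <= ncol(X) + 1) {
    stop_named("vascage_too_few_samples", "need n > number of covariates + 1")
  }
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_named("vascage_collinear_design",
               "rank-deficient design; collinear columns: %s",
               paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  rownames(coefs) <- c("(Intercept)", colnames(X))
  list(
    r2 = sm$r.squared,
    coefficients = coefs[, "Estimate"],
    coef_se = coefs[, "Std. Error"],
    coef_p = coefs[, "Pr(>|t|)"],
    n = n
  )
}
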