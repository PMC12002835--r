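# Independent brute-force / closed-form oracles used to validate the
# statistical kernels. These deliberately share no code with the package:
# each works directly from the textbook definition.

options(vascage.quiet = TRUE)

# Benjamini-Hochberg step-up by direct evaluation of the definition:
# sort p ascending, q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact one-sample signed-rank p by exhaustive enumeration over all 2^n
# sign assignments (midranks for ties). Two-sided doubled-tail convention.
oracle_signed_rank <- function(values, mu0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Uncorrected / Yates chi-squared for a 2x2 table from the closed form.
oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed one (standard 1e-7 relative tolerance).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H from the rank formula with tie correction.
oracle_kw <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(stat = h, p = stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
}

# OLS by explicit normal equations, with coefficient t tests.
oracle_ols <- function(y, X) {
  D <- cbind(1, as.matrix(X))
  xtx_inv <- solve(t(D) %*% D)
  beta <- xtx_inv %*% t(D) %*% y
  resid <- y - D %*% beta
  n <- length(y); k <- ncol(D)
  s2 <- sum(resid^2) / (n - k)
  se <- sqrt(diag(xtx_inv) * s2)
  tval <- beta / se
  list(
    beta = as.numeric(beta),
    se = as.numeric(se),
    p = as.numeric(2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)),
    r2 = 1 - sum(resid^2) / sum((y - mean(y))^2)
  )
}

# Random non-degenerate 2x2 table (no zero margins).
random_2x2 <- function() {
  repeat {
    cells <- rpois(4, lambda = sample(2:8, 1))
    if ((cells[1] + cells[2]) > 0 && (cells[3] + cells[4]) > 0 &&
        (cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0) {
      return(cells)
    }
  }
}
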