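# Label-free proteomics post-processing: filtering, two-sample t statistics
# with permutation-based FDR control, downshifted-Gaussian imputation,
# z-scoring, hierarchical clustering and PCA.

#' Construct a proteomics matrix
#'
#' Protein x sample quantity matrix with explicit missing cells (NA), a
#' per-sample group assignment, and a declared scale (`"raw"` or `"log2"`);
#' the scale is never auto-detected.
#'
#' @param values Numeric matrix, proteins x samples, NA = missing.
#' @param groups Character/factor vector of group labels, one per sample
#'   (named by sample id or in column order).
#' @param scale `"raw"` (all present values must be > 0) or `"log2"`.
#' @return An object of class `proteomics_matrix`.
#' @export
proteomics_matrix <- function(values, groups, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_named("vascage_invalid_matrix", "values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_named("vascage_duplicate_ids", "unique protein row names required")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_named("vascage_duplicate_ids", "unique sample column names required")
  }
  if (length(groups) != ncol(values)) {
    stop_named("vascage_invalid_groups", "one group label per sample required")
  }
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(values))) {
      stop_named("vascage_invalid_groups", "group names do not match sample ids")
    }
    groups <- groups[colnames(values)]
  }
  if (scale == "raw" && any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop_named("vascage_invalid_matrix",
               "raw-scale quantity <= 0 at protein %s, sample %s",
               rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  structure(
    list(values = values, groups = factor(as.character(groups)), scale = scale),
    class = "proteomics_matrix"
  )
}

#' @export
print.proteomics_matrix <- function(x, ...) {
  cat(sprintf("proteomics_matrix: %d proteins x %d samples (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale, 100 * mean(is.na(x$values))))
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$groups), table(x$groups)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' log2-transform a raw-scale proteomics matrix
#'
#' Missing cells stay missing; the scale flag is updated. Applying it to an
#' already log2-scale matrix is an error.
#'
#' @param m A raw-scale [proteomics_matrix].
#' @return The log2-scale matrix.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (m$scale != "raw") {
    stop_named("vascage_wrong_scale", "matrix is already on log2 scale")
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Filter proteins on valid values per group
#'
#' Retains proteins with at least `min_valid` present (non-missing) values in
#' every group; the removal count is logged. Idempotent.
#'
#' @param m A [proteomics_matrix].
#' @param min_valid Minimum present values required in each group.
#' @return The filtered matrix.
#' @export
filter_valid <- function(m, min_valid = 3) {
  stopifnot(inherits(m, "proteomics_matrix"))
  present <- !is.na(m$values)
  keep <- rep(TRUE, nrow(m$values))
  for (g in levels(m$groups)) {
    keep <- keep & rowSums(present[, m$groups == g, drop = FALSE]) >= min_valid
  }
  removed <- sum(!keep)
  if (removed > 0) {
    vg_log("proteomics_de", "filter_valid: removed %d of %d proteins (< %d valid in a group)",
           removed, nrow(m$values), min_valid)
  }
  m$values <- m$values[keep, , drop = FALSE]
  m
}

# Row-wise variance with NA handling via sums of squares (fast path for the
# permutation loop).
row_var_fast <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums(x^2, na.rm = TRUE)
  (ss - n * m^2) / (n - 1)
}

# Per-protein two-sample Student t statistics for a column split, with NA
# handling. Returns d = (mean1 - mean2) / (pooled SE + s0), the classic t
# (s0 = 0), df, and per-group valid counts. Vectorized over rows.
row_ttest_fast <- function(values, idx1, idx2, s0 = 0) {
  x1 <- values[, idx1, drop = FALSE]
  x2 <- values[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- row_var_fast(x1)
  v2 <- row_var_fast(x2)
  testable <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  sp2 <- pmax(sp2, 0)          # guard tiny negative values from cancellation
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- ifelse(testable, (m1 - m2) / (se + s0), NA_real_)
  t_classic <- ifelse(testable & se > 0, (m1 - m2) / se, ifelse(testable, 0, NA_real_))
  list(d = d, t = t_classic, df = df, diff = m1 - m2,
       n1 = n1, n2 = n2, testable = testable)
}

# All balanced two-group label assignments for sizes (n1, n2): the index
# sets of "group 1" among 1..(n1+n2). Identity excluded; the complement of
# the identity is retained. When more than `n_perm` distinct assignments
# exist, `n_perm` are sampled uniformly without replacement.
balanced_assignments <- function(n1, n2, n_perm, seed) {
  n <- n1 + n2
  total <- choose(n, n1)
  if (total - 1 <= n_perm || total <= 1e5) {
    all_idx <- utils::combn(n, n1, simplify = FALSE)
    identity <- seq_len(n1)
    all_idx <- Filter(function(ix) !identical(ix, identity), all_idx)
    if (length(all_idx) > n_perm) {
      all_idx <- with_seed(derive_seed(seed, "perm_sample"),
                           all_idx[sample(length(all_idx), n_perm)])
    } else {
      vg_log("proteomics_de", "only %d distinct permutations available; using all",
             length(all_idx))
    }
    return(all_idx)
  }
  # large designs: rejection-sample distinct assignments
  with_seed(derive_seed(seed, "perm_sample"), {
    seen <- new.env(hash = TRUE)
    out <- list()
    identity_key <- paste(seq_len(n1), collapse = ",")
    while (length(out) < n_perm) {
      ix <- sort(sample(n, n1))
      key <- paste(ix, collapse = ",")
      if (key != identity_key && is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1]] <- ix
      }
    }
    out
  })
}

#' Two-sample t test with permutation-based FDR control
#'
#' For each protein the statistic is `d = (mean1 - mean2) / (pooled SE +
#' s0)` (Student's pooled-variance t when `s0 = 0`). Group labels are then
#' permuted `n_perm` times — assignments sampled uniformly without
#' replacement from the distinct balanced label assignments, excluding the
#' identity — and for a symmetric threshold `|d| >= c` the estimated FDR is
#' the mean permutation count of `|d*| >= c` divided by the observed count.
#' After enforcing monotonicity of FDR in c, the significant set is the
#' largest threshold set with estimated FDR at most `fdr`. Proteins with
#' fewer than two valid values in either group are untested. Deterministic
#' given `seed`.
#'
#' @param m A filtered, log2-scale [proteomics_matrix] with exactly 2 groups.
#' @param n_perm Number of label permutations.
#' @param fdr Target false discovery rate.
#' @param s0 Fudge factor added to the pooled SE (0 = plain Student t).
#' @param seed Integer seed for the permutation sample.
#' @return Data frame with one row per protein: protein_id, log2fc, d, t, p
#'   (classic two-sided Student t p), significant, n_valid_g1, n_valid_g2.
#'   The contrast is oriented second factor level minus first (treatment
#'   minus reference when levels sort reference-first, e.g. Ctrl < KO), so
#'   positive log2fc means higher in the second group. Attributes:
#'   `threshold` (the |d| cutoff), `fdr_at_threshold`, `groups` (reference,
#'   treatment), `n_perm_used`.
#' @export
ttest_permutation_fdr <- function(m, n_perm = 250, fdr = 0.05, s0 = 0, seed) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (missing(seed)) stop_named("vascage_seed_required", "permutation FDR requires a seed")
  if (m$scale != "log2") stop_named("vascage_wrong_scale", "matrix must be on log2 scale")
  if (nlevels(m$groups) != 2) {
    stop_named("vascage_invalid_groups", "exactly 2 groups required")
  }
  ref <- levels(m$groups)[1]
  idx1 <- which(m$groups != ref)   # treatment (second level)
  idx2 <- which(m$groups == ref)   # reference (first level)
  obs <- row_ttest_fast(m$values, idx1, idx2, s0 = s0)

  perms <- balanced_assignments(length(idx1), length(idx2), n_perm, seed)
  cols <- c(idx1, idx2)
  n1 <- length(idx1)
  perm_d <- matrix(NA_real_, nrow(m$values), length(perms))
  for (k in seq_along(perms)) {
    p1 <- cols[perms[[k]]]
    p2 <- cols[-perms[[k]]]
    perm_d[, k] <- row_ttest_fast(m$values, p1, p2, s0 = s0)$d
  }

  abs_d <- abs(obs$d)
  tested <- which(obs$testable & is.finite(abs_d))
  significant <- rep(FALSE, nrow(m$values))
  threshold <- Inf
  fdr_at <- NA_real_
  if (length(tested) > 0) {
    cand <- sort(unique(abs_d[tested]), decreasing = TRUE)
    # exceedance counts via sorted vectors: #{x >= c} = N - #{x < c}
    obs_sorted <- sort(abs_d[tested])
    perm_sorted <- sort(abs(perm_d[is.finite(perm_d)]))
    n_obs_ge <- length(obs_sorted) -
      findInterval(cand, obs_sorted, left.open = TRUE)
    n_perm_ge <- (length(perm_sorted) -
      findInterval(cand, perm_sorted, left.open = TRUE)) / length(perms)
    est_fdr <- pmin(1, n_perm_ge / n_obs_ge)
    # enforce FDR(c) non-increasing in c: each threshold may adopt the
    # smallest estimate among all less stringent thresholds (suffix minimum
    # along cand, which is sorted by decreasing c)
    est_fdr <- rev(cummin(rev(est_fdr)))
    pass <- which(est_fdr <= fdr)
    if (length(pass) > 0) {
      threshold <- cand[max(pass)]
      fdr_at <- est_fdr[max(pass)]
      significant[tested] <- abs_d[tested] >= threshold
    }
  }
  p <- rep(NA_real_, nrow(m$values))
  p[obs$testable] <- 2 * stats::pt(abs(obs$t[obs$testable]),
                                   df = obs$df[obs$testable], lower.tail = FALSE)
  out <- data.frame(
    protein_id = rownames(m$values),
    log2fc = obs$diff,
    d = obs$d,
    t = obs$t,
    p = p,
    significant = significant,
    n_valid_g1 = obs$n2,   # first factor level (reference)
    n_valid_g2 = obs$n1,   # second factor level (treatment)
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "threshold") <- threshold
  attr(out, "fdr_at_threshold") <- fdr_at
  attr(out, "groups") <- levels(m$groups)
  attr(out, "n_perm_used") <- length(perms)
  vg_log("proteomics_de", "permutation FDR: %d significant of %d tested (|d| >= %.3g)",
         sum(significant), length(tested), threshold)
  out
}

#' Impute missing values from a downshifted Gaussian
#'
#' Per sample column with observed mean `mu` and SD `sigma`, each missing
#' cell is drawn independently from `Normal(mu - downshift * sigma,
#' (width * sigma)^2)` — the standard Perseus-style treatment of
#' missing-not-at-random low-abundance dropout. Observed cells are never
#' altered. Deterministic given `seed`.
#'
#' @param m A log2-scale [proteomics_matrix].
#' @param width Imputation width as a fraction of the column SD.
#' @param downshift Downshift in column-SD units.
#' @param seed Integer seed.
#' @return The matrix with all cells present.
#' @export
impute_downshift <- function(m, width = 0.4, downshift = 1.8, seed) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (missing(seed)) stop_named("vascage_seed_required", "imputation requires a seed")
  if (m$scale != "log2") stop_named("vascage_wrong_scale", "matrix must be on log2 scale")
  n_obs <- colSums(!is.na(m$values))
  if (any(n_obs < 2)) {
    stop_named("vascage_insufficient_observed",
               "column(s) with < 2 observed values: %s",
               paste(colnames(m$values)[n_obs < 2], collapse = ", "))
  }
  with_seed(derive_seed(seed, "impute"), {
    for (j in seq_len(ncol(m$values))) {
      miss <- which(is.na(m$values[, j]))
      if (length(miss) == 0) next
      mu <- mean(m$values[, j], na.rm = TRUE)
      sigma <- stats::sd(m$values[, j], na.rm = TRUE)
      m$values[miss, j] <- stats::rnorm(length(miss),
                                        mean = mu - downshift * sigma,
                                        sd = width * sigma)
    }
  })
  m
}

#' z-score each protein across samples
#'
#' Subtracts the row mean and divides by the row sample SD (n - 1
#' denominator). Requires a complete matrix; constant rows are an error.
#'
#' @param m A complete [proteomics_matrix].
#' @return The z-scored matrix.
#' @export
zscore_rows <- function(m) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (any(is.na(m$values))) {
    stop_named("vascage_missing_values", "matrix has missing cells; impute or filter first")
  }
  sds <- apply(m$values, 1, stats::sd)
  if (any(sds == 0)) {
    stop_named("vascage_constant_row", "constant protein row(s): %s",
               paste(utils::head(rownames(m$values)[sds == 0], 10), collapse = ", "))
  }
  m$values <- (m$values - rowMeans(m$values)) / sds
  m
}

#' Hierarchical clustering of proteins and samples
#'
#' Euclidean distance with average linkage over rows and, separately, over
#' columns. With `kmeans_pre = k`, rows are first reduced to k seeded
#' k-means centroids; the row dendrogram is then built on the centroids with
#' members attached via the returned cluster assignment.
#'
#' @param m A z-scored, complete [proteomics_matrix].
#' @param kmeans_pre Integer k for k-means row preprocessing, or `"off"`.
#' @param seed Seed for the k-means initialisation (required when
#'   `kmeans_pre` is numeric).
#' @return List with `row_hclust`, `col_hclust` (hclust objects),
#'   `row_order`, `col_order` (leaf orders) and, when preprocessing is on,
#'   `row_cluster` (protein -> centroid assignment).
#' @export
hcluster <- function(m, kmeans_pre = "off", seed = NULL) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (any(is.na(m$values))) {
    stop_named("vascage_missing_values", "matrix has missing cells")
  }
  if (nrow(m$values) < 2) stop_named("vascage_empty_input", "need >= 2 rows")
  x <- m$values
  row_cluster <- NULL
  if (!identical(kmeans_pre, "off")) {
    k <- as.integer(kmeans_pre)
    if (is.null(seed)) stop_named("vascage_seed_required", "k-means preprocessing requires a seed")
    km <- with_seed(derive_seed(seed, "kmeans"),
                    stats::kmeans(x, centers = k, nstart = 5))
    row_cluster <- stats::setNames(km$cluster, rownames(x))
    x <- km$centers
    rownames(x) <- sprintf("centroid_%d", seq_len(k))
    vg_log("proteomics_de", "k-means preprocessing: %d rows -> %d centroids (seed %d)",
           nrow(m$values), k, as.integer(seed))
  }
  row_h <- stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  col_h <- stats::hclust(stats::dist(t(m$values), method = "euclidean"), method = "average")
  list(row_hclust = row_h, col_hclust = col_h,
       row_order = row_h$labels[row_h$order],
       col_order = col_h$labels[col_h$order],
       row_cluster = row_cluster)
}

#' Principal component analysis of samples
#'
#' Centres each protein row, then computes sample scores by singular value
#' decomposition. The sign of each component is fixed so that the
#' coordinate with the largest absolute loading is positive, making output
#' deterministic.
#'
#' @param m A complete [proteomics_matrix].
#' @param n_components Number of components to return.
#' @return List with `scores` (sample x component matrix) and
#'   `explained_variance` (fractions, summing to <= 1).
#' @export
pca_scores <- function(m, n_components = 2) {
  stopifnot(inherits(m, "proteomics_matrix"))
  if (any(is.na(m$values))) {
    stop_named("vascage_missing_values", "matrix has missing cells; impute first")
  }
  if (n_components > min(dim(m$values))) {
    stop_named("vascage_invalid_spec", "n_components exceeds matrix dimensions")
  }
  pc <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained_variance = ev[seq_len(k)])
}
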