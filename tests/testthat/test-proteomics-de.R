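# Proteomics post-processing: transforms, filtering, permutation FDR,
# imputation, z-scoring, clustering, PCA.

toy_matrix <- function(values, groups = NULL, scale = "log2") {
  if (is.null(groups)) groups <- rep(c("A", "B"), each = ncol(values) / 2)
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  proteomics_matrix(values, groups, scale = scale)
}

test_that("log2_transform preserves missingness and inverts with 2^x", {
  v <- matrix(c(8, NA, 2, 1024), 2, 2)
  m <- toy_matrix(v, scale = "raw")
  lt <- log2_transform(m)
  expect_equal(lt$values[1, 1], 3)
  expect_true(is.na(lt$values[2, 1]))
  expect_equal(lt$scale, "log2")
  expect_equal(2^lt$values, m$values)
  expect_error(log2_transform(lt), class = "vascage_wrong_scale")
  expect_error(toy_matrix(matrix(c(-1, 2, 3, 4), 2, 2), scale = "raw"),
               class = "vascage_invalid_matrix")
})

test_that("filter_valid keeps proteins with min_valid in every group, idempotently", {
  v <- matrix(rnorm(36, 20), 3, 12)
  v[1, 1:3] <- NA          # 3 of 6 in group A -> boundary, kept
  v[2, 1:4] <- NA          # 2 of 6 in group A -> removed
  v[3, 7:11] <- NA         # 1 of 6 in group B -> removed
  m <- toy_matrix(v)
  f <- filter_valid(m, min_valid = 3)
  expect_equal(rownames(f$values), "P01")
  expect_identical(filter_valid(f, 3)$values, f$values)
  expect_equal(nrow(filter_valid(m, min_valid = 0)$values), 3)
})

test_that("per-protein t statistics match t.test and identical groups give no hits", {
  set.seed(10)
  v <- matrix(rnorm(60, 20, 1), 5, 12,
              dimnames = list(sprintf("P%02d", 1:5), sprintf("s%02d", 1:12)))
  m <- toy_matrix(v)
  de <- ttest_permutation_fdr(m, n_perm = 50, seed = 1)
  for (i in 1:5) {
    # contrast is second level minus first: B minus A
    tt <- t.test(v[i, 7:12], v[i, 1:6], var.equal = TRUE)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$log2fc[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-10)
  }
  # two groups with identical per-protein values: d = 0, nothing significant
  v2 <- cbind(v[, 1:6], v[, 1:6])
  colnames(v2) <- sprintf("s%02d", 1:12)
  de2 <- ttest_permutation_fdr(toy_matrix(v2), n_perm = 50, seed = 1)
  expect_true(all(de2$d == 0))
  expect_false(any(de2$significant))
})

test_that("permutation FDR flags strong effects, is seed-deterministic, and is seed-invariant when exhaustive", {
  set.seed(20)
  v <- matrix(rnorm(100 * 8, 20, 0.3), 100, 8)
  v[1:10, 5:8] <- v[1:10, 5:8] + 3   # 10 strongly shifted proteins
  m <- toy_matrix(v, groups = rep(c("A", "B"), each = 4))
  de_a <- ttest_permutation_fdr(m, n_perm = 250, seed = 5)
  de_b <- ttest_permutation_fdr(m, n_perm = 250, seed = 5)
  expect_identical(de_a, de_b)
  expect_true(all(de_a$significant[1:10]))
  expect_lt(mean(de_a$significant[-(1:10)]), 0.05)

  # choose(8,4) - 1 = 69 distinct permutations < n_perm: all are used and
  # the result no longer depends on the seed
  expect_equal(attr(de_a, "n_perm_used"), 69)
  de_c <- ttest_permutation_fdr(m, n_perm = 250, seed = 99)
  expect_identical(de_a$significant, de_c$significant)
})

test_that("proteins with under two valid values in a group are untested", {
  v <- matrix(rnorm(24, 20), 2, 12)
  v[1, 7:12] <- NA
  v[1, 7] <- 20
  de <- ttest_permutation_fdr(toy_matrix(v), n_perm = 20, seed = 1)
  expect_true(is.na(de$d[1]))
  expect_false(de$significant[1])
  expect_equal(de$n_valid_g2[1], 1)
})

test_that("impute_downshift draws from the downshifted Gaussian and leaves observed cells bitwise intact", {
  set.seed(30)
  obs <- rnorm(5000, 20, 1)
  obs <- (obs - mean(obs)) / sd(obs) + 20  # observed mean exactly 20, SD 1
  v <- matrix(c(obs, rep(NA_real_, 10000)), ncol = 1)
  rownames(v) <- sprintf("P%05d", seq_len(nrow(v)))
  colnames(v) <- "s1"
  m <- proteomics_matrix(v, groups = "A", scale = "log2")
  imp <- impute_downshift(m, width = 0.4, downshift = 1.8, seed = 7)
  filled <- imp$values[is.na(v[, 1]), 1]
  expect_equal(mean(filled), 20 - 1.8, tolerance = 0.02 / 1.8)
  expect_equal(sd(filled), 0.4, tolerance = 0.02 / 0.4)
  expect_identical(imp$values[!is.na(v[, 1]), 1], v[!is.na(v[, 1]), 1])

  imp2 <- impute_downshift(m, seed = 7)
  expect_identical(imp$values, imp2$values)
  # no missing cells -> identity
  full <- toy_matrix(matrix(rnorm(24, 20), 2, 12))
  expect_identical(impute_downshift(full, seed = 1)$values, full$values)
  # a column with < 2 observed values is an error naming the column
  bad <- v; bad[-1, 1] <- NA
  mb <- proteomics_matrix(bad, groups = "A", scale = "log2")
  expect_error(impute_downshift(mb, seed = 1), class = "vascage_insufficient_observed")
})

test_that("zscore_rows normalises with the sample-SD convention and is idempotent", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE),
                  groups = c("A", "A", "B"))
  z <- zscore_rows(m)
  expect_equal(z$values[1, ], c(s01 = -1, s02 = 0, s03 = 1))
  expect_equal(zscore_rows(z)$values, z$values)
  expect_error(zscore_rows(toy_matrix(matrix(c(2, 2, 2, 1, 2, 3), 2, 3, byrow = TRUE),
                                      groups = c("A", "A", "B"))),
               class = "vascage_constant_row")
})

test_that("hcluster separates a two-block design and merges duplicates at zero", {
  set.seed(40)
  v <- matrix(rnorm(50 * 12, 0, 0.2), 50, 12)
  v[1:25, 7:12] <- v[1:25, 7:12] + 4
  m <- toy_matrix(v)
  m <- zscore_rows(m)
  cl <- hcluster(m)
  top_split <- cutree(cl$col_hclust, k = 2)
  expect_length(unique(top_split[1:6]), 1)
  expect_length(unique(top_split[7:12]), 1)
  expect_false(top_split[1] == top_split[7])

  dup <- toy_matrix(cbind(v[, 1:11], v[, 11]))
  dcl <- hcluster(dup)
  expect_equal(min(dcl$col_hclust$height), 0)

  # k-means preprocessing returns an assignment covering all rows
  kcl <- hcluster(m, kmeans_pre = 5, seed = 3)
  expect_length(kcl$row_cluster, 50)
  expect_equal(nrow(as.matrix(stats::cophenetic(kcl$row_hclust))), 5)
  expect_error(hcluster(toy_matrix(matrix(1:12, 1, 12))), class = "vascage_empty_input")
})

test_that("pca_scores explains a rank-1 matrix on PC1 and separates groups", {
  u <- rnorm(30)
  w <- rnorm(10)
  m <- toy_matrix(outer(u, w) + matrix(rnorm(300, 0, 1e-8), 30, 10),
                  groups = rep(c("A", "B"), each = 5))
  res <- pca_scores(m, n_components = 2)
  expect_gt(res$explained_variance[1], 0.999)

  set.seed(50)
  v <- matrix(rnorm(200 * 12, 20, 0.3), 200, 12)
  v[1:40, 7:12] <- v[1:40, 7:12] + 2
  res <- pca_scores(toy_matrix(v), n_components = 2)
  pc1 <- res$scores[, 1]
  expect_true(max(pc1[1:6]) < min(pc1[7:12]) || min(pc1[1:6]) > max(pc1[7:12]))
  # deterministic sign convention
  res2 <- pca_scores(toy_matrix(v), n_components = 2)
  expect_identical(res$scores, res2$scores)
  expect_error(pca_scores(toy_matrix(v), n_components = 13),
               class = "vascage_invalid_spec")
})
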