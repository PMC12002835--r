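# Panel deviation testing, confounder-adjusted regression and ddCt.

corr_table_from_r <- function(r_values, tissue = "aorta") {
  out <- data.frame(
    gene_id = names(r_values), n = 100, r = unname(r_values), p = 0.5, q = 0.5,
    slope = 0, mean_tpm = 1, effect_proxy = 0, degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "tissue") <- tissue
  out
}

test_that("panel_deviation_test detects coordinated negative deviation", {
  set.seed(2)
  genome_r <- setNames(rnorm(500, 0, 0.1), sprintf("G%03d", 1:500))
  tab <- corr_table_from_r(genome_r)

  below <- names(sort(genome_r))[1:20]  # 20 genes all below the median
  res <- panel_deviation_test(gene_panel("down", below), tab)
  expect_equal(res$direction, -1)
  expect_lt(res$p, 0.001)
  expect_equal(res$n_mapped, 20)
  expect_equal(res$genome_median_r, median(genome_r))
})

test_that("a panel exactly symmetric around the genome median gives p = 1", {
  genome_r <- setNames(c(-(50:1), 0, 1:50) / 100, sprintf("S%03d", 1:101))
  tab <- corr_table_from_r(genome_r)  # median exactly 0
  sym_genes <- names(genome_r)[abs(genome_r) > 0.005 & abs(genome_r) < 0.055]
  expect_length(sym_genes, 10)  # r = -0.05..-0.01, 0.01..0.05
  res <- panel_deviation_test(gene_panel("sym", sym_genes), tab)
  expect_equal(res$p, 1)
  expect_equal(res$direction, 0)
})

test_that("panel_deviation_test excludes unmapped symbols and enforces minimums", {
  genome_r <- setNames(rnorm(100, 0, 0.1), sprintf("G%03d", 1:100))
  tab <- corr_table_from_r(genome_r)
  p <- gene_panel("mixed", c(names(genome_r)[1:8], "NOT_A_GENE"))
  res <- panel_deviation_test(p, tab)
  expect_equal(res$n_mapped, 8)
  expect_equal(res$unmapped, "NOT_A_GENE")

  tiny <- gene_panel("tiny", c(names(genome_r)[1:3], paste0("X", 1:3)))
  expect_error(panel_deviation_test(tiny, tab), class = "vascage_unmapped_panel")
})

test_that("covariate_model recovers known effects and respects nesting", {
  set.seed(11)
  n <- 400
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     age = runif(n, 20, 79),
                     sex = sample(1:2, n, TRUE))
  srf <- 50 + rnorm(n, 0, 5)
  cd68 <- 20 + rnorm(n, 0, 3)
  target <- 100 - 0.8 * meta$age + 0.5 * srf + rnorm(n, 0, 4)
  expr <- rbind(TARGET = pmax(target, 0), SRF = srf, CD68 = cd68)
  colnames(expr) <- meta$sample_id

  fit <- covariate_model("TARGET", c("SRF", "CD68"), expr, meta)
  expect_equal(unname(fit$coefficients["age"]), -0.8,
               tolerance = 2 * unname(fit$coef_se["age"]) / 0.8)
  expect_equal(unname(fit$coefficients["SRF"]), 0.5,
               tolerance = 2 * unname(fit$coef_se["SRF"]) / 0.5)
  expect_lt(fit$coef_p["age"], 1e-6)
  expect_gt(fit$coef_p["CD68"], 0.001)  # no injected CD68 effect

  # exact linear combination of covariates -> R^2 = 1
  expr2 <- rbind(TARGET = 2 * meta$age + srf, SRF = srf)
  colnames(expr2) <- meta$sample_id
  expect_equal(suppressWarnings(covariate_model("TARGET", "SRF", expr2, meta))$r2, 1)

  # dropping a real covariate can only lower R^2 (nested monotonicity)
  full <- covariate_model("TARGET", c("SRF", "CD68"), expr, meta)$r2
  reduced <- ols_fit(expr["TARGET", ], cbind(sex = meta$sex, SRF = srf, CD68 = cd68))$r2
  expect_gte(full, reduced)
  expect_error(covariate_model("NOPE", "SRF", expr, meta),
               class = "vascage_missing_gene")
})

test_that("delta_delta_ct matches a spreadsheet-style manual computation", {
  ct <- rbind(
    c1 = c(Gene = 24, Rn18s = 10),
    c2 = c(Gene = 25, Rn18s = 11),
    k1 = c(Gene = 27, Rn18s = 10.5),
    k2 = c(Gene = 26, Rn18s = 10.5)
  )
  res <- delta_delta_ct(ct, reference = "Rn18s", control_samples = c("c1", "c2"))
  # manual: dCt = (14, 14, 16.5, 15.5); control mean 14; ddCt = (0, 0, 2.5, 1.5)
  expect_equal(unname(res$fold[, "Gene"]), c(1, 1, 2^-2.5, 2^-1.5))
  expect_equal(unname(res$log2_fold[, "Gene"]), c(0, 0, -2.5, -1.5))
  # control geometric mean fold is exactly 1
  expect_equal(exp(mean(log(res$fold[c("c1", "c2"), "Gene"]))), 1)
})

test_that("ddCt is invariant to per-sample Ct offsets and excludes bad samples", {
  set.seed(4)
  ct <- cbind(GeneA = runif(6, 20, 30), GeneB = runif(6, 18, 28),
              Rn18s = runif(6, 9, 12))
  rownames(ct) <- paste0("s", 1:6)
  base <- delta_delta_ct(ct, "Rn18s", c("s1", "s2", "s3"))
  shifted <- ct; shifted["s4", ] <- shifted["s4", ] + 3
  shift_res <- delta_delta_ct(shifted, "Rn18s", c("s1", "s2", "s3"))
  expect_equal(base$fold, shift_res$fold)

  ct_na <- ct; ct_na["s5", "Rn18s"] <- NA
  res <- delta_delta_ct(ct_na, "Rn18s", c("s1", "s2", "s3"))
  expect_equal(res$excluded, "s5")
  expect_false("s5" %in% rownames(res$fold))
  expect_error(delta_delta_ct(ct, "Missing", "s1"), class = "vascage_missing_gene")
  expect_error(delta_delta_ct(cbind(ct, Bad = rep(50, 6)), "Rn18s", "s1"),
               class = "vascage_invalid_ct")
})
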