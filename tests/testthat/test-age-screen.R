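# The screen: per-tissue correlation tables, concordance filters, effect
# proxy ranking and age-bin summaries.

make_tables <- function(r, q) {
  # three single-row-per-gene correlation tables from R and q matrices
  lapply(seq_len(ncol(r)), function(j) {
    out <- data.frame(
      gene_id = rownames(r), n = 100, r = r[, j], p = q[, j] / 2, q = q[, j],
      slope = r[, j], mean_tpm = 10, effect_proxy = 10 * r[, j],
      degenerate = FALSE, stringsAsFactors = FALSE
    )
    attr(out, "tissue") <- paste0("t", j)
    out
  })
}

test_that("correlate_age flags degenerate genes and keeps them out of BH", {
  expr <- rbind(
    linear = 10 + 0.2 * (1:30),
    flat = rep(0, 30),
    noise = rnorm(30, 50, 5)
  )
  colnames(expr) <- paste0("s", 1:30)
  meta <- data.frame(sample_id = colnames(expr), age = 20 + (1:30) * 2)
  tab <- correlate_age(expr, meta, tissue = "aorta")
  expect_equal(tab$r[tab$gene_id == "linear"], 1)
  expect_true(tab$degenerate[tab$gene_id == "flat"])
  expect_true(is.na(tab$q[tab$gene_id == "flat"]))
  # BH over 2 non-degenerate genes only: q = min(1, 2p/rank) tail-min
  p_nd <- tab$p[!tab$degenerate]
  expect_equal(tab$q[!tab$degenerate], oracle_bh(p_nd))
  expect_equal(tab$effect_proxy, tab$mean_tpm * tab$slope)
  expect_equal(attr(tab, "tissue"), "aorta")
  expect_error(correlate_age(expr[, 1:2], meta[1:2, ]),
               class = "vascage_too_few_samples")
})

test_that("pan_arterial_set enforces significance and sign concordance", {
  r <- rbind(g1 = c(-0.3, -0.2, -0.25),
             g2 = c(-0.3, -0.2, -0.25),
             g3 = c(0.2, 0.2, -0.2),
             g4 = c(0.3, 0.3, 0.3))
  q <- rbind(g1 = c(0.01, 0.01, 0.01),
             g2 = c(0.01, 0.01, 0.06),
             g3 = c(0.01, 0.01, 0.01),
             g4 = c(0.04, 0.04, 0.04))
  res <- pan_arterial_set(make_tables(r, q), alpha = 0.05)
  expect_setequal(res$gene_id, c("g1", "g4"))
  expect_equal(res$mean_r[res$gene_id == "g1"], -0.25)
  expect_equal(res$direction, c(-1, 1))
})

test_that("extended_set applies the sum-of-R and secondary consistency cutoffs", {
  r <- rbind(in_ = c(-0.25, -0.25, -0.15),   # |sum| 0.65, sec -0.15
             weak_sec = c(-0.30, -0.30, -0.05), # sec below 0.1
             small_sum = c(-0.20, -0.15, -0.10), # |sum| 0.45
             pos = c(0.30, 0.30, 0.15))
  q <- matrix(0.01, nrow = 4, ncol = 3, dimnames = list(rownames(r), NULL))
  tabs <- make_tables(r, q)
  names(tabs) <- c("tibial", "aorta", "coronary")
  res <- extended_set(tabs, primary = c("tibial", "aorta"),
                      secondary = "coronary")
  expect_setequal(res$gene_id, c("in_", "pos"))
  expect_equal(res$sum_r[res$gene_id == "in_"], -0.65)

  # losing primary significance drops the gene
  q["in_", 1] <- 0.2
  tabs <- make_tables(r, q)
  names(tabs) <- c("tibial", "aorta", "coronary")
  expect_false("in_" %in% extended_set(tabs, c("tibial", "aorta"), "coronary")$gene_id)
})

test_that("concordance filters reject mismatched gene universes", {
  r <- matrix(0.3, 2, 3, dimnames = list(c("a", "b"), NULL))
  q <- matrix(0.01, 2, 3, dimnames = list(c("a", "b"), NULL))
  tabs <- make_tables(r, q)
  tabs[[3]]$gene_id <- c("a", "zzz")
  expect_error(pan_arterial_set(tabs), class = "vascage_universe_mismatch")
})

test_that("effect_proxy_rank sorts deterministically with lexicographic ties", {
  tab <- data.frame(
    gene_id = c("b", "a", "c", "d"), n = 10, r = 0, p = 1, q = 1,
    slope = c(-0.02, -0.02, 0.05, -1), mean_tpm = c(100, 100, 10, 1),
    effect_proxy = c(-2, -2, 0.5, -1), degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  res <- effect_proxy_rank(tab, k = 3, direction = "negative")
  expect_equal(res$gene_id, c("a", "b", "d"))
  res <- effect_proxy_rank(tab, k = 1, direction = "positive")
  expect_equal(res$gene_id, "c")
  expect_warning(effect_proxy_rank(tab, k = 10), "exceeds")
})

test_that("age_bin_summary uses closed floored-age bins and Kruskal-Wallis", {
  ages <- c(25, 39.9, 40.0, 55, 61, 79, 85)
  meta <- data.frame(sample_id = paste0("s", 1:7), age = ages)
  tpm <- setNames(c(5, 5, 3, 3, 1, 1, 99), meta$sample_id)
  res <- age_bin_summary(tpm, meta)
  expect_equal(res$summary$n, c(2L, 2L, 2L))  # age 85 dropped
  expect_equal(res$summary$median, c(5, 3, 1))
  expect_false(res$degenerate)
  expect_s3_class(res$test, "vascage_test")

  flat <- age_bin_summary(setNames(rep(2, 7), meta$sample_id), meta)
  expect_equal(flat$test$statistic, 0)
  expect_equal(flat$test$p_value, 1)

  young <- meta[meta$age < 40, ]
  res <- age_bin_summary(tpm[young$sample_id], young)
  expect_true(res$degenerate)
  expect_null(res$test)
})

test_that("screen output is invariant across repeated identical runs", {
  co <- gen_expression_cohort(cohort_spec(
    n_genes = 100, n_samples = c(a = 40, b = 30, c = 20),
    panel_spec = list(), seed = 33
  ))
  s1 <- run_aging_screen(co)
  s2 <- run_aging_screen(co)
  s1$manifest$timestamp <- s2$manifest$timestamp <- NULL
  expect_identical(s1, s2)
})
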