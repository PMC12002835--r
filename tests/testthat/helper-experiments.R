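# Shared simulation experiments for the recovery/calibration tests.
# Cohort sizes follow the package's standard evaluation conditions: three
# arterial tissues of 300/200/120 donors, 2,000 genes with 10% injected
# linear trends, and 6 vs 6 proteomes of 2,000 proteins.

screen_experiment <- function(seed, n_genes = 2000) {
  spec <- cohort_spec(
    n_genes = n_genes,
    n_samples = c(tibial = 300, aorta = 200, coronary = 120),
    seed = seed
  )
  co <- gen_expression_cohort(spec)
  panels <- gen_gene_panels(co$truth, seed = seed)
  res <- run_aging_screen(co, panels = panels)
  strong <- co$truth$gene_id[abs(co$truth$rel_slope) >= 0.3]
  null_genes <- co$truth$gene_id[!co$truth$age_dependent]
  list(
    pan_sens = mean(strong %in% res$pan_set$gene_id),
    ext_sens = mean(strong %in% res$extended_set$gene_id),
    pan_fp = sum(res$pan_set$gene_id %in% null_genes),
    panel_tests = res$panel_tests
  )
}

null_screen_experiment <- function(seed, n_genes = 2000) {
  spec <- cohort_spec(
    n_genes = n_genes,
    n_samples = c(tibial = 300, aorta = 200, coronary = 120),
    frac_age_dependent = 0, panel_spec = list(),
    seed = seed
  )
  co <- gen_expression_cohort(spec)
  nrow(run_aging_screen(co)$pan_set)
}

# Correlation table for a single null tissue, for panel-test calibration.
null_corr_table <- function(seed, n_genes = 2000, n = 300) {
  spec <- cohort_spec(
    n_genes = n_genes, n_samples = c(artery = n),
    frac_age_dependent = 0, panel_spec = list(), seed = seed
  )
  co <- gen_expression_cohort(spec)
  correlate_age(co$expression$artery, co$metadata, tissue = "artery")
}

injected_panel_experiment <- function(seed) {
  spec <- cohort_spec(
    n_genes = 1000, n_samples = c(artery = 300),
    panel_spec = list(list(name = "reg", size = 20, direction = -1)),
    seed = seed
  )
  co <- gen_expression_cohort(spec)
  tab <- correlate_age(co$expression$artery, co$metadata, tissue = "artery")
  panel <- gen_gene_panels(co$truth, seed = seed)$reg
  panel_deviation_test(panel, tab)
}

proteome_experiment <- function(seed, frac_de = 0.10) {
  spec <- proteome_spec(frac_de = frac_de, seed = seed)
  pr <- gen_proteome(spec)
  de <- ttest_permutation_fdr(filter_valid(pr$matrix), n_perm = 250,
                              fdr = 0.05, seed = seed)
  truth_de <- pr$truth$protein_id[pr$truth$de]
  hits <- de$protein_id[de$significant]
  list(
    n_sig = length(hits),
    realized_fdr = if (length(hits)) mean(!hits %in% truth_de) else 0,
    sensitivity = if (length(truth_de)) mean(truth_de %in% hits) else NA_real_
  )
}
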