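#!/usr/bin/env Rscript
# Step 3 — regulon attrition statistics.
#
# Tests whether the regulon panels' age-correlation coefficients deviate
# from the genome-wide median in each artery (one-sample Wilcoxon), fits
# the confounder-adjusted model for an emblematic declining gene, and shows
# the 2^-ddCt calculation on a small synthetic qPCR table.

suppressMessages(library(vascage))

data_dir <- "results/data"
screen_dir <- "results/screen"
out <- "results/regulon"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_corr <- function(path) {
  df <- utils::read.delim(path)
  names(df)[names(df) == "R"] <- "r"
  attr(df, "tissue") <- sub("^corr_(.*)\\.tsv$", "\\1", basename(path))
  df
}
tissues <- c("tibial", "aorta", "coronary")
tables <- lapply(setNames(tissues, tissues), function(ti) {
  read_corr(file.path(screen_dir, sprintf("corr_%s.tsv", ti)))
})
panels <- read_gene_panels(file.path(data_dir, "panels.tsv"))

rows <- list()
for (ti in tissues) {
  for (p in panels) {
    r <- panel_deviation_test(p, tables[[ti]])
    rows[[length(rows) + 1]] <- data.frame(
      tissue = ti, panel = r$panel, n_mapped = r$n_mapped,
      panel_median_r = r$panel_median_r, genome_median_r = r$genome_median_r,
      direction = r$direction, p = r$p)
  }
}
panel_tab <- do.call(rbind, rows)
utils::write.table(panel_tab, file.path(out, "panel_deviation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("panel deviation from genome median R (negative = coordinated decline):\n")
print(panel_tab, row.names = FALSE, digits = 3)

# confounder-adjusted regression: strongest declining panel gene in aorta,
# controlling for age, sex and three covariate transcripts
meta <- read_metadata(file.path(data_dir, "metadata.tsv"))
expr_aorta <- read_expression(file.path(data_dir, "expr_aorta.tsv"), meta = meta)
truth <- utils::read.delim(file.path(data_dir, "cohort_truth.tsv"))
panel_genes <- truth[!is.na(truth$panel), ]
target <- panel_genes$gene_id[which.min(panel_genes$rel_slope)]
covs <- setdiff(truth$gene_id[!truth$age_dependent], target)[1:3]
fit <- covariate_model(target, covs, expr_aorta,
                       meta[meta$tissue == "aorta", ])
cat(sprintf("\ncovariate model for %s (aorta): R^2 = %.3f, age beta = %.3f (p = %.2g)\n",
            target, fit$r2, fit$coefficients["age"], fit$coef_p["age"]))

# 2^-ddCt demonstration: a 6-sample qPCR table with a one-cycle shift in
# the knockout group (expected fold ~ 0.5)
ct <- rbind(
  Ctrl_1 = c(Mylk = 24.1, Rn18s = 10.2), Ctrl_2 = c(25.0, 11.1),
  Ctrl_3 = c(24.4, 10.6), KO_1 = c(25.6, 10.5),
  KO_2 = c(26.1, 11.0), KO_3 = c(25.9, 10.7))
dd <- delta_delta_ct(ct, reference = "Rn18s",
                     control_samples = c("Ctrl_1", "Ctrl_2", "Ctrl_3"))
cat(sprintf("ddCt: mean KO fold = %.2f (control geometric mean = %.2f)\n",
            mean(dd$fold[4:6, "Mylk"]), exp(mean(log(dd$fold[1:3, "Mylk"])))))
utils::write.table(data.frame(sample = rownames(dd$fold), dd$fold),
                   file.path(out, "ddct_folds.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
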