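#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs.
#
# Generates (a) a three-artery expression cohort (tibial 663, aorta 432,
# coronary 240 donors aged 20-79; 2,000 genes, 10% with linear TPM age
# trends; two 25-gene regulon panels with coordinated decline) and (b) a
# 6 control vs 6 knockout proteome (2,000 proteins, 10% DE at |log2FC| = 2,
# intensity-dependent dropout). Everything is written as TSV under
# results/data/ with the ground truth alongside.

suppressMessages(library(vascage))

seed <- 20240901
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- gen_expression_cohort(cohort_spec(seed = seed))
for (ti in names(cohort$expression)) {
  write_expression_tsv(cohort$expression[[ti]],
                       file.path(out, sprintf("expr_%s.tsv", ti)))
}
utils::write.table(cohort$metadata, file.path(out, "metadata.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cohort$truth, file.path(out, "cohort_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

panels <- gen_gene_panels(cohort$truth, seed = seed)
panel_df <- do.call(rbind, lapply(panels, function(p) {
  data.frame(panel_name = p$name, gene_symbol = p$symbols)
}))
utils::write.table(panel_df, file.path(out, "panels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

proteome <- gen_proteome(proteome_spec(seed = seed))
write_proteome_tsv(proteome$matrix, file.path(out, "proteome_ko.tsv"))
utils::write.table(
  data.frame(sample_id = colnames(proteome$matrix$values),
             group = as.character(proteome$matrix$groups)),
  file.path(out, "proteome_groups.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(proteome$truth, file.path(out, "proteome_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d genes x (%s) samples; %d age-dependent, %d panel genes\n",
            nrow(cohort$truth),
            paste(vapply(cohort$expression, ncol, 1L), collapse = "/"),
            sum(cohort$truth$age_dependent), sum(!is.na(cohort$truth$panel))))
cat(sprintf("proteome: %d proteins, %.1f%% missing, %d true DE\n",
            nrow(proteome$truth), 100 * mean(is.na(proteome$matrix$values)),
            sum(proteome$truth$de)))
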