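#!/usr/bin/env Rscript
# Step 5 — signature comparisons across contrasts.
#
# Builds a second, paired contrast sharing the knockout contrast's true
# effects (independent replicate noise — the analogue of a hypertensive
# challenge reproducing part of the knockout signature), then computes the
# directional overlap of the two significant sets, the panel-level
# fold-change reduction of the regulon, regulator-consistency counts
# against an activator/inhibitor annotation, and the novel-target
# intersection.

suppressMessages(library(vascage))
set.seed(20240905)

data_dir <- "results/data"
out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- utils::read.delim(file.path(data_dir, "proteome_truth.tsv"))
np <- nrow(truth)
ids <- truth$protein_id

# paired contrast: same per-protein true log2FCs, fresh baselines and noise
make_contrast <- function() {
  base <- rnorm(np, 25, 2)
  mu <- base + outer(truth$log2fc, c(rep(0, 6), rep(1, 6)))
  v <- matrix(rnorm(np * 12, mu, 0.3), np, 12,
              dimnames = list(ids, sprintf("s%02d", 1:12)))
  proteomics_matrix(v, rep(c("Ctrl", "Trt"), each = 6), scale = "log2")
}
de_ko <- ttest_permutation_fdr(filter_valid(make_contrast()), seed = 51)
de_angii <- ttest_permutation_fdr(filter_valid(make_contrast()), seed = 52)

ov <- directional_overlap(de_ko, de_angii)
cat(sprintf("directionally consistent significant overlap: %d proteins (%d discordant)\n",
            length(ov$overlap), length(ov$discordant)))
cat(sprintf("shared-truth recovery: %.2f\n",
            mean(toupper(truth$protein_id[truth$de]) %in% ov$overlap)))
writeLines(ov$overlap, file.path(out, "overlap_consistent.txt"))

# panel fold-change test: the 20 most repressed true-DE proteins act as the
# "regulon" panel; their log2FCs should be coherently negative
down_ids <- truth$protein_id[order(truth$log2fc)][1:20]
panel <- gene_panel("SRF_regulon_protein", down_ids)
pf <- panel_fc_test(panel, de_ko)
cat(sprintf("panel fold-change: median log2FC = %.2f, Wilcoxon p = %.2g\n",
            pf$median_log2fc, pf$test$p_value))

# regulator consistency: annotate 30 true-DE proteins as pathway
# activators/inhibitors at random; activator-up or inhibitor-down counts as
# activation-consistent
ann_ids <- sample(truth$protein_id[truth$de], 30)
ann <- data.frame(protein_id = ann_ids,
                  role = sample(c("activator", "inhibitor"), 30, replace = TRUE))
rc <- regulator_consistency(de_ko, ann)
cat(sprintf("regulators: %d of %d annotated are DE; %d change consistent with activation\n",
            rc$n_regulators_de, nrow(ann), rc$n_activation_consistent))
utils::write.table(rc$members, file.path(out, "regulator_consistency.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# novel targets: proteins reduced in the KO contrast, intersected with
# "transcripts induced by the transcription factor", minus known targets
reduced <- de_ko$protein_id[de_ko$significant & de_ko$log2fc < 0]
induced <- sample(truth$protein_id, 400)
known <- down_ids
novel <- intersect_novel_targets(reduced, induced, known)
cat(sprintf("novel candidate targets: %d (reduced %d, induced %d, known %d)\n",
            length(novel), length(reduced), length(induced), length(known)))
writeLines(novel, file.path(out, "novel_targets.txt"))
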