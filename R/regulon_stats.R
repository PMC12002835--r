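# Gene-panel (regulon) statistics: the panel deviation test against the
# genome-wide median correlation, confounder-adjusted regression for single
# target genes, and 2^-ddCt relative quantification for qPCR.

#' Construct a gene panel
#'
#' @param name Panel label.
#' @param symbols Character vector of unique gene identifiers.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0) stop_named("vascage_invalid_panel", "panel '%s' is empty", name)
  if (anyDuplicated(symbols)) {
    stop_named("vascage_invalid_panel", "panel '%s' has duplicate symbols", name)
  }
  structure(list(name = name, symbols = symbols), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Test a panel's age-correlations for deviation from the genome median
#'
#' The regulon-attrition statistic: the panel's per-gene correlation
#' coefficients (R) are extracted from a tissue's correlation table and
#' tested against the median R of all non-degenerate genes in that tissue
#' (typically close to 0) with the one-sample Wilcoxon signed-rank test. A
#' negative direction with small p indicates coordinated decline of the
#' panel with age beyond the genome-wide trend.
#'
#' @param panel A [gene_panel].
#' @param table A correlation table from [correlate_age].
#' @param min_mapped Minimum number of panel genes that must map to
#'   non-degenerate rows.
#' @param mode Passed to [wilcoxon_one_sample].
#' @return List with `tissue`, `panel`, `n_mapped`, `panel_median_r`,
#'   `genome_median_r`, `direction` (sign of the difference), `p`,
#'   `unmapped` and the full `test` object.
#' @export
panel_deviation_test <- function(panel, table, min_mapped = 5,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "gene_panel"))
  usable <- table[!table$degenerate, , drop = FALSE]
  hit <- match(panel$symbols, usable$gene_id)
  unmapped <- panel$symbols[is.na(hit)]
  if (length(unmapped) > 0) {
    vg_log("regulon_stats", "panel '%s': %d unmapped symbol(s)", panel$name, length(unmapped))
  }
  if (length(unmapped) > length(panel$symbols) / 2) {
    stop_named("vascage_unmapped_panel",
               "panel '%s': over half the symbols unmapped (%s)", panel$name,
               paste(utils::head(unmapped, 10), collapse = ", "))
  }
  r_panel <- usable$r[hit[!is.na(hit)]]
  if (length(r_panel) < min_mapped) {
    stop_named("vascage_unmapped_panel",
               "panel '%s': only %d gene(s) map to non-degenerate rows (< %d)",
               panel$name, length(r_panel), min_mapped)
  }
  mu0 <- stats::median(usable$r)
  test <- wilcoxon_one_sample(r_panel, mu0 = mu0, mode = mode)
  med_panel <- stats::median(r_panel)
  list(
    tissue = attr(table, "tissue"),
    panel = panel$name,
    n_mapped = length(r_panel),
    panel_median_r = med_panel,
    genome_median_r = mu0,
    direction = sign(med_panel - mu0),
    p = test$p_value,
    unmapped = unmapped,
    test = test
  )
}

#' Confounder-adjusted linear model for one target gene
#'
#' Regresses a target gene's TPM on donor age and sex plus the TPM of
#' covariate genes (defaults mirror a screen controlling for inflammation,
#' blood pressure and transcription-factor level: CD68, THBS4 and SRF),
#' reporting the model R-squared and two-sided coefficient p-values. Sex is
#' used as coded (1 = male, 2 = female), not recentred.
#'
#' @param target Target gene id (row of `expr`).
#' @param covariate_genes Character vector of covariate gene ids.
#' @param expr Gene x sample TPM matrix.
#' @param meta Metadata with `sample_id`, `age`, `sex`.
#' @return The [ols_fit] result, with covariates named age, sex and the
#'   covariate gene ids.
#' @export
covariate_model <- function(target, covariate_genes, expr, meta) {
  validate_expression(expr, meta)
  missing_genes <- setdiff(c(target, covariate_genes), rownames(expr))
  if (length(missing_genes) > 0) {
    stop_named("vascage_missing_gene", "gene(s) not in matrix: %s",
               paste(missing_genes, collapse = ", "))
  }
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  X <- cbind(age = as.numeric(meta$age), sex = as.numeric(meta$sex))
  for (g in covariate_genes) X <- cbind(X, expr[g, ])
  colnames(X) <- c("age", "sex", covariate_genes)
  ols_fit(expr[target, ], X)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(gene) - Ct(reference); ddCt subtracts the mean dCt
#' of the control group; fold change = `2^-ddCt`, so the control-group
#' geometric mean fold is 1 by construction. Samples missing the reference
#' gene are flagged and excluded. log2 fold-changes (`-ddCt`) are emitted
#' alongside folds because downstream statistics operate on log2 scale.
#'
#' @param ct Sample x gene matrix of Ct cycle values (may contain NA).
#' @param reference Reference (housekeeping) gene column name.
#' @param control_samples Character vector of control-group sample ids
#'   (row names of `ct`).
#' @return List with `fold` and `log2_fold` (sample x gene matrices for all
#'   non-reference genes) and `excluded` (samples without reference Ct).
#' @export
delta_delta_ct <- function(ct, reference, control_samples) {
  if (!is.matrix(ct)) ct <- as.matrix(ct)
  if (!reference %in% colnames(ct)) {
    stop_named("vascage_missing_gene", "reference gene '%s' not in Ct table", reference)
  }
  in_range <- is.na(ct) | (ct > 0 & ct < 45)
  if (!all(in_range)) {
    stop_named("vascage_invalid_ct", "Ct values must lie in (0, 45)")
  }
  if (!any(rownames(ct) %in% control_samples)) {
    stop_named("vascage_invalid_ct", "no control samples present in Ct table")
  }
  excluded <- rownames(ct)[is.na(ct[, reference])]
  if (length(excluded) > 0) {
    vg_log("regulon_stats", "ddCt: excluding %d sample(s) without reference Ct",
           length(excluded))
    ct <- ct[!rownames(ct) %in% excluded, , drop = FALSE]
  }
  genes <- setdiff(colnames(ct), reference)
  dct <- ct[, genes, drop = FALSE] - ct[, reference]
  ctrl <- rownames(dct) %in% control_samples
  ddct <- sweep(dct, 2, colMeans(dct[ctrl, , drop = FALSE], na.rm = TRUE))
  list(fold = 2^(-ddct), log2_fold = -ddct, excluded = excluded)
}
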