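# The transcriptome-wide aging screen: per-tissue correlation tables, the
# pan-arterial high-confidence set, the extended concordant set, effect-proxy
# ranking, and age-bin summaries.

validate_expression <- function(expr, meta = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_named("vascage_invalid_matrix", "expression must be a numeric matrix")
  }
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    stop_named("vascage_duplicate_ids", "expression requires unique gene row names")
  }
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr))) {
    stop_named("vascage_duplicate_ids", "expression requires unique sample column names")
  }
  if (any(!is.finite(expr)) || any(expr < 0)) {
    stop_named("vascage_invalid_matrix", "TPM values must be finite and non-negative")
  }
  if (!is.null(meta)) {
    missing_ids <- setdiff(colnames(expr), meta$sample_id)
    if (length(missing_ids) > 0) {
      stop_named("vascage_missing_metadata", "samples absent from metadata: %s",
                 paste(utils::head(missing_ids, 5), collapse = ", "))
    }
  }
  invisible(expr)
}

#' Correlate every gene's expression with donor age
#'
#' Applies the per-gene Pearson age correlation (see [pearson_age_corr]) to
#' every row of a TPM matrix, then computes Benjamini-Hochberg q-values
#' across the non-degenerate genes of the tissue. Genes with zero expression
#' variance (e.g. silent genes) are flagged degenerate, carry no q-value, and
#' are excluded from the BH denominator.
#'
#' @param expr Gene x sample TPM matrix with row/column names.
#' @param meta Data frame with columns `sample_id`, `age` (and optionally
#'   `sex`, `tissue`).
#' @param tissue Tissue label recorded on the output (defaults to the first
#'   `meta$tissue` value, else `"unknown"`).
#' @return A correlation table: data frame with columns gene_id, n, r, p, q,
#'   slope, mean_tpm, effect_proxy, degenerate, plus attributes `tissue` and
#'   `n_samples`. `effect_proxy = mean_tpm * slope`.
#' @export
correlate_age <- function(expr, meta, tissue = NULL) {
  validate_expression(expr, meta)
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  if (ncol(expr) < 3) stop_named("vascage_too_few_samples", "need >= 3 samples")
  age <- as.numeric(meta$age)
  if (any(!is.finite(age))) stop_named("vascage_invalid_metadata", "non-finite ages")
  if (stats::var(age) == 0) stop_named("vascage_constant_age", "constant age in cohort")
  if (is.null(tissue)) {
    tissue <- if ("tissue" %in% names(meta)) as.character(meta$tissue[1]) else "unknown"
  }

  n <- ncol(expr)
  xc <- age - mean(age)
  sxx <- sum(xc^2)
  mean_tpm <- rowMeans(expr)
  ec <- expr - mean_tpm
  syy <- rowSums(ec^2)
  sxy <- as.numeric(ec %*% xc)
  degenerate <- syy == 0

  r <- rep(NA_real_, nrow(expr))
  r[!degenerate] <- pmin(1, pmax(-1, sxy[!degenerate] /
                                   sqrt(sxx * syy[!degenerate])))
  slope <- sxy / sxx
  p <- rep(NA_real_, nrow(expr))
  ok <- !degenerate & abs(r) < 1
  tval <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[!degenerate & abs(r) == 1] <- .p_floor
  p[!degenerate] <- floor_p(p[!degenerate])$p

  q <- rep(NA_real_, nrow(expr))
  q[!degenerate] <- bh_adjust(p[!degenerate])

  if (any(degenerate)) {
    vg_log("age_screen", "%s: %d degenerate gene(s) excluded from BH",
           tissue, sum(degenerate))
  }
  out <- data.frame(
    gene_id = rownames(expr), n = n, r = r, p = p, q = q, slope = slope,
    mean_tpm = mean_tpm, effect_proxy = mean_tpm * slope,
    degenerate = degenerate, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "tissue") <- tissue
  attr(out, "n_samples") <- n
  out
}

check_same_universe <- function(tables) {
  ids <- lapply(tables, function(t) t$gene_id)
  for (i in seq_along(ids)[-1]) {
    extra <- c(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
    if (length(extra) > 0) {
      stop_named("vascage_universe_mismatch",
                 "gene universes differ between tables; e.g.: %s",
                 paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  invisible(ids[[1]])
}

#' Pan-arterial high-confidence gene set
#'
#' Genes with q below `alpha` in all three tissues and an identical
#' correlation sign throughout, reported with their mean R across tissues.
#'
#' @param tables List of exactly three correlation tables over the same gene
#'   universe (as from [correlate_age]).
#' @param alpha Per-tissue q-value threshold.
#' @return Data frame with columns gene_id, mean_r, direction.
#' @export
pan_arterial_set <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) == 3)
  ids <- check_same_universe(tables)
  tables <- lapply(tables, function(t) t[match(ids, t$gene_id), ])
  qm <- sapply(tables, function(t) t$q)
  rm_ <- sapply(tables, function(t) t$r)
  sig <- rowSums(qm < alpha, na.rm = FALSE) == 3 & !apply(is.na(qm), 1, any)
  sig[is.na(sig)] <- FALSE
  consistent <- abs(rowSums(sign(rm_))) == 3
  consistent[is.na(consistent)] <- FALSE
  keep <- sig & consistent
  out <- data.frame(
    gene_id = ids[keep],
    mean_r = rowMeans(rm_)[keep],
    direction = sign(rowMeans(rm_))[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Extended concordant gene set
#'
#' Genes significant (q < `alpha`) in both primary tissues, with an absolute
#' sum of R across all three tissues above `sum_r_cut` whose sign matches the
#' primary-tissue correlation signs, and a directionally consistent
#' secondary-tissue R with absolute value above `sec_r_cut`. This relaxes the
#' pan-arterial rule for a lower-powered secondary cohort while still
#' requiring concordance.
#'
#' @param tables Named list of three correlation tables (names = tissues).
#' @param primary Character vector of the two primary tissue names.
#' @param secondary The secondary tissue name.
#' @param alpha Primary-tissue q threshold.
#' @param sum_r_cut Threshold on |sum of R across all three tissues|.
#' @param sec_r_cut Threshold on |secondary R|.
#' @return Data frame with columns gene_id, sum_r, direction and one
#'   `r_<tissue>` column per tissue.
#' @export
extended_set <- function(tables, primary, secondary, alpha = 0.05,
                         sum_r_cut = 0.5, sec_r_cut = 0.1) {
  stopifnot(length(tables) == 3, length(primary) == 2, length(secondary) == 1,
            all(c(primary, secondary) %in% names(tables)))
  ids <- check_same_universe(tables)
  tables <- lapply(tables, function(t) t[match(ids, t$gene_id), ])
  r <- sapply(tables, function(t) t$r)       # columns in names(tables) order
  q <- sapply(tables, function(t) t$q)
  colnames(r) <- colnames(q) <- names(tables)

  sig_primary <- q[, primary[1]] < alpha & q[, primary[2]] < alpha
  sig_primary[is.na(sig_primary)] <- FALSE
  sum_r <- rowSums(r)
  prim_sign_consistent <- sign(r[, primary[1]]) == sign(r[, primary[2]]) &
    sign(sum_r) == sign(r[, primary[1]])
  sum_pass <- abs(sum_r) > sum_r_cut
  sec_pass <- sign(r[, secondary]) == sign(sum_r) & abs(r[, secondary]) > sec_r_cut
  keep <- sig_primary & prim_sign_consistent & sum_pass & sec_pass
  keep[is.na(keep)] <- FALSE

  out <- data.frame(gene_id = ids[keep], sum_r = sum_r[keep],
                    direction = sign(sum_r)[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (ti in names(tables)) out[[paste0("r_", ti)]] <- r[keep, ti]
  out[order(out$gene_id), , drop = FALSE]
}

#' Rank genes by the effect-size proxy
#'
#' Sorts non-degenerate genes by `effect_proxy = mean TPM x slope`, ascending
#' for `direction = "negative"` (largest absolute declines first) or
#' descending for `"positive"`, and returns the top `k`. Ties are broken by
#' lexicographic gene id so output is deterministic.
#'
#' @param table A correlation table.
#' @param k Number of genes to return.
#' @param direction `"negative"` or `"positive"`.
#' @return The top-k rows of the table, in rank order.
#' @export
effect_proxy_rank <- function(table, k, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  tab <- table[!table$degenerate, , drop = FALSE]
  if (nrow(tab) == 0) stop_named("vascage_empty_input", "no non-degenerate genes")
  if (k > nrow(tab)) {
    warning(sprintf("k = %d exceeds %d available genes; returning all", k, nrow(tab)))
    k <- nrow(tab)
  }
  ord <- if (direction == "negative") {
    order(tab$effect_proxy, tab$gene_id)
  } else {
    order(-tab$effect_proxy, tab$gene_id)
  }
  tab[ord[seq_len(k)], , drop = FALSE]
}

#' Summarise a gene's expression across age bins
#'
#' Assigns samples to closed age bins (default 20-39, 40-59, 60-79 years,
#' ages floored to integers first), reports per-bin n and median TPM, and
#' tests for differences between bins with the Kruskal-Wallis rank test.
#' Samples outside all bins are dropped with a logged count; any empty bin
#' yields a degenerate result with no test.
#'
#' @param tpm Named numeric vector of one gene's TPM (names = sample ids).
#' @param meta Metadata data frame with `sample_id` and `age`.
#' @param bins List of length-2 numeric vectors, the closed bin intervals.
#' @return List with `summary` (data frame: bin, n, median) and `test`
#'   (a [test_result] or NULL when any bin is empty).
#' @export
age_bin_summary <- function(tpm, meta,
                            bins = list(c(20, 39), c(40, 59), c(60, 79))) {
  meta <- meta[match(names(tpm), meta$sample_id), ]
  age <- floor(as.numeric(meta$age))
  labels <- vapply(bins, function(b) sprintf("%d-%d", b[1], b[2]), "")
  bin_of <- rep(NA_integer_, length(age))
  for (i in seq_along(bins)) {
    bin_of[age >= bins[[i]][1] & age <= bins[[i]][2]] <- i
  }
  dropped <- sum(is.na(bin_of))
  if (dropped > 0) vg_log("age_screen", "age_bin_summary: %d sample(s) outside all bins", dropped)
  groups <- lapply(seq_along(bins), function(i) unname(tpm[which(bin_of == i)]))
  summary <- data.frame(
    bin = labels,
    n = vapply(groups, length, 1L),
    median = vapply(groups, function(g) if (length(g)) stats::median(g) else NA_real_, 1),
    stringsAsFactors = FALSE
  )
  if (any(summary$n == 0)) {
    return(list(summary = summary, test = NULL, degenerate = TRUE))
  }
  list(summary = summary, test = kruskal_wallis(groups), degenerate = FALSE)
}
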