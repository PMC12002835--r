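# File formats, configuration, run manifests, and the two orchestrated
# workflows (aging screen; two-group proteome DE). TSV is the canonical
# interchange format; GCT 1.2 is supported read-only for expression; the
# dendrogram is written as Newick; the manifest as JSON. Missing proteomics
# cells are written as empty strings, round-trip safe with the wide
# DIA-NN-style reader.

#' Read an expression matrix (TSV or GCT 1.2)
#'
#' TSV: first column gene ids, header row of sample ids. GCT 1.2: `#1.2`
#' line, dimensions line, then Name/Description columns before samples.
#' Duplicate gene ids and negative TPM are rejected with named errors.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @param meta Optional metadata for sample-id cross-checking.
#' @return Numeric gene x sample matrix.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_named("vascage_file_not_found", "no such file: %s", path)
  if (format == "gct") {
    header <- readLines(path, n = 1)
    if (!identical(trimws(header), "#1.2")) {
      stop_named("vascage_parse_error", "%s line 1: expected '#1.2' GCT header", path)
    }
    df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- df[[1]]
    values <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- df[[1]]
    values <- as.matrix(df[, -1, drop = FALSE])
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    line <- which(gene_ids == dup)[2] + if (format == "gct") 3 else 1
    stop_named("vascage_duplicate_ids", "%s line %d: duplicate gene id '%s'",
               path, line, dup)
  }
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(rowSums(values < 0, na.rm = TRUE) > 0)[1]
    stop_named("vascage_parse_error", "%s: negative TPM for gene '%s'",
               path, gene_ids[bad])
  }
  validate_expression(values, meta)
  values
}

#' Write an expression matrix as TSV
#' @param expr Gene x sample matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata TSV (sample_id, age, sex, tissue)
#' @param path File path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "age")
  if (!all(needed %in% names(df))) {
    stop_named("vascage_parse_error", "%s: metadata needs columns %s",
               path, paste(needed, collapse = ", "))
  }
  if ("sex" %in% names(df) && !all(df$sex %in% c(1, 2))) {
    stop_named("vascage_parse_error", "%s: sex must be coded 1 (male) or 2 (female)", path)
  }
  df
}

#' Read a wide label-free proteomics matrix
#'
#' Wide TSV in the DIA-NN unique-genes layout: first column protein/gene
#' symbol, one column per sample; empty cells and literal `NaN`/`NA` are
#' parsed as missing. The intensity scale is never guessed: it must be
#' declared.
#'
#' @param path Matrix TSV path.
#' @param groups Named character vector (sample -> group), or a path to a
#'   two-column sample/group TSV.
#' @param scale `"raw"` or `"log2"` (required).
#' @return A [proteomics_matrix].
#' @export
read_proteome <- function(path, groups, scale) {
  if (missing(scale)) {
    stop_named("vascage_scale_undeclared",
               "intensity scale must be declared: scale = 'raw' or 'log2'")
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NaN", "NA"))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df[[1]]
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    gdf <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(gdf[[2]]), gdf[[1]])
  }
  proteomics_matrix(values, groups, scale = scale)
}

#' Write a proteomics matrix as wide TSV (empty cell = missing)
#' @param m A [proteomics_matrix].
#' @param path Output path.
#' @export
write_proteome_tsv <- function(m, path) {
  df <- data.frame(protein_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a correlation table with the stable column order
#'
#' Columns: gene_id, n, R, p, q, slope, mean_tpm, effect_proxy, degenerate.
#'
#' @param table Correlation table from [correlate_age].
#' @param path Output path.
#' @export
write_correlation_table <- function(table, path) {
  out <- data.frame(
    gene_id = table$gene_id, n = table$n, R = table$r, p = table$p,
    q = table$q, slope = table$slope, mean_tpm = table$mean_tpm,
    effect_proxy = table$effect_proxy, degenerate = table$degenerate,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene set as one symbol per line
#'
#' A `#`-prefixed header comment records the thresholds that produced the
#' set, so every emitted list is self-describing.
#'
#' @param ids Character vector of gene ids.
#' @param path Output path.
#' @param thresholds Named list recorded in the header.
#' @export
write_gene_set <- function(ids, path, thresholds = list()) {
  hdr <- if (length(thresholds)) {
    sprintf("# %s", paste(sprintf("%s=%s", names(thresholds),
                                  vapply(thresholds, format, "")), collapse = " "))
  } else "#"
  writeLines(c(hdr, ids), path)
  invisible(path)
}

#' Read gene panels from TSV or one-per-line text
#'
#' TSV with columns panel_name and gene_symbol, or plain text with
#' `# panel: <name>` headers introducing each block of one-symbol lines.
#'
#' @param path File path.
#' @return Named list of [gene_panel] objects.
#' @export
read_gene_panels <- function(path) {
  lines <- readLines(path)
  first_data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))][1]
  if (grepl("\t", first_data)) {
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    split_syms <- split(df[[2]], df[[1]])
  } else {
    split_syms <- list()
    current <- NULL
    for (ln in lines) {
      ln <- trimws(ln)
      if (grepl("^#\\s*panel:", ln)) {
        current <- trimws(sub("^#\\s*panel:", "", ln))
        split_syms[[current]] <- character()
      } else if (nzchar(ln) && !startsWith(ln, "#")) {
        if (is.null(current)) {
          stop_named("vascage_parse_error", "%s: symbol before any '# panel:' header", path)
        }
        split_syms[[current]] <- c(split_syms[[current]], ln)
      }
    }
  }
  lapply_names <- names(split_syms)
  panels <- lapply(lapply_names, function(nm) gene_panel(nm, split_syms[[nm]]))
  stats::setNames(panels, lapply_names)
}

#' Write a dendrogram as Newick
#' @param h An `hclust` object.
#' @param path Output path.
#' @export
write_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: screen alpha 0.05,
#' sum-of-R cutoff 0.5, secondary-R cutoff 0.1, age bins 20-39/40-59/60-79,
#' proteomics minimum 3 valid values per group, 250 permutations at FDR
#' 0.05 with s0 = 0, imputation width 0.4 and downshift 1.8. Overrides are
#' validated: unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    sum_r_cut = 0.5,
    sec_r_cut = 0.1,
    bins = list(c(20, 39), c(40, 59), c(60, 79)),
    min_valid = 3,
    n_perm = 250,
    fdr = 0.05,
    s0 = 0,
    width = 0.4,
    downshift = 1.8
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop_named("vascage_unknown_config", "unknown config key(s): %s",
               paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, overrides)
}

manifest_entry <- function(workflow, seed, config, inputs = character(),
                           outputs = character()) {
  list(
    tool = "vascage",
    version = as.character(utils::packageVersion("vascage")),
    workflow = workflow,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = config[!vapply(config, is.list, TRUE)],
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the multi-artery aging-screen workflow
#'
#' Correlates every gene with age in each tissue, derives the pan-arterial
#' and extended concordant sets (primary tissues = the two largest cohorts,
#' secondary = the smallest), runs the panel deviation test for any supplied
#' panels, and — when `out_dir` is given — writes all tables plus a JSON run
#' manifest. Re-running with identical inputs and config reproduces
#' identical artifacts (manifests differ only in timestamp).
#'
#' @param cohort List with `expression` (named list of matrices) and
#'   `metadata`, as from [gen_expression_cohort] or assembled from files.
#' @param panels Optional named list of [gene_panel] objects.
#' @param config Configuration from [default_config].
#' @param out_dir Optional output directory.
#' @return List with `tables` (per-tissue correlation tables), `pan_set`,
#'   `extended_set`, `panel_tests`, `manifest`.
#' @export
run_aging_screen <- function(cohort, panels = NULL, config = default_config(),
                             out_dir = NULL) {
  tissues <- names(cohort$expression)
  stopifnot(length(tissues) == 3)
  tables <- lapply(tissues, function(ti) {
    meta <- cohort$metadata[cohort$metadata$tissue == ti, , drop = FALSE]
    correlate_age(cohort$expression[[ti]], meta, tissue = ti)
  })
  names(tables) <- tissues
  sizes <- vapply(cohort$expression, ncol, 1L)
  primary <- names(sort(sizes, decreasing = TRUE))[1:2]
  secondary <- names(sort(sizes))[1]
  pan <- pan_arterial_set(tables, alpha = config$alpha)
  ext <- extended_set(tables, primary = primary, secondary = secondary,
                      alpha = config$alpha, sum_r_cut = config$sum_r_cut,
                      sec_r_cut = config$sec_r_cut)
  panel_tests <- NULL
  if (!is.null(panels)) {
    panel_tests <- do.call(rbind, lapply(tissues, function(ti) {
      do.call(rbind, lapply(panels, function(p) {
        res <- panel_deviation_test(p, tables[[ti]])
        data.frame(tissue = ti, panel = res$panel, n_mapped = res$n_mapped,
                   panel_median_r = res$panel_median_r,
                   genome_median_r = res$genome_median_r,
                   direction = res$direction, p = res$p,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(panel_tests) <- NULL
  }
  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ti in tissues) {
      f <- file.path(out_dir, sprintf("corr_%s.tsv", ti))
      write_correlation_table(tables[[ti]], f)
      outputs <- c(outputs, f)
    }
    f <- file.path(out_dir, "pan_arterial_set.txt")
    write_gene_set(pan$gene_id, f, list(alpha = config$alpha))
    outputs <- c(outputs, f)
    f <- file.path(out_dir, "extended_set.txt")
    write_gene_set(ext$gene_id, f,
                   list(alpha = config$alpha, sum_r_cut = config$sum_r_cut,
                        sec_r_cut = config$sec_r_cut))
    outputs <- c(outputs, f)
    if (!is.null(panel_tests)) {
      f <- file.path(out_dir, "panel_tests.tsv")
      utils::write.table(panel_tests, f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }
  manifest <- manifest_entry("aging-screen", seed = NA, config = config,
                             outputs = outputs)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(tables = tables, pan_set = pan, extended_set = ext,
       panel_tests = panel_tests, manifest = manifest)
}

#' Run the two-group proteome differential-expression workflow
#'
#' Filters on valid values per group, runs the permutation-FDR t test, then
#' — on the imputed matrix — PCA, and — on the z-scored significant
#' proteins — hierarchical clustering. Writes the DE table, PCA scores,
#' Newick dendrograms and a manifest when `out_dir` is given.
#'
#' @param m A log2-scale [proteomics_matrix] (use [log2_transform] first for
#'   raw data).
#' @param config Configuration from [default_config].
#' @param seed Integer seed covering permutation, imputation and clustering.
#' @param out_dir Optional output directory.
#' @return List with `de`, `pca`, `clustering`, `filtered`, `manifest`.
#' @export
run_proteome_de <- function(m, config = default_config(), seed, out_dir = NULL) {
  if (missing(seed)) stop_named("vascage_seed_required", "workflow requires a seed")
  stopifnot(inherits(m, "proteomics_matrix"))
  filtered <- filter_valid(m, min_valid = config$min_valid)
  de <- ttest_permutation_fdr(filtered, n_perm = config$n_perm,
                              fdr = config$fdr, s0 = config$s0, seed = seed)
  imputed <- impute_downshift(filtered, width = config$width,
                              downshift = config$downshift, seed = seed)
  pca <- pca_scores(imputed, n_components = 2)
  clustering <- NULL
  sig_ids <- de$protein_id[de$significant]
  if (length(sig_ids) >= 2) {
    sig <- imputed
    sig$values <- sig$values[sig_ids, , drop = FALSE]
    clustering <- hcluster(zscore_rows(sig))
  }
  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "de_results.tsv")
    utils::write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
    f <- file.path(out_dir, "pca_scores.tsv")
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores), pca$scores,
                 stringsAsFactors = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
    if (!is.null(clustering)) {
      f <- file.path(out_dir, "dendrogram_samples.nwk")
      write_newick(clustering$col_hclust, f)
      outputs <- c(outputs, f)
    }
  }
  manifest <- manifest_entry("proteome-de", seed = seed, config = config,
                             outputs = outputs)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(de = de, pca = pca, clustering = clustering, filtered = filtered,
       manifest = manifest)
}
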