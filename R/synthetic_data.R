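# Synthetic-data generators: seeded, ground-truth-labelled expression cohorts
# and two-group label-free proteomes with intensity-dependent missingness.
# These supply every downstream stage with inputs of known structure so the
# whole pipeline is testable without any external download.

#' Specify a multi-tissue expression cohort
#'
#' Defaults emulate the three GTEx arterial cohorts (tibial artery n = 663,
#' aorta n = 432, coronary artery n = 240; donors aged 20-79) with 10% of
#' genes carrying linear age trends on TPM scale and two "regulon" panels of
#' coordinately declining genes.
#'
#' @param n_genes Number of genes.
#' @param n_samples Named integer vector, samples per tissue.
#' @param age_range Length-2 numeric, donor age span in years.
#' @param frac_age_dependent Fraction of (non-panel) genes given age trends.
#' @param slope_scale Upper bound on the absolute relative slope `s`: an
#'   age-dependent gene's expected TPM is
#'   `baseline * (1 + s * (age - mid) / halfspan)`, so `|s|` is the relative
#'   change between the age midpoint and either extreme. Trend magnitudes are
#'   drawn uniformly on `[0.1, slope_scale]`.
#' @param noise_cv Coefficient of variation of multiplicative log-normal noise.
#' @param panel_spec List of panels, each `list(name=, size=, direction=)`
#'   with direction -1 (coordinated decline) or +1.
#' @param age_binning `"continuous"` for exact ages, `"decade"` to emit
#'   decade-bracket midpoints as public repositories do.
#' @param seed Integer seed (required; there is no implicit randomness).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 2000,
                        n_samples = c(tibial = 663, aorta = 432, coronary = 240),
                        age_range = c(20, 79),
                        frac_age_dependent = 0.10,
                        slope_scale = 0.6,
                        noise_cv = 0.5,
                        panel_spec = list(
                          list(name = "SRF_regulon", size = 25, direction = -1),
                          list(name = "YAP_TAZ_regulon", size = 25, direction = -1)
                        ),
                        age_binning = c("continuous", "decade"),
                        seed) {
  if (missing(seed)) stop_named("vascage_seed_required", "cohort_spec requires a seed")
  age_binning <- match.arg(age_binning)
  stopifnot(
    n_genes >= 1, all(n_samples >= 1), !is.null(names(n_samples)),
    length(age_range) == 2, age_range[1] < age_range[2],
    frac_age_dependent >= 0, frac_age_dependent <= 1,
    slope_scale >= 0, slope_scale < 1, noise_cv >= 0
  )
  structure(
    list(n_genes = as.integer(n_genes), n_samples = n_samples,
         age_range = age_range, frac_age_dependent = frac_age_dependent,
         slope_scale = slope_scale, noise_cv = noise_cv,
         panel_spec = panel_spec, age_binning = age_binning,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a multi-tissue expression cohort with ground truth
#'
#' Ages are drawn uniformly over the age range (optionally decade-binned to
#' midpoints); per-gene baseline TPM is log-normal; age-dependent genes have
#' expected TPM `baseline * (1 + s * (age - mid) / halfspan)` truncated at 0,
#' with panel genes receiving coordinated trends of the panel's direction;
#' multiplicative log-normal noise has coefficient of variation `noise_cv`.
#' Sex is assigned 1 (male) or 2 (female) at random. The same spec (including
#' its seed) always reproduces identical output; each random stream uses its
#' own derived child seed so adding a stream never perturbs the others.
#'
#' @param spec A [cohort_spec].
#' @return List with `expression` (named list of gene x sample TPM matrices,
#'   one per tissue), `metadata` (data frame: sample_id, age, sex, tissue)
#'   and `truth` (data frame: gene_id, rel_slope, slope_tpm_per_year,
#'   age_dependent, panel, baseline_tpm).
#' @export
gen_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ngen <- spec$n_genes
  gene_ids <- sprintf("GENE%05d", seq_len(ngen))
  mid <- mean(spec$age_range)
  halfspan <- diff(spec$age_range) / 2

  baseline <- with_seed(derive_seed(spec$seed, "baseline"),
                        stats::rlnorm(ngen, meanlog = log(10), sdlog = 1.5))

  # Assign panels first (disjoint gene blocks), then random trends elsewhere.
  panel <- rep(NA_character_, ngen)
  s <- numeric(ngen)
  with_seed(derive_seed(spec$seed, "trends"), {
    free <- seq_len(ngen)
    for (ps in spec$panel_spec) {
      if (ps$size > length(free)) {
        stop_named("vascage_invalid_spec", "panel '%s' larger than remaining gene pool", ps$name)
      }
      idx <- sample(free, ps$size)
      free <- setdiff(free, idx)
      panel[idx] <- ps$name
      s[idx] <- ps$direction * stats::runif(ps$size, 0.1, max(0.1, spec$slope_scale))
    }
    n_dep <- round(spec$frac_age_dependent * length(free))
    if (n_dep > 0) {
      idx <- sample(free, n_dep)
      s[idx] <- sample(c(-1, 1), n_dep, replace = TRUE) *
        stats::runif(n_dep, 0.1, max(0.1, spec$slope_scale))
    }
  })

  tissues <- names(spec$n_samples)
  ages <- with_seed(derive_seed(spec$seed, "ages"), {
    lapply(tissues, function(ti) {
      a <- stats::runif(spec$n_samples[[ti]], spec$age_range[1], spec$age_range[2])
      if (spec$age_binning == "decade") a <- (floor(a / 10) * 10) + 5
      a
    })
  })
  names(ages) <- tissues
  sex <- with_seed(derive_seed(spec$seed, "sex"), {
    lapply(tissues, function(ti) sample(1:2, spec$n_samples[[ti]], replace = TRUE))
  })
  names(sex) <- tissues

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  expression <- list()
  meta <- list()
  for (ti in tissues) {
    nsamp <- spec$n_samples[[ti]]
    ids <- sprintf("%s_S%04d", toupper(ti), seq_len(nsamp))
    expected <- baseline * (1 + outer(s, (ages[[ti]] - mid) / halfspan))
    n_neg <- sum(expected < 0)
    if (n_neg > 0.01 * length(expected)) {
      stop_named("vascage_invalid_spec",
                 "expected TPM negative in %.1f%% of cells; reduce slope_scale",
                 100 * n_neg / length(expected))
    }
    expected[expected < 0] <- 0
    noise <- with_seed(derive_seed(spec$seed, paste0("noise_", ti)), {
      if (spec$noise_cv == 0) {
        matrix(1, ngen, nsamp)
      } else {
        matrix(stats::rlnorm(ngen * nsamp, meanlog = -sdlog^2 / 2, sdlog = sdlog),
               ngen, nsamp)
      }
    })
    m <- expected * noise
    dimnames(m) <- list(gene_ids, ids)
    expression[[ti]] <- m
    meta[[ti]] <- data.frame(sample_id = ids, age = ages[[ti]],
                             sex = sex[[ti]], tissue = ti,
                             stringsAsFactors = FALSE)
  }

  truth <- data.frame(
    gene_id = gene_ids,
    rel_slope = s,
    slope_tpm_per_year = baseline * s / halfspan,
    age_dependent = s != 0,
    panel = panel,
    baseline_tpm = baseline,
    stringsAsFactors = FALSE
  )
  vg_log("synthetic_data", "cohort: %d genes, %d tissues, %d age-dependent genes",
         ngen, length(tissues), sum(truth$age_dependent))
  list(expression = expression, metadata = do.call(rbind, unname(meta)),
       truth = truth)
}

#' Emit injected trend panels plus random null panels
#'
#' Returns the panels whose genes carry injected coordinated trends (from the
#' simulator's truth table) together with `n_null_panels` panels sampled
#' uniformly from the whole gene universe, for calibration of the panel
#' deviation test.
#'
#' @param truth Truth table from [gen_expression_cohort].
#' @param n_null_panels Number of random panels to add.
#' @param panel_size Size of each null panel.
#' @param seed Integer seed.
#' @return Named list of [gene_panel] objects.
#' @export
gen_gene_panels <- function(truth, n_null_panels = 0, panel_size = 20, seed) {
  if (missing(seed)) stop_named("vascage_seed_required", "gen_gene_panels requires a seed")
  if (panel_size > nrow(truth)) {
    stop_named("vascage_invalid_spec", "panel_size exceeds the gene universe")
  }
  panels <- list()
  for (nm in unique(stats::na.omit(truth$panel))) {
    panels[[nm]] <- gene_panel(nm, truth$gene_id[!is.na(truth$panel) & truth$panel == nm])
  }
  if (n_null_panels > 0) {
    nulls <- with_seed(derive_seed(seed, "null_panels"), {
      lapply(seq_len(n_null_panels), function(i) {
        gene_panel(sprintf("null_%04d", i), sample(truth$gene_id, panel_size))
      })
    })
    names(nulls) <- vapply(nulls, function(p) p$name, "")
    panels <- c(panels, nulls)
  }
  panels
}

#' Specify a two-group label-free proteome
#'
#' Defaults emulate a 6 control vs 6 knockout aorta experiment quantified on
#' log2 intensity scale: per-protein baselines spread over a realistic
#' abundance range, 10% of proteins differentially expressed at |log2FC| =
#' `lfc_scale`, and missing-not-at-random dropout whose probability rises
#' sigmoidally as intensity falls.
#'
#' @param n_proteins Number of proteins.
#' @param groups List of `list(label=, n=)`, exactly the group layout.
#' @param frac_de Fraction of proteins differentially expressed.
#' @param lfc_scale Absolute log2 fold-change of DE proteins (sign random).
#' @param base_mean Mean of per-protein baseline log2 intensity.
#' @param mean_spread SD of per-protein baseline log2 intensity around
#'   `base_mean` (gives the abundance range that drives MNAR dropout).
#' @param base_sd Within-protein (replicate) SD on log2 scale.
#' @param dropout_midpoint log2 intensity at which dropout probability is 0.5.
#' @param dropout_steepness Sigmoid steepness (per log2 unit); 0 disables dropout.
#' @param seed Integer seed (required).
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins = 2000,
                          groups = list(list(label = "Ctrl", n = 6),
                                        list(label = "KO", n = 6)),
                          frac_de = 0.10,
                          lfc_scale = 2,
                          base_mean = 25,
                          mean_spread = 2,
                          base_sd = 0.3,
                          dropout_midpoint = 20,
                          dropout_steepness = 1,
                          seed) {
  if (missing(seed)) stop_named("vascage_seed_required", "proteome_spec requires a seed")
  stopifnot(
    n_proteins >= 1, length(groups) >= 2,
    all(vapply(groups, function(g) g$n >= 2, TRUE)),
    frac_de >= 0, frac_de <= 1, base_sd > 0, mean_spread >= 0,
    dropout_steepness >= 0
  )
  structure(
    list(n_proteins = as.integer(n_proteins), groups = groups,
         frac_de = frac_de, lfc_scale = lfc_scale, base_mean = base_mean,
         mean_spread = mean_spread, base_sd = base_sd,
         dropout_midpoint = dropout_midpoint,
         dropout_steepness = dropout_steepness, seed = as.integer(seed)),
    class = "proteome_spec"
  )
}

#' Generate a two-group proteome with MNAR missingness and ground truth
#'
#' log2 intensities are Normal(per-protein baseline + group effect,
#' `base_sd`); `round(frac_de * n_proteins)` proteins receive a log2FC of
#' `+/- lfc_scale` (sign random) in every non-reference group; each cell is
#' then independently set missing with probability
#' `sigmoid((dropout_midpoint - intensity) * dropout_steepness)`, so lower
#' intensities are missing more often (missing-not-at-random). Deterministic
#' under the spec's seed.
#'
#' @param spec A [proteome_spec].
#' @return List with `matrix` (a [proteomics_matrix], log2 scale) and
#'   `truth` (data frame: protein_id, log2fc, de).
#' @export
gen_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  np <- spec$n_proteins
  protein_ids <- sprintf("PROT%05d", seq_len(np))
  labels <- vapply(spec$groups, function(g) g$label, "")
  sizes <- vapply(spec$groups, function(g) as.integer(g$n), 1L)
  group_vec <- rep(labels, sizes)
  sample_ids <- unlist(lapply(seq_along(labels), function(i) {
    sprintf("%s_%d", labels[i], seq_len(sizes[i]))
  }))

  baseline <- with_seed(derive_seed(spec$seed, "protein_baseline"),
                        stats::rnorm(np, spec$base_mean, spec$mean_spread))
  n_de <- round(spec$frac_de * np)
  lfc <- numeric(np)
  if (n_de > 0) {
    lfc_vals <- with_seed(derive_seed(spec$seed, "de_effects"), {
      idx <- sample(np, n_de)
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      list(idx = idx, val = sgn * spec$lfc_scale)
    })
    lfc[lfc_vals$idx] <- lfc_vals$val
  }

  # group effect applies to every non-reference group (first group = reference)
  effect <- outer(lfc, as.numeric(group_vec != labels[1]))
  mu <- baseline + effect
  values <- with_seed(derive_seed(spec$seed, "intensities"), {
    matrix(stats::rnorm(np * length(group_vec), mu, spec$base_sd),
           np, length(group_vec))
  })
  if (spec$dropout_steepness > 0) {
    p_miss <- stats::plogis((spec$dropout_midpoint - values) * spec$dropout_steepness)
    miss <- with_seed(derive_seed(spec$seed, "dropout"), {
      matrix(stats::runif(length(values)) < p_miss, np, length(group_vec))
    })
    if (mean(miss) > 0.9) {
      stop_named("vascage_invalid_spec",
                 "dropout parameters yield %.0f%% missingness (> 90%%)", 100 * mean(miss))
    }
    values[miss] <- NA_real_
  }
  dimnames(values) <- list(protein_ids, sample_ids)
  m <- proteomics_matrix(values, stats::setNames(group_vec, sample_ids), scale = "log2")
  truth <- data.frame(protein_id = protein_ids, log2fc = lfc, de = lfc != 0,
                      stringsAsFactors = FALSE)
  vg_log("synthetic_data", "proteome: %d proteins, %s; %d DE; %.1f%% missing",
         np, paste(sprintf("%s n=%d", labels, sizes), collapse = " vs "),
         n_de, 100 * mean(is.na(values)))
  list(matrix = m, truth = truth)
}
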