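# Set- and panel-level comparisons across differential-expression results:
# directional overlap between contrasts, panel fold-change reduction,
# regulator-consistency counting, and novel-target intersection.
# Identifier matching is exact but case-insensitive; "significant" always
# means the DE result's permutation-FDR flag, never a raw p cut.

norm_id <- function(x) toupper(as.character(x))

#' Directional overlap between two differential-expression results
#'
#' Proteins significant in both results whose log2 fold-changes share the
#' same sign, plus the significant-but-discordant set. Computed over the
#' intersection of the two protein universes (logged). Symmetric in its
#' arguments.
#'
#' @param a,b Data frames as returned by [ttest_permutation_fdr].
#' @return List with `overlap`, `discordant` (sorted id vectors),
#'   `directions` (data frame of signs for the overlap), and `n_shared`.
#' @export
directional_overlap <- function(a, b) {
  shared <- intersect(norm_id(a$protein_id), norm_id(b$protein_id))
  if (length(shared) == 0) stop_named("vascage_empty_universe", "no shared proteins")
  vg_log("signature_overlap", "shared universe: %d proteins", length(shared))
  ia <- match(shared, norm_id(a$protein_id))
  ib <- match(shared, norm_id(b$protein_id))
  both_sig <- a$significant[ia] & b$significant[ib]
  same_sign <- sign(a$log2fc[ia]) == sign(b$log2fc[ib])
  overlap <- sort(shared[both_sig & same_sign])
  discordant <- sort(shared[both_sig & !same_sign])
  list(
    overlap = overlap,
    discordant = discordant,
    directions = data.frame(
      protein_id = overlap,
      direction = sign(a$log2fc[ia])[match(overlap, shared)],
      stringsAsFactors = FALSE
    ),
    n_shared = length(shared)
  )
}

#' Test a panel's fold-changes against zero
#'
#' One-sample Wilcoxon signed-rank test of the panel members' log2
#' fold-changes versus 0 — the panel-level analogue of asking whether a
#' regulon is coordinately reduced at the protein level — plus the panel
#' median log2FC and a per-member table.
#'
#' @param panel A [gene_panel].
#' @param de A DE result data frame with computed log2fc.
#' @param min_mapped Minimum panel members with a computed fold-change.
#' @return List with `test` (a [test_result]), `median_log2fc`, `n_mapped`,
#'   `members` (data frame), `unmapped`.
#' @export
panel_fc_test <- function(panel, de, min_mapped = 5) {
  stopifnot(inherits(panel, "gene_panel"))
  hit <- match(norm_id(panel$symbols), norm_id(de$protein_id))
  ok <- !is.na(hit) & is.finite(de$log2fc[hit])
  unmapped <- panel$symbols[!ok]
  if (sum(ok) < min_mapped) {
    stop_named("vascage_unmapped_panel",
               "panel '%s': only %d member(s) with a fold-change (< %d); unmapped: %s",
               panel$name, sum(ok), min_mapped,
               paste(utils::head(unmapped, 10), collapse = ", "))
  }
  lfc <- de$log2fc[hit[ok]]
  members <- data.frame(protein_id = de$protein_id[hit[ok]], log2fc = lfc,
                        significant = de$significant[hit[ok]],
                        stringsAsFactors = FALSE)
  list(test = wilcoxon_one_sample(lfc, mu0 = 0),
       median_log2fc = stats::median(lfc),
       n_mapped = sum(ok), members = members, unmapped = unmapped)
}

#' Count regulators changing consistently with pathway activation
#'
#' Given an annotation of pathway regulators as activators or inhibitors,
#' counts how many are differentially expressed and how many of those change
#' in the direction expected to activate the pathway (activator up, or
#' inhibitor down).
#'
#' @param de A DE result data frame.
#' @param ann Data frame with columns `protein_id` and `role` (`"activator"`
#'   or `"inhibitor"`); conflicting duplicate annotations are an error.
#' @return List with `n_regulators_de`, `n_activation_consistent`, and
#'   `members` (data frame with per-member direction and consistency).
#' @export
regulator_consistency <- function(de, ann) {
  if (nrow(ann) == 0) stop_named("vascage_empty_input", "empty annotation")
  if (!all(ann$role %in% c("activator", "inhibitor"))) {
    stop_named("vascage_invalid_annotation", "role must be 'activator' or 'inhibitor'")
  }
  key <- norm_id(ann$protein_id)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conflicts <- tapply(ann$role, key, function(r) length(unique(r)) > 1)
    if (any(conflicts)) {
      stop_named("vascage_invalid_annotation",
                 "conflicting roles for: %s",
                 paste(names(conflicts)[conflicts], collapse = ", "))
    }
    ann <- ann[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  hit <- match(key, norm_id(de$protein_id))
  present <- !is.na(hit)
  de_flag <- present & de$significant[hit]
  de_flag[is.na(de_flag)] <- FALSE
  lfc <- ifelse(present, de$log2fc[hit], NA_real_)
  consistent <- de_flag & ((ann$role == "activator" & lfc > 0) |
                           (ann$role == "inhibitor" & lfc < 0))
  members <- data.frame(
    protein_id = ann$protein_id[de_flag],
    role = ann$role[de_flag],
    log2fc = lfc[de_flag],
    activation_consistent = consistent[de_flag],
    stringsAsFactors = FALSE
  )
  members <- members[order(members$protein_id), , drop = FALSE]
  list(n_regulators_de = sum(de_flag),
       n_activation_consistent = sum(consistent),
       members = members)
}

#' Intersect reduced proteins with induced transcripts, minus known targets
#'
#' `(reduced proteins ∩ transcription-factor-induced transcripts) \ known
#' targets`, sorted deterministically — the novel-candidate-target
#' construction used to nominate previously unrecognised members of a
#' regulon.
#'
#' @param reduced_proteins,induced_transcripts,known_targets Character id
#'   vectors in a shared namespace.
#' @return Sorted character vector of candidate novel targets.
#' @export
intersect_novel_targets <- function(reduced_proteins, induced_transcripts,
                                    known_targets = character()) {
  sort(setdiff(intersect(norm_id(reduced_proteins), norm_id(induced_transcripts)),
               norm_id(known_targets)))
}
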