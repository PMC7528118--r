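#' Define a two-group phenotype contrast
#'
#' @param group_a Cultivar sample ids of the first group (e.g. trailing).
#' @param group_b Cultivar sample ids of the second group (e.g. upright).
#' @return A list of class `group_contrast`.
#' @export
group_contrast <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) abort("both contrast groups must be non-empty")
  if (length(intersect(group_a, group_b))) abort("contrast groups must be disjoint")
  structure(list(group_a = group_a, group_b = group_b), class = "group_contrast")
}

check_contrast <- function(panel, contrast) {
  miss <- setdiff(c(contrast$group_a, contrast$group_b), panel$samples$sample_id)
  if (length(miss)) abort(paste0("contrast sample(s) not in panel: ", paste(miss, collapse = ", ")))
}

#' Loci polymorphic between two phenotype groups
#'
#' A locus qualifies when at least one cross-group pair (one sample from
#' each group) has differing non-missing calls (the any-cross-pair rule).
#'
#' @param panel A [genotype_panel()].
#' @param contrast A [group_contrast()].
#' @return Logical vector over the panel's loci.
#' @export
between_group_polymorphic <- function(panel, contrast) {
  check_contrast(panel, contrast)
  keep <- rep(FALSE, n_loci(panel))
  for (a in contrast$group_a) {
    ca <- panel$calls[, a]
    for (b in contrast$group_b) {
      cb <- panel$calls[, b]
      keep <- keep | (!is.na(ca) & !is.na(cb) & ca != cb)
    }
  }
  keep
}

#' Fixed-difference loci between two phenotype groups
#'
#' Loci monomorphic within each group but differing between them: all
#' group-A calls are non-missing and identical, all group-B calls are
#' non-missing and identical, and the two shared calls differ.
#'
#' @inheritParams between_group_polymorphic
#' @return Logical vector over the panel's loci.
#' @export
fixed_difference_loci <- function(panel, contrast) {
  check_contrast(panel, contrast)
  mono_call <- function(ids) {
    sub <- panel$calls[, ids, drop = FALSE]
    first <- sub[, 1L]
    same <- rowSums(is.na(sub)) == 0L & rowSums(sub == first, na.rm = TRUE) == length(ids)
    ifelse(same, first, NA_character_)
  }
  ca <- mono_call(contrast$group_a)
  cb <- mono_call(contrast$group_b)
  !is.na(ca) & !is.na(cb) & ca != cb
}

#' Origin-category enrichment within a locus subset
#'
#' For each cultivar of the contrast, compares its category proportions
#' within a locus subset (typically the between-group polymorphic SNPs)
#' against its proportions in the whole panel (`ratio =
#' proportion_in_subset / proportion_in_whole`). The group-level summary
#' additionally reports, per category, each group's mean subset proportion
#' and its `relative_ratio` against the mean over all contrast cultivars
#' -- the self-normalizing statistic for judging whether one group is
#' enriched relative to the panel average.
#'
#' @param panel A [genotype_panel()].
#' @param contrast A [group_contrast()].
#' @param subset Logical locus vector (e.g. from
#'   [between_group_polymorphic()] or [fixed_difference_loci()]).
#' @inheritParams classify_locus
#' @return A list of class `enrichment_report` with tibbles `by_sample`
#'   (`sample_id`, `group`, `index`, `label`, `proportion_in_subset`,
#'   `proportion_in_whole`, `ratio`) and `by_group` (`group`, `index`,
#'   `label`, `mean_proportion_in_subset`, `mean_proportion_in_whole`,
#'   `mean_ratio`, `relative_ratio`).
#' @export
category_enrichment <- function(panel, contrast, subset,
                                mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  check_contrast(panel, contrast)
  if (!any(subset)) abort("empty locus subset")
  sub_panel <- subset_loci(panel, subset)
  ids <- c(contrast$group_a, contrast$group_b)
  grp <- c(rep("A", length(contrast$group_a)), rep("B", length(contrast$group_b)))
  by_sample <- purrr::map2_dfr(ids, grp, function(s, g) {
    whole <- category_profile(panel, s, mode)
    insub <- category_profile(sub_panel, s, mode)
    tibble(
      sample_id = s, group = g, index = whole$index, label = whole$label,
      proportion_in_subset = insub$proportion,
      proportion_in_whole = whole$proportion,
      ratio = ifelse(whole$proportion > 0, insub$proportion / whole$proportion, 0)
    )
  })
  overall <- dplyr::summarise(dplyr::group_by(by_sample, .data$index),
                              overall_subset = mean(.data$proportion_in_subset),
                              .groups = "drop")
  by_group <- dplyr::summarise(
    dplyr::group_by(by_sample, .data$group, .data$index, .data$label),
    mean_proportion_in_subset = mean(.data$proportion_in_subset),
    mean_proportion_in_whole = mean(.data$proportion_in_whole),
    mean_ratio = mean(.data$ratio), .groups = "drop"
  )
  by_group <- dplyr::left_join(by_group, overall, by = "index")
  by_group$relative_ratio <- ifelse(by_group$overall_subset > 0,
                                    by_group$mean_proportion_in_subset / by_group$overall_subset, 0)
  by_group$overall_subset <- NULL
  structure(list(by_sample = by_sample, by_group = dplyr::arrange(by_group, .data$group, .data$index)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>\n  by_group:\n")
  print(x$by_group, n = 24)
  invisible(x)
}

#' @exportS3Method
tidy.enrichment_report <- function(x, ...) x$by_sample

#' @exportS3Method
glance.enrichment_report <- function(x, ...) {
  cat7 <- x$by_group[x$by_group$index == 7L, ]
  tibble(
    cat7_relative_ratio_a = cat7$relative_ratio[cat7$group == "A"],
    cat7_relative_ratio_b = cat7$relative_ratio[cat7$group == "B"]
  )
}

#' Permutation p-value for a group's category enrichment
#'
#' Optional significance assessment beyond the descriptive proportions:
#' permutes the group labels of the contrast cultivars and recomputes the
#' group-A relative enrichment ratio for one category each time.
#'
#' @inheritParams category_enrichment
#' @param category Category index (default 7).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @return One-row tibble: `observed`, `p_value`, `n_perm`.
#' @export
enrichment_permutation_test <- function(panel, contrast, subset, category = 7L,
                                        n_perm = 200L, seed = 1L,
                                        mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  obs_rep <- category_enrichment(panel, contrast, subset, mode)
  obs <- obs_rep$by_group$relative_ratio[obs_rep$by_group$group == "A" &
                                           obs_rep$by_group$index == category]
  ids <- c(contrast$group_a, contrast$group_b)
  na <- length(contrast$group_a)
  stats_perm <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample(ids, length(ids))
    ct <- group_contrast(perm[seq_len(na)], perm[-seq_len(na)])
    rep_i <- category_enrichment(panel, ct, subset, mode)
    rep_i$by_group$relative_ratio[rep_i$by_group$group == "A" & rep_i$by_group$index == category]
  }, numeric(1)))
  tibble(observed = obs,
         p_value = (1 + sum(stats_perm >= obs)) / (1 + n_perm),
         n_perm = n_perm)
}

#' Transcripts with group-A-exclusive category-7 SNPs
#'
#' Transcripts carrying at least one shared/out heterozygous
#' (category 7) SNP in every group-A cultivar and none in any group-B
#' cultivar -- the candidate set for introgression linked to the group-A
#' phenotype.
#'
#' @inheritParams category_enrichment
#' @return Character vector of transcript ids.
#' @export
cat7_only_transcripts <- function(panel, contrast, mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  check_contrast(panel, contrast)
  tx <- panel$loci$transcript_id
  all_tx <- unique(tx)
  in_all_a <- rep(TRUE, length(all_tx))
  for (s in contrast$group_a) {
    cl <- classify_sample(panel, s, mode)
    has7 <- all_tx %in% unique(tx[cl$category == 7L])
    in_all_a <- in_all_a & has7
  }
  in_no_b <- rep(TRUE, length(all_tx))
  for (s in contrast$group_b) {
    cl <- classify_sample(panel, s, mode)
    has7 <- all_tx %in% unique(tx[cl$category == 7L])
    in_no_b <- in_no_b & !has7
  }
  sort(all_tx[in_all_a & in_no_b])
}

#' Map track of introgressed ("out") alleles for a contrast
#'
#' Counts, per placed map position, the SNPs in the out-carrying
#' categories (6--10) and in category 7 alone, restricted to loci
#' polymorphic between the contrast groups. Counts are reported per
#' cultivar of the contrast and pooled (summed) per group.
#'
#' @param panel A [genotype_panel()].
#' @param contrast A [group_contrast()].
#' @param placements Output of [place_transcripts()].
#' @inheritParams classify_locus
#' @return Tibble of class `introgression_track`: `track` (sample id,
#'   `"group_A"` or `"group_B"`), `linkage_group`, `cM`, `n_out_snps`,
#'   `n_cat7_snps`.
#' @export
introgression_track <- function(panel, contrast, placements,
                                mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  check_contrast(panel, contrast)
  poly <- between_group_polymorphic(panel, contrast)
  ids <- c(contrast$group_a, contrast$group_b)
  grp <- c(rep("group_A", length(contrast$group_a)), rep("group_B", length(contrast$group_b)))
  per_sample <- purrr::map2_dfr(ids, grp, function(s, g) {
    cl <- classify_sample(panel, s, mode)
    is_out <- poly & cl$category %in% OUT_CATEGORIES
    is_cat7 <- poly & cl$category == 7L
    snp <- tibble(transcript = panel$loci$transcript_id,
                  out = is_out, cat7 = is_cat7)
    joined <- dplyr::inner_join(as_tibble(placements), snp, by = "transcript",
                                relationship = "many-to-many")
    dplyr::summarise(dplyr::group_by(joined, .data$linkage_group, .data$cM),
                     n_out_snps = sum(.data$out), n_cat7_snps = sum(.data$cat7),
                     .groups = "drop") |>
      dplyr::mutate(track = s, group = g, .before = 1L)
  })
  pooled <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$group, .data$linkage_group, .data$cM),
    n_out_snps = sum(.data$n_out_snps), n_cat7_snps = sum(.data$n_cat7_snps),
    .groups = "drop"
  )
  pooled$track <- pooled$group
  out <- dplyr::bind_rows(per_sample, pooled)
  out <- out[, c("track", "group", "linkage_group", "cM", "n_out_snps", "n_cat7_snps")]
  out <- dplyr::arrange(out, .data$track, .data$linkage_group, .data$cM)
  class(out) <- c("introgression_track", class(out))
  out
}

#' @exportS3Method
autoplot.introgression_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cM, .data$n_out_snps)) +
    ggplot2::geom_col(width = 0.8, fill = "grey40") +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_cat7_snps), width = 0.8, fill = "firebrick") +
    ggplot2::facet_grid(track ~ linkage_group, scales = "free", space = "free_x") +
    ggplot2::labs(y = "out-category SNPs (red: category 7)") +
    ggplot2::theme_minimal()
}
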