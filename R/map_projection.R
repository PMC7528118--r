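#' Per-category similarity rates with the reference-species progenitor
#'
#' The fraction of allele copies identical to progenitor A implied by each
#' origin category: fully progenitor-A categories score 1, heterozygotes
#' carrying one progenitor-A (or shared) allele score 0.5, categories with
#' no progenitor-A allele score 0. UNKNOWN and MISSING are excluded
#' (`NA`): loci in those categories never enter a similarity mean.
#'
#' @return Named numeric vector of length 12 (index = category).
#' @export
similarity_rates <- function() {
  c(AX_HOM = 1, INT_HOM = 0, SHARED_HOM = 1, AX_INT_HET = 0.5,
    SHARED_HET = 0.5, AX_OUT_HET = 0.5, SHARED_OUT_HET = 0.5,
    INT_OUT_HET = 0, OUT_HOM = 0, OUT_OUT_HET = 0,
    UNKNOWN = NA_real_, MISSING = NA_real_)
}

#' Mean progenitor-A similarity of one transcript for one sample
#'
#' Assigns every classifiable SNP on the transcript its category
#' similarity rate and averages them.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Sample to score.
#' @param transcript_id Transcript.
#' @param rates Per-category rate vector, see [similarity_rates()].
#' @inheritParams classify_locus
#' @return A fraction in \[0, 1\], or `NA` when the transcript has no
#'   classifiable SNP for the sample.
#' @export
transcript_similarity <- function(panel, sample_id, transcript_id,
                                  rates = similarity_rates(),
                                  mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  idx <- panel$loci$transcript_id == transcript_id
  if (!any(idx)) abort(paste0("unknown transcript: ", transcript_id))
  sub <- subset_loci(panel, idx)
  cl <- classify_sample(sub, sample_id, mode)
  mean(rates[cl$category], na.rm = TRUE)
}

#' Place transcripts onto a linkage map
#'
#' A transcript is placed at every map marker whose (scaffold,
#' scaffold_pos) falls within one of the transcript's genomic anchors.
#' Placements on the same linkage group are merged by single-linkage
#' clustering at `merge_radius_cM` (merged position = unweighted mean cM of
#' the contributing markers); placements farther apart are all retained.
#'
#' @param map A [linkage_map()].
#' @param anchors Transcript-anchor tibble, see [read_transcript_anchors()].
#' @param merge_radius_cM Merge radius in centimorgans. Default 1.0.
#' @return Tibble with one row per placement: `transcript`,
#'   `linkage_group`, `cM`, `n_markers`, `markers` (comma-joined ids).
#' @export
place_transcripts <- function(map, anchors, merge_radius_cM = 1.0) {
  hits <- dplyr::inner_join(as_tibble(anchors), as_tibble(map),
                            by = "scaffold", relationship = "many-to-many")
  hits <- hits[hits$scaffold_pos >= hits$start & hits$scaffold_pos <= hits$end, ]
  if (nrow(hits) == 0L) {
    return(tibble(transcript = character(), linkage_group = character(),
                  cM = double(), n_markers = integer(), markers = character()))
  }
  hits <- dplyr::arrange(hits, .data$transcript, .data$linkage_group, .data$cM)
  grp <- dplyr::group_by(hits, .data$transcript, .data$linkage_group)
  placed <- dplyr::reframe(grp, {
    # single-linkage chaining in 1D: break where the gap exceeds the radius
    cm <- .data$cM
    mk <- .data$marker
    cluster <- cumsum(c(1, diff(cm) > merge_radius_cM))
    tibble(
      cM = as.vector(tapply(cm, cluster, mean)),
      n_markers = as.vector(tapply(cm, cluster, length)),
      markers = as.vector(tapply(mk, cluster, paste, collapse = ","))
    )
  })
  placed$n_markers <- as.integer(placed$n_markers)
  dplyr::arrange(placed, .data$transcript, .data$linkage_group, .data$cM)
}

#' Low-recombination intervals of a linkage map
#'
#' Flags map stretches where few markers span a long genetic distance, the
#' regions on which similarity is not reported to avoid biased estimates.
#' An interval between consecutive mapped markers is masked when it is
#' longer than `gap_cM` and fewer than `min_markers` markers lie strictly
#' inside it (with consecutive markers that count is always 0, so the gap
#' criterion drives the default rule).
#'
#' @param map A [linkage_map()].
#' @param gap_cM Gap threshold in cM. Default 5.
#' @param min_markers Intervening-marker threshold. Default 2.
#' @return Tibble `linkage_group`, `start_cM`, `end_cM` of masked (open)
#'   intervals.
#' @export
low_recombination_mask <- function(map, gap_cM = 5, min_markers = 2L) {
  df <- dplyr::arrange(as_tibble(map), .data$linkage_group, .data$cM)
  out <- dplyr::reframe(dplyr::group_by(df, .data$linkage_group), {
    cm <- sort(unique(.data[["cM"]]))
    if (length(cm) < 2L) {
      tibble(start_cM = double(), end_cM = double())
    } else {
      gaps <- diff(cm)
      bad <- which(gaps > gap_cM & 0L < min_markers)
      tibble(start_cM = cm[bad], end_cM = cm[bad + 1L])
    }
  })
  out
}

in_masked_interval <- function(linkage_group, cM, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(cM)))
  vapply(seq_along(cM), function(i) {
    m <- mask[mask$linkage_group == linkage_group[i], ]
    any(cM[i] > m$start_cM & cM[i] < m$end_cM)
  }, logical(1))
}

#' Progenitor-A similarity track along the linkage map
#'
#' Aggregates per-SNP similarity of all SNPs on the transcripts placed at
#' each map position (SNP-weighted, not per-transcript), producing the
#' per-sample rings of a map-wide similarity plot. Positions inside
#' masked low-recombination intervals are omitted, as are positions with
#' no classifiable SNP.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Sample to score (any sample, including the progenitors
#'   themselves).
#' @param placements Output of [place_transcripts()].
#' @param rates Per-category rates, see [similarity_rates()].
#' @param mask Optional masked intervals from [low_recombination_mask()].
#' @inheritParams classify_locus
#' @return Tibble of class `similarity_track`: `sample_id`,
#'   `linkage_group`, `cM`, `similarity`, `n_snps`.
#' @export
similarity_track <- function(panel, sample_id, placements,
                             rates = similarity_rates(), mask = NULL,
                             mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  cl <- classify_sample(panel, sample_id, mode)
  snp <- tibble(transcript = panel$loci$transcript_id,
                rate = rates[cl$category])
  snp <- snp[!is.na(snp$rate), ]
  joined <- dplyr::inner_join(as_tibble(placements), snp, by = "transcript",
                              relationship = "many-to-many")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$linkage_group, .data$cM),
    similarity = mean(.data$rate), n_snps = dplyr::n(), .groups = "drop"
  )
  out <- out[!in_masked_interval(out$linkage_group, out$cM, mask), ]
  out <- tibble(sample_id = sample_id, out)
  out <- dplyr::arrange(out, .data$linkage_group, .data$cM)
  class(out) <- c("similarity_track", class(out))
  out
}

#' @exportS3Method
autoplot.similarity_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cM, .data$similarity)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_snps), alpha = 0.6) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_grid(sample_id ~ linkage_group, scales = "free_x", space = "free_x") +
    ggplot2::scale_size_continuous(range = c(0.3, 2)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "similarity with progenitor A", size = "SNPs") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.category_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample_id, y = .data$proportion,
    fill = stats::reorder(.data$label, .data$index)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of SNPs", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
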