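#' Transcriptome heterozygosity per sample
#'
#' Heterozygosity rate = heterozygous SNP calls / total SNP calls for the
#' sample. By default the denominator is the sample's non-missing calls,
#' which avoids deflating rates for low-coverage samples; set
#' `denominator = "all_loci"` to divide by every locus of the panel
#' instead.
#'
#' @param panel A [genotype_panel()].
#' @param sample_ids Samples to report; defaults to all.
#' @param dataset Label recorded in the output (`"entire"` or
#'   `"no_missing"`); purely descriptive, apply [subset_no_missing()]
#'   beforehand to change the locus set.
#' @param denominator `"non_missing"` (default) or `"all_loci"`.
#' @return Tibble of class `heterozygosity_report`: `sample_id`, `dataset`,
#'   `n_het`, `n_total`, `rate`.
#' @export
heterozygosity <- function(panel, sample_ids = NULL, dataset = "entire",
                           denominator = c("non_missing", "all_loci")) {
  denominator <- match.arg(denominator)
  if (is.null(sample_ids)) sample_ids <- panel$samples$sample_id
  out <- purrr::map_dfr(sample_ids, function(s) {
    calls <- panel_calls(panel, s)
    n_total <- if (denominator == "non_missing") sum(!is.na(calls)) else length(calls)
    if (n_total == 0L) abort(paste0("no called loci for sample ", s))
    tibble(sample_id = s, dataset = dataset,
           n_het = sum(is_het_call(calls)), n_total = n_total,
           rate = sum(is_het_call(calls)) / n_total)
  })
  class(out) <- c("heterozygosity_report", class(out))
  out
}

#' Pairwise SNP-difference matrix
#'
#' For every pair of samples, the number of loci where both have
#' non-missing calls and their unordered allele pairs differ (a
#' homozygote and a heterozygote sharing one allele count as different).
#' With `comparison = "disjoint"`, only pairs of calls with no allele in
#' common are counted (a lenient allele-sharing convention).
#'
#' @param panel A [genotype_panel()].
#' @param comparison `"unequal"` (default) or `"disjoint"`.
#' @return A symmetric integer matrix of class `pairwise_snp_matrix` with
#'   zero diagonal, sample ids as dimnames.
#' @export
pairwise_snp_counts <- function(panel, comparison = c("unequal", "disjoint")) {
  comparison <- match.arg(comparison)
  ids <- panel$samples$sample_id
  if (length(ids) < 2L) abort("pairwise comparison needs at least 2 samples")
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  calls <- panel$calls
  a1 <- call_a1(calls); a2 <- call_a2(calls)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1L), length(ids))) {
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      if (comparison == "unequal") {
        d <- sum(ok & calls[, i] != calls[, j])
      } else {
        share <- a1[, i] == a1[, j] | a1[, i] == a2[, j] |
          a2[, i] == a1[, j] | a2[, i] == a2[, j]
        d <- sum(ok & !share)
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  class(m) <- c("pairwise_snp_matrix", class(m))
  m
}

#' @exportS3Method
tidy.pairwise_snp_matrix <- function(x, ...) {
  m <- unclass(x)
  df <- as_tibble(as.data.frame.table(m, responseName = "n_snps", stringsAsFactors = FALSE))
  names(df)[1:2] <- c("sample_a", "sample_b")
  df[df$sample_a < df$sample_b, ]
}

#' @exportS3Method
autoplot.heterozygosity_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$sample_id, .data$rate), y = .data$rate, fill = .data$dataset
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "heterozygosity rate", fill = "dataset") +
    ggplot2::theme_minimal()
}
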