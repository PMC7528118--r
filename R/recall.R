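#' Genotype re-calling thresholds
#'
#' Threshold rules for re-defining a diploid genotype from per-allele read
#' fractions. With read fraction `f(a) = reads(a) / total reads` at a cell:
#' homozygous-reference is called when `f(ref) >= hom_ref_min`; homozygous
#' for the most-supported alternative allele when `f(alt1) > hom_alt_min`;
#' heterozygous ref/alt1 when both `f(ref) > het_each_min` and
#' `f(alt1) > het_each_min` and `f(ref) + f(alt1) >= het_sum_min`. Cells
#' with total depth below `min_depth` are missing before any rule applies.
#' The mixed strict/non-strict inequalities are deliberate and preserved
#' exactly.
#'
#' @param hom_ref_min Minimum reference-read fraction for a hom-ref call
#'   (inclusive). Default 0.80.
#' @param hom_alt_min Alternative-read fraction above which a hom-alt call
#'   is made (exclusive). Default 0.80.
#' @param het_each_min Fraction each of ref and alt1 must exceed
#'   (exclusive) for a het call. Default 0.30.
#' @param het_sum_min Minimum (inclusive) for the ref+alt1 fraction sum of
#'   a het call. Default 0.80.
#' @param min_depth Minimum total read depth per cell. Default 5.
#' @return A list of class `recall_thresholds`.
#' @export
recall_thresholds <- function(hom_ref_min = 0.80, hom_alt_min = 0.80,
                              het_each_min = 0.30, het_sum_min = 0.80,
                              min_depth = 5L) {
  fr <- c(hom_ref_min, hom_alt_min, het_each_min, het_sum_min)
  if (any(fr < 0 | fr > 1)) abort("threshold fractions must lie in [0, 1]")
  if (min_depth < 1) abort("min_depth must be >= 1")
  structure(list(hom_ref_min = hom_ref_min, hom_alt_min = hom_alt_min,
                 het_each_min = het_each_min, het_sum_min = het_sum_min,
                 min_depth = as.integer(min_depth)),
            class = "recall_thresholds")
}

#' Re-call one genotype from allele read depths
#'
#' @param depths Named integer vector of read counts, names drawn from the
#'   locus' alleles (`ref` first is not required; lookup is by name).
#' @param ref Reference allele of the locus.
#' @param alt Character vector of alternative alleles in record order (ties
#'   in alternative support break toward the earlier-listed allele).
#' @param thresholds A [recall_thresholds()].
#' @return A sorted `"X/Y"` call string, or `NA` when no rule fires or the
#'   cell is below `min_depth`.
#' @export
recall_genotype <- function(depths, ref, alt, thresholds = recall_thresholds()) {
  bad <- setdiff(names(depths), c(ref, alt))
  if (length(bad)) abort(paste0("depth given for allele(s) not in locus: ", paste(bad, collapse = ", ")))
  d <- stats::setNames(rep(0L, 1L + length(alt)), c(ref, alt))
  d[names(depths)] <- as.integer(depths)
  arr <- array(d, dim = c(1L, 1L, length(d)))
  recall_calls(arr, ref, matrix(c(alt, rep(NA, length(d) - 1L - length(alt))), nrow = 1L),
               rep(length(alt), 1L), thresholds)[1L]
}

# vectorized core: depth array (loci x samples x allele slots), per-locus
# ref, alt matrix (loci x max_alt), alt counts
recall_calls <- function(depths, ref, alt_mat, n_alt, thresholds) {
  nl <- dim(depths)[1]; ns <- dim(depths)[2]; k <- dim(depths)[3]
  tot <- apply(depths, c(1, 2), function(v) sum(v, na.rm = TRUE))
  refd <- depths[, , 1, drop = FALSE]; dim(refd) <- c(nl, ns)
  # most-supported alternative allele; ties break to earliest record order
  best_alt_d <- matrix(-1L, nl, ns)
  best_alt <- matrix(NA_character_, nl, ns)
  for (a in seq_len(k - 1L)) {
    da <- depths[, , a + 1L, drop = FALSE]; dim(da) <- c(nl, ns)
    da[is.na(da)] <- -1L
    better <- da > best_alt_d
    best_alt_d[better] <- da[better]
    best_alt[better] <- matrix(alt_mat[, a], nl, ns)[better]
  }
  f_ref <- refd / tot
  f_alt <- best_alt_d / tot
  deep <- tot >= thresholds$min_depth
  aa <- deep & f_ref >= thresholds$hom_ref_min
  bb <- deep & !aa & f_alt > thresholds$hom_alt_min
  ab <- deep & !aa & !bb &
    f_ref > thresholds$het_each_min & f_alt > thresholds$het_each_min &
    (f_ref + f_alt) >= thresholds$het_sum_min
  ref_m <- matrix(ref, nl, ns)
  out <- matrix(NA_character_, nl, ns)
  out[aa] <- paste0(ref_m[aa], "/", ref_m[aa])
  out[bb] <- paste0(best_alt[bb], "/", best_alt[bb])
  out[ab] <- gt_pair(ref_m[ab], best_alt[ab])
  out
}

#' Re-call every genotype of a panel from its allele depths
#'
#' Replaces every call in the panel with the output of the threshold rules
#' applied to that cell's allele depths; the original calls are discarded.
#'
#' @param panel A [genotype_panel()] with depths.
#' @param thresholds A [recall_thresholds()].
#' @return A [genotype_panel()] with re-called genotypes (depths retained).
#' @export
recall_panel <- function(panel, thresholds = recall_thresholds()) {
  if (is.null(panel$depths)) abort("panel lacks allele depths; nothing to re-call")
  alt_list <- strsplit(panel$loci$alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  alt_mat <- matrix(NA_character_, nrow(panel$loci), max(n_alt))
  for (a in seq_len(max(n_alt))) {
    has <- n_alt >= a
    alt_mat[has, a] <- vapply(alt_list[has], `[`, "", a)
  }
  calls <- recall_calls(panel$depths, panel$loci$ref, alt_mat, n_alt, thresholds)
  genotype_panel(panel$loci, panel$samples, calls, panel$depths)
}

#' Keep loci informative about cultivar ancestry
#'
#' Drops loci where no polymorphism is detected between the cultivars and
#' the reference-species progenitor: a locus is kept exactly when at least
#' one cultivar has a non-missing call that differs (as an unordered allele
#' pair) from the `progenitor_a` call. The retained set is the "entire
#' dataset" every downstream stage consumes.
#'
#' @param panel A [genotype_panel()].
#' @return The filtered [genotype_panel()].
#' @export
filter_informative <- function(panel) {
  ax <- role_samples(panel, "progenitor_a")
  cults <- role_samples(panel, "cultivar")
  ax_calls <- panel$calls[, ax]
  keep <- rep(FALSE, n_loci(panel))
  for (s in cults) {
    cc <- panel$calls[, s]
    keep <- keep | (!is.na(cc) & (is.na(ax_calls) | cc != ax_calls))
  }
  subset_loci(panel, keep)
}

#' Keep loci fully called in every sample
#'
#' @param panel A [genotype_panel()].
#' @return A [genotype_panel()] with only loci where no sample is missing
#'   (the "no missing" dataset).
#' @export
subset_no_missing <- function(panel) {
  subset_loci(panel, rowSums(is.na(panel$calls)) == 0L)
}
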