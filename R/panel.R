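#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble is_tibble
NULL

SAMPLE_ROLES <- c("progenitor_a", "progenitor_b", "outgroup_species", "cultivar")
HABITS <- c("trailing", "mounded", "mounding_trailing", "upright", "none")

#' Build a sample manifest
#'
#' A sample manifest assigns each sequenced sample a role in the ancestry
#' dissection: exactly one `progenitor_a` (the reference species the panel was
#' called against), exactly one `progenitor_b` (the second progenitor), any
#' number of `outgroup_species` samples, and the `cultivar` samples whose
#' genomes are dissected. Cultivars additionally carry a growth-habit label
#' used by the phenotype-contrast analyses.
#'
#' @param df Data frame with columns `sample_id`, `role` and optionally
#'   `habit`. Roles must be one of `progenitor_a`, `progenitor_b`,
#'   `outgroup_species`, `cultivar`; habits one of `trailing`, `mounded`,
#'   `mounding_trailing`, `upright`, `none`.
#' @return A tibble of class `sample_manifest` with columns `sample_id`,
#'   `role`, `habit`. Non-cultivar samples always have habit `"none"`.
#' @export
sample_manifest <- function(df) {
  df <- as_tibble(df)
  if (!all(c("sample_id", "role") %in% names(df))) {
    abort("manifest needs `sample_id` and `role` columns")
  }
  if (!"habit" %in% names(df)) df$habit <- NA_character_
  df$habit[is.na(df$habit) | df$habit == ""] <- "none"
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in manifest")
  bad <- setdiff(unique(df$role), SAMPLE_ROLES)
  if (length(bad)) abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$habit), HABITS)
  if (length(bad)) abort(paste0("unknown habit(s): ", paste(bad, collapse = ", ")))
  if (sum(df$role == "progenitor_a") != 1L) abort("manifest must contain exactly one progenitor_a")
  if (sum(df$role == "progenitor_b") != 1L) abort("manifest must contain exactly one progenitor_b")
  if (any(df$role != "cultivar" & df$habit != "none")) {
    abort("habit labels are only meaningful for cultivars (use `none` otherwise)")
  }
  out <- df[, c("sample_id", "role", "habit")]
  class(out) <- c("sample_manifest", class(out))
  out
}

#' Read a sample manifest from TSV
#'
#' @param path Path to a tab-separated file with header columns `sample_id`,
#'   `role` and optionally `habit`.
#' @return A [sample_manifest()] tibble.
#' @export
read_sample_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  sample_manifest(df)
}

#' Construct a genotype panel
#'
#' The central container of the pipeline: SNP loci (rows) by samples
#' (columns) with one diploid genotype call per cell, optional per-allele
#' read depths, and the sample manifest. Calls are stored as `"X/Y"` strings
#' with the two single-nucleotide alleles in sorted order (the pair is
#' unordered); missing calls are `NA`.
#'
#' @param loci Tibble with columns `transcript_id`, `pos` (1-based position
#'   within the transcript), `ref` (single-nucleotide reference allele) and
#'   `alt` (comma-separated ordered alternative alleles as in a VCF record;
#'   multiallelic records are kept as single loci). Optional `scaffold`,
#'   `scaffold_pos` genomic anchors.
#' @param samples A [sample_manifest()] (or coercible data frame).
#' @param calls Character matrix, `nrow(loci)` x `nrow(samples)`, of sorted
#'   `"X/Y"` genotype strings or `NA`.
#' @param depths Optional integer array `loci x samples x alleles` of read
#'   counts, allele slot order `ref, alt1, alt2, ...`, `NA` beyond the locus'
#'   allele count.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(loci, samples, calls, depths = NULL) {
  loci <- as_tibble(loci)
  if (!inherits(samples, "sample_manifest")) samples <- sample_manifest(samples)
  for (col in c("transcript_id", "pos", "ref", "alt")) {
    if (!col %in% names(loci)) abort(paste0("loci lacks column `", col, "`"))
  }
  if (anyDuplicated(paste(loci$transcript_id, loci$pos))) {
    abort("duplicate locus: (transcript_id, pos) must be unique within a panel")
  }
  if (any(nchar(loci$ref) != 1L)) abort("ref alleles must be single nucleotides (SNP loci only)")
  alt_list <- strsplit(loci$alt, ",", fixed = TRUE)
  if (any(lengths(alt_list) == 0L)) abort("every locus needs a non-empty alt list")
  if (any(vapply(alt_list, anyDuplicated, 0L) > 0L)) abort("duplicate alt allele at a locus")
  if (any(mapply(function(r, a) r %in% a, loci$ref, alt_list))) {
    abort("alt alleles must be disjoint from the ref allele")
  }
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(loci) || ncol(calls) != nrow(samples)) {
    abort("calls matrix dimensions must match loci x samples")
  }
  dimnames(calls) <- list(NULL, samples$sample_id)
  if (!is.null(depths)) {
    if (length(dim(depths)) != 3L || dim(depths)[1] != nrow(loci) || dim(depths)[2] != nrow(samples)) {
      abort("depths must be a loci x samples x alleles array")
    }
    dimnames(depths) <- list(NULL, samples$sample_id, NULL)
  }
  structure(
    list(loci = loci, samples = samples, calls = calls, depths = depths),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d loci x %d samples (%s depths)\n",
    nrow(x$loci), nrow(x$samples), if (is.null(x$depths)) "no" else "with"
  ))
  roles <- table(x$samples$role)
  cat("  samples:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$loci), nrow(x$samples))

n_loci <- function(panel) nrow(panel$loci)

#' Sample ids holding a given role
#' @param panel A [genotype_panel()].
#' @param role One of `progenitor_a`, `progenitor_b`, `outgroup_species`, `cultivar`.
#' @return Character vector of sample ids (length 1 for progenitor roles).
#' @export
role_samples <- function(panel, role) {
  panel$samples$sample_id[panel$samples$role == role]
}

panel_calls <- function(panel, sample_id) {
  if (!sample_id %in% colnames(panel$calls)) {
    abort(paste0("unknown sample: ", sample_id))
  }
  panel$calls[, sample_id]
}

#' Subset a panel to a set of locus rows
#' @param panel A [genotype_panel()].
#' @param idx Logical or integer index over loci.
#' @return A [genotype_panel()] restricted to those loci.
#' @export
subset_loci <- function(panel, idx) {
  depths <- if (is.null(panel$depths)) NULL else panel$depths[idx, , , drop = FALSE]
  genotype_panel(panel$loci[idx, ], panel$samples, panel$calls[idx, , drop = FALSE], depths)
}

# sorted unordered diploid pair as a call string
gt_pair <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  out <- paste0(lo, "/", hi)
  out[is.na(a) | is.na(b)] <- NA_character_
  out
}

call_a1 <- function(calls) substr(calls, 1L, 1L)
call_a2 <- function(calls) substr(calls, 3L, 3L)
is_het_call <- function(calls) !is.na(calls) & call_a1(calls) != call_a2(calls)

#' @exportS3Method
tidy.genotype_panel <- function(x, ...) {
  long <- as_tibble(x$calls)
  long$transcript_id <- x$loci$transcript_id
  long$pos <- x$loci$pos
  out <- tidyr::pivot_longer(long, cols = -c("transcript_id", "pos"),
                             names_to = "sample_id", values_to = "call")
  dplyr::left_join(out, as_tibble(x$samples), by = "sample_id")
}

#' @exportS3Method
glance.genotype_panel <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci),
    n_samples = nrow(x$samples),
    n_cultivars = sum(x$samples$role == "cultivar"),
    n_transcripts = dplyr::n_distinct(x$loci$transcript_id),
    has_depths = !is.null(x$depths),
    missing_rate = mean(is.na(x$calls))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
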