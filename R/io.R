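#' Read a multi-sample VCF and manifest into a genotype panel
#'
#' Parses GT (and, when present, AD) fields from a VCF 4.x file called
#' against a transcriptome reference. `CHROM` is interpreted as the
#' transcript id and `POS` as the 1-based position within the transcript.
#' Multiallelic records are kept as single loci with the alt alleles in
#' record order; indel records (any allele longer than one base) are
#' rejected since the pipeline is SNP-only.
#'
#' @param vcf_path Path to the VCF (plain text or gzipped).
#' @param manifest_path Path to the sample-manifest TSV, or a
#'   [sample_manifest()] object. Every sample column of the VCF must appear
#'   in the manifest and vice versa; the panel's sample order is the
#'   manifest order, independent of VCF column order.
#' @return A [genotype_panel()]; `depths` is populated when the VCF carries
#'   per-sample AD fields.
#' @export
read_panel <- function(vcf_path, manifest_path) {
  manifest <- if (inherits(manifest_path, "sample_manifest")) manifest_path else read_sample_manifest(manifest_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_in_manifest <- setdiff(vcf_samples, manifest$sample_id)
  if (length(missing_in_manifest)) {
    abort(paste0("VCF sample(s) absent from manifest: ", paste(missing_in_manifest, collapse = ", ")))
  }
  unknown <- setdiff(manifest$sample_id, vcf_samples)
  if (length(unknown)) {
    abort(paste0("manifest sample(s) unknown to the VCF: ", paste(unknown, collapse = ", ")))
  }
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  if (anyDuplicated(key)) abort("duplicate locus: identical (CHROM, POS) records in VCF")

  loci <- tibble(
    transcript_id = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )
  if (any(nchar(loci$ref) != 1L) || any(nchar(gsub(",", "", loci$alt)) != lengths(strsplit(loci$alt, ",")))) {
    abort("non-SNP record in VCF (alleles must be single nucleotides)")
  }
  alleles <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                    loci$ref, loci$alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, manifest$sample_id, drop = FALSE]
  calls <- gt_codes_to_calls(gt, alleles)

  depths <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)AD(:|$)", fmt))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    ad <- ad[, manifest$sample_id, drop = FALSE]
    depths <- ad_strings_to_array(ad, lengths(alleles))
  }
  genotype_panel(loci, manifest, calls, depths)
}

# "i/j" (or phased "i|j") index codes -> sorted allele-character calls
gt_codes_to_calls <- function(gt, alleles) {
  n <- nrow(gt)
  out <- matrix(NA_character_, n, ncol(gt))
  for (j in seq_len(ncol(gt))) {
    codes <- gsub("|", "/", gt[, j], fixed = TRUE)
    parts <- strsplit(codes, "/", fixed = TRUE)
    ok <- !is.na(codes) & lengths(parts) == 2L
    i1 <- rep(NA_integer_, n); i2 <- rep(NA_integer_, n)
    i1[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 1L))) + 1L
    i2[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 2L))) + 1L
    a1 <- rep(NA_character_, n); a2 <- rep(NA_character_, n)
    idx <- which(!is.na(i1) & !is.na(i2))
    a1[idx] <- mapply(function(al, i) al[i], alleles[idx], i1[idx])
    a2[idx] <- mapply(function(al, i) al[i], alleles[idx], i2[idx])
    out[, j] <- gt_pair(a1, a2)
  }
  out
}

# "r,a1,a2" AD strings -> loci x samples x alleles integer array
ad_strings_to_array <- function(ad, n_alleles) {
  n <- nrow(ad); m <- ncol(ad); k <- max(n_alleles)
  arr <- array(NA_integer_, dim = c(n, m, k))
  for (j in seq_len(m)) {
    parts <- strsplit(ad[, j], ",", fixed = TRUE)
    for (i in which(!is.na(ad[, j]))) {
      v <- suppressWarnings(as.integer(parts[[i]]))
      v[is.na(v)] <- 0L
      arr[i, j, seq_len(min(length(v), n_alleles[i]))] <- v[seq_len(min(length(v), n_alleles[i]))]
    }
    # unobserved slots within the locus' allele count are zero depth
    for (a in seq_len(k)) {
      blank <- is.na(arr[, j, a]) & n_alleles >= a
      arr[blank, j, a] <- 0L
    }
  }
  arr
}

#' Write a genotype panel to a VCF file
#'
#' Emits an uncompressed, deterministically formatted VCF 4.2 with GT (and
#' AD when the panel has depths) so that a written panel re-read with
#' [read_panel()] round-trips calls and depths exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  loci <- panel$loci
  alleles <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                    loci$ref, loci$alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  has_ad <- !is.null(panel$depths)
  fmt <- if (has_ad) "GT:AD" else "GT"
  n <- nrow(loci)
  body <- character(n)
  sample_cols <- matrix("", n, nrow(panel$samples))
  for (j in seq_len(ncol(panel$calls))) {
    calls <- panel$calls[, j]
    a1 <- call_a1(calls); a2 <- call_a2(calls)
    gt <- rep("./.", n)
    idx <- which(!is.na(calls))
    if (length(idx)) {
      codes <- vapply(idx, function(i) {
        k <- sort(c(match(a1[i], alleles[[i]]), match(a2[i], alleles[[i]]))) - 1L
        if (anyNA(k)) abort(paste0("call allele not in locus definition at row ", i))
        paste0(k[1], "/", k[2])
      }, "")
      gt[idx] <- codes
    }
    if (has_ad) {
      ad <- vapply(seq_len(n), function(i) {
        v <- panel$depths[i, j, seq_along(alleles[[i]])]
        if (anyNA(v)) "." else paste(v, collapse = ",")
      }, "")
      sample_cols[, j] <- paste0(gt, ":", ad)
    } else {
      sample_cols[, j] <- gt
    }
  }
  fixed <- paste(loci$transcript_id, loci$pos, ".", loci$ref, loci$alt, ".", "PASS", ".", fmt, sep = "\t")
  body <- paste(fixed, apply(sample_cols, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybrisect",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            panel$samples$sample_id), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genetic linkage map from TSV
#'
#' @param path TSV with header columns `marker`, `linkage_group`, `cM`,
#'   `scaffold`, `scaffold_pos`.
#' @return A tibble of class `linkage_map`, markers sorted by
#'   (`linkage_group`, `cM`).
#' @export
read_linkage_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), linkage_group = readr::col_character(),
    cM = readr::col_double(), scaffold = readr::col_character(),
    scaffold_pos = readr::col_double()
  ))
  linkage_map(df)
}

#' Validate and sort a linkage-map table
#' @param df Data frame with `marker`, `linkage_group`, `cM`, `scaffold`,
#'   `scaffold_pos` columns.
#' @return Tibble of class `linkage_map` sorted by (`linkage_group`, `cM`).
#' @export
linkage_map <- function(df) {
  df <- as_tibble(df)
  need <- c("marker", "linkage_group", "cM", "scaffold", "scaffold_pos")
  if (!all(need %in% names(df))) abort("linkage map needs columns marker, linkage_group, cM, scaffold, scaffold_pos")
  if (any(df$cM < 0, na.rm = TRUE)) abort("negative cM in linkage map")
  if (anyDuplicated(df$marker)) abort("duplicate marker names in linkage map")
  out <- dplyr::arrange(df[, need], .data$linkage_group, .data$cM)
  class(out) <- c("linkage_map", class(out))
  out
}

#' Read transcript genomic anchors
#'
#' Anchors place transcripts on reference scaffolds so map markers falling
#' inside a transcript can position it on the linkage map. Accepts either a
#' TSV with header `transcript`, `scaffold`, `start`, `end` (1-based
#' inclusive) or a GFF3 file (the transcript id is taken from the `ID=`
#' attribute). A transcript may have several anchors, including on
#' different scaffolds; all are retained.
#'
#' @param path Input path.
#' @return Tibble with columns `transcript`, `scaffold`, `start`, `end`.
#' @export
read_transcript_anchors <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff")) {
    df <- readr::read_tsv(path, comment = "#", col_names = c(
      "scaffold", "source", "type", "start", "end", "score", "strand", "phase", "attributes"
    ), col_types = readr::cols(.default = readr::col_character(),
                               start = readr::col_double(), end = readr::col_double()))
    df$transcript <- sub(".*ID=([^;]+).*", "\\1", df$attributes)
    df <- df[, c("transcript", "scaffold", "start", "end")]
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(
      transcript = readr::col_character(), scaffold = readr::col_character(),
      start = readr::col_double(), end = readr::col_double()
    ))
  }
  transcript_anchors(df)
}

#' Validate a transcript-anchor table
#' @param df Data frame with `transcript`, `scaffold`, `start`, `end`.
#' @return Validated tibble.
#' @export
transcript_anchors <- function(df) {
  df <- as_tibble(df)[, c("transcript", "scaffold", "start", "end")]
  if (any(df$start > df$end)) abort("anchor with start > end")
  if (any(df$start < 1)) abort("anchors are 1-based: start must be >= 1")
  df
}

#' Write a tibble as a deterministic TSV
#' @param df Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
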