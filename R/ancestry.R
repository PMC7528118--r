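#' The 12-way progenitor-origin genotype taxonomy
#'
#' Every cultivar diploid call at a SNP locus is assigned, given the two
#' progenitor calls at that locus, to one of twelve categories describing
#' the origin of its two allele copies: derived from the reference-species
#' progenitor (`ax`), from the second progenitor (`int`), shared between
#' the progenitors, or novel ("out", interpreted as introgression from a
#' third species or an unsampled progenitor genotype). Category 7 is the
#' heterozygote with one allele equal to the progenitors' common allele and
#' one novel allele; the out-carrying categories are exactly 6--10.
#'
#' @return A tibble with columns `index` (1--12), `label`, `description`.
#' @export
genotype_categories <- function() {
  tibble(
    index = 1:12,
    label = c("AX_HOM", "INT_HOM", "SHARED_HOM", "AX_INT_HET", "SHARED_HET",
              "AX_OUT_HET", "SHARED_OUT_HET", "INT_OUT_HET", "OUT_HOM",
              "OUT_OUT_HET", "UNKNOWN", "MISSING"),
    description = c(
      "homozygous, progenitor-A allele",
      "homozygous, progenitor-B allele",
      "homozygous, allele shared by both progenitors",
      "heterozygous progenitor-A / progenitor-B",
      "heterozygous, equal to the progenitors' common heterozygous genotype",
      "heterozygous progenitor-A / out",
      "heterozygous shared / out",
      "heterozygous progenitor-B / out",
      "homozygous out",
      "heterozygous out1 / out2",
      "origin undetermined (progenitor call missing or ambiguous)",
      "cultivar call missing"
    )
  )
}

OUT_CATEGORIES <- 6:10

#' Classify one cultivar call by progenitor origin
#'
#' @param ax Progenitor-A call (`"X/Y"` string or `NA`).
#' @param int Progenitor-B call.
#' @param cultivar Cultivar call.
#' @param mode `"strict"` (default) treats any heterozygous progenitor call
#'   at a progenitor-polymorphic locus as uninterpretable (category 11,
#'   UNKNOWN), matching the assumption that the progenitors are homozygous;
#'   `"containment"` classifies each allele copy by membership in the
#'   progenitors' allele sets.
#' @return Integer category index 1--12; see [genotype_categories()].
#' @export
classify_locus <- function(ax, int, cultivar, mode = c("strict", "containment")) {
  classify_calls(ax, int, cultivar, match.arg(mode))[1L]
}

# vectorized classifier over parallel call vectors
classify_calls <- function(ax, int, cult, mode = "strict") {
  n <- length(cult)
  ax1 <- call_a1(ax); ax2 <- call_a2(ax)
  in1 <- call_a1(int); in2 <- call_a2(int)
  c1 <- call_a1(cult); c2 <- call_a2(cult)

  out <- integer(n)
  unknown <- is.na(ax) | is.na(int)
  sets_equal <- !unknown & ax == int   # calls stored sorted, so set equality = string equality
  if (mode == "strict") {
    het_prog <- (!is.na(ax) & ax1 != ax2) | (!is.na(int) & in1 != in2)
    unknown <- unknown | (!unknown & !sets_equal & het_prog)
  }
  missing <- !unknown & is.na(cult)
  live <- !unknown & !missing

  in_a <- function(x) live & (x == ax1 | x == ax2)
  in_b <- function(x) live & (x == in1 | x == in2)
  a1A <- in_a(c1); a1B <- in_b(c1)
  a2A <- in_a(c2); a2B <- in_b(c2)
  # per-copy origin: 1 ax-only, 2 int-only, 3 shared, 4 out
  orig <- function(inA, inB) ifelse(inA & inB, 3L, ifelse(inA, 1L, ifelse(inB, 2L, 4L)))
  o1 <- orig(a1A, a1B); o2 <- orig(a2A, a2B)
  hom <- live & c1 == c2

  res <- rep(NA_integer_, n)
  res[unknown] <- 11L
  res[missing] <- 12L
  # homozygotes: single copy origin decides
  res[hom & o1 == 1L] <- 1L
  res[hom & o1 == 2L] <- 2L
  res[hom & o1 == 3L] <- 3L
  res[hom & o1 == 4L] <- 9L
  # heterozygotes by unordered origin pair
  het <- live & !hom
  lo <- pmin(o1, o2); hi <- pmax(o1, o2)
  res[het & lo == 4L] <- 10L                 # out / out
  res[het & lo == 1L & hi == 4L] <- 6L       # ax / out
  res[het & lo == 2L & hi == 4L] <- 8L       # int / out
  res[het & lo == 3L & hi == 4L] <- 7L       # shared / out
  res[het & lo == 1L & hi == 2L] <- 4L       # ax / int
  res[het & lo == 3L & hi == 3L] <- 5L       # both copies shared
  # containment-mode leftovers: het pair wholly consistent with one progenitor
  left <- het & is.na(res)
  res[left & a1A & a2A] <- 1L
  left <- het & is.na(res)
  res[left & a1B & a2B] <- 2L
  res
}

# categories for one sample over all loci, plus progenitor-polymorphic flag
classify_sample <- function(panel, sample_id, mode = "strict") {
  ax <- panel$calls[, role_samples(panel, "progenitor_a")]
  int <- panel$calls[, role_samples(panel, "progenitor_b")]
  cult <- panel_calls(panel, sample_id)
  cat <- classify_calls(ax, int, cult, mode)
  poly <- !is.na(ax) & !is.na(int) & ax != int
  list(category = cat, progenitor_polymorphic = poly)
}

#' Per-locus origin categories for a set of samples
#'
#' @param panel A [genotype_panel()].
#' @param sample_ids Samples to classify; defaults to all non-progenitor
#'   samples.
#' @inheritParams classify_locus
#' @return A tibble with one row per locus x sample: `transcript_id`,
#'   `pos`, `sample_id`, `category` (1--12), `label`,
#'   `progenitor_polymorphic`.
#' @export
classify_panel <- function(panel, sample_ids = NULL, mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  if (is.null(sample_ids)) {
    sample_ids <- panel$samples$sample_id[!panel$samples$role %in% c("progenitor_a", "progenitor_b")]
  }
  labels <- genotype_categories()$label
  purrr::map_dfr(sample_ids, function(s) {
    cl <- classify_sample(panel, s, mode)
    tibble(
      transcript_id = panel$loci$transcript_id, pos = panel$loci$pos,
      sample_id = s, category = cl$category, label = labels[cl$category],
      progenitor_polymorphic = cl$progenitor_polymorphic
    )
  })
}

#' Category proportions for one sample
#'
#' Fraction of the panel's loci falling in each of the 12 origin
#' categories. UNKNOWN and MISSING are categories in their own right, so
#' the proportions always sum to 1 over the active dataset.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id A cultivar (or outgroup) sample; progenitor samples are
#'   rejected since their categories are self-referential.
#' @inheritParams classify_locus
#' @return Tibble of class `category_profile`: `sample_id`, `index`,
#'   `label`, `n`, `proportion` (12 rows).
#' @export
category_profile <- function(panel, sample_id, mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  role <- panel$samples$role[panel$samples$sample_id == sample_id]
  if (length(role) == 0L) abort(paste0("unknown sample: ", sample_id))
  if (role %in% c("progenitor_a", "progenitor_b")) {
    abort("category profiles are defined for non-progenitor samples")
  }
  cl <- classify_sample(panel, sample_id, mode)
  counts <- tabulate(cl$category, nbins = 12L)
  out <- genotype_categories()[, c("index", "label")]
  out$sample_id <- sample_id
  out$n <- counts
  out$proportion <- counts / n_loci(panel)
  out <- out[, c("sample_id", "index", "label", "n", "proportion")]
  class(out) <- c("category_profile", class(out))
  out
}

new_ancestry_estimate <- function(df) {
  class(df) <- c("ancestry_estimate", class(df))
  df
}

#' Allele-origin proportions by category counting (approach 1)
#'
#' Counts allele copies implied by the origin categories. Each classified
#' locus contributes two copies: homozygous categories contribute both
#' copies to one origin, heterozygous categories one copy to each side
#' (so heterozygous progenitor-origin and out SNPs carry half the weight
#' of their homozygous counterparts). UNKNOWN/MISSING loci are excluded
#' from the denominator and reported as a count.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Cultivar sample.
#' @inheritParams classify_locus
#' @return Tibble of class `ancestry_estimate` with `sample_id`, `model`,
#'   the five copy proportions `p_ax`, `p_int`, `p_shared`, `p_out`,
#'   `p_unknown` (summing to 1), the progenitor-polymorphic-denominator
#'   rates `p_ax_poly`, `p_int_poly` (copies over 2 x classified
#'   progenitor-polymorphic loci), `p_out_overall`, and the locus counts
#'   `n_classified`, `n_polymorphic`, `n_unknown`.
#' @export
allele_proportions_approach1 <- function(panel, sample_id, mode = c("strict", "containment")) {
  mode <- match.arg(mode)
  cl <- classify_sample(panel, sample_id, mode)
  counts <- tabulate(cl$category, nbins = 12L)
  poly_counts <- tabulate(cl$category[cl$progenitor_polymorphic], nbins = 12L)
  n_classified <- sum(counts[1:10])
  if (n_classified == 0L) abort("no classified loci for this sample")
  # per-category copy weights: (ax, int, shared, out)
  w <- matrix(c(
    2, 0, 0, 0,  # AX_HOM
    0, 2, 0, 0,  # INT_HOM
    0, 0, 2, 0,  # SHARED_HOM
    1, 1, 0, 0,  # AX_INT_HET
    0, 0, 2, 0,  # SHARED_HET
    1, 0, 0, 1,  # AX_OUT_HET
    0, 0, 1, 1,  # SHARED_OUT_HET
    0, 1, 0, 1,  # INT_OUT_HET
    0, 0, 0, 2,  # OUT_HOM
    0, 0, 0, 2   # OUT_OUT_HET
  ), nrow = 10L, byrow = TRUE)
  copies <- colSums(w * counts[1:10])
  denom <- 2 * n_classified
  n_poly <- sum(poly_counts[1:10])
  poly_copies <- colSums(w * poly_counts[1:10])
  new_ancestry_estimate(tibble(
    sample_id = sample_id, model = "approach1_alleles",
    p_ax = copies[1] / denom, p_int = copies[2] / denom,
    p_shared = copies[3] / denom, p_out = copies[4] / denom,
    p_unknown = 0,
    p_ax_poly = if (n_poly > 0) poly_copies[1] / (2 * n_poly) else NA_real_,
    p_int_poly = if (n_poly > 0) poly_copies[2] / (2 * n_poly) else NA_real_,
    p_out_overall = copies[4] / denom,
    n_classified = n_classified, n_polymorphic = n_poly,
    n_unknown = sum(counts[11:12])
  ))
}

#' Allele-origin proportions under the pure-parents boundary model
#'
#' Assumes hypothetical fully homozygous progenitors with no common allele:
#' progenitor A carries the reference allele (`0/0`) and progenitor B the
#' first alternative allele (`1/1`) at every locus. Cultivar allele copies
#' are then counted directly -- reference copies to `p_ax`, first-alternative
#' copies to `p_int`, any other allele to `p_out` -- independent of the
#' observed progenitor genotype calls. `p_shared` is identically 0;
#' missing cultivar calls contribute two copies to `p_unknown`.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Cultivar sample.
#' @return Tibble of class `ancestry_estimate` (proportions over 2 x all
#'   loci, summing to 1).
#' @export
pure_parents_model <- function(panel, sample_id) {
  cult <- panel_calls(panel, sample_id)
  ref <- panel$loci$ref
  alt1 <- vapply(strsplit(panel$loci$alt, ",", fixed = TRUE), `[`, "", 1L)
  c1 <- call_a1(cult); c2 <- call_a2(cult)
  count_copy <- function(x) {
    ax <- sum(x == ref, na.rm = TRUE)
    int <- sum(x == alt1, na.rm = TRUE)
    other <- sum(!is.na(x) & x != ref & x != alt1)
    c(ax, int, other)
  }
  k <- count_copy(c1) + count_copy(c2)
  n_unknown <- sum(is.na(cult))
  denom <- 2 * n_loci(panel)
  new_ancestry_estimate(tibble(
    sample_id = sample_id, model = "pure_parents",
    p_ax = k[1] / denom, p_int = k[2] / denom, p_shared = 0,
    p_out = k[3] / denom, p_unknown = 2 * n_unknown / denom,
    p_ax_poly = NA_real_, p_int_poly = NA_real_, p_out_overall = k[3] / denom,
    n_classified = n_loci(panel) - n_unknown, n_polymorphic = NA_integer_,
    n_unknown = n_unknown
  ))
}

#' Allele-origin proportions under the exact-parents boundary model
#'
#' Assumes the sequenced progenitor samples (with their observed
#' heterozygosity) are exactly the ancestral genotypes. Each cultivar
#' allele copy is assigned by membership in the progenitors' observed
#' allele sets: in A only -> `p_ax`, in B only -> `p_int`, in both ->
#' `p_shared`, in neither -> `p_out`. Loci with a missing progenitor or
#' cultivar call contribute two copies to `p_unknown`.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Cultivar sample.
#' @return Tibble of class `ancestry_estimate` (proportions over 2 x all
#'   loci, summing to 1).
#' @export
exact_parents_model <- function(panel, sample_id) {
  ax <- panel$calls[, role_samples(panel, "progenitor_a")]
  int <- panel$calls[, role_samples(panel, "progenitor_b")]
  cult <- panel_calls(panel, sample_id)
  unknown <- is.na(ax) | is.na(int) | is.na(cult)
  ax1 <- call_a1(ax); ax2 <- call_a2(ax)
  in1 <- call_a1(int); in2 <- call_a2(int)
  tally <- c(ax = 0L, int = 0L, shared = 0L, out = 0L)
  for (x in list(call_a1(cult), call_a2(cult))) {
    inA <- !unknown & (x == ax1 | x == ax2)
    inB <- !unknown & (x == in1 | x == in2)
    tally <- tally + c(
      sum(inA & !inB, na.rm = TRUE), sum(!inA & inB, na.rm = TRUE),
      sum(inA & inB, na.rm = TRUE), sum(!unknown & !inA & !inB, na.rm = TRUE)
    )
  }
  denom <- 2 * n_loci(panel)
  n_unknown <- sum(unknown)
  new_ancestry_estimate(tibble(
    sample_id = sample_id, model = "exact_parents",
    p_ax = tally[["ax"]] / denom, p_int = tally[["int"]] / denom,
    p_shared = tally[["shared"]] / denom, p_out = tally[["out"]] / denom,
    p_unknown = 2 * n_unknown / denom,
    p_ax_poly = NA_real_, p_int_poly = NA_real_,
    p_out_overall = tally[["out"]] / denom,
    n_classified = n_loci(panel) - n_unknown, n_polymorphic = NA_integer_,
    n_unknown = n_unknown
  ))
}

#' Estimate allele-origin proportions for cultivars
#'
#' Convenience wrapper running one or more ancestry models over a set of
#' cultivar samples.
#'
#' @param panel A [genotype_panel()].
#' @param sample_ids Cultivars; defaults to every cultivar in the manifest.
#' @param models Subset of `"approach1_alleles"`, `"pure_parents"`,
#'   `"exact_parents"`.
#' @return A tibble of class `ancestry_estimate`, one row per sample x
#'   model.
#' @export
estimate_ancestry <- function(panel, sample_ids = NULL,
                              models = c("approach1_alleles", "pure_parents", "exact_parents")) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(sample_ids)) sample_ids <- role_samples(panel, "cultivar")
  fns <- list(
    approach1_alleles = function(s) allele_proportions_approach1(panel, s),
    pure_parents = function(s) pure_parents_model(panel, s),
    exact_parents = function(s) exact_parents_model(panel, s)
  )
  out <- purrr::map_dfr(models, function(m) purrr::map_dfr(sample_ids, fns[[m]]))
  new_ancestry_estimate(out)
}

#' @exportS3Method
tidy.ancestry_estimate <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("sample_id", "model", "p_ax", "p_int", "p_shared", "p_out", "p_unknown")],
    cols = dplyr::starts_with("p_"), names_to = "origin", values_to = "proportion",
    names_prefix = "p_"
  )
}

#' @exportS3Method
glance.ancestry_estimate <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$model),
    n_samples = dplyr::n(),
    mean_p_ax = mean(.data$p_ax), mean_p_int = mean(.data$p_int),
    mean_p_out = mean(.data$p_out), .groups = "drop"
  )
}
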