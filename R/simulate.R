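# run code with a locally seeded Mersenne-Twister stream; the caller's RNG
# state is untouched
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

default_cultivars <- function() {
  tibble(
    id = c("trail_1", "trail_2", "trail_3", "upright_1", "upright_2", "upright_3"),
    habit = c(rep("trailing", 3), rep("upright", 3)),
    p_ax = c(0.45, 0.45, 0.50, 0.70, 0.68, 0.72),
    p_int = c(0.50, 0.50, 0.45, 0.27, 0.29, 0.25),
    p_out = c(0.05, 0.05, 0.05, 0.03, 0.03, 0.03),
    # trailing cultivars are left unconstrained (high heterozygosity);
    # upright cultivars are capped to the low rates typical of that group
    het_target = c(NA, NA, NA, 0.35, 0.35, 0.35)
  )
}

default_hotspots <- function() {
  tibble(
    hotspot_id = paste0("H", 1:5),
    linkage_group = c("LG1", "LG2", "LG3", "LG5", "LG7"),
    cM_start = c(20, 50, 70, 10, 40),
    cM_end = c(30, 60, 80, 20, 50),
    out_multiplier = 10,
    target_habit = "trailing"
  )
}

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the study conditions of a two-progenitor cultivar
#' panel: a low-heterozygosity reference-species progenitor and a highly
#' heterozygous second progenitor (59.3%), six cultivars (three trailing,
#' three upright) whose allele copies are mosaics of progenitor-A,
#' progenitor-B and outgroup origins, and five 10-cM introgression
#' hotspots where the outgroup probability of trailing cultivars is
#' multiplied tenfold.
#'
#' @param n_transcripts Number of transcripts (one synthetic scaffold
#'   each, tiled uniformly over the linkage groups).
#' @param snps_per_transcript_mean Mean SNPs per transcript (>= 1; the
#'   count is 1 + Poisson(mean - 1)).
#' @param het_ax,het_int Per-locus heterozygosity probability of
#'   progenitor A / progenitor B.
#' @param shared_allele_prob Probability that a locus where both
#'   progenitors are homozygous carries the same (reference) allele in
#'   both.
#' @param cultivars Tibble `id`, `habit`, `p_ax`, `p_int`, `p_out`,
#'   `het_target`; origin probabilities must sum to 1 per cultivar.
#'   `het_target` in \[0, 1\] draws the second allele copy independently
#'   with that probability (and duplicates the first otherwise), capping
#'   heterozygosity; `NA` means fully independent copies.
#' @param hotspots Tibble `hotspot_id`, `linkage_group`, `cM_start`,
#'   `cM_end`, `out_multiplier`, `target_habit`; inside a hotspot the
#'   outgroup probability of matching-habit cultivars is multiplied (and
#'   the origin vector renormalized).
#' @param missing_rate Per-cell missing probability (all samples).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean
#'   and dispersion (size) for [simulate_depths()].
#' @param error_rate Per-read miscall probability.
#' @param n_linkage_groups,lg_length_cM Map geometry.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 2000,
                              snps_per_transcript_mean = 3,
                              het_ax = 0.07, het_int = 0.593,
                              shared_allele_prob = 0.35,
                              cultivars = default_cultivars(),
                              hotspots = default_hotspots(),
                              missing_rate = 0.02,
                              depth_mean = 20, depth_dispersion = 5,
                              error_rate = 0.005,
                              n_linkage_groups = 7, lg_length_cM = 100,
                              seed = 1L) {
  cultivars <- as_tibble(cultivars)
  if (!"het_target" %in% names(cultivars)) cultivars$het_target <- NA_real_
  psum <- cultivars$p_ax + cultivars$p_int + cultivars$p_out
  if (any(abs(psum - 1) > 1e-9)) abort("cultivar origin probabilities must sum to 1")
  probs <- c(het_ax, het_int, shared_allele_prob, missing_rate, error_rate,
             cultivars$p_ax, cultivars$p_int, cultivars$p_out)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  hotspots <- as_tibble(hotspots)
  if (nrow(hotspots) > 0L && !"hotspot_id" %in% names(hotspots)) {
    hotspots$hotspot_id <- paste0("H", seq_len(nrow(hotspots)))
  }
  structure(list(
    n_transcripts = n_transcripts, snps_per_transcript_mean = snps_per_transcript_mean,
    het_ax = het_ax, het_int = het_int, shared_allele_prob = shared_allele_prob,
    cultivars = cultivars, hotspots = hotspots, missing_rate = missing_rate,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    error_rate = error_rate, n_linkage_groups = n_linkage_groups,
    lg_length_cM = lg_length_cM, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a genotype panel with ground truth
#'
#' Generates transcripts on synthetic scaffolds tiled over the linkage
#' groups, draws progenitor genotypes per locus (shared or polymorphic,
#' with the configured heterozygosity), then draws every cultivar allele
#' copy's origin from (`p_ax`, `p_int`, `p_out`) -- with `p_out` boosted
#' inside hotspots matching the cultivar's habit -- and the copy's allele
#' from the corresponding progenitor (or outgroup) allele set. Ground
#' truth records both the drawn origin of every copy and its effective
#' origin by progenitor-allele-set membership (a drawn progenitor copy
#' whose allele both progenitors carry is effectively `shared`).
#'
#' @param config A [simulation_config()].
#' @return A list of class `panel_simulation`: `panel`
#'   ([genotype_panel()], calls only), `map` ([linkage_map()]), `anchors`
#'   (transcript anchors), `truth` (class `simulation_truth`: tibbles
#'   `copies`, `loci`, `hotspots`), and `config`.
#' @export
simulate_panel <- function(config = simulation_config()) {
  with_rng(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  nt <- config$n_transcripts
  n_lg <- config$n_linkage_groups
  lg_of_tx <- ((seq_len(nt) - 1L) %% n_lg) + 1L
  per_lg <- ceiling(nt / n_lg)
  slot <- (seq_len(nt) - 1L) %/% n_lg
  cm_of_tx <- (slot + 0.5) / per_lg * config$lg_length_cM
  tx <- tibble(
    transcript_id = sprintf("t%05d", seq_len(nt)),
    scaffold = sprintf("Scf%05d", seq_len(nt)),
    linkage_group = paste0("LG", lg_of_tx),
    cM = cm_of_tx
  )
  anchors <- tibble(transcript = tx$transcript_id, scaffold = tx$scaffold,
                    start = 1, end = 1000)
  map <- linkage_map(tibble(
    marker = sprintf("m%05d", seq_len(nt)),
    linkage_group = tx$linkage_group, cM = tx$cM,
    scaffold = tx$scaffold, scaffold_pos = 500
  ))

  n_snp_tx <- 1L + stats::rpois(nt, max(0, config$snps_per_transcript_mean - 1))
  tx_idx <- rep(seq_len(nt), n_snp_tx)
  nl <- length(tx_idx)
  pos <- unlist(lapply(n_snp_tx, function(k) sort(sample.int(1000L, k))), use.names = FALSE)

  nucs <- c("A", "C", "G", "T")
  perm <- t(vapply(seq_len(nl), function(i) sample(nucs), character(4)))
  ref <- perm[, 1]; int_allele <- perm[, 2]; out1 <- perm[, 3]; out2 <- perm[, 4]

  a_het <- stats::runif(nl) < config$het_ax
  b_het <- stats::runif(nl) < config$het_int
  b_hom_shared <- stats::runif(nl) < config$shared_allele_prob
  # progenitor allele pairs: het = ref + second-progenitor allele (an
  # ancestral shared polymorphism), hom B = ref (shared) or the B allele
  ax1 <- ref; ax2 <- ifelse(a_het, int_allele, ref)
  bx1 <- ifelse(b_het, ref, ifelse(b_hom_shared, ref, int_allele))
  bx2 <- ifelse(b_het, int_allele, bx1)
  ax_call <- gt_pair(ax1, ax2)
  int_call <- gt_pair(bx1, bx2)
  poly <- ax_call != int_call

  cultivars <- config$cultivars
  hs <- config$hotspots
  locus_hotspot <- rep(NA_character_, nl)
  if (nrow(hs) > 0L) {
    lg <- tx$linkage_group[tx_idx]; cm <- tx$cM[tx_idx]
    for (h in seq_len(nrow(hs))) {
      inside <- lg == hs$linkage_group[h] & cm >= hs$cM_start[h] & cm <= hs$cM_end[h]
      locus_hotspot[inside & is.na(locus_hotspot)] <- hs$hotspot_id[h]
    }
  }

  draw_copy <- function(p_ax, p_int, p_out) {
    u <- stats::runif(nl)
    origin <- ifelse(u < p_ax, 1L, ifelse(u < p_ax + p_int, 2L, 3L))
    pick <- stats::runif(nl) < 0.5
    allele <- character(nl)
    allele[origin == 1L] <- ifelse(pick, ax1, ax2)[origin == 1L]
    allele[origin == 2L] <- ifelse(pick, bx1, bx2)[origin == 2L]
    allele[origin == 3L] <- ifelse(pick, out1, out2)[origin == 3L]
    list(origin = origin, allele = allele)
  }

  samples <- sample_manifest(tibble(
    sample_id = c("progenitor_a", "progenitor_b", cultivars$id),
    role = c("progenitor_a", "progenitor_b", rep("cultivar", nrow(cultivars))),
    habit = c("none", "none", cultivars$habit)
  ))
  calls <- matrix(NA_character_, nl, nrow(samples))
  colnames(calls) <- samples$sample_id
  calls[, "progenitor_a"] <- ax_call
  calls[, "progenitor_b"] <- int_call

  origin_levels <- c("ax", "int", "out")
  copies <- vector("list", nrow(cultivars))
  for (ci in seq_len(nrow(cultivars))) {
    cv <- cultivars[ci, ]
    p_ax <- rep(cv$p_ax, nl); p_int <- rep(cv$p_int, nl); p_out <- rep(cv$p_out, nl)
    if (nrow(hs) > 0L) {
      for (h in seq_len(nrow(hs))) {
        if (hs$target_habit[h] != cv$habit) next
        inside <- !is.na(locus_hotspot) & locus_hotspot == hs$hotspot_id[h]
        po <- pmin(0.95, cv$p_out * hs$out_multiplier[h])
        rest <- cv$p_ax + cv$p_int
        p_out[inside] <- po
        p_ax[inside] <- cv$p_ax / rest * (1 - po)
        p_int[inside] <- cv$p_int / rest * (1 - po)
      }
    }
    c1 <- draw_copy(p_ax, p_int, p_out)
    c2 <- draw_copy(p_ax, p_int, p_out)
    if (!is.na(cv$het_target)) {
      dup <- stats::runif(nl) >= cv$het_target
      c2$origin[dup] <- c1$origin[dup]
      c2$allele[dup] <- c1$allele[dup]
    }
    calls[, cv$id] <- gt_pair(c1$allele, c2$allele)
    in_a <- function(x) x == ax1 | x == ax2
    in_b <- function(x) x == bx1 | x == bx2
    eff <- function(allele) ifelse(in_a(allele) & in_b(allele), "shared",
                            ifelse(in_a(allele), "ax",
                            ifelse(in_b(allele), "int", "out")))
    copies[[ci]] <- tibble(
      transcript_id = rep(tx$transcript_id[tx_idx], 2L),
      pos = rep(pos, 2L),
      sample_id = cv$id,
      copy = rep(1:2, each = nl),
      allele = c(c1$allele, c2$allele),
      origin_drawn = origin_levels[c(c1$origin, c2$origin)],
      origin_effective = c(eff(c1$allele), eff(c2$allele))
    )
  }

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(nl * nrow(samples)) < config$missing_rate,
                   nl, nrow(samples))
    calls[drop] <- NA_character_
  }

  # alt list: second-progenitor allele first, then observed outgroup alleles
  a1 <- call_a1(calls); a2 <- call_a2(calls)
  seen <- function(x) rowSums(a1 == x | a2 == x, na.rm = TRUE) > 0
  alt <- int_allele
  o1s <- seen(out1); o2s <- seen(out2)
  alt <- ifelse(o1s, paste0(alt, ",", out1), alt)
  alt <- ifelse(o2s, paste0(alt, ",", out2), alt)

  loci <- tibble(
    transcript_id = tx$transcript_id[tx_idx], pos = pos, ref = ref, alt = alt,
    scaffold = tx$scaffold[tx_idx], scaffold_pos = pos
  )
  truth <- structure(list(
    copies = dplyr::bind_rows(copies),
    loci = tibble(transcript_id = loci$transcript_id, pos = pos,
                  progenitor_polymorphic = poly, hotspot_id = locus_hotspot),
    hotspots = hs
  ), class = "simulation_truth")

  structure(list(
    panel = genotype_panel(loci, samples, calls),
    map = map, anchors = anchors, truth = truth, config = config
  ), class = "panel_simulation")
}

#' Simulate per-allele read depths for a panel
#'
#' Draws a total read depth per cell from a negative binomial
#' (overdispersed, as in RNA-seq coverage), splits reads between the two
#' true alleles by a symmetric binomial, then miscalls each read with
#' probability `error_rate` to one of the locus' other alleles chosen
#' uniformly. Cells with missing true calls get zero depth.
#'
#' @param panel A [genotype_panel()] carrying true calls.
#' @param config A [simulation_config()] (depth and error parameters).
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return The panel with a populated `depths` array.
#' @export
simulate_depths <- function(panel, config = simulation_config(), seed = config$seed + 1L) {
  with_rng(seed, simulate_depths_impl(panel, config))
}

simulate_depths_impl <- function(panel, config) {
  nl <- n_loci(panel); ns <- nrow(panel$samples)
  alt_list <- strsplit(panel$loci$alt, ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alt_list)
  k <- max(n_alleles)
  allele_mat <- matrix(NA_character_, nl, k)
  allele_mat[, 1] <- panel$loci$ref
  for (a in 2:k) {
    has <- n_alleles >= a
    allele_mat[has, a] <- vapply(alt_list[has], `[`, "", a - 1L)
  }
  depths <- array(NA_integer_, dim = c(nl, ns, k))
  for (a in seq_len(k)) depths[, , a][matrix(n_alleles >= a, nl, ns)] <- 0L
  for (j in seq_len(ns)) {
    calls <- panel$calls[, j]
    tot <- stats::rnbinom(nl, mu = config$depth_mean, size = config$depth_dispersion)
    tot[is.na(calls)] <- 0L
    a1 <- call_a1(calls); a2 <- call_a2(calls)
    n1 <- stats::rbinom(nl, tot, 0.5); n1[is.na(n1)] <- 0L
    n2 <- tot - n1; n2[is.na(calls)] <- 0L
    match_slot <- function(x) {
      m <- allele_mat == x
      m[is.na(m)] <- FALSE
      max.col(m, ties.method = "first")
    }
    slot1 <- match_slot(a1); slot2 <- match_slot(a2)
    ok <- !is.na(calls)
    per_slot <- matrix(0L, nl, k)
    idx1 <- cbind(seq_len(nl), slot1)[ok, , drop = FALSE]
    idx2 <- cbind(seq_len(nl), slot2)[ok, , drop = FALSE]
    per_slot[idx1] <- per_slot[idx1] + n1[ok]
    per_slot[idx2] <- per_slot[idx2] + n2[ok]
    if (config$error_rate > 0) {
      for (a in seq_len(k)) {
        src <- per_slot[, a]
        can_err <- src > 0 & n_alleles > 1L & n_alleles >= a
        if (!any(can_err)) next
        n_err <- stats::rbinom(sum(can_err), src[can_err], config$error_rate)
        rows <- which(can_err)
        for (r in seq_along(rows)) {
          if (n_err[r] == 0L) next
          i <- rows[r]
          others <- setdiff(seq_len(n_alleles[i]), a)
          dest <- if (length(others) == 1L) rep(others, n_err[r]) else sample(others, n_err[r], replace = TRUE)
          per_slot[i, a] <- per_slot[i, a] - n_err[r]
          for (d in dest) per_slot[i, d] <- per_slot[i, d] + 1L
        }
      }
    }
    for (a in seq_len(k)) {
      has <- n_alleles >= a
      depths[, j, a][has] <- per_slot[has, a]
    }
  }
  genotype_panel(panel$loci, panel$samples, panel$calls, depths)
}

#' Write simulation ground truth to TSV files
#'
#' @param truth A `simulation_truth` (from [simulate_panel()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    copies = file.path(dir, "truth_copies.tsv"),
    loci = file.path(dir, "truth_loci.tsv"),
    hotspots = file.path(dir, "truth_hotspots.tsv")
  )
  write_tsv_plain(truth$copies, paths[["copies"]])
  write_tsv_plain(truth$loci, paths[["loci"]])
  write_tsv_plain(truth$hotspots, paths[["hotspots"]])
  invisible(paths)
}

#' Read simulation ground truth written by [write_truth()]
#' @param dir Directory holding the truth TSVs.
#' @return A `simulation_truth` list.
#' @export
read_truth <- function(dir) {
  structure(list(
    copies = readr::read_tsv(file.path(dir, "truth_copies.tsv"),
                             col_types = "ciciccc"),
    loci = readr::read_tsv(file.path(dir, "truth_loci.tsv"), col_types = "cilc"),
    hotspots = readr::read_tsv(file.path(dir, "truth_hotspots.tsv"),
                               col_types = readr::cols())
  ), class = "simulation_truth")
}

#' Write a complete simulated input bundle
#'
#' Materializes a simulation as the pipeline's on-disk input formats:
#' VCF, manifest TSV, linkage-map TSV, anchors TSV and truth TSVs.
#'
#' @param sim A `panel_simulation` from [simulate_panel()].
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "panel.vcf"),
    manifest = file.path(dir, "manifest.tsv"),
    map = file.path(dir, "map.tsv"),
    anchors = file.path(dir, "anchors.tsv")
  )
  write_panel_vcf(sim$panel, paths[["vcf"]])
  write_tsv_plain(as_tibble(sim$panel$samples), paths[["manifest"]])
  write_tsv_plain(as_tibble(sim$map), paths[["map"]])
  write_tsv_plain(sim$anchors, paths[["anchors"]])
  c(paths, write_truth(sim$truth, dir))
  invisible(paths)
}

#' Score hotspot recovery of an introgression track
#'
#' Bins each linkage group into intervals of `bin_cM`, ranks bins of the
#' given track row-set by category-7 SNP count and checks how many of the
#' planted hotspots contain one of the top-`k` bins.
#'
#' @param track An [introgression_track()] tibble.
#' @param hotspots Hotspot tibble (`linkage_group`, `cM_start`, `cM_end`).
#' @param track_id Which track to score (default `"group_A"`).
#' @param bin_cM Bin width; defaults to the hotspot width.
#' @param statistic `"n_cat7_snps"` (default) or `"n_out_snps"`.
#' @return Number of planted hotspots recovered among the top-k bins
#'   (k = number of hotspots).
#' @export
hotspot_recovery <- function(track, hotspots, track_id = "group_A",
                             bin_cM = NULL, statistic = "n_cat7_snps") {
  tr <- track[track$track == track_id, ]
  if (is.null(bin_cM)) bin_cM <- stats::median(hotspots$cM_end - hotspots$cM_start)
  tr$bin <- floor(tr$cM / bin_cM)
  bins <- dplyr::summarise(dplyr::group_by(tr, .data$linkage_group, .data$bin),
                           n = sum(.data[[statistic]]), .groups = "drop")
  bins <- dplyr::arrange(bins, dplyr::desc(.data$n))
  top <- bins[seq_len(min(nrow(hotspots), nrow(bins))), ]
  top$mid <- (top$bin + 0.5) * bin_cM
  hits <- vapply(seq_len(nrow(hotspots)), function(h) {
    any(top$linkage_group == hotspots$linkage_group[h] &
          top$mid > hotspots$cM_start[h] & top$mid < hotspots$cM_end[h])
  }, logical(1))
  sum(hits)
}
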