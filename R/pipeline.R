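#' Configuration for a full pipeline run
#'
#' @param vcf,manifest,map,anchors Input paths; leave `NULL` together with
#'   a non-`NULL` `simulation` to run on a simulated bundle.
#' @param simulation Optional [simulation_config()]; when given, inputs
#'   are generated in memory instead of read from disk.
#' @param thresholds A [recall_thresholds()]; applied only when depths are
#'   available.
#' @param recall Re-call genotypes from depths before analysis.
#' @param dataset `"entire"` (cultivar-informative loci) or
#'   `"no_missing"` (additionally fully called).
#' @param models Ancestry models to run.
#' @param contrast Optional [group_contrast()]; `"auto"` builds a
#'   trailing-vs-upright contrast from the manifest habits; `NULL` skips
#'   the enrichment stage.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed (simulation and any resampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, manifest = NULL, map = NULL, anchors = NULL,
                            simulation = simulation_config(),
                            thresholds = recall_thresholds(), recall = TRUE,
                            dataset = c("entire", "no_missing"),
                            models = c("approach1_alleles", "pure_parents", "exact_parents"),
                            contrast = "auto", out_dir = tempfile("hybrisect_run_"),
                            seed = 1L) {
  structure(list(
    vcf = vcf, manifest = manifest, map = map, anchors = anchors,
    simulation = simulation, thresholds = thresholds, recall = recall,
    dataset = match.arg(dataset), models = models, contrast = contrast,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

auto_contrast <- function(manifest) {
  a <- manifest$sample_id[manifest$role == "cultivar" & manifest$habit == "trailing"]
  b <- manifest$sample_id[manifest$role == "cultivar" & manifest$habit == "upright"]
  if (length(a) == 0L || length(b) == 0L) return(NULL)
  group_contrast(a, b)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage [", name, "] failed: ", conditionMessage(e)))
  })
}

#' Run the full ancestry-dissection pipeline
#'
#' Orders the stages end to end: input loading (or simulation), genotype
#' re-calling from depths, the cultivar-informative and no-missing locus
#' filters, heterozygosity and pairwise SNP counts, per-cultivar category
#' profiles, allele-origin estimates under the requested models, map
#' placement and similarity tracks, and -- when a contrast is available --
#' the group enrichment report, category-7-exclusive transcript list and
#' introgression tracks. All tables are written as TSV under `out_dir`
#' together with a JSON run manifest (effective configuration hash,
#' package version, per-stage locus counts); outputs are byte-identical
#' across reruns with the same configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the report tibbles, the
#'   panel, the run manifest, and `paths` of the written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  counts <- list()
  if (!is.null(config$vcf)) {
    panel <- stage("load", read_panel(config$vcf, config$manifest))
    map <- if (!is.null(config$map)) stage("load", read_linkage_map(config$map)) else NULL
    anchors <- if (!is.null(config$anchors)) stage("load", read_transcript_anchors(config$anchors)) else NULL
    sim <- NULL
  } else {
    sim <- stage("simulate", simulate_panel(config$simulation))
    panel <- stage("simulate", simulate_depths(sim$panel, config$simulation))
    map <- sim$map
    anchors <- sim$anchors
  }
  counts$input_loci <- n_loci(panel)

  if (config$recall && !is.null(panel$depths)) {
    panel <- stage("recall", recall_panel(panel, config$thresholds))
  }
  panel_entire <- stage("filter", filter_informative(panel))
  counts$entire_loci <- n_loci(panel_entire)
  panel_nm <- stage("filter", subset_no_missing(panel_entire))
  counts$no_missing_loci <- n_loci(panel_nm)
  active <- if (config$dataset == "entire") panel_entire else panel_nm

  het <- dplyr::bind_rows(
    stage("diversity", heterozygosity(panel_entire, dataset = "entire")),
    stage("diversity", heterozygosity(panel_nm, dataset = "no_missing"))
  )
  pw <- stage("diversity", pairwise_snp_counts(active))

  cults <- role_samples(active, "cultivar")
  profiles <- stage("dissect", purrr::map_dfr(cults, function(s) category_profile(active, s)))
  ancestry <- stage("dissect", estimate_ancestry(active, cults, config$models))

  placements <- tracks <- NULL
  if (!is.null(map) && !is.null(anchors)) {
    placements <- stage("project", place_transcripts(map, anchors))
    mask <- stage("project", low_recombination_mask(map))
    tracks <- stage("project", purrr::map_dfr(
      c(role_samples(active, "progenitor_a"), role_samples(active, "progenitor_b"),
        role_samples(active, "outgroup_species"), cults),
      function(s) similarity_track(active, s, placements, mask = mask)
    ))
  }

  contrast <- config$contrast
  if (identical(contrast, "auto")) contrast <- auto_contrast(active$samples)
  enrichment <- cat7_tx <- intro_tracks <- NULL
  if (!is.null(contrast)) {
    poly <- stage("enrich", between_group_polymorphic(active, contrast))
    counts$between_group_polymorphic <- sum(poly)
    enrichment <- stage("enrich", category_enrichment(active, contrast, poly))
    cat7_tx <- stage("enrich", cat7_only_transcripts(active, contrast))
    if (!is.null(placements)) {
      intro_tracks <- stage("enrich", introgression_track(active, contrast, placements))
    }
  }

  run_manifest <- list(
    package = "hybrisect",
    version = as.character(utils::packageVersion("hybrisect")),
    seed = config$seed,
    dataset = config$dataset,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    locus_counts = counts
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    heterozygosity = file.path(config$out_dir, "heterozygosity.tsv"),
    pairwise = file.path(config$out_dir, "pairwise_snp_counts.tsv"),
    profiles = file.path(config$out_dir, "category_profiles.tsv"),
    ancestry = file.path(config$out_dir, "ancestry_estimates.tsv"),
    manifest = file.path(config$out_dir, "run_manifest.json")
  )
  write_tsv_plain(het, paths[["heterozygosity"]])
  write_tsv_plain(tidy(pw), paths[["pairwise"]])
  write_tsv_plain(as_tibble(profiles), paths[["profiles"]])
  write_tsv_plain(as_tibble(ancestry), paths[["ancestry"]])
  if (!is.null(tracks)) {
    paths[["tracks"]] <- file.path(config$out_dir, "similarity_tracks.tsv")
    write_tsv_plain(as_tibble(tracks), paths[["tracks"]])
  }
  if (!is.null(enrichment)) {
    paths[["enrichment_by_sample"]] <- file.path(config$out_dir, "enrichment_by_sample.tsv")
    paths[["enrichment_by_group"]] <- file.path(config$out_dir, "enrichment_by_group.tsv")
    paths[["cat7_transcripts"]] <- file.path(config$out_dir, "cat7_only_transcripts.tsv")
    write_tsv_plain(enrichment$by_sample, paths[["enrichment_by_sample"]])
    write_tsv_plain(enrichment$by_group, paths[["enrichment_by_group"]])
    write_tsv_plain(tibble(transcript = cat7_tx), paths[["cat7_transcripts"]])
  }
  if (!is.null(intro_tracks)) {
    paths[["introgression_tracks"]] <- file.path(config$out_dir, "introgression_tracks.tsv")
    write_tsv_plain(as_tibble(intro_tracks), paths[["introgression_tracks"]])
  }
  jsonlite::write_json(run_manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)

  structure(list(
    panel = active, heterozygosity = het, pairwise = pw, profiles = profiles,
    ancestry = ancestry, placements = placements, tracks = tracks,
    enrichment = enrichment, cat7_transcripts = cat7_tx,
    introgression_tracks = intro_tracks, contrast = contrast,
    run_manifest = run_manifest, paths = paths, simulation = sim
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  loci:", paste(sprintf("%s=%s", names(x$run_manifest$locus_counts),
                               unlist(x$run_manifest$locus_counts)), collapse = ", "), "\n")
  cat("  outputs:", dirname(x$paths[[1]]), "\n")
  invisible(x)
}
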