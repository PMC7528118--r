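toy_map <- function(cm, lg = "LG1") {
  linkage_map(tibble::tibble(
    marker = paste0("m", seq_along(cm)), linkage_group = lg, cM = cm,
    scaffold = "S1", scaffold_pos = seq(100, by = 100, length.out = length(cm))
  ))
}

test_that("transcripts are placed at in-range markers, merged within the radius, kept apart beyond it", {
  anchors <- tibble::tibble(transcript = "t1", scaffold = "S1", start = 50, end = 1000)

  # single marker inside the anchored range
  pl <- place_transcripts(toy_map(7.5), anchors)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$cM, 7.5)

  # two markers 0.5 cM apart merge at their mean
  pl <- place_transcripts(toy_map(c(10, 10.5)), anchors)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$cM, 10.25)
  expect_equal(pl$n_markers, 2L)

  # two markers 35 cM apart stay separate placements
  pl <- place_transcripts(toy_map(c(5, 40)), anchors)
  expect_equal(pl$cM, c(5, 40))

  # an out-of-range marker yields nothing
  far <- tibble::tibble(transcript = "t2", scaffold = "S1", start = 2000, end = 3000)
  expect_equal(nrow(place_transcripts(toy_map(5), far)), 0L)
})

test_that("placement is monotone: adding markers never removes a placement", {
  anchors <- tibble::tibble(transcript = "t1", scaffold = "S1", start = 1, end = 1000)
  base <- place_transcripts(toy_map(c(3, 20)), anchors)
  more <- place_transcripts(toy_map(c(3, 20, 50, 80)), anchors)
  for (cm in base$cM) {
    expect_true(any(abs(more$cM - cm) <= 1), label = paste("placement near", cm))
  }
  expect_gte(nrow(more), nrow(base))
})

test_that("transcript similarity averages the per-category rates", {
  # three SNPs on one transcript: hom-A (1), A/B het (0.5), hom-B (0)
  p <- make_panel(c("A/A", "A/A", "A/A"), c("G/G", "G/G", "G/G"),
                  list(cv = c("A/A", "A/G", "G/G")))
  expect_equal(transcript_similarity(p, "cv", "t1"), 0.5)
  p2 <- make_panel(rep("A/A", 3), rep("G/G", 3), list(cv = rep("A/A", 3)))
  expect_equal(transcript_similarity(p2, "cv", "t1"), 1)
  # unclassifiable transcripts give NA (skipped from tracks)
  p3 <- make_panel(rep(NA_character_, 2), rep("G/G", 2), list(cv = rep("A/A", 2)))
  expect_true(is.nan(transcript_similarity(p3, "cv", "t1")))
})

test_that("similarity tracks aggregate SNP-weighted means and respect the mask", {
  sim <- simulate_panel(simulation_config(n_transcripts = 60, seed = 41))
  pl <- place_transcripts(sim$map, sim$anchors)
  tr <- similarity_track(sim$panel, "trail_1", pl)
  expect_true(all(tr$similarity >= 0 & tr$similarity <= 1))
  expect_true(all(tr$n_snps > 0))

  # two transcripts at one merged position, equal SNP counts, rates 1 and 0 -> 0.5
  p <- make_panel(c("A/A", "A/A"), c("G/G", "G/G"), list(cv = c("A/A", "G/G")),
                  transcript_id = c("tA", "tB"))
  map <- linkage_map(tibble::tibble(
    marker = c("m1", "m2"), linkage_group = "LG1", cM = c(10, 10.4),
    scaffold = c("SA", "SB"), scaffold_pos = 500
  ))
  anchors <- tibble::tibble(transcript = c("tA", "tB"), scaffold = c("SA", "SB"),
                            start = 1, end = 1000)
  pl2 <- place_transcripts(map, anchors)
  tr2 <- similarity_track(p, "cv", pl2)
  expect_equal(nrow(tr2), 2L)  # separate transcripts, shared marker window
  expect_equal(sort(tr2$similarity), c(0, 1))

  # masked interval positions are omitted
  cm <- c(0, 1, 2, 30, 31)  # 2 -> 30 is a low-recombination gap
  map3 <- toy_map(cm)
  mask <- low_recombination_mask(map3, gap_cM = 5)
  expect_equal(nrow(mask), 1L)
  expect_equal(c(mask$start_cM, mask$end_cM), c(2, 30))
  p3 <- make_panel(rep("A/A", 1), rep("G/G", 1), list(cv = "A/A"), transcript_id = "t1")
  anch <- tibble::tibble(transcript = "t1", scaffold = "S1", start = 1, end = 1000)
  # t1 sits at 15 cM (inside the masked gap)
  map_in <- linkage_map(tibble::tibble(marker = c("a", "b", "c"), linkage_group = "LG1",
                                       cM = c(0, 15, 40), scaffold = c("SX", "S1", "SY"),
                                       scaffold_pos = 500))
  pl3 <- place_transcripts(map_in, anch)
  msk <- tibble::tibble(linkage_group = "LG1", start_cM = 10, end_cM = 20)
  expect_equal(nrow(similarity_track(p3, "cv", pl3)), 1L)
  expect_equal(nrow(similarity_track(p3, "cv", pl3, mask = msk)), 0L)
})

test_that("the reference progenitor's own track is 1 where it is homozygous and classified", {
  cfg <- simulation_config(n_transcripts = 120, het_ax = 0, missing_rate = 0, seed = 42)
  sim <- simulate_panel(cfg)
  pl <- place_transcripts(sim$map, sim$anchors)
  tr <- similarity_track(sim$panel, "progenitor_a", pl)
  expect_true(all(tr$similarity == 1))
})

test_that("the genome-wide track mean recovers the simulated progenitor-A fraction", {
  cv <- tibble::tibble(id = "cv", habit = "upright", p_ax = 0.62, p_int = 0.33,
                       p_out = 0.05, het_target = NA_real_)
  cfg <- simulation_config(n_transcripts = 7000, het_ax = 0, het_int = 0,
                           shared_allele_prob = 0, cultivars = cv,
                           hotspots = no_hotspots(), missing_rate = 0, seed = 43)
  sim <- simulate_panel(cfg)
  pl <- place_transcripts(sim$map, sim$anchors)
  tr <- similarity_track(sim$panel, "cv", pl)
  grand <- sum(tr$similarity * tr$n_snps) / sum(tr$n_snps)
  expect_equal(grand, 0.62, tolerance = 0.02 / 0.62)

  # a map interval overwritten to be fully progenitor-B-derived drops to 0
  p <- sim$panel
  in_I <- sim$map$linkage_group[match(p$loci$scaffold, sim$map$scaffold)] == "LG1" &
    sim$map$cM[match(p$loci$scaffold, sim$map$scaffold)] <= 30
  p$calls[in_I, "cv"] <- p$calls[in_I, "progenitor_b"]
  tr2 <- similarity_track(p, "cv", pl)
  lg1 <- tr2[tr2$linkage_group == "LG1" & tr2$cM <= 30, ]
  expect_true(all(lg1$similarity <= 0.5))
})
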