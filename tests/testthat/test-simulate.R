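test_that("identical seeds reproduce identical panels bit for bit", {
  cfg <- simulation_config(n_transcripts = 80, seed = 12)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$calls, s2$panel$calls)
  expect_identical(s1$truth$copies, s2$truth$copies)
  dir <- withr::local_tempdir()
  write_panel_vcf(simulate_depths(s1$panel, cfg), file.path(dir, "a.vcf"))
  write_panel_vcf(simulate_depths(s2$panel, cfg), file.path(dir, "b.vcf"))
  expect_identical(readLines(file.path(dir, "a.vcf")), readLines(file.path(dir, "b.vcf")))
  # and the generator leaves the session RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_panel(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero outgroup probability yields no out labels and no out categories", {
  cv <- tibble::tibble(id = c("x", "y"), habit = "upright",
                       p_ax = c(0.6, 0.4), p_int = c(0.4, 0.6), p_out = 0,
                       het_target = NA_real_)
  cfg <- simulation_config(n_transcripts = 300, cultivars = cv,
                           hotspots = no_hotspots(), missing_rate = 0, seed = 13)
  sim <- simulate_panel(cfg)
  expect_false(any(sim$truth$copies$origin_drawn == "out"))
  cl <- classify_panel(sim$panel, c("x", "y"))
  expect_false(any(cl$category %in% 6:10))
})

test_that("truth origin fractions converge to the configured proportions", {
  cv <- tibble::tibble(id = "cv", habit = "upright", p_ax = 0.55, p_int = 0.35,
                       p_out = 0.10, het_target = NA_real_)
  cfg <- simulation_config(n_transcripts = 17000, cultivars = cv,
                           hotspots = no_hotspots(), seed = 14)
  sim <- simulate_panel(cfg)
  frac <- as.numeric(prop.table(table(sim$truth$copies$origin_drawn))[c("ax", "int", "out")])
  expect_true(all(abs(frac - c(0.55, 0.35, 0.10)) < 0.01))
})

test_that("het_target caps cultivar heterozygosity without distorting origin marginals", {
  cv <- tibble::tibble(id = c("free", "low"), habit = "upright",
                       p_ax = 0.5, p_int = 0.4, p_out = 0.1,
                       het_target = c(NA, 0.1))
  cfg <- simulation_config(n_transcripts = 3000, cultivars = cv,
                           hotspots = no_hotspots(), missing_rate = 0, seed = 15)
  sim <- simulate_panel(cfg)
  h <- heterozygosity(sim$panel, c("free", "low"))
  expect_lt(h$rate[2], h$rate[1] / 3)
  tr <- sim$truth$copies
  f_low <- prop.table(table(tr$origin_drawn[tr$sample_id == "low"]))
  expect_equal(unname(f_low["ax"]), 0.5, tolerance = 0.05)
})

test_that("hotspots concentrate outgroup copies only in matching-habit cultivars", {
  cfg <- simulation_config(n_transcripts = 2000, seed = 16)
  sim <- simulate_panel(cfg)
  tr <- dplyr::left_join(sim$truth$copies, sim$truth$loci,
                         by = c("transcript_id", "pos"))
  trailing <- sim$config$cultivars$id[sim$config$cultivars$habit == "trailing"]
  tt <- tr[tr$sample_id %in% trailing, ]
  rate_in <- mean(tt$origin_drawn[!is.na(tt$hotspot_id)] == "out")
  rate_out <- mean(tt$origin_drawn[is.na(tt$hotspot_id)] == "out")
  expect_gte(rate_in / rate_out, max(sim$config$hotspots$out_multiplier) / 2)
  up <- tr[!tr$sample_id %in% trailing, ]
  rate_up_in <- mean(up$origin_drawn[!is.na(up$hotspot_id)] == "out")
  rate_up_out <- mean(up$origin_drawn[is.na(up$hotspot_id)] == "out")
  expect_lt(rate_up_in / rate_up_out, 2)
})

test_that("simulated depths drive the re-caller to the expected regimes", {
  cv <- tibble::tibble(id = "cv", habit = "upright", p_ax = 0.5, p_int = 0.5,
                       p_out = 0, het_target = NA_real_)
  base <- simulation_config(n_transcripts = 1200, cultivars = cv,
                            hotspots = no_hotspots(), missing_rate = 0,
                            error_rate = 0, depth_mean = 50, seed = 17)
  sim <- simulate_panel(base)
  rc <- recall_panel(simulate_depths(sim$panel, base))
  het <- is_het_call(sim$panel$calls[, "cv"])
  agree <- rc$calls[het, "cv"] == sim$panel$calls[het, "cv"]
  expect_gt(mean(agree, na.rm = TRUE), 0.99)
  # unconditionally (counting depth-filtered cells) a little looser
  expect_gt(mean(!is.na(agree) & agree), 0.97)

  shallow <- simulation_config(n_transcripts = 600, cultivars = cv,
                               hotspots = no_hotspots(), missing_rate = 0,
                               depth_mean = 2, seed = 18)
  sim2 <- simulate_panel(shallow)
  rc2 <- recall_panel(simulate_depths(sim2$panel, shallow))
  expect_gt(mean(is.na(rc2$calls)), 0.5)
})

test_that("truth tables round-trip through TSV", {
  sim <- simulate_panel(simulation_config(n_transcripts = 30, seed = 19))
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$copies, sim$truth$copies)
  expect_equal(back$loci, sim$truth$loci)
  expect_equal(back$hotspots$hotspot_id, sim$truth$hotspots$hotspot_id)

  empty <- sim$truth
  empty$copies <- empty$copies[0, ]
  write_truth(empty, dir)
  expect_equal(nrow(readr::read_tsv(file.path(dir, "truth_copies.tsv"),
                                    col_types = "ciciccc")), 0L)
})

test_that("end-to-end: classification plus approach-1 recovers clean simulated proportions", {
  cv <- tibble::tibble(id = c("u", "v"), habit = "upright",
                       p_ax = c(0.7, 0.45), p_int = c(0.25, 0.45),
                       p_out = c(0.05, 0.10), het_target = NA_real_)
  cfg <- simulation_config(n_transcripts = 4000, het_ax = 0, het_int = 0,
                           shared_allele_prob = 0, cultivars = cv,
                           hotspots = no_hotspots(), missing_rate = 0, seed = 20)
  sim <- simulate_panel(cfg)
  for (i in 1:2) {
    e <- allele_proportions_approach1(sim$panel, cv$id[i])
    expect_equal(c(e$p_ax, e$p_int, e$p_out),
                 c(cv$p_ax[i], cv$p_int[i], cv$p_out[i]), tolerance = 0.02)
  }
})
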