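test_that("classify_locus assigns the canonical categories", {
  lab <- function(i) genotype_categories()$label[i]
  cases <- list(
    list("A/A", "G/G", "A/A", "AX_HOM"),
    list("A/A", "G/G", "G/G", "INT_HOM"),
    list("A/A", "A/A", "A/A", "SHARED_HOM"),
    list("A/A", "G/G", "A/G", "AX_INT_HET"),
    list("A/G", "A/G", "A/G", "SHARED_HET"),
    list("A/A", "G/G", "A/T", "AX_OUT_HET"),
    list("A/A", "A/A", "A/T", "SHARED_OUT_HET"),
    list("A/A", "G/G", "G/T", "INT_OUT_HET"),
    list("A/A", "G/G", "T/T", "OUT_HOM"),
    list("A/A", "G/G", "C/T", "OUT_OUT_HET"),
    list("A/A", NA, "A/A", "UNKNOWN"),
    list("A/A", "G/G", NA, "MISSING"),
    list("A/G", "G/G", "A/G", "UNKNOWN")  # strict: het progenitor, differing sets
  )
  for (cs in cases) {
    expect_identical(lab(classify_locus(cs[[1]], cs[[2]], cs[[3]])), cs[[4]],
                     label = paste(unlist(cs[1:3]), collapse = " | "))
  }
  # containment mode resolves what strict calls unknown
  expect_identical(lab(classify_locus("A/G", "G/G", "A/G", mode = "containment")), "AX_HOM")
  # G sits in both progenitor allele sets here, so a G/G call is shared
  expect_identical(lab(classify_locus("A/G", "G/G", "G/G", mode = "containment")), "SHARED_HOM")
  expect_identical(lab(classify_locus("A/G", "C/C", "C/C", mode = "containment")), "INT_HOM")
  expect_identical(lab(classify_locus("A/G", "C/C", "A/G", mode = "containment")), "AX_HOM")
  expect_identical(lab(classify_locus("A/G", "G/G", "A/T", mode = "containment")), "AX_OUT_HET")
})

test_that("classification is total over all genotype combinations and honors the taxonomy pins", {
  alleles <- c("A", "C", "G", "T")
  pairs <- c(NA_character_, apply(expand.grid(alleles, alleles), 1, function(x) {
    paste(sort(x), collapse = "/")
  }))
  pairs <- unique(pairs)
  combos <- expand.grid(ax = pairs, int = pairs, cult = pairs,
                        stringsAsFactors = FALSE)
  got <- classify_calls(combos$ax, combos$int, combos$cult, "strict")
  expect_false(anyNA(got))
  expect_true(all(got %in% 1:12))
  expect_setequal(unique(got), 1:12)

  set_of <- function(call) unique(c(substr(call, 1, 1), substr(call, 3, 3)))
  # category 7 fires exactly on (shared progenitor allele)/novel heterozygotes
  is7 <- vapply(seq_len(nrow(combos)), function(i) {
    ax <- combos$ax[i]; int <- combos$int[i]; cult <- combos$cult[i]
    if (anyNA(c(ax, int, cult))) return(FALSE)
    A <- set_of(ax); B <- set_of(int)
    if (!setequal(A, B) && (length(A) > 1 || length(B) > 1)) return(FALSE)  # strict unknown
    shared <- intersect(A, B)
    cs <- c(substr(cult, 1, 1), substr(cult, 3, 3))
    if (cs[1] == cs[2]) return(FALSE)
    novel <- setdiff(cs, union(A, B))
    length(novel) == 1 && any(cs %in% shared)
  }, logical(1))
  expect_identical(got == 7L, is7)

  # out-carrying categories are exactly those with a novel allele copy
  has_out_copy <- vapply(seq_len(nrow(combos)), function(i) {
    ax <- combos$ax[i]; int <- combos$int[i]; cult <- combos$cult[i]
    if (anyNA(c(ax, int, cult))) return(NA)
    A <- set_of(ax); B <- set_of(int)
    cs <- c(substr(cult, 1, 1), substr(cult, 3, 3))
    length(setdiff(cs, union(A, B))) > 0
  }, logical(1))
  classified <- got %in% 1:10
  expect_identical(got[classified] %in% 6:10, has_out_copy[classified])
})

test_that("category profiles match the hand-counted worked example and sum to one", {
  p <- toy10_panel()
  prof <- category_profile(p, "CV")
  byl <- setNames(prof$proportion, prof$label)
  expect_equal(unname(byl[c("AX_HOM", "INT_HOM", "AX_INT_HET", "SHARED_HOM", "SHARED_OUT_HET")]),
               c(0.4, 0.2, 0.2, 0.1, 0.1))
  expect_equal(sum(prof$proportion), 1, tolerance = 1e-12)
  expect_error(category_profile(p, "AX"), "non-progenitor")

  # an all-missing cultivar is all MISSING
  p2 <- make_panel(rep("A/A", 4), rep("G/G", 4), list(cv = rep(NA_character_, 4)))
  prof2 <- category_profile(p2, "cv")
  expect_equal(prof2$proportion[prof2$label == "MISSING"], 1)
})

test_that("approach-1 allele counting reproduces the worked example", {
  est <- allele_proportions_approach1(toy10_panel(), "CV")
  expect_equal(est$p_ax_poly, 10 / 16)
  expect_equal(est$p_int_poly, 6 / 16)
  expect_equal(est$p_out_overall, 1 / 20)  # the shared/out het carries one out copy
  expect_equal(est$p_ax + est$p_int + est$p_shared + est$p_out + est$p_unknown, 1,
               tolerance = 1e-12)
  expect_equal(est$n_polymorphic, 8L)

  # a cultivar identical to progenitor A everywhere
  p <- make_panel(rep("A/A", 6), rep("G/G", 6), list(cv = rep("A/A", 6)))
  e <- allele_proportions_approach1(p, "cv")
  expect_equal(c(e$p_ax, e$p_int, e$p_out), c(1, 0, 0))
})

test_that("the pure-parents model counts ref/alt1/other copies and ignores progenitor calls", {
  p <- make_panel(rep("A/A", 4), rep("G/G", 4),
                  list(cv = c("A/A", "A/G", "G/G", "A/T")),
                  ref = rep("A", 4), alt = rep("G,T", 4))
  e <- pure_parents_model(p, "cv")
  expect_equal(c(e$p_ax, e$p_int, e$p_out), c(4, 3, 1) / 8)
  expect_equal(e$p_shared, 0)

  # permuting the observed progenitor genotypes changes nothing
  p2 <- p
  p2$calls[, "AX"] <- c("G/G", "A/T", NA, "T/T")
  p2$calls[, "INT"] <- c("A/A", NA, "A/G", "A/A")
  expect_equal(pure_parents_model(p2, "cv"), e)

  expect_equal(pure_parents_model(make_panel(rep("A/A", 3), rep("G/G", 3),
                                             list(cv = rep("A/A", 3))), "cv")$p_ax, 1)
  expect_equal(pure_parents_model(make_panel(rep("A/A", 3), rep("G/G", 3),
                                             list(cv = rep("C/C", 3)),
                                             alt = rep("C,G", 3)), "cv")$p_int, 1)
})

test_that("the exact-parents model assigns copies by progenitor allele-set membership", {
  # observed het progenitor: A/G vs G/G, cultivar A/G -> half ax, half shared
  p <- make_panel("A/G", "G/G", list(cv = "A/G"))
  e <- exact_parents_model(p, "cv")
  expect_equal(c(e$p_ax, e$p_shared), c(0.5, 0.5))

  # allele in neither progenitor counts as out
  p2 <- make_panel("A/A", "G/G", list(cv = "A/T"))
  e2 <- exact_parents_model(p2, "cv")
  expect_equal(c(e2$p_ax, e2$p_out), c(0.5, 0.5))

  # identical to progenitor A with disjoint progenitors
  p3 <- make_panel(rep("A/A", 5), rep("G/G", 5), list(cv = rep("A/A", 5)))
  expect_equal(exact_parents_model(p3, "cv")$p_ax, 1)

  # missing progenitor or cultivar call goes to unknown (two copies)
  p4 <- make_panel(c("A/A", NA), c("G/G", "G/G"), list(cv = c(NA, "A/A")))
  e4 <- exact_parents_model(p4, "cv")
  expect_equal(e4$p_unknown, 1)
})

test_that("proportions are conserved on random panels", {
  for (seed in 1:6) {
    p <- random_panel(seed)
    for (s in c("c1", "c2")) {
      prof <- category_profile(p, s)
      expect_equal(sum(prof$proportion), 1, tolerance = 1e-9)
      est <- estimate_ancestry(p, s)
      sums <- est$p_ax + est$p_int + est$p_shared + est$p_out + est$p_unknown
      expect_equal(sums, rep(1, nrow(est)), tolerance = 1e-9)
    }
  }
})

test_that("approach-1 estimates recover simulated origin fractions on clean panels", {
  cv <- tibble::tibble(id = "cv", habit = "upright",
                       p_ax = 0.6, p_int = 0.3, p_out = 0.1, het_target = NA_real_)
  cfg <- simulation_config(n_transcripts = 2500, het_ax = 0, het_int = 0,
                           shared_allele_prob = 0, cultivars = cv,
                           hotspots = no_hotspots(), missing_rate = 0, seed = 21)
  sim <- simulate_panel(cfg)
  e <- allele_proportions_approach1(sim$panel, "cv")
  expect_equal(c(e$p_ax, e$p_int, e$p_out), c(0.6, 0.3, 0.1), tolerance = 0.03)
  expect_equal(e$p_shared, 0)
})
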