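# in-code fixtures and independent oracles shared across the suite

# panel from explicit calls; cults is a named list of call vectors
make_panel <- function(ax, int, cults, ref = NULL, alt = NULL,
                       transcript_id = NULL, habit = NULL) {
  nl <- length(ax)
  if (is.null(ref)) ref <- rep("A", nl)
  if (is.null(alt)) alt <- rep("C,G,T", nl)
  if (is.null(transcript_id)) transcript_id <- rep("t1", nl)
  loci <- tibble::tibble(transcript_id = transcript_id, pos = seq_len(nl),
                         ref = ref, alt = alt)
  ids <- c("AX", "INT", names(cults))
  if (is.null(habit)) habit <- rep("upright", length(cults))
  samples <- sample_manifest(tibble::tibble(
    sample_id = ids,
    role = c("progenitor_a", "progenitor_b", rep("cultivar", length(cults))),
    habit = c("none", "none", habit)
  ))
  calls <- cbind(ax, int, do.call(cbind, cults))
  genotype_panel(loci, samples, calls)
}

# the 10-locus worked example: 8 progenitor-polymorphic loci (4 hom-A,
# 2 hom-B, 2 A/B het) plus one shared-hom and one shared/out-het locus
toy10_panel <- function() {
  ax <- c(rep("A/A", 8), "A/A", "A/A")
  int <- c(rep("G/G", 8), "A/A", "A/A")
  cult <- c(rep("A/A", 4), rep("G/G", 2), rep("A/G", 2), "A/A", "A/T")
  make_panel(ax, int, list(CV = cult), ref = rep("A", 10),
             alt = rep("G,T", 10))
}

# random panel over {A,C,G,T} with missingness; two cultivars
random_panel <- function(seed, nl = 40, miss = 0.1) {
  set.seed(seed)
  draw <- function() {
    a1 <- sample(c("A", "C", "G", "T"), nl, replace = TRUE)
    a2 <- sample(c("A", "C", "G", "T"), nl, replace = TRUE)
    calls <- mapply(function(x, y) paste(sort(c(x, y)), collapse = "/"), a1, a2)
    calls[runif(nl) < miss] <- NA
    unname(calls)
  }
  make_panel(draw(), draw(), list(c1 = draw(), c2 = draw()),
             ref = rep("A", nl), alt = rep("C,G,T", nl))
}

# independent re-implementation of the three textual re-calling rules,
# kept deliberately naive: evaluated per rule on raw fractions
oracle_recall <- function(counts, ref, alt) {
  total <- sum(counts)
  if (total < 5) return(NA_character_)
  f <- counts / total
  if (f[[ref]] >= 0.8) return(paste(ref, ref, sep = "/"))
  alt_counts <- counts[alt]
  best <- alt[which.max(alt_counts)]  # which.max keeps first on ties
  if (f[[best]] > 0.8) return(paste(best, best, sep = "/"))
  if (f[[ref]] > 0.3 && f[[best]] > 0.3 && f[[ref]] + f[[best]] >= 0.8) {
    return(paste(sort(c(ref, best)), collapse = "/"))
  }
  NA_character_
}

trailing_contrast <- function() {
  group_contrast(c("trail_1", "trail_2", "trail_3"),
                 c("upright_1", "upright_2", "upright_3"))
}

no_hotspots <- function() hybrisect:::default_hotspots()[0, ]
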