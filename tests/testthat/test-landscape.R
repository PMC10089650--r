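test_that("Kimura divergence reproduces hand-derived cases", {
  ## identical pair
  expect_equal(kimura_cpg_divergence(strrep("ACGT", 25), strrep("ACGT", 25)), 0)
  ## 10 comparable sites, 1 non-CpG transition: -50 ln(0.8)
  expect_equal(kimura_cpg_divergence("AATTAATTAA", "AATTAATTAG"),
               -50 * log(0.8), tolerance = 1e-9)
  expect_equal(-50 * log(0.8), 11.15718, tolerance = 1e-5)
  ## transition at a consensus CpG counts 1/10: p = 0.1/4
  expect_equal(kimura_cpg_divergence("ACGA", "ATGA"),
               oracle_kimura("ACGA", "ATGA"), tolerance = 1e-12)
  expect_equal(kimura_cpg_divergence("ACGA", "ATGA"),
               -50 * log(1 - 2 * (0.1 / 4)), tolerance = 1e-9)
  ## doubly transitioned CpG counts once
  expect_equal(kimura_cpg_divergence("ACGA", "ATAA"),
               oracle_kimura("ACGA", "ATAA"), tolerance = 1e-12)
  ## gaps and N excluded from site counts: 9 comparable sites, 1 transition
  expect_equal(kimura_cpg_divergence("AATTAATTA-", "AATTAATTGN"),
               -50 * log(1 - 2 / 9), tolerance = 1e-9)
  ## saturation is an error
  expect_error(kimura_cpg_divergence("AAAA", "GGGG"), "saturat")
  expect_error(kimura_cpg_divergence("AAA", "AA"), "equal length")
  expect_error(kimura_cpg_divergence("AXA", "AAA"), "only contain")
})

test_that("Kimura divergence equals the site-classification oracle on random pairs", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:300) {
    pr <- random_aligned_pair(len = 200, sub_rate = runif(1, 0, 0.25),
                              gap_rate = 0.03, n_rate = 0.02)
    expected <- tryCatch(oracle_kimura(pr$cons, pr$copy), error = function(e) NA)
    if (is.na(expected) || !is.finite(expected)) next
    expect_equal(kimura_cpg_divergence(pr$cons, pr$copy), expected,
                 tolerance = 1e-9)
    ## with CpG correction off, equals textbook K2P
    expect_equal(kimura_cpg_divergence(pr$cons, pr$copy, cpg_correction = FALSE),
                 oracle_kimura(pr$cons, pr$copy, cpg = FALSE),
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("plain K2P matches ape's K80 distance on an ungapped pair", {
  skip_if_not_installed("ape")
  set.seed(3)
  pr <- random_aligned_pair(len = 600, sub_rate = 0.12, gap_rate = 0,
                            n_rate = 0)
  mat <- rbind(strsplit(tolower(pr$cons), "")[[1]],
               strsplit(tolower(pr$copy), "")[[1]])
  rownames(mat) <- c("a", "b")
  ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80")) * 100
  expect_equal(kimura_cpg_divergence(pr$cons, pr$copy, cpg_correction = FALSE),
               ref, tolerance = 1e-6)
})

test_that("occupancy uses union semantics and the layout total", {
  layout <- genome_layout(data.frame(name = "chr1", length = 1e6))
  ## 110 kb of LTR in a 1-Mb genome -> 11%
  ann <- make_ann("chr1", c(0, 200000), c(100000, 210000), te_class = "LTR",
                  superfamily = "ERVK")
  occ <- occupancy_by_class(ann, layout)
  expect_equal(occ$pct[occ$te_class == "LTR"], 11)
  ## abutting same-class intervals counted once (no double count)
  ann2 <- make_ann("chr1", c(0, 1000), c(1000, 2000), te_class = "SINE",
                   superfamily = "Alu")
  occ2 <- occupancy_by_class(ann2, layout)
  expect_equal(occ2$bp[occ2$te_class == "SINE"], 2000)
  ## empty annotations -> all zeros
  occ3 <- occupancy_by_class(ann2[0, ], layout)
  expect_true(all(occ3$bp == 0))
  ## invariant under row permutation
  sim <- simulate_genome(sim_config(seed = 8))
  shuffled <- sim$annotations[sample(nrow(sim$annotations)), ]
  class(shuffled) <- class(sim$annotations)
  expect_equal(occupancy_by_class(shuffled, sim$layout),
               occupancy_by_class(sim$annotations, sim$layout))
})

test_that("divergence profile respects half-open bins and conserves mass", {
  layout <- genome_layout(data.frame(name = "chr1", length = 1e6))
  ann <- make_ann("chr1", c(0, 2000, 4000), c(1000, 3000, 5000),
                  te_class = "LTR", superfamily = "ERVK",
                  divergence = c(0.5, 1.0, 65))
  prof <- divergence_profile(ann, layout)
  ## element at 0.5% -> bin [0,1); element exactly at 1.0 -> bin [1,2)
  expect_equal(prof$bp[prof$bin_lo == 0 & prof$bin_hi == 1], 1000)
  expect_equal(prof$bp[prof$bin_lo == 1 & prof$bin_hi == 2], 1000)
  ## divergence 65 lands in the overflow bin [60, Inf)
  expect_equal(prof$bp[prof$bin_lo == 60], 1000)
  ## mass conservation against occupancy totals per class, on a full genome
  sim <- simulate_genome(sim_config(seed = 8))
  prof2 <- divergence_profile(sim$annotations, sim$layout)
  occ <- occupancy_by_class(sim$annotations, sim$layout)
  for (cl in unique(prof2$group)) {
    expect_equal(sum(prof2$bp[prof2$group == cl]),
                 occ$bp[occ$te_class == cl])
  }
})

test_that("young-TE composition test matches the Fisher oracle", {
  ## table [[3,1],[1,3]]: 3 young LTRs, 1 old LTR, 1 young LINE, 3 old LINEs
  ann <- make_ann("c", seq(0, 7000, by = 1000), seq(500, 7500, by = 1000),
                  te_class = c(rep("LTR", 4), rep("LINE", 4)),
                  superfamily = c(rep("ERVK", 4), rep("L1", 4)),
                  divergence = c(0.1, 0.2, 0.3, 5, 0.4, 6, 7, 8))
  r <- young_te_enrichment(ann, young_threshold = 1, focal_class = "LTR")
  expect_equal(r$p, 34 / 70, tolerance = 1e-12)
  expect_equal(r$observed, 3)
  ## identical compositions -> p = 1
  ann2 <- make_ann("c", seq(0, 3000, by = 1000), seq(500, 3500, by = 1000),
                   te_class = c("LTR", "LTR", "LINE", "LINE"),
                   superfamily = c("ERVK", "ERVK", "L1", "L1"),
                   divergence = c(0.5, 5, 0.5, 5))
  expect_equal(young_te_enrichment(ann2, focal_class = "LTR")$p, 1)
  expect_error(young_te_enrichment(ann2, focal_class = "DNA"), "focal class")
})

test_that("ancient-LINE comparison reports proportions and an enumeration-checked p", {
  mk <- function(n_anc, n_new) {
    n <- n_anc + n_new
    make_ann("c", seq(0, by = 2000, length.out = n),
             seq(1000, by = 2000, length.out = n),
             subfamily = c(rep("L1_anc", n_anc), rep("L1_new", n_new)),
             lineage_specific = c(rep(FALSE, n_anc), rep(TRUE, n_new)))
  }
  a <- mk(16, 84); b <- mk(9, 91)
  r <- ancient_line_comparison(a, b, ancient_labels = "L1_anc")
  expect_equal(r$proportions$ancient_pct, c(16, 9))
  expect_equal(r$p, oracle_fisher(matrix(c(16, 84, 9, 91), 2, byrow = TRUE)),
               tolerance = 1e-9)
  ## identical compositions -> p = 1
  r2 <- ancient_line_comparison(mk(5, 5), mk(5, 5), "L1_anc")
  expect_equal(r2$p, 1)
  ## empty label set -> warning, proportions 0, test skipped
  expect_warning(r3 <- ancient_line_comparison(a, b, character()), "empty")
  expect_true(all(r3$proportions$ancient_pct == 0))
  expect_true(is.na(r3$p))
})
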