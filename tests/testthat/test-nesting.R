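# hand-built chromosome: LINE fragment pair conjoining across an ERV
nest_fixture <- function(fragB_cons_start = 2001, fragB_strand = "+",
                         fragA_strand = "+", erv_gap = 0) {
  te_annotations(data.frame(
    element_id = 1:3,
    chrom = "chr1",
    start = c(1000, 3000 + erv_gap, 8000),
    end = c(3000, 8000, 12100),
    strand = c(fragA_strand, "+", fragB_strand),
    subfamily = c("L1_x", "ERV_y", "L1_x"),
    te_class = c("LINE", "LTR", "LINE"),
    superfamily = c("L1", "ERVK", "L1"),
    lineage_specific = TRUE,
    divergence_pct = 10,
    cons_start = c(1, 1, fragB_cons_start),
    cons_end = c(2000, 4000, fragB_cons_start + 4099),
    cons_remaining = 0, stringsAsFactors = FALSE))
}

test_that("a conjoining LINE pair split by an ERV yields one full-length call", {
  calls <- detect_interruptions(nest_fixture())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$classification, "full_length")
  expect_equal(calls$cons_gap_bp, "0")
  expect_equal(calls$conjoined_cons_len, 6100)
  expect_equal(calls$n_fragments, 2)
  expect_equal(calls$line_fragment_ids, "1,3")
  expect_equal(calls$erv_ids, "2")
  expect_equal(calls$span_start, 1000)
  expect_equal(calls$span_end, 12100)
})

test_that("consensus gaps, strand mismatches, and missing ERVs block calls", {
  ## consensus gap of 600 exceeds the 100-bp tolerance
  expect_equal(nrow(detect_interruptions(nest_fixture(fragB_cons_start = 2601))), 0)
  ## fragment strand mismatch
  expect_equal(nrow(detect_interruptions(nest_fixture(fragB_strand = "-"))), 0)
  ## intact LINE with no internal ERV: null case
  solo <- make_ann("chr1", 1000, 7100, subfamily = "L1_x", cons_end = 6100)
  expect_equal(nrow(detect_interruptions(solo)), 0)
  ## unannotated junction gap beyond tolerance
  expect_equal(nrow(detect_interruptions(nest_fixture(erv_gap = 200))), 0)
  ## within tolerance it still calls
  expect_equal(nrow(detect_interruptions(nest_fixture(erv_gap = 30))), 1)
  ## unsorted input is an error
  un <- nest_fixture()[c(2, 1, 3), ]
  expect_error(detect_interruptions(un), "sorted")
})

test_that("minus-strand fragments conjoin in mirrored consensus order", {
  ann <- te_annotations(data.frame(
    element_id = 1:3, chrom = "chr1",
    start = c(1000, 3000, 8000), end = c(3000, 8000, 12100),
    strand = c("-", "+", "-"),
    subfamily = c("L1_x", "ERV_y", "L1_x"),
    te_class = c("LINE", "LTR", "LINE"),
    superfamily = c("L1", "ERVK", "L1"),
    lineage_specific = TRUE, divergence_pct = 10,
    ## left fragment carries the consensus tail, right one the head
    cons_start = c(4101, 1, 1), cons_end = c(6100, 4000, 4100),
    cons_remaining = 0, stringsAsFactors = FALSE))
  calls <- detect_interruptions(ann)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$conjoined_cons_len, 6100)
  ## the same coordinates on the plus strand do not conjoin
  ann2 <- ann
  ann2$strand <- c("+", "+", "+")
  expect_equal(nrow(detect_interruptions(te_annotations(ann2))), 0)
})

test_that("strict mode drops non-ERV interlopers and >2-fragment chains; relaxed keeps them", {
  ## a SINE between the fragments blocks the strict call
  base <- nest_fixture()
  sine <- data.frame(element_id = 4, chrom = "chr1", start = 4000, end = 4100,
                     strand = "+", subfamily = "B1", te_class = "SINE",
                     superfamily = "Alu", lineage_specific = TRUE,
                     divergence_pct = 5, cons_start = 1, cons_end = 100,
                     cons_remaining = 0, stringsAsFactors = FALSE)
  with_sine <- te_annotations(rbind(as.data.frame(base), sine))
  expect_equal(nrow(detect_interruptions(with_sine, strict = TRUE)), 0)
  ## relaxed mode tolerates covered junctions only; the SINE leaves ERV
  ## coverage intact here because the ERV spans the whole junction
  expect_equal(nrow(detect_interruptions(with_sine, strict = FALSE)), 1)
  ## three conjoining fragments: discarded in strict, one chained call relaxed
  tri <- te_annotations(data.frame(
    element_id = 1:5, chrom = "chr1",
    start = c(1000, 3000, 8000, 10100, 15000),
    end = c(3000, 8000, 10100, 15000, 15800),
    strand = "+",
    subfamily = c("L1_x", "ERV_y", "L1_x", "ERV_y", "L1_x"),
    te_class = c("LINE", "LTR", "LINE", "LTR", "LINE"),
    superfamily = c("L1", "ERVK", "L1", "ERVK", "L1"),
    lineage_specific = TRUE, divergence_pct = 10,
    cons_start = c(1, 1, 2001, 1, 4101),
    cons_end = c(2000, 4000, 4100, 4000, 4900),
    cons_remaining = 0, stringsAsFactors = FALSE))
  expect_equal(nrow(detect_interruptions(tri, strict = TRUE)), 0)
  rel <- detect_interruptions(tri, strict = FALSE)
  expect_equal(nrow(rel), 1)
  expect_equal(rel$n_fragments, 3)
  expect_equal(rel$classification, "fragmented")
})

test_that("relaxed-mode call counts dominate strict-mode counts on simulated genomes", {
  for (s in c(2, 12)) {
    sim <- simulate_genome(sim_config(seed = s))
    ns <- nrow(detect_interruptions(sim$annotations, strict = TRUE))
    nr <- nrow(detect_interruptions(sim$annotations, strict = FALSE))
    expect_gte(nr, ns)
  }
})

test_that("the ERV-in-LINE permutation test rewards planted nesting and respects seeds", {
  sim <- simulate_genome(sim_config(seed = 14))
  res <- permutation_erv_in_line(sim$annotations, n_perm = 99, seed = 5)
  expect_true(all(res$q >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
  ## planted interrupting subfamilies carry real signal: the minimum p over
  ## ERVK subfamilies should be at the permutation floor
  ervk <- res[grepl("ERVK", res$unit), ]
  expect_equal(min(ervk$p), 1 / 100)
  ## identical seed, permuted row order: identical per-subfamily results
  shuffled <- sim$annotations[sample(nrow(sim$annotations)), ]
  shuffled <- te_annotations(shuffled)
  res2 <- permutation_erv_in_line(shuffled, n_perm = 99, seed = 5)
  expect_equal(res2, res)
  ## different seed may differ; same convention though
  expect_error(permutation_erv_in_line(sim$annotations, n_perm = 0, seed = 1),
               "n_perm")
  expect_error(permutation_erv_in_line(sim$annotations, n_perm = 99),
               "seed")
})
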