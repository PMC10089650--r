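test_that("identical seeds give identical simulations; different seeds differ", {
  cfg <- sim_config(seed = 23)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$kznf_divergence, s2$kznf_divergence)
  s3 <- simulate_genome(sim_config(seed = 24))
  expect_false(identical(s1$annotations, s3$annotations))
  ## byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1); p2 <- write_simulation(s2, d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), label = k)
  }
})

test_that("every planted event is recoverable from the emitted annotations", {
  sim <- simulate_genome(sim_config(seed = 25))
  tr <- sim$truth$interruptions
  calls <- detect_interruptions(sim$annotations)
  ## one call per planted interruption, at the planted span
  expect_equal(nrow(calls), nrow(tr))
  key_calls <- paste(calls$chrom, calls$span_start, calls$span_end)
  key_truth <- paste(tr$chrom, tr$span_start, tr$span_end)
  expect_setequal(key_calls, key_truth)
  ## the interrupting ERV ids match the manifest
  m <- match(key_truth, key_calls)
  expect_equal(as.integer(calls$erv_ids[m]), tr$erv_id)
  ## planted hotspot windows are called
  hs <- call_hotspots(sim$annotations, sim$layout)
  hw <- sim$truth$hotspot_windows
  called_keys <- paste(hs$chrom[hs$is_hotspot], hs$start[hs$is_hotspot])
  expect_true(all(paste(hw$chrom, hw$start) %in% called_keys))
  ## all planted elements are present in the annotation table
  expect_true(all(unlist(strsplit(tr$fragment_ids, ",")) %in%
                    sim$annotations$element_id))
  expect_true(all(tr$erv_id %in% sim$annotations$element_id))
})

test_that("annotations are overlap-free and within bounds under rejection placement", {
  sim <- simulate_genome(sim_config(seed = 26))
  ann <- sim$annotations
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  len <- sim$layout$chromosomes$length[match(ann$chrom,
                                             sim$layout$chromosomes$name)]
  expect_true(all(ann$end <= len & ann$start >= 0))
  ## consensus coordinates are internally consistent
  expect_true(all(ann$cons_start >= 1 & ann$cons_start <= ann$cons_end))
  expect_true(all(ann$cons_remaining >= 0))
})

test_that("null_config strips every plant, preserves seeds, and is idempotent", {
  cfg <- sim_config(seed = 27, upstream_bias = list(subfamily = "Pman_ERVK_2",
                                                    factor = 10,
                                                    window_bp = 5000),
                    sd = list(n = 3, width = 2e4))
  nc <- null_config(cfg)
  expect_equal(nc$interruptions$n, 0)
  expect_equal(nc$hotspots$n, 0)
  expect_null(nc$upstream_bias$subfamily)
  expect_equal(nc$sd$n, 0)
  expect_equal(nc$genes$kznf$div_mean_hotspot, nc$genes$kznf$div_mean_other)
  expect_equal(nc$seed, cfg$seed)
  expect_identical(null_config(nc), nc)
  sim <- simulate_genome(nc)
  expect_null(sim$truth$interruptions)
  expect_null(sim$truth$hotspot_windows)
  expect_equal(nrow(sim$sd_intervals), 0)
})

test_that("zero-TE configurations emit an empty but valid annotation set", {
  subs <- default_subfamilies()
  subs$n_copies <- 0
  cfg <- sim_config(seed = 28, subfamilies = subs,
                    interruptions = list(n = 0, host_subfamily = "L1_Pman1",
                                         erv_subfamilies = NULL,
                                         cons_total_range = c(5500, 6300)),
                    hotspots = list(n = 0, width = 1e5, multiplier = 1,
                                    mode = "independent-insertion",
                                    erv_subfamilies = NULL),
                    genes = list(n = 10, coding_frac = 0.7, lncRNA_frac = 0.15,
                                 kznf = list(n_clusters = 0,
                                             genes_per_cluster = 0,
                                             hotspot_frac = 0,
                                             div_mean_hotspot = 17,
                                             div_mean_other = 17,
                                             div_sd = 5)))
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotations), 0)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  back <- read_te_annotations(paths["out"], "out")
  expect_equal(nrow(back), 0)
})

test_that("over-stuffed configurations fail with a capacity error", {
  subs <- default_subfamilies()
  subs$n_copies[1] <- 50000
  cfg <- sim_config(seed = 29, n_chromosomes = 1, chromosome_length = 2e5,
                    subfamilies = subs)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("the bundled landscape-like configuration shows the planted shape", {
  sim <- simulate_genome(paperlike_config(seed = 30))
  prof <- divergence_profile(sim$annotations, sim$layout)
  young <- prof[prof$bin_hi <= 5, ]
  ltr_young <- sum(young$bp[young$group == "LTR"])
  line_young <- sum(young$bp[young$group == "LINE"])
  expect_gt(ltr_young, line_young)
  ## hotspot-colocated KZNF clusters come out enriched
  hs <- call_hotspots(sim$annotations, sim$layout, genes = sim$genes)
  hg <- hotspot_gene_content(sim$genes, hs)
  expect_lt(hg$p * 1, 0.05)
  ## the planted upstream subfamily is the top enrichment hit
  ue <- upstream_enrichment(sim$annotations, sim$genes, sim$layout,
                            n_perm = 199, seed = 31)
  best <- ue$unit[which.min(ue$p)]
  expect_equal(best, sim$config$upstream_bias$subfamily)
})
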