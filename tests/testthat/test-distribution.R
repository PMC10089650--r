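small_layout <- function(len = 1e6, n = 1)
  genome_layout(data.frame(name = paste0("chr", seq_len(n)), length = len))

test_that("feature coverage divides covered bp by feature bp", {
  layout <- small_layout()
  genes <- gene_annotations(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000, end = 11000, strand = "+",
    biotype = "coding", is_kznf = FALSE, is_lineage_specific = FALSE,
    cds = I(list(cbind(start = 10000, end = 11000)))))
  ## 250 bp of a TE inside the 1000-bp CDS
  ann <- make_ann("chr1", 10750, 11250, te_class = "LTR",
                  superfamily = "ERVK")
  cov <- feature_te_coverage(ann, genes, layout)
  expect_equal(cov$coverage[cov$feature == "CDS" & cov$te_class == "LTR"],
               0.25)
  ## a TE fully outside features counts only on the chromosome row
  ann2 <- make_ann("chr1", 500000, 501000, te_class = "LTR",
                   superfamily = "ERVK")
  cov2 <- feature_te_coverage(ann2, genes, layout)
  expect_equal(cov2$covered_bp[cov2$feature == "CDS"], 0)
  expect_equal(cov2$covered_bp[cov2$feature == "chr1"], 1000)
})

test_that("CDS-avoiding TEs reach the maximal depletion p under permutation", {
  set.seed(41)
  layout <- small_layout(2e5)
  ## CDS tiles half the chromosome; TEs all in the other half
  genes <- gene_annotations(data.frame(
    gene_id = "g1", chrom = "chr1", start = 0, end = 1e5, strand = "+",
    biotype = "coding", is_kznf = FALSE, is_lineage_specific = FALSE,
    cds = I(list(cbind(start = 0, end = 1e5)))))
  starts <- seq(100000, 195000, by = 5000)
  ann <- make_ann("chr1", starts, starts + 1000, te_class = "LTR",
                  superfamily = "ERVK")
  cov <- feature_te_coverage(ann, genes, layout, with_null = TRUE,
                             n_perm = 99, seed = 3)
  row <- cov[cov$feature == "CDS" & cov$te_class == "LTR", ]
  expect_equal(row$covered_bp, 0)
  expect_equal(row$p_depletion, 1 / 100)
})

test_that("nearest-gene distances honour strand and overlap conventions", {
  layout <- small_layout()
  genes <- gene_annotations(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(10000, 30000), end = c(12000, 31000),
    strand = c("+", "-"), biotype = "coding",
    is_kznf = FALSE, is_lineage_specific = FALSE))
  ann <- make_ann("chr1", c(5000, 11000, 40000), c(6000, 11500, 41000),
                  strand = c("+", "+", "-"), te_class = "LTR",
                  superfamily = "ERVK")
  ds <- nearest_gene_distances(ann, genes, "stranded")
  ## gap of 4000 to the same-strand gene
  expect_equal(ds$distance[1], 4000)
  ## overlapping pair: 0
  expect_equal(ds$distance[2], 0)
  ## minus-strand element matches the minus-strand gene
  expect_equal(ds$distance[3], 9000)
  du <- nearest_gene_distances(ann, genes, "unstranded")
  expect_equal(du$distance[1], 4000)
  ## stranded distance with no same-strand gene is missing
  solo_genes <- gene_annotations(data.frame(
    gene_id = "gp", chrom = "chr1", start = 10000, end = 12000,
    strand = "+", biotype = "coding", is_kznf = FALSE,
    is_lineage_specific = FALSE))
  neg <- make_ann("chr1", 5000, 6000, strand = "-", te_class = "LTR",
                  superfamily = "ERVK")
  expect_true(is.na(nearest_gene_distances(neg, solo_genes,
                                           "stranded")$distance))
})

test_that("upstream counting is strand-aware and windows clip at chromosome edges", {
  layout <- small_layout()
  genes <- gene_annotations(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(10000, 50000), end = c(12000, 52000),
    strand = c("+", "-"), biotype = "coding", is_kznf = FALSE,
    is_lineage_specific = FALSE))
  ## + TE inside [5000, 10000) upstream of the + gene: counted
  ann_in <- make_ann("chr1", 6000, 6500, te_class = "LTR",
                     superfamily = "ERVK", subfamily = "sfU")
  r_in <- upstream_enrichment(ann_in, genes, layout, n_perm = 49, seed = 1)
  expect_equal(r_in$observed[r_in$unit == "sfU"], 1)
  ## the same element on the minus strand is not counted
  ann_out <- make_ann("chr1", 6000, 6500, strand = "-", te_class = "LTR",
                      superfamily = "ERVK", subfamily = "sfU")
  r_out <- upstream_enrichment(ann_out, genes, layout, n_perm = 49, seed = 1)
  expect_equal(r_out$observed[r_out$unit == "sfU"], 0)
  ## minus-strand gene: upstream lies right of the gene end
  ann_m <- make_ann("chr1", 53000, 53400, strand = "-", te_class = "LTR",
                    superfamily = "ERVK", subfamily = "sfU")
  r_m <- upstream_enrichment(ann_m, genes, layout, n_perm = 49, seed = 1)
  expect_equal(r_m$observed[r_m$unit == "sfU"], 1)
  ## regions clip at chromosome starts
  edge_gene <- gene_annotations(data.frame(
    gene_id = "g0", chrom = "chr1", start = 2000, end = 4000, strand = "+",
    biotype = "coding", is_kznf = FALSE, is_lineage_specific = FALSE))
  reg <- tescape:::upstream_regions(edge_gene, layout)
  expect_equal(reg$start, 0)
  expect_equal(reg$end, 2000)
})

test_that("hotspot calling follows the interpolated quantile and the tie rule", {
  layout <- small_layout(1e6)
  ## build 10 windows with densities 0.0 ... 0.9 via one element per window
  starts <- seq(0, 9e5, by = 1e5)
  dens <- seq(0, 0.9, by = 0.1)
  keep <- dens > 0
  ann <- make_ann("chr1", starts[keep], starts[keep] + dens[keep] * 1e5,
                  te_class = "LTR", superfamily = "ERVK")
  hs <- call_hotspots(ann, layout, window_bp = 1e5)
  expect_equal(attr(hs, "threshold"), 0.855, tolerance = 1e-12)
  expect_equal(sum(hs$is_hotspot), 1)
  expect_equal(hs$erv_density, dens, tolerance = 1e-12)
  ## degenerate uniform nonzero densities: >= threshold flags all
  ann_u <- make_ann("chr1", starts, starts + 20000, te_class = "LTR",
                    superfamily = "ERVK")
  hs_u <- call_hotspots(ann_u, layout, window_bp = 1e5)
  expect_true(all(hs_u$is_hotspot))
  ## empty annotations: densities 0, no hotspots under the > 0 guard
  hs_0 <- call_hotspots(ann_u[0, ], layout, window_bp = 1e5)
  expect_false(any(hs_0$is_hotspot))
  ## trailing partial window is normalized by its own length
  layout_part <- small_layout(2.5e5)
  ann_p <- make_ann("chr1", 210000, 235000, te_class = "LTR",
                    superfamily = "ERVK")
  hs_p <- call_hotspots(ann_p, layout_part, window_bp = 1e5)
  expect_equal(hs_p$end[3] - hs_p$start[3], 5e4)
  expect_equal(hs_p$erv_density[3], 0.5)
})

test_that("neighbour deltas pair consecutive elements and split by hotspot", {
  layout <- small_layout(1e6)
  ann <- make_ann("chr1", c(1000, 5000, 9000), c(2000, 6000, 10000),
                  te_class = "LTR", superfamily = "ERVK",
                  divergence = c(10, 12, 20))
  hs <- call_hotspots(ann, layout, window_bp = 1e5)
  nd <- neighbor_divergence_delta(ann, hs)
  expect_equal(nd$pairs$delta, c(2, 8))
  ## single element: no pairs
  nd1 <- neighbor_divergence_delta(ann[1, ], hs)
  expect_equal(nrow(nd1$pairs), NULL)
})

test_that("gene-ERV density association recovers planted signs", {
  wins <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e5),
                     end = seq(1e5, 1e6, 1e5))
  ## exactly anti-correlated densities
  wins$erv_density <- seq(0.05, 0.5, length.out = 10)
  wins$gene_density <- 0.6 - wins$erv_density
  a <- suppressWarnings(gene_erv_density_association(wins))
  expect_lt(a$coefficient, 0)
  expect_lt(a$p, 1e-10)
  ## constant gene density: coefficient 0
  wins$gene_density <- 0.3
  a0 <- suppressWarnings(gene_erv_density_association(wins))
  expect_equal(a0$coefficient, 0, tolerance = 1e-12)
  ## binomial-logit family keeps the sign
  wins$gene_density <- 0.6 - wins$erv_density
  ab <- gene_erv_density_association(wins, family = "binomial")
  expect_lt(ab$coefficient, 0)
})

test_that("hotspot gene content matches the enumeration Fisher", {
  layout <- small_layout(1e6)
  ## hotspot = densest window; flagged genes all inside it
  starts <- seq(0, 9e5, by = 1e5)
  ann <- make_ann("chr1", starts, starts + c(rep(1000, 9), 50000),
                  te_class = "LTR", superfamily = "ERVK")
  hs <- call_hotspots(ann, layout, window_bp = 1e5)
  expect_equal(sum(hs$is_hotspot), 1)
  genes <- gene_annotations(data.frame(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
    start = c(seq(905000, 935000, length.out = 4),    # 4 flagged, in hotspot
              seq(5000, 800000, length.out = 16)),    # 16 others, outside
    end = c(seq(906000, 936000, length.out = 4),
            seq(6000, 801000, length.out = 16)),
    strand = "+", biotype = "coding",
    is_kznf = c(rep(TRUE, 4), rep(FALSE, 16)),
    is_lineage_specific = c(rep(TRUE, 4), rep(FALSE, 16))))
  r <- hotspot_gene_content(genes, hs)
  expect_equal(r$flagged_in, 4)
  expect_equal(r$p, oracle_fisher(matrix(c(4, 0, 0, 16), 2, byrow = TRUE)),
               tolerance = 1e-9)
  expect_lt(r$p, 0.05)
  ## proportional distribution: p = 1
  genes2 <- genes
  genes2$is_kznf <- rep(c(TRUE, FALSE), 10)
  genes2$is_lineage_specific <- genes2$is_kznf
  ## place all genes outside the hotspot so both groups are all-out
  genes2$start <- seq(5000, 800000, length.out = 20)
  genes2$end <- genes2$start + 1000
  genes2 <- gene_annotations(as.data.frame(genes2))
  expect_equal(hotspot_gene_content(genes2, hs)$p, 1)
  expect_error(hotspot_gene_content(genes2[!genes2$is_kznf, ], hs),
               "no flagged")
})

test_that("window densities partition ERV-covered bp per chromosome", {
  sim <- simulate_genome(sim_config(seed = 17))
  hs <- call_hotspots(sim$annotations, sim$layout)
  erv <- sim$annotations[sim$annotations$te_class == "LTR", ]
  for (ch in unique(hs$chrom)) {
    w <- hs[hs$chrom == ch, ]
    lhs <- sum(w$erv_density * (w$end - w$start))
    sub <- erv[erv$chrom == ch, ]
    rhs <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(sub$start + 1, sub$end))))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("the SD confound check flags SD-tiled upstream regions", {
  layout <- small_layout(1e6)
  genes <- gene_annotations(data.frame(
    gene_id = sprintf("g%d", 1:5), chrom = "chr1",
    start = seq(100000, 500000, by = 1e5),
    end = seq(102000, 502000, by = 1e5), strand = "+",
    biotype = "coding", is_kznf = FALSE, is_lineage_specific = FALSE))
  ## one element upstream of each gene
  ann <- make_ann("chr1", seq(96000, 496000, by = 1e5),
                  seq(96500, 496500, by = 1e5),
                  te_class = "LTR", superfamily = "ERVK", subfamily = "sfU")
  ## SDs tiling exactly the tested upstream regions
  sds <- data.frame(chrom = "chr1", start = seq(95000, 495000, by = 1e5),
                    end = seq(100000, 500000, by = 1e5))
  r <- sd_confound_check(sds, ann, genes, layout, "sfU", n_perm = 99,
                         seed = 2)
  expect_equal(r$p, 1 / 100)
  expect_true(r$flagged)
  ## zero SDs: p = 1, no flag
  r0 <- sd_confound_check(sds[0, ], ann, genes, layout, "sfU", n_perm = 99,
                          seed = 2)
  expect_equal(r0$p, 1)
  expect_false(r0$flagged)
})
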