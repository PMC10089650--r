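#!/usr/bin/env Rscript
## Genomic distribution of TEs: feature coverage with a CDS depletion null,
## stranded vs unstranded nearest-gene distances, 5-kb upstream enrichment
## with the segmental-duplication confound check, ERV hotspot calling,
## neighbour delta-divergence, and the gene-ERV density association.

library(tescape)

ann <- read_te_annotations("results/sim/te.tsv", "tsv")
genes <- read_genes("results/sim/genes.gff3", "gff3")
layout <- read_layout("results/sim/layout.tsv")
sds <- utils::read.delim("results/sim/sd.bed", header = FALSE,
                         col.names = c("chrom", "start", "end"))

cov <- feature_te_coverage(ann, genes, layout, with_null = TRUE,
                           n_perm = 100, seed = 990101)
write_table(cov, "results/feature_coverage.tsv")
cds <- cov[cov$feature == "CDS", ]
cat(sprintf("CDS coverage (LTR): %.3f; permutation p: depletion %.3g / enrichment %.3g\n",
            cds$coverage[cds$te_class == "LTR"],
            cds$p_depletion[cds$te_class == "LTR"],
            cds$p_enrichment[cds$te_class == "LTR"]))

erv <- ann[ann$te_class == "LTR", ]
nm <- compare_nearest_gene_modes(erv, genes)
cat(sprintf("stranded vs unstranded nearest-gene distances: MWU p = %.3g\n",
            nm$p))

ue <- upstream_enrichment(ann, genes, layout, n_perm = 1000, seed = 990201)
write_table(ue, "results/upstream_enrichment.tsv")
top <- ue[order(ue$q), ][1, ]
cat(sprintf("top upstream-enriched subfamily: %s (ratio %.1f, q = %.3g)\n",
            top$unit, top$ratio, top$q))

sdc <- sd_confound_check(sds, ann, genes, layout,
                         subfamilies = ue$unit[ue$q < 0.05 & ue$ratio > 1],
                         n_perm = 500, seed = 990301)
write_table(sdc, "results/sd_confound.tsv")
if (any(sdc$flagged))
  cat("SD-confounded subfamilies dropped:",
      paste(sdc$unit[sdc$flagged], collapse = ", "), "\n")

hs <- call_hotspots(ann, layout, genes = genes)
write_table(hs, "results/hotspots.tsv")
cat(sprintf("hotspots: %d of %d 100-kb windows at threshold %.3f\n",
            sum(hs$is_hotspot), nrow(hs), attr(hs, "threshold")))

nd <- neighbor_divergence_delta(ann, hs)
cat(sprintf("neighbour |delta divergence| in vs out of hotspots: medians %.2f / %.2f, MWU p = %.3g\n",
            nd$median_in, nd$median_out, nd$p))

assoc <- gene_erv_density_association(hs)
cat(sprintf("gene density ~ ERV density: coefficient %.3f, p = %.3g\n",
            assoc$coefficient, assoc$p))

hg <- hotspot_gene_content(genes, hs)
write_table(hg, "results/hotspot_gene_content.tsv")
cat(sprintf("lineage-specific KZNFs in hotspots: %d/%d (hotspots %.1f%% of genome), p = %.3g\n",
            hg$flagged_in, hg$n_flagged, 100 * hg$hotspot_genome_frac, hg$p))
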