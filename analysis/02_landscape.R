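#!/usr/bin/env Rscript
## Genome occupancy by TE class and the divergence-binned landscape profile,
## plus the young-TE composition test: is the LTR class overrepresented
## among elements under 1% divergence from their consensus?

library(tescape)

ann <- read_te_annotations("results/sim/te.tsv", "tsv")
layout <- read_layout("results/sim/layout.tsv")

occ <- occupancy_by_class(ann, layout)
write_table(occ, "results/occupancy.tsv")
cat("occupancy (% of genome):\n")
print(occ, row.names = FALSE)

prof <- divergence_profile(ann, layout, bin_width = 1)
write_table(prof, "results/landscape_profile.tsv")
young <- prof[prof$bin_hi <= 3, ]
cat(sprintf("\nyoungest 3%% bins: LTR %.0f kb vs LINE %.0f kb\n",
            sum(young$bp[young$group == "LTR"]) / 1e3,
            sum(young$bp[young$group == "LINE"]) / 1e3))

yt <- young_te_enrichment(ann, young_threshold = 1, focal_class = "LTR")
write_table(yt, "results/young_te_fisher.tsv")
cat(sprintf("young-TE Fisher test (LTR focal, <1%% divergence): p = %.3g, ratio = %.2f\n",
            yt$p, yt$ratio))
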