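#!/usr/bin/env Rscript
## Generate the synthetic study genome: 10 Mb over five chromosomes, ~5,000
## TE annotations from a cricetid-like subfamily community, 50 planted
## ERV-in-LINE interruptions, five planted ERV hotspot windows with
## half-colocated lineage-specific KZNF clusters, and the matched null
## genome with every plant stripped. All downstream steps read these files.

library(tescape)

seed <- 20240101 %% 1000003
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results/sim_null", recursive = TRUE, showWarnings = FALSE)

cfg <- paperlike_config(seed = seed)
cfg$sd <- list(n = 3, width = 2e4)
sim <- simulate_genome(cfg)
write_simulation(sim, "results/sim")
cat(sprintf("study genome: %d TE annotations, %d genes, %d planted interruptions\n",
            nrow(sim$annotations), nrow(sim$genes),
            nrow(sim$truth$interruptions)))

nsim <- simulate_genome(null_config(cfg))
write_simulation(nsim, "results/sim_null")
cat(sprintf("null genome:  %d TE annotations, no planted structure\n",
            nrow(nsim$annotations)))
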