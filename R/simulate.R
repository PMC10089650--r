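#' Default subfamily table for synthetic genomes
#'
#' A small community qualitatively shaped like a cricetid rodent genome: one
#' recently active lineage-specific L1, one ancient shared mammalian L1, a
#' lineage-specific SINE, six lineage-specific ERVK subfamilies (the dominant
#' recent invaders), ancestral ERVL/MaLR elements, and a relic DNA
#' transposon. Copy lengths are drawn as a uniform fraction of the consensus
#' in `[frac_min, frac_max]`; per-copy divergence is normal
#' `(div_mean, div_sd)` truncated at 0.
#'
#' @return data.frame with columns `name`, `te_class`, `superfamily`,
#'   `consensus_length`, `n_copies`, `div_mean`, `div_sd`,
#'   `lineage_specific`, `frac_min`, `frac_max`.
#' @export
default_subfamilies <- function() {
  df <- rbind(
    data.frame(name = "L1_Pman1", te_class = "LINE", superfamily = "L1",
               consensus_length = 6400, n_copies = 700, div_mean = 18,
               div_sd = 6, lineage_specific = TRUE,
               frac_min = 0.06, frac_max = 0.35),
    data.frame(name = "L1_Mam", te_class = "LINE", superfamily = "L1",
               consensus_length = 6000, n_copies = 300, div_mean = 30,
               div_sd = 4, lineage_specific = FALSE,
               frac_min = 0.10, frac_max = 0.30),
    data.frame(name = "B1_Pman", te_class = "SINE", superfamily = "Alu",
               consensus_length = 150, n_copies = 1500, div_mean = 12,
               div_sd = 6, lineage_specific = TRUE,
               frac_min = 0.60, frac_max = 1.00),
    data.frame(name = paste0("Pman_ERVK_", 1:6), te_class = "LTR",
               superfamily = "ERVK",
               consensus_length = c(2400, 1800, 3000, 2600, 2000, 2800),
               n_copies = 250, div_mean = c(16, 15, 17, 16, 14, 18),
               div_sd = 4, lineage_specific = TRUE,
               frac_min = 0.12, frac_max = 0.55),
    data.frame(name = "MT2_Mam", te_class = "LTR", superfamily = "ERVL",
               consensus_length = 500, n_copies = 200, div_mean = 28,
               div_sd = 5, lineage_specific = FALSE,
               frac_min = 0.40, frac_max = 1.00),
    data.frame(name = "MTA_MaLR", te_class = "LTR", superfamily = "MaLR",
               consensus_length = 600, n_copies = 200, div_mean = 25,
               div_sd = 5, lineage_specific = FALSE,
               frac_min = 0.40, frac_max = 1.00),
    data.frame(name = "Charlie1", te_class = "DNA", superfamily = "hAT",
               consensus_length = 2500, n_copies = 300, div_mean = 32,
               div_sd = 5, lineage_specific = FALSE,
               frac_min = 0.05, frac_max = 0.30))
  rownames(df) <- NULL
  df
}

#' Synthetic-genome configuration
#'
#' Bundles every knob of the generator: genome layout, the subfamily
#' community, planted ERV-in-LINE interruptions, ERV hotspots (by independent
#' insertion or segmental duplication), a planted upstream-bias subfamily,
#' genes with KZNF clusters, and segmental-duplication intervals.
#'
#' @param seed integer seed; the same seed reproduces the genome bit for bit.
#' @param n_chromosomes,chromosome_length layout (defaults 5 x 2 Mb).
#' @param subfamilies subfamily table as in [default_subfamilies()].
#' @param interruptions list: `n`, `host_subfamily`, `erv_subfamilies`
#'   (NULL = all lineage-specific ERVKs), `cons_total_range` (united
#'   consensus span, bp).
#' @param hotspots list: `n`, `width`, `multiplier` (target hotspot ERV
#'   density over the background ERV density), `mode`
#'   (`"independent-insertion"` or `"segmental-duplication"`),
#'   `erv_subfamilies` (NULL = lineage-specific ERVKs).
#' @param upstream_bias list: `subfamily` (NULL = no plant), `factor`,
#'   `window_bp`.
#' @param genes list: `n`, `coding_frac`, `lncRNA_frac`, `kznf` sub-list
#'   (`n_clusters`, `genes_per_cluster` (even), `hotspot_frac`,
#'   `div_mean_hotspot`, `div_mean_other`, `div_sd`).
#' @param sd list: `n`, `width` for free-floating SD intervals (SD-mode
#'   hotspots emit their own covering SDs).
#' @param allow_overlap place elements without rejection sampling (used for
#'   large calibration genomes where only annotation order matters).
#' @param max_place_tries rejection-sampling retry cap per element; cap
#'   exhaustion is an error.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5,
                       chromosome_length = 2e6,
                       subfamilies = default_subfamilies(),
                       interruptions = list(n = 50,
                                            host_subfamily = "L1_Pman1",
                                            erv_subfamilies = NULL,
                                            cons_total_range = c(5500, 6300)),
                       hotspots = list(n = 5, width = 1e5, multiplier = 2.5,
                                       mode = "independent-insertion",
                                       erv_subfamilies = NULL),
                       upstream_bias = list(subfamily = NULL, factor = 1,
                                            window_bp = 5000),
                       genes = list(n = 400, coding_frac = 0.7,
                                    lncRNA_frac = 0.15,
                                    kznf = list(n_clusters = 4,
                                                genes_per_cluster = 24,
                                                hotspot_frac = 0.5,
                                                div_mean_hotspot = 17.2,
                                                div_mean_other = 22.2,
                                                div_sd = 5)),
                       sd = list(n = 0, width = 2e4),
                       allow_overlap = FALSE,
                       max_place_tries = 200) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              subfamilies = subfamilies, interruptions = interruptions,
              hotspots = hotspots, upstream_bias = upstream_bias,
              genes = genes, sd = sd, allow_overlap = allow_overlap,
              max_place_tries = max_place_tries)
  class(cfg) <- "sim_config"
  cfg
}

#' Strip all planted structure from a configuration
#'
#' Returns the matched null configuration used for calibration runs: no
#' interruptions, no hotspot density multiplier, no upstream bias, no KZNF
#' age shift, no SDs. Seeds and community composition are preserved;
#' idempotent.
#'
#' @param base a [sim_config()].
#' @return a [sim_config()].
#' @export
null_config <- function(base) {
  stopifnot(inherits(base, "sim_config"))
  base$interruptions$n <- 0
  base$hotspots$n <- 0
  base$upstream_bias$subfamily <- NULL
  base$upstream_bias$factor <- 1
  base$genes$kznf$hotspot_frac <- 0
  base$genes$kznf$div_mean_hotspot <- base$genes$kznf$div_mean_other
  base$sd$n <- 0
  base
}

#' A small configuration qualitatively echoing the deer-mouse landscape
#'
#' Young ERVK subfamilies dominate the low-divergence end of the landscape
#' while LINE gains decline below ~15% divergence; hotspots carry colocated
#' lineage-specific KZNF clusters; one ERVK subfamily is planted with an
#' upstream bias.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
paperlike_config <- function(seed = 1L) {
  sub <- default_subfamilies()
  ## young, expanded lineage-specific ERVKs; declining recent LINE and SINE
  ## activity, so LTR elements dominate both the genome and its young end
  ervk <- grepl("^Pman_ERVK_", sub$name)
  sub$div_mean[ervk] <- c(3, 5, 7, 9, 11, 14)
  sub$div_sd[ervk] <- 2.5
  sub$n_copies[ervk] <- 320
  sub$div_mean[sub$name == "L1_Pman1"] <- 20
  sub$div_sd[sub$name == "L1_Pman1"] <- 5
  sub$n_copies[sub$name == "L1_Pman1"] <- 550
  sub$div_mean[sub$name == "B1_Pman"] <- 15
  sub$div_sd[sub$name == "B1_Pman"] <- 5
  sim_config(seed = seed, subfamilies = sub,
             upstream_bias = list(subfamily = "Pman_ERVK_6", factor = 5,
                                  window_bp = 5000))
}

#' Calibration configuration: one tested subfamily, no planted structure
#'
#' Builds a null genome for one permutation-calibration replicate: a
#' dominant LINE subfamily plus a single tested ERV subfamily, and a dense
#' gene complement for the upstream statistic. One tested subfamily per
#' genome keeps calibration replicates independent: with several tested
#' subfamilies in one genome, each subfamily's elements sit in the others'
#' permutation contexts, the resulting p-values are correlated, and a
#' goodness-of-fit test over such replicates misreads the correlation as
#' miscalibration. High copy numbers keep the count statistics'
#' permutation p-values nearly continuous (the tie atom at the count's mode
#' shrinks with the square root of the expected count). Placement allows
#' overlap: only annotation order and region membership enter the
#' calibrated statistics.
#'
#' @param seed integer seed.
#' @param erv_copies copy number of the tested ERV subfamily (default 2000;
#'   vary it across replicates to de-alias the residual discreteness).
#' @return a [sim_config()].
#' @export
calibration_config <- function(seed = 1L, erv_copies = 2000) {
  sub <- rbind(
    data.frame(name = "L1_dom", te_class = "LINE", superfamily = "L1",
               consensus_length = 6400, n_copies = 12000, div_mean = 18,
               div_sd = 6, lineage_specific = TRUE,
               frac_min = 0.05, frac_max = 0.25),
    data.frame(name = "ERVK_cal", te_class = "LTR", superfamily = "ERVK",
               consensus_length = 1500, n_copies = erv_copies, div_mean = 15,
               div_sd = 4, lineage_specific = TRUE,
               frac_min = 0.2, frac_max = 0.6))
  null_config(sim_config(
    seed = seed, n_chromosomes = 5, chromosome_length = 4e6,
    subfamilies = sub,
    genes = list(n = 2000, coding_frac = 0.7, lncRNA_frac = 0.15,
                 kznf = list(n_clusters = 0, genes_per_cluster = 0,
                             hotspot_frac = 0, div_mean_hotspot = 20,
                             div_mean_other = 20, div_sd = 5)),
    allow_overlap = TRUE))
}

## ---- placement machinery ---------------------------------------------------

new_occupancy <- function(chrom_names) {
  occ <- new.env(parent = emptyenv())
  for (ch in chrom_names) assign(ch, list(S = numeric(), E = numeric()), occ)
  occ
}

occ_add <- function(occ, chrom, s, e) {
  cur <- get(chrom, occ)
  assign(chrom, list(S = c(cur$S, s), E = c(cur$E, e)), occ)
}

occ_free <- function(occ, chrom, s, e) {
  cur <- get(chrom, occ)
  !any(s < cur$E & e > cur$S)
}

place_interval <- function(occ, chrom, len, lo, hi, tries, allow_overlap) {
  if (hi - lo < len) return(NA_real_)
  for (t in seq_len(tries)) {
    s <- lo + floor(stats::runif(1) * (hi - lo - len + 1))
    if (allow_overlap || occ_free(occ, chrom, s, s + len)) {
      occ_add(occ, chrom, s, s + len)
      return(s)
    }
  }
  NA_real_
}

trunc_norm <- function(n, mean, sd, lo = 0) pmax(lo, stats::rnorm(n, mean, sd))

## ---- generator -------------------------------------------------------------

#' Generate a synthetic genome with planted ground truth
#'
#' Places TE annotations, genes, and SD intervals according to `config`:
#' background TE copies uniform per chromosome (chromosome chosen
#' proportionally to length; rejection sampling keeps annotations
#' overlap-free unless `allow_overlap`), planted LINE-interruption triples
#' with exactly conjoining consensus coordinates and zero genomic junction
#' gaps, hotspot windows filled to the configured density multiplier, a
#' planted upstream-bias subfamily, and KZNF clusters (optionally colocated
#' with hotspots) together with a pairwise divergence matrix. Identical
#' seeds give identical output, byte for byte once written.
#'
#' @param config a [sim_config()].
#' @return object of class `te_simulation`: list with `config`, `layout`,
#'   `annotations`, `genes`, `sd_intervals`, `kznf_divergence` (matrix or
#'   NULL), and `truth` (planted interruptions, hotspot windows, upstream
#'   plant, KZNF groups, seeds).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_len <- rep(config$chromosome_length, config$n_chromosomes)
  names(chrom_len) <- chrom_names
  layout <- genome_layout(data.frame(name = chrom_names, length = chrom_len))
  occ <- new_occupancy(chrom_names)
  sub <- config$subfamilies
  rows <- list()
  next_id <- 1L
  add_row <- function(chrom, start, end, strand, sfrow, divergence,
                      cons_start, cons_end) {
    id <- next_id
    rows[[length(rows) + 1]] <<- data.frame(
      element_id = id, chrom = chrom, start = start, end = end,
      strand = strand, subfamily = sfrow$name, te_class = sfrow$te_class,
      superfamily = sfrow$superfamily,
      lineage_specific = sfrow$lineage_specific,
      divergence_pct = round(divergence, 2),
      cons_start = cons_start, cons_end = cons_end,
      cons_remaining = sfrow$consensus_length - cons_end,
      stringsAsFactors = FALSE)
    next_id <<- next_id + 1L
    id
  }
  sample_chrom <- function() sample(chrom_names, 1, prob = chrom_len)
  sf_row <- function(name) {
    i <- match(name, sub$name)
    if (is.na(i)) stop("unknown subfamily in config: ", name)
    sub[i, ]
  }
  cap_stop <- function(what)
    stop("placement capacity exhausted while placing ", what,
         "; reduce copy numbers or enlarge the genome")

  ervk_ls <- sub$name[sub$te_class == "LTR" & sub$lineage_specific]
  truth <- list(seed = config$seed)

  ## --- planted hotspot windows (selected before genes so KZNF clusters can
  ##     colocate); grid-aligned so analysis windows line up
  hs_n <- config$hotspots$n
  hs <- NULL
  if (hs_n > 0) {
    width <- config$hotspots$width
    per_chrom <- floor(chrom_len[1] / width)
    slots <- expand.grid(chrom = chrom_names,
                         win = seq_len(per_chrom) - 1,
                         stringsAsFactors = FALSE)
    if (hs_n > nrow(slots)) cap_stop("hotspot windows")
    pick <- slots[sample(nrow(slots), hs_n), , drop = FALSE]
    hs <- data.frame(chrom = pick$chrom, start = pick$win * width,
                     end = pick$win * width + width,
                     mode = config$hotspots$mode, stringsAsFactors = FALSE)
    hs <- hs[order(hs$chrom, hs$start), ]
    rownames(hs) <- NULL
  }
  truth$hotspot_windows <- hs

  ## --- genes (own occupancy; genes may overlap TEs but not each other)
  gocc <- new_occupancy(chrom_names)
  gene_rows <- list()
  kz <- config$genes$kznf
  kznf_meta <- NULL
  gi <- 1L
  add_gene <- function(chrom, start, end, strand, biotype, is_kznf,
                       is_ls, cds) {
    id <- sprintf("g%04d", gi)
    gene_rows[[length(gene_rows) + 1]] <<- data.frame(
      gene_id = id, chrom = chrom, start = start, end = end, strand = strand,
      biotype = biotype, is_kznf = is_kznf, is_lineage_specific = is_ls,
      stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows)]]$cds <<- list(cds)
    gi <<- gi + 1L
    id
  }
  make_cds <- function(start, end) {
    n_ex <- sample(2:4, 1)
    width <- end - start
    ex_s <- sort(start + floor(stats::runif(n_ex) * (width - 300)))
    ex_e <- pmin(ex_s + 100 + floor(stats::runif(n_ex) * 200), end)
    keep <- ex_e > ex_s
    cbind(start = ex_s[keep], end = ex_e[keep])
  }
  ## KZNF clusters
  if (kz$n_clusters > 0) {
    gpc <- 2 * floor(kz$genes_per_cluster / 2)  # even pairing
    n_hot <- round(kz$n_clusters * kz$hotspot_frac)
    if (!is.null(hs) && n_hot > nrow(hs)) n_hot <- nrow(hs)
    if (is.null(hs)) n_hot <- 0
    hot_windows <- if (n_hot > 0) sample(nrow(hs), n_hot) else integer()
    groups <- character(); ids <- character()
    for (cl in seq_len(kz$n_clusters)) {
      in_hot <- cl <= n_hot
      glen_rng <- c(1200, 2200); gap_rng <- c(300, 800)
      need <- gpc * (glen_rng[2] + gap_rng[2])
      if (in_hot) {
        w <- hs[hot_windows[cl], ]
        chrom <- w$chrom
        lo <- w$start; hi <- min(w$end + 2e4, chrom_len[chrom])
      } else {
        chrom <- sample_chrom()
        lo <- 0; hi <- chrom_len[chrom]
        if (!is.null(hs)) {
          ## keep non-hotspot clusters out of hotspot windows
          for (t in 1:50) {
            pos0 <- floor(stats::runif(1) * (hi - need))
            sel <- hs$chrom == chrom & hs$start < pos0 + need & hs$end > pos0
            if (!any(sel)) { lo <- pos0; hi <- pos0 + need; break }
          }
        }
      }
      pos <- lo + floor(stats::runif(1) *
                          max(1, (hi - lo - gpc * (glen_rng[1] + gap_rng[1]))))
      for (g in seq_len(gpc)) {
        glen <- round(stats::runif(1, glen_rng[1], glen_rng[2]))
        if (pos + glen > chrom_len[chrom]) break
        strand <- sample(c("+", "-"), 1)
        id <- add_gene(chrom, pos, pos + glen, strand, "coding", TRUE, TRUE,
                       make_cds(pos, pos + glen))
        occ_add(gocc, chrom, pos, pos + glen)
        ids <- c(ids, id)
        groups <- c(groups, if (in_hot) "hotspot" else "other")
        pos <- pos + glen + round(stats::runif(1, gap_rng[1], gap_rng[2]))
      }
    }
    kznf_meta <- data.frame(gene_id = ids, group = groups,
                            stringsAsFactors = FALSE)
  }
  ## background genes
  n_bg <- config$genes$n
  bty <- sample(c("coding", "lncRNA", "other"), n_bg, replace = TRUE,
                prob = c(config$genes$coding_frac, config$genes$lncRNA_frac,
                         1 - config$genes$coding_frac -
                           config$genes$lncRNA_frac))
  in_hotspot_win <- function(ch, s, e) {
    if (is.null(hs)) return(FALSE)
    sel <- hs$chrom == ch
    any(s < hs$end[sel] & e > hs$start[sel])
  }
  for (g in seq_len(n_bg)) {
    glen <- round(switch(bty[g],
                         coding = stats::runif(1, 3000, 15000),
                         lncRNA = stats::runif(1, 2000, 10000),
                         other = stats::runif(1, 1000, 5000)))
    s <- NA_real_
    for (t in seq_len(config$max_place_tries)) {
      ch <- sample_chrom()
      cand <- floor(stats::runif(1) * (chrom_len[ch] - glen))
      ## ERV hotspots are gene-poor: background genes avoid planted windows
      if (in_hotspot_win(ch, cand, cand + glen)) next
      if (config$allow_overlap || occ_free(gocc, ch, cand, cand + glen)) {
        occ_add(gocc, ch, cand, cand + glen)
        s <- cand
        break
      }
    }
    if (is.na(s)) cap_stop("genes")
    strand <- sample(c("+", "-"), 1)
    cds <- if (bty[g] == "coding") make_cds(s, s + glen) else NULL
    add_gene(ch, s, s + glen, strand, bty[g], FALSE, FALSE, cds)
  }
  genes <- gene_annotations(do.call(rbind, gene_rows))

  ## KZNF pairwise divergence matrix (duplicate pairs within clusters)
  kznf_divergence <- NULL
  if (!is.null(kznf_meta) && nrow(kznf_meta) >= 2) {
    kznf_divergence <- simulate_kznf_matrix(
      kznf_meta, c(hotspot = kz$div_mean_hotspot, other = kz$div_mean_other),
      kz$div_sd)
  }
  truth$kznf <- list(
    meta = kznf_meta,
    planted_shift = kz$div_mean_other - kz$div_mean_hotspot)

  ## --- planted interruption triples
  intr <- config$interruptions
  intr_truth <- list()
  if (intr$n > 0) {
    host <- sf_row(intr$host_subfamily)
    erv_pool <- intr$erv_subfamilies
    if (is.null(erv_pool)) erv_pool <- ervk_ls
    for (k in seq_len(intr$n)) {
      cons_total <- round(stats::runif(1, intr$cons_total_range[1],
                                       min(intr$cons_total_range[2],
                                           host$consensus_length)))
      cut <- round(cons_total * stats::runif(1, 0.25, 0.75))
      erv <- sf_row(sample(erv_pool, 1))
      erv_len <- round(erv$consensus_length * stats::runif(1, 0.5, 0.9))
      lenA <- cut; lenB <- cons_total - cut
      total <- lenA + erv_len + lenB
      placed <- FALSE
      for (t in seq_len(config$max_place_tries)) {
        ch <- sample_chrom()
        s <- place_interval(occ, ch, total, 0, chrom_len[ch],
                            config$max_place_tries, config$allow_overlap)
        if (!is.na(s)) { placed <- TRUE; break }
      }
      if (!placed) cap_stop("planted interruptions")
      strand <- sample(c("+", "-"), 1)
      d_host <- trunc_norm(1, host$div_mean, host$div_sd)
      d_erv <- trunc_norm(1, erv$div_mean, erv$div_sd)
      ## minus-strand fragments appear in mirrored consensus order
      consA <- if (strand == "+") c(1, cut) else c(cut + 1, cons_total)
      consB <- if (strand == "+") c(cut + 1, cons_total) else c(1, cut)
      idA <- add_row(ch, s, s + lenA, strand, host, d_host,
                     consA[1], consA[2])
      erv_cs <- sample(seq_len(erv$consensus_length - erv_len + 1), 1)
      idE <- add_row(ch, s + lenA, s + lenA + erv_len,
                     sample(c("+", "-"), 1), erv, d_erv,
                     erv_cs, erv_cs + erv_len - 1)
      idB <- add_row(ch, s + lenA + erv_len, s + total, strand, host, d_host,
                     consB[1], consB[2])
      intr_truth[[k]] <- data.frame(
        chrom = ch, span_start = s, span_end = s + total, strand = strand,
        line_subfamily = host$name, erv_subfamily = erv$name,
        fragment_ids = paste(idA, idB, sep = ","), erv_id = idE,
        cons_total = cons_total, stringsAsFactors = FALSE)
    }
  }
  truth$interruptions <- if (length(intr_truth)) do.call(rbind, intr_truth)
                         else NULL

  ## --- planted upstream-bias copies
  ub <- config$upstream_bias
  truth$upstream <- NULL
  if (!is.null(ub$subfamily) && ub$factor > 1) {
    sfr <- sf_row(ub$subfamily)
    win <- ub$window_bp
    up <- upstream_regions(genes, layout, win)
    reg_idx <- make_region_index(up)
    merged_bp <- sum(vapply(reg_idx, function(ix) sum(ix$E - ix$S),
                            numeric(1)))
    u <- merged_bp / sum(chrom_len)          # both strand layers together
    expect <- sfr$n_copies * u / 2           # element strand must match too
    n_plant <- min(sfr$n_copies, round(ub$factor * expect))
    planted_ids <- integer()
    for (k in seq_len(n_plant)) {
      len <- round(sfr$consensus_length *
                     stats::runif(1, sfr$frac_min, sfr$frac_max))
      done <- FALSE
      for (t in seq_len(config$max_place_tries)) {
        g <- genes[sample(nrow(genes), 1), ]
        lo <- if (g$strand == "+") max(0, g$start - win) else g$end
        hi <- if (g$strand == "+") g$start
              else min(chrom_len[g$chrom], g$end + win)
        if (hi - lo < len) next
        s <- place_interval(occ, g$chrom, len, lo, hi, 5,
                            config$allow_overlap)
        if (!is.na(s)) {
          cs <- sample(seq_len(sfr$consensus_length - len + 1), 1)
          planted_ids <- c(planted_ids,
                           add_row(g$chrom, s, s + len, g$strand, sfr,
                                   trunc_norm(1, sfr$div_mean, sfr$div_sd),
                                   cs, cs + len - 1))
          done <- TRUE
          break
        }
      }
      if (!done) cap_stop("upstream-biased copies")
    }
    truth$upstream <- list(subfamily = ub$subfamily, factor = ub$factor,
                           n_planted = length(planted_ids),
                           expected_uniform = expect,
                           element_ids = planted_ids)
    sub$n_copies[sub$name == ub$subfamily] <-
      sub$n_copies[sub$name == ub$subfamily] - length(planted_ids)
  }

  ## --- hotspot filling
  if (!is.null(hs)) {
    is_ltr <- sub$te_class == "LTR"
    baseline_density <- sum(sub$n_copies[is_ltr] * sub$consensus_length[is_ltr] *
                              (sub$frac_min[is_ltr] + sub$frac_max[is_ltr]) / 2) /
      sum(chrom_len)
    pool <- config$hotspots$erv_subfamilies
    if (is.null(pool)) pool <- ervk_ls
    for (i in seq_len(nrow(hs))) {
      target_extra <- (config$hotspots$multiplier - 1) * baseline_density *
        (hs$end[i] - hs$start[i])
      added <- 0
      if (hs$mode[i] == "segmental-duplication") {
        sfr <- sf_row(sample(pool, 1))
        len0 <- round(sfr$consensus_length * stats::runif(1, 0.3, 0.5))
        d0 <- trunc_norm(1, sfr$div_mean, sfr$div_sd)
        cs0 <- sample(seq_len(sfr$consensus_length - len0 + 1), 1)
        strand0 <- sample(c("+", "-"), 1)
        while (added < target_extra) {
          s <- place_interval(occ, hs$chrom[i], len0, hs$start[i], hs$end[i],
                              config$max_place_tries, config$allow_overlap)
          if (is.na(s)) break
          add_row(hs$chrom[i], s, s + len0, strand0, sfr,
                  d0 + stats::rnorm(1, 0, 0.05), cs0, cs0 + len0 - 1)
          added <- added + len0
        }
      } else {
        while (added < target_extra) {
          sfr <- sf_row(sample(pool, 1))
          len <- round(sfr$consensus_length *
                         stats::runif(1, sfr$frac_min, sfr$frac_max))
          s <- place_interval(occ, hs$chrom[i], len, hs$start[i], hs$end[i],
                              config$max_place_tries, config$allow_overlap)
          if (is.na(s)) break
          cs <- sample(seq_len(sfr$consensus_length - len + 1), 1)
          add_row(hs$chrom[i], s, s + len, sample(c("+", "-"), 1), sfr,
                  trunc_norm(1, sfr$div_mean, sfr$div_sd), cs, cs + len - 1)
          added <- added + len
        }
      }
    }
  }

  ## --- SD-mode hotspots are themselves segmental duplications; free SDs too
  sd_rows <- list()
  if (!is.null(hs)) {
    for (i in which(hs$mode == "segmental-duplication")) {
      sd_rows[[length(sd_rows) + 1]] <-
        data.frame(chrom = hs$chrom[i], start = hs$start[i], end = hs$end[i],
                   stringsAsFactors = FALSE)
    }
  }
  if (config$sd$n > 0) {
    for (k in seq_len(config$sd$n)) {
      ch <- sample_chrom()
      s <- floor(stats::runif(1) * (chrom_len[ch] - config$sd$width))
      sd_rows[[length(sd_rows) + 1]] <-
        data.frame(chrom = ch, start = s, end = s + config$sd$width,
                   stringsAsFactors = FALSE)
    }
  }
  sd_intervals <- if (length(sd_rows)) do.call(rbind, sd_rows)
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  truth$sd_intervals <- sd_intervals

  ## --- background copies
  for (i in seq_len(nrow(sub))) {
    sfr <- sub[i, ]
    n <- sfr$n_copies
    if (n <= 0) next
    if (config$allow_overlap) {
      ## overlap-tolerant mode: draw all copies of the subfamily at once
      lens <- pmax(30, round(sfr$consensus_length *
                               stats::runif(n, sfr$frac_min, sfr$frac_max)))
      chs <- sample(chrom_names, n, replace = TRUE, prob = chrom_len)
      starts <- floor(stats::runif(n) * (chrom_len[chs] - lens))
      css <- floor(stats::runif(n) *
                     pmax(1, sfr$consensus_length - lens + 1)) + 1
      ids <- next_id + seq_len(n) - 1L
      rows[[length(rows) + 1]] <- data.frame(
        element_id = ids, chrom = chs, start = starts, end = starts + lens,
        strand = sample(c("+", "-"), n, replace = TRUE),
        subfamily = sfr$name, te_class = sfr$te_class,
        superfamily = sfr$superfamily,
        lineage_specific = sfr$lineage_specific,
        divergence_pct = round(trunc_norm(n, sfr$div_mean, sfr$div_sd), 2),
        cons_start = css,
        cons_end = pmin(css + lens - 1, sfr$consensus_length),
        cons_remaining = pmax(0, sfr$consensus_length -
                                pmin(css + lens - 1, sfr$consensus_length)),
        stringsAsFactors = FALSE)
      next_id <- next_id + n
      next
    }
    for (k in seq_len(n)) {
      len <- max(30, round(sfr$consensus_length *
                             stats::runif(1, sfr$frac_min, sfr$frac_max)))
      placed <- FALSE
      for (t in seq_len(config$max_place_tries)) {
        ch <- sample_chrom()
        s <- place_interval(occ, ch, len, 0, chrom_len[ch], 3,
                            config$allow_overlap)
        if (!is.na(s)) {
          cs <- sample(seq_len(max(1, sfr$consensus_length - len + 1)), 1)
          add_row(ch, s, s + len, sample(c("+", "-"), 1), sfr,
                  trunc_norm(1, sfr$div_mean, sfr$div_sd),
                  cs, min(cs + len - 1, sfr$consensus_length))
          placed <- TRUE
          break
        }
      }
      if (!placed) cap_stop(sfr$name)
    }
  }

  annotations <- if (length(rows))
    te_annotations(do.call(rbind, rows), layout) else empty_te_annotations()
  structure(list(config = config, layout = layout, annotations = annotations,
                 genes = genes, sd_intervals = sd_intervals,
                 kznf_divergence = kznf_divergence, truth = truth),
            class = "te_simulation")
}

#' @export
print.te_simulation <- function(x, ...) {
  cat("te_simulation:", nrow(x$annotations), "TE annotations,",
      nrow(x$genes), "genes on", nrow(x$layout$chromosomes),
      "chromosomes (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Simulate a KZNF pairwise divergence matrix
#'
#' Genes are paired within their group in input order; each designated
#' duplicate pair receives a divergence drawn from the group's normal
#' distribution (truncated to [0.5, 39]); all other entries are uniform on
#' [40, 60], so each gene's nearest duplicate is its designated partner.
#'
#' @param meta data.frame with `gene_id` and `group` (`"hotspot"` or
#'   `"other"`); group sizes should be even.
#' @param means named vector: mean divergence per group.
#' @param sd common standard deviation.
#' @return symmetric percent-divergence matrix with gene ids as dimnames.
#' @export
simulate_kznf_matrix <- function(meta, means, sd) {
  n <- nrow(meta)
  m <- matrix(stats::runif(n * n, 40, 60), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  dimnames(m) <- list(meta$gene_id, meta$gene_id)
  for (grp in unique(meta$group)) {
    idx <- which(meta$group == grp)
    pairs <- split(idx, ceiling(seq_along(idx) / 2))
    for (pr in pairs) {
      if (length(pr) == 2) {
        d <- min(39, max(0.5, stats::rnorm(1, means[[grp]], sd)))
        m[pr[1], pr[2]] <- d
        m[pr[2], pr[1]] <- d
      }
    }
  }
  m
}

#' Write a simulated dataset to disk
#'
#' Emits the RepeatMasker-dialect `.out`, the exact TSV dialect, genes as
#' GFF3, the layout TSV, SD intervals as BED3, the KZNF divergence matrix as
#' TSV, and the truth manifest as JSON. Identical simulations produce
#' byte-identical files.
#'
#' @param sim a [simulate_genome()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "te_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(out = file.path(dir, "te.out"),
             tsv = file.path(dir, "te.tsv"),
             genes = file.path(dir, "genes.gff3"),
             layout = file.path(dir, "layout.tsv"),
             sd = file.path(dir, "sd.bed"),
             kznf = file.path(dir, "kznf_divergence.tsv"),
             truth = file.path(dir, "truth.json"))
  write_te_out(sim$annotations, paths["out"])
  write_table(sim$annotations, paths["tsv"])
  write_genes_gff3(sim$genes, paths["genes"])
  write_layout(sim$layout, paths["layout"])
  writeLines(sprintf("%s\t%d\t%d", sim$sd_intervals$chrom,
                     as.integer(sim$sd_intervals$start),
                     as.integer(sim$sd_intervals$end)), paths["sd"])
  if (!is.null(sim$kznf_divergence)) {
    utils::write.table(sim$kznf_divergence, paths["kznf"], sep = "\t",
                       quote = FALSE, col.names = NA)
  } else {
    writeLines(character(), paths["kznf"])
  }
  truth <- sim$truth
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths["truth"])
  invisible(paths)
}

## ---- sequence-level helpers ------------------------------------------------

#' Random nucleotide sequence
#' @param n length in bp.
#' @param gc GC content (default 0.42, rodent-like).
#' @return character scalar.
#' @export
random_seq <- function(n, gc = 0.42) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Mutate a sequence to a target substitution level
#'
#' Substitutes a `pct` percent of positions (chosen without replacement) with
#' a random different base; transitions are favoured 2:1 over each
#' transversion, the usual mammalian bias.
#'
#' @param seq nucleotide string.
#' @param pct percent of positions to substitute.
#' @param protect integer positions never mutated (e.g. alignment edges).
#' @return mutated sequence.
#' @export
mutate_seq <- function(seq, pct, protect = integer()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  eligible <- setdiff(seq_along(chars), protect)
  n_mut <- round(length(chars) * pct / 100)
  if (n_mut == 0) return(seq)
  pos <- sample(eligible, min(n_mut, length(eligible)))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in pos) {
    b <- chars[i]
    if (!b %in% names(transition)) next
    others <- setdiff(c("A", "C", "G", "T"), b)
    weights <- ifelse(others == transition[[b]], 2, 1)
    chars[i] <- sample(others, 1, prob = weights)
  }
  paste(chars, collapse = "")
}

#' Construct an ERV-like element with a diverged LTR pair
#'
#' Builds LTR + internal + LTR, where the two LTRs started identical and each
#' accumulated `ltr_divergence_pct / 2` percent substitutions (so their
#' pairwise identity is about `100 - ltr_divergence_pct`). Substitution
#' positions at the outermost 3 bp of each LTR are protected so local
#' alignment recovers the full repeat.
#'
#' @param ltr_len LTR length (default 300).
#' @param internal_len internal region length (default 1500).
#' @param ltr_divergence_pct total pairwise divergence between the LTRs.
#' @return list with `seq`, `ltr_len`, `internal_len`, `true_identity_pct`.
#' @export
simulate_erv_sequence <- function(ltr_len = 300, internal_len = 1500,
                                  ltr_divergence_pct = 0) {
  ltr0 <- random_seq(ltr_len)
  protect <- c(1:3, (ltr_len - 2):ltr_len)
  half <- ltr_divergence_pct / 2
  ltr5 <- mutate_seq(ltr0, half, protect)
  ltr3 <- mutate_seq(ltr0, half, protect)
  eq <- sum(strsplit(ltr5, "")[[1]] == strsplit(ltr3, "")[[1]])
  list(seq = paste0(ltr5, random_seq(internal_len), ltr3),
       ltr_len = ltr_len, internal_len = internal_len,
       true_identity_pct = 100 * eq / ltr_len)
}

#' Simulate sequence copies of a subfamily
#'
#' Mutated copies of one random consensus; optionally an embedded long ORF
#' (stop-free, ATG-initiated) marking autonomous coding capacity, and
#' optionally N-runs (assembly gaps).
#'
#' @param n number of copies.
#' @param consensus_length consensus length in bp.
#' @param divergence_pct substitution percent per copy.
#' @param orf_codons if > 0, an ORF of this many codons is embedded in the
#'   consensus (and inherited, mutations aside, by copies).
#' @param gap_frac fraction of copies given a 50-bp N-run.
#' @return list with `consensus` and data.frame `copies` (`element_id`,
#'   `seq`, `has_gap`, `is_fulllength`).
#' @export
simulate_subfamily_copies <- function(n, consensus_length = 3000,
                                      divergence_pct = 5, orf_codons = 0,
                                      gap_frac = 0) {
  cons <- random_seq(consensus_length)
  if (orf_codons > 0) {
    start_at <- 100
    ## sample sense codons so only the ORF's own frame is stop-free
    sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")),
                           1, paste, collapse = ""),
                     c("TAA", "TAG", "TGA", "ATG"))
    ## leading stop pins the ORF start to this ATG
    body <- paste0("TAA", "ATG",
                   paste(sample(sense, orf_codons - 1, replace = TRUE),
                         collapse = ""),
                   "TAA")
    cons <- paste0(substr(cons, 1, start_at - 1), body,
                   substr(cons, start_at + nchar(body), consensus_length))
  }
  copies <- lapply(seq_len(n), function(i) {
    s <- mutate_seq(cons, divergence_pct)
    has_gap <- stats::runif(1) < gap_frac
    if (has_gap) {
      at <- sample(nchar(s) - 60, 1)
      s <- paste0(substr(s, 1, at), strrep("N", 50),
                  substr(s, at + 51, nchar(s)))
    }
    data.frame(element_id = i, seq = s, has_gap = has_gap,
               is_fulllength = TRUE, stringsAsFactors = FALSE)
  })
  list(consensus = cons, copies = do.call(rbind, copies))
}
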