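#' TE coverage over genomic features
#'
#' Proportion of feature nucleotides attributed to TEs, per feature class
#' (CDS, lncRNA, gene bodies, and each chromosome) and TE class. With
#' `with_null = TRUE` a per-chromosome uniform re-placement null is run and
#' two one-sided permutation p-values (depletion and enrichment) are attached
#' per feature/TE-class pair.
#'
#' @param annotations [te_annotations()], overlap-resolved.
#' @param genes [gene_annotations()].
#' @param layout [genome_layout()].
#' @param with_null run the permutation null? Default FALSE.
#' @param n_perm permutations for the null (default 100).
#' @param seed integer seed (required when `with_null`).
#' @return data.frame with `feature`, `te_class`, `feature_bp`, `covered_bp`,
#'   `coverage`, and (with null) `p_depletion`, `p_enrichment`.
#' @export
feature_te_coverage <- function(annotations, genes, layout, with_null = FALSE,
                                n_perm = 100, seed = NULL) {
  feats <- feature_ranges(genes, layout)
  te_classes <- sort(unique(annotations$te_class))
  cover_one <- function(te_gr_red, feat) {
    if (!length(feat) || !length(te_gr_red)) return(0)
    sum(IRanges::width(suppressWarnings(
      GenomicRanges::intersect(te_gr_red, feat))))
  }
  rows <- list()
  te_red <- lapply(te_classes, function(cl)
    GenomicRanges::reduce(ann_granges(
      annotations[annotations$te_class == cl, , drop = FALSE])))
  names(te_red) <- te_classes
  for (f in names(feats)) {
    fb <- sum(IRanges::width(feats[[f]]))
    for (cl in te_classes) {
      cb <- cover_one(te_red[[cl]], feats[[f]])
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, te_class = cl, feature_bp = fb, covered_bp = cb,
        coverage = if (fb > 0) cb / fb else 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (with_null) {
    if (is.null(seed)) stop("seed required when with_null = TRUE")
    chrom_len <- chromosome_lengths(annotations, layout)
    null_cov <- array(0, dim = c(n_perm, length(feats), length(te_classes)),
                      dimnames = list(NULL, names(feats), te_classes))
    lens_by_class <- split(annotations$end - annotations$start,
                           annotations$te_class)
    chrom_by_class <- split(annotations$chrom, annotations$te_class)
    set.seed(derive_seed(seed, "feature_te_coverage"))
    for (b in seq_len(n_perm)) {
      for (cl in te_classes) {
        lens <- lens_by_class[[cl]]
        chs <- chrom_by_class[[cl]]
        new_start <- replace_uniform(lens, chrom_len[chs])
        gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
          chs, IRanges::IRanges(new_start + 1, new_start + lens)))
        for (f in names(feats))
          null_cov[b, f, cl] <- cover_one(gr, feats[[f]])
      }
    }
    out$p_depletion <- NA_real_
    out$p_enrichment <- NA_real_
    for (i in seq_len(nrow(out))) {
      null <- null_cov[, out$feature[i], out$te_class[i]]
      out$p_depletion[i] <- (sum(null <= out$covered_bp[i]) + 1) / (n_perm + 1)
      out$p_enrichment[i] <- (sum(null >= out$covered_bp[i]) + 1) / (n_perm + 1)
    }
  }
  rownames(out) <- NULL
  out
}

feature_ranges <- function(genes, layout) {
  cds_list <- list()
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    if (!is.null(cds) && nrow(cds))
      cds_list[[length(cds_list) + 1]] <-
        GenomicRanges::GRanges(genes$chrom[i],
                               IRanges::IRanges(cds[, 1] + 1, cds[, 2]))
  }
  feats <- list(
    CDS = if (length(cds_list))
      GenomicRanges::reduce(do.call(c, cds_list)) else GenomicRanges::GRanges(),
    lncRNA = GenomicRanges::reduce(ann_granges(
      genes[genes$biotype == "lncRNA", , drop = FALSE])),
    gene_body = GenomicRanges::reduce(ann_granges(genes)))
  for (i in seq_len(nrow(layout$chromosomes))) {
    nm <- layout$chromosomes$name[i]
    feats[[nm]] <- GenomicRanges::GRanges(
      nm, IRanges::IRanges(1, layout$chromosomes$length[i]))
  }
  feats
}

#' Nearest-gene distances for TE elements
#'
#' Distance in bp between each element and its nearest gene (0 when they
#' overlap). `mode = "stranded"` restricts candidate genes to those on the
#' element's strand; elements with no candidate gene get NA.
#'
#' @param annotations [te_annotations()].
#' @param genes [gene_annotations()].
#' @param mode `"stranded"` or `"unstranded"`.
#' @return data.frame with `element_id`, `distance`, `mode`.
#' @export
nearest_gene_distances <- function(annotations,
                                   genes, mode = c("stranded", "unstranded")) {
  mode <- match.arg(mode)
  te_gr <- ann_granges(annotations)
  dist <- rep(NA_real_, nrow(annotations))
  if (mode == "unstranded") {
    gg <- ann_granges(genes)
    hits <- suppressWarnings(GenomicRanges::distanceToNearest(te_gr, gg))
    dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  } else {
    for (s in c("+", "-")) {
      qi <- which(annotations$strand == s)
      gsel <- genes[genes$strand == s, , drop = FALSE]
      if (!length(qi) || !nrow(gsel)) next
      hits <- suppressWarnings(
        GenomicRanges::distanceToNearest(te_gr[qi], ann_granges(gsel)))
      dist[qi[S4Vectors::queryHits(hits)]] <- S4Vectors::mcols(hits)$distance
    }
  }
  data.frame(element_id = annotations$element_id, distance = dist,
             mode = mode, stringsAsFactors = FALSE)
}

#' Compare stranded vs unstranded nearest-gene distances
#'
#' Two-sided Mann-Whitney U between the stranded and unstranded distance
#' distributions of the same elements (NA distances dropped).
#'
#' @param annotations,genes as in [nearest_gene_distances()].
#' @return list with `stranded`, `unstranded` (distance tables), `U`, `p`.
#' @export
compare_nearest_gene_modes <- function(annotations, genes) {
  ds <- nearest_gene_distances(annotations, genes, "stranded")
  du <- nearest_gene_distances(annotations, genes, "unstranded")
  mwu <- mann_whitney_u(ds$distance[!is.na(ds$distance)],
                        du$distance[!is.na(du$distance)])
  list(stranded = ds, unstranded = du, U = mwu$U, p = mwu$p)
}

## per-gene 5' upstream windows, clipped to chromosome bounds; NOT merged
upstream_regions <- function(genes, layout, window_bp = 5000) {
  len <- layout$chromosomes$length[match(genes$chrom, layout$chromosomes$name)]
  start <- ifelse(genes$strand == "+", pmax(0, genes$start - window_bp),
                  genes$end)
  end <- ifelse(genes$strand == "+", genes$start,
                pmin(len, genes$end + window_bp))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = end, strand = genes$strand, stringsAsFactors = FALSE)
}

## does [s, e) overlap any of the sorted disjoint intervals [S, E)?
overlaps_sorted <- function(s, e, S, E) {
  if (!length(S)) return(rep(FALSE, length(s)))
  i <- findInterval(s, S)
  inside <- i >= 1 & s < E[pmax(i, 1)]
  nxt <- i + 1
  spans <- nxt <= length(S) & S[pmin(nxt, length(S))] < e
  inside | spans
}

#' Enrichment of TE subfamilies in 5-kb upstream gene regions
#'
#' For each subfamily, counts elements lying (with >= 1 bp overlap) in the
#' `window_bp` region upstream of a gene's transcription start on the same
#' strand as that gene. The expected count is the mean over `n_perm`
#' per-chromosome uniform re-placements of the subfamily's elements. Both the
#' permutation p-value (upper tail) and a two-sided Fisher's exact p
#' (observed vs rounded expected, in/out of regions) are reported; `q`
#' Bonferroni-adjusts the Fisher p over subfamilies, `q_perm` the permutation
#' p.
#'
#' @param annotations [te_annotations()] sorted.
#' @param genes [gene_annotations()].
#' @param layout [genome_layout()].
#' @param window_bp upstream window (default 5000).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed (child seeds per subfamily).
#' @param subfamilies subfamilies to test (default: all in `annotations`).
#' @return data.frame per subfamily: `unit`, `n_elements`, `observed`,
#'   `expected_mean`, `ratio`, `p`, `q`, `p_perm`, `q_perm`, `test`.
#' @export
upstream_enrichment <- function(annotations, genes, layout, window_bp = 5000,
                                n_perm = 1000, seed, subfamilies = NULL) {
  if (missing(seed)) stop("seed must be given explicitly")
  regions <- upstream_regions(genes, layout, window_bp)
  ## merged per (chrom, strand) interval lists for fast overlap counting
  reg_idx <- make_region_index(regions)
  chrom_len <- chromosome_lengths(annotations, layout)
  if (is.null(subfamilies)) subfamilies <- sort(unique(annotations$subfamily))
  rows <- lapply(subfamilies, function(sf) {
    foc <- annotations[annotations$subfamily == sf, , drop = FALSE]
    if (!nrow(foc)) return(NULL)
    obs <- count_in_regions(foc$chrom, foc$start, foc$end, foc$strand, reg_idx)
    lens <- foc$end - foc$start
    set.seed(derive_seed(seed, sf))
    null <- vapply(seq_len(n_perm), function(b) {
      ns <- replace_uniform(lens, chrom_len[foc$chrom])
      count_in_regions(foc$chrom, ns, ns + lens, foc$strand, reg_idx)
    }, numeric(1))
    pv <- permutation_pvalue(obs, null)
    exp_r <- round(pv$null_mean)
    tab <- matrix(c(obs, nrow(foc) - obs, exp_r, nrow(foc) - exp_r), 2,
                  byrow = TRUE)
    fisher_p <- fisher_exact_two_sided(tab)
    cbind(enrichment_row(sf, obs, pv$null_mean, fisher_p, "fisher+permutation"),
          n_elements = nrow(foc), p_perm = pv$p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no elements in any requested subfamily")
  out <- do.call(rbind, rows)
  out$q <- bonferroni(out$p)
  out$q_perm <- bonferroni(out$p_perm)
  rownames(out) <- NULL
  out[, c("unit", "n_elements", "observed", "expected_mean", "ratio",
          "p", "q", "p_perm", "q_perm", "test")]
}

make_region_index <- function(regions) {
  idx <- list()
  for (key in unique(paste(regions$chrom, regions$strand))) {
    sel <- paste(regions$chrom, regions$strand) == key
    r <- GenomicRanges::reduce(IRanges::IRanges(regions$start[sel] + 1,
                                                regions$end[sel]))
    idx[[key]] <- list(S = IRanges::start(r) - 1, E = IRanges::end(r))
  }
  idx
}

count_in_regions <- function(chrom, start, end, strand, reg_idx) {
  total <- 0
  key <- paste(chrom, strand)
  for (k in unique(key)) {
    ix <- reg_idx[[k]]
    if (is.null(ix)) next
    sel <- key == k
    total <- total + sum(overlaps_sorted(start[sel], end[sel], ix$S, ix$E))
  }
  total
}

#' Segmental-duplication confound check for upstream enrichment
#'
#' An apparent upstream enrichment of a subfamily can be manufactured by
#' segmental duplications (SDs) that copied a gene together with its upstream
#' element. For each tested subfamily, SD coverage (bp) within the upstream
#' regions of genes that harbour at least one same-orientation element of the
#' subfamily is compared against `n_perm` per-chromosome re-placements of the
#' SD intervals; subfamilies whose regions are significantly SD-covered are
#' flagged (and should be dropped from the enrichment report).
#'
#' @param sd_intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param annotations [te_annotations()].
#' @param genes [gene_annotations()].
#' @param layout [genome_layout()].
#' @param subfamilies subfamilies to check.
#' @param window_bp upstream window (default 5000).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param alpha flag threshold on the permutation p (default 0.05).
#' @return data.frame per subfamily: `unit`, `n_genes`, `sd_bp_observed`,
#'   `sd_bp_expected`, `p`, `flagged`.
#' @export
sd_confound_check <- function(sd_intervals, annotations, genes, layout,
                              subfamilies, window_bp = 5000, n_perm = 1000,
                              seed, alpha = 0.05) {
  if (missing(seed)) stop("seed must be given explicitly")
  regions <- upstream_regions(genes, layout, window_bp)
  chrom_len <- chromosome_lengths(annotations, layout)
  sd_gr <- if (nrow(sd_intervals))
    GenomicRanges::GRanges(sd_intervals$chrom,
                           IRanges::IRanges(sd_intervals$start + 1,
                                            sd_intervals$end))
    else GenomicRanges::GRanges()
  rows <- lapply(subfamilies, function(sf) {
    foc <- annotations[annotations$subfamily == sf, , drop = FALSE]
    ## genes with >= 1 same-orientation element in their upstream region
    harb <- vapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      any(foc$chrom == r$chrom & foc$strand == r$strand &
            foc$start < r$end & foc$end > r$start)
    }, logical(1))
    reg <- regions[harb, , drop = FALSE]
    if (!nrow(reg))
      return(data.frame(unit = sf, n_genes = 0, sd_bp_observed = 0,
                        sd_bp_expected = 0, p = 1, flagged = FALSE,
                        stringsAsFactors = FALSE))
    reg_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      reg$chrom, IRanges::IRanges(reg$start + 1, reg$end)))
    cover <- function(gr) {
      if (!length(gr)) return(0)
      sum(IRanges::width(GenomicRanges::intersect(GenomicRanges::reduce(gr),
                                                  reg_gr)))
    }
    obs <- cover(sd_gr)
    if (!length(sd_gr)) {
      return(data.frame(unit = sf, n_genes = nrow(reg), sd_bp_observed = 0,
                        sd_bp_expected = 0, p = 1, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    lens <- sd_intervals$end - sd_intervals$start
    set.seed(derive_seed(seed, paste0("sd:", sf)))
    null <- vapply(seq_len(n_perm), function(b) {
      ns <- replace_uniform(lens, chrom_len[sd_intervals$chrom])
      cover(GenomicRanges::GRanges(sd_intervals$chrom,
                                   IRanges::IRanges(ns + 1, ns + lens)))
    }, numeric(1))
    pv <- permutation_pvalue(obs, null)
    data.frame(unit = sf, n_genes = nrow(reg), sd_bp_observed = obs,
               sd_bp_expected = pv$null_mean, p = pv$p,
               flagged = pv$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call ERV hotspots in tiling windows
#'
#' Tiles each chromosome with non-overlapping `window_bp` windows (the
#' trailing partial window keeps its actual length) and computes the
#' proportion of nucleotides attributed to the filtered TEs ("ERV density")
#' and, when genes are given, gene density. A window is a hotspot when its
#' density is at or above the `percentile`-th linearly interpolated quantile
#' of all window densities (and above zero).
#'
#' @param annotations [te_annotations()].
#' @param layout [genome_layout()].
#' @param genes optional [gene_annotations()] for gene density.
#' @param window_bp window size (default 100,000).
#' @param percentile hotspot percentile (default 95).
#' @param te_filter logical vector over annotation rows selecting the TEs
#'   whose density defines hotspots; default LTR-class elements.
#' @return data.frame with `chrom`, `start`, `end`, `erv_density`,
#'   `gene_density`, `is_hotspot`; attribute `threshold`.
#' @export
call_hotspots <- function(annotations, layout, genes = NULL,
                          window_bp = 1e5, percentile = 95,
                          te_filter = NULL) {
  if (is.null(te_filter)) te_filter <- annotations$te_class == "LTR"
  te <- annotations[te_filter, , drop = FALSE]
  wins <- tile_windows(layout, window_bp)
  wins$erv_density <- window_cover(te, wins) / (wins$end - wins$start)
  wins$gene_density <- if (!is.null(genes))
    window_cover(genes, wins) / (wins$end - wins$start) else NA_real_
  thr <- stats::quantile(wins$erv_density, percentile / 100, names = FALSE,
                         type = 7)
  wins$is_hotspot <- wins$erv_density >= thr & wins$erv_density > 0
  attr(wins, "threshold") <- thr
  wins
}

tile_windows <- function(layout, window_bp) {
  rows <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    starts <- seq(0, len - 1, by = window_bp)
    data.frame(chrom = layout$chromosomes$name[i], start = starts,
               end = pmin(starts + window_bp, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## covered bp of (reduced) intervals per window
window_cover <- function(df, wins) {
  if (!nrow(df)) return(numeric(nrow(wins)))
  red <- GenomicRanges::reduce(ann_granges(df))
  win_gr <- GenomicRanges::GRanges(wins$chrom,
                                   IRanges::IRanges(wins$start + 1, wins$end))
  cov <- numeric(nrow(wins))
  hits <- GenomicRanges::findOverlaps(win_gr, red)
  if (length(hits)) {
    ov <- IRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                              red[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(w))] <- as.numeric(w)
  }
  cov
}

#' Neighbour delta-divergence inside vs outside hotspots
#'
#' For consecutive same-chromosome elements of the filtered set (default
#' LTR-class), the statistic is |div(neighbour 1) - div(neighbour 2)|. Pairs
#' whose two members both overlap hotspot windows form the hotspot class;
#' the two classes are compared with the two-sided Mann-Whitney U test.
#' Near-zero deltas inside hotspots are the signature of hotspot formation by
#' segmental duplication; large deltas point to independent insertions.
#'
#' @param annotations [te_annotations()] sorted.
#' @param hotspots output of [call_hotspots()].
#' @param te_filter logical vector selecting elements (default LTR-class).
#' @return list with `pairs` (data.frame: `chrom`, `delta`, `in_hotspot`),
#'   `U`, `p`, `n_in`, `n_out`, `median_in`, `median_out`.
#' @export
neighbor_divergence_delta <- function(annotations, hotspots,
                                      te_filter = NULL) {
  if (is.null(te_filter)) te_filter <- annotations$te_class == "LTR"
  te <- annotations[te_filter, , drop = FALSE]
  hs <- hotspots[hotspots$is_hotspot, , drop = FALSE]
  in_hs <- if (nrow(hs)) {
    key <- split(seq_len(nrow(hs)), hs$chrom)
    vapply(seq_len(nrow(te)), function(i) {
      j <- key[[te$chrom[i]]]
      if (is.null(j)) return(FALSE)
      any(te$start[i] < hs$end[j] & te$end[i] > hs$start[j])
    }, logical(1))
  } else rep(FALSE, nrow(te))
  pairs <- list()
  for (ch in unique(te$chrom)) {
    sel <- which(te$chrom == ch)
    if (length(sel) < 2) next
    a <- sel[-length(sel)]; b <- sel[-1]
    pairs[[length(pairs) + 1]] <- data.frame(
      chrom = ch, delta = abs(te$divergence_pct[a] - te$divergence_pct[b]),
      in_hotspot = in_hs[a] & in_hs[b], stringsAsFactors = FALSE)
  }
  if (!length(pairs)) return(list(pairs = NULL, U = NA, p = NA_real_,
                                  n_in = 0, n_out = 0,
                                  median_in = NA_real_, median_out = NA_real_))
  pr <- do.call(rbind, pairs)
  din <- pr$delta[pr$in_hotspot]; dout <- pr$delta[!pr$in_hotspot]
  if (!length(din) || !length(dout))
    return(list(pairs = pr, U = NA, p = NA_real_, n_in = length(din),
                n_out = length(dout), median_in = stats::median(din),
                median_out = stats::median(dout)))
  mwu <- mann_whitney_u(din, dout)
  list(pairs = pr, U = mwu$U, p = mwu$p, n_in = length(din),
       n_out = length(dout), median_in = stats::median(din),
       median_out = stats::median(dout))
}

#' Gene density vs ERV density association over windows
#'
#' Regresses window gene density on ERV density (ordinary least squares by
#' default; `family = "binomial"` fits a quasibinomial logit weighted by
#' window length). The contract is the coefficient sign and its p-value.
#'
#' @param windows output of [call_hotspots()] with gene densities filled.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @return list with `coefficient`, `p`, `family`, `fit`.
#' @export
gene_erv_density_association <- function(windows,
                                         family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (all(is.na(windows$gene_density)))
    stop("windows carry no gene densities; call call_hotspots() with genes")
  if (family == "gaussian") {
    fit <- stats::lm(gene_density ~ erv_density, data = windows)
    co <- summary(fit)$coefficients
  } else {
    fit <- stats::glm(gene_density ~ erv_density, data = windows,
                      family = stats::quasibinomial(),
                      weights = windows$end - windows$start)
    co <- summary(fit)$coefficients
  }
  coefficient <- co["erv_density", 1]
  p <- if (nrow(co) > 1 && !is.na(co["erv_density", 4]))
    co["erv_density", 4] else NA_real_
  list(coefficient = coefficient, p = p, family = family, fit = fit)
}

#' Flagged-gene content of hotspots
#'
#' Two-sided Fisher's exact test of the 2x2 table (flagged vs other genes) x
#' (in vs out of hotspot windows); "in" means >= 1 bp overlap with a hotspot
#' window. Default flag: lineage-specific KZNFs.
#'
#' @param genes [gene_annotations()].
#' @param hotspots output of [call_hotspots()].
#' @param flag logical vector over genes (default
#'   `is_kznf & is_lineage_specific`).
#' @return one-row data.frame: `n_flagged`, `flagged_in`, `other_in`,
#'   `n_other`, `hotspot_genome_frac`, `ratio`, `p`.
#' @export
hotspot_gene_content <- function(genes, hotspots, flag = NULL) {
  if (is.null(flag)) flag <- genes$is_kznf & genes$is_lineage_specific
  if (!any(flag)) stop("no flagged genes")
  hs <- hotspots[hotspots$is_hotspot, , drop = FALSE]
  in_hs <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- hs$chrom == genes$chrom[i]
    any(genes$start[i] < hs$end[sel] & genes$end[i] > hs$start[sel])
  }, logical(1))
  tab <- matrix(c(sum(flag & in_hs), sum(flag & !in_hs),
                  sum(!flag & in_hs), sum(!flag & !in_hs)), 2, byrow = TRUE)
  frac_in_expected <- sum(!flag & in_hs) / max(1, sum(!flag))
  data.frame(
    n_flagged = sum(flag), flagged_in = tab[1, 1],
    other_in = tab[2, 1], n_other = sum(!flag),
    hotspot_genome_frac = sum(hs$end - hs$start) /
      sum(hotspots$end - hotspots$start),
    ratio = if (frac_in_expected > 0)
      (tab[1, 1] / sum(flag)) / frac_in_expected else Inf,
    p = fisher_exact_two_sided(tab), stringsAsFactors = FALSE)
}
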