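# Independent oracles used to pin expected values. Each is written as a
# direct, brute-force transcription of the definition, deliberately sharing
# no code path with the package implementation.

# per-site classification oracle for CpG-adjusted K2P: transitions detected
# via the purine test, CpG membership via a scan of the ungapped consensus
oracle_kimura <- function(cons, copy, cpg = TRUE) {
  cc <- strsplit(toupper(cons), "")[[1]]
  pp <- strsplit(toupper(copy), "")[[1]]
  nt <- c("A", "C", "G", "T")
  ug_idx <- which(cc != "-")
  cpg_member <- integer(length(cc))
  if (cpg && length(ug_idx) > 1) {
    k <- 0
    for (i in seq_len(length(ug_idx) - 1)) {
      if (cc[ug_idx[i]] == "C" && cc[ug_idx[i + 1]] == "G") {
        k <- k + 1
        cpg_member[ug_idx[i]] <- k
        cpg_member[ug_idx[i + 1]] <- k
      }
    }
  }
  n <- 0; ts_plain <- 0; tv <- 0; ts_cpg_ids <- integer()
  purine <- c("A", "G")
  for (i in seq_along(cc)) {
    if (!(cc[i] %in% nt) || !(pp[i] %in% nt)) next
    n <- n + 1
    if (cc[i] == pp[i]) next
    if ((cc[i] %in% purine) == (pp[i] %in% purine)) {
      if (cpg_member[i] > 0) ts_cpg_ids <- c(ts_cpg_ids, cpg_member[i])
      else ts_plain <- ts_plain + 1
    } else {
      tv <- tv + 1
    }
  }
  p <- (ts_plain + length(unique(ts_cpg_ids)) / 10) / n
  q <- tv / n
  -50 * log((1 - 2 * p - q) * sqrt(1 - 2 * q))
}

# random gapped aligned pair with controlled substitution/gap/N rates
random_aligned_pair <- function(len = 300, sub_rate = 0.1, gap_rate = 0.02,
                                n_rate = 0.01) {
  bases <- c("A", "C", "G", "T")
  cons <- sample(bases, len, replace = TRUE)
  copy <- cons
  mut <- runif(len) < sub_rate
  copy[mut] <- vapply(cons[mut],
                      function(b) sample(setdiff(bases, b), 1), "")
  copy[runif(len) < gap_rate] <- "-"
  copy[runif(len) < n_rate] <- "N"
  cons[runif(len) < gap_rate] <- "-"
  list(cons = paste(cons, collapse = ""), copy = paste(copy, collapse = ""))
}

# full-enumeration two-sided Fisher oracle via the factorial formula
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  ptab <- function(x) exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
                            lfactorial(c2) - lfactorial(n) - lfactorial(x) -
                            lfactorial(r1 - x) - lfactorial(c1 - x) -
                            lfactorial(r2 - c1 + x))
  p_obs <- ptab(a)
  tot <- 0
  for (x in max(0, c1 - r2):min(r1, c1)) {
    px <- ptab(x)
    if (px <= p_obs * (1 + 1e-9)) tot <- tot + px
  }
  min(1, tot)
}

# permutation-enumeration two-sided MWU oracle (symmetric rule on U)
oracle_mwu <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# double-loop nearest-duplicate oracle
oracle_nearest_duplicate <- function(m) {
  ids <- rownames(m)
  out <- data.frame(gene_id = ids, nearest_duplicate_id = NA_character_,
                    nearest_divergence = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    best <- Inf; partner <- NA_character_
    for (j in seq_along(ids)) {
      if (i == j) next
      if (m[i, j] < best ||
          (m[i, j] == best && ids[j] < partner)) {
        best <- m[i, j]; partner <- ids[j]
      }
    }
    out$nearest_duplicate_id[i] <- partner
    out$nearest_divergence[i] <- best
  }
  out
}

# small te_annotations builder for hand-constructed scenarios
make_ann <- function(chrom, start, end, strand = "+", subfamily = "sf",
                     te_class = "LINE", divergence = 10, cons_start = 1,
                     cons_end = NULL, superfamily = "L1",
                     lineage_specific = TRUE, ids = NULL) {
  n <- length(start)
  rep_n <- function(x) rep_len(x, n)
  if (is.null(cons_end)) cons_end <- cons_start + (end - start) - 1
  te_annotations(data.frame(
    element_id = if (is.null(ids)) seq_len(n) else ids,
    chrom = rep_n(chrom), start = start, end = end, strand = rep_n(strand),
    subfamily = rep_n(subfamily), te_class = rep_n(te_class),
    superfamily = rep_n(superfamily),
    lineage_specific = rep_n(lineage_specific),
    divergence_pct = rep_n(divergence),
    cons_start = rep_n(cons_start), cons_end = rep_n(cons_end),
    cons_remaining = 0, stringsAsFactors = FALSE))
}

# compact config used by the segmental-duplication hotspot power runs
sd_hotspot_config <- function(seed) {
  subs <- default_subfamilies()
  subs$n_copies <- round(subs$n_copies * 0.4)
  sim_config(
    seed = seed, n_chromosomes = 2, chromosome_length = 2.5e6,
    subfamilies = subs,
    interruptions = list(n = 0, host_subfamily = "L1_Pman1",
                         erv_subfamilies = NULL,
                         cons_total_range = c(5500, 6300)),
    hotspots = list(n = 3, width = 1e5, multiplier = 2.5,
                    mode = "segmental-duplication", erv_subfamilies = NULL),
    genes = list(n = 80, coding_frac = 0.7, lncRNA_frac = 0.15,
                 kznf = list(n_clusters = 0, genes_per_cluster = 0,
                             hotspot_frac = 0, div_mean_hotspot = 17.2,
                             div_mean_other = 22.2, div_sd = 5)))
}
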