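#' CpG-corrected Kimura 2-parameter divergence
#'
#' Computes K2P divergence between a subfamily consensus and a copy from a
#' gapped pairwise alignment: K = -1/2 ln((1 - 2p - q) sqrt(1 - 2q)), with p
#' and q the transition and transversion proportions over comparable sites
#' (both bases in A/C/G/T; gaps and N excluded). The CpG adjustment follows
#' the standard repeat-annotation convention: at positions inside a consensus
#' CpG dinucleotide, a transition is counted 1/10, and two transitions within
#' the same CpG count as a single (1/10) transition. Transversions always
#' count fully.
#'
#' @param consensus,copy equal-length gapped sequences over A/C/G/T/N/-
#'   (character scalars).
#' @param cpg_correction apply the CpG down-weighting? Default TRUE; with
#'   FALSE this is textbook K2P.
#' @return divergence in percent (100 * K).
#' @export
kimura_cpg_divergence <- function(consensus, copy, cpg_correction = TRUE) {
  cons <- strsplit(toupper(consensus), "")[[1]]
  cp <- strsplit(toupper(copy), "")[[1]]
  if (length(cons) != length(cp))
    stop("consensus and copy must be aligned to equal length")
  ok_chr <- c("A", "C", "G", "T", "N", "-")
  if (!all(cons %in% ok_chr) || !all(cp %in% ok_chr))
    stop("sequences may only contain A, C, G, T, N, -")
  nt <- c("A", "C", "G", "T")
  comparable <- cons %in% nt & cp %in% nt
  n_sites <- sum(comparable)
  if (n_sites < 1) stop("no comparable (ungapped, unambiguous) sites")

  ## consensus CpG dinucleotides: a C whose next non-gap consensus base is G;
  ## cpg_id labels both members of each CpG with a shared id
  cpg_id <- integer(length(cons))
  if (cpg_correction) {
    non_gap <- which(cons != "-")
    bases <- cons[non_gap]
    is_c <- bases == "C"
    nxt_g <- c(bases[-1] == "G", FALSE)
    starts <- which(is_c & nxt_g)
    for (k in seq_along(starts)) {
      cpg_id[non_gap[starts[k]]] <- k
      cpg_id[non_gap[starts[k] + 1]] <- k
    }
  }

  is_transition <- function(a, b)
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  diff_site <- comparable & cons != cp
  ts <- diff_site & is_transition(cons, cp)
  tv <- diff_site & !is_transition(cons, cp)

  ts_weight <- 0
  if (any(ts)) {
    in_cpg <- ts & cpg_id > 0
    ts_weight <- sum(ts & cpg_id == 0)
    if (any(in_cpg)) {
      ## doubly transitioned CpGs collapse to one 1/10 transition
      ts_weight <- ts_weight + length(unique(cpg_id[in_cpg])) / 10
    }
  }
  p <- ts_weight / n_sites
  q <- sum(tv) / n_sites
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0)
    stop("divergence saturated: 1-2p-q or 1-2q not positive")
  100 * (-0.5 * log(w1 * sqrt(w2)))
}

#' Genome occupancy by TE class
#'
#' Per-class occupied bp (union of that class's intervals, so abutting or
#' duplicated intervals are never double counted) and percent of the assembly.
#'
#' @param annotations [te_annotations()], expected overlap-resolved.
#' @param layout [genome_layout()].
#' @return data.frame with `te_class`, `bp`, `pct`.
#' @export
occupancy_by_class <- function(annotations, layout) {
  classes <- c("LINE", "SINE", "LTR", "DNA", "other")
  bp <- vapply(classes, function(cl) {
    sub <- annotations[annotations$te_class == cl, , drop = FALSE]
    if (!nrow(sub)) return(0)
    sum(IRanges::width(GenomicRanges::reduce(ann_granges(sub))))
  }, numeric(1))
  data.frame(te_class = classes, bp = as.numeric(bp),
             pct = 100 * bp / genome_size(layout),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Divergence-binned TE landscape profile
#'
#' Assigns each element's length to the half-open divergence bin
#' `[lo, lo + bin_width)` containing its annotated divergence; divergences at
#' or above `max_div` fall into one overflow bin. This is the classic repeat
#' landscape: per-class genomic bp as a function of CpG-corrected Kimura
#' divergence from the consensus.
#'
#' @param annotations [te_annotations()].
#' @param layout [genome_layout()].
#' @param bin_width bin width in percent (default 1).
#' @param by grouping column: `"te_class"` (default) or `"subfamily"`.
#' @param max_div start of the overflow bin (default 60).
#' @return data.frame with `group`, `bin_lo`, `bin_hi`, `bp`, `pct_genome`;
#'   attribute `genome_size`.
#' @export
divergence_profile <- function(annotations, layout, bin_width = 1,
                               by = c("te_class", "subfamily"), max_div = 60) {
  by <- match.arg(by)
  edges <- seq(0, max_div, by = bin_width)
  bin_lo <- c(edges, max_div)[seq_len(length(edges) + 1)]
  bin <- pmin(floor(annotations$divergence_pct / bin_width),
              length(edges))  # overflow bin index
  bin[annotations$divergence_pct >= max_div] <- length(edges)
  grp <- annotations[[by]]
  len <- annotations$end - annotations$start
  agg <- stats::aggregate(len, by = list(group = grp, bin = bin), FUN = sum)
  out <- data.frame(
    group = agg$group,
    bin_lo = agg$bin * bin_width,
    bin_hi = ifelse(agg$bin >= length(edges), Inf, (agg$bin + 1) * bin_width),
    bp = as.numeric(agg$x), stringsAsFactors = FALSE)
  out$bin_hi[out$bin_lo >= max_div] <- Inf
  out$bin_lo[out$bin_lo >= max_div] <- max_div
  out$pct_genome <- 100 * out$bp / genome_size(layout)
  out <- out[order(out$group, out$bin_lo), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_size") <- genome_size(layout)
  out
}

enrichment_row <- function(unit, observed, expected, p, test, q = NA_real_) {
  data.frame(unit = unit, observed = observed, expected_mean = expected,
             ratio = if (expected > 0) observed / expected
                     else if (observed > 0) Inf else NA_real_,
             p = p, q = q, test = test, stringsAsFactors = FALSE)
}

#' Young-TE composition test
#'
#' Is the focal class overrepresented among the youngest TEs in the genome?
#' Builds the 2x2 table (focal class vs all other classes) x (divergence below
#' `young_threshold` vs not) and applies the two-sided Fisher's exact test.
#' Units are element counts by default; `units = "bp"` weights by element
#' length in kb (rounded).
#'
#' @param annotations [te_annotations()].
#' @param young_threshold divergence cutoff in percent (default 1).
#' @param focal_class one of LINE/SINE/LTR/DNA/other.
#' @param units `"elements"` (default) or `"bp"`.
#' @return one-row enrichment data.frame (`unit`, `observed`, `expected_mean`,
#'   `ratio`, `p`, `q`, `test`).
#' @export
young_te_enrichment <- function(annotations, young_threshold = 1,
                                focal_class = "LTR",
                                units = c("elements", "bp")) {
  units <- match.arg(units)
  focal <- annotations$te_class == focal_class
  if (!any(focal)) stop("no elements of focal class ", focal_class)
  young <- annotations$divergence_pct < young_threshold
  w <- if (units == "elements") rep(1, nrow(annotations))
       else round((annotations$end - annotations$start) / 1000)
  tab <- matrix(c(sum(w[focal & young]), sum(w[focal & !young]),
                  sum(w[!focal & young]), sum(w[!focal & !young])),
                nrow = 2, byrow = TRUE)
  p <- fisher_exact_two_sided(tab)
  expected <- sum(tab[1, ]) * sum(tab[, 1]) / sum(tab)
  enrichment_row(focal_class, tab[1, 1], expected, p, "fisher")
}

#' Ancient-LINE representation between two genomes
#'
#' Splits each genome's LINE complement into ancient shared subfamilies
#' (`subfamily %in% ancient_labels`) versus the rest, reports bp proportions,
#' and tests the element-count composition difference with the two-sided
#' Fisher's exact test.
#'
#' @param annotations_a,annotations_b [te_annotations()] for the two genomes.
#' @param ancient_labels character vector of ancient LINE subfamily names; if
#'   empty, proportions are 0 and the test is skipped with a warning.
#' @return list with `proportions` (data.frame per genome: ancient bp, total
#'   LINE bp, pct) and `p`.
#' @export
ancient_line_comparison <- function(annotations_a, annotations_b,
                                    ancient_labels) {
  split_one <- function(ann) {
    lines <- ann[ann$te_class == "LINE", , drop = FALSE]
    anc <- lines$subfamily %in% ancient_labels
    len <- lines$end - lines$start
    c(n_ancient = sum(anc), n_other = sum(!anc),
      bp_ancient = sum(len[anc]), bp_total = sum(len))
  }
  a <- split_one(annotations_a); b <- split_one(annotations_b)
  prop <- data.frame(
    genome = c("a", "b"),
    ancient_bp = c(a["bp_ancient"], b["bp_ancient"]),
    line_bp = c(a["bp_total"], b["bp_total"]),
    ancient_pct = 100 * c(
      if (a["bp_total"] > 0) a["bp_ancient"] / a["bp_total"] else 0,
      if (b["bp_total"] > 0) b["bp_ancient"] / b["bp_total"] else 0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!length(ancient_labels)) {
    warning("ancient_labels is empty; Fisher test skipped")
    return(list(proportions = prop, p = NA_real_))
  }
  tab <- matrix(c(a["n_ancient"], a["n_other"],
                  b["n_ancient"], b["n_other"]), nrow = 2, byrow = TRUE)
  list(proportions = prop, p = fisher_exact_two_sided(tab))
}
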