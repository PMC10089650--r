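#' Detect ERV insertions that interrupt LINEs
#'
#' Scans each chromosome for ordered runs `fragA ... (ERV elements only) ...
#' fragB` in which the two LINE fragments share subfamily and strand and
#' conjoin at the correct coordinates with respect to their subfamily
#' consensus: on the plus strand `|cons_start(B) - cons_end(A) - 1| <=
#' cons_gap_tol`, mirror-reversed on the minus strand. The genomic interval
#' between the fragments must be covered by ERV (LTR-class) annotations, with
#' at most `genomic_gap_tol` unannotated bp at any junction.
#'
#' In strict mode (the full-length census) a call must consist of exactly two
#' LINE fragments, no non-ERV annotation may sit between them, chains of more
#' than two conjoining fragments are discarded, and only reconstructions whose
#' united consensus span exceeds 5,000 bp (a full-length LINE) are returned.
#' Relaxed mode chains fragments transitively and also returns `fragmented`
#' calls.
#'
#' @param annotations [te_annotations()] sorted by (chrom, start) and
#'   overlap-resolved; unsorted input is an error.
#' @param cons_gap_tol tolerated consensus-coordinate gap at a junction
#'   (default 100 bp).
#' @param genomic_gap_tol tolerated unannotated bp at each genomic junction
#'   (default 50 bp).
#' @param strict strict census mode (default TRUE).
#' @param full_length_bp consensus span defining a full-length LINE (default
#'   5000).
#' @return data.frame of interruption calls: `line_subfamily`,
#'   `line_fragment_ids`, `erv_ids` (comma-separated id lists), `chrom`,
#'   `span_start`, `span_end`, `conjoined_cons_len`, `cons_gap_bp`,
#'   `n_fragments`, `classification`.
#' @export
detect_interruptions <- function(annotations, cons_gap_tol = 100,
                                 genomic_gap_tol = 50, strict = TRUE,
                                 full_length_bp = 5000) {
  if (!nrow(annotations)) return(empty_interruptions())
  if (!is_sorted_ann(annotations))
    stop("annotations must be sorted by (chrom, start)")
  calls <- list()
  for (chrom in unique(annotations$chrom)) {
    sub <- annotations[annotations$chrom == chrom, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3) next
    is_line <- sub$te_class == "LINE"
    is_erv <- sub$te_class == "LTR"
    consumed <- logical(n)
    for (i in seq_len(n)) {
      if (!is_line[i] || consumed[i]) next
      ## grow a chain of conjoining fragments starting at i
      chain <- i
      erv_ids <- integer(0)
      cons_gaps <- numeric(0)
      cur <- i
      repeat {
        nxt <- find_next_fragment(sub, cur, is_line, is_erv,
                                  cons_gap_tol, genomic_gap_tol, strict)
        if (is.null(nxt)) break
        chain <- c(chain, nxt$j)
        erv_ids <- c(erv_ids, nxt$erv_ids)
        cons_gaps <- c(cons_gaps, nxt$cons_gap)
        cur <- nxt$j
        if (strict && length(chain) > 2) break
      }
      if (length(chain) < 2) next
      if (strict && length(chain) > 2) {
        ## census excludes LINEs split into more than two fragments
        consumed[chain] <- TRUE
        next
      }
      consumed[chain] <- TRUE
      cons_lo <- min(sub$cons_start[chain])
      cons_hi <- max(sub$cons_end[chain])
      span_len <- cons_hi - cons_lo + 1
      classification <- if (span_len > full_length_bp) "full_length"
                        else "fragmented"
      if (strict && classification != "full_length") next
      calls[[length(calls) + 1]] <- data.frame(
        line_subfamily = sub$subfamily[i],
        line_fragment_ids = paste(sub$element_id[chain], collapse = ","),
        erv_ids = paste(sub$element_id[erv_ids], collapse = ","),
        chrom = chrom,
        span_start = sub$start[chain[1]],
        span_end = sub$end[chain[length(chain)]],
        conjoined_cons_len = span_len,
        cons_gap_bp = paste(cons_gaps, collapse = ","),
        n_fragments = length(chain),
        classification = classification,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_interruptions())
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$span_start), , drop = FALSE]
}

empty_interruptions <- function() {
  data.frame(line_subfamily = character(), line_fragment_ids = character(),
             erv_ids = character(), chrom = character(),
             span_start = numeric(), span_end = numeric(),
             conjoined_cons_len = numeric(), cons_gap_bp = character(),
             n_fragments = integer(), classification = character(),
             stringsAsFactors = FALSE)
}

## next conjoining fragment after index cur, or NULL; checks the interleaving
## elements and both the consensus and genomic junction conditions
find_next_fragment <- function(sub, cur, is_line, is_erv,
                               cons_gap_tol, genomic_gap_tol, strict) {
  n <- nrow(sub)
  j <- cur + 1
  between <- integer(0)
  while (j <= n) {
    if (is_line[j] && sub$subfamily[j] == sub$subfamily[cur] &&
        sub$strand[j] == sub$strand[cur]) {
      if (!length(between)) return(NULL)       # no interruption between
      if (strict && !all(is_erv[between])) return(NULL)
      ervs <- between[is_erv[between]]
      if (!length(ervs)) return(NULL)
      ## consensus conjoining (mirror-reversed on the minus strand)
      cons_gap <- if (sub$strand[cur] == "+")
        sub$cons_start[j] - sub$cons_end[cur] - 1
      else
        sub$cons_start[cur] - sub$cons_end[j] - 1
      if (abs(cons_gap) > cons_gap_tol) return(NULL)
      ## genomic junctions: interval between fragments must be ERV-covered
      if (!junctions_covered(sub$end[cur], sub$start[j],
                             sub$start[ervs], sub$end[ervs],
                             genomic_gap_tol)) return(NULL)
      return(list(j = j, erv_ids = ervs, cons_gap = cons_gap))
    }
    if (is_line[j] && strict &&
        (sub$subfamily[j] != sub$subfamily[cur] ||
         sub$strand[j] != sub$strand[cur])) return(NULL)
    between <- c(between, j)
    j <- j + 1
  }
  NULL
}

## every maximal uncovered run between the two fragments must be small
junctions_covered <- function(left_end, right_start, erv_starts, erv_ends,
                              tol) {
  o <- order(erv_starts)
  erv_starts <- erv_starts[o]; erv_ends <- erv_ends[o]
  pos <- left_end
  for (k in seq_along(erv_starts)) {
    if (erv_starts[k] - pos > tol) return(FALSE)
    pos <- max(pos, erv_ends[k])
  }
  right_start - pos <= tol
}

#' Per-subfamily enrichment of ERVs inside LINEs, by permutation
#'
#' For each ERV (LTR-class) subfamily, the observed statistic is the number of
#' its elements directly flanked on both sides by LINE fragments of one and
#' the same subfamily and strand (the interruption flanking criterion without
#' the full-length requirement). The null re-places that subfamily's elements
#' uniformly on their chromosomes, preserving lengths and counts, with all
#' other annotations fixed, and recomputes the statistic `n_perm` times.
#' p = (#\{null >= observed\} + 1)/(n_perm + 1); Q is Bonferroni over tested
#' subfamilies; the enrichment ratio is observed over the null mean.
#'
#' @param annotations [te_annotations()] sorted and overlap-resolved.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed; child seeds are derived per subfamily via
#'   [derive_seed()], so results do not depend on annotation-file order.
#' @param alpha significance level recorded alongside the calls (default
#'   0.01).
#' @param flank_gap_tol maximum bp between an ERV and each flanking LINE
#'   fragment; `Inf` (default) requires only that the nearest annotated
#'   neighbours on both sides be same-subfamily LINEs.
#' @param require_conjoined additionally require the two flanking fragments to
#'   conjoin in consensus coordinates within `cons_gap_tol` (default FALSE).
#' @param cons_gap_tol consensus gap tolerance when `require_conjoined`
#'   (default 100).
#' @param layout optional [genome_layout()]; defaults to per-chromosome spans
#'   of the observed annotations.
#' @return data.frame, one row per ERV subfamily: `unit`, `observed`,
#'   `expected_mean`, `ratio`, `p`, `q`, `test`, `significant`.
#' @export
permutation_erv_in_line <- function(annotations, n_perm = 1000, seed,
                                    alpha = 0.01, flank_gap_tol = Inf,
                                    require_conjoined = FALSE,
                                    cons_gap_tol = 100, layout = NULL) {
  if (missing(seed)) stop("seed must be given explicitly")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is_sorted_ann(annotations))
    stop("annotations must be sorted by (chrom, start)")
  chrom_len <- chromosome_lengths(annotations, layout)
  subfams <- sort(unique(annotations$subfamily[annotations$te_class == "LTR"]))
  rows <- lapply(subfams, function(sf) {
    focal <- annotations$subfamily == sf
    ctx <- annotations[!focal, , drop = FALSE]
    foc <- annotations[focal, , drop = FALSE]
    if (!nrow(foc)) return(NULL)
    ctx_by_chrom <- split(seq_len(nrow(ctx)), ctx$chrom)
    obs <- flank_count(foc$chrom, foc$start, foc$end, foc$strand,
                       ctx, ctx_by_chrom, flank_gap_tol,
                       require_conjoined, cons_gap_tol)
    lens <- foc$end - foc$start
    set.seed(derive_seed(seed, sf))
    null <- vapply(seq_len(n_perm), function(b) {
      new_start <- replace_uniform(lens, chrom_len[foc$chrom])
      flank_count(foc$chrom, new_start, new_start + lens, foc$strand,
                  ctx, ctx_by_chrom, flank_gap_tol,
                  require_conjoined, cons_gap_tol)
    }, numeric(1))
    pv <- permutation_pvalue(obs, null)
    enrichment_row(sf, obs, pv$null_mean, pv$p, "permutation")
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(unit = character(), observed = numeric(),
                      expected_mean = numeric(), ratio = numeric(),
                      p = numeric(), q = numeric(), test = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bonferroni(out$p)
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}

chromosome_lengths <- function(annotations, layout = NULL) {
  if (!is.null(layout)) {
    len <- layout$chromosomes$length
    names(len) <- layout$chromosomes$name
    return(len)
  }
  tapply(annotations$end, annotations$chrom, max)
}

## count focal elements whose nearest context neighbours on both sides are
## LINE fragments of one same subfamily and strand (vectorised per chromosome)
flank_count <- function(chrom, start, end, strand, ctx, ctx_by_chrom,
                        flank_gap_tol, require_conjoined, cons_gap_tol) {
  total <- 0
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ci <- ctx_by_chrom[[ch]]
    if (is.null(ci) || length(ci) < 2) next
    cs <- ctx$start[ci]; ce <- ctx$end[ci]
    ## context rows are sorted by start within chromosome
    li <- findInterval(start[sel], cs)
    ri <- li + 1
    ok <- li >= 1 & ri <= length(ci)
    if (!any(ok)) next
    lidx <- ci[pmax(li, 1)]; ridx <- ci[pmin(ri, length(ci))]
    good <- ok &
      ctx$te_class[lidx] == "LINE" & ctx$te_class[ridx] == "LINE" &
      ctx$subfamily[lidx] == ctx$subfamily[ridx] &
      ctx$strand[lidx] == ctx$strand[ridx]
    if (is.finite(flank_gap_tol)) {
      good <- good &
        (start[sel] - ctx$end[lidx]) <= flank_gap_tol &
        (ctx$start[ridx] - end[sel]) <= flank_gap_tol
    }
    if (require_conjoined) {
      cons_gap <- ifelse(ctx$strand[lidx] == "+",
                         ctx$cons_start[ridx] - ctx$cons_end[lidx] - 1,
                         ctx$cons_start[lidx] - ctx$cons_end[ridx] - 1)
      good <- good & abs(cons_gap) <= cons_gap_tol
    }
    total <- total + sum(good, na.rm = TRUE)
  }
  total
}
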