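#' Find the LTR pair of an ERV element
#'
#' ERV long terminal repeats are identical at insertion, so percent identity
#' between an element's 5' and 3' LTRs estimates insertion age. The best local
#' alignment (Smith-Waterman via Biostrings; match +1, mismatch -1, gap -2)
#' between a prefix window and a suffix window of the element is taken as the
#' LTR pair; the window is `min(2000, floor(len/3))` bp.
#'
#' @param element_seq nucleotide string (A/C/G/T/N).
#' @param min_ltr_len minimum aligned length to accept (default 100 bp).
#' @param min_identity minimum percent identity to accept (default 80).
#' @return `NULL` if no acceptable pair; otherwise list with `ltr5` and `ltr3`
#'   (1-based [start, end] on the element), `identity_pct`, `aligned_len`.
#' @export
find_ltr_pair <- function(element_seq, min_ltr_len = 100, min_identity = 80) {
  seq <- toupper(element_seq)
  if (grepl("[^ACGTN]", seq)) stop("non-nucleotide characters in element_seq")
  len <- nchar(seq)
  if (len <= 2 * min_ltr_len)
    stop("element shorter than 2 * min_ltr_len")
  window <- min(2000L, as.integer(floor(len / 3)))
  prefix <- substr(seq, 1, window)
  suffix_off <- len - window
  suffix <- substr(seq, suffix_off + 1, len)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(prefix), Biostrings::DNAString(suffix),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  aligned_len <- Biostrings::nchar(al)
  if (aligned_len < min_ltr_len) return(NULL)
  identity <- Biostrings::pid(al)
  if (identity < min_identity) return(NULL)
  pr <- al@pattern@range
  sr <- al@subject@range
  list(ltr5 = c(start = IRanges::start(pr), end = IRanges::end(pr)),
       ltr3 = c(start = suffix_off + IRanges::start(sr),
                end = suffix_off + IRanges::end(sr)),
       identity_pct = identity,
       aligned_len = aligned_len)
}

#' Per-subfamily summary of LTR pair identities
#'
#' @param pairs data.frame with columns `subfamily` and `identity_pct` (one
#'   row per dated element).
#' @return data.frame per subfamily: `n`, `median`, `q1`, `q3`. Subfamilies
#'   with no identities are omitted with a warning.
#' @export
ltr_identity_distribution <- function(pairs) {
  stopifnot(all(c("subfamily", "identity_pct") %in% names(pairs)))
  keep <- !is.na(pairs$identity_pct)
  dropped <- setdiff(unique(pairs$subfamily), unique(pairs$subfamily[keep]))
  if (length(dropped))
    warning("subfamilies without LTR identities omitted: ",
            paste(dropped, collapse = ", "))
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(subfamily = character(), n = integer(),
                      median = numeric(), q1 = numeric(), q3 = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(pairs$identity_pct, pairs$subfamily),
    function(v) {
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3])
    }))
  out <- cbind(data.frame(subfamily = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Find open reading frames
#'
#' Maximal ATG-to-stop spans of at least `min_len_codons` codons (codon count
#' excludes the stop). ORFs whose span contains an ambiguous base (N) are
#' rejected. `frames = "given-strand"` scans the three forward frames;
#' `"six-frame"` also scans the reverse complement.
#'
#' @param seq nucleotide string.
#' @param min_len_codons minimum ORF length in codons (default 100).
#' @param frames `"given-strand"` (default) or `"six-frame"`.
#' @return data.frame with `start`, `end` (1-based inclusive on the input
#'   sequence, stop codon included), `strand`, `frame`, `length_codons`.
#' @export
find_orfs <- function(seq, min_len_codons = 100,
                      frames = c("given-strand", "six-frame")) {
  frames <- match.arg(frames)
  seq <- toupper(seq)
  out <- scan_orfs_fwd(seq, min_len_codons, "+")
  if (frames == "six-frame") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rev_hits <- scan_orfs_fwd(rc, min_len_codons, "-")
    if (nrow(rev_hits)) {
      n <- nchar(seq)
      s <- n - rev_hits$end + 1
      e <- n - rev_hits$start + 1
      rev_hits$start <- s; rev_hits$end <- e
    }
    out <- rbind(out, rev_hits)
  }
  out[order(out$start), , drop = FALSE]
}

scan_orfs_fwd <- function(seq, min_len_codons, strand) {
  stops <- c("TAA", "TAG", "TGA")
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (fr in 0:2) {
    starts0 <- seq(1 + fr, nchar(seq) - 2, by = 3)
    if (!length(starts0)) next
    codons <- substring(seq, starts0, starts0 + 2)
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && is_atg[i]) open_at <- i
      if (!is.na(open_at) && is_stop[i]) {
        n_codons <- i - open_at
        if (n_codons >= min_len_codons) {
          s <- starts0[open_at]; e <- starts0[i] + 2
          if (!any(chars[s:e] == "N")) {
            hits[[length(hits) + 1]] <- data.frame(
              start = s, end = e, strand = strand, frame = fr + 1,
              length_codons = n_codons, stringsAsFactors = FALSE)
          }
        }
        open_at <- NA_integer_
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), length_codons = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Classify an ERV subfamily as autonomous or nonautonomous
#'
#' Mirrors the conservative short-read-assembly rule: a subfamily is called
#' nonautonomous only if at least `min_copies` full-length copies free of
#' assembly gaps and ambiguous nucleotides exist and none of them carries a
#' qualifying ORF. A subfamily is autonomous if any full-length copy carries
#' both `gag` and `pro-pol` evidence (explicit domain labels when supplied;
#' otherwise the ORF length proxy: any ORF of at least `orf_min_codons`
#' codons counts as qualifying machinery). Anything else is ambiguous.
#'
#' @param copies data.frame with columns `element_id`, `seq`, `has_gap`,
#'   `is_fulllength`, and optionally `orf_labels` (comma-separated domain
#'   labels, e.g. `"gag,pro-pol"`).
#' @param min_copies full-length gap-free copies required for a nonautonomous
#'   call (default 5).
#' @param orf_min_codons ORF length proxy threshold in codons (default 200).
#' @return object of class `autonomy_call`: list with `status`
#'   (`autonomous`/`nonautonomous`/`ambiguous`), `n_fulllength_gapfree`, and
#'   `orf_evidence` (data.frame).
#' @export
classify_autonomy <- function(copies, min_copies = 5, orf_min_codons = 200) {
  if (!nrow(copies)) stop("no copies supplied")
  stopifnot(all(c("element_id", "seq", "has_gap", "is_fulllength")
                %in% names(copies)))
  has_labels <- "orf_labels" %in% names(copies)
  fl <- copies$is_fulllength & !copies$has_gap
  evidence <- list()
  qualifying <- logical(nrow(copies))
  autonomous_machinery <- logical(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    if (!copies$is_fulllength[i]) next
    labels <- if (has_labels && !is.na(copies$orf_labels[i]) &&
                  nzchar(copies$orf_labels[i]))
      trimws(strsplit(copies$orf_labels[i], ",")[[1]]) else character()
    if (length(labels)) {
      qualifying[i] <- TRUE
      autonomous_machinery[i] <- all(c("gag", "pro-pol") %in% labels)
      evidence[[length(evidence) + 1]] <- data.frame(
        element_id = copies$element_id[i],
        orf_length_codons = NA_integer_,
        label = paste(labels, collapse = ","), stringsAsFactors = FALSE)
    } else if (!is.na(copies$seq[i]) && nzchar(copies$seq[i])) {
      orfs <- find_orfs(copies$seq[i], min_len_codons = orf_min_codons)
      if (nrow(orfs)) {
        qualifying[i] <- TRUE
        evidence[[length(evidence) + 1]] <- data.frame(
          element_id = copies$element_id[i],
          orf_length_codons = max(orfs$length_codons),
          label = "orf-proxy", stringsAsFactors = FALSE)
      }
    }
  }
  orf_evidence <- if (length(evidence)) do.call(rbind, evidence)
    else data.frame(element_id = integer(), orf_length_codons = integer(),
                    label = character(), stringsAsFactors = FALSE)
  n_fl <- sum(fl)
  status <- if (any(autonomous_machinery)) "autonomous"
    else if (n_fl >= min_copies && !any(qualifying[fl])) "nonautonomous"
    else if (!has_labels && any(qualifying & copies$is_fulllength)) "ambiguous"
    else "ambiguous"
  structure(list(status = status, n_fulllength_gapfree = n_fl,
                 orf_evidence = orf_evidence),
            class = "autonomy_call")
}

#' @export
print.autonomy_call <- function(x, ...) {
  cat("autonomy:", x$status, "(", x$n_fulllength_gapfree,
      "full-length gap-free copies,", nrow(x$orf_evidence), "ORF records )\n")
  invisible(x)
}

#' Flag elements eligible for machinery screening
#'
#' Internal-machinery (ORF/domain) screening is restricted to LINE elements
#' longer than 2,700 bp and LTR elements longer than 5,000 bp; other elements
#' are too short to encode complete machinery.
#'
#' @param annotations [te_annotations()].
#' @param line_min_bp,ltr_min_bp length cutoffs (defaults 2700 and 5000).
#' @return logical vector, one element per annotation row.
#' @export
machinery_screen_candidates <- function(annotations, line_min_bp = 2700,
                                        ltr_min_bp = 5000) {
  len <- annotations$end - annotations$start
  (annotations$te_class == "LINE" & len > line_min_bp) |
    (annotations$te_class == "LTR" & len > ltr_min_bp)
}

#' Full-length test against a subfamily consensus
#'
#' A copy is full length when its length is within `tol_frac` of the
#' consensus length and it starts within `edge_tol` bp of the consensus start
#' and ends within `edge_tol` bp of the consensus end.
#'
#' @param annotations [te_annotations()].
#' @param consensus_length named numeric vector: consensus length per
#'   subfamily.
#' @param tol_frac length tolerance as a fraction (default 0.10).
#' @param edge_tol maximum missing consensus bp at each edge (default 20).
#' @return logical vector.
#' @export
is_full_length <- function(annotations, consensus_length, tol_frac = 0.10,
                           edge_tol = 20) {
  cl <- consensus_length[annotations$subfamily]
  len <- annotations$end - annotations$start
  unname(!is.na(cl) &
           abs(len - cl) <= tol_frac * cl &
           annotations$cons_start <= edge_tol + 1 &
           annotations$cons_remaining <= edge_tol)
}
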