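#' Genome layout
#'
#' A minimal description of an assembly: ordered chromosomes with lengths and,
#' optionally, assembly-gap (N-run) intervals. All coordinates in `tescape` are
#' 0-based half-open; external 1-based inclusive formats (RepeatMasker `.out`,
#' GFF3) are converted at the boundary.
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (bp, positive integer-valued).
#' @param gaps optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) giving assembly N-runs.
#' @return An object of class `genome_layout`: a list with elements
#'   `chromosomes` and `gaps`.
#' @examples
#' genome_layout(data.frame(name = c("chr1", "chr2"), length = c(1e6, 5e5)))
#' @export
genome_layout <- function(chromosomes, gaps = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  rownames(chromosomes) <- NULL
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.null(gaps)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(gaps)))
    len <- chromosomes$length[match(gaps$chrom, chromosomes$name)]
    if (anyNA(len) || any(gaps$start < 0) || any(gaps$end > len))
      stop("gap intervals must lie within chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, gaps = gaps),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Total assembly length of a genome layout
#' @param layout a [genome_layout()].
#' @return total bp (numeric).
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chromosomes$length)
}

te_annotation_cols <- c("element_id", "chrom", "start", "end", "strand",
                        "subfamily", "te_class", "superfamily",
                        "lineage_specific", "divergence_pct",
                        "cons_start", "cons_end", "cons_remaining")

#' TE annotation table
#'
#' Canonical container for annotated repeat fragments. Each row is one
#' RepeatMasker-style hit: genomic interval (0-based half-open), strand,
#' subfamily and class/superfamily labels, CpG-corrected Kimura divergence from
#' the subfamily consensus (percent, as carried by the annotation), and 1-based
#' positions of the fragment on the subfamily consensus (`cons_start` <=
#' `cons_end` on both strands; `cons_remaining` is consensus bp past
#' `cons_end`).
#'
#' @param df data.frame carrying the columns named in the description. Missing
#'   optional columns (`superfamily`, `lineage_specific`, `cons_remaining`) are
#'   filled with defaults.
#' @param layout optional [genome_layout()]; if given, intervals are checked
#'   against chromosome bounds.
#' @param sort sort rows by (chrom, start)? Default TRUE.
#' @return data.frame of class `te_annotations`, sorted by (chrom, start).
#' @export
te_annotations <- function(df, layout = NULL, sort = TRUE) {
  stopifnot(is.data.frame(df))
  if (!"superfamily" %in% names(df)) df$superfamily <- NA_character_
  if (!"lineage_specific" %in% names(df)) df$lineage_specific <- FALSE
  if (!"cons_remaining" %in% names(df)) df$cons_remaining <- 0L
  missing_cols <- setdiff(te_annotation_cols, names(df))
  if (length(missing_cols))
    stop("missing TE annotation columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, te_annotation_cols]
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$subfamily <- as.character(df$subfamily)
  df$te_class <- as.character(df$te_class)
  df$superfamily <- as.character(df$superfamily)
  validate_te_annotations(df, layout)
  if (sort) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("te_annotations", "data.frame")
  df
}

validate_te_annotations <- function(df, layout = NULL) {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("start >= end in annotation row(s) ", paste(head(bad), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$cons_start > df$cons_end))
    stop("cons_start > cons_end (consensus coordinates must be normalized)")
  if (any(df$divergence_pct < 0, na.rm = TRUE))
    stop("divergence_pct must be >= 0")
  if (any(df$start < 0))
    stop("genomic coordinates must be >= 0")
  if (!is.null(layout)) {
    len <- layout$chromosomes$length[match(df$chrom, layout$chromosomes$name)]
    if (anyNA(len)) {
      unk <- unique(df$chrom[is.na(len)])
      stop("unknown chromosome(s) for supplied layout: ",
           paste(unk, collapse = ", "))
    }
    if (any(df$end > len))
      stop("annotation interval(s) exceed chromosome length")
  }
  invisible(df)
}

#' Gene annotation table
#'
#' Gene intervals with strand, biotype (`coding`, `lncRNA`, `other`), CDS
#' sub-intervals (list column of two-column matrices, 0-based half-open), and
#' flags for KRAB zinc-finger (KZNF) genes and lineage specificity.
#'
#' @param df data.frame with at least `gene_id`, `chrom`, `start`, `end`,
#'   `strand`. Missing `biotype` defaults to `"other"`, flags to FALSE, `cds`
#'   to empty.
#' @param sort sort rows by (chrom, start)? Default TRUE.
#' @return data.frame of class `gene_annotations`.
#' @export
gene_annotations <- function(df, sort = TRUE) {
  stopifnot(is.data.frame(df),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  if (!"biotype" %in% names(df)) df$biotype <- "other"
  if (!"is_kznf" %in% names(df)) df$is_kznf <- FALSE
  if (!"is_lineage_specific" %in% names(df)) df$is_lineage_specific <- FALSE
  if (!"cds" %in% names(df)) df$cds <- replicate(nrow(df), NULL, simplify = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$biotype <- as.character(df$biotype)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(df$start >= df$end))
    stop("gene start must be < end")
  for (i in seq_len(nrow(df))) {
    cds <- df$cds[[i]]
    if (!is.null(cds) && length(cds)) {
      if (any(cds[, 1] < df$start[i]) || any(cds[, 2] > df$end[i]))
        stop("CDS intervals must lie within the gene body (gene ",
             df$gene_id[i], ")")
    }
  }
  df <- df[, c("gene_id", "chrom", "start", "end", "strand", "biotype",
               "is_kznf", "is_lineage_specific", "cds")]
  if (sort) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotations", "data.frame")
  df
}

## GRanges bridge used by the interval-heavy stages.
ann_granges <- function(df, use_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if (use_strand) df$strand else rep("*", nrow(df)))
}

is_sorted_ann <- function(df) {
  !is.unsorted(order(df$chrom, df$start)) &&
    identical(order(df$chrom, df$start), seq_len(nrow(df)))
}
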