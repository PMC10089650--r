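#' Read TE annotations
#'
#' Parses repeat annotations from either the RepeatMasker `.out` dialect
#' (15-column whitespace body; a 3-line header is tolerated) or the package's
#' own TSV dialect (as written by [write_table()], round-trip exact).
#'
#' `.out` genomic coordinates are 1-based inclusive and converted to the
#' internal 0-based half-open convention. On minus-strand (`C`) hits the three
#' consensus-position columns appear in `(left) end begin` order; they are
#' normalized on read so that `cons_start <= cons_end` always holds.
#' Lineage-specific status is not carried by `.out`; subfamilies whose name
#' starts with one of `lineage_prefixes` are flagged.
#'
#' @param path file path.
#' @param dialect `"out"` or `"tsv"`.
#' @param layout optional [genome_layout()] used to validate chromosome names
#'   and bounds (unknown chromosome is an error).
#' @param lineage_prefixes character vector of subfamily name prefixes marking
#'   lineage-specific subfamilies in the `.out` dialect (default `"Pman"`).
#' @return [te_annotations()] sorted by (chrom, start).
#' @export
read_te_annotations <- function(path, dialect = c("out", "tsv"), layout = NULL,
                                lineage_prefixes = "Pman") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$lineage_specific <- as.logical(df$lineage_specific)
    return(te_annotations(df, layout))
  }
  lines <- readLines(path)
  ## tolerate the standard 3-line header (two column-name lines + blank)
  body_idx <- which(!grepl("^\\s*$", lines) &
                      !grepl("^\\s*(SW|score|bit)\\b", lines, ignore.case = TRUE))
  recs <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14)
      stop("malformed .out line ", i, ": expected >= 14 fields, got ", length(f))
    strand <- f[9]
    if (!strand %in% c("+", "C", "-"))
      stop("malformed .out line ", i, ": bad strand field '", strand, "'")
    gstart <- suppressWarnings(as.numeric(f[6]))
    gend <- suppressWarnings(as.numeric(f[7]))
    if (is.na(gstart) || is.na(gend))
      stop("malformed .out line ", i, ": non-numeric genomic coordinates")
    if (gend < gstart)
      stop("malformed .out line ", i, ": end < start")
    unparen <- function(x) as.numeric(gsub("[()]", "", x))
    if (strand == "+") {
      cs <- as.numeric(f[12]); ce <- as.numeric(f[13]); cl <- unparen(f[14])
    } else {
      ## complement hits print (left) end begin
      cl <- unparen(f[12]); ce <- as.numeric(f[13]); cs <- as.numeric(f[14])
    }
    if (is.na(cs) || is.na(ce) || cs > ce)
      stop("malformed .out line ", i, ": bad consensus coordinates")
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    recs[[k]] <- data.frame(
      element_id = if (length(f) >= 15) as.integer(f[15]) else k,
      chrom = f[5],
      start = gstart - 1, end = gend,
      strand = if (strand == "+") "+" else "-",
      subfamily = f[10],
      te_class = normalize_te_class(cf[1]),
      superfamily = if (length(cf) > 1) cf[2] else NA_character_,
      lineage_specific = any(startsWith(f[10], lineage_prefixes)),
      divergence_pct = as.numeric(f[2]),
      cons_start = cs, cons_end = ce, cons_remaining = cl,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  if (is.null(df)) df <- empty_te_annotations()
  te_annotations(df, layout)
}

normalize_te_class <- function(x) {
  x <- sub("\\?$", "", x)
  ifelse(x %in% c("LINE", "SINE", "LTR", "DNA"), x, "other")
}

empty_te_annotations <- function() {
  df <- data.frame(element_id = integer(), chrom = character(),
                   start = numeric(), end = numeric(), strand = character(),
                   subfamily = character(), te_class = character(),
                   superfamily = character(), lineage_specific = logical(),
                   divergence_pct = numeric(), cons_start = numeric(),
                   cons_end = numeric(), cons_remaining = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("te_annotations", "data.frame")
  df
}

#' Write TE annotations in the RepeatMasker .out dialect
#'
#' Inverse of [read_te_annotations()] for the `.out` dialect (score, del and
#' ins columns are written as 0; divergence is carried). Minus-strand hits are
#' written with the `C` strand code and `(left) end begin` consensus order.
#'
#' @param ann [te_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_out <- function(ann, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query            matching            repeat              position in repeat",
    "score   div. del. ins.  sequence  begin  end        (left)     repeat              class/family      begin  end    (left)     ID",
    "")
  fmt_row <- function(r) {
    cons <- if (r$strand == "+")
      sprintf("%d %d (%d)", as.integer(r$cons_start), as.integer(r$cons_end),
              as.integer(r$cons_remaining))
    else
      sprintf("(%d) %d %d", as.integer(r$cons_remaining), as.integer(r$cons_end),
              as.integer(r$cons_start))
    cls <- if (is.na(r$superfamily)) r$te_class
           else paste0(r$te_class, "/", r$superfamily)
    sprintf("%5d %6.2f %4.1f %4.1f  %s %d %d (%d) %s %s %s %s %d",
            0L, r$divergence_pct, 0, 0, r$chrom,
            as.integer(r$start + 1), as.integer(r$end), 0L,
            if (r$strand == "+") "+" else "C",
            r$subfamily, cls, cons, as.integer(r$element_id))
  }
  body <- if (nrow(ann)) vapply(seq_len(nrow(ann)),
                                function(i) fmt_row(ann[i, ]), character(1))
          else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resolve overlapping annotations in favour of the longer element
#'
#' In every set of mutually overlapping annotations (pairwise overlap of at
#' least `min_overlap_bp`), only the longest element is retained; ties are
#' broken by lower divergence, then by smaller start. Losing elements are
#' removed whole (no truncation), so the output is overlap-free at the
#' threshold. Idempotent; never removes non-overlapping elements.
#'
#' @param annotations [te_annotations()] sorted by (chrom, start).
#' @param min_overlap_bp minimum shared bp for two elements to conflict
#'   (default 1).
#' @return filtered [te_annotations()].
#' @export
resolve_overlaps <- function(annotations, min_overlap_bp = 1) {
  stopifnot(min_overlap_bp >= 1)
  if (!nrow(annotations)) return(annotations)
  if (!is_sorted_ann(annotations))
    stop("annotations must be sorted by (chrom, start)")
  gr <- ann_granges(annotations)
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap_bp,
                                      drop.self = TRUE, drop.redundant = FALSE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n <- nrow(annotations)
  len <- annotations$end - annotations$start
  ## priority: longer first, then lower divergence, then smaller start
  prio <- order(-len, annotations$divergence_pct, annotations$start)
  keep <- logical(n)
  nbrs <- split(sh, factor(qh, levels = seq_len(n)))
  for (i in prio) {
    keep[i] <- !any(keep[nbrs[[i]]])
  }
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("te_annotations", "data.frame")
  out
}

#' Read gene annotations
#'
#' GFF3 and BED are ingested through `rtracklayer`; the package's own TSV
#' dialect (from [write_table()] with `cds` serialized) round-trips exactly.
#' GFF3 rows of type `gene` become records; rows of type `CDS` are attached to
#' their gene via the `gene_id` (or `Parent`) attribute. Biotype is read from
#' the `biotype`/`gene_biotype` attribute (`protein_coding` -> `coding`,
#' `lncRNA` kept, anything else `other`); KZNF and lineage flags are read from
#' the attribute keys given by `attr_kznf`/`attr_lineage` (values `1`, `true`,
#' `yes` are truthy). BED input yields `biotype = "other"` and FALSE flags.
#'
#' @param path file path.
#' @param format `"gff3"`, `"bed"`, or `"tsv"`.
#' @param attr_kznf,attr_lineage GFF3 attribute keys for the two flags.
#' @return [gene_annotations()] sorted by (chrom, start).
#' @export
read_genes <- function(path, format = c("gff3", "bed", "tsv"),
                       attr_kznf = "kznf", attr_lineage = "lineage_specific") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(req %in% names(df)))
      stop("missing mandatory columns: ", paste(setdiff(req, names(df)), collapse = ", "))
    df$cds <- lapply(df$cds, deserialize_intervals)
    df$is_kznf <- as.logical(df$is_kznf)
    df$is_lineage_specific <- as.logical(df$is_lineage_specific)
    return(gene_annotations(df))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (!length(gr)) stop("no records in BED file")
    df <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    if (any(df$strand == "*"))
      stop("BED input must carry strand (BED6)")
    return(gene_annotations(df))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  if (!"type" %in% names(md)) stop("GFF3 input lacks a type column")
  is_gene <- md$type == "gene"
  if (!any(is_gene)) stop("no gene records in GFF3 input")
  gid_of <- function(idx) {
    if ("gene_id" %in% names(md) && !is.na(md$gene_id[idx])) md$gene_id[idx]
    else if ("ID" %in% names(md)) md$ID[idx] else NA_character_
  }
  truthy <- function(v) !is.na(v) & tolower(as.character(v)) %in% c("1", "true", "yes")
  attr_col <- function(key) {
    if (key %in% names(md)) unlist_attr(md[[key]]) else rep(NA_character_, length(gr))
  }
  gidx <- which(is_gene)
  gene_ids <- vapply(gidx, gid_of, character(1))
  biotype_raw <- {
    b <- attr_col("biotype"); b2 <- attr_col("gene_biotype")
    ifelse(is.na(b), b2, b)
  }[gidx]
  biotype <- ifelse(is.na(biotype_raw), "other",
             ifelse(biotype_raw == "protein_coding", "coding",
             ifelse(biotype_raw == "lncRNA", "lncRNA", "other")))
  df <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[gidx],
    start = GenomicRanges::start(gr)[gidx] - 1,
    end = GenomicRanges::end(gr)[gidx],
    strand = as.character(GenomicRanges::strand(gr))[gidx],
    biotype = biotype,
    is_kznf = truthy(attr_col(attr_kznf)[gidx]),
    is_lineage_specific = truthy(attr_col(attr_lineage)[gidx]),
    stringsAsFactors = FALSE)
  ## attach CDS intervals by gene_id / Parent
  cidx <- which(md$type == "CDS")
  cds_parent <- if (length(cidx)) {
    p <- if ("gene_id" %in% names(md)) unlist_attr(md$gene_id)[cidx] else NA
    fallback <- if ("Parent" %in% names(md))
      vapply(md$Parent[cidx], function(v) if (length(v)) as.character(v[1]) else NA_character_,
             character(1)) else rep(NA_character_, length(cidx))
    ifelse(is.na(p), fallback, p)
  } else character()
  df$cds <- lapply(df$gene_id, function(g) {
    j <- cidx[which(cds_parent == g)]
    if (!length(j)) return(NULL)
    cbind(start = GenomicRanges::start(gr)[j] - 1, end = GenomicRanges::end(gr)[j])
  })
  gene_annotations(df)
}

unlist_attr <- function(v) {
  if (is.list(v))
    vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
           character(1))
  else as.character(v)
}

#' Write gene annotations as GFF3
#'
#' Inverse of [read_genes()] for the GFF3 format; biotype and the KZNF /
#' lineage flags are emitted as attributes, CDS intervals as child rows.
#'
#' @param genes [gene_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  biotype_out <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "other")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf("ID=%s;gene_id=%s;biotype=%s;kznf=%d;lineage_specific=%d",
                     g$gene_id, g$gene_id, biotype_out[[g$biotype]],
                     as.integer(g$is_kznf), as.integer(g$is_lineage_specific))
    lines <- c(lines, paste(g$chrom, "tescape", "gene", g$start + 1, g$end,
                            ".", g$strand, ".", attrs, sep = "\t"))
    cds <- g$cds[[1]]
    if (!is.null(cds) && nrow(cds)) {
      for (j in seq_len(nrow(cds))) {
        lines <- c(lines, paste(g$chrom, "tescape", "CDS", cds[j, 1] + 1,
                                cds[j, 2], ".", g$strand, "0",
                                sprintf("Parent=%s;gene_id=%s", g$gene_id, g$gene_id),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

serialize_intervals <- function(x) {
  if (is.null(x) || !length(x)) return("")
  paste(sprintf("%d-%d", as.integer(x[, 1]), as.integer(x[, 2])), collapse = ";")
}

deserialize_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  cbind(start = as.numeric(vapply(parts, `[`, "", 1)),
        end = as.numeric(vapply(parts, `[`, "", 2)))
}

#' Round-trip TSV emitter for result tables
#'
#' Writes any tescape record table (TE annotations, gene annotations,
#' enrichment results, hotspot windows, ...) as TSV such that reading it back
#' with [read_table()] (or the matching typed reader) reproduces the input.
#' List columns of intervals (gene `cds`) are serialized as
#' `start-end;start-end`.
#'
#' @param records data.frame (possibly zero rows; a header-only file is then
#'   written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records)
  for (nm in names(df)) {
    if (is.list(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], serialize_intervals, character(1))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read/write a genome layout as TSV
#'
#' Two-column `name`/`length` table; gap intervals, when present, are stored in
#' a companion block prefixed with `#gap`.
#' @param layout a [genome_layout()].
#' @param path file path.
#' @return `read_layout`: a [genome_layout()]; `write_layout`: `path`.
#' @export
write_layout <- function(layout, path) {
  lines <- c("name\tlength",
             sprintf("%s\t%d", layout$chromosomes$name,
                     as.integer(layout$chromosomes$length)))
  if (!is.null(layout$gaps) && nrow(layout$gaps)) {
    lines <- c(lines, sprintf("#gap\t%s\t%d\t%d", layout$gaps$chrom,
                              as.integer(layout$gaps$start),
                              as.integer(layout$gaps$end)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  gap_lines <- grep("^#gap\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#gap")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  gaps <- NULL
  if (length(gap_lines)) {
    parts <- do.call(rbind, strsplit(gap_lines, "\t", fixed = TRUE))
    gaps <- data.frame(chrom = parts[, 2], start = as.numeric(parts[, 3]),
                       end = as.numeric(parts[, 4]), stringsAsFactors = FALSE)
  }
  genome_layout(df, gaps)
}
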