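#' Nearest-duplicate divergence per gene
#'
#' KZNF families evolve by birth-death duplication, so each gene's most recent
#' duplicate is the gene with the lowest pairwise divergence to it. Given a
#' symmetric pairwise divergence matrix (percent; zero diagonal; gene ids as
#' dimnames), returns each gene's minimal off-diagonal divergence and partner;
#' ties broken by lexicographically smaller partner id.
#'
#' @param divergence_matrix symmetric numeric matrix with gene ids as
#'   dimnames; asymmetry beyond 1e-9 is an error.
#' @param dedupe_pairs count each mutual pair once instead of per gene
#'   (default FALSE).
#' @return data.frame with `gene_id`, `nearest_duplicate_id`,
#'   `nearest_divergence`.
#' @export
nearest_duplicate_divergence <- function(divergence_matrix,
                                         dedupe_pairs = FALSE) {
  m <- as.matrix(divergence_matrix)
  if (nrow(m) != ncol(m) || nrow(m) < 2)
    stop("divergence matrix must be square with >= 2 genes")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m)))
    stop("divergence matrix must carry gene ids as dimnames")
  if (max(abs(m - t(m))) > 1e-9)
    stop("divergence matrix is asymmetric beyond tolerance 1e-9")
  ids <- rownames(m)
  diag(m) <- Inf
  out <- data.frame(gene_id = ids, nearest_duplicate_id = NA_character_,
                    nearest_divergence = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- m[i, ]
    best <- min(v)
    cand <- ids[which(abs(v - best) <= 0)]
    out$nearest_duplicate_id[i] <- sort(cand)[1]
    out$nearest_divergence[i] <- best
  }
  if (dedupe_pairs) {
    key <- apply(cbind(out$gene_id, out$nearest_duplicate_id), 1,
                 function(r) paste(sort(r), collapse = "|"))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Annotate KZNF records with hotspot membership
#'
#' A gene is "in hotspot" when its interval intersects any hotspot window by
#' at least 1 bp.
#'
#' @param records output of [nearest_duplicate_divergence()].
#' @param genes [gene_annotations()] carrying the same gene ids.
#' @param hotspots output of [call_hotspots()].
#' @return `records` with an `in_hotspot` logical column.
#' @export
kznf_hotspot_membership <- function(records, genes, hotspots) {
  hs <- hotspots[hotspots$is_hotspot, , drop = FALSE]
  idx <- match(records$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("records contain gene ids absent from genes")
  records$in_hotspot <- vapply(idx, function(i) {
    sel <- hs$chrom == genes$chrom[i]
    any(genes$start[i] < hs$end[sel] & genes$end[i] > hs$start[sel])
  }, logical(1))
  records
}

#' Compare duplicate ages of hotspot vs non-hotspot KZNFs
#'
#' Two-sided Mann-Whitney U on `nearest_divergence` between genes inside and
#' outside ERV hotspots. Lower divergence means younger duplicates.
#'
#' @param records data.frame with `nearest_divergence` and `in_hotspot`.
#' @return list with `U`, `p`, `n_in`, `n_out`, `median_in`, `median_out`.
#' @export
compare_hotspot_ages <- function(records) {
  stopifnot(all(c("nearest_divergence", "in_hotspot") %in% names(records)))
  din <- records$nearest_divergence[records$in_hotspot]
  dout <- records$nearest_divergence[!records$in_hotspot]
  if (!length(din) || !length(dout))
    stop("both hotspot and non-hotspot groups must be non-empty")
  mwu <- mann_whitney_u(din, dout)
  list(U = mwu$U, p = mwu$p, n_in = length(din), n_out = length(dout),
       median_in = stats::median(din), median_out = stats::median(dout))
}

#' Kernel-density peaks of divergence distributions
#'
#' Gaussian KDE with Scott's bandwidth (sd * n^(-1/5)) evaluated on a
#' regular grid over [0, max + 3 bw]; the peak is the grid argmax (ties take
#' the lower value). Used to compare the age peaks of hotspot KZNF
#' duplicates against ERVK within-subfamily divergences.
#'
#' @param samples_by_group named list of percent-divergence vectors.
#' @param grid_step grid spacing in percent (default 0.1).
#' @return named numeric vector of peak locations.
#' @export
kde_peaks <- function(samples_by_group, grid_step = 0.1) {
  stopifnot(is.list(samples_by_group), length(names(samples_by_group)) > 0)
  vapply(samples_by_group, function(x) {
    x <- as.numeric(x)
    if (!length(x)) return(NA_real_)
    if (stats::sd(x) == 0 || length(x) < 2) return(x[1])
    bw <- stats::sd(x) * length(x)^(-1 / 5)
    grid_to <- max(x) + 3 * bw
    n_grid <- max(2L, ceiling(grid_to / grid_step) + 1L)
    d <- stats::density(x, bw = bw, from = 0, to = grid_to, n = n_grid)
    d$x[which.max(d$y)]
  }, numeric(1))
}
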