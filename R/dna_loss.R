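#' DNA-loss coefficient k
#'
#' Under the exponential decay model E = A e^(-kt) — E extant ancestral DNA,
#' A ancestral assembly size, t time in million years — the loss coefficient
#' is k = ln(A/E)/t per My. The rodent-literature convention is A = 2.8 Gb
#' and t = 100 My.
#'
#' @param E_bp extant ancestral DNA (bp, > 0).
#' @param A_bp ancestral assembly size (bp, > 0).
#' @param t_my time in million years (> 0).
#' @return object of class `loss_coefficient`: list with `E_bp`, `A_bp`,
#'   `t_my`, `k`.
#' @examples
#' compute_k(2.8e9 * exp(-1), 2.8e9, 100)$k  # 0.01
#' @export
compute_k <- function(E_bp, A_bp, t_my) {
  if (E_bp <= 0) stop("E_bp must be positive")
  if (A_bp <= 0) stop("A_bp must be positive")
  if (t_my <= 0) stop("t_my must be positive")
  structure(list(E_bp = E_bp, A_bp = A_bp, t_my = t_my,
                 k = log(A_bp / E_bp) / t_my),
            class = "loss_coefficient")
}

#' @export
print.loss_coefficient <- function(x, ...) {
  cat(sprintf("DNA loss coefficient k = %.4g /My (E = %.4g bp, A = %.4g bp, t = %g My)\n",
              x$k, x$E_bp, x$A_bp, x$t_my))
  invisible(x)
}

#' Extant ancestral DNA from a repeat annotation
#'
#' Two readings of "ancestral DNA remaining" are supported. The conventional
#' reading takes the extant assembly minus the bp attributed to
#' lineage-specific TEs (everything not gained on the terminal branch). The
#' literal reading takes bp attributed to ancient shared TEs minus bp
#' attributed to lineage-specific TEs; it can be negative, in which case an
#' error directs the user to the conventional mode. Both quantities are
#' attached as attributes whichever mode is returned.
#'
#' @param annotations [te_annotations()], overlap-resolved.
#' @param assembly_bp extant assembly size in bp.
#' @param ancient_labels subfamily names counted as ancient shared TEs.
#' @param mode `"conventional"` (default) or `"literal"`.
#' @return E in bp (numeric scalar) with attributes `conventional` and
#'   `literal`.
#' @export
extant_ancestral_dna <- function(annotations, assembly_bp, ancient_labels,
                                 mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  union_bp <- function(sub) {
    if (!nrow(sub)) return(0)
    sum(IRanges::width(GenomicRanges::reduce(ann_granges(sub))))
  }
  ls_bp <- union_bp(annotations[annotations$lineage_specific, , drop = FALSE])
  anc_bp <- union_bp(annotations[annotations$subfamily %in% ancient_labels, ,
                                 drop = FALSE])
  conventional <- assembly_bp - ls_bp
  literal <- anc_bp - ls_bp
  if (mode == "literal" && literal <= 0)
    stop("literal reading gives non-positive E (ancient ", anc_bp,
         " bp vs lineage-specific ", ls_bp,
         " bp); use mode = 'conventional'")
  E <- if (mode == "conventional") conventional else literal
  attr(E, "conventional") <- conventional
  attr(E, "literal") <- literal
  E
}
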