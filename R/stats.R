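#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with fixed margins,
#' using the probability-mass rule: the p-value is the sum of probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (relative slack 1e-12 for ties). Any zero margin gives p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2)) # 34/70
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(abs(table - round(table)) > 1e-8))
    stop("table must contain nonnegative integers")
  table <- round(table)
  m <- sum(table[1, ])          # row 1 margin
  n <- sum(table[2, ])          # row 2 margin
  k <- sum(table[, 1])          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2]) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  probs <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(table[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Two-sided Mann-Whitney U test
#'
#' U counts wins of `x` over `y` (ties half). For `n_x + n_y <= 20` without
#' ties, the exact null distribution of U is used; with ties at that size, the
#' p-value is computed by full enumeration of group assignments on midranks.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction. The two-sided p-value is P(|U - mu| >= |u - mu|),
#' exploiting the symmetry of the permutation distribution of U.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest `n_x + n_y` for the exact/enumeration branch
#'   (default 20).
#' @return list with `U`, `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= exact_max && !has_ties) {
    ## exact distribution of U (no ties)
    supp <- 0:(nx * ny)
    probs <- stats::dwilcox(supp, nx, ny)
    p <- sum(probs[abs(supp - mu) >= abs(U - mu) - 1e-9])
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  if (nx + ny <= exact_max) {
    ## ties: enumerate all assignments of the midranks to group x
    idx <- utils::combn(nx + ny, nx)
    Us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = min(1, p), method = "enumeration"))
  }
  ## normal approximation with tie correction + continuity correction
  ntot <- nx + ny
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1))
  sigma2 <- nx * ny / 12 * ((ntot + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-max(z, 0))
  list(U = U, p = min(1, p), method = "normal")
}

#' Bonferroni adjustment
#'
#' q_i = min(1, m * p_i), the correction used throughout the pipeline.
#' @param pvals numeric vector of p-values.
#' @return adjusted q-values, same length.
#' @export
bonferroni <- function(pvals) {
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Permutation p-value with the (r + 1)/(n + 1) convention
#'
#' Upper-tail p-value of an observed count against a simulated null sample,
#' never exactly zero at finite permutation numbers.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics (length = number of
#'   permutations, >= 1).
#' @return list with `p`, `null_mean`, and `ratio` (= observed / null mean;
#'   `Inf` when the null mean is 0 and observed > 0, `NA` when both are 0).
#' @export
permutation_pvalue <- function(observed, null) {
  n <- length(null)
  if (n < 1) stop("need at least one permutation")
  p <- (sum(null >= observed) + 1) / (n + 1)
  nm <- mean(null)
  ratio <- if (nm > 0) observed / nm else if (observed > 0) Inf else NA_real_
  list(p = p, null_mean = nm, ratio = ratio)
}

#' Derive a child RNG seed from a base seed and a string key
#'
#' Subfamily-level permutation analyses draw their randomness from child seeds
#' obtained by hashing (seed, key), so per-subfamily results do not depend on
#' the order in which subfamilies are processed. Plain 31-polynomial string
#' hash folded with the seed modulo 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param key character scalar.
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

## uniform per-chromosome re-placement preserving lengths and chromosome
## assignment; returns new starts (0-based)
replace_uniform <- function(lens, chrom_len) {
  floor(stats::runif(length(lens)) * pmax(chrom_len - lens, 1))
}
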