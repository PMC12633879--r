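# Small statistical primitives shared across modules.

#' Two-sided Fisher's exact test for 2x2 tables, vectorized
#'
#' Computes the two-sided Fisher exact p-value for one or many 2x2 tables
#' with rows `(a, b)` and `(c, d)`. The two-sided p is the standard
#' sum-of-probabilities rule: the total hypergeometric probability of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table (within a small relative slack, as in [stats::fisher.test()]).
#'
#' The conditional distribution is over the first cell `a` given margins,
#' so the work per table is proportional to the smaller first-column or
#' first-row margin; with codon-level counts this is fast enough to test
#' every codon of a transcriptome.
#'
#' @param a,b,c,d Integer vectors (recycled to common length) giving the
#'   cells of each table: row 1 = `(a, b)`, row 2 = `(c, d)`.
#' @return A numeric vector of two-sided p-values. A fully empty table
#'   (all four cells zero) yields `p = 1`.
#' @examples
#' fisher_exact_2x2(2, 98, 2, 98) # identical rows -> 1
#' fisher_exact_2x2(0, 100, 20, 180)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, n))
  b <- as.numeric(rep_len(b, n))
  c <- as.numeric(rep_len(c, n))
  d <- as.numeric(rep_len(d, n))
  if (any(a < 0 | b < 0 | c < 0 | d < 0, na.rm = TRUE)) {
    abort("all table cells must be nonnegative")
  }
  k  <- a + c  # first-column margin
  n1 <- a + b  # row-1 margin
  n2 <- c + d  # row-2 margin
  lo <- pmax(0, k - n2)
  hi <- pmin(k, n1)
  len <- hi - lo + 1
  idx <- rep.int(seq_len(n), len)
  x <- sequence(len, from = lo, by = 1)
  lp <- dhyper(x, n1[idx], n2[idx], k[idx], log = TRUE)
  lobs <- dhyper(a, n1, n2, k, log = TRUE)
  # relative slack matching fisher.test()'s relErr = 1 + 1e-7
  keep <- lp <= lobs[idx] + log(1 + 1e-7)
  p <- rowsum(ifelse(keep, exp(lp), 0), idx)[, 1]
  unname(pmin(p, 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR, as used for every
#' multiple-testing family in this package (per-replicate codon tests,
#' motif cells, per-contrast gene tests). Thin wrapper around
#' [stats::p.adjust()] so the correction used is explicit and testable in
#' one place.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s are propagated.
#' @return Adjusted values, monotone nondecreasing in `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Used to compare relative peak positions between directions. Uses the
#' exact null distribution when both groups have at most `exact_max_n`
#' observations and there are no ties, and the normal approximation with
#' tie correction (and continuity correction) otherwise.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_max_n Largest per-group size for the exact path.
#' @return A one-row tibble with `statistic` (rank-sum W for `x`),
#'   `p_value`, and `exact` (logical, which path was used).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         exact = use_exact)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `hits` marked items when `draws` items
#' are sampled without replacement from a background of `total` items of
#' which `marked` are marked.
#'
#' @param hits Observed number of marked items among the draws.
#' @param marked Number of marked items in the background.
#' @param total Background size.
#' @param draws Number of items drawn.
#' @return Upper-tail p-value `P(X >= hits)`.
#' @export
hypergeom_upper_p <- function(hits, marked, total, draws) {
  if (any(draws > total) || any(marked > total)) {
    abort("'marked' and 'draws' cannot exceed 'total'")
  }
  phyper(hits - 1, marked, total - marked, draws, lower.tail = FALSE)
}

# weighted median (lower-midpoint convention); used by the LAD slope fit
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# One Dirichlet-multinomial draw: `size` counts over categories with
# concentration vector `alpha`. Infinite concentrations fall back to a
# plain multinomial at the normalized weights.
rdirmult <- function(size, alpha, weights = alpha) {
  if (size == 0) return(integer(length(weights)))
  if (any(!is.finite(alpha))) {
    p <- weights / sum(weights)
  } else {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g <- weights
    p <- g / sum(g)
  }
  as.integer(rmultinom(1, size, p))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
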