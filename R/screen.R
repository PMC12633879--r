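# Barcode-screen analysis: native TMM normalization, timepoint-vs-pool
# enrichment, the aneuploid-vs-euploid 2-fold rule, and hit classification.

#' Trimmed mean of M-values normalization factors
#'
#' Native implementation of TMM: for each sample versus the reference
#' (the sample whose 75th count-percentile is closest to the mean), gene
#' log-ratios (M) and average log-abundances (A) are computed on
#' library-size-scaled counts; the most extreme 30% of M values and 5% of
#' A values are trimmed; the factor is the precision-weighted mean of the
#' remaining M values (weights = inverse binomial variances); factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Long count tibble (`gene_id`, `sample_id`, `count`) with
#'   at least two samples.
#' @param log_ratio_trim,abundance_trim Two-sided trim fractions.
#' @return Tibble `sample_id`, `factor`; the reference sample id is stored
#'   in the `"reference"` attribute.
#' @export
tmm_factors <- function(counts, log_ratio_trim = 0.3, abundance_trim = 0.05) {
  wide <- tidyr::pivot_wider(counts, id_cols = "gene_id",
                             names_from = "sample_id", values_from = "count")
  m <- as.matrix(wide[, -1])
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("samples with all-zero counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  # reference: upper-quartile of scaled counts closest to the mean
  f75 <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(f75 - mean(f75)))
  ref <- m[, ref_i]
  ref_lib <- lib[ref_i]

  one_factor <- function(obs, obs_lib) {
    logR <- log2((obs / obs_lib) / (ref / ref_lib))
    absE <- (log2(obs / obs_lib) + log2(ref / ref_lib)) / 2
    v <- (obs_lib - obs) / obs_lib / obs + (ref_lib - ref) / ref_lib / ref
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]
    absE <- absE[fin]
    v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * log_ratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * abundance_trim) + 1
    hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    if (abs(f) < 1e-6) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(m)), function(j) one_factor(m[, j], lib[j]), numeric(1))
  f <- f / exp(mean(log(f)))
  out <- tibble(sample_id = colnames(m), factor = unname(f))
  attr(out, "reference") <- colnames(m)[ref_i]
  out
}

#' Barcode enrichment at a timepoint versus the starting pool
#'
#' Computes, per strain, each gene's log2 fold change of TMM-normalized
#' barcode abundance at `timepoint` versus the starting pool, with a
#' p-value from a moderated two-sample test on log2 normalized abundances
#' across replicates (limma) and BH correction across genes. Externally
#' computed statistics with the same columns can be substituted downstream.
#'
#' @param counts Long barcode count tibble.
#' @param design Sample sheet: `sample_id`, `strain`, `timepoint`,
#'   `replicate`.
#' @param factors TMM factors from [tmm_factors()] (default: computed on
#'   `counts`).
#' @param strain Strain to score.
#' @param timepoint Timepoint contrasted against the pool.
#' @param pool_timepoint Label of the starting-pool samples.
#' @return Tibble `gene_id`, `strain`, `timepoint`, `log2fc`, `p_value`,
#'   `fdr`.
#' @export
enrichment_scores <- function(counts, design, factors = tmm_factors(counts),
                              strain, timepoint, pool_timepoint = "pool") {
  sel <- design[design$strain == strain &
                  design$timepoint %in% c(timepoint, pool_timepoint), ]
  if (!any(sel$timepoint == pool_timepoint)) abort("no pool samples present")
  wide <- tidyr::pivot_wider(counts[counts$sample_id %in% sel$sample_id, ],
                             id_cols = "gene_id",
                             names_from = "sample_id", values_from = "count")
  m <- as.matrix(wide[, -1])
  lib <- colSums(m)
  fct <- setNames(factors$factor, factors$sample_id)[colnames(m)]
  cpm <- t(t(m) / (lib * fct)) * 1e6
  lm2 <- log2(cpm + 0.5)
  grp <- factor(ifelse(sel$timepoint[match(colnames(m), sel$sample_id)] ==
                         pool_timepoint, "pool", "late"),
                levels = c("pool", "late"))
  if (min(table(grp)) < 2) abort("need >= 2 replicates per condition")
  fit <- limma::eBayes(limma::lmFit(lm2, stats::model.matrix(~grp)))
  tibble(gene_id = wide$gene_id, strain = strain, timepoint = timepoint,
         log2fc = fit$coefficients[, 2], p_value = fit$p.value[, 2]) %>%
    mutate(fdr = bh_adjust(.data$p_value))
}

#' Select aneuploid-specific screen hits
#'
#' A gene is a hit iff it is significantly enriched at day 28 versus the
#' pool in the aneuploid (positive log2 fold change, FDR < `fdr_cut`) and
#' its linear enrichment exceeds the euploid's by at least `fold_cut`
#' (`2^(log2fc_aneuploid - log2fc_euploid) >= fold_cut`).
#'
#' @param aneuploid_scores,euploid_scores Per-gene scores from
#'   [enrichment_scores()] at day 28 (shared gene universe).
#' @param fdr_cut FDR threshold in the aneuploid (default 0.1, the relaxed
#'   screen cutoff; 0.05 is the strict alternative).
#' @param fold_cut Minimum linear enrichment difference.
#' @return Tibble of selected genes: `gene_id`, `log2fc_aneuploid`,
#'   `fdr_aneuploid`, `log2fc_euploid`, `linear_diff`.
#' @export
select_hits <- function(aneuploid_scores, euploid_scores,
                        fdr_cut = 0.1, fold_cut = 2.0) {
  j <- inner_join(
    select(aneuploid_scores, "gene_id", log2fc_aneuploid = "log2fc",
           fdr_aneuploid = "fdr"),
    select(euploid_scores, "gene_id", log2fc_euploid = "log2fc"),
    by = "gene_id"
  )
  if (nrow(j) != nrow(aneuploid_scores)) {
    warn("score tables do not share the full gene universe")
  }
  j %>%
    mutate(linear_diff = 2^(.data$log2fc_aneuploid - .data$log2fc_euploid)) %>%
    filter(.data$log2fc_aneuploid > 0,
           .data$fdr_aneuploid < fdr_cut,
           .data$linear_diff >= fold_cut)
}

#' Classify hits as life-span-specific or early-benefit
#'
#' A selected hit is `lifespan_specific` when its aneuploid enrichment at
#' day 28 exceeds its day-1 enrichment more than `fold_cut`-fold
#' (`2^(log2fc_d28 - log2fc_d1) > fold_cut`), indicating a benefit
#' emerging during chronological aging; otherwise it is `early_benefit`
#' (already enriched at day 1).
#'
#' @param hits Output of [select_hits()].
#' @param d1_scores,d28_scores Aneuploid [enrichment_scores()] at day 1
#'   and day 28.
#' @param fold_cut Classification threshold on the d28/d1 linear ratio.
#' @return `hits` with `log2fc_d1`, `log2fc_d28`, `d28_vs_d1_linear`,
#'   `class` columns added.
#' @export
classify_hits <- function(hits, d1_scores, d28_scores, fold_cut = 2.0) {
  j <- hits %>%
    inner_join(select(d1_scores, "gene_id", log2fc_d1 = "log2fc"),
               by = "gene_id") %>%
    inner_join(select(d28_scores, "gene_id", log2fc_d28 = "log2fc"),
               by = "gene_id")
  if (nrow(j) != nrow(hits)) abort("hits must be a subset of the scored genes")
  j %>%
    mutate(d28_vs_d1_linear = 2^(.data$log2fc_d28 - .data$log2fc_d1),
           class = ifelse(.data$d28_vs_d1_linear > fold_cut,
                          "lifespan_specific", "early_benefit"))
}
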