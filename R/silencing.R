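# Spike-in slope normalization and the transcriptome-silencing-defect
# gene-selection rule, with a pluggable per-gene contrast engine.

#' Per-sample scale factors from spike-in genes
#'
#' Fits, for every sample, a through-origin regression of its spike-in
#' gene counts against the reference sample's, and returns the scale
#' factor `1/slope` per sample. Applying the factors and re-fitting gives
#' slope 1 for every sample (idempotence). Three fits are available:
#' `"logratio"` (default; geometric mean of the per-gene count ratios,
#' i.e. the through-origin fit on the log scale, and the maximum-likelihood
#' slope under multiplicative log-normal noise), `"lad"` (least absolute
#' deviations on the raw counts, i.e. the `x`-weighted median of ratios),
#' and `"ols"` (ordinary least squares through the origin).
#'
#' @param counts Long count tibble (`gene_id`, `sample_id`, `count`).
#' @param spike_genes Character vector of spike-in gene ids (>= 5 usable).
#' @param reference Reference sample id (its factor is 1).
#' @param method `"logratio"`, `"lad"`, or `"ols"`.
#' @return A `spike_norm` object; `tidy()` gives per-sample `sample_id`,
#'   `slope`, `factor`, `n_spikes`; `glance()` the method, reference and
#'   spike count.
#' @export
spike_slope_factors <- function(counts, spike_genes, reference,
                                method = c("logratio", "lad", "ols")) {
  method <- match.arg(method)
  sp <- counts[counts$gene_id %in% spike_genes, ]
  if (!reference %in% sp$sample_id) abort("reference sample not found in counts")
  wide <- tidyr::pivot_wider(sp, id_cols = "gene_id",
                             names_from = "sample_id", values_from = "count")
  ref <- wide[[reference]]
  samples <- setdiff(names(wide), "gene_id")
  fit_one <- function(s) {
    y <- wide[[s]]
    ok <- !is.na(ref) & !is.na(y) & ref > 0 & y > 0
    if (sum(ok) < 5) {
      abort(paste0("fewer than 5 usable spike genes for sample ", s))
    }
    x <- ref[ok]
    yy <- y[ok]
    slope <- switch(method,
                    logratio = exp(mean(log(yy / x))),
                    lad = weighted_median(yy / x, w = x),
                    ols = sum(x * yy) / sum(x^2))
    if (!is.finite(slope) || slope <= 0) {
      abort(paste0("degenerate spike slope for sample ", s))
    }
    tibble(sample_id = s, slope = slope, factor = 1 / slope, n_spikes = sum(ok))
  }
  factors <- bind_rows(lapply(samples, fit_one))
  structure(
    list(factors = factors, reference = reference, method = method,
         spike_genes = intersect(spike_genes, sp$gene_id)),
    class = "spike_norm"
  )
}

#' @export
print.spike_norm <- function(x, ...) {
  cat("<spike_norm> ", nrow(x$factors), " samples, ",
      length(x$spike_genes), " spike genes, method = ", x$method,
      ", reference = ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Apply spike-in scale factors to a count table
#'
#' Multiplies every sample's counts by its scale factor; spike genes can
#' be dropped from the output. Re-fitting [spike_slope_factors()] on the
#' result returns factors of 1 (idempotence).
#'
#' @param counts Long count tibble.
#' @param factors A `spike_norm` object or a tibble with `sample_id`,
#'   `factor`.
#' @param drop_spikes Drop the spike genes from the output (requires a
#'   `spike_norm` input to know them).
#' @return The normalized long tibble.
#' @export
apply_factors <- function(counts, factors, drop_spikes = FALSE) {
  ftab <- if (inherits(factors, "spike_norm")) factors$factors else factors
  out <- counts %>%
    left_join(select(ftab, "sample_id", "factor"), by = "sample_id") %>%
    mutate(factor = tidyr::replace_na(.data$factor, 1),
           count = .data$count * .data$factor) %>%
    select(-"factor")
  if (drop_spikes) {
    if (!inherits(factors, "spike_norm")) {
      abort("drop_spikes = TRUE requires a spike_norm object")
    }
    out <- out[!out$gene_id %in% factors$spike_genes, ]
  }
  out
}

#' Built-in per-gene contrast engine
#'
#' A moderated two-sample test on log2 spike-normalized counts, computed
#' with an empirical-Bayes pooled variance (limma), producing the contrast
#' statistics that the silencing selection rule consumes: each quiescent
#' timepoint versus euploid log phase within the euploid, and each
#' aneuploid versus the euploid at each quiescent timepoint. Externally
#' computed per-gene statistics in the same layout are accepted by
#' [call_silencing_defect()] interchangeably.
#'
#' @param norm_counts Spike-normalized long count tibble.
#' @param design Sample sheet: `sample_id`, `strain` (`"euploid"` or
#'   aneuploid labels), `timepoint`; the first level of `timepoints` is
#'   the proliferating baseline.
#' @param timepoints Ordered timepoint labels (default: order of
#'   appearance; the first is the log-phase baseline).
#' @return A tibble of contrast statistics: `gene_id`, `contrast`
#'   (`"euploid_repression"` or `"aneuploid_vs_euploid"`), `strain`,
#'   `timepoint`, `log2fc`, `p_value`, `fdr` (BH within contrast).
#' @export
builtin_contrast_test <- function(norm_counts, design,
                                  timepoints = unique(design$timepoint)) {
  baseline <- timepoints[1]
  mat <- tidyr::pivot_wider(norm_counts, id_cols = "gene_id",
                            names_from = "sample_id", values_from = "count")
  genes <- mat$gene_id
  m <- log2(as.matrix(mat[, -1]) + 0.5)
  rownames(m) <- genes

  run_contrast <- function(samples_a, samples_b, contrast, strain, timepoint) {
    if (length(samples_a) < 2 || length(samples_b) < 2) {
      abort(paste0("contrast ", contrast, " (", strain, ", ", timepoint,
                   ") needs >= 2 replicates per condition"))
    }
    sub <- m[, c(samples_a, samples_b), drop = FALSE]
    grp <- factor(rep(c("a", "b"), c(length(samples_a), length(samples_b))),
                  levels = c("b", "a"))
    dm <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(sub, dm))
    tibble(gene_id = genes, contrast = contrast, strain = strain,
           timepoint = timepoint,
           log2fc = fit$coefficients[, 2],
           p_value = fit$p.value[, 2]) %>%
      mutate(fdr = bh_adjust(.data$p_value))
  }

  sid <- function(strain, tp) {
    design$sample_id[design$strain == strain & design$timepoint == tp]
  }
  aneuploids <- setdiff(unique(design$strain), "euploid")
  quiescent <- setdiff(timepoints, baseline)

  out <- list()
  for (tp in quiescent) {
    out[[length(out) + 1]] <- run_contrast(
      sid("euploid", tp), sid("euploid", baseline),
      "euploid_repression", "euploid", tp)
    for (an in aneuploids) {
      out[[length(out) + 1]] <- run_contrast(
        sid(an, tp), sid("euploid", tp),
        "aneuploid_vs_euploid", an, tp)
    }
  }
  bind_rows(out)
}

#' Select silencing-defect genes
#'
#' Implements the selection rule for genes that fail transcriptome
#' silencing in aneuploids: a gene is selected iff it is significantly
#' repressed in the euploid (negative log2 fold change versus log phase,
#' FDR < `alpha`, at some quiescent timepoint) AND, for every aneuploid
#' strain, it is significantly higher than the euploid (positive log2 fold
#' change, FDR < `alpha`) at at least one timepoint.
#'
#' @param stats Contrast statistics as produced by
#'   [builtin_contrast_test()] (or imported externally in the same
#'   layout).
#' @param alpha FDR threshold for both conditions.
#' @param aneuploids Aneuploid strains that must all concur (default: all
#'   aneuploid strains present in `stats`); an aneuploid listed here but
#'   missing from `stats` is an error.
#' @return Character vector of selected gene ids.
#' @export
call_silencing_defect <- function(stats, alpha = 0.05, aneuploids = NULL) {
  need <- c("gene_id", "contrast", "strain", "timepoint", "log2fc", "fdr")
  if (!all(need %in% names(stats))) {
    abort(paste0("stats must have columns: ", paste(need, collapse = ", ")))
  }
  present <- unique(stats$strain[stats$contrast == "aneuploid_vs_euploid"])
  aneuploids <- aneuploids %||% present
  missing <- setdiff(aneuploids, present)
  if (length(missing) > 0) {
    abort(paste0("missing aneuploid-vs-euploid contrasts for: ",
                 paste(missing, collapse = ", ")))
  }
  repressed <- stats %>%
    filter(.data$contrast == "euploid_repression",
           .data$log2fc < 0, .data$fdr < alpha) %>%
    pull(.data$gene_id) %>%
    unique()
  higher <- stats %>%
    filter(.data$contrast == "aneuploid_vs_euploid",
           .data$strain %in% aneuploids,
           .data$log2fc > 0, .data$fdr < alpha) %>%
    distinct(.data$gene_id, .data$strain) %>%
    count(.data$gene_id, name = "n_strains") %>%
    filter(.data$n_strains == length(aneuploids)) %>%
    pull(.data$gene_id)
  sort(intersect(repressed, higher))
}
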