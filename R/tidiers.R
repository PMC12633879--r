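# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy peak-call results
#'
#' @param x A `ribo_peaks` from [call_peaks()].
#' @param ... Unused.
#' @return One row per significant codon call.
#' @export
tidy.ribo_peaks <- function(x, ...) x$calls

#' @rdname tidy.ribo_peaks
#' @return For `glance()`, per-replicate tested/significant codon counts.
#' @export
glance.ribo_peaks <- function(x, ...) {
  mutate(x$n_tested, alpha = x$alpha, n_genes = length(x$genes))
}

#' Tidy replicate-combined peak calls
#'
#' @param x A `ribo_peaks_combined` from [combine_replicates()].
#' @param ... Unused.
#' @return One row per retained site.
#' @export
tidy.ribo_peaks_combined <- function(x, ...) x$sites

#' @rdname tidy.ribo_peaks_combined
#' @return For `glance()`, site and transcript counts per direction plus
#'   the number of direction conflicts discarded.
#' @export
glance.ribo_peaks_combined <- function(x, ...) {
  mutate(x$summary, n_conflicts = nrow(x$conflicts), alpha = x$alpha)
}

#' Tidy spike-in normalization factors
#'
#' @param x A `spike_norm` from [spike_slope_factors()].
#' @param ... Unused.
#' @return Per-sample `sample_id`, `slope`, `factor`, `n_spikes`.
#' @export
tidy.spike_norm <- function(x, ...) x$factors

#' @rdname tidy.spike_norm
#' @export
glance.spike_norm <- function(x, ...) {
  tibble(method = x$method, reference = x$reference,
         n_spike_genes = length(x$spike_genes),
         n_samples = nrow(x$factors))
}

#' Tidy P-site assignment results
#'
#' @param x A `ribo_psites` from [assign_psites()].
#' @param ... Unused.
#' @return The dense per-codon count table.
#' @export
tidy.ribo_psites <- function(x, ...) x$counts

#' @rdname tidy.ribo_psites
#' @return For `glance()`, read bookkeeping (input, assigned, dropped,
#'   unknown-chromosome counts and the offset used).
#' @export
glance.ribo_psites <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_assigned = x$n_assigned,
         n_dropped = x$n_dropped,
         n_unknown_chromosome = x$n_unknown_chromosome,
         offset_nt = x$offset_nt)
}
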