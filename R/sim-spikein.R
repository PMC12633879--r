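# Spike-in RNA-seq simulation for the transcriptome-silencing analysis.

#' Simulate spike-in normalized RNA-seq counts with a planted silencing defect
#'
#' Emulates per-cell-normalized bulk RNA-seq of euploid and aneuploid
#' strains through quiescence entry. Each sample carries a true global
#' scale factor (emulating cell number / library differences); spike-in
#' gene counts are `base * scale * log-normal(noise_cv)` and carry no
#' biology. Host genes fall into three groups: constitutive, repressed
#' (silenced `repression_log2`-fold at quiescent timepoints in every
#' strain), and planted silencing-defect genes, which are repressed in the
#' euploid but stay at log-phase abundance in every aneuploid strain.
#'
#' @param config A [sim_config()] whose `spike` slot is a [spike_config()]
#'   (noise uses `config$seed + 2`).
#' @return A `ribo_spikein` list: `counts` (long tibble `gene_id`,
#'   `sample_id`, `count`), `samples` (tibble `sample_id`, `strain`,
#'   `timepoint`, `replicate`), `spike_genes` (character), and `truth`
#'   (`scale_factors` = true per-sample normalization factors relative to
#'   the reference sample, `defect_genes`, `repressed_genes`).
#' @export
simulate_spikein <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$spike
  if (is.null(sc)) abort("config$spike must be a spike_config()")
  with_seed(config$seed + 2L, {
    strains <- c("euploid", paste0("aneuploid", seq_len(sc$n_aneuploids)))
    samples <- tidyr::expand_grid(strain = strains,
                                  timepoint = sc$timepoints,
                                  replicate = seq_len(sc$replicates)) %>%
      mutate(sample_id = paste(.data$strain, .data$timepoint,
                               paste0("rep", .data$replicate), sep = "_"))
    ns <- nrow(samples)

    scale_s <- sc$scale_factors
    if (is.null(scale_s)) {
      scale_s <- 2^rnorm(ns, 0, 0.5)
      scale_s[1] <- 1
    } else {
      scale_s <- rep_len(unname(scale_s), ns)
    }

    spike_ids <- sprintf("spike%03d", seq_len(sc$n_spike_genes))
    expr_ids <- sprintf("g%04d", seq_len(sc$n_expr_genes))
    n_rep_genes <- max(sc$n_defect_genes,
                       round(sc$frac_repressed * sc$n_expr_genes))
    repressed <- expr_ids[seq_len(n_rep_genes)]
    defect <- expr_ids[seq_len(sc$n_defect_genes)]

    base_expr <- round(2^rnorm(sc$n_expr_genes, 8, 2)) + 1
    base_spike <- round(2^rnorm(sc$n_spike_genes, 8, 1.5)) + 1

    quiescent <- samples$timepoint != sc$timepoints[1]
    aneuploid <- samples$strain != "euploid"

    count_one <- function(si) {
      mult <- rep(1, sc$n_expr_genes)
      if (quiescent[si]) {
        rep_here <- expr_ids %in% repressed
        if (aneuploid[si]) rep_here <- rep_here & !(expr_ids %in% defect)
        mult[rep_here] <- 2^sc$repression_log2
      }
      # abundances stay continuous so that exact scalings survive zero noise
      expr_cnt <- base_expr * mult * scale_s[si] *
        exp(rnorm(sc$n_expr_genes, 0, lognorm_sd(sc$biol_cv)))
      spike_cnt <- base_spike * scale_s[si] *
        exp(rnorm(sc$n_spike_genes, 0, lognorm_sd(sc$noise_cv)))
      tibble(gene_id = c(expr_ids, spike_ids),
             sample_id = samples$sample_id[si],
             count = as.numeric(c(expr_cnt, spike_cnt)))
    }
    counts <- bind_rows(lapply(seq_len(ns), count_one))

    structure(
      list(counts = counts,
           samples = select(samples, "sample_id", "strain", "timepoint", "replicate"),
           spike_genes = spike_ids,
           truth = list(
             scale_factors = tibble(sample_id = samples$sample_id,
                                    true_scale = scale_s,
                                    norm_factor = scale_s[1] / scale_s),
             defect_genes = defect,
             repressed_genes = repressed),
           config = config),
      class = "ribo_spikein"
    )
  })
}

# sdlog such that a log-normal with meanlog 0 has the requested CV
lognorm_sd <- function(cv) sqrt(log(1 + cv^2))
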