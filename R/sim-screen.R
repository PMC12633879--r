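# Pooled barcode-screen count simulation.

#' Simulate barcode counts for the pooled overexpression screen
#'
#' Generates negative-binomial barcode counts for euploid and aneuploid
#' pools at the starting pool, day 1 and day 28 timepoints, in replicate.
#' Library proportions are log-normal across genes. Planted hits have their
#' proportion multiplied by `2^effect_log2` in the aneuploid pool at their
#' class-appropriate timepoints: "early" hits at day 1 and day 28, "late"
#' (life-span-specific) hits at day 28 only. Euploid pools are unperturbed.
#'
#' @param config A [sim_config()] whose `screen` slot is a
#'   [screen_config()] (noise uses `config$seed + 3`).
#' @return A `ribo_screen` list: `counts` (long tibble `gene_id`,
#'   `sample_id`, `count`), `samples` (tibble `sample_id`, `strain`,
#'   `timepoint`, `replicate`), and `truth` (`hits`: tibble `gene_id`,
#'   `class` in `early`/`late`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$screen
  if (is.null(sc)) abort("config$screen must be a screen_config()")
  with_seed(config$seed + 3L, {
    samples <- tidyr::expand_grid(strain = sc$strains,
                                  timepoint = sc$timepoints,
                                  replicate = seq_len(sc$replicates)) %>%
      mutate(sample_id = paste(.data$strain, .data$timepoint,
                               paste0("rep", .data$replicate), sep = "_"))
    gene_ids <- sprintf("orf%04d", seq_len(sc$n_genes))
    base_prop <- 2^rnorm(sc$n_genes, 0, sc$base_log2_sd)
    base_prop <- base_prop / sum(base_prop)

    planted <- sample(gene_ids, sc$n_early + sc$n_late)
    hits <- tibble(gene_id = planted,
                   class = rep(c("early", "late"), c(sc$n_early, sc$n_late)))

    count_one <- function(si) {
      p <- base_prop
      if (samples$strain[si] == "aneuploid") {
        boost <- switch(samples$timepoint[si],
                        pool = character(0),
                        d1 = hits$gene_id[hits$class == "early"],
                        d28 = hits$gene_id)
        p[gene_ids %in% boost] <- p[gene_ids %in% boost] * 2^sc$effect_log2
      }
      mu <- p / sum(base_prop) * sc$depth
      tibble(gene_id = gene_ids,
             sample_id = samples$sample_id[si],
             count = as.numeric(rnbinom(sc$n_genes, mu = mu,
                                        size = 1 / sc$nb_dispersion)))
    }
    counts <- bind_rows(lapply(seq_len(nrow(samples)), count_one))

    structure(
      list(counts = counts,
           samples = select(samples, "sample_id", "strain", "timepoint", "replicate"),
           truth = list(hits = hits),
           config = config),
      class = "ribo_screen"
    )
  })
}
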