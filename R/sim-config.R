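# Configuration objects for the synthetic-data generators.

#' Describe a set of planted ribosome stall sites
#'
#' A stall spec plants codons whose footprint occupancy is multiplied by
#' `fold` in one condition, with the residue decoded at the stalled codon
#' (P site) and the next codon (A site) drawn from weighted residue sets.
#' Defaults mirror the stall chemistry reported for quiescent aneuploid
#' yeast: lysine/asparagine in the P site, glycine/glutamate in the A site,
#' and an 8-fold occupancy elevation.
#'
#' @param n_sites Number of stall sites to plant.
#' @param fold Occupancy multiplier at the stalled codon (> 1).
#' @param affected_condition `"aneuploid"` or `"euploid"`: the condition in
#'   which the elevation appears.
#' @param p_site_residues,a_site_residues Named numeric vectors of residue
#'   sampling weights (one-letter amino-acid codes), or `NULL` to leave the
#'   residue at background composition.
#' @param placement_bias `NULL` for uniform placement along the testable
#'   codon range, or `c(shape1, shape2)` of a Beta distribution over
#'   relative codon position (e.g. `c(1, 3)` skews sites toward the 5' end,
#'   reproducing the positional shift seen for aneuploid-enhanced peaks).
#' @return A `stall_spec` list.
#' @export
stall_spec <- function(n_sites = 0,
                       fold = 8,
                       affected_condition = c("aneuploid", "euploid"),
                       p_site_residues = c(K = 0.5, N = 0.5),
                       a_site_residues = c(G = 0.5, E = 0.5),
                       placement_bias = NULL) {
  affected_condition <- match.arg(affected_condition)
  stopifnot(n_sites >= 0, fold > 1)
  check_weights <- function(w, what) {
    if (is.null(w)) return(invisible())
    if (is.null(names(w)) || any(!names(w) %in% AA_ALPHABET_20) || any(w < 0) ||
        sum(w) <= 0) {
      abort(paste0("'", what, "' must be a named nonnegative weight vector over ",
                   "one-letter amino-acid codes"))
    }
  }
  check_weights(p_site_residues, "p_site_residues")
  check_weights(a_site_residues, "a_site_residues")
  if (!is.null(placement_bias) &&
      (length(placement_bias) != 2 || any(placement_bias <= 0))) {
    abort("'placement_bias' must be NULL or two positive Beta shape parameters")
  }
  structure(
    list(n_sites = as.integer(n_sites), fold = fold,
         affected_condition = affected_condition,
         p_site_residues = p_site_residues,
         a_site_residues = a_site_residues,
         placement_bias = placement_bias),
    class = "stall_spec"
  )
}

#' Spike-in RNA-seq simulation settings
#'
#' Configures the transcriptome-silencing simulation: foreign spike-in genes
#' added at known per-sample scale factors (emulating a fixed number of
#' spiked cells per sample), quiescence-repressed host genes, and a planted
#' "silencing defect" gene set whose abundance fails to drop in every
#' aneuploid strain.
#'
#' @param n_spike_genes Number of spike-in genes (>= 5).
#' @param scale_factors Optional named per-sample true scale factors; the
#'   first (reference) sample must be 1. `NULL` draws them log-normally with
#'   the reference fixed at 1.
#' @param noise_cv Coefficient of variation of the independent log-normal
#'   measurement noise applied per observation.
#' @param n_expr_genes Number of host (experimental) genes.
#' @param n_defect_genes Number of planted silencing-defect genes.
#' @param n_aneuploids Number of aneuploid strains (the selection rule
#'   requires concordance across all of them).
#' @param timepoints Sample timepoints; the first is the proliferating
#'   (log-phase) baseline, later ones are quiescent.
#' @param replicates Biological replicates per strain x timepoint.
#' @param repression_log2 Log2 change of repressed host genes in quiescence
#'   (euploid silencing; default -3, an 8-fold drop).
#' @param frac_repressed Fraction of host genes silenced in quiescence.
#' @param biol_cv Coefficient of variation of host-gene biological noise.
#' @return A `spike_config` list.
#' @export
spike_config <- function(n_spike_genes = 50,
                         scale_factors = NULL,
                         noise_cv = 0.1,
                         n_expr_genes = 1000,
                         n_defect_genes = 50,
                         n_aneuploids = 4,
                         timepoints = c("log", "d1", "d3"),
                         replicates = 2,
                         repression_log2 = -3,
                         frac_repressed = 0.5,
                         biol_cv = 0.2) {
  stopifnot(n_spike_genes >= 5, noise_cv >= 0, n_expr_genes > 0,
            n_defect_genes >= 0, n_defect_genes <= n_expr_genes,
            n_aneuploids >= 1, length(timepoints) >= 2, replicates >= 1,
            frac_repressed > 0, frac_repressed <= 1, biol_cv >= 0)
  if (!is.null(scale_factors) && abs(scale_factors[[1]] - 1) > 1e-12) {
    abort("the reference (first) scale factor must equal 1")
  }
  structure(
    list(n_spike_genes = as.integer(n_spike_genes),
         scale_factors = scale_factors, noise_cv = noise_cv,
         n_expr_genes = as.integer(n_expr_genes),
         n_defect_genes = as.integer(n_defect_genes),
         n_aneuploids = as.integer(n_aneuploids),
         timepoints = timepoints, replicates = as.integer(replicates),
         repression_log2 = repression_log2, frac_repressed = frac_repressed,
         biol_cv = biol_cv),
    class = "spike_config"
  )
}

#' Barcode-screen simulation settings
#'
#' Configures the pooled gene-overexpression screen: barcoded plasmids
#' carried through euploid and aneuploid pools sampled at the starting pool,
#' day 1, and day 28, in biological triplicate. Planted hits rise in the
#' aneuploid pool only: "early" hits are enriched at both day 1 and day 28,
#' "late" (life-span-specific) hits at day 28 only.
#'
#' @param n_genes Library size (genes/barcodes).
#' @param n_early,n_late Planted hit counts per class.
#' @param effect_log2 Log2 enrichment of a planted hit at its class-appropriate
#'   timepoints in the aneuploid pool.
#' @param replicates Biological replicates per strain x timepoint.
#' @param nb_dispersion Negative-binomial dispersion of barcode counts
#'   (`size = 1/nb_dispersion`).
#' @param depth Sequencing depth per sample.
#' @param base_log2_sd Spread of log2 library proportions across barcodes.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_genes = 5000,
                          n_early = 10,
                          n_late = 10,
                          effect_log2 = 3,
                          replicates = 3,
                          nb_dispersion = 0.1,
                          depth = 2e6,
                          base_log2_sd = 1) {
  stopifnot(n_genes > 0, n_early >= 0, n_late >= 0,
            n_early + n_late <= n_genes, replicates >= 1,
            nb_dispersion > 0, depth > 0, base_log2_sd >= 0)
  structure(
    list(n_genes = as.integer(n_genes), n_early = as.integer(n_early),
         n_late = as.integer(n_late), effect_log2 = effect_log2,
         replicates = as.integer(replicates), nb_dispersion = nb_dispersion,
         depth = depth, base_log2_sd = base_log2_sd,
         timepoints = c("pool", "d1", "d28"),
         strains = c("euploid", "aneuploid")),
    class = "screen_config"
  )
}

#' Top-level simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults are the
#' package's study conditions: a yeast-like genome of single-exon genes over
#' 16 chromosomes with chromosome XII duplicated at a full 2-fold dosage,
#' log-normal gene expression, Dirichlet-multinomial codon-level footprint
#' counts with moderate biological overdispersion, and two replicates per
#' condition.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#'   Derived generators use fixed offsets from it (genome `seed`, footprints
#'   `seed + 1`, spike-in `seed + 2`, screen `seed + 3`) so their random
#'   streams are distinct but reproducible.
#' @param n_genes Number of genes in the simulated genome.
#' @param codon_length_range Inclusive range of gene lengths in codons
#'   (including the stop codon); the minimum is 41 so that every gene has a
#'   nonempty gene body.
#' @param n_chromosomes Number of chromosomes; genes are assigned round-robin.
#' @param duplicated_chromosome Chromosome label carried in two copies by the
#'   aneuploid, or `NULL` for none.
#' @param dosage_fold Expression multiplier for genes on the duplicated
#'   chromosome in aneuploid samples (>= 1). Default 2.0, a true duplication;
#'   the attenuated 1.7 observed in vivo is a configurable alternative.
#' @param expression_log2_mean,expression_log2_sd Log2-normal per-gene
#'   expression parameters.
#' @param dispersion Dirichlet concentration per codon; larger values give
#'   counts closer to multinomial (use `Inf` for exactly multinomial).
#' @param depth Total footprint count per sample.
#' @param n_replicates Replicates per condition.
#' @param stall_specs List of [stall_spec()] objects to plant.
#' @param utr_weight Relative occupancy weight of the flanking upstream and
#'   downstream window codons versus a CDS codon.
#' @param spike Optional [spike_config()].
#' @param screen Optional [screen_config()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200,
                       codon_length_range = c(150, 450),
                       n_chromosomes = 16,
                       duplicated_chromosome = "chrXII",
                       dosage_fold = 2.0,
                       expression_log2_mean = 4,
                       expression_log2_sd = 1,
                       dispersion = 10,
                       depth = 1e6,
                       n_replicates = 2,
                       stall_specs = list(),
                       utr_weight = 0.1,
                       spike = NULL,
                       screen = NULL) {
  stopifnot(length(codon_length_range) == 2,
            n_genes > 0, n_chromosomes >= 1, dosage_fold >= 1,
            dispersion > 0, depth > 0, n_replicates >= 1,
            utr_weight >= 0, expression_log2_sd >= 0)
  if (codon_length_range[1] < 41) {
    abort("codon_length_range must be >= 41 codons so gene bodies are nonempty")
  }
  if (inherits(stall_specs, "stall_spec")) stall_specs <- list(stall_specs)
  if (!all(vapply(stall_specs, inherits, logical(1), "stall_spec"))) {
    abort("'stall_specs' must be a list of stall_spec() objects")
  }
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(n_chromosomes))))
  if (!is.null(duplicated_chromosome) && !duplicated_chromosome %in% chroms) {
    abort(paste0("duplicated_chromosome '", duplicated_chromosome,
                 "' is not among the ", n_chromosomes, " simulated chromosomes"))
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         codon_length_range = as.integer(codon_length_range),
         n_chromosomes = as.integer(n_chromosomes),
         chromosomes = chroms,
         duplicated_chromosome = duplicated_chromosome,
         dosage_fold = dosage_fold,
         expression_log2_mean = expression_log2_mean,
         expression_log2_sd = expression_log2_sd,
         dispersion = dispersion, depth = depth,
         n_replicates = as.integer(n_replicates),
         stall_specs = stall_specs, utr_weight = utr_weight,
         spike = spike, screen = screen),
    class = "sim_config"
  )
}
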