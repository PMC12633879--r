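# Euploid-vs-aneuploid trace comparison and codon-level differential
# pause-site calling.

#' Uncentered Pearson correlation of two occupancy traces
#'
#' Cosine similarity `sum(a*b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`:
#' scale-invariant, no mean subtraction, equal to 1 for proportional
#' traces. Returns 0 (with a warning) if either vector is all-zero.
#'
#' @param trace_a,trace_b Numeric vectors of equal length >= 2.
#' @return The correlation, in `[-1, 1]` (nonnegative for nonnegative traces).
#' @examples
#' uncentered_correlation(c(1, 2, 3), c(3, 2, 1)) # 10/14
#' @export
uncentered_correlation <- function(trace_a, trace_b) {
  if (length(trace_a) != length(trace_b)) abort("traces must have equal length")
  if (length(trace_a) < 2) abort("traces must have length >= 2")
  na <- sqrt(sum(trace_a^2))
  nb <- sqrt(sum(trace_b^2))
  if (na == 0 || nb == 0) {
    warn("all-zero trace; correlation set to 0")
    return(0)
  }
  sum(trace_a * trace_b) / (na * nb)
}

#' Per-transcript trace correlations between conditions
#'
#' Computes the uncentered Pearson correlation of the euploid and aneuploid
#' occupancy traces of every gene, paired by replicate, restricted to CDS
#' codons. Genes with similar pausing in both conditions sit near 1;
#' condition-specific pauses pull the correlation down.
#'
#' @param occupancy Output of [normalize_occupancy()] covering all samples
#'   in `pairs`.
#' @param models Gene-model tibble with `gene_id`, `n_codons`.
#' @param pairs Tibble pairing samples by replicate: columns `replicate`,
#'   `euploid`, `aneuploid` (sample ids).
#' @param genes Optional analysis gene set (e.g. [shared_retained_genes()]).
#' @return Tibble `gene_id`, `replicate`, `correlation`.
#' @export
correlate_all <- function(occupancy, models, pairs, genes = NULL) {
  if (!is.null(genes)) occupancy <- occupancy[occupancy$gene_id %in% genes, ]
  occupancy <- occupancy %>%
    inner_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    filter(.data$codon >= 1, .data$codon <= .data$n_codons)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    e <- occupancy[occupancy$sample_id == pairs$euploid[i], ]
    a <- occupancy[occupancy$sample_id == pairs$aneuploid[i], ]
    j <- inner_join(select(e, "gene_id", "codon", e_occ = "occupancy"),
                    select(a, "gene_id", "codon", a_occ = "occupancy"),
                    by = c("gene_id", "codon"))
    j %>%
      group_by(.data$gene_id) %>%
      summarise(correlation = uncentered_correlation(.data$e_occ, .data$a_occ),
                .groups = "drop") %>%
      mutate(replicate = pairs$replicate[i])
  })
  bind_rows(out) %>% select("gene_id", "replicate", "correlation")
}

#' Fisher's exact test for one codon
#'
#' Two-sided Fisher exact p for the 2x2 table with rows euploid/aneuploid
#' and columns (reads at the codon, reads in the gene body excluding that
#' codon). Body counts are raw, un-normalized sums.
#'
#' @param codon_e,codon_a Reads at the codon in euploid / aneuploid.
#' @param body_e,body_a Gene-body reads (including the codon; the codon's
#'   own reads are subtracted internally when it lies in the body, so the
#'   two columns are disjoint).
#' @param codon_in_body Is the tested codon part of the gene body?
#' @return Two-sided p-value (1, with no signal, for an all-zero table).
#' @export
codon_fisher_test <- function(codon_e, body_e, codon_a, body_a,
                              codon_in_body = TRUE) {
  rest_e <- body_e - if (codon_in_body) codon_e else 0
  rest_a <- body_a - if (codon_in_body) codon_a else 0
  if (any(rest_e < 0 | rest_a < 0)) abort("codon counts exceed body counts")
  fisher_exact_2x2(codon_e, rest_e, codon_a, rest_a)
}

#' Call differentially occupied codons between euploid and aneuploid
#'
#' For every CDS codon of every retained gene, tests the codon's read count
#' against the gene-body count (euploid versus aneuploid, each replicate
#' pair separately) with the two-sided Fisher exact test, applies
#' Benjamini-Hochberg correction over all codons tested within the
#' replicate, and labels significant codons by direction using the
#' pseudocounted normalized occupancy ratio (aneuploid / euploid).
#'
#' @param counts Long count tibble covering all samples in `pairs`.
#' @param models Gene-model tibble.
#' @param pairs Replicate pairing tibble (`replicate`, `euploid`,
#'   `aneuploid`).
#' @param genes Analysis gene set (default: genes retained in every sample
#'   of every pair at `min_body_reads = 50`).
#' @param alpha FDR threshold for a call.
#' @param min_total Minimum combined codon count for a codon to be tested.
#' @param exclude_codon_from_body If `TRUE` (default) the tested codon's
#'   reads are removed from the body column so the table columns are
#'   disjoint.
#' @param pseudocount Pseudocount for the direction/ratio computation.
#' @return A `ribo_peaks` object; `tidy()` gives the calls (`replicate`,
#'   `gene_id`, `codon`, `p_value`, `fdr`, `direction`, `ratio`,
#'   `relative_position`), `glance()` per-replicate test and call counts.
#' @export
call_peaks <- function(counts, models, pairs, genes = NULL, alpha = 0.05,
                       min_total = 0, exclude_codon_from_body = TRUE,
                       pseudocount = 1) {
  if (is.null(genes)) {
    flt <- filter_genes(counts, models, min_body_reads = 50)
    genes <- shared_retained_genes(
      flt, sample_ids = unique(c(pairs$euploid, pairs$aneuploid)))
  }
  models <- models[models$gene_id %in% genes & models$n_codons >= 41L, ]
  if (nrow(models) == 0) abort("no genes in the analysis set")
  cds <- counts %>%
    filter(.data$gene_id %in% models$gene_id, .data$codon >= 1) %>%
    inner_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    filter(.data$codon <= .data$n_codons)

  calls <- list()
  n_tested <- list()
  for (i in seq_len(nrow(pairs))) {
    e <- cds[cds$sample_id == pairs$euploid[i], ]
    a <- cds[cds$sample_id == pairs$aneuploid[i], ]
    j <- inner_join(
      select(e, "gene_id", "codon", "n_codons", count_e = "count"),
      select(a, "gene_id", "codon", count_a = "count"),
      by = c("gene_id", "codon")
    )
    body <- j %>%
      group_by(.data$gene_id) %>%
      summarise(
        body_e = sum(.data$count_e[.data$codon >= 21L &
                                     .data$codon <= .data$n_codons[1] - 20L]),
        body_a = sum(.data$count_a[.data$codon >= 21L &
                                     .data$codon <= .data$n_codons[1] - 20L]),
        n_body = sum(.data$codon >= 21L & .data$codon <= .data$n_codons[1] - 20L),
        .groups = "drop")
    j <- inner_join(j, body, by = "gene_id") %>%
      filter(.data$count_e + .data$count_a >= min_total)

    in_body <- j$codon >= 21L & j$codon <= j$n_codons - 20L
    rest_e <- j$body_e - ifelse(exclude_codon_from_body & in_body, j$count_e, 0)
    rest_a <- j$body_a - ifelse(exclude_codon_from_body & in_body, j$count_a, 0)
    p <- fisher_exact_2x2(j$count_e, rest_e, j$count_a, rest_a)
    fdr <- bh_adjust(p)
    occ_e <- (j$count_e + pseudocount) /
      ((j$body_e + pseudocount * j$n_body) / j$n_body)
    occ_a <- (j$count_a + pseudocount) /
      ((j$body_a + pseudocount * j$n_body) / j$n_body)
    ratio <- occ_a / occ_e
    n_tested[[i]] <- tibble(replicate = pairs$replicate[i], n_tested = nrow(j),
                            n_significant = sum(fdr < alpha & ratio != 1))
    sig <- fdr < alpha & ratio != 1
    calls[[i]] <- tibble(
      replicate = pairs$replicate[i],
      gene_id = j$gene_id[sig], codon = j$codon[sig],
      p_value = p[sig], fdr = fdr[sig],
      direction = ifelse(ratio[sig] > 1, "aneuploid_higher", "euploid_higher"),
      ratio = ratio[sig],
      relative_position = j$codon[sig] / j$n_codons[sig]
    )
  }
  structure(
    list(calls = bind_rows(calls), n_tested = bind_rows(n_tested),
         alpha = alpha, genes = genes),
    class = "ribo_peaks"
  )
}

#' @export
print.ribo_peaks <- function(x, ...) {
  cat("<ribo_peaks> ", nrow(x$calls), " calls over ",
      sum(x$n_tested$n_tested), " tested codons (FDR < ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Combine replicate-level peak calls
#'
#' Takes the union of significant codons across replicates. Codons called
#' in different replicates with conflicting directions are discarded and
#' reported. Site and transcript counts per direction are available via
#' `glance()`.
#'
#' @param peaks A `ribo_peaks` from [call_peaks()].
#' @return A `ribo_peaks_combined` object; `tidy()` gives one row per
#'   retained site (`gene_id`, `codon`, `direction`, `n_replicates`,
#'   `min_fdr`, `mean_ratio`, `relative_position`).
#' @export
combine_replicates <- function(peaks) {
  stopifnot(inherits(peaks, "ribo_peaks"))
  by_site <- peaks$calls %>%
    group_by(.data$gene_id, .data$codon) %>%
    summarise(n_directions = dplyr::n_distinct(.data$direction),
              direction = .data$direction[1],
              n_replicates = dplyr::n_distinct(.data$replicate),
              min_fdr = min(.data$fdr),
              mean_ratio = exp(mean(log(.data$ratio))),
              relative_position = .data$relative_position[1],
              .groups = "drop")
  conflicts <- by_site %>% filter(.data$n_directions > 1)
  if (nrow(conflicts) > 0) {
    warn(paste0(nrow(conflicts),
                " sites significant in opposite directions were discarded"))
  }
  combined <- by_site %>%
    filter(.data$n_directions == 1) %>%
    select(-"n_directions")
  summary <- combined %>%
    group_by(.data$direction) %>%
    summarise(n_sites = dplyr::n(),
              n_transcripts = dplyr::n_distinct(.data$gene_id),
              .groups = "drop")
  structure(
    list(sites = combined, conflicts = select(conflicts, -"n_directions"),
         summary = summary, alpha = peaks$alpha),
    class = "ribo_peaks_combined"
  )
}

#' @export
print.ribo_peaks_combined <- function(x, ...) {
  cat("<ribo_peaks_combined>\n")
  print(x$summary)
  if (nrow(x$conflicts) > 0) {
    cat(nrow(x$conflicts), "direction-conflicting sites discarded\n")
  }
  invisible(x)
}

#' Positional shift between peak directions
#'
#' Two-sided Wilcoxon rank-sum test comparing the relative transcript
#' positions (codon index / transcript length) of euploid-higher versus
#' aneuploid-higher peaks. A significant shift with lower aneuploid
#' positions indicates aneuploid-enhanced pausing nearer the start of
#' transcripts.
#'
#' @param combined A `ribo_peaks_combined`, or a numeric vector of
#'   euploid-higher relative positions.
#' @param positions_aneuploid When `combined` is a numeric vector, the
#'   aneuploid-higher relative positions.
#' @return One-row tibble: `statistic`, `p_value`, `exact`,
#'   `median_euploid`, `median_aneuploid`.
#' @export
peak_position_test <- function(combined, positions_aneuploid = NULL) {
  if (inherits(combined, "ribo_peaks_combined")) {
    x <- combined$sites$relative_position[combined$sites$direction == "euploid_higher"]
    y <- combined$sites$relative_position[combined$sites$direction == "aneuploid_higher"]
  } else {
    x <- combined
    y <- positions_aneuploid
  }
  if (length(x) == 0 || length(y) == 0) abort("both direction sets must be nonempty")
  wilcoxon_rank_sum(x, y) %>%
    mutate(median_euploid = median(x), median_aneuploid = median(y))
}

#' Chromosome enrichment among peak transcripts
#'
#' Upper-tail hypergeometric test for over-representation of transcripts
#' from a target chromosome among peak-bearing transcripts, against the
#' background of all measured transcripts.
#'
#' @param peak_genes Character vector of peak-bearing gene ids (must be a
#'   subset of `measured_genes`).
#' @param measured_genes Character vector: the measured background.
#' @param models Gene-model tibble mapping `gene_id` to `chromosome`.
#' @param target_chromosome Chromosome label to test.
#' @return One-row tibble: `n_peak`, `n_peak_target`, `n_measured`,
#'   `n_measured_target`, `p_value`.
#' @export
chromosome_enrichment <- function(peak_genes, measured_genes, models,
                                  target_chromosome) {
  peak_genes <- unique(peak_genes)
  measured_genes <- unique(measured_genes)
  if (!all(peak_genes %in% measured_genes)) {
    abort("peak transcripts must be a subset of measured transcripts")
  }
  chrom <- setNames(models$chromosome, models$gene_id)
  on_target <- function(g) sum(chrom[g] == target_chromosome, na.rm = TRUE)
  k <- on_target(peak_genes)
  tibble(
    n_peak = length(peak_genes),
    n_peak_target = k,
    n_measured = length(measured_genes),
    n_measured_target = on_target(measured_genes),
    p_value = hypergeom_upper_p(k, on_target(measured_genes),
                                length(measured_genes), length(peak_genes))
  )
}
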