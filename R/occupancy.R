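# P-site assignment, frame QC, gene-body occupancy normalization, the
# 50-read gene filter, and the chromosome dosage summary.

# extended-window constants: 24 upstream codons (-72 nt) and 20 downstream
# codons (+60 nt past the stop)
UPSTREAM_CODONS <- 24L
DOWNSTREAM_CODONS <- 20L

#' Assign footprint 5' ends to P-site codons
#'
#' Places each read's P site `offset_nt` into the read (genomic position
#' `pos5 + offset` on the plus strand, `pos5 - offset` on the minus strand)
#' and maps it to the extended codon index of every gene whose window it
#' falls in, on the matching strand. The window spans 72 nt upstream of the
#' ATG to 60 nt past the stop; codon 1 is the ATG, upstream codons are
#' -24..-1, downstream codons follow the stop. Reads whose P site falls in
#' no gene window are dropped and counted; reads on chromosomes absent from
#' the models are dropped with a warning. A read overlapping two gene
#' windows is counted for both genes.
#'
#' @param read_starts Tibble with `chromosome`, `strand`, `pos5` (1-based
#'   5' position) and optionally `sample_id`.
#' @param models Gene-model tibble (`gene_id`, `chromosome`, `strand`,
#'   `cds_start`, `cds_end`, `n_codons`).
#' @param offset_nt P-site offset in nucleotides (default 12).
#' @return A `ribo_psites` list: `counts` (dense long tibble `sample_id`,
#'   `gene_id`, `codon`, `count` over the extended window), `assignments`
#'   (per-read gene/codon hits), and bookkeeping counts `n_reads`,
#'   `n_assigned` (reads hitting >= 1 window), `n_dropped`,
#'   `n_unknown_chromosome`.
#' @export
assign_psites <- function(read_starts, models, offset_nt = 12) {
  stopifnot(all(c("chromosome", "strand", "pos5") %in% names(read_starts)))
  if (!"sample_id" %in% names(read_starts)) read_starts$sample_id <- "sample1"
  n_reads <- nrow(read_starts)

  known <- read_starts$chromosome %in% unique(models$chromosome)
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " reads on chromosomes absent from the gene models were dropped"))
    read_starts <- read_starts[known, ]
  }

  psite <- ifelse(read_starts$strand == "+",
                  read_starts$pos5 + offset_nt,
                  read_starts$pos5 - offset_nt)
  chroms <- unique(c(models$chromosome, read_starts$chromosome))
  reads_gr <- GenomicRanges::GRanges(
    seqnames = factor(read_starts$chromosome, chroms),
    ranges = IRanges::IRanges(psite, width = 1),
    strand = read_starts$strand
  )
  win_start <- ifelse(models$strand == "+",
                      models$cds_start - 3L * UPSTREAM_CODONS,
                      models$cds_start - 3L * DOWNSTREAM_CODONS)
  win_end <- ifelse(models$strand == "+",
                    models$cds_end + 3L * DOWNSTREAM_CODONS,
                    models$cds_end + 3L * UPSTREAM_CODONS)
  win_gr <- GenomicRanges::GRanges(
    seqnames = factor(models$chromosome, chroms),
    ranges = IRanges::IRanges(win_start, win_end),
    strand = models$strand
  )
  hits <- GenomicRanges::findOverlaps(reads_gr, win_gr, ignore.strand = FALSE)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  off <- ifelse(models$strand[gi] == "+",
                psite[ri] - models$cds_start[gi],
                models$cds_end[gi] - psite[ri])
  codon <- off %/% 3L
  codon <- ifelse(off >= 0, codon + 1L, codon)

  assignments <- tibble(
    sample_id = read_starts$sample_id[ri],
    gene_id = models$gene_id[gi],
    codon = as.integer(codon),
    offset_nt_from_atg = as.integer(off)
  )
  n_assigned <- length(unique(ri))
  n_dropped <- nrow(read_starts) - n_assigned

  counts <- assignments %>%
    count(.data$sample_id, .data$gene_id, .data$codon, name = "count") %>%
    complete_codon_grid(models, unique(read_starts$sample_id))

  structure(
    list(counts = counts, assignments = assignments,
         n_reads = n_reads, n_assigned = n_assigned, n_dropped = n_dropped,
         n_unknown_chromosome = n_unknown, offset_nt = offset_nt),
    class = "ribo_psites"
  )
}

# dense grid over the extended codon window for every model x sample
complete_codon_grid <- function(counts, models, sample_ids) {
  grid <- tidyr::expand_grid(sample_id = sample_ids,
                             gene_id = models$gene_id) %>%
    left_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    mutate(codon = purrr::map(.data$n_codons, function(m) {
      c(seq.int(-UPSTREAM_CODONS, -1L), seq_len(m + DOWNSTREAM_CODONS))
    })) %>%
    select(-"n_codons") %>%
    tidyr::unnest("codon")
  grid %>%
    left_join(counts, by = c("sample_id", "gene_id", "codon")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))
}

#' Reading-frame distribution of assigned P sites
#'
#' Fraction of P sites landing in each frame (0/1/2 nt offset from the
#' nearest codon start) among reads whose P site falls inside a CDS,
#' reported per sample. In-frame libraries give (1, 0, 0).
#'
#' @inheritParams assign_psites
#' @return Tibble `sample_id`, `frame` (0..2), `n`, `fraction`.
#' @export
frame_distribution <- function(read_starts, models, offset_nt = 12) {
  ps <- assign_psites(read_starts, models, offset_nt = offset_nt)
  cds <- ps$assignments %>%
    inner_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    filter(.data$offset_nt_from_atg >= 0,
           .data$offset_nt_from_atg < 3L * .data$n_codons)
  cds %>%
    mutate(frame = .data$offset_nt_from_atg %% 3L) %>%
    count(.data$sample_id, .data$frame) %>%
    group_by(.data$sample_id) %>%
    tidyr::complete(frame = 0:2, fill = list(n = 0L)) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
}

# CDS body codon range used for normalization and filtering
body_range <- function(n_codons) list(lo = 21L, hi = n_codons - 20L)

#' Pseudocounted gene-body occupancy normalization
#'
#' Converts per-codon counts to occupancy: `(count + pseudocount)` divided
#' by the mean pseudocounted count over the gene body (CDS codons 21 to
#' `n_codons - 20`, where `n_codons` includes the stop codon). By
#' construction, mean occupancy over body codons is 1 for every gene.
#' Genes shorter than 41 codons have an empty body and are skipped with a
#' reason.
#'
#' @param counts Long count tibble (`sample_id`, `gene_id`, `codon`,
#'   `count`), e.g. `simulate_footprints(...)$counts` or
#'   `assign_psites(...)$counts`.
#' @param models Gene-model tibble with `gene_id`, `n_codons`.
#' @param pseudocount Added to every codon count (default 1; 0 gives the
#'   scale-invariant no-pseudocount limit used in some tests).
#' @return Tibble `sample_id`, `gene_id`, `codon`, `count`, `occupancy`,
#'   `body_mean` (the per-gene, per-sample denominator). Skipped genes are
#'   recorded in the `"skipped"` attribute.
#' @export
normalize_occupancy <- function(counts, models, pseudocount = 1) {
  short <- models$gene_id[models$n_codons < 41L]
  if (length(short) > 0) {
    counts <- counts[!counts$gene_id %in% short, ]
  }
  out <- counts %>%
    inner_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    group_by(.data$sample_id, .data$gene_id) %>%
    mutate(
      body_mean = mean(.data$count[.data$codon >= 21L &
                                     .data$codon <= .data$n_codons - 20L] +
                         pseudocount),
      occupancy = (.data$count + pseudocount) / .data$body_mean
    ) %>%
    ungroup() %>%
    select(-"n_codons")
  attr(out, "skipped") <- tibble(gene_id = short,
                                 reason = rep("body_shorter_than_41_codons",
                                              length(short)))
  out
}

#' Retain genes by gene-body read count
#'
#' A gene is retained in a sample when its raw gene-body count (CDS codons
#' 21..`n_codons - 20`) reaches `min_body_reads`; the default 50 reproduces
#' the profiling analysis filter. Use [shared_retained_genes()] for the
#' intersection across the samples of a comparison.
#'
#' @inheritParams normalize_occupancy
#' @param min_body_reads Retention threshold on raw body reads.
#' @return Tibble `sample_id`, `gene_id`, `body_reads`, `retained`.
#' @export
filter_genes <- function(counts, models, min_body_reads = 50) {
  counts %>%
    inner_join(select(models, "gene_id", "n_codons"), by = "gene_id") %>%
    filter(.data$n_codons >= 41L) %>%
    group_by(.data$sample_id, .data$gene_id) %>%
    summarise(body_reads = sum(.data$count[.data$codon >= 21L &
                                             .data$codon <= .data$n_codons[1] - 20L]),
              .groups = "drop") %>%
    mutate(retained = .data$body_reads >= min_body_reads)
}

#' @rdname filter_genes
#' @param filtered Output of [filter_genes()].
#' @param sample_ids Samples whose retained sets are intersected (default
#'   all samples present).
#' @return For `shared_retained_genes()`, a character vector of genes
#'   retained in every listed sample.
#' @export
shared_retained_genes <- function(filtered, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(filtered$sample_id)
  sets <- filtered %>%
    filter(.data$sample_id %in% sample_ids, .data$retained) %>%
    group_by(.data$gene_id) %>%
    summarise(n = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  sort(sets$gene_id[sets$n == length(sample_ids)])
}

#' Per-chromosome dosage summary from footprint counts
#'
#' For each retained gene, computes the ratio of its share of gene-body
#' reads in the aneuploid sample to its share in the euploid sample, and
#' reports the per-chromosome median. With `rescale = "median"` (default)
#' the per-gene ratios are first divided by the genome-wide median ratio,
#' removing the compositional shift that the extra chromosome imposes on
#' every other gene's share; `rescale = "none"` reports raw proportion
#' ratios.
#'
#' @inheritParams normalize_occupancy
#' @param euploid_sample,aneuploid_sample Sample ids to compare.
#' @param genes Optional character vector restricting the analysis set
#'   (e.g. [shared_retained_genes()]).
#' @param rescale `"median"` or `"none"`.
#' @return Tibble `chromosome`, `median_fold`, `n_genes`.
#' @export
chromosome_dosage <- function(counts, models, euploid_sample, aneuploid_sample,
                              genes = NULL, rescale = c("median", "none")) {
  rescale <- match.arg(rescale)
  body <- filter_genes(counts, models, min_body_reads = 0) %>%
    filter(.data$sample_id %in% c(euploid_sample, aneuploid_sample))
  if (!is.null(genes)) body <- body[body$gene_id %in% genes, ]
  wide <- body %>%
    select("sample_id", "gene_id", "body_reads") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "body_reads")
  e <- wide[[euploid_sample]]
  a <- wide[[aneuploid_sample]]
  keep <- e > 0 & a > 0
  wide <- wide[keep, ]
  ratio <- (a[keep] / sum(a[keep])) / (e[keep] / sum(e[keep]))
  if (rescale == "median") ratio <- ratio / median(ratio)
  wide %>%
    mutate(ratio = ratio) %>%
    inner_join(select(models, "gene_id", "chromosome"), by = "gene_id") %>%
    group_by(.data$chromosome) %>%
    summarise(median_fold = median(.data$ratio), n_genes = dplyr::n(),
              .groups = "drop")
}
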