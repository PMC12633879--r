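# Codon-level footprint count simulation and the optional read-start emitter.

#' Simulate per-codon P-site footprint counts
#'
#' Draws one count table per sample (euploid and aneuploid, `n_replicates`
#' each). Per-gene read mass is proportional to
#' `2^Normal(expression_log2_mean, sd) * n_codons`, multiplied by
#' `dosage_fold` for genes on the duplicated chromosome in aneuploid
#' samples; the per-gene expression draw is shared by all samples, so
#' between-sample differences come from dosage, stalls and counting noise
#' only. Within a gene, reads are allocated over the extended codon window
#' (24 upstream codons, the CDS, 20 downstream codons) by a
#' Dirichlet-multinomial: CDS codons have weight 1 (stall codons multiplied
#' by their `fold` in the affected condition), window codons weight
#' `utr_weight`, and per-codon concentration `dispersion` controls
#' biological overdispersion. Sample totals are multinomial at `depth`.
#'
#' @param genome A `ribo_genome` from [generate_genome()].
#' @param config The same [sim_config()] used for the genome (footprint
#'   noise uses `config$seed + 1`).
#' @return A `ribo_footprints` list: `counts` (long tibble `sample_id`,
#'   `gene_id`, `codon`, `count`, dense over the extended window; `codon`
#'   is -24..-1 upstream, 1..n CDS, n+1..n+20 downstream), `samples`
#'   (tibble `sample_id`, `condition`, `replicate`), and `truth`
#'   (`stalls`, per-gene `expression`, the config).
#' @export
simulate_footprints <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "ribo_genome"), inherits(config, "sim_config"))
  genes <- genome$genes
  with_seed(config$seed + 1L, {
    samples <- tidyr::expand_grid(condition = c("euploid", "aneuploid"),
                                  replicate = seq_len(config$n_replicates)) %>%
      mutate(sample_id = paste0(.data$condition, "_rep", .data$replicate)) %>%
      select("sample_id", "condition", "replicate")

    expr_log2 <- rnorm(nrow(genes), config$expression_log2_mean,
                       config$expression_log2_sd)
    expression <- tibble(gene_id = genes$gene_id,
                         chromosome = genes$chromosome,
                         expr_log2 = expr_log2)
    dup <- !is.null(config$duplicated_chromosome) &
      genes$chromosome == (config$duplicated_chromosome %||% "")

    # per-gene extended-window base weights and stall positions
    ext_len <- 24L + genes$n_codons + 20L
    stalls <- genome$truth$stalls

    per_sample <- lapply(seq_len(nrow(samples)), function(si) {
      cond <- samples$condition[si]
      mass <- 2^expr_log2 * genes$n_codons
      if (cond == "aneuploid") mass[dup] <- mass[dup] * config$dosage_fold
      gene_tot <- as.integer(rmultinom(1, config$depth, mass / sum(mass)))
      counts <- vector("list", nrow(genes))
      for (i in seq_len(nrow(genes))) {
        m <- genes$n_codons[i]
        w <- c(rep(config$utr_weight, 24), rep(1, m), rep(config$utr_weight, 20))
        if (nrow(stalls) > 0) {
          st <- stalls[stalls$gene_id == genes$gene_id[i] &
                         stalls$condition == cond, ]
          if (nrow(st) > 0) w[24L + st$codon] <- w[24L + st$codon] * st$fold
        }
        alpha <- config$dispersion * w / mean(w)
        counts[[i]] <- rdirmult(gene_tot[i], alpha, w)
      }
      tibble(
        sample_id = samples$sample_id[si],
        gene_id = rep(genes$gene_id, ext_len),
        codon = unlist(lapply(genes$n_codons, function(m) {
          c(-24:-1, seq_len(m + 20L))
        })),
        count = unlist(counts)
      )
    })

    structure(
      list(counts = bind_rows(per_sample), samples = samples,
           truth = list(stalls = stalls, expression = expression),
           config = config),
      class = "ribo_footprints"
    )
  })
}

#' @export
print.ribo_footprints <- function(x, ...) {
  cat("<ribo_footprints> ", length(unique(x$counts$gene_id)), " genes x ",
      nrow(x$samples), " samples; ", sum(x$counts$count), " footprints\n",
      sep = "")
  invisible(x)
}

#' Emit read-start records with known P-site truth
#'
#' Expands the codon counts of one simulated sample into per-read 5' end
#' records: each read's 5' end is placed exactly 12 nt upstream (in the
#' reading direction) of the first nucleotide of its P-site codon, on the
#' gene's strand. `frame_jitter` optionally shifts a uniform 0/1/2 nt offset
#' into each 5' end, for exercising the reading-frame QC.
#'
#' @param footprints A `ribo_footprints`.
#' @param genome The matching `ribo_genome`.
#' @param sample_id Sample to emit (default: first).
#' @param offset_nt P-site offset used when placing 5' ends.
#' @param frame_jitter If `TRUE`, add a uniform 0/1/2 nt jitter.
#' @return A tibble (`read_id`, `chromosome`, `strand`, `pos5` 1-based 5'
#'   position, and the ground truth `gene_id`, `codon`).
#' @export
emit_read_starts <- function(footprints, genome,
                             sample_id = footprints$samples$sample_id[1],
                             offset_nt = 12, frame_jitter = FALSE) {
  stopifnot(inherits(footprints, "ribo_footprints"), inherits(genome, "ribo_genome"))
  cnt <- footprints$counts %>%
    filter(.data$sample_id == .env$sample_id, .data$count > 0) %>%
    inner_join(genome$genes, by = "gene_id")
  # nt offset of the codon's first nucleotide from the A of ATG
  off <- ifelse(cnt$codon > 0, 3L * (cnt$codon - 1L), 3L * cnt$codon)
  psite <- ifelse(cnt$strand == "+", cnt$cds_start + off, cnt$cds_end - off)
  pos5 <- ifelse(cnt$strand == "+", psite - offset_nt, psite + offset_nt)
  reads <- tibble(
    chromosome = rep(cnt$chromosome, cnt$count),
    strand = rep(cnt$strand, cnt$count),
    pos5 = rep(as.integer(pos5), cnt$count),
    gene_id = rep(cnt$gene_id, cnt$count),
    codon = rep(cnt$codon, cnt$count)
  )
  if (frame_jitter) {
    j <- sample(0:2, nrow(reads), replace = TRUE)
    reads$pos5 <- reads$pos5 + ifelse(reads$strand == "+", j, -j)
  }
  reads %>%
    mutate(read_id = sprintf("read%07d", row_number())) %>%
    select("read_id", "chromosome", "strand", "pos5", "gene_id", "codon")
}

#' Write / read a plain read-start table
#'
#' On disk the table is tab-separated with a 0-based `pos0` column
#' (`read_id`, `chromosome`, `strand`, `pos0`); in memory the package uses
#' 1-based `pos5`.
#'
#' @param reads Tibble with `read_id`, `chromosome`, `strand`, `pos5`.
#' @param path Output path.
#' @return `write_read_starts()` returns `path` invisibly;
#'   `read_read_starts()` returns the in-memory (1-based) tibble.
#' @export
write_read_starts <- function(reads, path) {
  reads %>%
    mutate(pos0 = .data$pos5 - 1L) %>%
    select("read_id", "chromosome", "strand", "pos0") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_read_starts
#' @export
read_read_starts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    read_id = readr::col_character(),
                    chromosome = readr::col_character(),
                    strand = readr::col_character(),
                    pos0 = readr::col_integer())) %>%
    mutate(pos5 = .data$pos0 + 1L) %>%
    select("read_id", "chromosome", "strand", "pos5")
}
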