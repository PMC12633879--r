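# Synthetic genome generator: single-exon gene models with planted stall
# residues, assembled into chromosome sequences for read-level testing.

#' Generate a synthetic yeast-like genome with planted stall sites
#'
#' Builds `n_genes` single-exon genes (ATG start, stop end, no internal
#' stops, length divisible by 3), assigns them round-robin to chromosomes on
#' random strands, embeds them in intergenic spacer sequence, and plants the
#' stall sites requested by `config$stall_specs`: the residue decoded at
#' each stall codon (P site) and the following codon (A site) is drawn from
#' the spec's weighted residue sets; everywhere else codons are drawn
#' uniformly from the 61 sense codons. Stall codons are restricted to the
#' gene body (codons 21..n-20) with at least a 10-codon flank inside the
#' CDS, so every planted site is testable and motif-extractable downstream.
#'
#' @param config A [sim_config()].
#' @return A `ribo_genome` list with elements
#'   * `genes`: tibble of gene models (`gene_id`, `chromosome`, `strand`,
#'     `cds_start`, `cds_end` 1-based inclusive genomic coordinates,
#'     `cds_seq`, `protein` with terminal `*`, `n_codons` including stop);
#'   * `chrom_seq`: named character vector of chromosome sequences;
#'   * `truth`: list with `stalls`, a tibble of planted sites (`gene_id`,
#'     `codon`, `fold`, `condition`, realized `p_residue`, `a_residue`).
#' @examples
#' g <- generate_genome(sim_config(seed = 7, n_genes = 20))
#' g$genes
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    len <- sample(seq(config$codon_length_range[1], config$codon_length_range[2]),
                  n, replace = TRUE)
    genes <- tibble(
      gene_id = sprintf("gene%04d", seq_len(n)),
      chromosome = config$chromosomes[(seq_len(n) - 1) %% config$n_chromosomes + 1],
      strand = sample(c("+", "-"), n, replace = TRUE),
      n_codons = as.integer(len)
    )

    # plant stall sites (distinct gene/codon pairs across all specs)
    stalls <- plant_stall_sites(genes, config$stall_specs)

    # codon sequences: ATG | background sense codons | stop
    codon_mat <- lapply(seq_len(n), function(i) {
      m <- len[i]
      cods <- c("ATG",
                SENSE_CODONS[sample.int(length(SENSE_CODONS), m - 2, replace = TRUE)],
                STOP_CODONS[sample.int(length(STOP_CODONS), 1)])
      cods
    })
    if (nrow(stalls) > 0) {
      # plant A-site residues first, then P-site residues, so the residue at
      # every stall codon is exactly the drawn P-site residue
      for (pass in c("a", "p")) {
        for (j in seq_len(nrow(stalls))) {
          gi <- match(stalls$gene_id[j], genes$gene_id)
          if (pass == "a" && !is.na(stalls$a_residue[j])) {
            codon_mat[[gi]][stalls$codon[j] + 1] <-
              sample_codons_for_aa(stalls$a_residue[j])
          }
          if (pass == "p" && !is.na(stalls$p_residue[j])) {
            codon_mat[[gi]][stalls$codon[j]] <-
              sample_codons_for_aa(stalls$p_residue[j])
          }
        }
      }
    }
    genes$cds_seq <- vapply(codon_mat, paste0, character(1), collapse = "")
    genes$protein <- translate_cds(genes$cds_seq)

    # record realized stall residues from the final proteome
    if (nrow(stalls) > 0) {
      gi <- match(stalls$gene_id, genes$gene_id)
      stalls$p_residue <- substr(genes$protein[gi], stalls$codon, stalls$codon)
      stalls$a_residue <- substr(genes$protein[gi], stalls$codon + 1, stalls$codon + 1)
    }

    # assemble chromosomes: 500-nt spacers between genes, minus-strand genes
    # inserted as the reverse complement of their CDS
    gap <- 500L
    chrom_seq <- setNames(vector("list", config$n_chromosomes), config$chromosomes)
    starts <- integer(n)
    ends <- integer(n)
    for (ch in config$chromosomes) {
      idx <- which(genes$chromosome == ch)
      pieces <- character(0)
      pos <- 0L
      for (i in idx) {
        pieces <- c(pieces, random_dna(gap))
        pos <- pos + gap
        cds_len <- 3L * genes$n_codons[i]
        insert <- if (genes$strand[i] == "+") genes$cds_seq[i] else revcomp(genes$cds_seq[i])
        starts[i] <- pos + 1L
        ends[i] <- pos + cds_len
        pieces <- c(pieces, insert)
        pos <- pos + cds_len
      }
      pieces <- c(pieces, random_dna(gap))
      chrom_seq[[ch]] <- paste0(pieces, collapse = "")
    }
    genes$cds_start <- starts
    genes$cds_end <- ends
    genes <- genes[, c("gene_id", "chromosome", "strand", "cds_start",
                       "cds_end", "cds_seq", "protein", "n_codons")]

    structure(
      list(genes = genes, chrom_seq = unlist(chrom_seq),
           truth = list(stalls = stalls), config = config),
      class = "ribo_genome"
    )
  })
}

#' @export
print.ribo_genome <- function(x, ...) {
  cat("<ribo_genome> ", nrow(x$genes), " genes on ",
      length(x$chrom_seq), " chromosomes; ",
      nrow(x$truth$stalls), " planted stall sites\n", sep = "")
  invisible(x)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Sample planted stall positions for every spec; keeps gene/codon pairs
# distinct and inside the testable body range with full 10-codon flanks.
plant_stall_sites <- function(genes, stall_specs) {
  out <- list()
  taken <- character(0)
  for (s in stall_specs) {
    if (s$n_sites == 0) next
    rows <- vector("list", s$n_sites)
    for (j in seq_len(s$n_sites)) {
      for (try in 1:200) {
        gi <- sample.int(nrow(genes), 1)
        m <- genes$n_codons[gi]
        lo <- 21L
        hi <- m - 21L  # keep the A site and a 10-codon 3' flank inside the CDS
        if (hi < lo) next
        rel <- if (is.null(s$placement_bias)) runif(1) else
          rbeta(1, s$placement_bias[1], s$placement_bias[2])
        codon <- lo + as.integer(floor(rel * (hi - lo + 1)))
        codon <- min(codon, hi)
        key <- paste(genes$gene_id[gi], codon)
        # keep P/A plantings of different sites from touching
        near <- paste(genes$gene_id[gi], c(codon - 1L, codon, codon + 1L))
        if (!any(near %in% taken)) {
          taken <- c(taken, key)
          rows[[j]] <- tibble(
            gene_id = genes$gene_id[gi], codon = codon, fold = s$fold,
            condition = s$affected_condition,
            p_residue = if (is.null(s$p_site_residues)) NA_character_ else
              sample(names(s$p_site_residues), 1, prob = s$p_site_residues),
            a_residue = if (is.null(s$a_site_residues)) NA_character_ else
              sample(names(s$a_site_residues), 1, prob = s$a_site_residues)
          )
          break
        }
      }
      if (is.null(rows[[j]])) {
        abort("could not place all stall sites; increase gene number or length")
      }
    }
    out <- c(out, rows)
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), codon = integer(), fold = numeric(),
                  condition = character(), p_residue = character(),
                  a_residue = character()))
  }
  bind_rows(out)
}
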