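# Gene-model IO: GFF3/FASTA reading with the analysis exclusion rules,
# writing of simulated genomes, and proteome background frequencies.

#' Load validated gene models from GFF3 + FASTA
#'
#' Reads CDS features from a GFF3 file and the corresponding genome FASTA,
#' and builds one gene model per single-exon, ATG-initiated gene.
#' Minus-strand CDSs are reverse-complemented before translation. Genes are
#' excluded (with a reason) when they have more than one CDS segment
#' (treated as intron-containing), do not start with ATG, have a length not
#' divisible by 3, or contain an internal stop codon.
#'
#' @param gff3 Path to a GFF3 file with CDS features (1-based inclusive
#'   coordinates; segments grouped by `Parent`, falling back to `ID`).
#' @param fasta Path to the genome FASTA the coordinates refer to.
#' @return A list with `models` (tibble `gene_id`, `chromosome`, `strand`,
#'   `cds_start`, `cds_end`, `cds_seq`, `protein`, `n_codons`) and
#'   `excluded` (tibble `gene_id`, `reason`).
#' @export
load_gene_models <- function(gff3, fasta) {
  gr <- rtracklayer::import(gff3)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0) abort("no CDS features found in the GFF3 file")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))

  parent_raw <- S4Vectors::mcols(gr)$Parent
  parent <- if (is.null(parent_raw)) {
    rep(NA_character_, length(gr))
  } else if (methods::is(parent_raw, "List")) {
    vapply(as.list(parent_raw), function(v) {
      if (length(v)) as.character(v[[1]]) else NA_character_
    }, character(1))
  } else {
    as.character(parent_raw)
  }
  id <- as.character(S4Vectors::mcols(gr)$ID %||% rep(NA_character_, length(gr)))
  gene <- ifelse(is.na(parent) | parent == "", id, parent)
  gene <- sub("^gene:", "", gene)
  if (any(is.na(gene))) abort("CDS features must carry a Parent or ID attribute")

  feats <- tibble(
    gene_id = gene,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  bad_chrom <- setdiff(unique(feats$chromosome), names(seqs))
  if (length(bad_chrom) > 0) {
    abort(paste0("GFF3 references sequences absent from the FASTA: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  oob <- feats$start < 1 | feats$end > Biostrings::width(seqs)[match(feats$chromosome, names(seqs))]
  if (any(oob)) {
    abort(paste0("CDS coordinates out of sequence bounds for: ",
                 paste(unique(feats$gene_id[oob]), collapse = ", ")))
  }

  models <- list()
  excluded <- list()
  for (g in unique(feats$gene_id)) {
    f <- feats[feats$gene_id == g, ]
    if (nrow(f) > 1) {
      excluded[[g]] <- "intron"
      next
    }
    nt <- as.character(Biostrings::subseq(seqs[[f$chromosome]], f$start, f$end))
    if (f$strand == "-") nt <- revcomp(nt)
    if (nchar(nt) %% 3 != 0) {
      excluded[[g]] <- "length_not_divisible_by_3"
      next
    }
    if (substr(nt, 1, 3) != "ATG") {
      excluded[[g]] <- "no_atg"
      next
    }
    prot <- translate_cds(nt)
    body <- substr(prot, 1, nchar(prot) - 1)
    if (grepl("\\*", body)) {
      warn(paste0("gene ", g, " contains an internal stop codon; excluded"))
      excluded[[g]] <- "internal_stop"
      next
    }
    models[[g]] <- tibble(
      gene_id = g, chromosome = f$chromosome, strand = f$strand,
      cds_start = f$start, cds_end = f$end, cds_seq = nt, protein = prot,
      n_codons = nchar(nt) %/% 3L
    )
  }
  list(
    models = if (length(models)) bind_rows(models) else
      tibble(gene_id = character(), chromosome = character(),
             strand = character(), cds_start = integer(), cds_end = integer(),
             cds_seq = character(), protein = character(), n_codons = integer()),
    excluded = tibble(gene_id = names(excluded),
                      reason = unlist(excluded, use.names = FALSE) %||% character())
  )
}

#' Write a simulated genome to FASTA + GFF3
#'
#' @param genome A `ribo_genome` from [generate_genome()].
#' @param fasta,gff3 Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_genome <- function(genome, fasta, gff3) {
  stopifnot(inherits(genome, "ribo_genome"))
  seqs <- Biostrings::DNAStringSet(genome$chrom_seq)
  Biostrings::writeXStringSet(seqs, fasta)

  g <- genome$genes
  gene_gr <- GenomicRanges::GRanges(
    seqnames = g$chromosome,
    ranges = IRanges::IRanges(g$cds_start, g$cds_end),
    strand = g$strand,
    source = "ribopause", type = "gene", ID = g$gene_id
  )
  cds_gr <- GenomicRanges::GRanges(
    seqnames = g$chromosome,
    ranges = IRanges::IRanges(g$cds_start, g$cds_end),
    strand = g$strand,
    source = "ribopause", type = "CDS", phase = 0L,
    ID = paste0(g$gene_id, ".cds"), Parent = g$gene_id
  )
  all_gr <- c(gene_gr, cds_gr)
  all_gr <- all_gr[order(as.character(GenomicRanges::seqnames(all_gr)),
                         GenomicRanges::start(all_gr))]
  rtracklayer::export(all_gr, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Proteome background residue frequencies
#'
#' Counts every residue (20 amino acids plus the stop symbol `*`) over the
#' proteins of the chosen scope and returns background frequencies for the
#' motif-enrichment test. The `measured_genes` scope restricts the
#' background to the genes actually profiled.
#'
#' @param models Gene-model tibble (needs `gene_id`, `protein`), e.g.
#'   `generate_genome(...)$genes` or `load_gene_models(...)$models`.
#' @param scope `"all_genes"` or `"measured_genes"`.
#' @param measured Character vector of measured gene ids (required when
#'   `scope = "measured_genes"`).
#' @return A `ribo_proteome` list: `proteins` (named character), `counts`
#'   (named integer over the 21 symbols), `freq` (frequencies summing to
#'   1), `total`.
#' @export
build_proteome <- function(models, scope = c("all_genes", "measured_genes"),
                           measured = NULL) {
  scope <- match.arg(scope)
  stopifnot(nrow(models) > 0)
  if (scope == "measured_genes") {
    if (is.null(measured)) abort("scope = 'measured_genes' requires 'measured'")
    models <- models[models$gene_id %in% measured, ]
    if (nrow(models) == 0) abort("no models left in the measured scope")
  }
  prots <- setNames(models$protein, models$gene_id)
  tab <- table(factor(strsplit(paste0(prots, collapse = ""), "")[[1]],
                      levels = AA_ALPHABET_21))
  counts <- setNames(as.integer(tab), AA_ALPHABET_21)
  total <- sum(counts)
  structure(
    list(proteins = prots, counts = counts, freq = counts / total,
         total = total, scope = scope),
    class = "ribo_proteome"
  )
}

#' @export
print.ribo_proteome <- function(x, ...) {
  cat("<ribo_proteome> ", length(x$proteins), " proteins, ",
      x$total, " residues (scope: ", x$scope, ")\n", sep = "")
  invisible(x)
}

#' Write a proteome to FASTA
#'
#' @param proteome A `ribo_proteome`.
#' @param path Output path.
#' @export
write_proteome <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome$proteins), path)
  invisible(path)
}
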