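# Standard genetic code lookups shared by the generators and annotation IO.

GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE

SENSE_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL != "*"]
STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"]
CODONS_BY_AA <- split(names(GENETIC_CODE_TBL), unname(GENETIC_CODE_TBL))
AA_ALPHABET_20 <- sort(unique(unname(GENETIC_CODE_TBL[GENETIC_CODE_TBL != "*"])))
AA_ALPHABET_21 <- c(AA_ALPHABET_20, "*")

# sample one codon for each residue in `aa` (uniform over synonymous codons)
sample_codons_for_aa <- function(aa) {
  vapply(aa, function(r) {
    cods <- CODONS_BY_AA[[r]]
    cods[sample.int(length(cods), 1)]
  }, character(1), USE.NAMES = FALSE)
}

# translate a vector of in-frame CDS strings to proteins (with terminal "*")
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     if.fuzzy.codon = "X"))
}
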