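# Shared fixtures: small simulated datasets built in code.

small_config <- function(seed = 101, depth = 1e5, ...) {
  sim_config(seed = seed, n_genes = 40, codon_length_range = c(60, 120),
             n_chromosomes = 4, duplicated_chromosome = "chrII",
             depth = depth, ...)
}

replicate_pairs <- function(n = 2) {
  tibble::tibble(replicate = seq_len(n),
                 euploid = paste0("euploid_rep", seq_len(n)),
                 aneuploid = paste0("aneuploid_rep", seq_len(n)))
}

# hand-built single-gene count table over the extended window
one_gene_counts <- function(n_codons, cds_counts,
                            sample_id = "s1", gene_id = "g1") {
  tibble::tibble(
    sample_id = sample_id, gene_id = gene_id,
    codon = c(-24:-1, seq_len(n_codons + 20L)),
    count = c(rep(0L, 24), cds_counts, rep(0L, 20))
  )
}

one_gene_model <- function(n_codons, gene_id = "g1", chromosome = "chrI") {
  tibble::tibble(gene_id = gene_id, chromosome = chromosome, strand = "+",
                 cds_start = 1L, cds_end = 3L * n_codons,
                 cds_seq = NA_character_, protein = NA_character_,
                 n_codons = as.integer(n_codons))
}

# independent brute-force two-sided Fisher p from log-binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + c
  n1 <- a + b
  n2 <- c + d
  lo <- max(0, k - n2)
  hi <- min(k, n1)
  xs <- lo:hi
  logp <- lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(n1 + n2, k)
  obs <- logp[xs == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

# independent BH oracle: sort, cumulative minimum from the largest p
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

lognorm_sd_test <- function(cv) sqrt(log(1 + cv^2))

# exhaustive two-sided Wilcoxon rank-sum p by enumerating group assignments
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(i) sum(ranks[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
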