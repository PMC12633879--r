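# Generators: determinism, construction invariants, planted truth.

test_that("genome generation is deterministic and well-formed", {
  cfg <- small_config(seed = 7)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))

  d <- withr::local_tempdir()
  write_genome(g1, file.path(d, "x1.fa"), file.path(d, "x1.gff3"))
  write_genome(g2, file.path(d, "x2.fa"), file.path(d, "x2.gff3"))
  expect_identical(readBin(file.path(d, "x1.fa"), "raw", 1e7),
                   readBin(file.path(d, "x2.fa"), "raw", 1e7))
  expect_identical(readBin(file.path(d, "x1.gff3"), "raw", 1e7),
                   readBin(file.path(d, "x2.gff3"), "raw", 1e7))

  # every CDS: ATG start, stop end, no internal stops, length %% 3 == 0
  expect_true(all(nchar(g1$genes$cds_seq) %% 3 == 0))
  expect_true(all(substr(g1$genes$cds_seq, 1, 3) == "ATG"))
  prot <- g1$genes$protein
  expect_true(all(substr(prot, nchar(prot), nchar(prot)) == "*"))
  expect_false(any(grepl("\\*", substr(prot, 1, nchar(prot) - 1))))
  expect_true(all(nchar(prot) == g1$genes$n_codons))
})

test_that("length range below 41 codons is a configuration error", {
  expect_error(sim_config(codon_length_range = c(30, 100)), "41")
})

test_that("planted stall residues appear in the translated proteome", {
  cfg <- small_config(seed = 13, stall_specs = list(
    stall_spec(n_sites = 15, p_site_residues = c(K = 1),
               a_site_residues = c(G = 1))))
  g <- generate_genome(cfg)
  st <- g$truth$stalls
  expect_equal(nrow(st), 15)
  prot <- setNames(g$genes$protein, g$genes$gene_id)
  expect_true(all(substr(prot[st$gene_id], st$codon, st$codon) == "K"))
  expect_true(all(substr(prot[st$gene_id], st$codon + 1, st$codon + 1) == "G"))
  # stall codons lie in the testable body range
  n_cod <- setNames(g$genes$n_codons, g$genes$gene_id)
  expect_true(all(st$codon >= 21 & st$codon <= n_cod[st$gene_id] - 21))
})

test_that("footprint counts are deterministic and conserve depth", {
  cfg <- small_config(seed = 19)
  g <- generate_genome(cfg)
  fp1 <- simulate_footprints(g)
  fp2 <- simulate_footprints(g)
  expect_identical(fp1$counts, fp2$counts)
  totals <- dplyr::count(fp1$counts, sample_id, wt = count)
  expect_true(all(totals$n == cfg$depth))
})

test_that("multinomial limit gives uniform within-gene CDS counts", {
  # dispersion -> Inf, equal expression, no stalls: chi-square GOF should
  # not reject uniformity for >= 95% of genes at alpha = 0.01
  cfg <- sim_config(seed = 23, n_genes = 60, codon_length_range = c(60, 100),
                    n_chromosomes = 4, duplicated_chromosome = NULL,
                    expression_log2_sd = 0, dispersion = Inf, depth = 5e5,
                    n_replicates = 1)
  g <- generate_genome(cfg)
  fp <- simulate_footprints(g)
  cds <- dplyr::inner_join(fp$counts,
                           dplyr::select(g$genes, gene_id, n_codons),
                           by = "gene_id")
  cds <- cds[cds$sample_id == "euploid_rep1" & cds$codon >= 1 &
               cds$codon <= cds$n_codons, ]
  pvals <- vapply(split(cds$count, cds$gene_id), function(x) {
    suppressWarnings(stats::chisq.test(x)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("dosage fold appears in aneuploid counts on the duplicated chromosome", {
  cfg <- sim_config(seed = 29, n_genes = 120, codon_length_range = c(80, 160),
                    n_chromosomes = 8, duplicated_chromosome = "chrIII",
                    depth = 1e6, n_replicates = 1)
  g <- generate_genome(cfg)
  fp <- simulate_footprints(g)
  tot <- fp$counts |>
    dplyr::count(sample_id, gene_id, wt = count, name = "reads") |>
    tidyr::pivot_wider(names_from = sample_id, values_from = reads) |>
    dplyr::inner_join(dplyr::select(g$genes, gene_id, chromosome),
                      by = "gene_id")
  ratio <- (tot$aneuploid_rep1 / sum(tot$aneuploid_rep1)) /
    (tot$euploid_rep1 / sum(tot$euploid_rep1))
  ratio <- ratio / stats::median(ratio)
  dup_med <- stats::median(ratio[tot$chromosome == "chrIII"])
  expect_gte(dup_med, 1.9)
  expect_lte(dup_med, 2.1)
})

test_that("read-start emitter places 5' ends 12 nt from the true P site", {
  cfg <- small_config(seed = 31, depth = 2e4)
  g <- generate_genome(cfg)
  fp <- simulate_footprints(g)
  reads <- emit_read_starts(fp, g, "euploid_rep1")
  gm <- g$genes[match(reads$gene_id, g$genes$gene_id), ]
  off <- ifelse(reads$codon > 0, 3L * (reads$codon - 1L), 3L * reads$codon)
  expected <- ifelse(gm$strand == "+", gm$cds_start + off - 12L,
                     gm$cds_end - off + 12L)
  expect_identical(reads$pos5, as.integer(expected))
})

test_that("spike-in simulation honours exact scale factors at zero noise", {
  cfg <- sim_config(seed = 37, spike = spike_config(
    n_spike_genes = 10, scale_factors = c(1, 0.5), noise_cv = 0,
    n_expr_genes = 20, n_defect_genes = 5, n_aneuploids = 1,
    timepoints = c("log", "d1"), replicates = 1))
  sim <- simulate_spikein(cfg)
  sp <- sim$counts[sim$counts$gene_id %in% sim$spike_genes, ]
  wide <- tidyr::pivot_wider(sp, id_cols = gene_id,
                             names_from = sample_id, values_from = count)
  s <- sim$samples$sample_id
  # factors recycle over samples: even samples at half the reference
  expect_equal(wide[[s[2]]], wide[[s[1]]] * 0.5)
  # planted defect genes recorded in truth and only there
  expect_length(sim$truth$defect_genes, 5)
  expect_true(all(sim$truth$defect_genes %in% sim$counts$gene_id))
})

test_that("screen counts are deterministic with class-appropriate enrichment", {
  cfg <- sim_config(seed = 41, screen = screen_config(
    n_genes = 300, n_early = 4, n_late = 4, effect_log2 = 4,
    nb_dispersion = 0.05, depth = 3e5))
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$counts, s2$counts)

  mean_count <- function(strain, tp, genes) {
    ids <- s1$samples$sample_id[s1$samples$strain == strain &
                                  s1$samples$timepoint == tp]
    sub <- s1$counts[s1$counts$sample_id %in% ids &
                       s1$counts$gene_id %in% genes, ]
    mean(sub$count)
  }
  early <- s1$truth$hits$gene_id[s1$truth$hits$class == "early"]
  late <- s1$truth$hits$gene_id[s1$truth$hits$class == "late"]
  # late hits rise only at d28; early hits at both d1 and d28
  expect_gt(mean_count("aneuploid", "d28", late),
            4 * mean_count("aneuploid", "pool", late))
  expect_lt(mean_count("aneuploid", "d1", late),
            2 * mean_count("aneuploid", "pool", late))
  expect_gt(mean_count("aneuploid", "d1", early),
            4 * mean_count("aneuploid", "pool", early))
  # euploid pools unperturbed
  expect_lt(mean_count("euploid", "d28", c(early, late)),
            2 * mean_count("euploid", "pool", c(early, late)))
})
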