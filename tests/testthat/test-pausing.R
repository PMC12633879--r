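# Trace correlation, Fisher/BH oracles, peak calling, positional and
# chromosomal statistics.

test_that("uncentered correlation matches the direct formula", {
  expect_equal(uncentered_correlation(1:5, 1:5), 1)
  expect_equal(uncentered_correlation(c(1, 2, 3), 7 * c(1, 2, 3)), 1)
  expect_equal(uncentered_correlation(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(uncentered_correlation(1:3, 1:4), "equal length")
  expect_warning(z <- uncentered_correlation(c(0, 0), c(1, 2)), "all-zero")
  expect_equal(z, 0)
})

test_that("Fisher exact p matches enumeration oracle and fisher.test", {
  set.seed(73)
  for (i in 1:1000) {
    a <- sample(0:60, 1); b <- sample(0:440, 1)
    c <- sample(0:60, 1); d <- sample(0:440, 1)
    p <- fisher_exact_2x2(a, b, c, d)
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
  # spot-check the standard library on a subset
  for (i in 1:50) {
    a <- sample(0:40, 1); b <- sample(0:200, 1)
    c <- sample(0:40, 1); d <- sample(0:200, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(2, 98, 2, 98), 1)
  # row swap leaves the two-sided p unchanged
  expect_equal(fisher_exact_2x2(0, 100, 20, 180),
               fisher_exact_2x2(20, 180, 0, 100))
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
})

test_that("codon Fisher test excludes the codon from its body column", {
  # (0,100 / 20,180): oracle to 1e-9
  expect_equal(codon_fisher_test(0, 100, 20, 200),
               oracle_fisher_p(0, 100, 20, 180), tolerance = 1e-9)
  expect_error(codon_fisher_test(10, 5, 0, 10), "exceed")
})

test_that("BH adjustment equals the sort/cummin oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(79)
  for (i in 1:25) {
    p <- runif(400)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # one large family
  p <- runif(10000)
  expect_identical(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Wilcoxon exact path equals full enumeration for small n", {
  res <- wilcoxon_rank_sum(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)
  set.seed(83)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1), 3); y <- round(runif(n2), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y))
  }
  # identical multisets are ties -> approximate path, p ~ 1
  same <- wilcoxon_rank_sum(c(0.2, 0.4, 0.6) + 0, c(0.2, 0.4, 0.6))
  expect_false(same$exact)
  expect_gt(same$p_value, 0.9)
})

test_that("identical matrices give correlation 1 and zero peak calls", {
  g <- generate_genome(small_config(seed = 87))
  fp <- simulate_footprints(g)
  eu <- fp$counts[fp$counts$sample_id == "euploid_rep1", ]
  both <- dplyr::bind_rows(eu, dplyr::mutate(eu, sample_id = "aneuploid_rep1"))
  occ <- normalize_occupancy(both, g$genes)
  pairs <- tibble::tibble(replicate = 1L, euploid = "euploid_rep1",
                          aneuploid = "aneuploid_rep1")
  cors <- correlate_all(occ, g$genes, pairs)
  expect_true(all(abs(cors$correlation - 1) < 1e-12))
  pk <- call_peaks(both, g$genes, pairs)
  expect_equal(nrow(tidy(pk)), 0)
})

test_that("shuffling the gene pairing destroys high correlations", {
  g <- generate_genome(small_config(seed = 89, depth = 2e5))
  fp <- simulate_footprints(g)
  occ <- normalize_occupancy(fp$counts, g$genes)
  pairs <- replicate_pairs(1)
  paired <- correlate_all(occ, g$genes, pairs)
  # shuffle: relabel the aneuploid traces with a permuted gene map
  an <- occ[occ$sample_id == "aneuploid_rep1", ]
  set.seed(1)
  ids <- unique(an$gene_id)
  perm <- setNames(sample(ids), ids)
  lens <- setNames(g$genes$n_codons, g$genes$gene_id)
  an_perm <- an |>
    dplyr::mutate(gene_id = unname(perm[gene_id])) |>
    dplyr::filter(codon >= 1, codon <= lens[gene_id])
  shuf <- dplyr::bind_rows(occ[occ$sample_id == "euploid_rep1", ], an_perm)
  shuffled <- correlate_all(shuf, g$genes, pairs)
  expect_lt(median(shuffled$correlation), median(paired$correlation))
})

test_that("peak-call directions are always consistent with the occupancy ratio", {
  cfg <- small_config(seed = 93, depth = 2e5,
                      stall_specs = list(stall_spec(n_sites = 10, fold = 6)))
  g <- generate_genome(cfg)
  fp <- simulate_footprints(g)
  pk <- call_peaks(fp$counts, g$genes, replicate_pairs(2))
  calls <- tidy(pk)
  expect_gt(nrow(calls), 0)
  expect_true(all((calls$ratio > 1) == (calls$direction == "aneuploid_higher")))
  expect_true(all(calls$fdr >= calls$p_value))
  expect_true(all(calls$relative_position > 0 & calls$relative_position <= 1))
})

test_that("replicate combination unions calls and drops direction conflicts", {
  mk_calls <- function(rep, gene, codon, dir) {
    tibble::tibble(replicate = rep, gene_id = gene, codon = codon,
                   p_value = 1e-4, fdr = 1e-3, direction = dir, ratio = ifelse(
                     dir == "aneuploid_higher", 3, 1 / 3),
                   relative_position = codon / 100)
  }
  pk <- structure(list(
    calls = dplyr::bind_rows(
      mk_calls(1L, "gA", 30L, "aneuploid_higher"),
      mk_calls(1L, "gB", 40L, "euploid_higher"),
      mk_calls(2L, "gA", 30L, "aneuploid_higher"),
      mk_calls(2L, "gC", 50L, "aneuploid_higher"),
      mk_calls(1L, "gD", 60L, "aneuploid_higher"),
      mk_calls(2L, "gD", 60L, "euploid_higher")),
    n_tested = tibble::tibble(replicate = 1:2, n_tested = 1000L,
                              n_significant = 3L),
    alpha = 0.05, genes = c("gA", "gB", "gC", "gD")), class = "ribo_peaks")
  expect_warning(cmb <- combine_replicates(pk), "opposite directions")
  sites <- tidy(cmb)
  expect_setequal(sites$gene_id, c("gA", "gB", "gC"))
  expect_equal(sites$n_replicates[sites$gene_id == "gA"], 2L)
  expect_equal(cmb$conflicts$gene_id, "gD")
  gl <- glance(cmb)
  expect_equal(gl$n_sites[gl$direction == "aneuploid_higher"], 2L)

  # identical replicate sets -> combined equals either set
  pk2 <- pk
  pk2$calls <- dplyr::bind_rows(mk_calls(1L, "gA", 30L, "aneuploid_higher"),
                                mk_calls(2L, "gA", 30L, "aneuploid_higher"))
  cmb2 <- combine_replicates(pk2)
  expect_equal(nrow(tidy(cmb2)), 1)
})

test_that("peak position test reproduces hand enumerations", {
  expect_equal(peak_position_test(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))$p_value, 0.1)
  same <- peak_position_test(c(0.1, 0.5, 0.9) + 0, c(0.1, 0.5, 0.9))
  expect_gt(same$p_value, 0.9)
})

test_that("chromosome enrichment matches closed-form tails", {
  models <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                           chromosome = rep(c("chrT", paste0("chr", 1:9)), 20))
  measured <- models$gene_id
  # all 20 peak genes on the target chromosome, background 10% on it
  peaks <- models$gene_id[models$chromosome == "chrT"]
  res <- chromosome_enrichment(peaks, measured, models, "chrT")
  expect_lt(res$p_value, 1e-19)
  expect_equal(res$p_value,
               1 / choose(200, 20), tolerance = 1e-12)
  # peak set = all measured -> p = 1
  all_res <- chromosome_enrichment(measured, measured, models, "chrT")
  expect_equal(all_res$p_value, 1)
  expect_error(chromosome_enrichment(c("nope"), measured, models, "chrT"),
               "subset")
  # null calibration: random subsets reject at ~alpha
  set.seed(97)
  rej <- mean(replicate(400, {
    chromosome_enrichment(sample(measured, 25), measured, models, "chrT")$p_value < 0.05
  }))
  expect_lt(rej, 0.1)
})
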