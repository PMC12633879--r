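# Spike-in slope normalization and the silencing-defect selection rule.

long_counts <- function(mat) {
  tibble::tibble(gene_id = rep(rownames(mat), ncol(mat)),
                 sample_id = rep(colnames(mat), each = nrow(mat)),
                 count = as.numeric(mat))
}

test_that("spike slope factors recover exact scalings", {
  m <- matrix(c(10, 20, 40, 80, 160, 320,
                20, 40, 80, 160, 320, 640), ncol = 2,
              dimnames = list(paste0("sp", 1:6), c("ref", "double")))
  cnt <- long_counts(m)
  for (method in c("logratio", "lad", "ols")) {
    sn <- spike_slope_factors(cnt, rownames(m), "ref", method = method)
    f <- tidy(sn)
    expect_equal(f$slope[f$sample_id == "double"], 2)
    expect_equal(f$factor[f$sample_id == "double"], 0.5)
    expect_equal(f$factor[f$sample_id == "ref"], 1)
  }
  expect_error(spike_slope_factors(cnt[cnt$gene_id %in% paste0("sp", 1:3), ],
                                   paste0("sp", 1:3), "ref"), "fewer than 5")
})

test_that("applying factors is idempotent and rescales column sums exactly", {
  cfg <- sim_config(seed = 109, spike = spike_config(
    n_spike_genes = 30, noise_cv = 0.15, n_expr_genes = 100,
    n_aneuploids = 1, replicates = 1))
  sim <- simulate_spikein(cfg)
  ref <- sim$samples$sample_id[1]
  sn <- spike_slope_factors(sim$counts, sim$spike_genes, ref)
  norm <- apply_factors(sim$counts, sn)
  refit <- spike_slope_factors(norm, sim$spike_genes, ref)
  expect_lt(max(abs(tidy(refit)$slope - 1)), 1e-6)
  # column sums scale exactly by the factors
  s0 <- dplyr::count(sim$counts, sample_id, wt = count, name = "total")
  s1 <- dplyr::count(norm, sample_id, wt = count, name = "total")
  f <- dplyr::inner_join(tidy(sn), dplyr::inner_join(s0, s1, by = "sample_id"),
                         by = "sample_id")
  expect_equal(f$total.y, f$total.x * f$factor)
  # identity factors are a no-op
  same <- apply_factors(sim$counts,
                        tibble::tibble(sample_id = unique(sim$counts$sample_id),
                                       factor = 1))
  expect_equal(same$count, sim$counts$count)
})

test_that("scale factors are recovered from noisy spikes within tolerance", {
  errs <- c()
  for (s in 1:3) {
    cfg <- sim_config(seed = 110 + s, spike = spike_config(
      n_spike_genes = 50, noise_cv = 0.1, n_expr_genes = 50,
      n_aneuploids = 2, replicates = 1))
    sim <- simulate_spikein(cfg)
    sn <- spike_slope_factors(sim$counts, sim$spike_genes,
                              sim$samples$sample_id[1])
    j <- dplyr::inner_join(tidy(sn), sim$truth$scale_factors, by = "sample_id")
    errs <- c(errs, abs(j$factor / j$norm_factor - 1))
  }
  expect_lte(median(errs), 0.02)
  expect_lte(max(errs), 0.1)
})

test_that("built-in contrast engine controls the null and finds planted changes", {
  set.seed(5)
  n <- 400
  base <- 2^rnorm(n, 8, 1)
  mk_sample <- function(mult, id) {
    tibble::tibble(gene_id = sprintf("g%03d", 1:n), sample_id = id,
                   count = base * mult * exp(rnorm(n, 0, lognorm_sd_test(0.2))))
  }
  # null: two identical conditions
  design <- tibble::tibble(
    sample_id = c("eu_log_1", "eu_log_2", "eu_d1_1", "eu_d1_2"),
    strain = "euploid", timepoint = rep(c("log", "d1"), each = 2))
  cnt <- dplyr::bind_rows(mk_sample(1, "eu_log_1"), mk_sample(1, "eu_log_2"),
                          mk_sample(1, "eu_d1_1"), mk_sample(1, "eu_d1_2"))
  st <- builtin_contrast_test(cnt, design)
  expect_lte(mean(st$fdr < 0.05), 0.10)

  # power: 8-fold planted changes, cv 0.2, n = 2
  up <- sprintf("g%03d", 1:40)
  mult_up <- ifelse(sprintf("g%03d", 1:n) %in% up, 8, 1)
  cnt2 <- dplyr::bind_rows(
    mk_sample(1, "eu_log_1"), mk_sample(1, "eu_log_2"),
    mk_sample(mult_up, "eu_d1_1"), mk_sample(mult_up, "eu_d1_2"))
  st2 <- builtin_contrast_test(cnt2, design)
  hits <- st2[st2$gene_id %in% up, ]
  expect_gte(mean(hits$fdr < 0.05 & hits$log2fc > 0), 0.9)
})

test_that("silencing-defect rule passes an exhaustive truth-table check", {
  aneus <- paste0("an", 1:4)
  tps <- c("d1", "d3")
  # enumerate all gene patterns: euploid repression significance per
  # timepoint (4 combos) x, per aneuploid, any-timepoint positive
  # significance (2 combos each)
  combos <- expand.grid(eu_d1 = c(TRUE, FALSE), eu_d3 = c(TRUE, FALSE),
                        a1 = c(TRUE, FALSE), a2 = c(TRUE, FALSE),
                        a3 = c(TRUE, FALSE), a4 = c(TRUE, FALSE))
  genes <- sprintf("G%03d", seq_len(nrow(combos)))
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    for (tp in tps) {
      sig <- co[[paste0("eu_", tp)]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = genes[i], contrast = "euploid_repression",
        strain = "euploid", timepoint = tp,
        log2fc = ifelse(sig, -2, -0.1), fdr = ifelse(sig, 0.001, 0.5))
    }
    for (k in 1:4) {
      sig <- co[[paste0("a", k)]]
      # significant at d1 only when flagged; never at d3
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = genes[i], contrast = "aneuploid_vs_euploid",
        strain = aneus[k], timepoint = "d1",
        log2fc = ifelse(sig, 2, 0.2), fdr = ifelse(sig, 0.01, 0.8))
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = genes[i], contrast = "aneuploid_vs_euploid",
        strain = aneus[k], timepoint = "d3", log2fc = 0.1, fdr = 0.9)
    }
  }
  stats <- dplyr::bind_rows(rows)
  got <- call_silencing_defect(stats, alpha = 0.05)
  want <- genes[(combos$eu_d1 | combos$eu_d3) &
                  combos$a1 & combos$a2 & combos$a3 & combos$a4]
  expect_setequal(got, sort(want))

  # 3-of-4 aneuploids is never enough
  expect_false(any(genes[combos$a1 & combos$a2 & combos$a3 & !combos$a4] %in% got))
  # significant repression with the wrong sign does not count
  neg <- stats
  neg$log2fc[neg$contrast == "euploid_repression"] <-
    abs(neg$log2fc[neg$contrast == "euploid_repression"])
  expect_length(call_silencing_defect(neg), 0)
  # a requested aneuploid missing from the table errors by name
  expect_error(call_silencing_defect(stats, aneuploids = c(aneus, "an5")), "an5")
  # dropping one aneuploid's rows can only grow the required intersection
  sub <- stats[stats$strain != "an4", ]
  got3 <- call_silencing_defect(sub)
  expect_true(all(got %in% got3))
})

test_that("planted silencing-defect genes are recovered end to end", {
  cfg <- sim_config(seed = 127, spike = spike_config(
    n_spike_genes = 40, noise_cv = 0.1, n_expr_genes = 300,
    n_defect_genes = 30, n_aneuploids = 4, replicates = 2, biol_cv = 0.15))
  sim <- simulate_spikein(cfg)
  sn <- spike_slope_factors(sim$counts, sim$spike_genes,
                            sim$samples$sample_id[1])
  norm <- apply_factors(sim$counts, sn, drop_spikes = TRUE)
  st <- builtin_contrast_test(norm, sim$samples)
  got <- call_silencing_defect(st)
  truth <- sim$truth$defect_genes
  sens <- mean(truth %in% got)
  expect_gte(sens, 0.95)
  expect_lte(length(setdiff(got, truth)), 3)
})
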