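test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_snps = 100), "sim_config")
  expect_error(sim_config(n_snps = 3, n_selected_loci = 4), "n_selected_loci")
  expect_error(sim_config(freq_high_group = 1.2), "proportions")
  expect_error(sim_config(missing_rate = -0.1), "proportions")
  expect_error(sim_config(n_lines = 0), "counts|n_high")
  expect_error(sim_config(n_high = 64, n_lines = 64), "n_high")
})

test_that("identical configs give byte-identical genotypes and phenotypes", {
  cfg <- sim_config(n_snps = 200, seed = 42)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$geno$map, b$geno$map)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_phenotypes(a$geno, a$truth, cfg),
                   simulate_phenotypes(b$geno, b$truth, cfg))
  # a different seed changes the draw
  c2 <- simulate_genotypes(sim_config(n_snps = 200, seed = 43))
  expect_false(identical(a$geno$calls, c2$geno$calls))
})

test_that("genotypes respect configured structure", {
  cfg <- sim_config(n_snps = 300, missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(cfg)
  expect_false(anyNA(sim$geno$calls))
  expect_true(all(sim$geno$calls %in% c(0L, 2L)))
  # positions strictly increasing within chromosomes
  by_chr <- split(sim$geno$map$pos, sim$geno$map$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  # selected loci exist in the map
  expect_true(all(sim$truth$selected_loci$marker %in% sim$geno$map$marker))
  # masked run has missing calls near the configured rate
  cfg2 <- sim_config(n_snps = 300, missing_rate = 0.1, seed = 3)
  sim2 <- simulate_genotypes(cfg2)
  expect_gt(mean(is.na(sim2$geno$calls)), 0.07)
  expect_lt(mean(is.na(sim2$geno$calls)), 0.13)
})

test_that("group frequencies at a selected locus match the binomial law", {
  # large panel: observed group frequencies within 3 binomial SDs of target
  cfg <- sim_config(n_lines = 2000, n_high = 1000, n_snps = 50,
                    n_selected_loci = 1, freq_high_group = 0.43,
                    freq_low_group = 0.03, missing_rate = 0, seed = 11)
  sim <- simulate_genotypes(cfg)
  j <- match(sim$truth$selected_loci$marker, sim$geno$map$marker)
  h <- sim$truth$groups$group == "H"
  p_h <- mean(sim$geno$calls[h, j]) / 2
  p_l <- mean(sim$geno$calls[!h, j]) / 2
  expect_lt(abs(p_h - 0.43), 3 * sqrt(0.43 * 0.57 / 1000))
  expect_lt(abs(p_l - 0.03), 3 * sqrt(0.03 * 0.97 / 1000))
})

test_that("per-locus sample frequencies are unbiased for configured values", {
  cfg <- sim_config(n_lines = 600, n_high = 300, n_snps = 400,
                    n_selected_loci = 0, missing_rate = 0, seed = 5,
                    background_freq_range = c(0.3, 0.7))
  sim <- simulate_genotypes(cfg)
  freq <- colMeans(sim$geno$calls) / 2
  # neutral law is uniform(0.3, 0.7): mean of sample frequencies near 0.5
  expect_lt(abs(mean(freq) - 0.5), 0.02)
  # no differentiation when groups share frequencies
  grp <- sim$truth$groups
  p_h <- colMeans(sim$geno$calls[grp$group == "H", ]) / 2
  p_l <- colMeans(sim$geno$calls[grp$group == "L", ]) / 2
  expect_lt(mean(abs(p_h - p_l)), 0.05)
})

test_that("true NFA equals a recount from emitted genotypes", {
  cfg <- sim_config(n_snps = 300, missing_rate = 0, seed = 9)
  sim <- simulate_genotypes(cfg)
  sel <- sim$truth$selected_loci
  j <- match(sel$marker, sim$geno$map$marker)
  fav_is_alt <- sel$favorable_allele == sim$geno$map$alt[j]
  target <- ifelse(fav_is_alt, 2L, 0L)
  recount <- rowSums(sweep(sim$geno$calls[, j, drop = FALSE], 2, target, `==`))
  expect_identical(as.integer(recount), sim$truth$nfa$true_nfa)
})

test_that("phenotypes follow the additive low-N model", {
  cfg <- sim_config(n_snps = 50, n_lines = 10, n_high = 5, missing_rate = 0,
                    effect_per_favorable_allele = 0, block_sd = 0,
                    residual_sd = 0, n_environments = 1, env_effect = 0,
                    seed = 2)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  # degenerate noise: every LN plot sits exactly at the LN baseline
  expect_true(all(ph$grain_yield[ph$n_level == "LN"] == cfg$baseline_ln[1]))
  expect_true(all(ph$grain_yield[ph$n_level == "IN"] == cfg$baseline_in[1]))
  # both N levels present for every line x environment x replicate
  counts <- dplyr::count(ph, line, environment, rep)
  expect_true(all(counts$n == 2))

  # linearity: k favorable alleles add exactly k * effect under LN
  cfg2 <- sim_config(n_snps = 50, n_lines = 10, n_high = 5, missing_rate = 0,
                     effect_per_favorable_allele = 500, block_sd = 0,
                     residual_sd = 0, n_environments = 1, env_effect = 0,
                     seed = 2)
  sim2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotypes(sim2$geno, sim2$truth, cfg2)
  ln <- dplyr::filter(ph2, n_level == "LN", rep == 1)
  nfa <- sim2$truth$nfa$true_nfa[match(ln$line, sim2$truth$nfa$line)]
  expect_equal(ln$grain_yield, cfg2$baseline_ln[1] + 500 * nfa)
})

test_that("phenotype simulation rejects mismatched inputs", {
  cfg <- sim_config(n_snps = 20, n_lines = 6, n_high = 3, seed = 1)
  sim <- simulate_genotypes(cfg)
  bad_truth <- sim$truth
  bad_truth$nfa$line <- paste0("X", bad_truth$nfa$line)
  expect_error(simulate_phenotypes(sim$geno, bad_truth, cfg), "disagree")
  expect_error(sim_config(residual_sd = -1), "non-negative|deviations")
})
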