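test_that("theta matches the step-by-step oracle on random configurations", {
  withr::with_seed(19, {
    for (i in 1:100) {
      n <- sample(5:80, 2)
      p <- runif(2)
      expect_equal(wc_theta(n, p), oracle_wc_theta(n, p), tolerance = 1e-12)
    }
  })
})

test_that("theta is invariant to allele relabelling", {
  withr::with_seed(20, {
    for (i in 1:20) {
      n <- sample(5:60, 2)
      p <- runif(2)
      expect_equal(wc_theta(n, p), wc_theta(n, 1 - p), tolerance = 1e-12)
    }
  })
})

test_that("theta hits its theoretical anchors", {
  # no differentiation at equal frequencies: estimator at or below zero
  expect_lte(wc_theta(c(30, 30), c(0.4, 0.4)), 0)
  # complete fixation at large equal n approaches 1
  expect_gt(wc_theta(c(5000, 5000), c(1, 0)), 0.999)
  # monomorphic overall: undefined
  expect_true(is.na(wc_theta(c(20, 20), c(0, 0))))
  expect_true(is.na(wc_theta(c(20, 20), c(1, 1))))
})

test_that("wc_fst computes per-marker group stats through the same theta", {
  g <- random_geno(20, 30, missing_rate = 0.1, seed = 23)
  grp <- tibble::tibble(line = line_ids(g),
                        group = rep(c("H", "L"), c(9, 11)))
  fst <- wc_fst(g, grp)
  expect_equal(nrow(fst), 30)
  for (j in c(1, 7, 30)) {
    x_h <- g$calls[1:9, j]
    x_l <- g$calls[10:20, j]
    n <- c(sum(!is.na(x_h)), sum(!is.na(x_l)))
    p <- c(mean(x_h, na.rm = TRUE), mean(x_l, na.rm = TRUE)) / 2
    expect_equal(fst$n_1[j], n[1])
    expect_equal(fst$p_1[j], p[1])
    expect_equal(fst$fst[j], oracle_wc_theta(n, p), tolerance = 1e-12)
  }
  expect_error(wc_fst(g, tibble::tibble(line = line_ids(g), group = "A")),
               "two groups")
  # markers where a group has < 2 informative lines are flagged, kept
  g2 <- g
  g2$calls[1:8, 5] <- NA
  fst2 <- wc_fst(geno_matrix(g2$calls, g2$map), grp)
  expect_true(is.na(fst2$fst[5]))
  expect_equal(fst2$note[5], "insufficient_lines")
})

test_that("outlier selection is strict and reports the genome-wide mean", {
  fst <- tibble::tibble(
    marker = c("a", "b", "c"), chrom = 1L, pos = 1:3, ref = "A", alt = "G",
    n_1 = 10L, n_2 = 10L, p_1 = 0.5, p_2 = 0.1,
    fst = c(0.19, 0.20, 0.21), outlier = FALSE, note = ""
  )
  class(fst) <- c("fst_table", class(fst))
  out <- outlier_scan(fst, threshold = 0.2)
  expect_equal(out$marker, "c")
  expect_equal(attr(out, "mean_fst"), 0.2)
  # all-undefined input warns and returns an empty set
  fst$fst <- NA_real_
  expect_warning(out2 <- outlier_scan(fst), "monomorphic")
  expect_equal(nrow(out2), 0)
})

test_that("favorable alleles are the H-enriched alleles", {
  # marker 1: alt enriched in H; marker 2: ref enriched in H;
  # marker 3: fixed in H, absent in L; marker 4: exact tie
  calls <- rbind(
    L1 = c(2L, 0L, 2L, 2L), L2 = c(2L, 0L, 2L, 0L), L3 = c(0L, 0L, 2L, 2L),
    L4 = c(0L, 2L, 0L, 2L), L5 = c(0L, 2L, 0L, 0L), L6 = c(2L, 2L, 0L, 2L)
  )
  g <- toy_geno(calls, ref = rep("A", 4), alt = rep("G", 4))
  grp <- tibble::tibble(line = rownames(calls),
                        group = rep(c("H", "L"), each = 3))
  outliers <- tibble::tibble(marker = g$map$marker)
  expect_warning(fav <- favorable_alleles(g, grp, outliers), "equal group")
  expect_equal(nrow(fav), 3)                       # tie excluded
  m1 <- fav[fav$marker == "M001", ]
  expect_equal(m1$favorable_allele, "G")
  expect_equal(m1$ffa_h, 2 / 3)
  expect_equal(m1$ffa_l, 1 / 3)
  m2 <- fav[fav$marker == "M002", ]
  expect_equal(m2$favorable_allele, "A")           # ref enriched in H
  expect_equal(m2$ffa_h, 1)
  expect_equal(m2$ffa_l, 0)
  m3 <- fav[fav$marker == "M003", ]
  expect_equal(c(m3$ffa_h, m3$ffa_l), c(1, 0))
  expect_true(all(fav$ffa_h >= fav$ffa_l))
})

test_that("NFA counts favorable homozygotes with missing as zero", {
  calls <- rbind(L1 = c(2L, 2L, 2L), L2 = c(NA, NA, NA), L3 = c(2L, 0L, NA))
  g <- toy_geno(calls)
  fav <- tibble::tibble(marker = g$map$marker, chrom = 1L, pos = g$map$pos,
                        alleles = "A/G", favorable_allele = "G",
                        ffa_h = 0.5, ffa_l = 0.1)
  nfa <- nfa_scores(g, fav)
  expect_equal(nfa$nfa, c(3L, 0L, 1L))
  # rescale mode divides by completeness
  nfa2 <- nfa_scores(g, fav, missing_mode = "rescale")
  expect_equal(nfa2$nfa, c(3, 0, 1 / (2 / 3)))
})

test_that("NFA recount on simulated data equals the planted truth", {
  cfg <- sim_config(n_snps = 150, missing_rate = 0, seed = 25,
                    freq_high_group = c(0.9, 0.8, 0.85, 0.95),
                    freq_low_group = c(0.05, 0.1, 0.05, 0.1))
  sim <- simulate_genotypes(cfg)
  outliers <- tibble::tibble(marker = sim$truth$selected_loci$marker)
  fav <- favorable_alleles(sim$geno, sim$truth$groups, outliers)
  expect_equal(sort(fav$marker), sort(sim$truth$selected_loci$marker))
  nfa <- nfa_scores(sim$geno, fav)
  expect_identical(nfa$nfa,
                   sim$truth$nfa$true_nfa[match(nfa$line,
                                                sim$truth$nfa$line)])
})

test_that("association returns exact values on noiseless data", {
  nfa <- tibble::tibble(line = sprintf("L%d", 1:10), nfa = c(0:4, 0:4))
  lnae <- tibble::tibble(line = nfa$line, lnae = 1000 + 250 * nfa$nfa)
  a <- suppressWarnings(nfa_lnae_association(nfa, lnae))  # perfect fit
  expect_equal(a$r, 1, tolerance = 1e-12)
  expect_equal(a$r_squared, 1, tolerance = 1e-12)
  expect_equal(a$slope, 250, tolerance = 1e-10)
  expect_equal(a$intercept, 1000, tolerance = 1e-8)
  # R^2 equals squared r on noisy data too (simple-regression identity)
  withr::with_seed(26, {
    lnae$lnae <- lnae$lnae + rnorm(10, 0, 300)
  })
  b <- nfa_lnae_association(nfa, lnae)
  expect_equal(b$r_squared, b$r^2, tolerance = 1e-12)
  # degenerate NFA flagged
  flat <- tibble::tibble(line = nfa$line, nfa = 2L)
  expect_error(nfa_lnae_association(flat, lnae), "zero variance")
})
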