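test_that("compute_lnae follows the yield-by-ratio definition", {
  expect_equal(compute_lnae(3000, 6000), 1500)   # 3000^2 / 6000
  expect_equal(compute_lnae(2500, 2500), 2500)   # ratio-1 limit: LNAE = GY
  expect_equal(compute_lnae(0, 4000), 0)
  # scale consistency: scaling both yields by c scales LNAE by c
  g <- c(1200, 3400, 2800)
  expect_equal(compute_lnae(3 * g, 3 * rev(g)), 3 * compute_lnae(g, rev(g)))
  expect_error(compute_lnae(100, 0), "positive")
  expect_error(compute_lnae(-5, 100), "non-negative")
})

test_that("adjusted means reduce to raw means without block structure", {
  cfg <- sim_config(n_snps = 20, n_lines = 12, n_high = 6, block_sd = 0,
                    residual_sd = 1e-6, n_environments = 1, env_effect = 0,
                    seed = 31)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  adj <- adjusted_means(ph)
  raw <- ph |>
    dplyr::group_by(line, environment, n_level) |>
    dplyr::summarise(raw_mean = mean(grain_yield), .groups = "drop")
  both <- dplyr::inner_join(adj, raw, by = c("line", "environment", "n_level"))
  expect_equal(both$adj_mean, both$raw_mean, tolerance = 1e-6)
  expect_true(all(both$sigma2_block >= 0))
})

test_that("adjusted means are unbiased and beat raw means under block noise", {
  # repeated incomplete-block trials with known line effects
  set.seed(77)
  n_sims <- 60
  n_lines <- 16
  line_eff <- seq(0, 1500, length.out = n_lines)
  names(line_eff) <- sprintf("L%03d", seq_len(n_lines))
  err_adj <- err_raw <- matrix(NA_real_, n_sims, n_lines)
  for (s in seq_len(n_sims)) {
    rows <- list()
    for (r in 1:2) {
      block_of <- ceiling(sample.int(n_lines) / 4)
      b_eff <- rnorm(4, 0, 400)
      rows[[r]] <- tibble::tibble(
        line = names(line_eff), environment = "e1", n_level = "LN", rep = r,
        block = sprintf("r%d_b%d", r, block_of),
        grain_yield = 3000 + line_eff + b_eff[block_of] + rnorm(n_lines, 0, 200)
      )
    }
    ph <- dplyr::bind_rows(rows)
    adj <- suppressWarnings(adjusted_means(ph))
    raw <- tapply(ph$grain_yield, ph$line, mean)
    cent <- function(x) x - mean(x)
    err_adj[s, ] <- cent(adj$adj_mean[match(names(line_eff), adj$line)]) -
      cent(line_eff)
    err_raw[s, ] <- cent(raw[names(line_eff)]) - cent(line_eff)
  }
  bias <- mean(err_adj)
  rmse_adj <- sqrt(mean(err_adj^2))
  rmse_raw <- sqrt(mean(err_raw^2))
  expect_lt(abs(bias), 25)
  expect_lt(rmse_adj, rmse_raw)
})

test_that("degenerate phenotype designs follow the declared policy", {
  ph <- tibble::tibble(
    line = rep(c("L1", "L2"), 2), environment = "e1",
    n_level = rep(c("IN", "LN"), each = 2), rep = 1L, block = "b1",
    grain_yield = c(5000, 5200, 3000, 3100)
  )
  expect_warning(expect_warning(adj <- adjusted_means(ph),
                                "single replicate"))
  expect_equal(adj$adj_mean[adj$line == "L1" & adj$n_level == "IN"], 5000)
  expect_error(adjusted_means(ph, single_rep_policy = "error"),
               "single replicate")
})

test_that("a line absent from one trial is flagged missing, not fabricated", {
  cfg <- sim_config(n_snps = 10, n_lines = 8, n_high = 4, seed = 4,
                    n_environments = 2)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  ph <- dplyr::filter(ph, !(line == "L001" & environment == "env2"))
  adj <- adjusted_means(ph)
  gone <- dplyr::filter(adj, line == "L001", environment == "env2")
  expect_true(all(is.na(gone$adj_mean)))
  there <- dplyr::filter(adj, line == "L001", environment == "env1")
  expect_true(all(is.finite(there$adj_mean)))
})

test_that("lnae_anova matches hand-computed sums of squares", {
  # balanced 3 lines x 2 environments, values chosen for clean arithmetic
  tab <- tibble::tibble(
    line = rep(c("A", "B", "C"), 2),
    environment = rep(c("e1", "e2"), each = 3),
    lnae = c(10, 14, 18, 12, 16, 26)
  )
  # grand mean 16; env means 14, 18 -> SS_env = 3*(4+4) = 24
  # line means 11, 15, 22 -> SS_line = 2*(25+1+36) = 124
  # total SS = 36+4+4+16+0+100 = 160 -> SS_res = 160-24-124 = 12
  an <- lnae_anova(tab)
  tt <- tidy(an)
  expect_equal(tt$sumsq[tt$term == "environment"], 24)
  expect_equal(tt$sumsq[tt$term == "line"], 124)
  expect_equal(tt$sumsq[tt$term == "Residuals"], 12)
  expect_equal(an$error_df, 2)
  expect_equal(an$f_line, (124 / 2) / (12 / 2))
})

test_that("lnae_anova guards its preconditions and degenerate input", {
  one_env <- tibble::tibble(line = c("A", "B"), environment = "e1",
                            lnae = c(1, 2))
  expect_error(lnae_anova(one_env), ">= 2 environments")
  flat <- tibble::tibble(line = rep(c("A", "B"), 2),
                         environment = rep(c("e1", "e2"), each = 2),
                         lnae = 5)
  an <- suppressWarnings(lnae_anova(flat))  # identical values: F undefined
  expect_true(is.na(an$f_line))
})

test_that("combined LNAE equals the least-squares line estimate", {
  cfg <- sim_config(n_snps = 40, n_lines = 10, n_high = 5, seed = 6)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  ln <- lnae_table(adjusted_means(ph))
  # balanced data: arithmetic mean and model-based estimate coincide
  expect_equal(ln$combined$lnae_mean, ln$combined$lnae_ls, tolerance = 1e-8)
  expect_true(all(ln$by_env$lnae >= 0))
})
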