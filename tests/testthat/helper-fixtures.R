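# shared fixture builders and independent oracles

# small genotype matrix from a plain calls matrix (lines x markers)
toy_geno <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(calls)
  map <- tibble::tibble(
    marker = colnames(calls) %||% sprintf("M%03d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% seq_len(m) * 1000L,
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m)
  )
  colnames(calls) <- map$marker
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  }
  geno_matrix(calls, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_geno <- function(n_lines, n_markers, missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    f <- runif(n_markers, 0.1, 0.9)
    calls <- matrix(
      2L * rbinom(n_lines * n_markers, 1, rep(f, each = n_lines)),
      n_lines, n_markers
    )
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA_integer_
    }
    toy_geno(calls)
  })
}

# independent step-by-step Weir-Cockerham theta for haploid samples,
# written as a literal transcription of the moment formulas (r groups)
oracle_wc_theta <- function(n, p) {
  r <- length(n)
  n_total <- 0
  for (i in seq_len(r)) n_total <- n_total + n[i]
  n_bar <- n_total / r
  sum_sq <- 0
  for (i in seq_len(r)) sum_sq <- sum_sq + n[i]^2
  n_c <- (n_total - sum_sq / n_total) / (r - 1)
  p_bar <- 0
  for (i in seq_len(r)) p_bar <- p_bar + n[i] * p[i] / n_total
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + n[i] * (p[i] - p_bar)^2 / ((r - 1) * n_bar)
  t1 <- s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r) / (n_bar - 1)
  t2 <- p_bar * (1 - p_bar) * (n_c - 1) / (n_bar - 1) +
    (1 + (r - 1) * (n_bar - n_c) / (n_bar - 1)) * s2 / r
  t1 / t2
}

# brute-force 1-IBS over a pair of call vectors
oracle_ibs_pair <- function(x, y) {
  shared <- which(!is.na(x) & !is.na(y))
  if (length(shared) == 0) return(NA_real_)
  ibs <- numeric(length(shared))
  for (k in seq_along(shared)) {
    a <- x[shared[k]] / 2
    b <- y[shared[k]] / 2
    ibs[k] <- a * b + (1 - a) * (1 - b)
  }
  1 - mean(ibs)
}

# brute-force all-pairs LD pruning with the package's removal rule
oracle_ld_prune_keep <- function(calls, maf, pos, r2_threshold) {
  keep <- rep(TRUE, ncol(calls))
  repeat {
    alive <- which(keep)
    if (length(alive) < 2) return(keep)
    best <- c(NA, NA)
    best_r2 <- r2_threshold
    for (jj in seq_along(alive)) {
      for (ii in seq_along(alive)) {
        if (ii <= jj) next
        r <- suppressWarnings(cor(calls[, alive[ii]], calls[, alive[jj]],
                                  use = "pairwise.complete.obs"))
        r2 <- if (is.finite(r)) r^2 else 0
        if (r2 > best_r2) {
          best_r2 <- r2
          best <- c(alive[jj], alive[ii])  # (col, row) order as in package
        }
      }
    }
    if (is.na(best[1])) return(keep)
    a <- best[1]; b <- best[2]
    drop <- if (isTRUE(maf[a] < maf[b])) a
            else if (isTRUE(maf[b] < maf[a])) b
            else if (pos[a] > pos[b]) a else b
    keep[drop] <- FALSE
  }
}

# Procrustes distance after optimal translation/rotation/reflection/scale-free
# superimposition (orthogonal Procrustes; no scaling)
procrustes_error <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(sum((yc %*% rot - xc)^2))
}

# phenotype table for a one-way layout with replicate noise (no block model)
toy_lnae_env <- function(line_means, n_env, error_sd, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(line = names(line_means),
                       environment = sprintf("env%d", seq_len(n_env))) |>
      dplyr::mutate(lnae = line_means[line] + rnorm(dplyr::n(), 0, error_sd))
  })
}
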