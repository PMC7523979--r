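#' Configuration for the synthetic inbred-panel generator
#'
#' Defines the statistical structure of a simulated maize diversity panel:
#' fully homozygous lines split a priori into a high (H) and a low (L)
#' low-N-tolerance group, a neutral SNP background with one shared allele
#' frequency per locus, a small number of selected loci with group-specific
#' allele frequencies, and paired optimal-N (IN) / low-N (LN) yield trials
#' in which each favorable allele adds yield under low N only.
#'
#' Defaults mirror a 64-line tropical panel: 29 H / 35 L lines, 12,050 SNPs
#' over 10 chromosomes, four selected loci with H/L alternate-allele
#' frequencies (0.33, 0.03), (0.22, 0), (0.43, 0.03), (0.24, 0), three
#' environments with two replicates in incomplete blocks of 8 plots, and N
#' doses of 150/60, 100/35 and 100/35 kg ha^-1 (IN/LN).
#'
#' @param n_lines Number of inbred lines.
#' @param n_high Number of lines carrying the high-tolerance (H) truth label;
#'   the remaining `n_lines - n_high` are labelled L.
#' @param n_snps Total number of biallelic SNPs.
#' @param n_chromosomes Number of chromosomes markers are spread over.
#' @param chromosome_length_bp Length of each chromosome in bp.
#' @param n_selected_loci Number of loci with group-contrasting frequencies.
#' @param freq_high_group,freq_low_group Alternate-allele frequency of each
#'   selected locus in the H and L groups; recycled to `n_selected_loci`.
#' @param background_freq_range Range of the uniform law the neutral
#'   per-locus allele frequencies are drawn from.
#' @param effect_per_favorable_allele Yield (kg ha^-1) added to low-N plots
#'   per favorable allele carried.
#' @param n_environments Number of environments (site-years).
#' @param n_reps Replicates per environment and N level.
#' @param n_doses Data frame with one row per environment and columns
#'   `dose_in`, `dose_ln` (kg N ha^-1); recycled if fewer rows than
#'   environments.
#' @param baseline_in,baseline_ln Mean plot yield (kg ha^-1) of a line with
#'   zero favorable alleles under IN and LN; length 1 or `n_environments`.
#' @param env_effect Additive environment effect on both baselines
#'   (kg ha^-1); length `n_environments`.
#' @param block_size Plots per incomplete block within a replicate.
#' @param residual_sd,block_sd Plot residual and block-effect standard
#'   deviations (kg ha^-1).
#' @param missing_rate Proportion of genotype calls masked as missing.
#' @param seed Integer seed driving every random draw of the generator.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_genotypes()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_lines = 64,
                       n_high = 29,
                       n_snps = 12050,
                       n_chromosomes = 10,
                       chromosome_length_bp = 2.1e8,
                       n_selected_loci = 4,
                       freq_high_group = c(0.33, 0.22, 0.43, 0.24),
                       freq_low_group = c(0.03, 0.00, 0.03, 0.00),
                       background_freq_range = c(0.05, 0.95),
                       effect_per_favorable_allele = 800,
                       n_environments = 3,
                       n_reps = 2,
                       n_doses = data.frame(dose_in = c(150, 100, 100),
                                            dose_ln = c(60, 35, 35)),
                       baseline_in = 6000,
                       baseline_ln = 3000,
                       env_effect = c(0, -250, 250),
                       block_size = 8,
                       residual_sd = 1200,
                       block_sd = 250,
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_high = as.integer(n_high),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = chromosome_length_bp,
    n_selected_loci = as.integer(n_selected_loci),
    freq_high_group = rep_len(freq_high_group, max(n_selected_loci, 1L)),
    freq_low_group = rep_len(freq_low_group, max(n_selected_loci, 1L)),
    background_freq_range = background_freq_range,
    effect_per_favorable_allele = effect_per_favorable_allele,
    n_environments = as.integer(n_environments),
    n_reps = as.integer(n_reps),
    n_doses = {
      nd <- as.data.frame(n_doses)
      nd[rep_len(seq_len(nrow(nd)), n_environments), , drop = FALSE]
    },
    baseline_in = rep_len(baseline_in, n_environments),
    baseline_ln = rep_len(baseline_ln, n_environments),
    env_effect = rep_len(env_effect, n_environments),
    block_size = as.integer(block_size),
    residual_sd = residual_sd, block_sd = block_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$freq_high_group, cfg$freq_low_group, cfg$missing_rate,
             cfg$background_freq_range)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$n_lines, cfg$n_snps, cfg$n_chromosomes, cfg$n_environments,
              cfg$n_reps, cfg$block_size)
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  if (cfg$n_selected_loci < 0) stop("n_selected_loci must be >= 0", call. = FALSE)
  if (cfg$n_selected_loci >= cfg$n_snps) {
    stop("n_selected_loci must be smaller than n_snps", call. = FALSE)
  }
  if (cfg$n_high <= 0 || cfg$n_high >= cfg$n_lines) {
    stop("n_high must be strictly between 0 and n_lines", call. = FALSE)
  }
  if (cfg$residual_sd < 0 || cfg$block_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d lines (%d H / %d L), %d SNPs on %d chromosomes, ",
           "%d selected loci, %d env x %d reps, seed %d\n"),
    x$n_lines, x$n_high, x$n_lines - x$n_high, x$n_snps, x$n_chromosomes,
    x$n_selected_loci, x$n_environments, x$n_reps, x$seed
  ))
  invisible(x)
}

with_sim_seed <- function(seed, offset, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate genotypes of an inbred diversity panel
#'
#' Draws fully homozygous biallelic calls for a panel of lines. Neutral loci
#' share one allele frequency across the two truth groups (uniform on
#' `background_freq_range`); selected loci are drawn with group-specific
#' frequencies `freq_high_group` / `freq_low_group`. Calls are masked as
#' missing uniformly at `missing_rate`. Marker positions are sorted within
#' chromosomes.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `geno`: a [geno_matrix()];
#'   * `truth`: a `sim_truth` list with `selected_loci` (tibble: `marker`,
#'     `chrom`, `pos`, `favorable_allele`, `freq_high`, `freq_low`),
#'     `groups` (tibble: `line`, `group` in `{"H","L"}`) and `nfa`
#'     (tibble: `line`, `true_nfa`, the pre-masking count of favorable
#'     homozygous loci).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 0L, {
    n <- config$n_lines
    m <- config$n_snps
    lines <- sprintf("L%03d", seq_len(n))
    group <- rep(c("H", "L"), c(config$n_high, n - config$n_high))

    # marker map: near-equal split over chromosomes, sorted unique positions
    chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), m))
    pos <- unlist(lapply(split(seq_len(m), chrom_of), function(idx) {
      sort(sample.int(config$chromosome_length_bp, length(idx)))
    }), use.names = FALSE)
    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, m, replace = TRUE)
    alt <- vapply(ref, function(a) sample(setdiff(nucs, a), 1L), character(1))
    map <- tibble::tibble(
      marker = sprintf("SNP_%05d", seq_len(m)),
      chrom = chrom_of, pos = pos, ref = ref, alt = unname(alt)
    )

    k <- config$n_selected_loci
    sel_idx <- if (k > 0) sort(sample.int(m, k)) else integer(0)

    freq <- runif(m, config$background_freq_range[1],
                  config$background_freq_range[2])
    fmat <- matrix(freq, n, m, byrow = TRUE)
    if (k > 0) {
      fh <- config$freq_high_group[seq_len(k)]
      fl <- config$freq_low_group[seq_len(k)]
      fmat[group == "H", sel_idx] <- matrix(fh, config$n_high, k, byrow = TRUE)
      fmat[group == "L", sel_idx] <- matrix(fl, n - config$n_high, k,
                                            byrow = TRUE)
    }
    calls <- matrix(2L * rbinom(n * m, 1L, as.vector(fmat)), n, m,
                    dimnames = list(lines, map$marker))

    # favorable allele = the one enriched in H; with freq_high >= freq_low the
    # alternate allele is favorable, otherwise the reference allele
    truth_sel <- if (k > 0) {
      fh <- config$freq_high_group[seq_len(k)]
      fl <- config$freq_low_group[seq_len(k)]
      alt_fav <- fh >= fl
      tibble::tibble(
        marker = map$marker[sel_idx],
        chrom = map$chrom[sel_idx],
        pos = map$pos[sel_idx],
        favorable_allele = ifelse(alt_fav, map$alt[sel_idx], map$ref[sel_idx]),
        freq_high = fh, freq_low = fl
      )
    } else {
      tibble::tibble(marker = character(), chrom = integer(), pos = integer(),
                     favorable_allele = character(), freq_high = double(),
                     freq_low = double())
    }

    true_nfa <- if (k > 0) {
      fav_is_alt <- truth_sel$favorable_allele == map$alt[sel_idx]
      target <- ifelse(fav_is_alt, 2L, 0L)
      rowSums(sweep(calls[, sel_idx, drop = FALSE], 2, target, `==`))
    } else {
      rep(0L, n)
    }

    if (config$missing_rate > 0) {
      calls[runif(n * m) < config$missing_rate] <- NA_integer_
    }

    truth <- structure(list(
      selected_loci = truth_sel,
      groups = tibble::tibble(line = lines, group = group),
      nfa = tibble::tibble(line = lines, true_nfa = as.integer(true_nfa))
    ), class = "sim_truth")

    list(geno = geno_matrix(calls, map), truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d selected loci; %d H / %d L lines\n",
              nrow(x$selected_loci), sum(x$groups$group == "H"),
              sum(x$groups$group == "L")))
  invisible(x)
}

#' Simulate plot-level grain yields of a simulated panel
#'
#' Generates paired optimal-N (IN) and low-N (LN) plot yields for every line
#' x environment x replicate. The model is
#' `yield = baseline(N level, environment) + effect * true_nfa (LN plots
#' only) + block + residual`, with block effects `N(0, block_sd^2)` drawn
#' per incomplete block (lines are grouped into blocks of `block_size`
#' within each replicate) and plot residuals `N(0, residual_sd^2)`.
#' Negative yields are truncated at zero.
#'
#' @param geno A [geno_matrix()] from [simulate_genotypes()].
#' @param truth The matching `sim_truth`.
#' @param config The [sim_config()] used to generate them.
#' @return A tibble with columns `line`, `environment`, `n_level`
#'   (`"IN"`/`"LN"`), `rep`, `block`, `grain_yield`.
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (config$residual_sd < 0) stop("residual_sd must be non-negative", call. = FALSE)
  lines <- line_ids(geno)
  if (!setequal(lines, truth$nfa$line)) {
    stop("line ids in `geno` and `truth` disagree", call. = FALSE)
  }
  nfa <- truth$nfa$true_nfa[match(lines, truth$nfa$line)]
  n <- length(lines)

  with_sim_seed(config$seed, 1L, {
    grid <- tidyr::expand_grid(
      environment = sprintf("env%d", seq_len(config$n_environments)),
      n_level = c("IN", "LN"),
      rep = seq_len(config$n_reps)
    )
    out <- purrr::pmap(grid, function(environment, n_level, rep) {
      e <- as.integer(sub("env", "", environment))
      block_of <- ceiling(sample.int(n) / config$block_size)
      b_eff <- rnorm(max(block_of), 0, config$block_sd)
      base <- if (n_level == "IN") {
        config$baseline_in[e] + config$env_effect[e]
      } else {
        config$baseline_ln[e] + config$env_effect[e]
      }
      gain <- if (n_level == "LN") config$effect_per_favorable_allele * nfa else 0
      yield <- base + gain + b_eff[block_of] + rnorm(n, 0, config$residual_sd)
      tibble::tibble(
        line = lines, environment = environment, n_level = n_level,
        rep = rep, block = sprintf("%s_r%d_b%d", environment, rep, block_of),
        grain_yield = pmax(yield, 0)
      )
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$environment, .data$n_level,
                   .data$rep, .data$line)
  })
}
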