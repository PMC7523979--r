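#' Pipeline configuration
#'
#' Declarative settings for the end-to-end scan: simulation (or input
#' paths), QC thresholds, Scott-Knott level, Fst threshold, seed and output
#' directory. Defaults encode the study settings: call rate 0.90, MAF 0.05,
#' LD r^2 0.13, alpha 0.05, Fst threshold 0.2.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest and driving every
#'   random draw.
#' @param sim A [sim_config()]; if `NULL`, `geno_path`/`pheno_path` must
#'   point at existing inputs.
#' @param geno_path,pheno_path Optional input files (VCF or tabular dialect;
#'   phenotype CSV) used when `sim` is `NULL`.
#' @param min_call_rate,min_maf QC thresholds (see [filter_markers()]).
#' @param ld_r2,ld_window,ld_step LD pruning settings (see [ld_prune()]).
#' @param sk_alpha Scott-Knott significance level.
#' @param fst_threshold Directional-selection threshold.
#' @param n_axes Principal coordinate axes to keep.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            geno_path = NULL,
                            pheno_path = NULL,
                            min_call_rate = 0.90,
                            min_maf = 0.05,
                            ld_r2 = 0.13,
                            ld_window = 50,
                            ld_step = 5,
                            sk_alpha = 0.05,
                            fst_threshold = 0.2,
                            n_axes = 2) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              geno_path = geno_path, pheno_path = pheno_path,
              min_call_rate = min_call_rate, min_maf = min_maf,
              ld_r2 = ld_r2, ld_window = as.integer(ld_window),
              ld_step = as.integer(ld_step), sk_alpha = sk_alpha,
              fst_threshold = fst_threshold, n_axes = as.integer(n_axes))
  stopifnot(
    cfg$min_call_rate >= 0, cfg$min_call_rate <= 1,
    cfg$min_maf >= 0, cfg$min_maf <= 0.5,
    cfg$ld_r2 >= 0, cfg$ld_r2 <= 1, cfg$ld_window >= 2, cfg$ld_step >= 1,
    cfg$sk_alpha > 0, cfg$sk_alpha < 1,
    cfg$fst_threshold >= 0, cfg$fst_threshold <= 1, cfg$n_axes >= 1
  )
  if (is.null(cfg$sim)) {
    for (p in c(cfg$geno_path, cfg$pheno_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input not found: ", p %||% "(missing path)", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the low-N selection-scan pipeline
#'
#' Chains the stages: simulate (or load) genotypes and phenotypes, adjusted
#' means and LNAE, ANOVA and Scott-Knott grouping, marker QC and LD
#' pruning, 1-IBS distances and PCoA, the per-SNP Fst contrast scan,
#' favorable-allele and NFA scoring, and the NFA-LNAE association. All
#' tables are written to `out_dir` as delimited text along with a
#' machine-readable JSON manifest of thresholds, counts and the seed;
#' plots are saved as PNG files. Fails with a stage-named error on the
#' first broken stage.
#'
#' @param config A [pipeline_config()].
#' @param write_plots Save the Manhattan, PCoA and NFA-LNAE figures
#'   (default `TRUE`).
#' @return Invisibly, a list with every intermediate result (`geno`,
#'   `truth`, `pheno`, `adj`, `lnae`, `anova`, `sk`, `groups`, `qc`,
#'   `dist`, `pcoa`, `fst`, `outliers`, `fav`, `nfa`, `assoc`, `manifest`).
#' @export
run_pipeline <- function(config, write_plots = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()

  stage("simulate", {
    if (!is.null(config$sim)) {
      sim <- simulate_genotypes(config$sim)
      out$geno <- sim$geno
      out$truth <- sim$truth
      out$pheno <- simulate_phenotypes(sim$geno, sim$truth, config$sim)
      write_genotypes_table(out$geno, file.path(config$out_dir, "genotypes.tsv"))
      write_phenotypes(out$pheno, file.path(config$out_dir, "phenotypes.csv"))
      write_sim_truth(out$truth, file.path(config$out_dir, "sim_truth.tsv"))
    } else {
      out$geno <- if (grepl("\\.vcf$", config$geno_path)) {
        read_genotypes_vcf(config$geno_path)
      } else {
        read_genotypes_table(config$geno_path)
      }
      out$truth <- NULL
      out$pheno <- read_phenotypes(config$pheno_path)
    }
  })

  stage("pheno", {
    out$adj <- adjusted_means(out$pheno)
    out$lnae <- lnae_table(out$adj)
    out$anova <- lnae_anova(out$lnae$by_env)
    out$sk <- scott_knott(
      setNames(out$lnae$combined$lnae_mean, out$lnae$combined$line),
      error_ms = out$anova$error_ms, error_df = out$anova$error_df,
      alpha = config$sk_alpha, n_rep = out$anova$n_env
    )
    out$groups <- sk_two_groups(out$sk)
    readr::write_tsv(out$lnae$by_env,
                     file.path(config$out_dir, "lnae_by_env.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$lnae$combined,
                     file.path(config$out_dir, "lnae_combined.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(out$anova),
                     file.path(config$out_dir, "lnae_anova.tsv"),
                     progress = FALSE)
    readr::write_tsv(
      dplyr::left_join(out$groups,
                       dplyr::select(tidy(out$sk), "line", sk_group = "group"),
                       by = "line"),
      file.path(config$out_dir, "groups.tsv"), progress = FALSE)
  })

  stage("qc", {
    f <- filter_markers(out$geno, config$min_call_rate, config$min_maf)
    p <- ld_prune(f$geno, config$ld_r2, config$ld_window, config$ld_step)
    out$qc <- list(geno = p$geno,
                   report = dplyr::bind_rows(f$report, p$report))
    readr::write_tsv(out$qc$report, file.path(config$out_dir, "qc_report.tsv"),
                     progress = FALSE)
  })

  stage("diversity", {
    out$dist <- ibs_distance(out$qc$geno)
    out$pcoa <- pcoa(out$dist, n_axes = config$n_axes)
    write_distance_matrix(out$dist,
                          file.path(config$out_dir, "distance_1_ibs.tsv"))
    readr::write_tsv(out$pcoa$coordinates,
                     file.path(config$out_dir, "pcoa_coordinates.tsv"),
                     progress = FALSE)
  })

  stage("scan", {
    out$fst <- wc_fst(out$qc$geno, out$groups,
                      threshold = config$fst_threshold)
    out$outliers <- outlier_scan(out$fst, config$fst_threshold)
    out$fav <- favorable_alleles(out$qc$geno, out$groups, out$outliers)
    out$nfa <- nfa_scores(out$qc$geno, out$fav)
    out$assoc <- nfa_lnae_association(out$nfa, out$lnae$combined)
    readr::write_tsv(tibble::as_tibble(out$fst),
                     file.path(config$out_dir, "fst_table.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(out$outliers),
                     file.path(config$out_dir, "fst_outliers.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$fav,
                     file.path(config$out_dir, "favorable_alleles.tsv"),
                     progress = FALSE)
    readr::write_tsv(
      dplyr::left_join(out$nfa,
                       dplyr::select(out$lnae$combined, "line",
                                     lnae = "lnae_mean"), by = "line"),
      file.path(config$out_dir, "nfa_scores.tsv"), progress = FALSE)
  })

  if (write_plots) {
    stage("plots", {
      ggplot2::ggsave(file.path(config$out_dir, "fst_manhattan.png"),
                      plot_fst_manhattan(out$fst), width = 8, height = 3.5,
                      dpi = 150)
      ggplot2::ggsave(file.path(config$out_dir, "pcoa.png"),
                      plot_pcoa(out$pcoa, out$groups), width = 5, height = 4,
                      dpi = 150)
      ggplot2::ggsave(file.path(config$out_dir, "nfa_lnae.png"),
                      plot_nfa_lnae(out$assoc), width = 5, height = 4,
                      dpi = 150)
    })
  }

  stage("manifest", {
    manifest <- list(
      package = "nitroscan",
      version = as.character(utils::packageVersion("nitroscan")),
      seed = config$seed,
      thresholds = list(
        min_call_rate = config$min_call_rate, min_maf = config$min_maf,
        ld_r2 = config$ld_r2, ld_window = config$ld_window,
        ld_step = config$ld_step, sk_alpha = config$sk_alpha,
        fst_threshold = config$fst_threshold
      ),
      counts = list(
        n_lines = nrow(out$geno$calls),
        markers_in = ncol(out$geno$calls),
        markers_post_qc = ncol(out$qc$geno$calls),
        n_groups = nrow(out$sk$group_means),
        n_high = sum(out$groups$group == "H"),
        n_low = sum(out$groups$group == "L"),
        n_outliers = nrow(out$outliers)
      ),
      results = list(
        mean_fst = attr(out$outliers, "mean_fst"),
        max_fst = max(out$fst$fst, na.rm = TRUE),
        nfa_lnae_r = out$assoc$r,
        nfa_lnae_r2 = out$assoc$r_squared
      ),
      outlier_markers = out$outliers$marker
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  })

  invisible(out)
}
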