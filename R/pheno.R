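#' Mixed-model adjusted line means per environment and N level
#'
#' Fits, separately for every environment x N level, the linear mixed model
#' `grain_yield ~ rep + line + (1 | block)` — fixed intercept, replicate and
#' genotype effects, random incomplete-block effects — and returns the
#' genotype adjusted means (BLUEs, i.e. fixed-effect solutions averaged over
#' replicates) together with the fitted variance components. With zero block
#' variance the adjusted means coincide with ordinary least-squares line
#' means.
#'
#' @param pheno A plot-level phenotype tibble with columns `line`,
#'   `environment`, `n_level`, `rep`, `block`, `grain_yield`
#'   (see [read_phenotypes()]).
#' @param single_rep_policy What to do when an environment x N level has a
#'   single replicate, leaving no basis for block-variance estimation:
#'   `"warn"` (default) returns raw line means with a warning, `"error"`
#'   aborts.
#' @return A tibble with one row per (line, environment, n_level):
#'   `adj_mean` (kg ha^-1, `NA` when the line is absent from that trial),
#'   `sigma2_block`, `sigma2_resid`.
#' @export
adjusted_means <- function(pheno, single_rep_policy = c("warn", "error")) {
  single_rep_policy <- match.arg(single_rep_policy)
  all_lines <- sort(unique(pheno$line))
  cells <- dplyr::distinct(pheno, .data$environment, .data$n_level)

  fit_cell <- function(environment, n_level) {
    dat <- dplyr::filter(pheno, .data$environment == .env$environment,
                         .data$n_level == .env$n_level)
    dat$line <- factor(dat$line)
    dat$rep <- factor(dat$rep)
    n_rep <- nlevels(dat$rep)
    if (n_rep < 2) {
      msg <- sprintf("single replicate in %s/%s: returning raw line means",
                     environment, n_level)
      if (single_rep_policy == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      raw <- dplyr::summarise(dplyr::group_by(dat, .data$line),
                              adj_mean = mean(.data$grain_yield),
                              .groups = "drop")
      return(tibble::tibble(
        line = all_lines, environment = environment, n_level = n_level,
        adj_mean = raw$adj_mean[match(all_lines, raw$line)],
        sigma2_block = NA_real_, sigma2_resid = NA_real_
      ))
    }
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(grain_yield ~ rep + line + (1 | block), data = dat,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == "block"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    # BLUE of each line = fixed-effect prediction averaged over replicates
    grid <- expand.grid(line = levels(dat$line), rep = levels(dat$rep))
    grid$pred <- predict(fit, newdata = grid, re.form = NA)
    blue <- tapply(grid$pred, grid$line, mean)
    tibble::tibble(
      line = all_lines, environment = environment, n_level = n_level,
      adj_mean = as.numeric(blue[all_lines]),
      sigma2_block = s2b, sigma2_resid = s2e
    )
  }
  dplyr::bind_rows(purrr::pmap(cells, fit_cell))
}

#' Low-N agronomic efficiency index
#'
#' `LNAE = GY_LN * (GY_LN / GY_IN) = GY_LN^2 / GY_IN`: the absolute grain
#' yield under low N weighted by the low-N to optimal-N yield ratio, so that
#' high LNAE requires both yielding well under N stress and losing little
#' yield relative to optimal fertilization. Scale-consistent: scaling both
#' yields by `c` scales LNAE by `c`.
#'
#' @param gy_ln,gy_in Grain yield (kg ha^-1) under low and optimal N;
#'   vectorized. `gy_in` must be positive, `gy_ln` non-negative.
#' @return LNAE on the same kg ha^-1 scale.
#' @export
compute_lnae <- function(gy_ln, gy_in) {
  if (any(gy_in <= 0, na.rm = TRUE)) {
    stop("gy_in must be strictly positive", call. = FALSE)
  }
  if (any(gy_ln < 0, na.rm = TRUE)) {
    stop("gy_ln must be non-negative", call. = FALSE)
  }
  gy_ln^2 / gy_in
}

#' Per-line LNAE table from adjusted means
#'
#' Pairs the IN and LN adjusted means of every line x environment and
#' applies [compute_lnae()]. The combined per-line estimate is provided
#' both as the arithmetic mean over environments and as the least-squares
#' line estimate of the two-way (environment + line) model; the two agree
#' in balanced data.
#'
#' @param adj Adjusted means from [adjusted_means()], or any tibble with
#'   columns `line`, `environment`, `n_level`, `adj_mean`.
#' @param index Index function of `(gy_ln, gy_in)`; defaults to
#'   [compute_lnae()]. Pluggable so other stress-tolerance indices can reuse
#'   the pairing logic.
#' @return A list with
#'   * `by_env`: tibble `line`, `environment`, `lnae`;
#'   * `combined`: tibble `line`, `lnae_mean`, `lnae_ls` (least-squares
#'     estimate; equals `lnae_mean` when every line is observed in every
#'     environment).
#' @export
lnae_table <- function(adj, index = compute_lnae) {
  wide <- tidyr::pivot_wider(
    dplyr::select(adj, "line", "environment", "n_level", "adj_mean"),
    names_from = "n_level", values_from = "adj_mean"
  )
  if (!all(c("IN", "LN") %in% names(wide))) {
    stop("adjusted means must cover both IN and LN levels", call. = FALSE)
  }
  by_env <- dplyr::transmute(
    dplyr::filter(wide, !is.na(.data$IN) & !is.na(.data$LN)),
    line = .data$line, environment = .data$environment,
    lnae = index(.data$LN, .data$IN)
  )
  comb_mean <- dplyr::summarise(dplyr::group_by(by_env, .data$line),
                                lnae_mean = mean(.data$lnae), .groups = "drop")
  lnae_ls <- ls_line_means(by_env)
  combined <- dplyr::left_join(comb_mean, lnae_ls, by = "line")
  list(by_env = by_env, combined = combined)
}

# least-squares line estimates from lnae ~ environment + line,
# averaged over environments (classical LS means)
ls_line_means <- function(by_env) {
  if (length(unique(by_env$environment)) < 2) {
    return(tibble::tibble(line = unique(by_env$line),
                          lnae_ls = tapply(by_env$lnae, by_env$line, mean)[
                            unique(by_env$line)]))
  }
  dat <- by_env
  dat$line <- factor(dat$line)
  dat$environment <- factor(dat$environment)
  fit <- lm(lnae ~ environment + line, data = dat)
  grid <- expand.grid(line = levels(dat$line),
                      environment = levels(dat$environment))
  grid$pred <- predict(fit, newdata = grid)
  tibble::tibble(
    line = levels(dat$line),
    lnae_ls = as.numeric(tapply(grid$pred, grid$line, mean))
  )
}

#' Two-way ANOVA of the LNAE index
#'
#' Fixed-effects analysis of variance `lnae ~ environment + line` on the
#' per-environment LNAE values; the line effect's F test decides whether
#' means clustering (Scott-Knott) is warranted, and the residual mean square
#' and degrees of freedom feed [scott_knott()] as its error terms.
#'
#' @param by_env Tibble `line`, `environment`, `lnae` (the `by_env` element
#'   of [lnae_table()]).
#' @return An object of class `lnae_anova` with elements `table` (tidy ANOVA
#'   tibble), `f_line`, `p_line`, `error_ms`, `error_df`, `n_env`, `fit`.
#' @export
lnae_anova <- function(by_env) {
  n_env <- length(unique(by_env$environment))
  if (n_env < 2) {
    stop("lnae_anova needs >= 2 environments: with a single environment the ",
         "line effect cannot be tested against this model; compare lines ",
         "directly or supply an external error term to scott_knott()",
         call. = FALSE)
  }
  dat <- by_env
  dat$line <- factor(dat$line)
  dat$environment <- factor(dat$environment)
  fit <- lm(lnae ~ environment + line, data = dat)
  an <- anova(fit)
  tab <- tibble::tibble(
    term = rownames(an), df = an$Df, sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`, statistic = an$`F value`, p.value = an$`Pr(>F)`
  )
  res <- tab[tab$term == "Residuals", ]
  lin <- tab[tab$term == "line", ]
  structure(list(
    table = tab,
    f_line = if (res$df > 0 && res$meansq > 0) lin$statistic else NA_real_,
    p_line = if (res$df > 0 && res$meansq > 0) lin$p.value else NA_real_,
    error_ms = res$meansq,
    error_df = res$df,
    n_env = n_env,
    fit = fit
  ), class = "lnae_anova")
}

#' @export
print.lnae_anova <- function(x, ...) {
  cat("Two-way fixed-effects ANOVA of LNAE (environment + line)\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @rdname lnae_anova
#' @param x An `lnae_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lnae_anova <- function(x, ...) x$table

#' @rdname lnae_anova
#' @exportS3Method generics::glance
glance.lnae_anova <- function(x, ...) {
  tibble::tibble(f_line = x$f_line, p_line = x$p_line,
                 error_ms = x$error_ms, error_df = x$error_df,
                 n_env = x$n_env)
}
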