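#' Weir-Cockerham theta for haploid-coded samples
#'
#' Moment estimator of the fixation index between populations from sample
#' allele frequencies, in the variant appropriate for fully inbred lines:
#' each line contributes a single allele draw, so there is no
#' within-individual component. With `r` groups of sizes `n_i` and
#' alternate-allele frequencies `p_i`:
#' \deqn{\bar n = \frac{1}{r}\sum n_i,\quad
#'   n_c = \frac{\sum n_i - \sum n_i^2 / \sum n_i}{r - 1},\quad
#'   \bar p = \frac{\sum n_i p_i}{\sum n_i},\quad
#'   s^2 = \frac{\sum n_i (p_i - \bar p)^2}{(r-1)\bar n},}
#' \deqn{T_1 = s^2 - \frac{\bar p(1-\bar p) - s^2 (r-1)/r}{\bar n - 1},\quad
#'   T_2 = \frac{\bar p (1-\bar p)(n_c - 1)}{\bar n - 1} +
#'   \left[1 + \frac{(r-1)(\bar n - n_c)}{\bar n - 1}\right]\frac{s^2}{r},}
#' \deqn{\theta = T_1 / T_2.}
#' Monomorphic configurations (`T_2 = 0`) return `NA`. Small-sample
#' estimates can be negative; they are reported as computed (see
#' `clamp` in [wc_fst()]). Invariant to relabelling ref/alt
#' (`p -> 1 - p` in every group).
#'
#' @param n Vector of per-group sample sizes (allele draws).
#' @param p Vector of per-group alternate-allele frequencies.
#' @return The theta estimate (scalar).
#' @references Weir, B. S. & Cockerham, C. C. (1984). Estimating F-statistics
#'   for the analysis of population structure. Evolution 38, 1358-1370.
#' @export
wc_theta <- function(n, p) {
  stopifnot(length(n) == length(p), length(n) >= 2)
  if (any(n < 1)) return(NA_real_)
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1) return(NA_real_)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  t1 <- s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1)
  t2 <- pbar * (1 - pbar) * (nc - 1) / (nbar - 1) +
    (1 + (r - 1) * (nbar - nc) / (nbar - 1)) * s2 / r
  if (t2 == 0) return(NA_real_)
  t1 / t2
}

#' Per-SNP Weir-Cockerham Fst between two phenotypic groups
#'
#' Computes [wc_theta()] for every marker between exactly two groups of
#' inbred lines (each non-missing line contributing one allele draw).
#' Markers at which either group has fewer than two informative lines, or
#' which are monomorphic across both groups, get `NA` theta and are flagged
#' in `note` rather than dropped.
#'
#' @param geno A [geno_matrix()].
#' @param groups Tibble `line`, `group` with exactly two group labels (e.g.
#'   from [sk_two_groups()]), or a named character vector.
#' @param threshold Outlier threshold on theta; markers strictly above it
#'   are flagged `outlier` (default 0.2).
#' @param clamp If `TRUE`, negative theta estimates are clamped to 0
#'   (default `FALSE`: report as computed).
#' @return A tibble (class `fst_table`) with one row per marker: `marker`,
#'   `chrom`, `pos`, `ref`, `alt`, `n_1`, `n_2`, `p_1`, `p_2` (per-group
#'   non-missing line counts and alternate-allele frequencies, groups in
#'   alphabetical label order, so H before L), `fst`, `outlier`, `note`.
#' @export
wc_fst <- function(geno, groups, threshold = 0.2, clamp = FALSE) {
  grp <- as_group_tbl(groups)
  labs <- sort(unique(grp$group))
  if (length(labs) != 2) {
    stop("exactly two groups required, got ", length(labs), call. = FALSE)
  }
  lines <- line_ids(geno)
  gvec <- grp$group[match(lines, grp$line)]
  if (anyNA(gvec)) {
    stop("group assignment missing for line(s): ",
         paste(head(lines[is.na(gvec)], 5), collapse = ", "), call. = FALSE)
  }
  calls <- geno$calls
  stats_for <- function(lab) {
    sub <- calls[gvec == lab, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- colMeans(sub, na.rm = TRUE) / 2
    list(n = n, p = p)
  }
  s1 <- stats_for(labs[1])
  s2 <- stats_for(labs[2])
  fst <- vapply(seq_len(ncol(calls)), function(j) {
    if (s1$n[j] < 2 || s2$n[j] < 2) return(NA_real_)
    wc_theta(c(s1$n[j], s2$n[j]), c(s1$p[j], s2$p[j]))
  }, double(1))
  if (clamp) fst <- pmax(fst, 0)
  note <- dplyr::case_when(
    s1$n < 2 | s2$n < 2 ~ "insufficient_lines",
    is.na(fst) ~ "monomorphic",
    TRUE ~ ""
  )
  out <- dplyr::bind_cols(geno$map, tibble::tibble(
    n_1 = unname(as.integer(s1$n)), n_2 = unname(as.integer(s2$n)),
    p_1 = unname(ifelse(s1$n > 0, s1$p, NA_real_)),
    p_2 = unname(ifelse(s2$n > 0, s2$p, NA_real_)),
    fst = fst,
    outlier = !is.na(fst) & fst > threshold,
    note = note
  ))
  attr(out, "group_labels") <- labs
  attr(out, "threshold") <- threshold
  class(out) <- c("fst_table", class(out))
  out
}

as_group_tbl <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("line", "group") %in% names(groups)))
    tibble::as_tibble(groups[c("line", "group")])
  } else {
    tibble::tibble(line = names(groups), group = unname(as.character(groups)))
  }
}

#' Select outlier markers from an Fst scan
#'
#' Markers with Fst strictly above the threshold, sorted by chromosome and
#' position, with the genome-wide mean Fst attached as attribute
#' `mean_fst` (mean over defined estimates).
#'
#' @param fst An `fst_table` from [wc_fst()].
#' @param threshold Directional-selection threshold (default 0.2).
#' @return The outlier subset of the table (possibly empty), sorted;
#'   attributes `mean_fst` and `threshold`.
#' @export
outlier_scan <- function(fst, threshold = 0.2) {
  defined <- !is.na(fst$fst)
  if (!any(defined)) {
    warning("no defined Fst estimates (all markers monomorphic?)",
            call. = FALSE)
  }
  out <- dplyr::arrange(fst[defined & fst$fst > threshold, ],
                        .data$chrom, .data$pos)
  attr(out, "mean_fst") <- mean(fst$fst[defined])
  attr(out, "threshold") <- threshold
  out
}

#' Favorable alleles at outlier markers
#'
#' For each outlier marker, the favorable allele is the one enriched in the
#' high-LNAE (H) group, i.e. whose frequency in H exceeds its frequency in
#' L; its frequency in both groups is reported (`ffa_h >= ffa_l` by
#' construction). Markers with exactly equal group frequencies carry no
#' favorable allele and are excluded with a warning.
#'
#' @param geno A [geno_matrix()] (supplies allele labels).
#' @param groups Two-group assignment with labels `"H"` and `"L"` (higher-
#'   mean group labelled H, as produced by [sk_two_groups()]).
#' @param outliers Outlier subset from [outlier_scan()] (or any `fst_table`
#'   rows).
#' @return A tibble `marker`, `chrom`, `pos`, `alleles`, `favorable_allele`,
#'   `ffa_h`, `ffa_l`.
#' @export
favorable_alleles <- function(geno, groups, outliers) {
  grp <- as_group_tbl(groups)
  if (!setequal(unique(grp$group), c("H", "L"))) {
    stop("groups must be labelled \"H\" and \"L\"", call. = FALSE)
  }
  lines <- line_ids(geno)
  gvec <- grp$group[match(lines, grp$line)]
  j <- match(outliers$marker, geno$map$marker)
  if (anyNA(j)) {
    stop("outlier marker(s) absent from genotype matrix", call. = FALSE)
  }
  freq_in <- function(lab) {
    sub <- geno$calls[gvec == lab, j, drop = FALSE]
    colMeans(sub, na.rm = TRUE) / 2
  }
  p_h <- freq_in("H")
  p_l <- freq_in("L")
  map <- geno$map[j, ]
  tie <- p_h == p_l
  if (any(tie, na.rm = TRUE)) {
    warning("no favorable allele at marker(s) with equal group frequencies: ",
            paste(map$marker[which(tie)], collapse = ", "), call. = FALSE)
  }
  alt_fav <- unname(p_h > p_l)
  p_h <- unname(p_h)
  p_l <- unname(p_l)
  out <- tibble::tibble(
    marker = map$marker, chrom = map$chrom, pos = map$pos,
    alleles = paste0(map$ref, "/", map$alt),
    favorable_allele = ifelse(alt_fav, map$alt, map$ref),
    ffa_h = ifelse(alt_fav, p_h, 1 - p_h),
    ffa_l = ifelse(alt_fav, p_l, 1 - p_l)
  )
  out[!tie | is.na(tie), ]
}

#' Number of favorable alleles per line
#'
#' Counts, for every line, the outlier markers at which it is homozygous
#' for the favorable allele. A missing genotype contributes 0 by default
#' (conservative); `missing_mode = "rescale"` instead scales the count by
#' the line's completeness over the outlier set.
#'
#' @param geno A [geno_matrix()].
#' @param fav Favorable-allele table from [favorable_alleles()].
#' @param missing_mode `"zero"` (default) or `"rescale"`.
#' @return Tibble `line`, `nfa` (`nfa` integer under `"zero"`).
#' @export
nfa_scores <- function(geno, fav, missing_mode = c("zero", "rescale")) {
  missing_mode <- match.arg(missing_mode)
  if (nrow(fav) < 1) stop("no favorable alleles defined", call. = FALSE)
  j <- match(fav$marker, geno$map$marker)
  stopifnot(!anyNA(j))
  fav_is_alt <- fav$favorable_allele == geno$map$alt[j]
  target <- ifelse(fav_is_alt, 2L, 0L)
  sub <- geno$calls[, j, drop = FALSE]
  hit <- sweep(sub, 2, target, `==`)
  nfa <- rowSums(hit, na.rm = TRUE)
  if (missing_mode == "rescale") {
    complete <- rowMeans(!is.na(sub))
    nfa <- unname(ifelse(complete > 0, nfa / complete, 0))
  } else {
    nfa <- unname(as.integer(nfa))
  }
  tibble::tibble(line = line_ids(geno), nfa = nfa)
}

#' Association between favorable-allele count and LNAE
#'
#' Pearson correlation (with two-sided t-test) between per-line NFA and
#' LNAE, plus the simple least-squares regression of LNAE on NFA. For this
#' simple regression `R^2 = r^2` by identity, asserted internally.
#'
#' @param nfa Tibble `line`, `nfa` from [nfa_scores()].
#' @param lnae Tibble with `line` and an LNAE column (`lnae`, `lnae_mean`
#'   or `lnae_ls`; the first present is used), e.g. `combined` from
#'   [lnae_table()].
#' @return An object of class `nfa_assoc`: list with `r`, `p_value`,
#'   `slope`, `intercept`, `r_squared`, `n`, `data` (the joined tibble).
#' @export
nfa_lnae_association <- function(nfa, lnae) {
  lcol <- intersect(c("lnae", "lnae_mean", "lnae_ls"), names(lnae))[1]
  if (is.na(lcol)) stop("no LNAE column found", call. = FALSE)
  dat <- dplyr::inner_join(nfa, dplyr::select(lnae, "line",
                                              lnae = dplyr::all_of(lcol)),
                           by = "line")
  dat <- dat[stats::complete.cases(dat[c("nfa", "lnae")]), ]
  if (nrow(dat) < 3) stop("need >= 3 lines with both NFA and LNAE",
                          call. = FALSE)
  if (var(dat$nfa) == 0) {
    stop("NFA has zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(dat$nfa, dat$lnae, method = "pearson")
  fit <- lm(lnae ~ nfa, data = dat)
  r2 <- summary(fit)$r.squared
  stopifnot(abs(r2 - unname(ct$estimate)^2) < 1e-8)
  structure(list(
    r = unname(ct$estimate), p_value = ct$p.value,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, n = nrow(dat), data = tibble::as_tibble(dat)
  ), class = "nfa_assoc")
}

#' @export
print.nfa_assoc <- function(x, ...) {
  cat(sprintf(
    "NFA-LNAE association over %d lines\n  Pearson r = %.3f (p = %.3g)\n  LNAE = %.1f + %.1f x NFA, R^2 = %.3f\n",
    x$n, x$r, x$p_value, x$intercept, x$slope, x$r_squared
  ))
  invisible(x)
}

#' @rdname nfa_lnae_association
#' @param x An `nfa_assoc` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nfa_assoc <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "nfa"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname nfa_lnae_association
#' @exportS3Method generics::glance
glance.nfa_assoc <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p_value, r.squared = x$r_squared,
                 n = x$n)
}
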