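#' Marker quality control: call rate and minor allele frequency
#'
#' Keeps markers whose call rate and minor-allele frequency both meet their
#' thresholds (inclusive: `>=`). MAF is computed on non-missing calls, each
#' inbred line contributing one allele draw. Marker order is preserved.
#'
#' @param geno A [geno_matrix()].
#' @param min_call_rate Minimum fraction of non-missing lines (default 0.90).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @return A list with `geno` (filtered [geno_matrix()]) and `report`
#'   (a `qc_report` tibble row: markers in/out, removals per rule,
#'   thresholds).
#' @export
filter_markers <- function(geno, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  st <- marker_stats(geno)
  fail_cr <- st$call_rate < min_call_rate
  fail_maf <- !fail_cr & (is.na(st$maf) | st$maf < min_maf)
  keep <- !fail_cr & !fail_maf
  if (!any(keep)) {
    warning("no markers survive QC thresholds", call. = FALSE)
  }
  report <- qc_report(
    step = "filter_markers",
    markers_in = nrow(st), markers_out = sum(keep),
    removed_call_rate = sum(fail_cr), removed_maf = sum(fail_maf),
    removed_ld = 0L,
    thresholds = sprintf("call_rate>=%g, maf>=%g", min_call_rate, min_maf)
  )
  list(geno = geno[, which(keep)], report = report)
}

#' Sliding-window LD pruning
#'
#' Within each chromosome, examines windows of `window` markers advancing by
#' `step` markers. In every window, while any surviving pair has squared
#' Pearson correlation of allele-count codes (computed over
#' pairwise-complete lines) strictly above `r2_threshold`, the pair with the
#' highest r-squared is resolved by dropping its lower-MAF member (ties:
#' drop the later position). Deterministic for a given input.
#'
#' @param geno A [geno_matrix()] sorted by chromosome and position (the
#'   constructor guarantees this).
#' @param r2_threshold Remove one of any pair with r^2 strictly above this
#'   (default 0.13, a typical panel-average LD level).
#' @param window Window size in markers (default 50).
#' @param step Window advance in markers (default 5).
#' @return A list with `geno` (pruned matrix) and `report` (`qc_report`).
#' @export
ld_prune <- function(geno, r2_threshold = 0.13, window = 50, step = 5) {
  if (window < 2) stop("window must be >= 2 markers", call. = FALSE)
  stopifnot(step >= 1, r2_threshold >= 0, r2_threshold <= 1)
  st <- marker_stats(geno)
  m <- ncol(geno$calls)
  keep <- rep(TRUE, m)
  for (chr in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == chr)
    starts <- seq(1L, max(length(idx) - 1L, 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      keep <- prune_window(geno$calls, keep, win, r2_threshold, st$maf,
                           geno$map$pos)
      if (s + window - 1L >= length(idx)) break
    }
  }
  report <- qc_report(
    step = "ld_prune",
    markers_in = m, markers_out = sum(keep),
    removed_call_rate = 0L, removed_maf = 0L, removed_ld = sum(!keep),
    thresholds = sprintf("r2>%g, window=%d, step=%d", r2_threshold,
                         as.integer(window), as.integer(step))
  )
  list(geno = geno[, which(keep)], report = report)
}

# resolve all violating pairs among surviving markers of one window
prune_window <- function(calls, keep, win, r2_threshold, maf, pos) {
  repeat {
    alive <- win[keep[win]]
    if (length(alive) < 2) return(keep)
    cc <- suppressWarnings(cor(calls[, alive, drop = FALSE],
                               use = "pairwise.complete.obs"))
    r2 <- cc^2
    r2[!is.finite(r2)] <- 0
    r2[upper.tri(r2, diag = TRUE)] <- 0  # keep lower triangle: i > j
    if (max(r2) <= r2_threshold) return(keep)
    hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    a <- alive[hit[["col"]]]
    b <- alive[hit[["row"]]]
    drop <- if (isTRUE(maf[a] < maf[b])) a
            else if (isTRUE(maf[b] < maf[a])) b
            else if (pos[a] > pos[b]) a else b
    keep[drop] <- FALSE
  }
}

qc_report <- function(step, markers_in, markers_out, removed_call_rate,
                      removed_maf, removed_ld, thresholds) {
  out <- tibble::tibble(
    step = step,
    markers_in = as.integer(markers_in),
    removed_call_rate = as.integer(removed_call_rate),
    removed_maf = as.integer(removed_maf),
    removed_ld = as.integer(removed_ld),
    markers_out = as.integer(markers_out),
    thresholds = thresholds
  )
  stopifnot(out$markers_out ==
              out$markers_in - out$removed_call_rate - out$removed_maf -
              out$removed_ld)
  class(out) <- c("qc_report", class(out))
  out
}
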