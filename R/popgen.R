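#' Identity-by-state genetic distance
#'
#' For every pair of lines, over the markers non-missing in both, the
#' identity by state of a marker is the probability that one allele drawn
#' from each line matches: 1 for identical homozygotes, 0 for opposite
#' homozygotes (1/2 would apply to a heterozygote, which inbred panels do
#' not carry). The distance is `1 - mean IBS`. Invariant to swapping the
#' ref/alt labelling of any marker.
#'
#' @param geno A [geno_matrix()] with at least two lines.
#' @return An object of class `ibs_dist`: list with `distance` (symmetric
#'   matrix in `[0,1]`, zero diagonal, `NA` for pairs sharing no markers)
#'   and `n_shared` (matrix of per-pair marker counts).
#' @export
ibs_distance <- function(geno) {
  calls <- geno$calls
  if (nrow(calls) < 2) stop("need at least 2 lines", call. = FALSE)
  a <- calls / 2                     # alt-allele dose per draw, in {0, 1/2, 1}
  obs <- !is.na(a)
  a0 <- a
  a0[!obs] <- 0
  # per-pair expected matches: sum over shared markers of a_i a_j + (1-a_i)(1-a_j)
  m_alt <- tcrossprod(a0)
  m_ref <- tcrossprod((1 - a0) * obs)
  n_shared <- tcrossprod(obs * 1)
  ibs <- (m_alt + m_ref) / n_shared
  d <- 1 - ibs
  diag(d) <- 0
  d[n_shared == 0] <- NA_real_
  diag(d) <- 0
  if (any(n_shared == 0 & row(n_shared) != col(n_shared))) {
    warning("pair(s) with zero shared markers: distance set to NA",
            call. = FALSE)
  }
  dimnames(d) <- list(rownames(calls), rownames(calls))
  dimnames(n_shared) <- dimnames(d)
  structure(list(distance = d, n_shared = n_shared), class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  v <- x$distance[lower.tri(x$distance)]
  cat(sprintf("<ibs_dist> %d lines; 1-IBS range %.3f-%.3f (mean %.3f)\n",
              nrow(x$distance), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              mean(v, na.rm = TRUE)))
  invisible(x)
}

#' @rdname ibs_distance
#' @param x An `ibs_dist` object.
#' @param ... Unused.
#' @return [tidy.ibs_dist()]: long tibble `line1`, `line2`, `distance`,
#'   `n_shared` over unordered pairs.
#' @exportS3Method generics::tidy
tidy.ibs_dist <- function(x, ...) {
  lt <- lower.tri(x$distance)
  tibble::tibble(
    line1 = rownames(x$distance)[row(x$distance)[lt]],
    line2 = colnames(x$distance)[col(x$distance)[lt]],
    distance = x$distance[lt],
    n_shared = as.integer(x$n_shared[lt])
  )
}

#' Write / read a square distance matrix as delimited text
#' @param dist An `ibs_dist` or square matrix.
#' @param path Output path (TSV with a header of line ids).
#' @export
write_distance_matrix <- function(dist, path) {
  d <- if (inherits(dist, "ibs_dist")) dist$distance else dist
  df <- data.frame(line = rownames(d), d, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    line = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  d <- as.matrix(df[-1])
  rownames(d) <- df$line
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: squared distances are double-centered
#' (`-1/2 J D^2 J`) and eigendecomposed; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Negative
#' eigenvalues, which arise when the distance is not Euclidean, are
#' reported and their axes dropped.
#'
#' @param dist An `ibs_dist`, `dist` or complete square symmetric matrix.
#' @param n_axes Number of axes to return (default 2; capped at the number
#'   of positive eigenvalues).
#' @param standardize If `TRUE`, columns of the coordinate matrix are
#'   rescaled to unit variance after extraction. Off by default: plain
#'   double-centered coordinates preserve the distance geometry.
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (tibble `line`, `Axis1`, ..., plus nothing else), `eigenvalues` (all,
#'   sorted descending), `prop_variance` (share of the positive-eigenvalue
#'   total per returned axis), `trace` (of the double-centered matrix).
#' @export
pcoa <- function(dist, n_axes = 2, standardize = FALSE) {
  d <- if (inherits(dist, "ibs_dist")) dist$distance else as.matrix(dist)
  if (anyNA(d)) {
    stop("distance matrix has missing entries; complete the pairs (e.g. ",
         "drop lines with no shared markers) before ordination",
         call. = FALSE)
  }
  n <- nrow(d)
  b <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  ee <- eigen(b, symmetric = TRUE)
  pos <- ee$values > sqrt(.Machine$double.eps) * max(abs(ee$values), 1)
  k <- min(n_axes, sum(pos))
  coords <- ee$vectors[, which(pos)[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ee$values[which(pos)[seq_len(k)]]), k, k)
  if (standardize && k > 0) coords <- scale(coords)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(line = rownames(d) %||% sprintf("L%03d", seq_len(n))),
      tibble::as_tibble(coords)
    ),
    eigenvalues = ee$values,
    prop_variance = ee$values[which(pos)[seq_len(k)]] / sum(ee$values[pos]),
    trace = sum(diag(b))
  ), class = "pcoa_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates) - 1L
  cat(sprintf("<pcoa_result> %d lines, %d axes (%s of variance)\n",
              nrow(x$coordinates), k,
              paste(sprintf("%.1f%%", 100 * x$prop_variance),
                    collapse = " + ")))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pcoa_result <- function(x, ...) x$coordinates

#' Evanno delta-K from structure-run log-likelihoods
#'
#' Summarizes externally produced Bayesian population-structure runs.
#' For each interior K of a consecutive range with replicate runs,
#' `delta_K = mean over replicates |L_r(K+1) - 2 L_r(K) + L_r(K-1)| /
#' sd over replicates of L(K)`; the endpoints of the K range get no value.
#' Replicates must be paired across K by run id. Where the L(K) replicates
#' have zero spread, delta-K is undefined and flagged `NA`.
#'
#' @param tab Tibble with columns `K`, `run`, `logL` (one row per run).
#' @return Tibble `K`, `mean_logL`, `sd_logL`, `delta_k`.
#' @export
evanno_delta_k <- function(tab) {
  stopifnot(all(c("K", "run", "logL") %in% names(tab)))
  ks <- sort(unique(tab$K))
  if (length(ks) < 3 || !all(diff(ks) == 1)) {
    stop("need >= 3 consecutive K values", call. = FALSE)
  }
  runs <- tapply(tab$run, tab$K, function(r) length(unique(r)))
  if (any(runs < 2)) stop("need >= 2 replicate runs per K", call. = FALSE)
  wide <- tidyr::pivot_wider(tab, names_from = "K", values_from = "logL",
                             names_prefix = "K")
  if (anyNA(wide)) stop("replicates must be paired across all K", call. = FALSE)
  lmat <- as.matrix(wide[paste0("K", ks)])
  mean_l <- colMeans(lmat)
  sd_l <- apply(lmat, 2, sd)
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    second <- lmat[, i + 1] - 2 * lmat[, i] + lmat[, i - 1]
    dk[i] <- if (sd_l[i] > 0) mean(abs(second)) / sd_l[i] else NA_real_
  }
  out <- tibble::tibble(K = ks, mean_logL = unname(mean_l),
                        sd_logL = unname(sd_l), delta_k = dk)
  zero_sd <- sd_l == 0 & seq_along(ks) %in% seq(2, length(ks) - 1)
  if (any(zero_sd)) {
    warning("zero replicate spread at K = ",
            paste(ks[zero_sd], collapse = ", "),
            ": delta-K undefined there", call. = FALSE)
  }
  out
}
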