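#' Scott-Knott clustering of treatment means
#'
#' Recursive divisive clustering of ordered means (Scott & Knott 1974).
#' Means are sorted in descending order; among all cut points of the ordered
#' means, the split maximizing the between-group sum of squares
#' \eqn{B_0} is tested with the likelihood-ratio-type statistic
#' \deqn{\lambda = \frac{\pi}{2(\pi - 2)} \, \frac{B_0}{\hat\sigma_0^2},
#' \qquad \hat\sigma_0^2 = \frac{\sum_i (\bar y_i - \bar y)^2 +
#' \nu s_{\bar y}^2}{g + \nu},}
#' where \eqn{g} is the number of means in the group under test,
#' \eqn{s_{\bar y}^2 = \mathrm{error\_ms} / n_{rep}} is the variance of a
#' treatment mean and \eqn{\nu = \mathrm{error\_df}}. Heterogeneity is
#' declared when \eqn{\lambda} exceeds the \eqn{\chi^2} quantile at
#' \eqn{\nu_0 = g / (\pi - 2)} (fractional) degrees of freedom; significant
#' groups are split and each part re-tested until no split is significant.
#' The result is a partition into non-overlapping groups, labelled 1, 2, ...
#' in descending order of group mean.
#'
#' A cut never separates exactly equal means, and a group whose members are
#' all equal is never split. Ties in the sort are broken by name for
#' determinism.
#'
#' @param values Named numeric vector of treatment (line) means, or a
#'   two-column data frame (`line`, value).
#' @param error_ms Error mean square from the ANOVA the means came from.
#' @param error_df Its degrees of freedom.
#' @param alpha Significance level of the splitting test, in (0, 1).
#' @param n_rep Number of replicates underlying each mean, so that
#'   `error_ms / n_rep` is the variance of a mean. Use 1 if `error_ms` is
#'   already on the mean scale.
#' @return An object of class `scott_knott`: list with `groups` (tibble
#'   `line`, `value`, `group`), `group_means` (tibble `group`, `mean`, `n`),
#'   `splits` (tibble of per-split statistics `g`, `b0`, `sigma02`,
#'   `lambda`, `df0`, `critical`, `significant`), `alpha`, `error_ms`,
#'   `error_df`, `n_rep`.
#' @references Scott, A. J. & Knott, M. (1974). A cluster analysis method
#'   for grouping means in the analysis of variance. Biometrics 30, 507-512.
#' @export
scott_knott <- function(values, error_ms, error_df, alpha = 0.05, n_rep = 1) {
  if (is.data.frame(values)) {
    stopifnot(ncol(values) >= 2)
    v <- values[[2]]
    names(v) <- values[[1]]
    values <- v
  }
  if (is.null(names(values))) {
    names(values) <- sprintf("t%03d", seq_along(values))
  }
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 means", call. = FALSE)
  if (error_ms < 0) stop("error_ms must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)

  ord <- order(-values, names(values))
  y <- values[ord]
  s2y <- error_ms / n_rep
  nu <- error_df
  splits <- list()

  assign_groups <- function(idx) {
    res <- sk_test(y[idx], s2y, nu, alpha)
    if (!is.null(res)) {
      splits[[length(splits) + 1L]] <<- res$stats
      if (res$stats$significant) {
        left <- idx[seq_len(res$cut)]
        right <- idx[-seq_len(res$cut)]
        return(c(assign_groups(left), assign_groups(right)))
      }
    }
    list(idx)
  }
  parts <- assign_groups(seq_along(y))

  groups <- tibble::tibble(
    line = names(y), value = unname(y),
    group = rep(seq_along(parts), lengths(parts))
  )
  group_means <- dplyr::summarise(dplyr::group_by(groups, .data$group),
                                  mean = mean(.data$value),
                                  n = dplyr::n(), .groups = "drop")
  structure(list(
    groups = groups,
    group_means = group_means,
    splits = if (length(splits)) dplyr::bind_rows(splits) else
      tibble::tibble(g = integer(), b0 = double(), sigma02 = double(),
                     lambda = double(), df0 = double(), critical = double(),
                     significant = logical()),
    alpha = alpha, error_ms = error_ms, error_df = error_df, n_rep = n_rep
  ), class = "scott_knott")
}

# test one ordered group of means for a significant best split;
# returns NULL when no admissible cut exists
sk_test <- function(y, s2y, nu, alpha) {
  g <- length(y)
  if (g < 2) return(NULL)
  # candidate cuts only between strictly different adjacent means:
  # a cut never separates exactly-equal values
  adm <- unname(which(diff(y) != 0))
  if (length(adm) == 0) return(NULL)
  tot <- sum(y)
  b0 <- vapply(adm, function(k) {
    t1 <- sum(y[seq_len(k)])
    t1^2 / k + (tot - t1)^2 / (g - k) - tot^2 / g
  }, double(1))
  best <- which.max(b0)
  cut <- adm[best]
  b0max <- b0[best]
  sigma02 <- (sum((y - mean(y))^2) + nu * s2y) / (g + nu)
  lambda <- pi / (2 * (pi - 2)) * b0max / sigma02
  df0 <- g / (pi - 2)
  crit <- qchisq(1 - alpha, df = df0)
  list(cut = cut, stats = tibble::tibble(
    g = g, b0 = b0max, sigma02 = sigma02, lambda = lambda, df0 = df0,
    critical = crit, significant = lambda > crit
  ))
}

#' @export
print.scott_knott <- function(x, ...) {
  k <- nrow(x$group_means)
  cat(sprintf("Scott-Knott partition: %d group(s) of %d means (alpha = %g)\n",
              k, nrow(x$groups), x$alpha))
  print(as.data.frame(x$group_means), row.names = FALSE)
  invisible(x)
}

#' @rdname scott_knott
#' @param x A `scott_knott` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scott_knott <- function(x, ...) x$groups

#' @rdname scott_knott
#' @exportS3Method generics::glance
glance.scott_knott <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$group_means), n_means = nrow(x$groups),
    alpha = x$alpha, error_ms = x$error_ms, error_df = x$error_df
  )
}

#' Two-group H/L assignment from a Scott-Knott partition
#'
#' Collapses a Scott-Knott partition into the binary contrast used by the
#' selection scan: lines in the top group(s) covering the highest means are
#' labelled `"H"`, the rest `"L"`. With exactly two Scott-Knott groups this
#' is the partition itself.
#'
#' @param sk A [scott_knott()] result.
#' @param n_top Number of leading groups to merge into H (default 1).
#' @return Tibble `line`, `group` with levels `"H"` and `"L"`.
#' @export
sk_two_groups <- function(sk, n_top = 1) {
  stopifnot(inherits(sk, "scott_knott"))
  if (nrow(sk$group_means) < 2) {
    stop("Scott-Knott found a single homogeneous group; no H/L contrast",
         call. = FALSE)
  }
  tibble::tibble(
    line = sk$groups$line,
    group = ifelse(sk$groups$group <= n_top, "H", "L")
  )
}
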