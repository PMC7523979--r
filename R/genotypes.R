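#' Genotype matrix for a panel of inbred lines
#'
#' Container for biallelic SNP calls on fully homozygous material. Calls are
#' coded as copies of the alternate allele per line: `0` (homozygous
#' reference), `2` (homozygous alternate) or `NA` (missing). Heterozygous
#' calls never occur in inbred lines; the I/O layer enforces a policy for
#' them (see [read_genotypes_vcf()]).
#'
#' @param calls Integer matrix, lines in rows and markers in columns, values
#'   in `{0, 2, NA}`. Row names are line ids, column names marker ids.
#' @param map Data frame with one row per marker: `marker`, `chrom`,
#'   `pos` (1-based bp), `ref`, `alt` (single-nucleotide allele labels).
#'
#' @details Markers are kept sorted by chromosome then position; `calls`
#'   columns are reordered to match. Positions must be unique within a
#'   chromosome.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (integer matrix) and `map` (tibble).
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- tibble::as_tibble(map)
  stopifnot(
    all(c("marker", "chrom", "pos", "ref", "alt") %in% names(map)),
    ncol(calls) == nrow(map)
  )
  if (is.null(colnames(calls)) && ncol(calls) > 0) {
    colnames(calls) <- map$marker
  }
  if (ncol(calls) > 0 &&
      !identical(colnames(calls), as.character(map$marker))) {
    stop("column names of `calls` must match `map$marker`", call. = FALSE)
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  }
  bad <- setdiff(unique(as.vector(calls)), c(0L, 2L, NA))
  if (length(bad) > 0) {
    stop("genotype calls must be 0, 2 or NA; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(map$ref) || !ok_allele(map$alt)) {
    stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(map[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in marker map", call. = FALSE)
  }
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d lines x %d markers on %d chromosome(s); %.2f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Line identifiers of a genotype matrix
#' @param geno A [geno_matrix()].
#' @return Character vector of line ids.
#' @export
line_ids <- function(geno) rownames(geno$calls)

#' Subset a genotype matrix by lines and/or markers
#' @param x A [geno_matrix()].
#' @param lines,markers Indices, logical masks or names; default keeps all.
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, lines = NULL, markers = NULL, ...) {
  if (is.null(lines)) lines <- seq_len(nrow(x$calls))
  if (is.null(markers)) markers <- seq_len(ncol(x$calls))
  if (is.character(markers)) markers <- match(markers, x$map$marker)
  geno_matrix(x$calls[lines, markers, drop = FALSE],
              x$map[markers, , drop = FALSE])
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `line`, `marker`, `chrom`, `pos`, `call`.
#' @exportS3Method generics::tidy
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    line = rep(rownames(x$calls), times = ncol(x$calls)),
    marker = rep(x$map$marker, each = nrow(x$calls)),
    chrom = rep(x$map$chrom, each = nrow(x$calls)),
    pos = rep(x$map$pos, each = nrow(x$calls)),
    call = as.integer(x$calls)
  )
}

#' Per-marker summary of a genotype matrix
#'
#' Call rate and alternate/minor allele frequency per marker, computed on
#' non-missing calls only. For inbred lines each line contributes a single
#' allele draw (`calls / 2`).
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with `marker`, `chrom`, `pos`, `n_called`, `call_rate`,
#'   `freq_alt`, `maf`.
#' @exportS3Method generics::glance
glance.geno_matrix <- function(x, ...) {
  marker_stats(x)
}

marker_stats <- function(geno) {
  calls <- geno$calls
  n_called <- colSums(!is.na(calls))
  freq_alt <- colMeans(calls, na.rm = TRUE) / 2
  freq_alt[n_called == 0] <- NA_real_
  tibble::tibble(
    marker = geno$map$marker,
    chrom = geno$map$chrom,
    pos = geno$map$pos,
    n_called = as.integer(n_called),
    call_rate = n_called / nrow(calls),
    freq_alt = freq_alt,
    maf = pmin(freq_alt, 1 - freq_alt)
  )
}
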