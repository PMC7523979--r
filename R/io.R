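#' Read a genotype matrix from VCF
#'
#' Parses a VCF 4.x file of biallelic SNPs into a [geno_matrix()].
#' Homozygous reference calls become `0`, homozygous alternate `2`, missing
#' (`./.` or `.`) `NA`. The panel is assumed inbred, so heterozygous calls
#' are unexpected: under `het_policy = "missing"` (default) they are set to
#' `NA` with a warning, under `"strict"` they raise an error.
#'
#' @param path Path to a plain-text VCF file with a GT FORMAT field.
#' @param het_policy `"missing"` or `"strict"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path, het_policy = c("missing", "strict")) {
  het_policy <- match.arg(het_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) at VCF data line(s) ",
         paste(which(multi), collapse = ", "),
         "; split them before import", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  parse_gt <- function(g) {
    if (is.na(g) || any(strsplit(g, "/", fixed = TRUE)[[1]] == ".")) {
      return(NA_integer_)
    }
    a <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
    if (length(unique(a)) > 1L) return(-1L)  # heterozygous sentinel
    if (a[1] == 0L) 0L else 2L
  }
  # genotype strings take few distinct values; code each once and look up
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  lev <- unique(as.vector(gt_norm))
  codes <- vapply(lev, parse_gt, integer(1))
  calls <- matrix(codes[match(gt_norm, lev)], nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  n_het <- sum(calls == -1L, na.rm = TRUE)
  if (n_het > 0) {
    if (het_policy == "strict") {
      stop(n_het, " heterozygous call(s) found with het_policy = \"strict\"",
           call. = FALSE)
    }
    warning(n_het, " heterozygous call(s) set to missing", call. = FALSE)
    calls[calls == -1L] <- NA_integer_
  }
  calls <- t(calls)  # vcfR is markers x samples
  map <- tibble::tibble(
    marker = unname(fix[, "ID"]),
    chrom = type.convert(unname(fix[, "CHROM"]), as.is = TRUE),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"])
  )
  colnames(calls) <- map$marker
  geno_matrix(calls, map)
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal plain-text VCF 4.2 with a GT field, coding homozygous
#' diploid calls (`0/0`, `1/1`, `./.`) as is conventional for array data on
#' inbred material.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  map <- geno$map
  gt <- matrix("0/0", nrow(map), nrow(geno$calls))
  tcalls <- t(geno$calls)
  gt[tcalls == 2L] <- "1/1"
  gt[is.na(tcalls)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nitroscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$calls)), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos, map$marker, map$ref, map$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the tabular genotype dialect
#'
#' A tab-delimited genotype table whose first column is `line` and remaining
#' columns are marker ids, cells holding nucleotide pairs (`"AA"`, `"GG"`,
#' `"NN"` for missing), accompanied by a map sidecar (`marker`, `chrom`,
#' `pos`, `ref`, `alt`). Cells must match the map's two alleles.
#'
#' @param path Path to the genotype table.
#' @param map_path Path to the map sidecar (default `<path>.map`).
#' @return [read_genotypes_table()]: a [geno_matrix()].
#' @export
read_genotypes_table <- function(path, map_path = paste0(path, ".map")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    line = readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  map <- readr::read_tsv(map_path, col_types = "ccicc", progress = FALSE)
  markers <- setdiff(names(tab), "line")
  if (!setequal(markers, map$marker)) {
    stop("markers in genotype table and map sidecar disagree", call. = FALSE)
  }
  map <- map[match(markers, map$marker), ]
  cells <- as.matrix(tab[markers])
  calls <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = list(tab$line, markers))
  for (j in seq_along(markers)) {
    homo_ref <- strrep(map$ref[j], 2)
    homo_alt <- strrep(map$alt[j], 2)
    x <- cells[, j]
    ok <- x %in% c(homo_ref, homo_alt, "NN")
    if (!all(ok)) {
      stop("alleles not matching the map at marker ", markers[j], ": ",
           paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
    }
    calls[x == homo_ref, j] <- 0L
    calls[x == homo_alt, j] <- 2L
  }
  map$chrom <- type.convert(map$chrom, as.is = TRUE)
  geno_matrix(calls, map)
}

#' @rdname read_genotypes_table
#' @param geno A [geno_matrix()] to write.
#' @export
write_genotypes_table <- function(geno, path, map_path = paste0(path, ".map")) {
  map <- geno$map
  cells <- matrix("NN", nrow(geno$calls), ncol(geno$calls))
  homo_ref <- matrix(strrep(map$ref, 2), nrow(geno$calls), ncol(geno$calls),
                     byrow = TRUE)
  homo_alt <- matrix(strrep(map$alt, 2), nrow(geno$calls), ncol(geno$calls),
                     byrow = TRUE)
  cells[which(geno$calls == 0L)] <- homo_ref[which(geno$calls == 0L)]
  cells[which(geno$calls == 2L)] <- homo_alt[which(geno$calls == 2L)]
  tab <- tibble::as_tibble(as.data.frame(cells))
  names(tab) <- map$marker
  tab <- dplyr::bind_cols(tibble::tibble(line = rownames(geno$calls)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(map, map_path, progress = FALSE)
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' Expects delimited text (comma or tab, sniffed) with header columns
#' `line`, `environment`, `n_level`, `rep`, `block`, `grain_yield`.
#' N level must be `"IN"` or `"LN"`; yields must be non-negative; duplicate
#' (line, environment, n_level, rep) keys are rejected.
#'
#' @param path Path to the phenotype file.
#' @return A tibble of typed plot records.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  ph <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    line = readr::col_character(), environment = readr::col_character(),
    n_level = readr::col_character(), rep = readr::col_integer(),
    block = readr::col_character(), grain_yield = readr::col_double()
  ), progress = FALSE)
  need <- c("line", "environment", "n_level", "rep", "block", "grain_yield")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols) > 0) {
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_n <- setdiff(unique(ph$n_level), c("IN", "LN"))
  if (length(bad_n) > 0) {
    stop("unknown N level token(s): ", paste(bad_n, collapse = ", "),
         call. = FALSE)
  }
  if (any(ph$grain_yield < 0, na.rm = TRUE)) {
    stop("negative grain yield found", call. = FALSE)
  }
  key <- ph[c("line", "environment", "n_level", "rep")]
  if (anyDuplicated(key)) {
    stop("duplicate (line, environment, n_level, rep) record(s)",
         call. = FALSE)
  }
  ph
}

#' Write a phenotype table
#' @param pheno A phenotype tibble as produced by [simulate_phenotypes()].
#' @param path Output path; written as CSV.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Write / read the simulation ground-truth sidecar
#'
#' Serializes a `sim_truth` to three delimited sections in one file
#' (selected loci, group labels, true favorable-allele counts).
#'
#' @param truth A `sim_truth` from [simulate_genotypes()].
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  sel <- truth$selected_loci
  lines <- c(
    "#selected_loci",
    paste(c("marker", "chrom", "pos", "favorable_allele", "freq_high",
            "freq_low"), collapse = "\t"),
    if (nrow(sel)) paste(sel$marker, sel$chrom, sel$pos, sel$favorable_allele,
                         sel$freq_high, sel$freq_low, sep = "\t"),
    "#groups",
    "line\tgroup",
    paste(truth$groups$line, truth$groups$group, sep = "\t"),
    "#nfa",
    "line\ttrue_nfa",
    paste(truth$nfa$line, truth$nfa$true_nfa, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  txt <- readLines(path)
  sec <- cumsum(startsWith(txt, "#"))
  parse_sec <- function(i) {
    block <- txt[sec == i & !startsWith(txt, "#")]
    readr::read_tsv(I(paste(block, collapse = "\n")), col_types = readr::cols(),
                    progress = FALSE)
  }
  sel <- parse_sec(1)
  structure(list(
    selected_loci = sel,
    groups = parse_sec(2),
    nfa = parse_sec(3)
  ), class = "sim_truth")
}
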