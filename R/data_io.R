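## Genotype, population and environment containers plus quality filters.
## Genotypes are integer counts of the derived (or, when the ancestral state
## is unknown, an arbitrary reference) allele: 0/1/2 for diploids, NA missing.

#' SNP genotype table
#'
#' Container for per-individual SNP genotypes together with SNP annotation
#' (contig/gene membership, position, whether the derived allele is known)
#' and the individual-to-population mapping.
#'
#' @param genotypes Integer matrix, individuals x SNPs, values in
#'   `0:ploidy` or `NA` (missing).  Column names are SNP ids if `snp_info`
#'   is not supplied; row names are individual ids.
#' @param snp_info Data frame with columns `snp_id`, `contig_id`, and
#'   optionally `position` (default 0) and `derived_known` (default `TRUE`).
#'   One row per genotype column, in column order.
#' @param pop_of_individual Named character vector mapping individual id to
#'   population id (names = individual ids), or an unnamed vector in row
#'   order of `genotypes`.
#' @param ploidy 2 (default) for 0/1/2 diploid codes, 1 for haploid 0/1 data.
#'
#' @return An object of class `snp_table`: a list with elements `genotypes`,
#'   `snp` (annotation data frame), `individuals` (data frame with
#'   `individual_id`, `pop_id`) and `ploidy`.
#' @export
snp_table <- function(genotypes, snp_info = NULL, pop_of_individual, ploidy = 2L) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  bad <- !is.na(genotypes) & (genotypes < 0L | genotypes > ploidy)
  if (any(bad)) stop("genotype codes must be in 0..ploidy or NA")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(snp_info)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
    snp_info <- data.frame(snp_id = ids, contig_id = ids,
                           stringsAsFactors = FALSE)
  }
  snp_info <- as.data.frame(snp_info)
  if (!all(c("snp_id", "contig_id") %in% names(snp_info)))
    stop("snp_info needs columns 'snp_id' and 'contig_id'")
  if (nrow(snp_info) != ncol(genotypes))
    stop("snp_info rows must match genotype columns")
  if (anyDuplicated(snp_info$snp_id)) stop("snp_id values must be unique")
  if (is.null(snp_info$position)) snp_info$position <- 0L
  if (any(snp_info$position < 0)) stop("position must be >= 0")
  if (is.null(snp_info$derived_known)) snp_info$derived_known <- TRUE
  colnames(genotypes) <- snp_info$snp_id

  if (is.null(names(pop_of_individual))) {
    if (length(pop_of_individual) != nrow(genotypes))
      stop("pop_of_individual must cover every individual")
    names(pop_of_individual) <- rownames(genotypes)
  }
  miss <- setdiff(rownames(genotypes), names(pop_of_individual))
  if (length(miss))
    stop("individuals without a population: ", paste(miss, collapse = ", "))
  individuals <- data.frame(
    individual_id = rownames(genotypes),
    pop_id = unname(as.character(pop_of_individual[rownames(genotypes)])),
    stringsAsFactors = FALSE)

  structure(list(genotypes = genotypes, snp = snp_info,
                 individuals = individuals, ploidy = as.integer(ploidy)),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d individuals x %d SNPs (%d populations, ploidy %d)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$individuals$pop_id)), x$ploidy))
  invisible(x)
}

#' @export
`[.snp_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  snp_table(x$genotypes[i, j, drop = FALSE], x$snp[j, , drop = FALSE],
            setNames(x$individuals$pop_id, x$individuals$individual_id)[i],
            ploidy = x$ploidy)
}

#' Population table
#'
#' @param pop_id Character vector of unique population ids.
#' @param latitude,longitude Degrees.
#' @param elevation Meters.
#' @param n_individuals Integer sample size per population (>= 1).
#' @return A `data.frame` of class `population_frame`.
#' @export
population_frame <- function(pop_id, latitude = NA_real_, longitude = NA_real_,
                             elevation = NA_real_, n_individuals = 1L) {
  if (anyDuplicated(pop_id)) stop("pop_id values must be unique")
  if (any(n_individuals < 1L)) stop("n_individuals must be >= 1")
  out <- data.frame(pop_id = as.character(pop_id), latitude = latitude,
                    longitude = longitude, elevation = elevation,
                    n_individuals = as.integer(n_individuals),
                    stringsAsFactors = FALSE)
  class(out) <- c("population_frame", "data.frame")
  out
}

#' Population x environment matrix
#'
#' @param values Numeric matrix, populations x variables, with row names =
#'   population ids and column names = variable names.  No missing cells.
#' @param category Optional named character vector tagging each variable with
#'   a category (e.g. Aridity, Freezing, Geography).
#' @return An object of class `env_matrix`.
#' @export
env_matrix <- function(values, category = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("environment matrix must have no missing cells")
  if (is.null(rownames(values))) stop("row names (population ids) required")
  if (is.null(colnames(values))) stop("column names (variable names) required")
  if (is.null(category)) {
    category <- setNames(rep("other", ncol(values)), colnames(values))
  } else {
    category <- setNames(as.character(category[colnames(values)]), colnames(values))
    category[is.na(category)] <- "other"
  }
  structure(list(values = values, category = category), class = "env_matrix")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("env_matrix: %d populations x %d variables\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$category))
  invisible(x)
}

#' Filter SNPs on minor allele frequency and genotyping rate
#'
#' Retains SNPs with pooled minor allele frequency strictly greater than
#' `maf_min` and genotyping success rate strictly greater than
#' `callrate_min`, computed across all genotyped individuals pooled.
#'
#' @param snps A [snp_table].
#' @param maf_min Minimum (exclusive) minor allele frequency in `[0, 1]`.
#' @param callrate_min Minimum (exclusive) fraction of individuals with a
#'   non-missing genotype, in `[0, 1]`.
#' @return A filtered [snp_table]; SNP order is preserved.
#' @export
filter_snps <- function(snps, maf_min = 0.05, callrate_min = 0.10) {
  stopifnot(inherits(snps, "snp_table"))
  if (ncol(snps$genotypes) == 0L) stop("empty SNP table")
  if (maf_min < 0 || maf_min > 1 || callrate_min < 0 || callrate_min > 1)
    stop("thresholds must be in [0, 1]")
  g <- snps$genotypes
  n_called <- colSums(!is.na(g))
  callrate <- n_called / nrow(g)
  p <- colSums(g, na.rm = TRUE) / (snps$ploidy * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  keep <- n_called > 0L & maf > maf_min & callrate > callrate_min
  snps[, which(keep)]
}

#' Per-population derived-allele frequencies
#'
#' Frequency is (derived allele count) / (ploidy x genotyped individuals)
#' within each population; missing genotypes are excluded from numerator and
#' denominator.  Cells with zero genotyped individuals are `NA`.
#'
#' @param snps A [snp_table].
#' @param pops Optional [population_frame]; populations absent from the
#'   genotype data raise an error, and output rows follow its order.
#' @return An object of class `freq_matrix`: list with `freq`
#'   (populations x SNPs, in `[0, 1]` or `NA`) and `n_genotyped`
#'   (integer counts of genotyped individuals per cell).
#' @export
population_frequencies <- function(snps, pops = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  pop <- snps$individuals$pop_id
  pop_ids <- sort(unique(pop))  # canonical order: invariant to input order
  if (!is.null(pops)) {
    unknown <- setdiff(pop, pops$pop_id)
    if (length(unknown))
      stop("individuals mapped to unknown population id: ",
           paste(unknown, collapse = ", "))
    pop_ids <- pops$pop_id
  }
  g <- snps$genotypes
  fac <- factor(pop, levels = pop_ids)
  n_gen <- rowsum(1L * !is.na(g), fac)
  cnt <- rowsum(ifelse(is.na(g), 0L, g), fac)
  freq <- cnt / (snps$ploidy * n_gen)
  freq[n_gen == 0L] <- NA_real_
  freq_matrix(freq, n_genotyped = n_gen)
}

#' Construct a frequency matrix
#'
#' @param freq Numeric matrix, populations x SNPs, values in `[0, 1]` or `NA`.
#' @param n_genotyped Optional matching integer matrix of genotyped-individual
#'   counts per cell.
#' @return An object of class `freq_matrix`.
#' @export
freq_matrix <- function(freq, n_genotyped = NULL) {
  freq <- as.matrix(freq)
  if (any(freq < -1e-12 | freq > 1 + 1e-12, na.rm = TRUE))
    stop("frequencies must be in [0, 1]")
  if (is.null(rownames(freq))) rownames(freq) <- paste0("pop", seq_len(nrow(freq)))
  if (is.null(colnames(freq))) colnames(freq) <- paste0("snp", seq_len(ncol(freq)))
  if (is.null(n_genotyped)) {
    n_genotyped <- matrix(NA_integer_, nrow(freq), ncol(freq),
                          dimnames = dimnames(freq))
  } else {
    n_genotyped <- as.matrix(n_genotyped)
    dimnames(n_genotyped) <- dimnames(freq)
  }
  structure(list(freq = freq, n_genotyped = n_genotyped), class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %d populations x %d SNPs (%d missing cells)\n",
              nrow(x$freq), ncol(x$freq), sum(is.na(x$freq))))
  invisible(x)
}

## ---- readers -------------------------------------------------------------

#' Read genotypes from a VCF file
#'
#' Parses GT fields into derived-allele counts.  If an `AA` INFO tag is
#' present and matches REF or ALT, genotypes are polarized so that 1 counts
#' the derived (non-ancestral) allele and `derived_known` is set; otherwise
#' the ALT allele is counted and `derived_known` is `FALSE`.
#' Requires the `vcfR` package.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param pop_of_individual Named character vector mapping sample id to
#'   population id.
#' @return A [snp_table].
#' @export
read_vcf_genotypes <- function(path, pop_of_individual) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == "."))
        return(NA_integer_)
      sum(al != "0")
    }, integer(1))
  }
  codes <- t(apply(gt, 1, count_alt))  # snps x individuals
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, sep = ":"), fix$ID)
  aa <- vcfR::extract.info(v, element = "AA")
  derived_known <- !is.na(aa) & (toupper(aa) == toupper(fix$REF) |
                                 toupper(aa) == toupper(fix$ALT))
  flip <- derived_known & toupper(aa) == toupper(fix$ALT)
  codes[flip, ] <- 2L - codes[flip, ]
  geno <- t(codes)
  colnames(geno) <- ids
  snp_info <- data.frame(snp_id = ids, contig_id = fix$CHROM,
                         position = as.integer(fix$POS),
                         derived_known = derived_known,
                         stringsAsFactors = FALSE)
  snp_table(geno, snp_info, pop_of_individual)
}

#' Read a genotype matrix, population table or environment matrix from TSV
#'
#' `read_genotype_matrix` expects individuals in rows and SNPs in columns
#' (0/1/2 codes, NA for missing); `read_population_table` expects columns
#' `pop_id`, `latitude`, `longitude`, `elevation`, `n_individuals`;
#' `read_env_table` expects population ids in the first column and one
#' numeric column per variable, with an optional sidecar YAML file mapping
#' variable names to categories.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param pop_of_individual For genotypes: named vector individual -> pop.
#' @param category_yaml For environments: optional YAML path of
#'   `variable: category` pairs.
#' @return A [snp_table], [population_frame] or [env_matrix] respectively.
#' @export
read_genotype_matrix <- function(path, pop_of_individual) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  snp_table(m, pop_of_individual = pop_of_individual)
}

#' @rdname read_genotype_matrix
#' @export
read_population_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  population_frame(d$pop_id, d$latitude, d$longitude, d$elevation,
                   d$n_individuals)
}

#' @rdname read_genotype_matrix
#' @export
read_env_table <- function(path, category_yaml = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  category <- NULL
  if (!is.null(category_yaml)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading category sidecars requires the 'yaml' package")
    category <- unlist(yaml::read_yaml(category_yaml))
  }
  env_matrix(as.matrix(d), category = category)
}

#' Write a frequency matrix as TSV
#'
#' @param freqs A [freq_matrix].
#' @param path Output path; populations in rows, SNPs in columns.
#' @export
write_freq_matrix <- function(freqs, path) {
  write.table(data.frame(pop_id = rownames(freqs$freq), freqs$freq,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a frequency matrix written by [write_freq_matrix()]
#' @param path TSV path with `pop_id` first column.
#' @return A [freq_matrix].
#' @export
read_freq_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  freq_matrix(as.matrix(d))
}
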