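## Linkage disequilibrium as the squared Pearson correlation of genotype
## codes across individuals, with gene-pair and module-pair means.

#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of genotype codes across individuals with
#' complete data at both SNPs; `NA` (with attribute `reason`) when fewer
#' than 2 such individuals exist or the overlap is monomorphic at either
#' SNP.  Invariant to allele recoding at either SNP.
#'
#' @param snps A [snp_table].
#' @param snp_a,snp_b SNP ids or column indices.
#' @return r^2 in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(snps, snp_a, snp_b) {
  g <- snps$genotypes
  a <- g[, snp_a]; b <- g[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(structure(NA_real_, reason = "fewer than 2 shared individuals"))
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(NA_real_, reason = "monomorphic overlap"))
  cor(a, b)^2
}

#' Full r-squared matrix among SNPs
#'
#' @param snps A [snp_table] (typically restricted to candidate SNPs).
#' @return Symmetric SNPs x SNPs matrix with unit diagonal; cells with
#'   monomorphic or insufficient overlap are `NA`.
#' @export
r2_matrix <- function(snps) {
  g <- snps$genotypes
  r <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
  diag(r) <- 1
  r
}

#' Gene-pair mean linkage disequilibrium
#'
#' Mean r^2 over all SNP pairs annotated to each pair of contigs, after
#' excluding SNPs genotyped in fewer than `min_genotyped` individuals (the
#' count threshold guards gene-level means against small-sample noise).
#' The diagonal is the within-gene mean excluding self-pairs.
#'
#' @param snps A [snp_table].
#' @param min_genotyped Minimum individuals genotyped per SNP (default 250,
#'   matching large range-wide panels; lower it for small synthetic panels).
#' @return A list of class `ld_summary`: `gene_r2` (gene-pair mean matrix),
#'   `snp_r2` (SNP-level matrix), `n_genotyped` (per-SNP counts) and
#'   `contig_of_snp`.
#' @export
gene_pair_mean_ld <- function(snps, min_genotyped = 250) {
  if (min_genotyped < 2) stop("min_genotyped must be >= 2")
  n_geno <- colSums(!is.na(snps$genotypes))
  keep <- which(n_geno >= min_genotyped)
  if (!length(keep)) stop("no SNP genotyped in at least ", min_genotyped,
                          " individuals")
  sub <- snps[, keep]
  r2 <- r2_matrix(sub)
  contig <- sub$snp$contig_id
  genes <- unique(contig)
  out <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (i in seq_along(genes)) for (j in i:length(genes)) {
    ix <- which(contig == genes[i]); jx <- which(contig == genes[j])
    vals <- r2[ix, jx, drop = FALSE]
    if (i == j) {
      if (length(ix) < 2) { out[i, j] <- NA_real_; next }
      vals <- vals[upper.tri(vals)]  # exclude self-pairs
    }
    out[i, j] <- out[j, i] <- if (all(is.na(vals))) NA_real_ else
      mean(vals, na.rm = TRUE)
  }
  structure(list(gene_r2 = out, snp_r2 = r2,
                 n_genotyped = n_geno[keep],
                 contig_of_snp = setNames(contig, sub$snp$snp_id),
                 min_genotyped = min_genotyped),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("ld_summary: %d SNPs in %d genes (min %d genotyped)\n",
              ncol(x$snp_r2), nrow(x$gene_r2), x$min_genotyped))
  invisible(x)
}

#' Module-pair mean linkage disequilibrium
#'
#' Mean r^2 within and between co-association modules (self-pairs excluded
#' from within-module means).  Elevated within-module LD relative to
#' between-module LD indicates that co-association clustering tracks
#' statistical associations among the underlying genotypes.
#'
#' @param ld An `ld_summary` (SNP-level matrix used), or a plain symmetric
#'   r^2 matrix.
#' @param modules Integer/character partition named by SNP id covering the
#'   SNPs in `ld`.
#' @return Symmetric modules x modules matrix of mean r^2.
#' @export
module_ld_summary <- function(ld, modules) {
  r2 <- if (inherits(ld, "ld_summary")) ld$snp_r2 else as.matrix(ld)
  ids <- rownames(r2)
  if (is.null(names(modules))) names(modules) <- ids
  if (!all(ids %in% names(modules)))
    stop("modules must cover all SNPs in the LD matrix")
  mod <- modules[ids]
  levs <- sort(unique(mod))
  out <- matrix(NA_real_, length(levs), length(levs),
                dimnames = list(levs, levs))
  for (i in seq_along(levs)) for (j in i:length(levs)) {
    ix <- which(mod == levs[i]); jx <- which(mod == levs[j])
    vals <- r2[ix, jx, drop = FALSE]
    if (i == j) {
      if (length(ix) < 2) next
      vals <- vals[upper.tri(vals)]
    }
    out[i, j] <- out[j, i] <- mean(vals, na.rm = TRUE)
  }
  out
}
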