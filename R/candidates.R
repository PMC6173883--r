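## Top-candidate detection: per-environment outlier flags, gene-level
## binomial enrichment ("index" P), and the dual Bonferroni + Bayes-factor
## SNP criterion inside top candidate genes.

#' Flag per-environment outlier SNPs
#'
#' A SNP is flagged for an environment when its `|rho|` strictly exceeds the
#' genome-wide empirical quantile of `|rho|` for that environment.
#'
#' @param assoc An `assoc_matrix`.
#' @param quantile Empirical quantile in (0, 1); default 0.99.
#' @return Logical SNPs x environments matrix (`NA` rho gives `FALSE`).
#' @export
flag_outlier_snps <- function(assoc, quantile = 0.99) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  a <- abs(assoc$rho)
  cut <- apply(a, 2, stats::quantile, probs = quantile, na.rm = TRUE,
               names = FALSE)
  flags <- sweep(a, 2, cut, ">")
  flags[is.na(flags)] <- FALSE
  flags
}

#' Top candidate genes by binomial outlier enrichment
#'
#' For each contig with n SNPs of which k are outliers (a SNP counts once if
#' flagged in any environment), computes the binomial tail probability
#' P(X >= k | n, p-bar) with p-bar the genome-wide outlier fraction.  Because
#' SNPs within a contig are not independent, this P value is an enrichment
#' index rather than an exact probability; the restrictive default cutoff
#' compensates.
#'
#' @param flags Logical SNPs x environments matrix from [flag_outlier_snps()].
#' @param contig_of_snp Character vector (named by SNP id, or in row order)
#'   mapping each SNP to its contig/gene.
#' @param p_cutoff Candidate cutoff on the tail index (default `1e-9`).
#' @return A list of class `candidate_set` with a `genes` data frame
#'   (`contig_id`, `n_snps`, `n_outlier_snps`, `binomial_tail_p`,
#'   `candidate`) and the outlier `flags`.
#' @export
top_candidate_genes <- function(flags, contig_of_snp, p_cutoff = 1e-9) {
  if (is.null(names(contig_of_snp)))
    names(contig_of_snp) <- rownames(flags)
  contig <- as.character(contig_of_snp[rownames(flags)])
  if (anyNA(contig)) stop("every SNP must be mapped to a contig")
  snp_out <- rowSums(flags) > 0
  n <- tapply(snp_out, contig, length)
  k <- tapply(snp_out, contig, sum)
  pbar <- mean(snp_out)
  tail_p <- pbinom(k - 1, n, pbar, lower.tail = FALSE)
  tail_p[k == 0] <- 1
  genes <- data.frame(contig_id = names(n), n_snps = as.integer(n),
                      n_outlier_snps = as.integer(k),
                      binomial_tail_p = as.numeric(tail_p),
                      stringsAsFactors = FALSE)
  genes$candidate <- genes$binomial_tail_p < p_cutoff
  genes <- genes[order(genes$binomial_tail_p), ]
  rownames(genes) <- NULL
  structure(list(genes = genes, flags = flags, p_cutoff = p_cutoff,
                 outlier_fraction = pbar,
                 contig_of_snp = setNames(contig, rownames(flags))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d/%d candidate genes",
              sum(x$genes$candidate), nrow(x$genes)))
  if (!is.null(x$snps))
    cat(sprintf("; %d top candidate SNPs", nrow(x$snps)))
  cat("\n")
  invisible(x)
}

#' Top candidate SNPs by the dual Bonferroni + Bayes-factor criterion
#'
#' Within top candidate genes, retains SNPs that for at least one
#' environment have (i) an uncorrected Spearman P value below the Bonferroni
#' cutoff and (ii) a structure-corrected log10 Bayes factor above `bf_min`.
#'
#' @param assoc_raw Uncorrected `assoc_matrix` (P-value layer used).
#' @param assoc_corrected Structure-corrected `assoc_matrix` with a
#'   `log10_bf` layer.
#' @param genes A `candidate_set` from [top_candidate_genes()].
#' @param alpha Family-wise error rate for the Bonferroni cutoff.
#' @param bf_min Minimum log10 Bayes factor (default 2).
#' @return The `candidate_set` augmented with a `snps` data frame
#'   (`snp_id`, `contig_id`, `passing_envs`) and `snp_flags` matrix.
#' @export
top_candidate_snps <- function(assoc_raw, assoc_corrected, genes,
                               alpha = 0.05, bf_min = 2) {
  if (!identical(rownames(assoc_raw$rho), rownames(assoc_corrected$rho)))
    stop("association layers must be aligned on SNP ids")
  if (is.null(assoc_corrected$log10_bf))
    stop("no Bayes-factor layer: compute corrected_associations() or load ",
         "external Bayes factors with read_bayenv_bf()")
  cutoff <- bonferroni_threshold(nrow(assoc_raw$rho), ncol(assoc_raw$rho),
                                 alpha)
  pass <- !is.na(assoc_raw$pvalue) & assoc_raw$pvalue < cutoff &
    !is.na(assoc_corrected$log10_bf) & assoc_corrected$log10_bf > bf_min
  cand_genes <- genes$genes$contig_id[genes$genes$candidate]
  in_gene <- genes$contig_of_snp[rownames(pass)] %in% cand_genes
  pass[!in_gene, ] <- FALSE
  keep <- rowSums(pass) > 0
  snps <- data.frame(
    snp_id = rownames(pass)[keep],
    contig_id = unname(genes$contig_of_snp[rownames(pass)[keep]]),
    passing_envs = apply(pass[keep, , drop = FALSE], 1, function(z)
      paste(colnames(pass)[z], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  genes$snps <- snps
  genes$snp_flags <- pass
  genes$bonferroni_cutoff <- cutoff
  genes$bf_min <- bf_min
  genes
}

#' Write candidate tables as TSV
#'
#' @param candidates A `candidate_set`.
#' @param dir Output directory; writes `genes.tsv` and (if present)
#'   `snps.tsv`.
#' @export
write_candidates_tsv <- function(candidates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(candidates$genes, file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(candidates$snps))
    write.table(candidates$snps, file.path(dir, "snps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
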