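## SNP x environment association statistics: uncorrected Spearman rank
## correlations with two-sided P values, population-covariance estimation
## from putatively neutral SNPs, covariance whitening, and a conjugate
## linear-model log10 Bayes factor on whitened frequencies.

#' Construct an association matrix
#'
#' @param rho SNPs x environments matrix of signed correlations in `[-1, 1]`.
#' @param pvalue Matching matrix of two-sided P values.
#' @param log10_bf Optional matching matrix of log10 Bayes factors.
#' @param corrected Logical; whether the statistics are structure-corrected.
#' @param n_used Optional matrix of populations used per cell.
#' @return An object of class `assoc_matrix`.
#' @export
assoc_matrix <- function(rho, pvalue = NULL, log10_bf = NULL,
                         corrected = FALSE, n_used = NULL) {
  rho <- as.matrix(rho)
  if (any(abs(rho) > 1 + 1e-8, na.rm = TRUE)) stop("|rho| must be <= 1")
  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(rho)))
      stop(what, " must match the dimensions of rho")
    dimnames(m) <- dimnames(rho)
    m
  }
  structure(list(rho = rho, pvalue = chk(pvalue, "pvalue"),
                 log10_bf = chk(log10_bf, "log10_bf"),
                 corrected = isTRUE(corrected),
                 n_used = chk(n_used, "n_used")),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d SNPs x %d environments (%s%s)\n",
              nrow(x$rho), ncol(x$rho),
              if (x$corrected) "structure-corrected" else "uncorrected",
              if (!is.null(x$log10_bf)) ", with BF layer" else ""))
  invisible(x)
}

## Average ranks (ties.method = "average"), NA kept as NA.
.rank_cols <- function(m) apply(m, 2, function(x) {
  r <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r[ok] <- rank(x[ok])
  r
})

#' Spearman correlations between allele frequencies and environments
#'
#' Computes Spearman's rho (average ranks for ties) between each SNP's
#' per-population derived-allele frequency and each environmental variable,
#' with two-sided P values.  P values use the t approximation for n >= 10
#' populations and an exact/complete permutation distribution for n < 10.
#' Cells with fewer than 3 jointly non-missing populations, or with a
#' constant frequency or environment, are returned as `NA`.
#'
#' @param freqs A [freq_matrix] (populations x SNPs).
#' @param envs An [env_matrix] with matching population rows.
#' @return An `assoc_matrix` with `rho`, `pvalue` and `n_used` layers.
#' @export
spearman_matrix <- function(freqs, envs) {
  f <- if (inherits(freqs, "freq_matrix")) freqs$freq else as.matrix(freqs)
  e <- if (inherits(envs, "env_matrix")) envs$values else as.matrix(envs)
  if (nrow(f) != nrow(e)) stop("populations must match between freqs and envs")
  if (!is.null(rownames(f)) && !is.null(rownames(e)) &&
      !identical(rownames(f), rownames(e)))
    e <- e[rownames(f), , drop = FALSE]

  n_snps <- ncol(f); n_envs <- ncol(e)
  rho <- p <- nu <- matrix(NA_real_, n_snps, n_envs,
                           dimnames = list(colnames(f), colnames(e)))
  complete_f <- !anyNA(f)
  if (complete_f) {
    rf <- .rank_cols(f)
    re <- .rank_cols(e)
    n <- nrow(f)
    sd_f <- apply(rf, 2, sd); sd_e <- apply(re, 2, sd)
    ok_f <- sd_f > 0; ok_e <- sd_e > 0
    if (any(ok_f) && any(ok_e)) {
      r <- suppressWarnings(cor(rf[, ok_f, drop = FALSE], re[, ok_e, drop = FALSE]))
      rho[ok_f, ok_e] <- r
    }
    nu[] <- n
    p[] <- .spearman_p(rho, nu)
    ## exact permutation for small panels
    if (n < 10) {
      for (j in seq_len(n_envs)) for (i in seq_len(n_snps))
        if (!is.na(rho[i, j]))
          p[i, j] <- .perm_p(rf[, i], re[, j])
    }
  } else {
    for (i in seq_len(n_snps)) {
      fi <- f[, i]
      for (j in seq_len(n_envs)) {
        ok <- !is.na(fi) & !is.na(e[, j])
        n <- sum(ok)
        nu[i, j] <- n
        if (n < 3) next
        rf <- rank(fi[ok]); re <- rank(e[ok, j])
        if (sd(rf) == 0 || sd(re) == 0) next
        r <- cor(rf, re)
        rho[i, j] <- r
        p[i, j] <- if (n < 10) .perm_p(rf, re) else .spearman_p(r, n)
      }
    }
  }
  assoc_matrix(rho, pvalue = p, n_used = nu)
}

## two-sided P from the t approximation; rho may be a matrix
.spearman_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tt <- abs(rho) * sqrt((n - 2) / (1 - r2))
  2 * pt(tt, df = n - 2, lower.tail = FALSE)
}

## exact permutation P over all n! rank permutations (n < 10)
.perm_p <- function(rf, re) {
  n <- length(rf)
  perms <- .all_perms(n)
  obs <- abs(cor(rf, re))
  stat <- abs(apply(perms, 1, function(ix) cor(rf, re[ix])))
  mean(stat >= obs - 1e-12)
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[k + seq_len(nrow(sub)), ] <- block
    k <- k + nrow(sub)
  }
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_snps,n_envs Numbers of SNPs and environmental variables tested.
#' @param alpha Family-wise error rate in (0, 1).
#' @return `alpha / (n_snps * n_envs)`.
#' @export
bonferroni_threshold <- function(n_snps, n_envs, alpha = 0.05) {
  if (n_snps < 1 || n_envs < 1) stop("n_snps and n_envs must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / (n_snps * n_envs)
}

#' Estimate the population covariance matrix from neutral SNPs
#'
#' Each SNP's frequency vector is centered by its across-population mean
#' p-bar and scaled by sqrt(p-bar (1 - p-bar)); the population x population
#' covariance of these standardized deviations is averaged across SNPs and
#' a ridge term is added to guarantee positive-definiteness.
#'
#' @param neutral_freqs A [freq_matrix] of putatively neutral SNPs.
#' @param regularization Ridge added as `regularization * mean(diag)`
#'   times the identity; the default `1e-6` keeps the estimate numerically
#'   positive-definite without distorting it.
#' @return A symmetric positive-definite matrix of class `pop_covariance`.
#' @export
estimate_pop_covariance <- function(neutral_freqs, regularization = 1e-6) {
  f <- if (inherits(neutral_freqs, "freq_matrix")) neutral_freqs$freq else
    as.matrix(neutral_freqs)
  if (nrow(f) < 2) stop("need at least 2 populations")
  keep <- colSums(is.na(f)) == 0
  f <- f[, keep, drop = FALSE]
  pbar <- colMeans(f)
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) stop("all neutral SNPs are monomorphic")
  f <- f[, poly, drop = FALSE]
  pbar <- pbar[poly]
  z <- sweep(f, 2, pbar) / rep(sqrt(pbar * (1 - pbar)), each = nrow(f))
  omega <- tcrossprod(z) / ncol(z)
  ridge <- regularization * mean(diag(omega))
  omega <- omega + diag(ridge, nrow(omega))
  dimnames(omega) <- list(rownames(f), rownames(f))
  class(omega) <- c("pop_covariance", "matrix")
  omega
}

#' Whiten allele frequencies by the population covariance
#'
#' Returns `solve(L, f - mean(f))` per SNP, where `cov = L L'` is the lower
#' Cholesky factor, so that whitened neutral frequencies have near-identity
#' population covariance.
#'
#' @param freqs A [freq_matrix] or plain populations x SNPs matrix (no
#'   missing cells).
#' @param cov A positive-definite `pop_covariance` matrix.
#' @return A populations x SNPs matrix of whitened centered frequencies.
#' @export
whiten_frequencies <- function(freqs, cov) {
  f <- if (inherits(freqs, "freq_matrix")) freqs$freq else as.matrix(freqs)
  if (nrow(f) != nrow(cov)) stop("dimension mismatch between freqs and cov")
  if (anyNA(f)) stop("whitening requires complete frequencies; impute or drop")
  L <- tryCatch(t(chol(cov)), error = function(e)
    stop("covariance is not positive-definite; increase 'regularization' in ",
         "estimate_pop_covariance()"))
  centered <- sweep(f, 2, colMeans(f))
  out <- forwardsolve(L, centered)
  dimnames(out) <- dimnames(f)
  out
}

#' Approximate log10 Bayes factor for a frequency-environment relation
#'
#' Single-SNP conjugate normal linear model on covariance-whitened
#' frequencies: the slope model puts a zero-mean normal prior on the
#' regression coefficient of the whitened frequency on the standardized
#' environment (g-prior with `g = n * prior_scale^2`) with a Jeffreys prior
#' on the residual variance; the null model has slope zero.  The Bayes
#' factor is available in closed form and is deterministic.
#'
#' @param whitened_freq Numeric vector (one whitened SNP across populations).
#' @param env Numeric vector of the environmental variable (standardized
#'   internally, so the result is invariant to affine rescaling).
#' @param prior_scale Prior scale of the standardized slope (default 1).
#' @return log10 of the Bayes factor (slope model over null model).
#' @export
approx_log10_bf <- function(whitened_freq, env, prior_scale = 1) {
  y <- as.numeric(whitened_freq)
  if (length(env) != length(y)) stop("env and whitened_freq lengths differ")
  n <- length(y)
  if (n < 3) stop("need at least 3 populations")
  if (sd(env) == 0) stop("constant environment")
  x <- (env - mean(env)) / sd(env)
  g <- n * prior_scale^2
  yy <- sum(y^2)
  if (yy == 0) return(0)
  r2 <- sum(x * y)^2 / (sum(x^2) * yy)
  log10_bf <- -0.5 * log10(1 + g) -
    (n / 2) * log10(1 - (g / (1 + g)) * r2)
  log10_bf
}

#' Structure-corrected association statistics
#'
#' Convenience wrapper: whitens frequencies by the population covariance,
#' computes Spearman correlations of the whitened frequencies with the
#' environments, and adds the conjugate log10 Bayes factor layer.
#'
#' @param freqs A [freq_matrix] (complete cells).
#' @param envs An [env_matrix].
#' @param cov A `pop_covariance`; if `NULL` it is estimated from `freqs`
#'   themselves (appropriate when most SNPs are neutral).
#' @param prior_scale Passed to [approx_log10_bf()].
#' @return A structure-corrected `assoc_matrix` with a `log10_bf` layer.
#' @export
corrected_associations <- function(freqs, envs, cov = NULL, prior_scale = 1) {
  f <- if (inherits(freqs, "freq_matrix")) freqs$freq else as.matrix(freqs)
  e <- if (inherits(envs, "env_matrix")) envs$values else as.matrix(envs)
  if (is.null(cov)) cov <- estimate_pop_covariance(freq_matrix(f))
  w <- whiten_frequencies(f, cov)
  base <- spearman_matrix(w, e)  # rank-based, so whitened scale is fine
  bf <- matrix(NA_real_, ncol(f), ncol(e), dimnames = dimnames(base$rho))
  for (j in seq_len(ncol(e)))
    for (i in seq_len(ncol(f)))
      bf[i, j] <- approx_log10_bf(w[, i], e[, j], prior_scale = prior_scale)
  assoc_matrix(base$rho, pvalue = base$pvalue, log10_bf = bf,
               corrected = TRUE, n_used = base$n_used)
}

## ---- TSV interchange -----------------------------------------------------

#' Write or read association layers as TSV (SNPs in rows)
#'
#' `write_assoc_tsv` writes each available layer (`rho`, `pvalue`,
#' `log10_bf`) to `<dir>/<layer>.tsv`.  `read_bayenv_bf` reads an external
#' Bayes-factor table whose replicate-chain columns (groups of consecutive
#' columns per environment) are averaged.
#'
#' @param assoc An `assoc_matrix`.
#' @param dir Output directory (created if needed).
#' @export
write_assoc_tsv <- function(assoc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in c("rho", "pvalue", "log10_bf")) {
    m <- assoc[[layer]]
    if (is.null(m)) next
    write.table(data.frame(snp_id = rownames(m), m, check.names = FALSE),
                file.path(dir, paste0(layer, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_assoc_tsv
#' @param path TSV with `snp_id` first column and
#'   `n_envs * n_chains` numeric columns ordered environment-major.
#' @param env_names Environment names, in column-group order.
#' @param n_chains Number of replicate chains per environment to average.
#' @return A SNPs x environments matrix of chain-averaged log10 BF.
#' @export
read_bayenv_bf <- function(path, env_names, n_chains = 3) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  m <- as.matrix(d)
  if (ncol(m) != length(env_names) * n_chains)
    stop("expected ", length(env_names) * n_chains, " columns, got ", ncol(m))
  out <- sapply(seq_along(env_names), function(j) {
    rowMeans(m[, (j - 1) * n_chains + seq_len(n_chains), drop = FALSE])
  })
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), env_names))
}
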