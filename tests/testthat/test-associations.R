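test_that("spearman_matrix recovers hand-computed rank correlations", {
  # monotone relation -> rho = 1
  f <- matrix(seq(0.05, 0.5, length.out = 10), 10, 1)
  e <- matrix(exp(seq(1, 5, length.out = 10)), 10, 1)
  expect_equal(unname(spearman_matrix(f, e)$rho[1, 1]), 1)

  # 1 - 6 sum(d^2) / (n (n^2 - 1)) with d^2 = 4 -> 0.8
  sm <- spearman_matrix(matrix(c(.1, .2, .3, .4, .5), 5, 1),
                        matrix(c(2, 1, 4, 3, 5), 5, 1))
  expect_equal(unname(sm$rho[1, 1]), 1 - 6 * 4 / (5 * 24))
  # exact permutation P at n = 5: 16 of 120 permutations reach |rho| >= 0.8
  expect_equal(unname(sm$pvalue[1, 1]), 16 / 120)

  # allele recoding flips rho, leaves P unchanged
  fe <- random_freq_env(12, 6, 4, seed = 2)
  a <- spearman_matrix(fe$f, fe$e)
  b <- spearman_matrix(freq_matrix(1 - fe$f$freq), fe$e)
  expect_equal(b$rho, -a$rho)
  expect_equal(b$pvalue, a$pvalue)
})

test_that("spearman_matrix flags degenerate and sparse cells as missing", {
  f <- cbind(const = rep(0.5, 8), ok = seq(0.1, 0.8, by = 0.1))
  e <- cbind(e1 = rnorm(8))
  rownames(f) <- rownames(e) <- paste0("p", 1:8)
  sm <- spearman_matrix(freq_matrix(f), env_matrix(e))
  expect_true(is.na(sm$rho["const", 1]))
  expect_false(is.na(sm$rho["ok", 1]))

  f2 <- f; f2[3:8, 2] <- NA  # only 2 usable populations
  sm2 <- spearman_matrix(freq_matrix(f2), env_matrix(e))
  expect_true(is.na(sm2$rho["ok", 1]))
  expect_equal(sm2$n_used["ok", 1], 2)
})

test_that("t-approximation P values match cor.test for larger panels", {
  fe <- random_freq_env(25, 5, 3, seed = 9)
  sm <- spearman_matrix(fe$f, fe$e)
  for (i in 1:5) for (j in 1:3) {
    ct <- suppressWarnings(cor.test(fe$f$freq[, i], fe$e$values[, j],
                                    method = "spearman"))
    expect_equal(unname(sm$rho[i, j]), unname(ct$estimate), tolerance = 1e-12)
  }
  # t-approximation agrees with the exact distribution to a few percent
  ct <- cor.test(fe$f$freq[, 1], fe$e$values[, 1], method = "spearman")
  expect_lt(abs(sm$pvalue[1, 1] - ct$p.value), 0.05)
})

test_that("P values are uniform under population permutation", {
  set.seed(4)
  n <- 15
  f <- runif(n, 0.1, 0.9)
  e <- rnorm(n)
  ps <- replicate(1000, {
    spearman_matrix(matrix(f, n, 1), matrix(sample(e), n, 1))$pvalue[1, 1]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bonferroni_threshold divides alpha by the number of tests", {
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 10, 0.05), 5e-5)
  # range-wide exome scan dimensions land just below 1e-8
  th <- bonferroni_threshold(585270, 22, 0.05)
  expect_equal(th, 0.05 / (585270 * 22))
  expect_lt(th, 1e-8)
  expect_error(bonferroni_threshold(0, 22, 0.05), ">= 1")
  expect_error(bonferroni_threshold(10, 10, 1.5), "alpha")
})

test_that("estimate_pop_covariance is near-identity for independent demes", {
  set.seed(11)
  n_pops <- 8; n_snps <- 4000
  pbar <- runif(n_snps, 0.2, 0.8)
  # iid binomial sampling noise around a shared mean, scaled by p(1-p):
  # standardized covariance should approach (1/2N) I; rescale to compare
  N <- 20
  f <- sapply(pbar, function(p) rbinom(n_pops, 2 * N, p) / (2 * N))
  om <- estimate_pop_covariance(freq_matrix(f))
  scaled <- om / mean(diag(om))
  # centering against the empirical mean induces the projection I - J/n,
  # so the expected scaled covariance is (I - J/n) / (1 - 1/n)
  expected <- (diag(n_pops) - 1 / n_pops) / (1 - 1 / n_pops)
  expect_lt(max(abs(scaled - expected)), 0.1)
})

test_that("estimate_pop_covariance symmetry, rank and error cases", {
  f <- matrix(runif(12, .2, .8), 4, 3)
  f2 <- f[c(1, 1, 2, 3, 4), ]  # duplicated population row
  om <- estimate_pop_covariance(freq_matrix(f2), regularization = 0)
  expect_equal(om[1, ], om[2, ])
  expect_equal(om, t(om))

  # single SNP: rank-1 plus ridge
  f1 <- matrix(c(.2, .5, .8), 3, 1)
  om1 <- estimate_pop_covariance(freq_matrix(f1), regularization = 0.01)
  z <- (f1 - mean(f1)) / sqrt(mean(f1) * (1 - mean(f1)))
  expect_equal(unclass(om1), tcrossprod(z) + diag(0.01 * mean(diag(tcrossprod(z))), 3),
               ignore_attr = TRUE)

  expect_error(estimate_pop_covariance(freq_matrix(matrix(0, 3, 2))),
               "monomorphic")
})

test_that("whiten_frequencies inverts the Cholesky factor exactly", {
  # identity covariance: output equals centered input
  f <- matrix(runif(15, .1, .9), 5, 3)
  I5 <- diag(5)
  expect_equal(whiten_frequencies(f, I5), sweep(f, 2, colMeans(f)),
               ignore_attr = TRUE)
  # cov = 4 I halves the deviations
  expect_equal(whiten_frequencies(f, 4 * I5),
               sweep(f, 2, colMeans(f)) / 2, ignore_attr = TRUE)

  # random SPD 3x3: verify L y = x by hand forward substitution
  set.seed(3)
  A <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3) * 0.5
  x <- matrix(c(.3, .6, .9), 3, 1)
  y <- whiten_frequencies(x, A)
  L <- t(chol(A))
  manual <- numeric(3)
  ctr <- x - mean(x)
  manual[1] <- ctr[1] / L[1, 1]
  manual[2] <- (ctr[2] - L[2, 1] * manual[1]) / L[2, 2]
  manual[3] <- (ctr[3] - L[3, 1] * manual[1] - L[3, 2] * manual[2]) / L[3, 3]
  expect_equal(as.numeric(y), manual)

  expect_error(whiten_frequencies(f, matrix(1, 5, 5)), "positive-definite")
})

test_that("whitening removes shared-history correlation between demes", {
  # two demes drawn from a common recent ancestor are strongly correlated
  # before correction; whitening against the estimated covariance should
  # leave them essentially uncorrelated
  set.seed(21)
  n_snps <- 4000
  base <- runif(n_snps, 0.2, 0.8)
  shared <- base + rnorm(n_snps, sd = 0.05)
  f <- rbind(p1 = shared + rnorm(n_snps, sd = 0.01),
             p2 = shared + rnorm(n_snps, sd = 0.01),
             p3 = base + rnorm(n_snps, sd = 0.05),
             p4 = base + rnorm(n_snps, sd = 0.05),
             p5 = base + rnorm(n_snps, sd = 0.05))
  f <- pmin(pmax(f, 0.01), 0.99)
  colnames(f) <- paste0("s", seq_len(n_snps))
  ctr <- sweep(f, 2, colMeans(f))
  raw12 <- cor(ctr[1, ], ctr[2, ])
  expect_gt(abs(raw12), 0.7)
  om_hat <- estimate_pop_covariance(freq_matrix(f))
  expect_gt(om_hat[1, 2], 0)          # the shared history is visible
  w <- whiten_frequencies(f, om_hat)
  expect_lt(abs(cor(w[1, ], w[2, ])), 0.2)
})

test_that("approx_log10_bf matches a numerical-integration oracle", {
  # closed-form conjugate BF vs 2-D quadrature over (slope, variance)
  set.seed(8)
  y <- c(0.12, -0.30, 0.25, -0.05, -0.02)
  env <- c(1.2, -0.8, 2.0, 0.3, -1.1)
  n <- length(y)
  x <- (env - mean(env)) / sd(env)
  prior_scale <- 1
  g <- n * prior_scale^2
  tau2 <- g / sum(x^2)  # prior variance of the slope, per unit sigma^2
  marg <- function(with_slope) {
    integrand_sigma <- function(s2) {
      if (with_slope) {
        inner <- function(beta) {
          exp(colSums(dnorm(outer(y, beta, function(yy, bb) yy - bb * x),
                            sd = sqrt(s2), log = TRUE))) *
            dnorm(beta, 0, sqrt(tau2 * s2))
        }
        stats::integrate(inner, -20, 20, rel.tol = 1e-10)$value / s2
      } else {
        exp(sum(dnorm(y, 0, sqrt(s2), log = TRUE))) / s2
      }
    }
    stats::integrate(Vectorize(integrand_sigma), 1e-6, 50,
                     rel.tol = 1e-9)$value
  }
  oracle <- log10(marg(TRUE) / marg(FALSE))
  expect_equal(approx_log10_bf(y, env, prior_scale), oracle, tolerance = 1e-4)
})

test_that("approx_log10_bf separates signal from orthogonal noise", {
  set.seed(5)
  n <- 20
  env <- rnorm(n)
  x <- (env - mean(env)) / sd(env)
  y_orth <- residuals(lm(rnorm(n) ~ x))    # orthogonal to env
  expect_lt(approx_log10_bf(y_orth, env), 0)
  y_lin <- 0.5 * x + rnorm(n, sd = 0.1)    # strong linear relation
  expect_gt(approx_log10_bf(y_lin, env), 2)
  expect_error(approx_log10_bf(y_lin, env[-1]), "length")
  expect_error(approx_log10_bf(y_lin, rep(1, n)), "constant")
})

test_that("approx_log10_bf is invariant to affine rescaling of env", {
  set.seed(6)
  y <- rnorm(12)
  env <- runif(12, -5, 30)
  expect_equal(approx_log10_bf(y, env), approx_log10_bf(y, 3.7 * env - 120))
})

test_that("corrected_associations attaches a finite BF layer", {
  fe <- random_freq_env(12, 8, 3, seed = 13)
  ca <- corrected_associations(fe$f, fe$e)
  expect_true(ca$corrected)
  expect_true(all(is.finite(ca$log10_bf)))
  expect_identical(dim(ca$log10_bf), dim(ca$rho))
})

test_that("external Bayes-factor tables average replicate chains", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  d <- data.frame(snp_id = "s1", m)
  tf <- tempfile(fileext = ".tsv")
  write.table(d, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  bf <- read_bayenv_bf(tf, env_names = c("MAT", "MAP"), n_chains = 3)
  expect_equal(unname(bf[1, ]), c(2, 5))
  expect_error(read_bayenv_bf(tf, env_names = c("a", "b", "c"), n_chains = 3),
               "columns")
})
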