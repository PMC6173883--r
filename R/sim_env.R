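## Synthetic multivariate environments: correlated observed variables plus
## a hidden selective variable whose correlation with each observed one is
## confined to a weak band, and inverse-distance interpolation of
## environments onto simulated locations.

#' Pine-like environmental correlation matrix
#'
#' A 22-variable target correlation matrix emulating a temperate-conifer
#' climate dataset: an Aridity block (precipitation, moisture deficit and
#' warm-season temperature variables), a Freezing block (cold-season and
#' frost-timing variables), and three weakly correlated Geography variables
#' (latitude, longitude, elevation), with moderate negative correlation
#' between the Aridity and Freezing blocks.
#'
#' @return A 22 x 22 positive-definite correlation matrix with variable
#'   names and a `"category"` attribute.
#' @export
pine_env_correlation <- function() {
  vars <- c(MAP = "Aridity", MSP = "Aridity", CMD = "Aridity",
            SHM = "Aridity", AHM = "Aridity", MWMT = "Aridity",
            DD5 = "Aridity", Eref = "Aridity", EXT = "Aridity",
            MAT = "Aridity",
            DD_0 = "Freezing", MCMT = "Freezing", EMT = "Freezing",
            bFFP = "Freezing", eFFP = "Freezing", FFP = "Freezing",
            NFFD = "Freezing", PAS = "Freezing", TD = "Freezing",
            LAT = "Geography", LONG = "Geography", ELEVATION = "Geography")
  k <- length(vars)
  cat_of <- unname(vars)
  C <- matrix(0, k, k, dimnames = list(names(vars), names(vars)))
  for (i in 1:k) for (j in 1:k) {
    if (i == j) { C[i, j] <- 1; next }
    a <- cat_of[i]; b <- cat_of[j]
    C[i, j] <-
      if (a == b && a != "Geography") 0.65
      else if (a == "Geography" && b == "Geography") 0.2
      else if ("Geography" %in% c(a, b)) 0.15
      else -0.3  # aridity vs freezing
  }
  attr(C, "category") <- vars
  C
}

#' Generate synthetic environments with a hidden selective variable
#'
#' Produces `n_pops` observations of `n_vars` observed Gaussian variables
#' whose sample correlation matrix equals `target_corr` exactly
#' (empirical construction, as in `MASS::mvrnorm(empirical = TRUE)`),
#' plus a hidden selective variable whose absolute sample correlation with
#' each observed variable lies in `[0, selective_corr_max]`.  The hidden
#' variable stands for an unmeasured environmental factor that drives
#' selection; the observed variables are what a field study measures.
#'
#' When `hidden` is supplied (e.g. the selection-surface values at sampled
#' demes), the observed variables are built around it: each observed
#' variable is `b_j x hidden + sqrt(1 - b_j^2) x noise`, with the noise
#' constructed exactly orthogonal to the hidden variable and its
#' correlation structure adjusted so the observed correlations still equal
#' `target_corr`.
#'
#' @param n_pops Number of populations (must exceed `n_vars + 2`).
#' @param n_vars Number of observed variables (default: all columns of
#'   `target_corr`).
#' @param target_corr Positive-definite target correlation matrix
#'   (default [pine_env_correlation()]).
#' @param selective_corr_max Upper bound on `|cor(hidden, observed)|`
#'   (default 0.2).
#' @param seed RNG seed.
#' @param hidden Optional numeric vector of length `n_pops` to use as the
#'   hidden variable (standardized internally).
#' @return List with `envs` (an [env_matrix]), `hidden` (the standardized
#'   hidden variable) and `hidden_corr` (achieved correlations).
#' @export
synthetic_environments <- function(n_pops = 250, n_vars = NULL,
                                   target_corr = pine_env_correlation(),
                                   selective_corr_max = 0.2, seed = 1L,
                                   hidden = NULL) {
  C <- as.matrix(target_corr)
  if (is.null(n_vars)) n_vars <- ncol(C)
  C <- C[seq_len(n_vars), seq_len(n_vars), drop = FALSE]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("target_corr must be positive definite")
  if (n_pops <= n_vars + 2)
    stop("n_pops must exceed n_vars + 2 for the empirical construction")
  if (selective_corr_max < 0 || selective_corr_max >= 1)
    stop("selective_corr_max must be in [0, 1)")
  set.seed(seed)

  std <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2) / (length(v) - 1)) }
  if (is.null(hidden)) hidden <- rnorm(n_pops)
  if (length(hidden) != n_pops) stop("hidden must have length n_pops")
  if (sd(hidden) == 0) stop("hidden variable is constant")
  h <- std(as.numeric(hidden))

  ## target correlations of each observed variable with the hidden one
  b <- runif(n_vars, 0, selective_corr_max) * sample(c(-1, 1), n_vars, TRUE)
  ## shrink if C - b b' loses positive definiteness (keeps the band)
  repeat {
    M <- tryCatch(chol(C - tcrossprod(b)), error = function(e) NULL)
    if (!is.null(M)) break
    b <- 0.9 * b
  }

  ## noise with exact identity sample covariance, exactly orthogonal to h
  Z <- MASS::mvrnorm(n_pops, mu = rep(0, n_vars), Sigma = diag(n_vars))
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z - h %*% (crossprod(h, Z) / sum(h^2))
  W <- Z %*% backsolve(chol(crossprod(Z) / (n_pops - 1)), diag(n_vars))
  X <- h %*% t(b) + W %*% M          # M is the upper Cholesky of C - b b'
  colnames(X) <- colnames(C)
  rownames(X) <- paste0("pop", seq_len(n_pops))

  achieved <- as.numeric(cor(X, h))
  category <- attr(target_corr, "category")
  list(envs = env_matrix(X, category = category),
       hidden = setNames(h, rownames(X)),
       hidden_corr = setNames(achieved, colnames(X)))
}

#' Inverse-distance-weighted interpolation of environments
#'
#' Interpolates each variable at query coordinates as the
#' inverse-distance-weighted (power 2) mean of the `k` nearest sample
#' sites.  A query coinciding with a sample site returns that site's value
#' exactly; queries outside the convex hull of the sample sites fall back
#' to the nearest site's value with a warning.
#'
#' @param sample_sites Data frame with columns `x`, `y` and one numeric
#'   column per variable.
#' @param query_sites Data frame/matrix with columns `x`, `y`.
#' @param power IDW exponent (default 2).
#' @param k Number of nearest neighbors (default 8).
#' @return Matrix of interpolated values, queries x variables.
#' @export
interpolate_environments <- function(sample_sites, query_sites,
                                     power = 2, k = 8) {
  ss <- as.data.frame(sample_sites)
  if (nrow(ss) < 3) stop("need at least 3 sample sites")
  vars <- setdiff(names(ss), c("x", "y"))
  V <- as.matrix(ss[, vars, drop = FALSE])
  q <- as.data.frame(query_sites)
  k <- min(k, nrow(ss))

  hull <- grDevices::chull(ss$x, ss$y)
  inside <- .in_poly(q$x, q$y, ss$x[hull], ss$y[hull])
  if (any(!inside))
    warning(sum(!inside), " query site(s) outside the convex hull: ",
            "using nearest-neighbor values")

  out <- matrix(NA_real_, nrow(q), length(vars),
                dimnames = list(NULL, vars))
  for (i in seq_len(nrow(q))) {
    d2 <- (ss$x - q$x[i])^2 + (ss$y - q$y[i])^2
    if (any(d2 == 0)) { out[i, ] <- V[which.min(d2), ]; next }
    if (!inside[i]) { out[i, ] <- V[which.min(d2), ]; next }
    nn <- order(d2)[seq_len(k)]
    w <- 1 / d2[nn]^(power / 2)
    out[i, ] <- colSums(V[nn, , drop = FALSE] * w) / sum(w)
  }
  out
}

## ray-casting point-in-polygon (boundary counts as inside)
.in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]
    hit <- FALSE
    j <- n
    for (i in seq_len(n)) {
      on_edge <- abs((vx[j] - vx[i]) * (y - vy[i]) -
                     (vy[j] - vy[i]) * (x - vx[i])) < 1e-12 &&
        x >= min(vx[i], vx[j]) - 1e-12 && x <= max(vx[i], vx[j]) + 1e-12 &&
        y >= min(vy[i], vy[j]) - 1e-12 && y <= max(vy[i], vy[j]) + 1e-12
      if (on_edge) { hit <- TRUE; break }
      if ((vy[i] > y) != (vy[j] > y) &&
          x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
        hit <- !hit
      j <- i
    }
    inside[p] <- hit
  }
  inside
}
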