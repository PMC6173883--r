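## Galaxy biplots: each SNP's association with one environment plotted
## against its association with a second, over a genome-wide bivariate
## prediction ellipse derived from the eigendecomposition of the 2x2
## covariance of allelic associations.

#' Biplot coordinates for an environment pair
#'
#' Returns `(rho(f, env1), rho(f, env2))` per SNP.  Because derived alleles
#' are coded 1, recoding an allele reflects its point through the origin,
#' so SNPs with unknown derived state can be dropped (`derived_only`).
#'
#' @param assoc An `assoc_matrix`.
#' @param env1,env2 Distinct environment names.
#' @param derived_known Optional logical vector (named by SNP id) marking
#'   SNPs whose derived allele is known.
#' @param derived_only Drop SNPs with unknown derived state (default FALSE).
#' @param env_cor Optional Spearman correlation between the two variables on
#'   the landscape, used to shade the quadrants where genome-wide covariance
#'   is expected (quadrants 1 and 3 when positive).
#' @return Data frame `snp_id`, `x`, `y` with attributes `env_cor` and
#'   `shaded_quadrants`.
#' @export
biplot_coordinates <- function(assoc, env1, env2, derived_known = NULL,
                               derived_only = FALSE, env_cor = NA_real_) {
  if (identical(env1, env2)) stop("env1 and env2 must differ")
  if (!all(c(env1, env2) %in% colnames(assoc$rho)))
    stop("environment not present in the association matrix")
  pts <- data.frame(snp_id = rownames(assoc$rho),
                    x = assoc$rho[, env1], y = assoc$rho[, env2],
                    stringsAsFactors = FALSE)
  if (derived_only) {
    if (is.null(derived_known))
      stop("derived_only = TRUE needs the derived_known flags")
    pts <- pts[derived_known[pts$snp_id] %in% TRUE, ]
  }
  rownames(pts) <- NULL
  attr(pts, "env_cor") <- env_cor
  attr(pts, "shaded_quadrants") <-
    if (is.na(env_cor)) NA_integer_ else if (env_cor >= 0) c(1L, 3L) else c(2L, 4L)
  attr(pts, "envs") <- c(env1, env2)
  pts
}

## first two numeric columns of a biplot point set, complete cases only
.xy <- function(points) {
  off <- isTRUE(colnames(points)[1] == "snp_id")
  m <- as.matrix(as.data.frame(points)[, c(1, 2) + off])
  m[complete.cases(m), , drop = FALSE]
}

#' Bivariate-normal prediction ellipse
#'
#' The (1 - alpha) prediction ellipse of a 2-D sample: centered on the
#' sample means, with semi-axes `l_j = sqrt(lambda_j * q)` where `lambda_j`
#' are the eigenvalues of the 2x2 sample covariance and `q` is the
#' chi-square quantile at probability `1 - alpha` with 2 degrees of
#' freedom, and orientation given by the leading eigenvector.
#'
#' @param points Two-column matrix or data frame (columns x, y) of at least
#'   3 non-collinear points, or a list with elements `center` and `cov` for
#'   a known distribution.
#' @param alpha Tail probability (default 0.05 for a 95% ellipse).
#' @return An object of class `prediction_ellipse` with fields `center`,
#'   `semi_axes` (l1 >= l2), `orientation` (radians of the major axis in
#'   (-pi/2, pi/2]), `alpha`, `cov` and `chisq_q`.
#' @export
prediction_ellipse <- function(points, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.list(points) && !is.null(points$cov)) {
    ctr <- points$center
    S <- points$cov
    n <- NA_integer_
  } else {
    m <- .xy(points)
    if (nrow(m) < 3) stop("need at least 3 points")
    if (nrow(m) < 200)
      warning("prediction ellipse assumes many unlinked SNPs; n = ", nrow(m))
    ctr <- colMeans(m)
    S <- cov(m)  # sample (n - 1) covariance
    n <- nrow(m)
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("singular covariance (collinear points): ellipse undefined")
  q <- qchisq(1 - alpha, df = 2)
  l <- sqrt(ev$values * q)
  v <- ev$vectors[, 1]
  theta <- atan2(v[2], v[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  structure(list(center = as.numeric(ctr), semi_axes = l,
                 orientation = theta, alpha = alpha, cov = S,
                 chisq_q = q, n = n),
            class = "prediction_ellipse")
}

#' @export
print.prediction_ellipse <- function(x, ...) {
  cat(sprintf(
    "prediction_ellipse (alpha = %g): center (%.3f, %.3f), l1 = %.3f, l2 = %.3f, angle = %.1f deg\n",
    x$alpha, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$orientation * 180 / pi))
  invisible(x)
}

#' Points on the ellipse boundary
#' @param ellipse A `prediction_ellipse`.
#' @param n Number of boundary points.
#' @return An n x 2 matrix tracing the ellipse.
#' @export
ellipse_boundary <- function(ellipse, n = 360) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  th <- ellipse$orientation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(cbind(a * cos(t), b * sin(t)) %*% t(R), 2, ellipse$center, "+")
}

#' Fraction of points inside a prediction ellipse
#'
#' A point is inside when its quadratic form
#' `(p - center)' cov^{-1} (p - center)` does not exceed the ellipse's
#' chi-square quantile.
#'
#' @param points Two-column matrix/data frame.
#' @param ellipse A `prediction_ellipse`.
#' @return Fraction of points inside, in `[0, 1]`.
#' @export
ellipse_coverage <- function(points, ellipse) {
  m <- .xy(points)
  d <- sweep(m, 2, ellipse$center)
  Sinv <- solve(ellipse$cov)
  qf <- rowSums((d %*% Sinv) * d)
  mean(qf <= ellipse$chisq_q)
}

#' Plot a galaxy biplot
#'
#' Base-graphics scatter of per-SNP associations for two environments with
#' the genome-wide 95% prediction ellipse and expected-covariance quadrant
#' shading; optional highlighting of candidate SNPs by module/group color.
#'
#' @param points Output of [biplot_coordinates()].
#' @param ellipse Optional `prediction_ellipse` (computed from `points` if
#'   `NULL`).
#' @param highlight Optional named (by snp_id) vector of colors for
#'   candidate SNPs.
#' @param ... Passed to `plot()`.
#' @export
plot_galaxy_biplot <- function(points, ellipse = NULL, highlight = NULL, ...) {
  if (is.null(ellipse)) ellipse <- prediction_ellipse(points)
  envs <- attr(points, "envs")
  lim <- range(c(points$x, points$y), na.rm = TRUE)
  plot(NA, xlim = lim, ylim = lim,
       xlab = if (!is.null(envs)) envs[1] else "x",
       ylab = if (!is.null(envs)) envs[2] else "y", ...)
  quads <- attr(points, "shaded_quadrants")
  if (!anyNA(quads)) {
    big <- max(abs(lim)) * 2
    for (q in quads) {
      sx <- if (q %in% c(1, 4)) c(0, big) else c(-big, 0)
      sy <- if (q %in% c(1, 2)) c(0, big) else c(-big, 0)
      graphics::rect(sx[1], sy[1], sx[2], sy[2], col = "grey92", border = NA)
    }
  }
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::points(points$x, points$y, pch = 16, cex = 0.4, col = "grey40")
  graphics::lines(ellipse_boundary(ellipse), lwd = 2)
  if (!is.null(highlight)) {
    ix <- points$snp_id %in% names(highlight)
    graphics::points(points$x[ix], points$y[ix], pch = 21,
                     bg = highlight[points$snp_id[ix]], cex = 0.9)
  }
  if (!anyNA(attr(points, "env_cor")))
    graphics::legend("bottomright", bty = "n",
                     legend = sprintf("rho = %.2f", attr(points, "env_cor")))
  invisible(ellipse)
}
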