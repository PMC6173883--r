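## Forward-time landscape simulator: independent haploid SNPs on a deme
## grid under isolation-by-distance (IBD) or range-expansion (1R, 2R)
## demographies, Gaussian dispersal, and spatially varying selection along
## a noisy north-south cline.

#' Simulation configuration
#'
#' @param width,height Grid size in demes.  The default 32 x 32 is a
#'   desk-scale landscape; the full-scale analog is 360 x 360.
#' @param demography `"IBD"` (equilibrium isolation by distance, whole grid
#'   occupied), `"1R"` (expansion from a single mid-south refugium) or
#'   `"2R"` (expansion from SW and SE corner refugia).
#' @param sigma Gaussian dispersal standard deviation in deme units.
#' @param kernel_radius Kernel truncation radius (default `ceiling(3 sigma)`).
#' @param capacity Haploid carrying capacity K per deme; `Inf` gives the
#'   deterministic (drift-free) recurrence.
#' @param generations Number of generations; defaults to 200 for IBD
#'   (quasi-equilibrium differentiation at the 32 x 32 extent) and 100 for
#'   the expansion scenarios (the front covers the grid and then settles),
#'   mirroring the 10:1 full-scale ratio of 10,000 IBD vs 1,000 expansion
#'   generations.
#' @param n_neutral Number of neutral loci.
#' @param n_selected Number of selected loci; the default is 1% of the
#'   total locus count.
#' @param s_values Selection coefficients assigned cyclically to selected
#'   loci, spanning weak (0.001) to strong (0.1).
#' @param cline_weight Weight w of the north-south cline in the selection
#'   surface (`w = 1` is a pure cline).
#' @param heterogeneity_scale Smoothing scale (demes) of the
#'   spatially autocorrelated component of the surface.
#' @param torus Use wraparound boundaries (default FALSE: reflecting).
#' @param front_speed Demes colonized per generation by the expansion front.
#' @param p0_range Range of initial allele frequencies (drawn per locus).
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(width = 32, height = 32,
                       demography = c("IBD", "1R", "2R"),
                       sigma = 1, kernel_radius = ceiling(3 * sigma),
                       capacity = 16, generations = NULL,
                       n_neutral = 1000, n_selected = NULL,
                       s_values = c(0.001, 0.005, 0.01, 0.05, 0.1),
                       cline_weight = 0.5, heterogeneity_scale = 4,
                       torus = FALSE, front_speed = 1,
                       p0_range = c(0.1, 0.9), seed = 1L) {
  demography <- match.arg(demography)
  if (sigma <= 0) stop("sigma must be > 0")
  if (!is.infinite(capacity) && capacity < 1) stop("capacity must be >= 1 or Inf")
  if (is.null(generations))
    generations <- if (demography == "IBD") 200L else 100L
  if (generations < 1) stop("generations must be >= 1")
  if (is.null(n_selected))
    n_selected <- max(0L, round(0.01 * n_neutral / 0.99))
  if (cline_weight < 0 || cline_weight > 1) stop("cline_weight must be in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 demography = demography, sigma = sigma,
                 kernel_radius = as.integer(kernel_radius),
                 capacity = capacity, generations = as.integer(generations),
                 n_neutral = as.integer(n_neutral),
                 n_selected = as.integer(n_selected), s_values = s_values,
                 cline_weight = cline_weight,
                 heterogeneity_scale = heterogeneity_scale,
                 torus = isTRUE(torus), front_speed = front_speed,
                 p0_range = p0_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  do.call(sim_config, yaml::read_yaml(path))
}

## deme coordinates, row-major with x fastest; "latitude" = y (north up)
.deme_coords <- function(config) {
  data.frame(deme = seq_len(config$width * config$height),
             x = rep(seq_len(config$width), times = config$height),
             y = rep(seq_len(config$height), each = config$width))
}

## truncated discretized Gaussian kernel offsets and weights
.kernel <- function(sigma, radius) {
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  r2 <- off$dx^2 + off$dy^2
  keep <- r2 <= radius^2
  list(dx = as.integer(off$dx[keep]), dy = as.integer(off$dy[keep]),
       w = exp(-r2[keep] / (2 * sigma^2)))
}

## generation at which each deme becomes occupied (0 = initial)
.occupation_schedule <- function(config) {
  co <- .deme_coords(config)
  refugia <- switch(config$demography,
    IBD = NULL,
    "1R" = data.frame(x = round(config$width / 2), y = 1),
    "2R" = data.frame(x = c(1, config$width), y = c(1, 1)))
  if (is.null(refugia)) return(integer(config$width * config$height))
  d <- sapply(seq_len(nrow(refugia)), function(i)
    pmax(abs(co$x - refugia$x[i]), abs(co$y - refugia$y[i])))
  dmin <- if (is.matrix(d)) apply(d, 1, min) else d
  as.integer(ceiling(dmin / config$front_speed))
}

#' Spatially varying selection surface
#'
#' `w * (normalized south-north position) + (1 - w) * (smoothed Gaussian
#' noise field)`, linearly rescaled to `[-1, 1]`.  With `w = 1` this is a
#' deterministic linear latitudinal cline; smaller `w` adds spatial
#' heterogeneity at the `heterogeneity_scale`.
#'
#' @param config A [sim_config()]; its `seed` (offset by a fixed constant
#'   so surface and dynamics draws are decoupled) makes the surface
#'   reproducible.
#' @return Numeric vector of per-deme surface values in `[-1, 1]`.
#' @export
selection_surface <- function(config) {
  w <- config$cline_weight
  co <- .deme_coords(config)
  lat <- 2 * (co$y - 1) / max(config$height - 1, 1) - 1
  if (w < 1) {
    set.seed(config$seed + 90321L)
    noise <- matrix(rnorm(config$width * config$height),
                    config$height, config$width)
    field <- .gauss_smooth(noise, config$heterogeneity_scale)
    field <- as.numeric(t(field))      # back to x-fastest order
    fsd <- sd(field)                   # degenerate on single-deme grids
    field <- if (is.finite(fsd) && fsd > 0)
      (field - mean(field)) / fsd else 0
  } else field <- 0
  raw <- w * lat + (1 - w) * field
  lo <- min(raw); hi <- max(raw)
  if (hi - lo < 1e-12) return(rep(0, length(raw)))
  2 * (raw - lo) / (hi - lo) - 1
}

## separable Gaussian blur with reflecting edges
.gauss_smooth <- function(m, scale) {
  r <- max(1L, ceiling(2 * scale))
  k <- exp(-(-r:r)^2 / (2 * scale^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -r:r, "+")
    # iterate: one bounce is not enough when the radius exceeds the extent
    while (any(idx < 1 | idx > n)) {
      idx[idx < 1] <- 1 - idx[idx < 1]
      idx[idx > n] <- 2 * n + 1 - idx[idx > n]
    }
    as.numeric(matrix(v[idx], n) %*% k)
  }
  nr <- nrow(m); nc <- ncol(m)
  m <- matrix(apply(m, 2, smooth1), nr, nc)   # reshape: apply drops dims
  t(matrix(apply(m, 1, smooth1), nc, nr))
}

#' Run the landscape simulation
#'
#' Iterates, per generation and occupied deme: kernel-weighted migration
#' over occupied demes, haploid selection
#' `p' = p (1 + s_d) / (1 + p s_d)` with `s_d = s x surface`, and binomial
#' drift with K haploids (skipped when `capacity = Inf`).  Expansion
#' scenarios colonize demes ring by ring outward from the refugia, new
#' demes being founded from adjacent occupied demes.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_state`: list with `freq` (loci x demes),
#'   `occupied` (logical per deme), `surface`, `s` (true selection
#'   coefficient per locus, 0 for neutral), `coords`, `config`.
#' @export
simulate_landscape <- function(config) {
  n_loci <- config$n_neutral + config$n_selected
  surface <- selection_surface(config)
  occ_gen <- .occupation_schedule(config)
  set.seed(config$seed)
  s <- c(rep(0, config$n_neutral),
         rep_len(config$s_values, config$n_selected))
  p0 <- runif(n_loci, config$p0_range[1], config$p0_range[2])
  D <- config$width * config$height
  freq <- matrix(rep(p0, D), nrow = n_loci, ncol = D)
  freq[, occ_gen > 0] <- NA_real_
  kern <- .kernel(config$sigma, config$kernel_radius)
  K <- if (is.infinite(config$capacity)) 0L else as.integer(config$capacity)
  out <- cpp_run_landscape(freq, occ_gen, config$width, config$height,
                           kern$dx, kern$dy, kern$w, config$torus,
                           s, surface, K, config$generations)
  rownames(out) <- c(paste0("neutral", seq_len(config$n_neutral)),
                     if (config$n_selected)
                       paste0("selected", seq_len(config$n_selected)))
  structure(list(freq = out, occupied = occ_gen <= config$generations,
                 surface = surface, s = setNames(s, rownames(out)),
                 coords = .deme_coords(config), config = config,
                 generation = config$generations),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "sim_state: %s %dx%d grid, %d loci (%d selected), generation %d, %d/%d demes occupied\n",
    x$config$demography, x$config$width, x$config$height, nrow(x$freq),
    x$config$n_selected, x$generation, sum(x$occupied), length(x$occupied)))
  invisible(x)
}

#' Per-locus F_ST across demes or populations
#'
#' The variance-ratio estimator `Var(p) / (p-bar (1 - p-bar))` with the
#' population (divide-by-n) variance of deme frequencies; globally
#' monomorphic loci are `NA` and excluded from the mean.  With equal
#' carrying capacity per deme no sample-size weighting is needed.
#'
#' @param state A `sim_state`, a [freq_matrix], or a plain
#'   populations x loci matrix.
#' @param neutral_only For `sim_state` input, restrict to neutral loci
#'   (default TRUE).
#' @return List with `fst` (per locus) and `mean` (across non-`NA` loci).
#' @export
weir_fst <- function(state, neutral_only = TRUE) {
  if (inherits(state, "sim_state")) {
    p <- t(state$freq[, state$occupied, drop = FALSE])
    if (neutral_only) p <- p[, state$s == 0, drop = FALSE]
  } else if (inherits(state, "freq_matrix")) {
    p <- state$freq
  } else p <- as.matrix(state)
  if (nrow(p) < 2) stop("need at least 2 occupied demes/populations")
  n <- nrow(p)
  pbar <- colMeans(p)
  v <- colMeans(p^2) - pbar^2          # population variance
  denom <- pbar * (1 - pbar)
  fst <- ifelse(denom > 0, pmax(v, 0) / denom, NA_real_)
  list(fst = fst, mean = mean(fst, na.rm = TRUE))
}

#' Calibrate carrying capacity to a target neutral F_ST
#'
#' Bisection on log2(K): mean neutral F_ST decreases monotonically in K, so
#' the bracket `k_bounds` is halved (on the log scale, rounding to integer
#' K) until the replicate-averaged mean F_ST is within `tolerance` of
#' `fst_target` or the bracket is exhausted.
#'
#' @param config A [sim_config()]; its `capacity` is ignored.
#' @param fst_target Target mean neutral F_ST in (0, 1) (default 0.05).
#' @param tolerance Convergence tolerance on mean F_ST (default 0.005).
#' @param k_bounds Integer search bracket for K.
#' @param n_seeds Replicate seeds averaged per evaluation (default 3).
#' @param max_iter Maximum bisection iterations.
#' @return List with `capacity` (calibrated K), `fst` (achieved mean at
#'   K), `trace` (data frame of evaluated K and F_ST) and `converged`.
#' @export
calibrate_capacity <- function(config, fst_target = 0.05, tolerance = 0.005,
                               k_bounds = c(2, 512), n_seeds = 3,
                               max_iter = 12) {
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0, 1)")
  eval_k <- function(K) {
    mean(vapply(seq_len(n_seeds), function(i) {
      cfg <- config
      cfg$capacity <- K
      cfg$seed <- config$seed + 1000L * i
      weir_fst(simulate_landscape(cfg))$mean
    }, numeric(1)))
  }
  trace <- data.frame(K = integer(0), fst = numeric(0))
  note <- function(K, fst) trace[nrow(trace) + 1L, ] <<- list(K, fst)

  lo <- as.integer(k_bounds[1]); hi <- as.integer(k_bounds[2])
  f_lo <- eval_k(lo); note(lo, f_lo)
  if (abs(f_lo - fst_target) <= tolerance)
    return(list(capacity = lo, fst = f_lo, trace = trace, converged = TRUE))
  f_hi <- eval_k(hi); note(hi, f_hi)
  if (abs(f_hi - fst_target) <= tolerance)
    return(list(capacity = hi, fst = f_hi, trace = trace, converged = TRUE))
  if ((f_lo - fst_target) * (f_hi - fst_target) > 0)
    stop(sprintf(
      "target F_ST %.3g unreachable in K bracket [%d, %d]: achieved [%.4f, %.4f]",
      fst_target, lo, hi, f_hi, f_lo))
  best <- if (abs(f_lo - fst_target) < abs(f_hi - fst_target))
    list(capacity = lo, fst = f_lo) else list(capacity = hi, fst = f_hi)
  for (it in seq_len(max_iter)) {
    mid <- as.integer(round(sqrt(as.numeric(lo) * as.numeric(hi))))
    if (mid <= lo || mid >= hi) break
    f_mid <- eval_k(mid); note(mid, f_mid)
    if (abs(f_mid - fst_target) < abs(best$fst - fst_target))
      best <- list(capacity = mid, fst = f_mid)
    if (abs(f_mid - fst_target) <= tolerance)
      return(list(capacity = mid, fst = f_mid, trace = trace,
                  converged = TRUE))
    if (f_mid > fst_target) lo <- mid else hi <- mid
  }
  c(best, list(trace = trace, converged = FALSE))
}

#' Sample populations from a simulated landscape
#'
#' Draws `n_pops` occupied demes (without replacement) as sampling
#' locations, returning their deme frequencies as the population allele
#' frequencies (each deme's K haploids are the population).
#'
#' @param state A `sim_state`.
#' @param n_pops Number of populations to sample.
#' @param seed RNG seed for the draw.
#' @return List with `freqs` (a [freq_matrix], populations x loci), `pops`
#'   (a [population_frame] with grid coordinates as latitude/longitude) and
#'   `hidden_env` (the selection-surface value at each sampled deme: the
#'   unmeasured selective environment).
#' @export
sample_populations <- function(state, n_pops = 50, seed = 1L) {
  occ <- which(state$occupied)
  if (n_pops > length(occ)) stop("fewer occupied demes than requested")
  set.seed(seed)
  demes <- sort(sample(occ, n_pops))
  f <- t(state$freq[, demes, drop = FALSE])
  rownames(f) <- paste0("pop", seq_len(n_pops))
  pops <- population_frame(rownames(f),
                           latitude = state$coords$y[demes],
                           longitude = state$coords$x[demes],
                           elevation = 0, n_individuals = 1L)
  list(freqs = freq_matrix(f), pops = pops,
       hidden_env = setNames(state$surface[demes], rownames(f)),
       demes = demes)
}

#' Write simulation outputs as TSV
#'
#' Writes `freqs.tsv` (sampled population frequencies), `envs.tsv`,
#' `truth.tsv` (locus, s, correlation with the selective surface) and
#' `config.yaml` under `dir`.
#'
#' @param state A `sim_state`.
#' @param sample Output of [sample_populations()].
#' @param envs Optional [env_matrix] of overlaid environments.
#' @param dir Output directory.
#' @export
write_simulation_tsv <- function(state, sample, envs = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_freq_matrix(sample$freqs, file.path(dir, "freqs.tsv"))
  if (!is.null(envs))
    write.table(data.frame(pop_id = rownames(envs$values), envs$values,
                           check.names = FALSE),
                file.path(dir, "envs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  surf_cor <- apply(sample$freqs$freq, 2, function(p)
    suppressWarnings(cor(p, sample$hidden_env, method = "spearman")))
  truth <- data.frame(locus = names(state$s), s = unname(state$s),
                      surface_rho = unname(surf_cor))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- unclass(state$config)
    cfg$capacity <- if (is.infinite(cfg$capacity)) "Inf" else cfg$capacity
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
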