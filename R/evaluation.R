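## Evaluation of candidate-detection criteria on simulated truth: false and
## true positive counts, node degree versus selection strength, the edge
## threshold sweep, and the principal-components-of-environments comparator.

#' Apply candidate criteria to simulated associations
#'
#' Counts neutral loci (false positives) and selected loci (true positives)
#' passing the chosen criteria in at least one environment.  `"strict"`
#' requires both the Bonferroni P-value criterion on the uncorrected
#' associations and `log10(BF) > bf_min` on the corrected layer (the
#' empirical-data criterion); `"relaxed"` requires the Bonferroni criterion
#' only, which admits false positives whose structure is then visible in
#' the co-association network.
#'
#' @param assoc_raw Uncorrected `assoc_matrix` for the simulated loci.
#' @param truth Named numeric vector of true selection coefficients per
#'   locus (0 = neutral), aligned to the association rows.
#' @param criteria `"strict"` or `"relaxed"`.
#' @param assoc_corrected Corrected `assoc_matrix` with `log10_bf`
#'   (required for `"strict"`).
#' @param alpha Family-wise rate for the Bonferroni cutoff.
#' @param bf_min Minimum log10 Bayes factor for `"strict"`.
#' @return List with `fp`, `tp`, `n_neutral`, `n_selected`, `passing`
#'   (logical per locus) and the `cutoff` used.
#' @export
apply_candidate_criteria <- function(assoc_raw, truth,
                                     criteria = c("strict", "relaxed"),
                                     assoc_corrected = NULL,
                                     alpha = 0.05, bf_min = 2) {
  criteria <- match.arg(criteria)
  ids <- rownames(assoc_raw$rho)
  if (!all(ids %in% names(truth)))
    stop("truth does not cover all loci in the association matrix")
  truth <- truth[ids]
  if (length(truth) == 0)
    return(list(fp = 0L, tp = 0L, n_neutral = 0L, n_selected = 0L,
                passing = logical(0), cutoff = NA_real_))
  cutoff <- bonferroni_threshold(nrow(assoc_raw$rho), ncol(assoc_raw$rho),
                                 alpha)
  pass <- !is.na(assoc_raw$pvalue) & assoc_raw$pvalue < cutoff
  if (criteria == "strict") {
    if (is.null(assoc_corrected) || is.null(assoc_corrected$log10_bf))
      stop("strict criteria need a corrected assoc_matrix with log10_bf")
    pass <- pass & !is.na(assoc_corrected$log10_bf) &
      assoc_corrected$log10_bf > bf_min
  }
  hit <- rowSums(pass) > 0
  list(fp = sum(hit & truth == 0), tp = sum(hit & truth > 0),
       n_neutral = sum(truth == 0), n_selected = sum(truth > 0),
       passing = setNames(hit, ids), cutoff = cutoff)
}

#' Node degree as a function of selection strength
#'
#' Summarizes co-association network degree per selection-coefficient class
#' (including s = 0, the neutral class).  Selected loci, sharing a common
#' selective surface, tend to be more densely connected than neutral false
#' positives.
#'
#' @param graph A `coassoc_graph` whose nodes are simulated loci.
#' @param truth Named numeric vector of true s per locus.
#' @return Data frame with `s`, `n`, `mean_degree`, `median_degree`,
#'   `max_degree`, plus the per-node table as attribute `"nodes"`.
#' @export
degree_by_selection <- function(graph, truth) {
  ids <- graph$nodes$snp_id
  if (!all(ids %in% names(truth)))
    stop("graph nodes must be a subset of the truth table")
  nodes <- data.frame(locus = ids, s = unname(truth[ids]),
                      degree = graph$nodes$degree)
  agg <- do.call(rbind, lapply(split(nodes, nodes$s), function(d)
    data.frame(s = d$s[1], n = nrow(d), mean_degree = mean(d$degree),
               median_degree = stats::median(d$degree),
               max_degree = max(d$degree))))
  rownames(agg) <- NULL
  attr(agg, "nodes") <- nodes
  agg
}

#' Choose the edge threshold that enriches selected-locus connections
#'
#' Sweeps candidate distance thresholds and scores each by
#' (mean degree of selected loci) - (mean degree of neutral loci); the
#' maximizing threshold enriches for connections among loci responding to
#' the common selective factor while limiting connections to false
#' positives.
#'
#' @param dist_mat Association-profile distance matrix of the passing loci.
#' @param truth Named numeric vector of true s per locus.
#' @param grid Candidate thresholds (default `seq(0.02, 0.5, by = 0.02)`).
#' @return List with `threshold` (the argmax), and `sweep` (data frame of
#'   threshold, mean degrees, score).
#' @export
sweep_edge_threshold <- function(dist_mat, truth,
                                 grid = seq(0.02, 0.5, by = 0.02)) {
  ids <- rownames(as.matrix(dist_mat))
  s <- truth[ids]
  res <- do.call(rbind, lapply(grid, function(th) {
    g <- build_coassociation_graph(dist_mat, th)
    deg <- setNames(g$nodes$degree, g$nodes$snp_id)[ids]
    msel <- if (any(s > 0)) mean(deg[s > 0]) else NA_real_
    mneu <- if (any(s == 0)) mean(deg[s == 0]) else 0
    data.frame(threshold = th, mean_degree_selected = msel,
               mean_degree_neutral = mneu, score = msel - mneu)
  }))
  best <- res$threshold[which.max(res$score)]
  list(threshold = best, sweep = res)
}

#' Associations with principal components of environments
#'
#' PCA comparator: environments are standardized and rotated with
#' `prcomp()`; SNP associations with the PC scores are computed with the
#' associations module, and a SNP is a PC outlier when its corrected
#' log10 Bayes factor on that axis exceeds `bf_min` (or, without a
#' covariance matrix, when its uncorrected P value passes the Bonferroni
#' cutoff).
#'
#' @param envs An [env_matrix].
#' @param freqs A [freq_matrix].
#' @param bf_min Outlier criterion on log10 BF (default 2).
#' @param n_axes Number of leading axes to test (default
#'   `min(10, n_vars)`).
#' @param cov Optional `pop_covariance` for the corrected layer; estimated
#'   from `freqs` when `NULL`.
#' @return List with `scores` (populations x axes), `variance_fraction`,
#'   `assoc` (corrected `assoc_matrix` vs the PC axes) and `outlier`
#'   (logical SNPs x axes).
#' @export
pca_environment_associations <- function(envs, freqs, bf_min = 2,
                                         n_axes = NULL, cov = NULL) {
  e <- if (inherits(envs, "env_matrix")) envs$values else as.matrix(envs)
  keep <- apply(e, 2, sd) > 0
  if (!all(keep)) {
    warning("dropping constant environmental variable(s): ",
            paste(colnames(e)[!keep], collapse = ", "))
    e <- e[, keep, drop = FALSE]
  }
  if (ncol(e) < 2) stop("need at least 2 variables")
  pc <- prcomp(e, center = TRUE, scale. = TRUE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(n_axes)) n_axes <- min(10L, ncol(pc$x))
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  assoc <- corrected_associations(freqs, env_matrix(scores), cov = cov)
  outlier <- !is.na(assoc$log10_bf) & assoc$log10_bf > bf_min
  list(scores = scores, variance_fraction = varfrac, assoc = assoc,
       outlier = outlier, loadings = pc$rotation)
}

#' Fraction of each group's candidate SNPs missed by PC outliers
#'
#' For each co-association group, the fraction of its candidate SNPs that
#' are not outliers on any of the first `n_axes` PC axes — the candidates a
#' PCA-first analysis would have missed.
#'
#' @param candidate_ids Character vector of candidate SNP ids.
#' @param pc_outlier Logical SNPs x axes matrix (rows named by SNP id).
#' @param groups Group labels named by SNP id.
#' @param n_axes Number of leading axes to consider (default: all columns).
#' @return Named numeric vector: per-group missed fraction in `[0, 1]`.
#' @export
group_pc_overlap <- function(candidate_ids, pc_outlier, groups,
                             n_axes = ncol(pc_outlier)) {
  if (!all(candidate_ids %in% rownames(pc_outlier)))
    stop("pc_outlier must cover all candidate SNPs")
  fl <- pc_outlier[candidate_ids, seq_len(n_axes), drop = FALSE]
  missed <- rowSums(fl) == 0
  grp <- groups[candidate_ids]
  sapply(split(missed, grp), mean)
}

#' Full evaluation report for one simulated dataset
#'
#' Runs the candidate criteria, builds the co-association network of the
#' passing loci at a threshold chosen by [sweep_edge_threshold()], and
#' summarizes degree by selection class.
#'
#' @param sample Output of [sample_populations()].
#' @param envs An [env_matrix] overlaid on the sampled demes.
#' @param state The `sim_state` the sample came from.
#' @param criteria `"strict"` or `"relaxed"`.
#' @param threshold Edge threshold, or `NULL` to sweep.
#' @param alpha,bf_min Criterion parameters.
#' @return List of class `evaluation_report`: `counts`, `degree_summary`,
#'   `graph`, `threshold`.
#' @export
evaluate_simulation <- function(sample, envs, state,
                                criteria = c("relaxed", "strict"),
                                threshold = NULL, alpha = 0.05, bf_min = 2) {
  criteria <- match.arg(criteria)
  raw <- spearman_matrix(sample$freqs, envs)
  corr <- if (criteria == "strict")
    corrected_associations(sample$freqs, envs) else NULL
  counts <- apply_candidate_criteria(raw, state$s, criteria,
                                     assoc_corrected = corr,
                                     alpha = alpha, bf_min = bf_min)
  hits <- names(counts$passing)[counts$passing]
  graph <- NULL; degree_summary <- NULL; th <- threshold
  if (length(hits) >= 2) {
    dmat <- association_distance_matrix(
      assoc_matrix(raw$rho[hits, , drop = FALSE]))
    if (is.null(th))
      th <- sweep_edge_threshold(dmat, state$s)$threshold
    graph <- build_coassociation_graph(dmat, th)
    degree_summary <- degree_by_selection(graph, state$s)
  }
  structure(list(counts = counts[c("fp", "tp", "n_neutral", "n_selected")],
                 degree_summary = degree_summary, graph = graph,
                 threshold = th, criteria = criteria),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (%s criteria): %d/%d neutral false positives, %d/%d selected true positives\n",
    x$criteria, x$counts$fp, x$counts$n_neutral, x$counts$tp,
    x$counts$n_selected))
  invisible(x)
}
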