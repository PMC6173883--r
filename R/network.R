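## Co-association structure: Euclidean distances between SNP association
## profiles, Ward clustering into major groups, threshold graphs whose
## connected components are the co-association modules, and per-gene
## environmental-pleiotropy tables.

#' Euclidean distance between SNP association profiles
#'
#' Pairwise Euclidean distance over each SNP's vector of associations with
#' all environments.  Signed correlations are the default; `signed = FALSE`
#' uses `|rho|` (the heatmap convention, which ignores allele polarity).
#'
#' @param assoc An `assoc_matrix`; its `rho` layer must be complete for the
#'   SNPs of interest (drop or impute missing cells first).
#' @param signed Use signed rho (default) or absolute values.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
association_distance_matrix <- function(assoc, signed = TRUE) {
  m <- if (inherits(assoc, "assoc_matrix")) assoc$rho else as.matrix(assoc)
  if (anyNA(m))
    stop("association profiles contain missing cells; drop or impute first")
  if (!signed) m <- abs(m)
  if (nrow(m) == 1L) {
    warning("single SNP: returning a 1x1 zero distance matrix")
    return(matrix(0, 1, 1, dimnames = list(rownames(m), rownames(m))))
  }
  as.matrix(dist(m, method = "euclidean"))
}

#' Ward clustering of SNPs into major groups
#'
#' Hierarchical clustering of the association-profile distance matrix with
#' the Ward.D2 criterion, cut into `k` groups.  The default `k = 4` mirrors
#' the four broad environmental groups (e.g. Aridity / Freezing / Geography
#' / Multi) and is a visualization choice, not an inference.
#'
#' @param dist_mat Symmetric distance matrix (or `dist`).
#' @param k Number of groups, `1 <= k <= n`.
#' @return Integer group labels named by SNP id, plus the `hclust` tree as
#'   attribute `"tree"`.
#' @export
ward_cluster_groups <- function(dist_mat, k = 4) {
  d <- if (inherits(dist_mat, "dist")) dist_mat else as.dist(dist_mat)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of SNPs")
  tree <- hclust(d, method = "ward.D2")
  labels <- cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Build the co-association graph
#'
#' Nodes are SNPs; an edge joins two SNPs when their association-profile
#' Euclidean distance is strictly below `threshold` (default 0.1).
#'
#' @param dist_mat Symmetric distance matrix from
#'   [association_distance_matrix()].
#' @param threshold Positive edge threshold.
#' @param groups Optional group labels (e.g. from [ward_cluster_groups()]).
#' @param contig_of_snp Optional named map SNP id -> contig/gene.
#' @return An object of class `coassoc_graph`: list with the `igraph`
#'   object, the node table, `threshold` and the distance matrix.
#' @export
build_coassociation_graph <- function(dist_mat, threshold = 0.1,
                                      groups = NULL, contig_of_snp = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  d <- as.matrix(dist_mat)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(d)))
  adj <- (d < threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  ij <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ij)) igraph::E(g)$distance <- d[ij]
  nodes <- data.frame(snp_id = ids, stringsAsFactors = FALSE)
  nodes$contig_id <- if (!is.null(contig_of_snp))
    as.character(contig_of_snp[ids]) else NA_character_
  nodes$group <- if (!is.null(groups)) as.integer(groups[ids]) else NA_integer_
  out <- structure(list(graph = g, nodes = nodes, threshold = threshold,
                        dist = d), class = "coassoc_graph")
  extract_modules(out)
}

#' Label co-association modules (connected components)
#'
#' @param graph A `coassoc_graph`.
#' @return The graph with `nodes$module` and `nodes$degree` filled in and a
#'   `modules` summary data frame (`module`, `n_snps`, `n_genes`).
#' @export
extract_modules <- function(graph) {
  comp <- igraph::components(graph$graph)
  graph$nodes$module <- comp$membership[graph$nodes$snp_id]
  graph$nodes$degree <- igraph::degree(graph$graph)[graph$nodes$snp_id]
  n_genes <- tapply(graph$nodes$contig_id, graph$nodes$module,
                    function(z) length(unique(z[!is.na(z)])))
  graph$modules <- data.frame(
    module = as.integer(names(table(graph$nodes$module))),
    n_snps = as.integer(table(graph$nodes$module)),
    n_genes = as.integer(n_genes))
  graph
}

#' @export
print.coassoc_graph <- function(x, ...) {
  cat(sprintf(
    "coassoc_graph: %d SNPs, %d edges (distance < %g), %d modules\n",
    nrow(x$nodes), igraph::ecount(x$graph), x$threshold, nrow(x$modules)))
  invisible(x)
}

#' Per-gene environmental pleiotropy table
#'
#' Fraction of each gene's candidate SNPs falling in each co-association
#' module (or major group); rows sum to 1.  Genes whose SNPs span several
#' distinct groups are candidates for environmental pleiotropy.
#'
#' @param graph A `coassoc_graph` with modules extracted, or an integer
#'   partition named by SNP id.
#' @param contig_of_snp Named map SNP id -> contig (defaults to the graph's
#'   node table).
#' @param by `"module"` (default) or `"group"`.
#' @return Genes x modules matrix of proportions.
#' @export
pleiotropy_table <- function(graph, contig_of_snp = NULL, by = "module") {
  if (inherits(graph, "coassoc_graph")) {
    part <- setNames(graph$nodes[[by]], graph$nodes$snp_id)
    if (is.null(contig_of_snp))
      contig_of_snp <- setNames(graph$nodes$contig_id, graph$nodes$snp_id)
  } else part <- graph
  contig <- as.character(contig_of_snp[names(part)])
  if (anyNA(contig)) stop("every SNP must be mapped to a contig")
  tab <- table(contig, part)
  prop <- tab / rowSums(tab)
  unclass(prop)
}

#' Module stability under edge-threshold perturbation
#'
#' Diagnostic report of module count and size distribution at the working
#' threshold and at +/- `delta`: co-association modules tend to be stable
#' when the threshold is raised slightly but can fragment when lowered.
#'
#' @param dist_mat Association-profile distance matrix.
#' @param threshold Working threshold (default 0.1).
#' @param delta Perturbation (default 0.05).
#' @return Data frame with one row per threshold: `threshold`, `n_edges`,
#'   `n_modules`, `n_singletons`, `largest_module`.
#' @export
threshold_stability <- function(dist_mat, threshold = 0.1, delta = 0.05) {
  ths <- unique(pmax(threshold + c(-delta, 0, delta), 1e-9))
  do.call(rbind, lapply(ths, function(th) {
    g <- build_coassociation_graph(dist_mat, th)
    data.frame(threshold = th,
               n_edges = igraph::ecount(g$graph),
               n_modules = nrow(g$modules),
               n_singletons = sum(g$modules$n_snps == 1L),
               largest_module = max(g$modules$n_snps))
  }))
}

#' Export the co-association graph
#'
#' Writes `edges.tsv` (snp_a, snp_b, distance), `nodes.tsv`, `graph.graphml`
#' and `modules.json` under `dir`.
#'
#' @param graph A `coassoc_graph`.
#' @param dir Output directory.
#' @export
write_coassoc_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_edgelist(graph$graph)
  edges <- data.frame(snp_a = el[, 1], snp_b = el[, 2],
                      distance = if (nrow(el)) igraph::E(graph$graph)$distance
                                 else numeric(0))
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(graph$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(graph$graph, file.path(dir, "graph.graphml"),
                      format = "graphml")
  jsonlite::write_json(graph$modules, file.path(dir, "modules.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
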