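# Small programmatic fixtures shared across tests.

# 10 individuals in 3 populations, 3 SNPs with hand-set genotypes
toy_snp_table <- function() {
  g <- rbind(
    c(0L, 2L, 1L), c(1L, 2L, 0L), c(2L, 2L, NA), c(0L, 1L, 1L),  # popA
    c(1L, 2L, 2L), c(0L, 2L, 2L), c(NA, 1L, 1L),                 # popB
    c(0L, 0L, 0L), c(1L, 0L, 1L), c(0L, 1L, NA))                 # popC
  rownames(g) <- paste0("ind", 1:10)
  info <- data.frame(snp_id = c("s1", "s2", "s3"),
                     contig_id = c("gA", "gA", "gB"),
                     position = c(10L, 50L, 5L))
  pops <- setNames(rep(c("popA", "popB", "popC"), c(4, 3, 3)),
                   rownames(g))
  snp_table(g, info, pops)
}

# recode one SNP of a snp_table: swap ancestral/derived
recode_snp <- function(snps, j) {
  g <- snps$genotypes
  g[, j] <- snps$ploidy - g[, j]
  snp_table(g, snps$snp, setNames(snps$individuals$pop_id,
                                  snps$individuals$individual_id),
            ploidy = snps$ploidy)
}

# random complete freq/env pair for property tests
random_freq_env <- function(n_pops, n_snps, n_envs, seed) {
  set.seed(seed)
  f <- matrix(runif(n_pops * n_snps, 0.05, 0.95), n_pops, n_snps,
              dimnames = list(paste0("p", 1:n_pops), paste0("s", 1:n_snps)))
  e <- matrix(rnorm(n_pops * n_envs), n_pops, n_envs,
              dimnames = list(paste0("p", 1:n_pops), paste0("e", 1:n_envs)))
  list(f = freq_matrix(f), e = env_matrix(e))
}

# union-find connected components, independent of igraph
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(n), find, integer(1))
  match(root, unique(root))
}
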