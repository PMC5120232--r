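# In-code fixtures shared across test files.

# brute-force upper-tail hypergeometric probability by direct summation of
# binomial-coefficient ratios; independent of the phyper-based implementation
brute_tail_p <- function(N, M, n, m) {
  ks <- seq(m, min(M, n))
  if (length(ks) == 0L) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# binary entropy in bits
h2 <- function(p) {
  p <- p[p > 0 & p < 1]
  if (length(p) == 0L) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# write a temporary file of lines, returning its path
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small deterministic toy instance used across modules:
# 6 genes, a hand-picked network and two small collections
toy_instance <- function() {
  u <- gene_universe(c("a", "b", "c", "d", "e", "f"))
  edges <- rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                 c("c", "d"), c("d", "e"))
  net <- interaction_network(edges, u)
  go <- term_collection(c("GO:T1", "GO:T2"), c("term one", "term two"),
                        list(c("a", "b", "c"), c("d", "e")), "GO")
  kegg <- term_collection(c("K1", "K2", "K3"),
                          c("path one", "path two", "path three"),
                          list(c("a", "d"), c("b", "c", "e"), c("f", "a")),
                          "KEGG")
  list(universe = u, network = net, go = go, kegg = kegg)
}

# small synthetic config keeping test runtimes low while preserving the
# planted-signal structure
small_config <- function(seed, rho = 0.6) {
  synthetic_config(n_genes = 600L, edge_prob = 0.01, n_go_terms = 60L,
                   n_kegg_terms = 20L, term_size_range = c(8L, 40L),
                   n_informative = 6L, n_positives = 40L, rho = rho,
                   seed = seed)
}

fixture_path <- function() {
  system.file("extdata", "pancreatic_maxrel_top22.tsv", package = "maxrelnet",
              mustWork = TRUE)
}

# rank features of a generated study; returns the ranking data frame with a
# logical `planted` column
rank_study <- function(study) {
  fm <- build_feature_matrix(study$universe, study$network,
                             study$go_collection, study$kegg_collection)
  labels <- label_samples(study$universe, study$positive_ids)
  r <- maxrel(fm, labels)$ranking
  r$planted <- r$feature_id %in% study$planted_term_ids
  r
}
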