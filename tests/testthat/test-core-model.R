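test_that("gene lists are read in file order with comments skipped", {
  p <- tmp_lines(c("# a comment", "g1", "g2", "", "g3"))
  u <- read_gene_list(p)
  expect_s3_class(u, "gene_universe")
  expect_identical(u$genes, c("g1", "g2", "g3"))
  expect_identical(u$size, 3L)
  # order-determinism: same file twice gives the identical object
  expect_identical(read_gene_list(p), u)
})

test_that("duplicate or empty gene lists are rejected", {
  expect_error(read_gene_list(tmp_lines(c("g1", "g1"))), "duplicate.*g1")
  expect_error(read_gene_list(tmp_lines("# only a comment")), "empty universe")
})

test_that("edge lists load symmetrically with self-loops removed", {
  u <- gene_universe(c("a", "b", "c"))
  p <- tmp_lines(c("a\tb", "a\ta", "b\tc"), ext = ".tsv")
  net <- read_edge_list(p, u)
  expect_setequal(gene_neighbors(net, "a"), "b")
  expect_setequal(gene_neighbors(net, "b"), c("a", "c"))
  expect_identical(unname(net$dropped["self_loops"]), 1L)
  # symmetry over all pairs
  for (g in u$genes) {
    for (nb in gene_neighbors(net, g)) {
      expect_true(g %in% gene_neighbors(net, nb))
    }
  }
})

test_that("edges outside the universe are dropped and counted", {
  u <- gene_universe(c("a", "b"))
  p <- tmp_lines(c("a\tb", "b\tc"), ext = ".tsv")
  expect_warning(net <- read_edge_list(p, u), "1 edge.*outside the universe")
  expect_identical(net$n_edges, 1L)
  expect_identical(unname(net$dropped["outside_universe"]), 1L)
  expect_identical(gene_neighbors(net, "c"), character(0))
})

test_that("malformed edge lines error and the score column filters correctly", {
  u <- gene_universe(c("a", "b", "c"))
  expect_error(read_edge_list(tmp_lines(c("a\tb", "justone")), u),
               "malformed network line 2")
  # optional confidence column is ignored unless a cutoff is set
  p <- tmp_lines(c("a\tb\t900", "b\tc\t150"), ext = ".tsv")
  expect_identical(read_edge_list(p, u)$n_edges, 2L)
  expect_identical(read_edge_list(p, u, min_score = 400)$n_edges, 1L)
  p2 <- tmp_lines(c("a\tb\t900", "b\tc"), ext = ".tsv")
  expect_error(read_edge_list(p2, u, min_score = 400),
               "line 2.*score missing")
})

test_that("GMT files parse to ordered term collections", {
  p <- tmp_lines(c("T1\tdesc one\tg1\tg2", "T2\tdesc two\tg3"), ext = ".gmt")
  tc <- read_gmt(p, "KEGG")
  expect_identical(tc$ids, c("T1", "T2"))
  expect_setequal(tc$genesets[["T1"]], c("g1", "g2"))
  expect_identical(tc$category, "KEGG")
  expect_identical(read_gmt(p, "KEGG"), tc)  # deterministic
  expect_error(read_gmt(tmp_lines("T1\tdesc"), "GO"), "malformed GMT line 1")
  expect_error(read_gmt(tmp_lines(c("T1\td\tg1", "T1\td\tg2")), "GO"),
               "duplicate term")
})

test_that("label_samples aligns with universe order and conserves counts", {
  u <- gene_universe(c("a", "b"))
  expect_identical(as.vector(label_samples(u, "a")), c(1L, 0L))
  expect_error(suppressWarnings(label_samples(u, "c")), "no positives")
  expect_warning(label_samples(u, c("a", "zz")), "dropped 1 positive")
  expect_error(label_samples(u, c("a", "b")), "no negatives")

  # property: positives + negatives = universe size for random cases
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    u2 <- gene_universe(sprintf("g%03d", seq_len(n)))
    pos <- sample(u2$genes, sample(seq_len(n - 1L), 1))
    lab <- label_samples(u2, pos)
    expect_identical(sum(lab == 1L) + sum(lab == 0L), n)
    expect_identical(sum(lab), length(pos))
    expect_identical(names(lab), u2$genes)
  }
})

test_that("feature-matrix and ranked-list TSVs round-trip at full precision", {
  toy <- toy_instance()
  fm <- build_feature_matrix(toy$universe, toy$network, toy$go, toy$kegg)
  p <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, p)
  back <- read_feature_matrix(p)
  expect_identical(unclass(back)[, ], unclass(fm)[, ])
  expect_identical(attr(back, "term_ids"), attr(fm, "term_ids"))
  expect_identical(attr(back, "categories"), attr(fm, "categories"))

  fit <- maxrel(fm, label_samples(toy$universe, c("a", "d")))
  p2 <- tempfile(fileext = ".tsv")
  write_ranked_list(fit, p2)
  back2 <- read_ranked_list(p2)
  expect_identical(back2$mi, fit$ranking$mi)
  expect_identical(back2$feature_id, fit$ranking$feature_id)
  expect_identical(back2$rank, fit$ranking$rank)
  expect_identical(names(back2), c("rank", "feature_id", "category", "mi"))
})

test_that("writers fail on unwritable paths", {
  toy <- toy_instance()
  fm <- build_feature_matrix(toy$universe, toy$network, toy$go, toy$kegg)
  expect_error(write_feature_matrix(fm, file.path(tempdir(), "no", "such",
                                                  "dir", "x.tsv")),
               "cannot write")
})
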