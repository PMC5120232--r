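#' Enrichment score of one gene against one term set
#'
#' The score is \eqn{-\log_{10}} of the upper-tail hypergeometric p-value
#' measuring the overlap between the term's gene set (G1, size `M`) and the
#' gene's network neighborhood (G2, size `n`), in a universe of `N` genes
#' with observed overlap `m = |G1 \cap G2|`. Both sets are intersected with
#' the universe before counting so that `N` is consistent across all
#' features. Larger scores indicate a closer association between the gene
#' and the term.
#'
#' Conventions: a gene with an empty neighborhood scores 0 (its overlap is
#' necessarily 0, so p = 1); p-values that underflow to zero are floored at
#' `p_floor` so scores stay finite.
#'
#' @param gene a gene identifier, must belong to the universe.
#' @param term_genes character vector of the term's annotated genes.
#' @param network an [interaction_network()].
#' @param universe a [gene_universe()].
#' @param p_floor smallest admissible p-value (default `1e-320`); scores
#'   are capped at `-log10(p_floor)`.
#' @return A non-negative, finite enrichment score.
#' @export
enrichment_score <- function(gene, term_genes, network, universe,
                             p_floor = 1e-320) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(network, "interaction_network"))
  if (!gene %in% universe$genes) {
    stop(sprintf("gene '%s' is not in the universe", gene), call. = FALSE)
  }
  g1 <- intersect(term_genes, universe$genes)
  if (length(g1) == 0L) {
    stop("term set is empty after universe intersection", call. = FALSE)
  }
  g2 <- intersect(gene_neighbors(network, gene), universe$genes)
  if (length(g2) == 0L) return(0)
  m <- length(intersect(g1, g2))
  p <- upper_tail_hypergeom_p(N = universe$size, M = length(g1),
                              n = length(g2), m = m)
  -log10(max(p, p_floor))
}

#' Build the gene-by-term enrichment feature matrix
#'
#' One row per gene, one column per term: GO columns first (collection
#' order), then KEGG columns. Each cell is the gene's [enrichment_score()]
#' for that term. Overlaps are computed for all gene/term pairs at once via
#' sparse adjacency-by-membership multiplication, chunked over genes to
#' bound memory, so genome-scale tables are feasible; every cell equals the
#' independent per-cell scalar computation.
#'
#' @param universe a [gene_universe()].
#' @param network an [interaction_network()].
#' @param go_collection a `"GO"` [term_collection()].
#' @param kegg_collection a `"KEGG"` [term_collection()].
#' @param genes optional character vector restricting the rows (default:
#'   whole universe, in universe order).
#' @param p_floor smallest admissible p-value, as in [enrichment_score()].
#' @return A numeric matrix of class `feature_matrix` with row names the
#'   genes, column names `"<term id>|<category>"`, and attributes
#'   `term_ids`, `categories` and `term_names`.
#' @export
build_feature_matrix <- function(universe, network, go_collection,
                                 kegg_collection, genes = NULL,
                                 p_floor = 1e-320) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(network, "interaction_network"),
            inherits(go_collection, "term_collection"),
            inherits(kegg_collection, "term_collection"))
  if (go_collection$category != "GO" || kegg_collection$category != "KEGG") {
    stop("collections must be tagged GO and KEGG respectively", call. = FALSE)
  }
  if (is.null(genes)) genes <- universe$genes
  unknown <- setdiff(genes, universe$genes)
  if (length(unknown) > 0L) {
    stop(sprintf("gene '%s' is not in the universe", unknown[1L]),
         call. = FALSE)
  }

  N <- universe$size
  gene_idx <- stats::setNames(seq_len(N), universe$genes)

  term_ids <- c(go_collection$ids, kegg_collection$ids)
  term_names <- c(go_collection$names, kegg_collection$names)
  categories <- c(rep("GO", length(go_collection$ids)),
                  rep("KEGG", length(kegg_collection$ids)))
  sets <- c(go_collection$genesets, kegg_collection$genesets)
  set_idx <- lapply(sets, function(s) unname(gene_idx[intersect(s, universe$genes)]))
  if (any(lengths(set_idx) == 0L)) {
    bad <- term_ids[which(lengths(set_idx) == 0L)[1L]]
    stop(sprintf("term '%s' is empty after universe intersection", bad),
         call. = FALSE)
  }
  n_terms <- length(term_ids)

  # sparse adjacency (symmetric) and term membership
  src <- rep(unname(gene_idx[names(network$adj)]), lengths(network$adj))
  dst <- unname(gene_idx[unlist(network$adj, use.names = FALSE)])
  A <- Matrix::sparseMatrix(i = src, j = dst, x = 1, dims = c(N, N))
  Tm <- Matrix::sparseMatrix(i = unlist(set_idx, use.names = FALSE),
                             j = rep(seq_len(n_terms), lengths(set_idx)),
                             x = 1, dims = c(N, n_terms))

  deg <- Matrix::rowSums(A)              # |G2| per universe gene
  M <- Matrix::colSums(Tm)               # |G1| per term
  rows <- unname(gene_idx[genes])

  out <- matrix(0, nrow = length(rows), ncol = n_terms,
                dimnames = list(genes, paste(term_ids, categories, sep = "|")))
  chunk <- max(1L, as.integer(5e7 / max(1L, n_terms)))
  for (start in seq(1L, length(rows), by = chunk)) {
    block <- rows[start:min(start + chunk - 1L, length(rows))]
    m <- as.matrix(A[block, , drop = FALSE] %*% Tm)
    n_vec <- deg[block]
    p <- phyper(m - 1,
                matrix(M, nrow = length(block), ncol = n_terms, byrow = TRUE),
                matrix(N - M, nrow = length(block), ncol = n_terms, byrow = TRUE),
                matrix(n_vec, nrow = length(block), ncol = n_terms),
                lower.tail = FALSE)
    out[start:(start + length(block) - 1L), ] <- -log10(pmax(pmin(p, 1), p_floor))
  }

  structure(out, term_ids = term_ids, categories = categories,
            term_names = term_names,
            class = c("feature_matrix", class(out)))
}

#' Feature metadata of a feature matrix
#'
#' @param x a `feature_matrix` from [build_feature_matrix()].
#' @return Data frame with columns `feature_id`, `category`, `name`.
#' @export
feature_meta <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  data.frame(feature_id = attr(x, "term_ids"),
             category = attr(x, "categories"),
             name = attr(x, "term_names"),
             stringsAsFactors = FALSE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cats <- table(attr(x, "categories"))
  cat(sprintf("Feature matrix: %d genes x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%d %s", cats, names(cats)), collapse = ", ")))
  invisible(x)
}
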