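#' Construct an undirected interaction network
#'
#' Edges are unordered gene pairs. Self-loops are removed, duplicate edges
#' collapsed, and edges with an endpoint outside the universe are dropped
#' (one warning reports the count; the counts are kept in the object under
#' `dropped`). A gene's neighbor set therefore never contains the gene
#' itself and is always a subset of the universe.
#'
#' @param edges two-column character matrix or data frame (geneA, geneB).
#' @param universe a [gene_universe()].
#' @return An object of class `interaction_network` with fields `adj`
#'   (named list of neighbor character vectors), `n_edges`, `dropped`
#'   (named counts: `outside_universe`, `self_loops`, `duplicates`) and
#'   `universe_size`.
#' @export
interaction_network <- function(edges, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2L) {
    stop("edge table must have at least two columns", call. = FALSE)
  }
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])

  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]

  known <- a %in% universe$genes & b %in% universe$genes
  n_outside <- sum(!known)
  a <- a[known]; b <- b[known]

  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dupe <- duplicated(key)
  n_dup <- sum(dupe)
  a <- a[!dupe]; b <- b[!dupe]

  if (n_outside > 0L) {
    warning(sprintf("dropped %d edge(s) with an endpoint outside the universe",
                    n_outside), call. = FALSE)
  }

  adj <- split(c(b, a), factor(c(a, b), levels = unique(c(a, b))))
  structure(list(adj = adj,
                 n_edges = length(a),
                 dropped = c(outside_universe = n_outside,
                             self_loops = n_self,
                             duplicates = n_dup),
                 universe_size = universe$size),
            class = "interaction_network")
}

#' Read a STRING-style edge list
#'
#' Tab-separated, two required columns (geneA, geneB) and an optional third
#' numeric confidence score. Lines starting with `#` and blank lines are
#' skipped. When `min_score` is given, edges whose score falls below it are
#' discarded before the network is built; without it any score column is
#' ignored.
#'
#' @param path path to the TSV edge list.
#' @param universe a [gene_universe()]; edges touching genes outside it are
#'   dropped with a counted warning.
#' @param min_score optional numeric confidence cutoff (default `NULL`,
#'   keep all edges).
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, universe, min_score = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("malformed network line %d: expected at least 2 tab-separated fields",
                 idx[bad]), call. = FALSE)
  }
  a <- trimws(vapply(fields, `[`, "", 1L))
  b <- trimws(vapply(fields, `[`, "", 2L))
  if (!is.null(min_score)) {
    score <- rep(NA_real_, length(fields))
    has3 <- nf >= 3L
    score[has3] <- suppressWarnings(as.numeric(vapply(fields[has3], `[`, "", 3L)))
    if (anyNA(score)) {
      bad <- which(is.na(score))[1L]
      stop(sprintf("malformed network line %d: confidence score missing or non-numeric",
                   idx[bad]), call. = FALSE)
    }
    keep_s <- score >= min_score
    a <- a[keep_s]; b <- b[keep_s]
  }
  interaction_network(cbind(a, b), universe)
}

#' Neighbor set of a gene
#'
#' @param network an [interaction_network()].
#' @param gene a gene identifier.
#' @return Character vector of neighbors (possibly empty).
#' @export
gene_neighbors <- function(network, gene) {
  stopifnot(inherits(network, "interaction_network"))
  nb <- network$adj[[gene]]
  if (is.null(nb)) character(0) else nb
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d edges over %d genes (%d with neighbors)\n",
              x$n_edges, x$universe_size, length(x$adj)))
  if (any(x$dropped > 0L)) {
    cat("  dropped on load:",
        paste(sprintf("%s=%d", names(x$dropped), x$dropped), collapse = ", "),
        "\n")
  }
  invisible(x)
}
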