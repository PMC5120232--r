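#' Construct a term collection
#'
#' A category-tagged, ordered mapping from term identifiers to annotated
#' gene sets (GO terms or KEGG pathways). Term order is preserved and
#' defines feature-column order within the category.
#'
#' @param ids character vector of unique term identifiers.
#' @param names character vector of term descriptions (same length).
#' @param genesets list of non-empty character vectors of member genes.
#' @param category `"GO"` or `"KEGG"`.
#' @return An object of class `term_collection`.
#' @seealso [read_gmt()]
#' @export
term_collection <- function(ids, names, genesets, category = c("GO", "KEGG")) {
  category <- match.arg(category)
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("empty term collection", call. = FALSE)
  if (length(names) != length(ids) || length(genesets) != length(ids)) {
    stop("ids, names and genesets must have equal length", call. = FALSE)
  }
  dup <- anyDuplicated(ids)
  if (dup > 0L) {
    stop(sprintf("duplicate term identifier '%s'", ids[dup]), call. = FALSE)
  }
  if (any(lengths(genesets) == 0L)) {
    empty <- ids[which(lengths(genesets) == 0L)[1L]]
    stop(sprintf("term '%s' has an empty gene set", empty), call. = FALSE)
  }
  genesets <- lapply(genesets, as.character)
  names(genesets) <- ids
  structure(list(category = category, ids = ids,
                 names = as.character(names), genesets = genesets),
            class = "term_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: tab-separated; column 1 is the term identifier,
#' column 2 a description, columns 3+ the member genes. Entries keep file
#' order. Member genes are not restricted here unless `universe` is given;
#' the enrichment encoder always intersects term sets with the universe at
#' scoring time, so `universe = NULL` is the usual choice.
#'
#' @param path path to the GMT file.
#' @param category `"GO"` or `"KEGG"` tag for every term in the file.
#' @param universe optional [gene_universe()]; if given, member genes
#'   outside it are dropped (counted warning) and terms left empty are
#'   removed (counted warning).
#' @return A [term_collection()].
#' @export
read_gmt <- function(path, category = c("GO", "KEGG"), universe = NULL) {
  category <- match.arg(category)
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields",
                 idx[bad]), call. = FALSE)
  }
  ids <- vapply(fields, `[`, "", 1L)
  nms <- vapply(fields, `[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "gene_universe"))
    before <- sum(lengths(sets))
    sets <- lapply(sets, intersect, universe$genes)
    n_genes_dropped <- before - sum(lengths(sets))
    if (n_genes_dropped > 0L) {
      warning(sprintf("dropped %d annotated gene(s) outside the universe",
                      n_genes_dropped), call. = FALSE)
    }
    nonempty <- lengths(sets) > 0L
    if (any(!nonempty)) {
      warning(sprintf("dropped %d term(s) empty after universe intersection",
                      sum(!nonempty)), call. = FALSE)
      ids <- ids[nonempty]; nms <- nms[nonempty]; sets <- sets[nonempty]
    }
  }
  term_collection(ids, nms, sets, category)
}

#' @export
length.term_collection <- function(x) length(x$ids)

#' @export
print.term_collection <- function(x, ...) {
  sz <- lengths(x$genesets)
  cat(sprintf("Term collection [%s]: %d terms, gene-set sizes %d-%d (median %g)\n",
              x$category, length(x$ids), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}
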