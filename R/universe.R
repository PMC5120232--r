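#' Construct a gene universe
#'
#' The universe is the ordered set of scorable genes. Its size `N` is the
#' population size of every hypergeometric test in the enrichment encoding,
#' so all term sets and neighborhoods are intersected with it before
#' counting.
#'
#' @param genes character vector of unique gene identifiers; order is kept.
#' @return An object of class `gene_universe` with fields `genes` and `size`.
#' @seealso [read_gene_list()]
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("empty universe", call. = FALSE)
  }
  dup <- anyDuplicated(genes)
  if (dup > 0L) {
    stop(sprintf("duplicate gene identifier '%s' in universe", genes[dup]),
         call. = FALSE)
  }
  structure(list(genes = genes, size = length(genes)),
            class = "gene_universe")
}

#' Read a gene universe from a plain-text gene list
#'
#' One identifier per line; lines starting with `#` are comments; blank
#' lines are ignored. File order defines the universe order.
#'
#' @param path path to the gene list file.
#' @return A [gene_universe()].
#' @export
read_gene_list <- function(path) {
  gene_universe(read_id_lines(path))
}

# shared plain-text id-list parser ('#' comments, blank lines skipped)
read_id_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("Gene universe: %d genes (%s%s)\n", x$size,
              paste(head(x$genes, 3L), collapse = ", "),
              if (x$size > 3L) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_universe <- function(x) x$size
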