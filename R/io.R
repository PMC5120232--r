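# TSV writers/readers for the pipeline's tabular artifacts. Numeric values
# are written with %.17g so a write/read round trip reproduces doubles
# exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a feature matrix to TSV
#'
#' Header row `gene` + one `"<term id>|<category>"` column per feature;
#' values at full double precision so a round trip through
#' [read_feature_matrix()] reproduces the matrix exactly.
#'
#' @param x a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  vals <- matrix(fmt_num(x), nrow = nrow(x))
  out <- cbind(gene = rownames(x), vals)
  colnames(out) <- c("gene", colnames(x))
  write_tsv_checked(out, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path path to the TSV.
#' @return A `feature_matrix` (term names are not stored in the TSV and
#'   come back as `NA`).
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") {
    stop("not a feature-matrix TSV: first column must be 'gene'", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("feature columns must be named '<term id>|<category>'", call. = FALSE)
  }
  structure(m,
            term_ids = vapply(parts, `[`, "", 1L),
            categories = vapply(parts, `[`, "", 2L),
            term_names = rep(NA_character_, ncol(m)),
            class = c("feature_matrix", class(m)))
}

#' Write a Max-Relevance ranked list to TSV
#'
#' Columns exactly `rank`, `feature_id`, `category`, `mi_value`, with MI at
#' full double precision.
#'
#' @param ranked a [maxrel()] fit or a ranked-list data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  r <- as_ranking_df(ranked)
  out <- data.frame(rank = r$rank,
                    feature_id = r$feature_id,
                    category = r$category,
                    mi_value = fmt_num(r$mi),
                    stringsAsFactors = FALSE)
  write_tsv_checked(out, path)
  invisible(path)
}

#' Read a ranked list written by [write_ranked_list()]
#'
#' Requires columns `rank`, `feature_id`, `category`, `mi_value`; an
#' optional `name` column (as in the shipped worked-example fixture) is
#' kept.
#'
#' @param path path to the TSV.
#' @return Data frame with columns `rank`, `feature_id`, `category`, `mi`
#'   (and `name` if present).
#' @export
read_ranked_list <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("rank", "feature_id", "category", "mi_value")
  if (!all(need %in% names(df))) {
    stop("ranked-list TSV must have columns rank, feature_id, category, mi_value",
         call. = FALSE)
  }
  keep <- c(need, intersect("name", names(df)))
  df <- df[, keep, drop = FALSE]
  names(df)[names(df) == "mi_value"] <- "mi"
  df$mi <- as.numeric(df$mi)
  as_ranking_df(df)
}

write_tsv_checked <- function(x, path) {
  ok <- tryCatch({
    suppressWarnings(
      write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = TRUE, fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}
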