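#' Label genes as positive (disease) or negative samples
#'
#' Every universe gene named in `positive_ids` gets label 1; all remaining
#' universe genes are treated as negatives (label 0), following the
#' standard construction for rare validated disease-gene sets: positives
#' are the validated genes, negatives everything else that is scorable.
#'
#' @param universe a [gene_universe()].
#' @param positive_ids character vector of positive gene identifiers; ids
#'   outside the universe are dropped with a counted warning.
#' @return Integer 0/1 vector aligned with (and named by) the universe
#'   order, with attribute `n_dropped` giving the number of positive ids
#'   not found in the universe.
#' @export
label_samples <- function(universe, positive_ids) {
  stopifnot(inherits(universe, "gene_universe"))
  positive_ids <- unique(as.character(positive_ids))
  inside <- positive_ids %in% universe$genes
  n_dropped <- sum(!inside)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d positive id(s) not in the universe", n_dropped),
            call. = FALSE)
  }
  pos <- positive_ids[inside]
  if (length(pos) == 0L) stop("no positives", call. = FALSE)
  if (length(pos) == universe$size) stop("no negatives", call. = FALSE)
  labels <- as.integer(universe$genes %in% pos)
  names(labels) <- universe$genes
  attr(labels, "n_dropped") <- n_dropped
  labels
}
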