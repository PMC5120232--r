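#' Discretization rule for mutual-information estimation
#'
#' Continuous enrichment scores are mapped to a small number of states
#' before the plug-in mutual-information estimate. The default is the
#' 3-state coding used by the mRMR reference implementation: values below
#' `mean - alpha*sd` are `low`, above `mean + alpha*sd` are `high`,
#' otherwise `mid`, with the population standard deviation. A 2-state
#' variant splits at the mean.
#'
#' @param num_states 2 or 3 (default 3).
#' @param alpha spread multiplier for the 3-state cutpoints (default 0.5).
#' @return An object of class `discretization_rule`.
#' @export
discretization_rule <- function(num_states = 3L, alpha = 0.5) {
  num_states <- as.integer(num_states)
  if (is.na(num_states) || num_states < 2L) {
    stop("num_states must be an integer >= 2", call. = FALSE)
  }
  if (num_states > 3L) {
    stop("only 2- or 3-state discretization is implemented", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a positive number", call. = FALSE)
  }
  structure(list(num_states = num_states, alpha = alpha),
            class = "discretization_rule")
}

#' Discretize a numeric vector
#'
#' @param x finite numeric vector, length >= 1.
#' @param rule a [discretization_rule()].
#' @return Factor of states: levels `low`/`mid`/`high` (3-state) or
#'   `low`/`high` (2-state). A constant vector maps to all-`mid`
#'   (3-state) or all-`low` (2-state), since its spread is zero.
#' @export
discretize <- function(x, rule = discretization_rule()) {
  stopifnot(inherits(rule, "discretization_rule"))
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("values must be finite numerics", call. = FALSE)
  }
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (rule$num_states == 2L) {
    states <- ifelse(x > mu, "high", "low")
    return(factor(states, levels = c("low", "high")))
  }
  lo <- mu - rule$alpha * sd_pop
  hi <- mu + rule$alpha * sd_pop
  states <- rep("mid", length(x))
  if (sd_pop > 0) {
    states[x < lo] <- "low"
    states[x > hi] <- "high"
  }
  factor(states, levels = c("low", "mid", "high"))
}

#' Plug-in mutual information between two discrete vectors
#'
#' \deqn{I(X;Y) = \sum_{x,y} p(x,y) \log_b \frac{p(x,y)}{p(x)\,p(y)}}
#' with empirical frequencies as the probabilities and `0 log 0 = 0`.
#' Base 2 (bits) by default. The estimator is symmetric, non-negative and
#' invariant under relabeling of states.
#'
#' @param x,y vectors of equal length (>= 2); any discrete coding
#'   (factor, character, integer) works.
#' @param base logarithm base (default 2).
#' @return Mutual information, a non-negative number.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y)) {
    stop("length mismatch between the two vectors", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  expected <- outer(px, py)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / expected[nz], base = base))
  max(mi, 0)
}

#' Max-Relevance ranking of features against a binary label
#'
#' The Max-Relevance criterion of mRMR: each feature column is discretized
#' (see [discretization_rule()]) and scored by its mutual information with
#' the binary class label; features are then ranked by MI in non-increasing
#' order. Ties keep the original column order. No Min-Redundancy step is
#' applied: the goal is to rank individual features by relevance, not to
#' assemble a minimal predictive subset.
#'
#' @param x a `feature_matrix` from [build_feature_matrix()], or any
#'   numeric matrix / data frame with one column per feature.
#' @param labels binary (0/1 or logical) vector, one element per row of
#'   `x`; both classes must be present.
#' @param rule a [discretization_rule()].
#' @param base logarithm base for the MI (default 2, bits).
#' @return An object of class `maxrel` with component `ranking`, a data
#'   frame with columns `rank`, `feature_id`, `category`, `mi` sorted by
#'   non-increasing `mi`, plus fit metadata. Methods: `print`, `summary`,
#'   `plot`, `as.data.frame`.
#' @examples
#' x <- cbind(signal = c(5, 5, 0, 0, 0, 0), noise = c(1, 0, 1, 0, 1, 0))
#' fit <- maxrel(x, labels = c(1, 1, 0, 0, 0, 0))
#' fit$ranking
#' @export
maxrel <- function(x, labels, rule = discretization_rule(), base = 2) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("x must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (length(labels) != nrow(x)) {
    stop("labels must have one element per row of x", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; both classes are required",
         call. = FALSE)
  }
  feature_id <- colnames(x)
  if (is.null(feature_id)) feature_id <- sprintf("f%d", seq_len(ncol(x)))
  category <- attr(x, "categories")
  if (is.null(category)) category <- rep(NA_character_, ncol(x))
  term_names <- attr(x, "term_names")
  if (!is.null(attr(x, "term_ids"))) feature_id <- attr(x, "term_ids")

  labf <- factor(labels, levels = c(0L, 1L))
  mi <- vapply(seq_len(ncol(x)), function(j) {
    mutual_information(labf, discretize(x[, j], rule), base = base)
  }, numeric(1))

  ord <- order(-mi, seq_along(mi))
  ranking <- data.frame(rank = seq_along(ord),
                        feature_id = feature_id[ord],
                        category = category[ord],
                        mi = mi[ord],
                        stringsAsFactors = FALSE)
  if (!is.null(term_names)) ranking$name <- term_names[ord]
  structure(list(ranking = ranking,
                 n_samples = nrow(x),
                 n_features = ncol(x),
                 n_positive = sum(labels == 1L),
                 rule = rule,
                 base = base,
                 call = match.call()),
            class = "maxrel")
}

#' @export
print.maxrel <- function(x, n = 10L, ...) {
  cat(sprintf("Max-Relevance ranking: %d features, %d samples (%d positive)\n",
              x$n_features, x$n_samples, x$n_positive))
  cat(sprintf("MI in bits (log base %g), %d-state discretization (alpha = %g)\n",
              x$base, x$rule$num_states, x$rule$alpha))
  print(head(x$ranking, n), row.names = FALSE)
  if (nrow(x$ranking) > n) cat(sprintf("... %d more\n", nrow(x$ranking) - n))
  invisible(x)
}

#' @export
summary.maxrel <- function(object, ...) {
  r <- object$ranking
  cat(sprintf("Max-Relevance ranking of %d features (%d samples, %d positive)\n",
              object$n_features, object$n_samples, object$n_positive))
  cat("MI distribution:\n")
  print(summary(r$mi))
  if (!all(is.na(r$category))) {
    cat("Features per category:\n")
    print(table(r$category))
  }
  cat("Top features:\n")
  print(head(r, 10L), row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.maxrel <- function(x, ...) x$ranking

#' @export
plot.maxrel <- function(x, tau = NULL, ...) {
  r <- x$ranking
  graphics::plot(r$rank, r$mi, type = "h", xlab = "rank",
                 ylab = sprintf("mutual information (log base %g)", x$base),
                 main = "Max-Relevance feature ranking", ...)
  if (!is.null(tau)) graphics::abline(h = tau, lty = 2, col = "red3")
  invisible(x)
}

# normalize a maxrel object or a ranked-list data frame to the internal
# (rank, feature_id, category, mi[, name]) shape, validating sortedness
as_ranking_df <- function(ranked) {
  if (inherits(ranked, "maxrel")) {
    r <- ranked$ranking
  } else if (is.data.frame(ranked)) {
    r <- ranked
    if ("mi_value" %in% names(r) && !"mi" %in% names(r)) {
      names(r)[names(r) == "mi_value"] <- "mi"
    }
    need <- c("rank", "feature_id", "category", "mi")
    if (!all(need %in% names(r))) {
      stop("ranked list must have columns rank, feature_id, category, mi_value",
           call. = FALSE)
    }
  } else {
    stop("ranked must be a maxrel fit or a ranked-list data frame",
         call. = FALSE)
  }
  if (nrow(r) > 1L && any(diff(r$mi) > 0)) {
    stop("ranked list is not sorted by non-increasing MI", call. = FALSE)
  }
  if (anyNA(r$mi) || any(r$mi < 0)) {
    stop("MI values must be non-negative and finite", call. = FALSE)
  }
  r
}

#' Select features with MI at or above a threshold
#'
#' Keeps the prefix of the Max-Relevance list whose (full-precision) MI is
#' `>= tau` — an inclusive threshold, so features exactly at `tau` are
#' retained. Global ranks are preserved.
#'
#' @param ranked a [maxrel()] fit or a ranked-list data frame with columns
#'   `rank`, `feature_id`, `category`, `mi_value` (as written by
#'   [write_ranked_list()] / read by [read_ranked_list()]).
#' @param tau MI threshold, `>= 0` (default 0.01).
#' @return An object of class `maxrel_selection` with fields `tau`,
#'   `selected` (data frame preserving global ranks) and `n_total`.
#' @export
select_features <- function(ranked, tau = 0.01) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("tau must be a single non-negative number", call. = FALSE)
  }
  r <- as_ranking_df(ranked)
  structure(list(tau = tau,
                 selected = r[r$mi >= tau, , drop = FALSE],
                 n_total = nrow(r)),
            class = "maxrel_selection")
}

#' @export
print.maxrel_selection <- function(x, ...) {
  cat(sprintf("Selected %d of %d features with MI >= %g\n",
              nrow(x$selected), x$n_total, x$tau))
  if (nrow(x$selected) > 0L && !all(is.na(x$selected$category))) {
    print(table(x$selected$category))
  }
  print(head(x$selected, 25L), row.names = FALSE)
  invisible(x)
}

#' Split a selection into KEGG and GO report tables
#'
#' Reproduces the usual two-table report layout: one table of selected KEGG
#' pathways and one of selected GO terms, each in global-rank order with
#' columns `feature_id`, `name`, `mi`, `rank` (rank is the global rank in
#' the full Max-Relevance list, not renumbered per table).
#'
#' @param selection a `maxrel_selection` from [select_features()].
#' @return Named list with data frames `kegg` and `go`.
#' @export
partition_by_category <- function(selection) {
  stopifnot(inherits(selection, "maxrel_selection"))
  s <- selection$selected
  if (nrow(s) > 0L) {
    bad <- setdiff(unique(s$category), c("GO", "KEGG"))
    if (length(bad) > 0L) {
      stop(sprintf("unknown feature category '%s'", bad[1L]), call. = FALSE)
    }
  }
  if (!"name" %in% names(s)) s$name <- NA_character_
  cols <- c("feature_id", "name", "mi", "rank")
  list(kegg = s[s$category == "KEGG", cols, drop = FALSE],
       go = s[s$category == "GO", cols, drop = FALSE])
}
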