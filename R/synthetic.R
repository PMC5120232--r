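#' Configuration of a synthetic planted-signal study
#'
#' Defines the study conditions the generator emulates: a sparse undirected
#' gene network over a few thousand genes, a few hundred GO-like and a few
#' dozen KEGG-like gene sets of realistic sizes, a small positive class,
#' and a handful of "informative" (planted) terms whose members are
#' over-represented among the positives' network neighbors.
#'
#' Defaults give 2,000 genes, an Erdős–Rényi background network with edge
#' probability 0.004 (mean degree about 8, of the order of a
#' high-confidence PPI network), 280 GO + 60 KEGG terms of 10–80 genes,
#' 10 planted terms (split across categories proportionally to their
#' sizes: 8 GO, 2 KEGG), 60 positives, and enrichment strength `rho = 0.6`.
#'
#' @param n_genes universe size.
#' @param edge_prob background edge probability of the Erdős–Rényi network.
#' @param n_go_terms,n_kegg_terms total term count per category (planted
#'   terms are drawn from among these).
#' @param term_size_range integer min/max genes per term.
#' @param n_informative number of planted informative terms.
#' @param n_positives number of positive (disease) genes.
#' @param rho enrichment strength in \[0, 1\]: the fraction of each positive
#'   gene's edges rewired toward planted-term members (0 = pure null).
#' @param seed integer seed; all randomness in [generate_study()] flows
#'   from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L, edge_prob = 0.004,
                             n_go_terms = 280L, n_kegg_terms = 60L,
                             term_size_range = c(10L, 80L),
                             n_informative = 10L, n_positives = 60L,
                             rho = 0.6, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), edge_prob = edge_prob,
              n_go_terms = as.integer(n_go_terms),
              n_kegg_terms = as.integer(n_kegg_terms),
              term_size_range = as.integer(term_size_range),
              n_informative = as.integer(n_informative),
              n_positives = as.integer(n_positives),
              rho = rho, seed = as.integer(seed))
  if (cfg$n_genes < 2L) stop("n_genes must be >= 2", call. = FALSE)
  if (edge_prob < 0 || edge_prob > 1) {
    stop("edge_prob must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_positives >= cfg$n_genes || cfg$n_positives < 1L) {
    stop("n_positives must be in [1, n_genes)", call. = FALSE)
  }
  if (cfg$n_informative > cfg$n_go_terms + cfg$n_kegg_terms) {
    stop("n_informative exceeds the total number of terms", call. = FALSE)
  }
  if (cfg$n_go_terms < 1L || cfg$n_kegg_terms < 1L) {
    stop("need at least one term per category", call. = FALSE)
  }
  if (length(cfg$term_size_range) != 2L ||
      cfg$term_size_range[1L] < 1L ||
      cfg$term_size_range[1L] > cfg$term_size_range[2L]) {
    stop("term_size_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (cfg$term_size_range[2L] > cfg$n_genes) {
    stop("term size exceeds the universe size", call. = FALSE)
  }
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# decode 1-based pair indices (column-major upper triangle of an n x n
# matrix: (1,2),(1,3),(2,3),(1,4),...) into (i, j) with i < j
decode_pair_index <- function(k, n) {
  j <- floor((1 + sqrt(8 * k - 7)) / 2) + 1
  # guard against sqrt rounding at large k
  j <- j - (choose(j - 1, 2) >= k)
  j <- j + (choose(j, 2) < k)
  i <- k - choose(j - 1, 2)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Generate a synthetic planted-signal study
#'
#' Produces a complete, reproducible study: universe, Erdős–Rényi
#' background network, GO-like and KEGG-like term collections, a positive
#' gene set and a set of planted informative terms. The signal mechanism is
#' edge *rewiring*: each positive gene redirects `max(1, round(rho *
#' degree))` of its edges (one added edge if its degree is 0; none at all
#' when `rho = 0`) toward members of the planted terms, assigned
#' round-robin over a random permutation of the planted terms. Rewiring
#' rather than edge addition keeps positives' degrees equal to their
#' background degrees, so degree itself carries no signal; what rises is
#' the overlap `m` between positives' neighborhoods and planted-term gene
#' sets, hence those terms' enrichment scores and MI.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_study`: list with `universe`,
#'   `network`, `go_collection`, `kegg_collection`, `positive_ids`,
#'   `planted_term_ids` and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  universe <- gene_universe(genes)

  # Erdős–Rényi background: draw the edge count, then distinct pair indices
  n_pairs <- n * (n - 1) / 2
  n_edges <- stats::rbinom(1L, n_pairs, config$edge_prob)
  adj <- vector("list", n)
  if (n_edges > 0L) {
    pairs <- decode_pair_index(sort(sample(n_pairs, n_edges)), n)
    for (gi in seq_len(n)) adj[[gi]] <- integer(0)
    sp_i <- split(pairs[, "i"], pairs[, "j"])
    sp_j <- split(pairs[, "j"], pairs[, "i"])
    for (g in names(sp_j)) adj[[as.integer(g)]] <- sp_j[[g]]
    for (g in names(sp_i)) {
      gi <- as.integer(g)
      adj[[gi]] <- c(adj[[gi]], sp_i[[g]])
    }
  } else {
    for (gi in seq_len(n)) adj[[gi]] <- integer(0)
  }

  # term collections: sizes uniform in range, members uniform without
  # replacement; terms may overlap, as real GO terms do
  draw_terms <- function(n_terms) {
    sizes <- sample(seq(config$term_size_range[1L], config$term_size_range[2L]),
                    n_terms, replace = TRUE)
    lapply(sizes, function(s) sort(sample.int(n, s)))
  }
  go_sets <- draw_terms(config$n_go_terms)
  kegg_sets <- draw_terms(config$n_kegg_terms)

  # positives and planted terms (planted split proportionally by category)
  positives <- sort(sample.int(n, config$n_positives))
  n_total_terms <- config$n_go_terms + config$n_kegg_terms
  n_pl_go <- min(config$n_go_terms,
                 round(config$n_informative * config$n_go_terms / n_total_terms))
  n_pl_kegg <- config$n_informative - n_pl_go
  if (n_pl_kegg > config$n_kegg_terms) {
    n_pl_go <- n_pl_go + (n_pl_kegg - config$n_kegg_terms)
    n_pl_kegg <- config$n_kegg_terms
  }
  planted_go <- if (n_pl_go > 0L) sort(sample.int(config$n_go_terms, n_pl_go)) else integer(0)
  planted_kegg <- if (n_pl_kegg > 0L) sort(sample.int(config$n_kegg_terms, n_pl_kegg)) else integer(0)
  planted_sets <- c(go_sets[planted_go], kegg_sets[planted_kegg])

  # rewire a rho fraction of each positive's edges toward planted members
  if (config$rho > 0 && length(planted_sets) > 0L) {
    for (p in positives) {
      d0 <- length(adj[[p]])
      k_total <- if (d0 == 0L) 1L else max(1L, as.integer(round(config$rho * d0)))
      rewire <- if (d0 > 0L) {
        sample(adj[[p]], min(k_total, d0))
      } else integer(0)
      term_order <- rep(sample(seq_along(planted_sets)), length.out = k_total)
      for (r in seq_len(k_total)) {
        members <- planted_sets[[term_order[r]]]
        cand <- setdiff(members, c(p, adj[[p]]))
        if (length(cand) == 0L) next
        v <- cand[sample.int(length(cand), 1L)]
        if (r <= length(rewire)) {
          u <- rewire[r]
          adj[[p]] <- setdiff(adj[[p]], u)
          adj[[u]] <- setdiff(adj[[u]], p)
        }
        adj[[p]] <- c(adj[[p]], v)
        adj[[v]] <- c(adj[[v]], p)
      }
    }
  }

  # assemble package objects
  deg <- lengths(adj)
  src <- rep(seq_len(n), deg)
  dst <- unlist(adj, use.names = FALSE)
  upper <- src < dst
  edges <- cbind(genes[src[upper]], genes[dst[upper]])
  network <- interaction_network(edges, universe)

  go_ids <- sprintf("sGO:%04d", seq_len(config$n_go_terms))
  kegg_ids <- sprintf("sKEGG:%04d", seq_len(config$n_kegg_terms))
  go_collection <- term_collection(
    go_ids, sprintf("synthetic GO-like term %d", seq_len(config$n_go_terms)),
    lapply(go_sets, function(s) genes[s]), "GO")
  kegg_collection <- term_collection(
    kegg_ids, sprintf("synthetic KEGG-like pathway %d", seq_len(config$n_kegg_terms)),
    lapply(kegg_sets, function(s) genes[s]), "KEGG")

  structure(list(universe = universe,
                 network = network,
                 go_collection = go_collection,
                 kegg_collection = kegg_collection,
                 positive_ids = genes[positives],
                 planted_term_ids = c(go_ids[planted_go], kegg_ids[planted_kegg]),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study (seed %d): %d genes, %d edges, ",
                     "%d GO + %d KEGG terms (%d planted), %d positives, rho = %g\n"),
              x$config$seed, x$universe$size, x$network$n_edges,
              length(x$go_collection), length(x$kegg_collection),
              length(x$planted_term_ids), length(x$positive_ids),
              x$config$rho))
  invisible(x)
}

#' Write a synthetic study to the pipeline's input formats
#'
#' Emits exactly what [run_pipeline()] consumes: a gene list, a TSV edge
#' list, two GMT files, a positives list, a JSON manifest (config, seed,
#' planted term ids) and a ready-to-run `config.yaml`.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir),
                             call. = FALSE)
  paths <- c(universe = file.path(dir, "genes.txt"),
             edges = file.path(dir, "edges.tsv"),
             go_gmt = file.path(dir, "go_terms.gmt"),
             kegg_gmt = file.path(dir, "kegg_pathways.gmt"),
             positives = file.path(dir, "positives.txt"),
             manifest = file.path(dir, "manifest.json"),
             config = file.path(dir, "config.yaml"))

  writeLines(c("# synthetic gene universe", study$universe$genes),
             paths["universe"])
  # edge list, one undirected edge per line, endpoints in universe order
  adj <- study$network$adj
  src <- rep(names(adj), lengths(adj))
  dst <- unlist(adj, use.names = FALSE)
  upper <- src < dst
  ord <- order(src[upper], dst[upper], method = "radix")
  writeLines(paste(src[upper][ord], dst[upper][ord], sep = "\t"),
             paths["edges"])
  write_gmt <- function(coll, path) {
    writeLines(vapply(seq_along(coll$ids), function(i) {
      paste(c(coll$ids[i], coll$names[i], coll$genesets[[i]]), collapse = "\t")
    }, ""), path)
  }
  write_gmt(study$go_collection, paths["go_gmt"])
  write_gmt(study$kegg_collection, paths["kegg_gmt"])
  writeLines(c("# synthetic positive (disease) genes", study$positive_ids),
             paths["positives"])
  jsonlite::write_json(
    list(config = unclass(study$config),
         planted_term_ids = study$planted_term_ids,
         n_edges = study$network$n_edges),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(
    list(universe = "genes.txt", edges = "edges.tsv",
         go_gmt = "go_terms.gmt", kegg_gmt = "kegg_pathways.gmt",
         positives = "positives.txt", output_dir = "results",
         discretization = list(num_states = 3L, alpha = 0.5),
         mi_log_base = 2, tau = 0.01, write_feature_matrix = TRUE),
    paths["config"])
  invisible(paths)
}
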