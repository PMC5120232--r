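#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: input paths, the optional
#' edge-confidence cutoff, discretization settings, the MI log base and the
#' selection threshold.
#'
#' @param universe,edges,go_gmt,kegg_gmt,positives input file paths (gene
#'   list, TSV edge list, two GMT files, positive gene list).
#' @param output_dir directory for the run artifacts.
#' @param min_edge_score optional numeric confidence cutoff for the edge
#'   list (default `NULL`, keep all edges).
#' @param num_states,alpha discretization settings, see
#'   [discretization_rule()].
#' @param mi_log_base logarithm base for the MI (default 2).
#' @param tau MI selection threshold (default 0.01).
#' @param write_feature_matrix whether to write the (possibly large)
#'   feature-matrix TSV (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(universe, edges, go_gmt, kegg_gmt, positives,
                            output_dir, min_edge_score = NULL,
                            num_states = 3L, alpha = 0.5, mi_log_base = 2,
                            tau = 0.01, write_feature_matrix = TRUE) {
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  structure(list(universe = universe, edges = edges, go_gmt = go_gmt,
                 kegg_gmt = kegg_gmt, positives = positives,
                 output_dir = output_dir, min_edge_score = min_edge_score,
                 num_states = as.integer(num_states), alpha = alpha,
                 mi_log_base = mi_log_base, tau = tau,
                 write_feature_matrix = isTRUE(write_feature_matrix)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative input paths are resolved against the YAML file's directory.
#' Recognized keys: `universe`, `edges`, `go_gmt`, `kegg_gmt`, `positives`,
#' `output_dir`, `min_edge_score`, `discretization` (`num_states`,
#' `alpha`), `mi_log_base`, `tau`, `write_feature_matrix`.
#'
#' @param path path to the YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  need <- c("universe", "edges", "go_gmt", "kegg_gmt", "positives", "output_dir")
  missing <- setdiff(need, names(y))
  if (length(missing) > 0L) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  disc <- y$discretization
  pipeline_config(
    universe = resolve(y$universe), edges = resolve(y$edges),
    go_gmt = resolve(y$go_gmt), kegg_gmt = resolve(y$kegg_gmt),
    positives = resolve(y$positives), output_dir = resolve(y$output_dir),
    min_edge_score = y$min_edge_score,
    num_states = if (is.null(disc$num_states)) 3L else disc$num_states,
    alpha = if (is.null(disc$alpha)) 0.5 else disc$alpha,
    mi_log_base = if (is.null(y$mi_log_base)) 2 else y$mi_log_base,
    tau = if (is.null(y$tau)) 0.01 else y$tau,
    write_feature_matrix = if (is.null(y$write_feature_matrix)) TRUE
                           else y$write_feature_matrix)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full encode–rank–select pipeline
#'
#' Reads the inputs, labels the genes, builds the enrichment feature
#' matrix, ranks the features by Max-Relevance MI, selects those with MI at
#' or above `tau`, and writes deterministic artifacts to
#' `config$output_dir`: `feature_matrix.tsv` (optional),
#' `maxrel_ranking.tsv`, `selected_kegg.tsv`, `selected_go.tsv` and a JSON
#' `run_manifest.json` (config echo, input MD5 checksums, row/column
#' counts). Rerunning on identical inputs reproduces the outputs
#' byte-for-byte. Any stage error aborts with a stage-named message.
#'
#' @param config a [pipeline_config()] or the path to a YAML config.
#' @param verbose print progress messages (default `FALSE`).
#' @return Invisibly, a list with the `maxrel` fit, the selection, the
#'   per-category tables and the artifact paths.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  inputs <- with_stage("load", {
    for (p in c(config$universe, config$edges, config$go_gmt,
                config$kegg_gmt, config$positives)) {
      if (!file.exists(p)) stop(sprintf("input file not found: '%s'", p))
    }
    universe <- read_gene_list(config$universe)
    network <- read_edge_list(config$edges, universe,
                              min_score = config$min_edge_score)
    say("loaded %d genes, %d edges (dropped: %s)", universe$size,
        network$n_edges,
        paste(sprintf("%s=%d", names(network$dropped), network$dropped),
              collapse = ", "))
    go <- read_gmt(config$go_gmt, "GO")
    kegg <- read_gmt(config$kegg_gmt, "KEGG")
    say("loaded %d GO and %d KEGG terms", length(go), length(kegg))
    list(universe = universe, network = network, go = go, kegg = kegg,
         positive_ids = read_id_lines(config$positives))
  })

  labels <- with_stage("label",
    label_samples(inputs$universe, inputs$positive_ids))
  say("labeled %d positives / %d negatives", sum(labels == 1L),
      sum(labels == 0L))

  fm <- with_stage("encode",
    build_feature_matrix(inputs$universe, inputs$network, inputs$go,
                         inputs$kegg))
  say("encoded %d genes x %d features", nrow(fm), ncol(fm))

  rule <- discretization_rule(config$num_states, config$alpha)
  fit <- with_stage("rank", maxrel(fm, labels, rule = rule,
                                   base = config$mi_log_base))
  sel <- with_stage("select", select_features(fit, tau = config$tau))
  tables <- with_stage("select", partition_by_category(sel))
  say("selected %d features (%d KEGG, %d GO) at tau = %g",
      nrow(sel$selected), nrow(tables$kegg), nrow(tables$go), config$tau)

  paths <- with_stage("write", {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- c(ranking = file.path(config$output_dir, "maxrel_ranking.tsv"),
             kegg = file.path(config$output_dir, "selected_kegg.tsv"),
             go = file.path(config$output_dir, "selected_go.tsv"),
             manifest = file.path(config$output_dir, "run_manifest.json"))
    write_ranked_list(fit, out["ranking"])
    write_selection_table(tables$kegg, out["kegg"])
    write_selection_table(tables$go, out["go"])
    if (config$write_feature_matrix) {
      out <- c(out, features = file.path(config$output_dir,
                                         "feature_matrix.tsv"))
      write_feature_matrix(fm, out["features"])
    }
    infiles <- c(universe = config$universe, edges = config$edges,
                 go_gmt = config$go_gmt, kegg_gmt = config$kegg_gmt,
                 positives = config$positives)
    md5 <- tools::md5sum(unname(infiles))
    names(md5) <- names(infiles)
    manifest <- list(
      config = unclass(config),
      input_md5 = as.list(md5),
      counts = list(n_genes = inputs$universe$size,
                    n_edges = inputs$network$n_edges,
                    n_features = ncol(fm),
                    n_go_terms = length(inputs$go),
                    n_kegg_terms = length(inputs$kegg),
                    n_positives = sum(labels == 1L),
                    n_negatives = sum(labels == 0L),
                    n_selected = nrow(sel$selected)))
    jsonlite::write_json(manifest, out["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    out
  })

  invisible(list(fit = fit, selection = sel, tables = tables, paths = paths))
}

# per-category report table: id, name, MI, global rank
write_selection_table <- function(tab, path) {
  out <- data.frame(feature_id = tab$feature_id,
                    name = tab$name,
                    mi_value = fmt_num(tab$mi),
                    rank = tab$rank,
                    stringsAsFactors = FALSE)
  write_tsv_checked(out, path)
  invisible(path)
}
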