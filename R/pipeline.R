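# End-to-end orchestration: ingest -> classify -> network -> report.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline; the defaults
#' reproduce the reference analysis choices exactly (1.5-sigma residual
#' band, phi t-test at 0.01, 2.56 log-RR confidence multiplier, minimum
#' core degree 5, PageRank damping 0.85).
#'
#' @param waking_path TSV mention table for the waking corpus.
#' @param reports_path JSONL dream-report file.
#' @param output_dir Directory for artifacts (created if missing).
#' @param k_sigma Residual threshold in standard deviations.
#' @param alpha Edge-filter significance level.
#' @param ci_multiplier Confidence multiplier on log RR.
#' @param min_core_degree Degree threshold of the network core.
#' @param damping PageRank damping factor.
#' @param lb_threshold Minimum lower confidence bound of RR for an edge.
#' @param phi_threshold Minimum phi for an edge.
#' @param weighted_pagerank Use edge weights in PageRank.
#' @param top_k Number of rows in the top-condition tables.
#' @param seed Integer seed recorded in the run log (the pipeline itself
#'   is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(waking_path, reports_path, output_dir,
                            k_sigma = 1.5, alpha = 0.01,
                            ci_multiplier = 2.56, min_core_degree = 5L,
                            damping = 0.85, lb_threshold = 1,
                            phi_threshold = 0, weighted_pagerank = TRUE,
                            top_k = 20L, seed = 1L) {
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop("`damping` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    waking_path = waking_path,
    reports_path = reports_path,
    output_dir = output_dir,
    k_sigma = check_positive_real(k_sigma, "k_sigma"),
    alpha = as.numeric(alpha),
    ci_multiplier = check_positive_real(ci_multiplier, "ci_multiplier"),
    min_core_degree = check_count(min_core_degree, "min_core_degree"),
    damping = as.numeric(damping),
    lb_threshold = as.numeric(lb_threshold),
    phi_threshold = as.numeric(phi_threshold),
    weighted_pagerank = isTRUE(weighted_pagerank),
    top_k = check_count(top_k, "top_k"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)),
    class = "pipeline_config")
}

#' Top-k conditions by count
#'
#' Ties are broken lexicographically so the table is deterministic.
#'
#' @param counts Named count vector or table.
#' @param k Number of rows; if larger than the table, the full table is
#'   returned.
#' @return Data frame `condition`, `count`, ordered by decreasing count.
#' @export
top_conditions <- function(counts, k) {
  k <- check_count(k, "k")
  counts <- as_named_counts(counts)
  ord <- order(-as.numeric(counts), names(counts))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(condition = names(counts)[ord],
             count = as.integer(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Ingests the two corpora, classifies conditions by relative rank
#' prevalence, builds the filtered co-occurrence network, and writes all
#' artifacts to the output directory: `classification.tsv`,
#' `iterations.json`, `network.graphml`, `edges.tsv`, `metrics.json` and
#' `run_log.txt`.  Deterministic given the configuration and inputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report` summarising corpus totals,
#'   class counts, network counts before/after filtering, giant
#'   component, per-class mean PageRank, assortativity and top-condition
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  mentions <- run_stage("ingest", read_mentions(config$waking_path))
  reports <- run_stage("ingest", read_reports(config$reports_path))

  counts_w <- run_stage("count", count_frequencies(mentions))
  counts_d <- run_stage("count", count_frequencies(reports))

  classification <- run_stage("classify",
    classify_conditions(counts_w, counts_d, k_sigma = config$k_sigma))

  network <- run_stage("network", condition_network(
    reports, classes = classification, alpha = config$alpha,
    lb_threshold = config$lb_threshold,
    phi_threshold = config$phi_threshold,
    ci_multiplier = config$ci_multiplier, damping = config$damping,
    weighted = config$weighted_pagerank))

  giant <- run_stage("network", giant_component(network))
  core <- run_stage("network",
                    extract_core(network, config$min_core_degree))
  mean_pr <- class_mean_pagerank(network)

  cls_tab <- classification$table
  report <- structure(list(
    corpus_totals = list(
      waking = list(records = length(unique(mentions$record_id)),
                    mentions = nrow(mentions),
                    unique_conditions = length(counts_w)),
      dreams = list(records = length(reports),
                    mentions = sum(lengths(lapply(reports, unique))),
                    unique_conditions = length(counts_d))),
    class_counts = as.list(table(factor(cls_tab$class,
                                        levels = CONDITION_CLASSES))),
    class_by_provenance = table(cls_tab$class, cls_tab$provenance),
    network = list(
      nodes_before_filter = network$n_nodes_before,
      edges_before_filter = network$n_edges_before,
      nodes_after_filter = network$n_nodes,
      edges_after_filter = network$n_edges,
      initial_singletons = length(network$singletons_initial),
      degenerate_edges = network$n_degenerate_edges,
      giant_component_nodes = if (length(giant$sizes)) giant$sizes[1] else 0L,
      giant_component_edges = igraph::ecount(giant$graph),
      n_components = giant$n_components,
      core_nodes = igraph::vcount(core),
      core_edges = igraph::ecount(core)),
    class_mean_pagerank = mean_pr,
    assortativity = network$assortativity,
    top_waking = top_conditions(counts_w, config$top_k),
    top_dreams = top_conditions(counts_d, config$top_k),
    config = config),
    class = "run_report")

  run_stage("write", {
    write_classification(classification,
                         file.path(config$output_dir, "classification.tsv"))
    write_iteration_trace(classification,
                          file.path(config$output_dir, "iterations.json"))
    write_network_graphml(network,
                          file.path(config$output_dir, "network.graphml"))
    write_edge_list(network, file.path(config$output_dir, "edges.tsv"))
    metrics <- list(
      corpus_totals = report$corpus_totals,
      class_counts = report$class_counts,
      network = report$network,
      class_mean_pagerank = as.list(report$class_mean_pagerank),
      assortativity = report$assortativity,
      parameters = config[setdiff(names(config),
                                  c("waking_path", "reports_path",
                                    "output_dir"))])
    jsonlite::write_json(metrics,
                         file.path(config$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    log_lines <- c(
      "dreamnet pipeline run",
      sprintf("seed: %d", config$seed),
      sprintf("parameters: k_sigma=%g alpha=%g ci_multiplier=%g min_core_degree=%d damping=%g lb_threshold=%g phi_threshold=%g weighted_pagerank=%s",
              config$k_sigma, config$alpha, config$ci_multiplier,
              config$min_core_degree, config$damping, config$lb_threshold,
              config$phi_threshold, config$weighted_pagerank),
      sprintf("waking mentions: %d rows (%d malformed dropped)",
              nrow(mentions), attr(mentions, "n_malformed") %||% 0L),
      sprintf("dream reports: %d", length(reports)),
      sprintf("classifier iterations: %d", length(classification$iterations)),
      sprintf("degenerate edges excluded: %d", network$n_degenerate_edges),
      sprintf("initial singleton conditions discarded: %d",
              length(network$singletons_initial)))
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  })

  report$classification <- classification
  report$network_model <- network
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  waking: %d mentions, %d unique conditions\n",
              x$corpus_totals$waking$mentions,
              x$corpus_totals$waking$unique_conditions))
  cat(sprintf("  dreams: %d reports, %d unique conditions\n",
              x$corpus_totals$dreams$records,
              x$corpus_totals$dreams$unique_conditions))
  cat(sprintf("  classes: TYPICAL_WAKING %d / EQUAL %d / TYPICAL_DREAM %d\n",
              x$class_counts$TYPICAL_WAKING, x$class_counts$EQUAL,
              x$class_counts$TYPICAL_DREAM))
  cat(sprintf("  network: %d/%d nodes, %d/%d edges after/before filter\n",
              x$network$nodes_after_filter, x$network$nodes_before_filter,
              x$network$edges_after_filter, x$network$edges_before_filter))
  cat(sprintf("  giant component: %d nodes, %d edges (of %d components)\n",
              x$network$giant_component_nodes,
              x$network$giant_component_edges, x$network$n_components))
  cat(sprintf("  assortativity: %s\n",
              if (is.na(x$assortativity)) "undefined"
              else sprintf("%.4f", x$assortativity)))
  cat("  mean PageRank by class:\n")
  print(x$class_mean_pagerank)
  invisible(x)
}
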