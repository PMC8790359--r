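# Co-occurrence network of conditions across dream reports.
#
# Nodes are conditions; two conditions are joined if they appear in the
# same report, with edge weight the number of reports containing both.
# Each candidate edge gets the statistic set used in comorbidity-network
# studies: relative risk RR = P_ij * N / (P_i * P_j) with a log-normal
# confidence interval, and the phi coefficient of the two presence
# indicators with a t-test p-value.  Edges are kept only when
# phi > 0, p < alpha and LB(RR) > 1.

#' Build co-occurrence counts from dream reports
#'
#' @param reports List of character vectors; each report is treated as a
#'   set of conditions (duplicates within a report are ignored).
#' @return An object of class `cooccurrence_counts`: `N` (number of
#'   reports), `P` (named vector, reports mentioning each condition),
#'   `pairs` (data frame `i`, `j`, `p_ij` for every unordered pair
#'   co-occurring in at least one report) and `conditions`.
#' @export
build_cooccurrence <- function(reports) {
  if (!is.list(reports) || length(reports) == 0) {
    stop("empty report list", call. = FALSE)
  }
  reports <- lapply(reports, function(r) unique(as.character(r)))
  conds <- sort(unique(unlist(reports, use.names = FALSE)))
  if (length(conds) == 0) {
    stop("reports contain no conditions", call. = FALSE)
  }
  N <- length(reports)
  ri <- rep(seq_len(N), lengths(reports))
  ci <- match(unlist(reports, use.names = FALSE), conds)
  B <- Matrix::sparseMatrix(i = ri, j = ci, x = 1,
                            dims = c(N, length(conds)))
  C <- Matrix::crossprod(B)
  P <- stats::setNames(as.integer(Matrix::diag(C)), conds)
  U <- methods::as(Matrix::triu(C, k = 1), "TsparseMatrix")
  ii <- U@i + 1L
  jj <- U@j + 1L
  ord <- order(ii, jj)
  pairs <- data.frame(i = conds[ii[ord]], j = conds[jj[ord]],
                      p_ij = as.integer(U@x[ord]),
                      stringsAsFactors = FALSE)
  structure(list(N = N, P = P, pairs = pairs, conditions = conds),
            class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf("Co-occurrence counts: %d reports, %d conditions, %d co-occurring pairs\n",
              x$N, length(x$conditions), nrow(x$pairs)))
  invisible(x)
}

#' Association statistics for condition pairs
#'
#' Vectorized computation of the full statistic set for 2x2 presence
#' tables: relative risk `rr = p_ij * n / (p_i * p_j)`, its log-scale
#' standard error `sigma_ij = sqrt(1/p_ij + 1/(p_i*p_j) - 1/n - 1/n^2)`
#' and confidence bounds `rr * exp(+/- ci_multiplier * sigma_ij)`;
#' the phi coefficient
#' `(p_ij*n - p_i*p_j) / sqrt(p_i*p_j*(n-p_i)*(n-p_j))` with
#' `t = phi * sqrt(n-2) / sqrt(1-phi^2)` and a two-sided p-value on
#' `n - 2` degrees of freedom (`|phi| = 1` gives `p = 0`).  Pairs where a
#' condition appears in every report (`p_i = n` or `p_j = n`) have an
#' undefined phi and are flagged `degenerate`.
#'
#' @param n Total number of reports (scalar, at least 3).
#' @param p_i,p_j Reports mentioning condition i resp. j.
#' @param p_ij Reports mentioning both (at least 1).
#' @param ci_multiplier Width of the confidence interval on log RR
#'   (default 2.56, a 99% interval).
#' @return Data frame with columns `p_i`, `p_j`, `weight`, `rr`,
#'   `sigma_ij`, `lb`, `ub`, `phi`, `t`, `p`, `degenerate`.
#' @export
pair_association <- function(n, p_i, p_j, p_ij, ci_multiplier = 2.56) {
  n <- check_count(n, "n", min = 3L)
  ci_multiplier <- check_positive_real(ci_multiplier, "ci_multiplier")
  k <- length(p_ij)
  stopifnot(length(p_i) == k, length(p_j) == k)
  if (any(p_ij < 1) || any(p_ij > pmin(p_i, p_j)) ||
      any(p_i > n) || any(p_j > n) || any(p_i + p_j - p_ij > n)) {
    stop("invalid co-occurrence counts: need 1 <= p_ij <= min(p_i, p_j) ",
         "<= n and p_i + p_j - p_ij <= n", call. = FALSE)
  }
  rr <- p_ij * n / (p_i * p_j)
  sigma_ij <- sqrt(pmax(1 / p_ij + 1 / (p_i * p_j) - 1 / n - 1 / n^2, 0))
  ub <- rr * exp(ci_multiplier * sigma_ij)
  lb <- rr * exp(-ci_multiplier * sigma_ij)
  degenerate <- (p_i == n) | (p_j == n)
  den <- as.numeric(p_i) * p_j * (n - p_i) * (n - p_j)
  phi <- ifelse(degenerate, NA_real_,
                (p_ij * n - as.numeric(p_i) * p_j) / sqrt(den))
  # clamp rounding overshoot so the t transform stays defined
  phi <- pmin(pmax(phi, -1), 1)
  perfect <- !degenerate & abs(phi) >= 1
  tt <- ifelse(degenerate, NA_real_,
               ifelse(perfect, sign(phi) * Inf,
                      phi * sqrt(n - 2) / sqrt(1 - phi^2)))
  p <- ifelse(degenerate, NA_real_,
              ifelse(perfect, 0, 2 * stats::pt(-abs(tt), df = n - 2)))
  data.frame(p_i = as.integer(p_i), p_j = as.integer(p_j),
             p_ij = as.integer(p_ij), weight = as.integer(p_ij),
             rr = rr, sigma_ij = sigma_ij, lb = lb, ub = ub,
             phi = phi, t = tt, p = p, degenerate = degenerate)
}

#' Edge statistics for all co-occurring pairs
#'
#' @param counts A [build_cooccurrence()] result.
#' @param ci_multiplier Confidence multiplier on log RR (default 2.56).
#' @return Data frame: one row per candidate edge (`i`, `j` plus the
#'   [pair_association()] columns).
#' @export
edge_statistics <- function(counts, ci_multiplier = 2.56) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  pr <- counts$pairs
  if (nrow(pr) == 0) {
    return(cbind(data.frame(i = character(0), j = character(0)),
                 pair_association(3, integer(0), integer(0), integer(0))))
  }
  stats <- pair_association(counts$N, counts$P[pr$i], counts$P[pr$j],
                            pr$p_ij, ci_multiplier)
  cbind(data.frame(i = pr$i, j = pr$j, stringsAsFactors = FALSE), stats)
}

#' Filter non-robust edges
#'
#' Keeps an edge only when `phi > phi_threshold`, `p < alpha` and
#' `lb > lb_threshold` (defaults 0, 0.01 and 1: positively associated,
#' significant, and whole confidence interval of RR above independence).
#' Degenerate edges (a condition present in every report) are always
#' dropped.
#'
#' @param stats Data frame from [edge_statistics()].
#' @param alpha Significance level for the phi t-test.
#' @param lb_threshold Minimum lower confidence bound of RR.
#' @param phi_threshold Minimum phi; set to `-Inf` (with large `alpha`
#'   and `lb_threshold = -Inf`) to disable filtering.
#' @return The subset of `stats` that passes.
#' @export
filter_edges <- function(stats, alpha = 0.01, lb_threshold = 1,
                         phi_threshold = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  keep <- !stats$degenerate &
    !is.na(stats$phi) & stats$phi > phi_threshold &
    stats$p < alpha & stats$lb > lb_threshold
  stats[which(keep), , drop = FALSE]
}

#' Drop singleton nodes
#'
#' @param conditions Character vector of node names.
#' @param edges Data frame with columns `i`, `j`.
#' @return The conditions incident to at least one edge, in input order.
#' @export
remove_singletons <- function(conditions, edges) {
  conditions[conditions %in% c(edges$i, edges$j)]
}

as_network_graph <- function(network) {
  if (inherits(network, "condition_network")) network$graph
  else if (inherits(network, "igraph")) network
  else stop("`network` must be a condition_network or igraph object",
            call. = FALSE)
}

resolve_classes <- function(classes) {
  if (is.null(classes)) return(NULL)
  if (inherits(classes, "condition_classification")) {
    stats::setNames(classes$table$class, classes$table$condition)
  } else if (is.character(classes) && !is.null(names(classes))) {
    classes
  } else {
    stop("`classes` must be a condition_classification or a named ",
         "character vector", call. = FALSE)
  }
}

#' Build the filtered condition co-occurrence network
#'
#' Runs the full network construction: co-occurrence counts, edge
#' statistics, significance filtering, singleton removal, then PageRank
#' centrality, connected components and (when class labels are supplied)
#' attribute assortativity.
#'
#' @param reports List of report condition sets.
#' @param classes Optional class labels for the nodes: a
#'   [classify_conditions()] result or a named character vector.
#' @param alpha,lb_threshold,phi_threshold Edge filter parameters, see
#'   [filter_edges()].
#' @param ci_multiplier Confidence multiplier on log RR (default 2.56).
#' @param damping PageRank damping factor (default 0.85).
#' @param weighted Use co-occurrence counts as PageRank edge weights
#'   (default TRUE).
#' @return An object of class `condition_network` wrapping an
#'   [igraph][igraph::igraph-package] graph (node attributes `class`,
#'   `provenance`, `pagerank`, `degree`; edge attributes `weight`, `rr`,
#'   `lb`, `ub`, `phi`, `p`) plus the unfiltered statistics, dropped
#'   singletons and component structure.
#' @export
condition_network <- function(reports, classes = NULL, alpha = 0.01,
                              lb_threshold = 1, phi_threshold = 0,
                              ci_multiplier = 2.56, damping = 0.85,
                              weighted = TRUE) {
  counts <- build_cooccurrence(reports)
  stats <- edge_statistics(counts, ci_multiplier)
  n_degenerate <- sum(stats$degenerate)
  edges <- filter_edges(stats, alpha, lb_threshold, phi_threshold)

  candidate_nodes <- remove_singletons(counts$conditions, stats)
  nodes <- remove_singletons(candidate_nodes, edges)

  cls <- resolve_classes(classes)
  prov <- if (inherits(classes, "condition_classification")) {
    stats::setNames(classes$table$provenance, classes$table$condition)
  } else NULL

  vdf <- data.frame(
    name = nodes,
    class = if (is.null(cls)) rep("unlabelled", length(nodes))
            else ifelse(is.na(cls[nodes]) | !(nodes %in% names(cls)),
                        "unlabelled", cls[nodes]),
    provenance = if (is.null(prov)) rep("unknown", length(nodes))
                 else ifelse(is.na(prov[nodes]) | !(nodes %in% names(prov)),
                             "unknown", prov[nodes]),
    stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j", "weight", "rr", "lb", "ub", "phi", "p")],
    directed = FALSE, vertices = vdf)

  pr <- igraph::page_rank(g, damping = damping,
                          weights = if (weighted) igraph::E(g)$weight
                                    else NA)$vector
  igraph::V(g)$pagerank <- as.numeric(pr)
  igraph::V(g)$degree <- as.numeric(igraph::degree(g))
  comp <- igraph::components(g)

  net <- structure(list(
    graph = g,
    counts = counts,
    stats = stats,
    edges = edges,
    nodes = nodes,
    classes = cls,
    pagerank = stats::setNames(as.numeric(pr), nodes),
    components = comp,
    singletons_initial = setdiff(counts$conditions, candidate_nodes),
    singletons_after_filter = setdiff(candidate_nodes, nodes),
    n_degenerate_edges = n_degenerate,
    n_nodes_before = length(candidate_nodes),
    n_edges_before = nrow(stats),
    n_nodes = length(nodes),
    n_edges = nrow(edges),
    parameters = list(alpha = alpha, lb_threshold = lb_threshold,
                      phi_threshold = phi_threshold,
                      ci_multiplier = ci_multiplier, damping = damping,
                      weighted = weighted)),
    class = "condition_network")
  net$assortativity <- if (is.null(cls)) NA_real_ else {
    suppressWarnings(attribute_assortativity(net))
  }
  net
}

#' @export
print.condition_network <- function(x, ...) {
  cat("Condition co-occurrence network\n")
  cat(sprintf("  %d reports; %d conditions (%d initial singletons discarded)\n",
              x$counts$N, length(x$counts$conditions),
              length(x$singletons_initial)))
  cat(sprintf("  edge filter: phi > %g, p < %g, LB(RR) > %g\n",
              x$parameters$phi_threshold, x$parameters$alpha,
              x$parameters$lb_threshold))
  cat(sprintf("  %d nodes / %d edges before filtering -> %d nodes / %d edges after\n",
              x$n_nodes_before, x$n_edges_before, x$n_nodes, x$n_edges))
  cat(sprintf("  components: %d (giant: %d nodes); assortativity: %s\n",
              x$components$no,
              if (x$components$no > 0) max(x$components$csize) else 0,
              if (is.na(x$assortativity)) "undefined"
              else sprintf("%.4f", x$assortativity)))
  invisible(x)
}

#' @export
summary.condition_network <- function(object, ...) {
  cls <- igraph::V(object$graph)$class
  out <- list(
    n_reports = object$counts$N,
    n_conditions = length(object$counts$conditions),
    n_nodes_before = object$n_nodes_before,
    n_edges_before = object$n_edges_before,
    n_nodes = object$n_nodes,
    n_edges = object$n_edges,
    n_degenerate_edges = object$n_degenerate_edges,
    class_counts = table(cls),
    class_mean_pagerank = class_mean_pagerank(object),
    assortativity = object$assortativity,
    component_sizes = sort(object$components$csize, decreasing = TRUE))
  class(out) <- "summary.condition_network"
  out
}

#' @export
print.summary.condition_network <- function(x, ...) {
  cat("Condition co-occurrence network summary\n")
  cat(sprintf("  reports: %d; conditions: %d\n", x$n_reports, x$n_conditions))
  cat(sprintf("  filtering: %d/%d nodes, %d/%d edges retained (%d degenerate edges)\n",
              x$n_nodes, x$n_nodes_before, x$n_edges, x$n_edges_before,
              x$n_degenerate_edges))
  cat("  node classes:\n")
  print(x$class_counts)
  cat("  mean PageRank by class:\n")
  print(x$class_mean_pagerank)
  cat(sprintf("  assortativity: %s; components: %d (largest %d)\n",
              if (is.na(x$assortativity)) "undefined"
              else sprintf("%.4f", x$assortativity),
              length(x$component_sizes),
              if (length(x$component_sizes)) x$component_sizes[1] else 0))
  invisible(x)
}

#' Plot a condition network
#'
#' Nodes are sized by PageRank and coloured by class.
#'
#' @param x A `condition_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.condition_network <- function(x, ...) {
  g <- x$graph
  cols <- c(TYPICAL_WAKING = "forestgreen", EQUAL = "darkorange",
            TYPICAL_DREAM = "steelblue", unlabelled = "grey60")
  vc <- cols[igraph::V(g)$class]
  vc[is.na(vc)] <- "grey60"
  pr <- igraph::V(g)$pagerank
  igraph::plot.igraph(g, vertex.color = vc, vertex.label = NA,
                      vertex.size = 3 + 40 * pr / max(pr), ...)
  invisible(x)
}

#' PageRank centrality
#'
#' Standard PageRank on the undirected graph (each undirected edge acts
#' as two directed edges; transition probability proportional to edge
#' weight when `weighted`).  Scores sum to 1; isolated nodes receive
#' teleport-only mass.
#'
#' @param network A `condition_network` or igraph object.
#' @param damping Damping factor (default 0.85).
#' @param weighted Use edge weights (default TRUE; needs a `weight`
#'   edge attribute).
#' @return Named numeric vector of scores summing to 1.
#' @export
pagerank_centrality <- function(network, damping = 0.85, weighted = TRUE) {
  g <- as_network_graph(network)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else NA
  pr <- igraph::page_rank(g, damping = damping, weights = w)$vector
  stats::setNames(as.numeric(pr), igraph::V(g)$name)
}

node_classes <- function(g, classes = NULL) {
  if (!is.null(classes)) {
    cls <- resolve_classes(classes)
    out <- cls[igraph::V(g)$name]
  } else if ("class" %in% igraph::vertex_attr_names(g)) {
    out <- igraph::V(g)$class
  } else {
    stop("no class labels available; supply `classes`", call. = FALSE)
  }
  out <- as.character(out)
  out[out == "unlabelled"] <- NA_character_
  out
}

#' Mean PageRank per node class
#'
#' @param network A `condition_network` or igraph with a `pagerank`
#'   vertex attribute.
#' @param classes Optional class labels (otherwise taken from the graph).
#' @return Named numeric vector of per-class arithmetic means; classes
#'   with no nodes are `NA` (undefined), never zero.
#' @export
class_mean_pagerank <- function(network, classes = NULL) {
  g <- as_network_graph(network)
  pr <- if (inherits(network, "condition_network")) network$pagerank
        else igraph::V(g)$pagerank
  if (is.null(pr)) pr <- pagerank_centrality(g)
  cls <- node_classes(g, classes)
  lev <- if (all(stats::na.omit(cls) %in% CONDITION_CLASSES)) {
    CONDITION_CLASSES
  } else sort(unique(stats::na.omit(cls)))
  out <- vapply(lev, function(l) {
    v <- pr[!is.na(cls) & cls == l]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  stats::setNames(out, lev)
}

#' Attribute assortativity over node classes
#'
#' Newman's discrete assortativity coefficient of the class-mixing matrix
#' of edges: +1 when edges only join same-class nodes, negative when
#' classes mix more than chance expects.
#'
#' @param network A `condition_network` or igraph object.
#' @param classes Optional class labels (otherwise taken from the graph).
#' @return A value in \[-1, 1\], or `NA` (with a warning) when fewer than
#'   two classes appear among edge endpoints.
#' @export
attribute_assortativity <- function(network, classes = NULL) {
  g <- as_network_graph(network)
  cls <- node_classes(g, classes)
  keepv <- which(!is.na(cls))
  sg <- igraph::induced_subgraph(g, keepv)
  if (igraph::ecount(sg) == 0) {
    warning("assortativity undefined: no edges between labelled nodes")
    return(NA_real_)
  }
  ends <- igraph::ends(sg, igraph::E(sg), names = FALSE)
  sub_cls <- cls[keepv]
  if (length(unique(sub_cls[as.vector(ends)])) < 2) {
    warning("assortativity undefined: single class among edge endpoints")
    return(NA_real_)
  }
  igraph::assortativity_nominal(sg, types = as.integer(factor(sub_cls)),
                                directed = FALSE)
}

#' Giant connected component
#'
#' @param network A `condition_network` or igraph object.
#' @return List with `graph` (induced subgraph of the largest component),
#'   `sizes` (all component sizes, decreasing), `n_components` and
#'   `membership`.
#' @export
giant_component <- function(network) {
  g <- as_network_graph(network)
  comp <- igraph::components(g)
  if (comp$no == 0) {
    return(list(graph = g, sizes = integer(0), n_components = 0L,
                membership = comp$membership))
  }
  largest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == largest))
  list(graph = sub, sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       n_components = as.integer(comp$no), membership = comp$membership)
}

#' Min-degree core of the network
#'
#' Induced subgraph on the nodes whose degree in the full network is at
#' least `min_degree`.  A single pass: degrees are measured once in the
#' full graph, not recomputed iteratively (this is not a k-core
#' decomposition).
#'
#' @param network A `condition_network` or igraph object.
#' @param min_degree Degree threshold (default 5).
#' @return The induced igraph subgraph.
#' @export
extract_core <- function(network, min_degree = 5L) {
  min_degree <- check_count(min_degree, "min_degree")
  g <- as_network_graph(network)
  igraph::induced_subgraph(g, which(igraph::degree(g) >= min_degree))
}

#' Write a condition network as GraphML
#'
#' @param network A `condition_network` or igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_network_graph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the filtered edge list as TSV
#'
#' @param network A `condition_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "condition_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
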