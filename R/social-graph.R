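#' Build a social graph from a roster
#'
#' A directed tie i -> j exists when i rated j at or above `threshold` on
#' the five-point scale; threshold 4 keeps "More than some" and "Most",
#' threshold 5 only "Most". In `reciprocal` mode an undirected edge requires
#' both directed ratings to clear the threshold (mutually reported ties are
#' more robust indicators of friendship); in `directed` mode each clearing
#' rating becomes an arc.
#'
#' @param roster a [roster_rating()].
#' @param threshold Likert cutoff, 4 or 5.
#' @param mode `"reciprocal"` (undirected, default) or `"directed"`.
#' @return An object of class `social_graph`: list with `graph` (igraph),
#'   `ids`, `threshold`, `mode`, `adjacency` (binary matrix).
#' @export
build_social_graph <- function(roster, threshold = 4, mode = c("reciprocal", "directed")) {
  stopifnot(inherits(roster, "roster_rating"))
  mode <- match.arg(mode)
  if (!threshold %in% c(4, 5)) stop("threshold must be 4 or 5")
  r <- unclass(roster)
  a <- !is.na(r) & r >= threshold
  if (mode == "reciprocal") {
    a <- a & t(a)
    g <- igraph::graph_from_adjacency_matrix(a * 1L, mode = "undirected", diag = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(a * 1L, mode = "directed", diag = FALSE)
  }
  structure(list(graph = g, ids = rownames(r), threshold = threshold,
                 mode = mode, adjacency = a * 1L,
                 cohort = attr(roster, "cohort")),
            class = "social_graph")
}

#' @export
print.social_graph <- function(x, ...) {
  cat("Social graph (", x$mode, ", threshold ", x$threshold, "): ",
      length(x$ids), " students, ", igraph::ecount(x$graph),
      if (x$mode == "reciprocal") " edges\n" else " arcs\n", sep = "")
  invisible(x)
}

#' Geodesic social distance between all pairs
#'
#' Breadth-first shortest path length on the reciprocal friendship graph.
#' A distance of 1 is a mutual friendship; 2 and 3 mean a mutual friend or
#' a friend of a friend. Unreachable pairs are `Inf`.
#'
#' @param graph a reciprocal [build_social_graph()] result.
#' @return Symmetric numeric matrix of class `social_distance` with zero
#'   diagonal; attribute `n_unreachable` counts unordered unreachable pairs.
#' @export
social_distance <- function(graph) {
  stopifnot(inherits(graph, "social_graph"))
  if (graph$mode != "reciprocal")
    stop("social distance is defined on the reciprocal graph; got a directed graph")
  d <- igraph::distances(graph$graph, algorithm = "unweighted")
  dimnames(d) <- list(graph$ids, graph$ids)
  attr(d, "n_unreachable") <- sum(is.infinite(d[upper.tri(d)]))
  class(d) <- c("social_distance", "matrix", "array")
  d
}

#' Louvain community detection with seeded restarts
#'
#' Runs multi-level modularity optimisation `restarts` times under derived
#' seeds and keeps the partition with the highest modularity (ties broken by
#' first occurrence in seeded order).
#'
#' @param graph an undirected [build_social_graph()] result with >= 1 edge.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed.
#' @param restarts number of restarts (default 100).
#' @return Object of class `community_partition`: list with `membership`
#'   (named integer vector), `modularity`, `gamma`, `seed`, `restarts`.
#' @export
detect_communities <- function(graph, gamma = 1, seed = 1, restarts = 100) {
  stopifnot(inherits(graph, "social_graph"))
  if (graph$mode != "reciprocal")
    stop("community detection expects the undirected reciprocal graph")
  if (igraph::ecount(graph$graph) < 1) stop("graph has no edges")
  best <- NULL
  for (r in seq_len(restarts)) {
    cl <- with_seed(child_seed(seed, paste0("louvain/", r)),
                    igraph::cluster_louvain(graph$graph, resolution = gamma))
    q <- igraph::modularity(graph$graph, igraph::membership(cl), resolution = gamma)
    if (is.null(best) || q > best$modularity + 1e-12)
      best <- list(membership = igraph::membership(cl), modularity = q)
  }
  memb <- as.integer(best$membership)
  names(memb) <- graph$ids
  structure(list(membership = memb, modularity = best$modularity,
                 gamma = gamma, seed = seed, restarts = restarts),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Louvain partition:", length(unique(x$membership)), "communities, Q =",
      round(x$modularity, 4), "(gamma =", x$gamma, ",", x$restarts, "restarts)\n")
  invisible(x)
}

#' Whole-network summary metrics
#'
#' Computes the standard sociometric description of a cohort: network
#' diameter (longest geodesic), Louvain modularity, mean path length over
#' reachable ordered pairs, reciprocity (proportion of arcs in the directed
#' graph that are mutual), density (edges over possible edges) and
#' max-normalised eigenvector centrality per student.
#'
#' @param graph reciprocal [build_social_graph()].
#' @param directed_counterpart the threshold-matched directed graph, used
#'   only for reciprocity; built from `roster` on the fly if omitted and a
#'   roster is supplied.
#' @param seed seed forwarded to [detect_communities()].
#' @return List of class `network_summary`.
#' @export
network_summary <- function(graph, directed_counterpart = NULL, seed = 1) {
  stopifnot(inherits(graph, "social_graph"))
  if (igraph::ecount(graph$graph) == 0) stop("graph has no edges")
  g <- graph$graph
  d <- igraph::distances(g, algorithm = "unweighted")
  finite <- d[is.finite(d) & d > 0]
  comm <- detect_communities(graph, seed = seed)
  recip <- NA_real_
  if (!is.null(directed_counterpart)) {
    stopifnot(inherits(directed_counterpart, "social_graph"),
              directed_counterpart$mode == "directed")
    recip <- igraph::reciprocity(directed_counterpart$graph)
  }
  ec <- igraph::eigen_centrality(g)$vector
  names(ec) <- graph$ids
  structure(list(
    diameter = max(finite),
    modularity = comm$modularity,
    mean_path_length = mean(finite),
    reciprocity = recip,
    density = igraph::edge_density(g),
    eigenvector_centrality = ec,
    n_communities = length(unique(comm$membership))
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  diameter         %g\n", x$diameter))
  cat(sprintf("  modularity       %.3f\n", x$modularity))
  cat(sprintf("  mean path length %.3f\n", x$mean_path_length))
  cat(sprintf("  reciprocity      %.3f\n", x$reciprocity))
  cat(sprintf("  density          %.3f\n", x$density))
  invisible(x)
}

#' Number of unordered dyads among n individuals
#'
#' @param n number of individuals (>= 2).
#' @return `n * (n - 1) / 2`.
#' @examples
#' count_dyads(59)  # 1711
#' @export
count_dyads <- function(n) {
  if (any(n < 2)) stop("n must be at least 2")
  n * (n - 1) / 2
}

#' Direct-tie proximity between scanned participants
#'
#' Aggregates the two directed Likert ratings of a dyad into a single
#' proximity score, for the robustness analysis that replaces thresholded
#' social distance by the raw magnitude of the direct tie.
#'
#' @param roster a [roster_rating()].
#' @param pairs two-column matrix or data.frame of student IDs.
#' @param rule aggregation rule: `"mean"` (default), `"min"` or `"max"`.
#' @return Numeric vector of per-pair proximities.
#' @export
direct_tie_distance <- function(roster, pairs, rule = c("mean", "min", "max")) {
  stopifnot(inherits(roster, "roster_rating"))
  rule <- match.arg(rule)
  pairs <- as.matrix(pairs)
  f <- switch(rule, mean = function(a, b) (a + b) / 2, min = pmin, max = pmax)
  r_ij <- roster[cbind(pairs[, 1], pairs[, 2])]
  r_ji <- roster[cbind(pairs[, 2], pairs[, 1])]
  if (any(is.na(r_ij)) || any(is.na(r_ji))) {
    bad <- which(is.na(r_ij) | is.na(r_ji))[1]
    stop("missing rating for pair (", pairs[bad, 1], ", ", pairs[bad, 2], ")")
  }
  as.numeric(f(r_ij, r_ji))
}

#' Write a social graph as edge list CSV and GraphML
#'
#' @param graph a [build_social_graph()] result.
#' @param csv_path,graphml_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the edge-list data.frame.
#' @export
write_social_graph <- function(graph, csv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(graph, "social_graph"))
  el <- igraph::as_edgelist(graph$graph)
  df <- data.frame(from = el[, 1], to = el[, 2])
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  invisible(df)
}
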