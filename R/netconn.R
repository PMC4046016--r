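#' Build a covariation graph from a thresholded map
#'
#' Selects the top \code{n_pairs} scoring pairs after discarding pairs
#' whose sequence distance |j - i| is below \code{min_seq_dist}, and turns
#' them into an unweighted adjacency matrix (all selected entries 1,
#' everything else including the diagonal 0).
#'
#' @param map A [covariation_map()].
#' @param n_pairs Number of top pairs (edges) to select.
#' @param min_seq_dist Minimum sequence distance d; pairs with
#'   |j - i| < d are discarded before ranking.
#' @return A \code{covariation_graph}: list with \code{adjacency} (L x L
#'   0/1 matrix), \code{pairs} (the selected \code{ranked_pairs}),
#'   \code{n_pairs}, \code{min_seq_dist}.
#' @export
build_graph <- function(map, n_pairs, min_seq_dist = 0L) {
  stopifnot(inherits(map, "covariation_map"))
  # |j - i| >= d  <=>  strictly more than d - 1 intervening offset
  pairs <- top_pairs(map, n_pairs, min_sep = min_seq_dist - 1L,
                     strict = TRUE)
  L <- map_size(map)
  adj <- matrix(0L, L, L)
  adj[cbind(pairs$i, pairs$j)] <- 1L
  adj[cbind(pairs$j, pairs$i)] <- 1L
  structure(list(adjacency = adj, pairs = pairs,
                 n_pairs = nrow(pairs),
                 min_seq_dist = as.integer(min_seq_dist)),
            class = "covariation_graph")
}

#' @export
print.covariation_graph <- function(x, ...) {
  cat(sprintf("covariation_graph: %d nodes, %d edges, min seq dist %d\n",
              nrow(x$adjacency), x$n_pairs, x$min_seq_dist))
  invisible(x)
}

#' Graph transitivity (global clustering coefficient)
#'
#' 3 x (number of triangles) / (number of connected triples); 0 when the
#' graph has edges but no connected triples, error on an empty graph.
#'
#' @param g A \code{covariation_graph}.
#' @return Ratio in [0, 1].
#' @export
graph_transitivity <- function(g) {
  stopifnot(inherits(g, "covariation_graph"))
  A <- g$adjacency
  if (sum(A) == 0L) stop("input error: empty graph")
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  triangles <- sum(diag(A %*% A %*% A)) / 6
  3 * triangles / triples
}

as_igraph <- function(g, contacts = NULL, drop_unweighted = FALSE) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  if (!is.null(contacts)) {
    el <- igraph::as_edgelist(ig)
    w <- contacts$distances[el]
    if (drop_unweighted && anyNA(w)) {
      ig <- igraph::delete_edges(ig, which(is.na(w)))
      w <- w[!is.na(w)]
    }
    igraph::E(ig)$weight <- w
  }
  ig
}

#' Shortest indirect structural path between a residue pair
#'
#' Finds the shortest path from i to j in the covariation graph with the
#' direct edge (i, j) removed, where the length of each step is the
#' structure centroid distance between its endpoints. Edges whose
#' endpoints lack structure coordinates are unusable and dropped.
#'
#' @param g A \code{covariation_graph}.
#' @param contacts A \code{contact_map} providing distances (Angstrom).
#' @param pair Length-2 integer vector (i, j).
#' @return List with \code{path_length} (Angstrom), \code{mean_step},
#'   \code{n_steps} and \code{path} (node sequence), or NULL when no
#'   indirect path exists.
#' @export
indirect_path_stats <- function(g, contacts, pair) {
  stopifnot(inherits(g, "covariation_graph"), inherits(contacts, "contact_map"),
            length(pair) == 2L)
  i <- pair[1]; j <- pair[2]
  ig <- as_igraph(g, contacts, drop_unweighted = TRUE)
  direct <- suppressWarnings(
    igraph::get_edge_ids(ig, c(i, j), error = FALSE))
  if (length(direct) && !is.na(direct) && direct > 0)
    ig <- igraph::delete_edges(ig, direct)
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = i, to = j,
                           weights = igraph::E(ig)$weight,
                           output = "both"))
  nodes <- as.integer(sp$vpath[[1]])
  if (length(nodes) < 2L) return(NULL)
  steps <- igraph::E(ig)$weight[as.integer(sp$epath[[1]])]
  list(path_length = sum(steps),
       mean_step = mean(steps),
       n_steps = length(steps),
       path = nodes)
}

#' Connectivity profile across graph-size thresholds
#'
#' For each pair count k on the grid, builds the covariation graph on the
#' top k pairs and averages the shortest-indirect-path statistics over all
#' selected pairs that possess an indirect path. Also returns the per-pair
#' (score, path length, mean step) table of the largest graph, used to
#' correlate covariation score with path geometry.
#'
#' @param map A [covariation_map()].
#' @param contacts A \code{contact_map}.
#' @param max_pairs Largest graph size (default 3L, i.e. three pairs per
#'   residue).
#' @param min_seq_dist Sequence-distance filter for graph edges.
#' @param grid Integer vector of pair counts; default 0.25L steps up to
#'   \code{max_pairs}.
#' @return List with \code{profile} (data.frame: n_pairs, mean_path_length,
#'   mean_step_length, n_with_path) and \code{pair_table} (data.frame at
#'   \code{max_pairs}: i, j, score, path_length, mean_step, n_steps).
#' @export
connectivity_profile <- function(map, contacts, max_pairs = NULL,
                                 min_seq_dist = 0L, grid = NULL) {
  L <- map_size(map)
  if (is.null(max_pairs)) max_pairs <- 3L * L
  if (is.null(grid))
    grid <- unique(pmin(round(seq(L / 4, max_pairs, by = L / 4)), max_pairs))
  prof <- data.frame(n_pairs = grid, mean_path_length = NA_real_,
                     mean_step_length = NA_real_, n_with_path = 0L)
  pair_table <- NULL
  for (q in seq_along(grid)) {
    g <- build_graph(map, grid[q], min_seq_dist)
    stats <- lapply(seq_len(nrow(g$pairs)), function(r)
      indirect_path_stats(g, contacts, c(g$pairs$i[r], g$pairs$j[r])))
    has <- !vapply(stats, is.null, TRUE)
    prof$n_with_path[q] <- sum(has)
    if (any(has)) {
      prof$mean_path_length[q] <-
        mean(vapply(stats[has], `[[`, 0, "path_length"))
      prof$mean_step_length[q] <-
        mean(vapply(stats[has], `[[`, 0, "mean_step"))
    }
    if (q == length(grid)) {
      pair_table <- g$pairs
      pair_table$path_length <- vapply(stats, function(s)
        if (is.null(s)) NA_real_ else s$path_length, 0)
      pair_table$mean_step <- vapply(stats, function(s)
        if (is.null(s)) NA_real_ else s$mean_step, 0)
      pair_table$n_steps <- vapply(stats, function(s)
        if (is.null(s)) NA_integer_ else s$n_steps, 0L)
    }
  }
  list(profile = prof, pair_table = pair_table)
}

#' Transitivity across graph-size or sequence-distance grids
#'
#' \code{vary_size}: transitivity of graphs built on a growing number of
#' top pairs at constant minimum sequence distance (default 6).
#' \code{vary_dist}: transitivity at constant graph size (default L) as
#' the minimum sequence distance grows. Grid points where the graph is
#' empty are reported as NA.
#'
#' @param map A [covariation_map()].
#' @param mode \code{"vary_size"} or \code{"vary_dist"}.
#' @param grid Integer vector: pair counts (vary_size) or sequence
#'   distances (vary_dist).
#' @param min_seq_dist Constant distance filter for \code{vary_size}.
#' @param n_pairs Constant graph size for \code{vary_dist} (default L).
#' @return data.frame: grid, transitivity.
#' @export
transitivity_profile <- function(map, mode = c("vary_size", "vary_dist"),
                                 grid, min_seq_dist = 6L, n_pairs = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(grid) >= 1L)
  if (is.null(n_pairs)) n_pairs <- map_size(map)
  tr <- vapply(grid, function(x) {
    g <- tryCatch(suppressWarnings(switch(mode,
      vary_size = build_graph(map, x, min_seq_dist),
      vary_dist = build_graph(map, n_pairs, x))),
      error = function(e) NULL)
    if (is.null(g) || sum(g$adjacency) == 0L) return(NA_real_)
    graph_transitivity(g)
  }, 0)
  data.frame(grid = grid, transitivity = tr)
}
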