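# Cluster-structure visualization: exact k-nearest-neighbour graph over
# latent features, minimum spanning tree (the tree-map style backbone),
# GraphML export for inspection of transitional overlap.

#' Exact k-nearest-neighbour graph on latent features
#'
#' Euclidean distances, ties broken by lower point index. Each point's `k`
#' out-neighbours are folded into an undirected, de-duplicated edge set.
#'
#' @param Z `latent_features` or numeric matrix `[n x d]`.
#' @param k Number of neighbours per point, `1 <= k < n`.
#' @return Object of class `neighbor_graph`: list with `edges` data frame
#'   (`i`, `j`, `weight`; `i < j`, 1-based), `n_nodes`, `k`.
#' @export
knn_graph <- function(Z, k) {
  Z <- as_feature_matrix(Z)
  n <- nrow(Z)
  k <- check_count(k, "k")
  if (k >= n) stop_bad_arg("k (%d) must be smaller than the number of points (%d)", k, n)
  D <- as.matrix(stats::dist(Z))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]  # stable order: ties resolve to lower index
    ii <- c(ii, rep(i, k))
    jj <- c(jj, nb)
  }
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  keep <- !duplicated(cbind(lo, hi))
  edges <- data.frame(i = lo[keep], j = hi[keep],
                      weight = D[cbind(lo[keep], hi[keep])])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_nodes = n, k = k), class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d undirected edges (k = %d)\n",
              x$n_nodes, nrow(x$edges), x$k))
  invisible(x)
}

#' Minimum spanning tree (forest) of a neighbour graph
#'
#' Kruskal's greedy algorithm with deterministic lexicographic tie-breaking:
#' edges are considered in increasing `(weight, i, j)` order. Disconnected
#' graphs yield a spanning forest with `n_nodes - n_components` edges.
#'
#' @param graph A [knn_graph()] result (or any list with `edges`/`n_nodes`).
#' @param node_labels Optional per-node labels carried into the layout.
#' @return Object of class `tree_layout`: `mst_edges` data frame,
#'   `node_labels`, `n_nodes`, `n_components`.
#' @export
mst <- function(graph, node_labels = NULL) {
  e <- graph$edges
  n <- graph$n_nodes
  ord <- order(e$weight, e$i, e$j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(e))
  for (idx in ord) {
    ri <- find(e$i[idx]); rj <- find(e$j[idx])
    if (ri != rj) {
      parent[ri] <- rj
      keep[idx] <- TRUE
    }
  }
  mst_edges <- e[keep, , drop = FALSE]
  mst_edges <- mst_edges[order(mst_edges$i, mst_edges$j), , drop = FALSE]
  rownames(mst_edges) <- NULL
  n_components <- n - sum(keep)
  structure(
    list(mst_edges = mst_edges, node_labels = node_labels,
         n_nodes = n, n_components = n_components),
    class = "tree_layout"
  )
}

#' @export
print.tree_layout <- function(x, ...) {
  cat(sprintf("<tree_layout> %d nodes, %d tree edges, %d component(s)\n",
              x$n_nodes, nrow(x$mst_edges), x$n_components))
  invisible(x)
}

#' Export a spanning tree with label attributes as GraphML
#'
#' Writes the tree with both the ground-truth labels and the cluster
#' assignments as node attributes, so standard graph tooling can render the
#' tree-map style view and transitional windows can be inspected against
#' their flanking activities.
#'
#' @param layout A [mst()] result.
#' @param true_labels,cluster_labels Per-node label vectors (length
#'   `n_nodes`).
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(layout, true_labels, cluster_labels, path) {
  if (is.null(layout) || layout$n_nodes < 1L)
    stop_bad_arg("empty layout: nothing to export")
  if (length(true_labels) != layout$n_nodes ||
      length(cluster_labels) != layout$n_nodes)
    stop_bad_arg("label vectors must have one entry per node (%d)", layout$n_nodes)
  vertices <- data.frame(
    name = as.character(seq_len(layout$n_nodes)),
    true_label = as.character(true_labels),
    cluster_label = as.character(cluster_labels),
    stringsAsFactors = FALSE
  )
  edges <- layout$mst_edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j),
               weight = edges$weight),
    directed = FALSE, vertices = vertices
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Fraction of transition windows adjacent to their flanking activities
#'
#' For every node carrying the reserved transition label, checks whether at
#' least one of its tree neighbours is labeled with one of the two
#' activities the transition connects (the paper-style "natural transition
#' triplet" structure).
#'
#' @param layout A [mst()] result over window-level features.
#' @param window_labels Per-window labels (0-based; reserved transition
#'   class = `k`).
#' @param flank_pairs Two-column matrix/data frame (`from`, `to`) giving
#'   each window's flanking activity pair; rows for non-transition windows
#'   are ignored (may be `NA`).
#' @param transition_class Integer code of the reserved transition label.
#' @return List with `fraction`, `n_transition`, `n_adjacent`.
#' @export
transition_adjacency <- function(layout, window_labels, flank_pairs,
                                 transition_class) {
  e <- layout$mst_edges
  adj <- vector("list", layout$n_nodes)
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- c(adj[[e$i[r]]], e$j[r])
    adj[[e$j[r]]] <- c(adj[[e$j[r]]], e$i[r])
  }
  trans_nodes <- which(window_labels == transition_class)
  if (length(trans_nodes) == 0L)
    return(list(fraction = NA_real_, n_transition = 0L, n_adjacent = 0L))
  flank_pairs <- as.matrix(flank_pairs)
  ok <- vapply(trans_nodes, function(v) {
    nbrs <- adj[[v]]
    if (length(nbrs) == 0L) return(FALSE)
    flank <- flank_pairs[v, ]
    any(window_labels[nbrs] %in% flank)
  }, logical(1))
  list(fraction = mean(ok), n_transition = length(trans_nodes),
       n_adjacent = sum(ok))
}
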