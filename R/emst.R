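## Approximate Euclidean minimum spanning tree segmentation.
##
## Aggregates are dense islands of localizations in a sparse background.
## An exact EMST on tens of thousands of points is wasteful; restricting
## candidate edges to each point's k nearest neighbors (k = 30 by default)
## gives the standard approximate EMST, which coincides with the exact tree
## whenever every true MST edge joins mutual near-neighbors -- practically
## always for SMLM point clouds. Cutting edges above the 95th length
## percentile separates high-density regions from low-density background.

## k-nearest-neighbor candidate edges, symmetrized (edge kept if either
## endpoint lists the other). Brute force in blocks; fine at the point
## counts a single field of view produces.
.knn_edges <- function(pts, k) {
  n <- nrow(pts)
  k <- min(k, n - 1L)
  ej <- matrix(0L, n, k)
  ed <- matrix(0, n, k)
  block <- max(1L, 2^21 %/% n)  # ~16 MB per distance block
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx <- outer(pts[idx, 1], pts[, 1], "-")
    dy <- outer(pts[idx, 2], pts[, 2], "-")
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(idx), idx)] <- Inf
    for (r in seq_along(idx)) {
      v <- d2[r, ]
      th <- sort.int(v, partial = k)[k]
      cand <- which(v <= th)
      cand <- cand[order(v[cand])][seq_len(k)]
      ej[idx[r], ] <- cand
      ed[idx[r], ] <- sqrt(v[cand])
    }
  }
  ei <- rep(seq_len(n), times = k)
  ## undirected de-duplication
  a <- pmin(ei, as.vector(ej)); b <- pmax(ei, as.vector(ej))
  keep <- !duplicated(cbind(a, b))
  data.frame(i = a[keep], j = b[keep], length = as.vector(ed)[keep])
}

## Minimum cross-distance pair between two index sets.
.nearest_pair <- function(pts, ia, ib) {
  dx <- outer(pts[ia, 1], pts[ib, 1], "-")
  dy <- outer(pts[ia, 2], pts[ib, 2], "-")
  d2 <- dx * dx + dy * dy
  w <- arrayInd(which.min(d2), dim(d2))
  c(i = ia[w[1]], j = ib[w[2]], d = sqrt(d2[w[1], w[2]]))
}

#' Approximate Euclidean minimum spanning tree on a k-NN candidate graph
#'
#' Builds the symmetrized k-nearest-neighbor graph of the points and returns
#' its minimum spanning tree. If the candidate graph is disconnected, the
#' components are first bridged through their mutually nearest point pairs so
#' a single spanning tree exists. With `k >= n - 1` the result is the exact
#' Euclidean MST.
#'
#' @param points a two-column matrix/data.frame of nm coordinates, or a
#'   [localization_table()].
#' @param k number of nearest-neighbor candidates per point (default 30).
#' @return object of class `spatial_graph`: list with `edges`
#'   (data.frame `i`, `j`, `length` in nm), `n_nodes`, and the point
#'   coordinates.
#' @export
build_knn_emst <- function(points, k = 30) {
  pts <- .coords(points)
  n <- nrow(pts)
  stopifnot(k >= 1)
  if (n == 0) stop("no points")
  if (n == 1)
    return(structure(list(edges = data.frame(i = integer(0), j = integer(0),
                                             length = numeric(0)),
                          n_nodes = 1L, points = pts),
                     class = "spatial_graph"))
  cand <- .knn_edges(pts, k)
  g <- igraph::graph_from_edgelist(cbind(cand$i, cand$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  while (comp$no > 1) {
    ## bridge the two components whose mutually nearest points are closest
    best <- NULL
    members <- split(seq_len(n), comp$membership)
    for (a in seq_len(comp$no - 1)) for (b in (a + 1):comp$no) {
      np <- .nearest_pair(pts, members[[a]], members[[b]])
      if (is.null(best) || np["d"] < best["d"]) best <- np
    }
    cand <- rbind(cand, data.frame(i = min(best["i"], best["j"]),
                                   j = max(best["i"], best["j"]),
                                   length = best["d"]))
    g <- igraph::add_edges(g, c(best["i"], best["j"]))
    comp <- igraph::components(g)
  }
  gw <- igraph::graph_from_edgelist(cbind(cand$i, cand$j), directed = FALSE)
  gw <- igraph::add_vertices(gw, max(0L, n - igraph::vcount(gw)))
  igraph::E(gw)$weight <- cand$length
  igraph::E(gw)$eid <- seq_len(nrow(cand))
  mst <- igraph::mst(gw, weights = igraph::E(gw)$weight)
  keep <- igraph::E(mst)$eid
  structure(list(edges = cand[sort(keep), , drop = FALSE],
                 n_nodes = n, points = pts),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d nodes, %d edges (EMST)\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

.graph_components <- function(graph, edges) {
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  igraph::components(g)$membership
}

.make_cluster <- function(id, members, pts) {
  structure(list(id = id, members = members,
                 bbox = c(xmin = min(pts[members, 1]),
                          xmax = max(pts[members, 1]),
                          ymin = min(pts[members, 2]),
                          ymax = max(pts[members, 2]))),
            class = "aggregate_cluster")
}

#' @export
print.aggregate_cluster <- function(x, ...) {
  cat(sprintf("aggregate_cluster #%s: %d localizations, bbox %.0f x %.0f nm\n",
              x$id, length(x$members),
              x$bbox["xmax"] - x$bbox["xmin"],
              x$bbox["ymax"] - x$bbox["ymin"]))
  invisible(x)
}

#' Cut a spanning tree at an edge-length percentile
#'
#' Deletes every edge strictly longer than the given percentile of all edge
#' lengths (linear-interpolation percentile, R quantile type 7) and returns
#' the resulting connected components as aggregate candidates. This is the
#' density cut that separates aggregates from background.
#'
#' @param graph a `spatial_graph` from [build_knn_emst()].
#' @param percentile cut percentile of the edge-length distribution
#'   (default 95).
#' @return list of `aggregate_cluster` objects, ordered by decreasing size
#'   then by first member index.
#' @export
cut_tree_at_percentile <- function(graph, percentile = 95) {
  stopifnot(inherits(graph, "spatial_graph"))
  edges <- graph$edges
  if (nrow(edges)) {
    thr <- stats::quantile(edges$length, percentile / 100, type = 7,
                           names = FALSE)
    edges <- edges[edges$length <= thr, , drop = FALSE]
  }
  membership <- .graph_components(graph, edges)
  comps <- split(seq_len(graph$n_nodes), membership)
  ord <- order(-lengths(comps), vapply(comps, min, 0L))
  comps <- comps[ord]
  lapply(seq_along(comps), function(i)
    .make_cluster(i, comps[[i]], graph$points))
}

#' Discard aggregates below a size threshold
#'
#' Aggregates with fewer detected fluorophores than `min_size` (default 100)
#' are excluded; the survivors are re-indexed deterministically by
#' decreasing size, ties by first member index.
#'
#' @param clusters list of `aggregate_cluster` objects.
#' @param min_size minimum number of member localizations.
#' @return filtered, re-indexed list of `aggregate_cluster` objects.
#' @export
filter_clusters <- function(clusters, min_size = 100) {
  stopifnot(min_size >= 1)
  keep <- clusters[vapply(clusters, function(cl) length(cl$members), 0L) >=
                     min_size]
  if (!length(keep)) return(list())
  ord <- order(-vapply(keep, function(cl) length(cl$members), 0L),
               vapply(keep, function(cl) min(cl$members), 0L))
  keep <- keep[ord]
  for (i in seq_along(keep)) keep[[i]]$id <- i
  keep
}

#' Segment aggregates from a localization table
#'
#' Convenience wrapper: EMST over all localizations, percentile cut, size
#' filter.
#'
#' @param table a [localization_table()].
#' @param knn nearest-neighbor candidates per point.
#' @param percentile edge-length cut percentile.
#' @param min_size minimum aggregate size (localizations).
#' @return list of `aggregate_cluster` objects.
#' @export
segment_aggregates <- function(table, knn = 30, percentile = 95,
                               min_size = 100) {
  emst <- build_knn_emst(table, k = knn)
  filter_clusters(cut_tree_at_percentile(emst, percentile), min_size)
}

#' Per-frame refined membership of an aggregate
#'
#' REPLOM localizations are permanent records of growth, so the point set of
#' an aggregate at frame `f` is the cumulative set of its members detected
#' at or before `f`. That set is refined by a second, stricter EMST cut (10
#' neighbors, 400 nm cutoff by default) and the largest connected subgroup
#' is defined to be the aggregate for that frame; ties are broken by the
#' earliest first-detection frame, then by lowest member index.
#'
#' @param cluster an `aggregate_cluster`.
#' @param table the [localization_table()] the cluster was segmented from.
#' @param frame frame index (within the table's frame range).
#' @param k refinement nearest-neighbor count.
#' @param cutoff refinement edge cutoff in nm.
#' @return list of class `frame_membership` with `cluster_id`, `frame`,
#'   `members` (row indices into `table`, possibly empty).
#' @export
frame_membership <- function(cluster, table, frame, k = 10, cutoff = 400) {
  stopifnot(inherits(cluster, "aggregate_cluster"),
            inherits(table, "localization_table"))
  if (frame < min(table$frame) || frame > max(table$frame))
    stop("frame ", frame, " outside table range")
  members <- cluster$members[table$frame[cluster$members] <= frame]
  out <- function(m) structure(list(cluster_id = cluster$id, frame = frame,
                                    members = m),
                               class = "frame_membership")
  if (length(members) == 0) return(out(integer(0)))
  if (length(members) == 1) return(out(members))
  pts <- cbind(table$x[members], table$y[members])
  emst <- build_knn_emst(pts, k = k)
  edges <- emst$edges[emst$edges$length <= cutoff, , drop = FALSE]
  membership <- .graph_components(emst, edges)
  comps <- split(seq_along(members), membership)
  sizes <- lengths(comps)
  first_frame <- vapply(comps, function(ix)
    min(table$frame[members[ix]]), 0)
  first_idx <- vapply(comps, function(ix) min(members[ix]), 0L)
  best <- order(-sizes, first_frame, first_idx)[1]
  out(sort(members[comps[[best]]]))
}
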