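# Exact range queries on trees and forests, with triangle-inequality
# pruning, distance-call instrumentation, and a brute-force oracle.

#' Children that must be visited for a range query at one node
#'
#' For each pivot `j` with median distance `dm_j` and node band half-width
#' `tau`, the low side (bit 0) must be searched iff `d(q, p_j) - r < dm_j -
#' tau` and the high side (bit 1) iff `d(q, p_j) + r >= dm_j + tau`; by the
#' triangle inequality any point in a skipped side is strictly farther than
#' `r` from the query. The visited children are the Cartesian product of
#' the needed sides under the [child_label()] bit convention. When the
#' query interval lies entirely inside a pivot's exclusion band no child of
#' this node can contain a hit (those points live in later trees of the
#' forest) and the empty set is returned.
#'
#' @param pivot_distances distances from the query to the node's pivots
#'   (pivot 0 first).
#' @param medians per-pivot median distances.
#' @param tau the node's exclusion band half-width.
#' @param r query radius.
#' @return sorted integer vector of child labels to visit.
#' @export
#' @examples
#' # four pivots p0..p3, medians c(15, 14, 15, 16), tau = 2, radius 4:
#' children_to_visit(c(2, 14, 18, 26), c(15, 14, 15, 16), tau = 2, r = 4)
children_to_visit <- function(pivot_distances, medians, tau, r) {
  d <- length(pivot_distances)
  stopifnot(length(medians) == d, tau >= 0, r >= 0)
  sides <- vector("list", d)
  for (j in seq_len(d)) {
    s <- integer(0)
    if (pivot_distances[j] - r < medians[j] - tau) s <- c(s, 0L)
    if (pivot_distances[j] + r >= medians[j] + tau) s <- c(s, 1L)
    if (length(s) == 0L) return(integer(0))
    sides[[j]] <- s
  }
  grid <- expand.grid(sides, KEEP.OUT.ATTRS = FALSE)
  labels <- as.integer(as.matrix(grid) %*% 2L^(seq_len(d) - 1L))
  sort(labels)
}

.query_tree <- function(forest, root, q_enc, r, counter) {
  hits_idx <- integer(0); hits_dist <- numeric(0)
  nodes <- 0L
  visit <- function(node) {
    nodes <<- nodes + 1L
    if (node$is_leaf) {
      dv <- .dist_block(forest$dist, forest$enc, node$points, q_enc)
      counter$calls <- counter$calls + length(node$points)
      sel <- dv <= r
      hits_idx <<- c(hits_idx, node$points[sel])
      hits_dist <<- c(hits_dist, dv[sel])
      return(invisible())
    }
    pd <- .dist_block(forest$dist, forest$enc, node$pivots, q_enc)
    counter$calls <- counter$calls + length(node$pivots)
    sel <- pd <= r
    hits_idx <<- c(hits_idx, node$pivots[sel])
    hits_dist <<- c(hits_dist, pd[sel])
    for (lab in children_to_visit(pd, node$medians, node$tau, r)) {
      ch <- node$children[[lab + 1L]]
      if (!is.null(ch)) visit(ch)
    }
  }
  visit(root)
  list(idx = hits_idx, dist = hits_dist, nodes = nodes)
}

.query_result <- function(forest, idx, dist, calls, nodes) {
  hits <- cbind(forest$points[idx, , drop = FALSE],
                data.frame(distance = dist))
  hits <- hits[order(idx), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- "data.frame"
  structure(list(hits = hits, point_index = sort(idx),
                 distance_calls = calls, nodes_visited = nodes),
            class = "apf_query")
}

#' @export
print.apf_query <- function(x, ...) {
  cat(sprintf("<apf_query> %d hit(s), %d distance call(s), %d node(s) visited\n",
              nrow(x$hits), x$distance_calls, x$nodes_visited))
  if (nrow(x$hits)) print(head(x$hits, 10))
  invisible(x)
}

#' Exact range query on a forest or a single tree
#'
#' Returns every indexed point within distance `r` of the query — no false
#' positives, no false negatives, for any radius (including radii larger
#' than the build `tau`). Each tree of the forest is searched in turn and
#' the results are pooled; pivots are real index points and are tested for
#' membership at their own node. `distance_calls` counts pairwise distance
#' evaluations, the standard cost measure for metric indexes.
#'
#' @param forest an `apforest` (or `ref_index`).
#' @param q query k-mer string (length must equal the index k).
#' @param r non-negative query radius.
#' @param tree for `range_query_tree`, the 1-based tree number to search.
#' @return an `apf_query`: `hits` data frame (`seq`, `chrom`, `start`,
#'   `strand`, `distance`), `distance_calls`, `nodes_visited`.
#' @export
range_query <- function(forest, q, r) {
  if (inherits(forest, "ref_index")) forest <- forest$forest
  stopifnot(inherits(forest, "apforest"))
  q_enc <- encode_seq(q)
  if (length(q_enc) != forest$k) {
    stop("query length ", length(q_enc), " != index k ", forest$k)
  }
  if (r < 0) stop("radius must be non-negative")
  counter <- new.env(parent = emptyenv()); counter$calls <- 0L
  idx <- integer(0); dst <- numeric(0); nodes <- 0L
  for (root in forest$trees) {
    res <- .query_tree(forest, root, q_enc, r, counter)
    idx <- c(idx, res$idx); dst <- c(dst, res$dist); nodes <- nodes + res$nodes
  }
  .query_result(forest, idx, dst, counter$calls, nodes)
}

#' @rdname range_query
#' @export
range_query_tree <- function(forest, q, r, tree = 1L) {
  if (inherits(forest, "ref_index")) forest <- forest$forest
  stopifnot(inherits(forest, "apforest"))
  q_enc <- encode_seq(q)
  if (length(q_enc) != forest$k) stop("query length != index k")
  counter <- new.env(parent = emptyenv()); counter$calls <- 0L
  res <- .query_tree(forest, forest$trees[[tree]], q_enc, r, counter)
  .query_result(forest, res$idx, res$dist, counter$calls, res$nodes)
}

#' Brute-force range scan (correctness oracle)
#'
#' Linear scan over all points, computing every distance in plain
#' vectorised R (independently of the C kernel and of the tree traversal).
#' This is the oracle that the indexed queries are verified against.
#'
#' @param points a [kmer_points()] table, character vector, or `apforest`.
#' @param q query k-mer string.
#' @param r radius.
#' @param dist a `dist_fn` (default unweighted Hamming); ignored when
#'   `points` is a forest (the forest's own metric is used).
#' @return data frame of hits with a `distance` column, in point order.
#' @export
brute_force_range <- function(points, q, r, dist = hamming_distance()) {
  if (inherits(points, "ref_index")) points <- points$forest
  if (inherits(points, "apforest")) {
    dist <- points$dist
    points <- points$points
  }
  points <- .as_kmer_points(points)
  q_enc <- encode_seq(q)
  if (nrow(points) == 0L) dv <- numeric(0)
  else if (dist$type == "hamming") {
    enc <- encode_seqs(points$seq)
    if (length(q_enc) != nrow(enc)) stop("query length != point length")
    dv <- colSums(enc != q_enc | enc == 0L)
  } else {
    dv <- vapply(points$seq, function(s) dist$pair(s, tolower(q)), numeric(1),
                 USE.NAMES = FALSE)
  }
  out <- cbind(points[dv <= r, , drop = FALSE],
               data.frame(distance = dv[dv <= r]))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Nearest indexed points within a maximum radius
#'
#' All points achieving the minimum distance to `q`, provided that minimum
#' is at most `r_max`; implemented as one exact range query post-filtered
#' to the tied minimum. Used by the mapper to collect top-scoring seeds.
#'
#' @inheritParams range_query
#' @param r_max maximum radius to consider.
#' @return an `apf_query` whose hits all share the minimal distance (empty
#'   when nothing lies within `r_max`).
#' @export
nearest_within <- function(forest, q, r_max) {
  res <- range_query(forest, q, r_max)
  if (nrow(res$hits) == 0L) return(res)
  dmin <- min(res$hits$distance)
  keep <- res$hits$distance == dmin
  res$point_index <- res$point_index[keep]
  res$hits <- res$hits[keep, , drop = FALSE]
  rownames(res$hits) <- NULL
  res
}
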