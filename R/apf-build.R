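# Construction of the adaptive projection forest: multi-pivot
# excluded-middle vantage-point trees chained into a forest through their
# exclusion sets.

#' Build parameters for the adaptive projection forest
#'
#' Three quantities control the exclusion machinery: `tau`, the half-width
#' of the exclusion band around each pivot's median distance; `m`, the
#' maximum tolerated fraction of a node's points falling in the exclusion
#' region; and `D`, the maximum number of pivots per node (a node with `d`
#' pivots has `2^d` children). When `tau` is numeric it is applied at every
#' node and `m` acts as the pivot-addition cap: pivots are added one at a
#' time until the realized exclusion fraction drops to `m` or `d = D`. When
#' `tau = "auto"`, each node derives the largest integer band half-width
#' whose exclusion fraction stays within `m`.
#'
#' A point is excluded at a node when, for some pivot `j` with median
#' distance `dm_j`, its distance `d` satisfies `dm_j - tau <= d < dm_j +
#' tau` (half-open, union over pivots). Excluded points are withheld from
#' all children and seed the next tree of the forest.
#'
#' @param tau exclusion half-width in distance units, or `"auto"`.
#' @param m maximum exclusion fraction in `[0, 1]`.
#' @param D maximum pivots per node (integer >= 1).
#' @param leaf_size maximum number of points held in a leaf.
#' @param pivot_strategy `"optimal"` (next pivot at the median distance from
#'   the previous one), `"random"`, or `"poor"` (closest to the previous
#'   one; included for index-quality experiments).
#' @param seed RNG seed making the build deterministic.
#' @return an object of class `apf_params`.
#' @export
apf_params <- function(tau = 2, m = 0.1, D = 4, leaf_size = 32,
                       pivot_strategy = c("optimal", "random", "poor"),
                       seed = 1L) {
  pivot_strategy <- match.arg(pivot_strategy)
  if (!identical(tau, "auto")) {
    tau <- as.numeric(tau)
    if (is.na(tau) || tau < 0) stop("tau must be >= 0 or \"auto\"")
  }
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  D <- as.integer(D); leaf_size <- as.integer(leaf_size)
  if (D < 1L) stop("D must be >= 1")
  if (leaf_size < 1L) stop("leaf_size must be >= 1")
  structure(list(tau = tau, m = m, D = D, leaf_size = leaf_size,
                 pivot_strategy = pivot_strategy, seed = as.integer(seed)),
            class = "apf_params")
}

#' @export
print.apf_params <- function(x, ...) {
  cat(sprintf("<apf_params> tau=%s m=%g D=%d leaf_size=%d strategy=%s seed=%d\n",
              format(x$tau), x$m, x$D, x$leaf_size, x$pivot_strategy, x$seed))
  invisible(x)
}

#' Child label from per-pivot distances
#'
#' Bit `j` of the label is 0 when the distance to pivot `j` is strictly
#' below that pivot's median distance, and 1 when it is greater than or
#' equal to it; the label is the integer with those bits (`sum(bit_j *
#' 2^j)`). With four pivots, a point at or above the median for pivots 0, 2
#' and 3 but below it for pivot 1 gets label 13 (binary 1101 reading pivot
#' 3 down to pivot 0).
#'
#' @param distances per-pivot distances of one point (pivot 0 first).
#' @param medians per-pivot median distances.
#' @return integer child label in `[0, 2^d)`.
#' @export
#' @examples
#' child_label(c(5, 1, 7, 9), c(4, 3, 6, 8))  # 13
child_label <- function(distances, medians) {
  d <- length(distances)
  stopifnot(length(medians) == d)
  as.integer(sum(as.integer(distances >= medians) * 2^(seq_len(d) - 1L)))
}

#' Select a pivot from a point set
#'
#' Implements the three pivot-selection strategies studied with the index:
#' `"optimal"` picks the point whose distance to the previous pivot equals
#' the (upper) median of all candidate distances; `"random"` draws
#' uniformly; `"poor"` picks the candidate closest to the previous pivot
#' (excluding distance-0 duplicates), the deliberate worst case. The first
#' pivot of a node is always a uniform random draw. Ties are broken by the
#' lowest `(chrom, start, strand)` triple so builds are reproducible.
#'
#' @param points a [kmer_points()] table (or character vector of k-mers).
#' @param strategy one of `"optimal"`, `"random"`, `"poor"`.
#' @param prev row index of the previous pivot in `points`, or `NULL` for
#'   the first pivot.
#' @param dist a `dist_fn` (default unweighted Hamming).
#' @param seed optional seed for the random draws.
#' @return the row index of the selected pivot.
#' @export
select_pivot <- function(points, strategy = c("optimal", "random", "poor"),
                         prev = NULL, dist = hamming_distance(), seed = NULL) {
  strategy <- match.arg(strategy)
  points <- .as_kmer_points(points)
  enc <- encode_seqs(points$seq)
  rank <- order(points$chrom, points$start, points$strand)
  tie_rank <- integer(nrow(points)); tie_rank[rank] <- seq_len(nrow(points))
  cand <- setdiff(seq_len(nrow(points)), prev)
  if (length(cand) == 0L) stop("no candidate points")
  draw <- function() cand[sample.int(length(cand), 1L)]
  pick <- function() {
    if (strategy == "random" || is.null(prev)) return(draw())
    dv <- .dist_block(dist, enc, cand, enc[, prev])
    if (strategy == "optimal") {
      target <- upper_median(dv)
      hits <- cand[dv == target]
    } else {
      pos <- dv > 0
      if (!any(pos)) return(cand[which.min(tie_rank[cand])])
      hits <- cand[pos][dv[pos] == min(dv[pos])]
    }
    hits[which.min(tie_rank[hits])]
  }
  if (is.null(seed)) pick() else with_seed(seed, pick())
}

# ---- internal construction -------------------------------------------------

# Partition one node's point set (indices into the build matrix).
# Returns list(leaf=TRUE) when the node degenerates, else
# list(leaf=FALSE, pivots, medians, tau, excl_frac, children=list of index
# vectors (length 2^d), excluded = index vector).
.partition_node <- function(idx, env) {
  params <- env$params; dist <- env$dist; enc <- env$enc
  m_cap <- params$m
  S <- idx
  pivots <- integer(0)
  dvecs <- list()
  medians <- numeric(0)
  tau <- if (identical(params$tau, "auto")) NA_real_ else params$tau
  p <- S[sample.int(length(S), 1L)]
  repeat {
    pos <- match(p, S)
    S <- S[-pos]
    if (length(dvecs)) dvecs <- lapply(dvecs, function(v) v[-pos])
    if (length(S) == 0L) return(list(leaf = TRUE))
    dv <- .dist_block(dist, enc, S, enc[, p])
    if (length(pivots) == 0L && diff(range(dv)) == 0) {
      # no separating information from any pivot of an equidistant cloud
      return(list(leaf = TRUE))
    }
    pivots <- c(pivots, p)
    dvecs[[length(pivots)]] <- dv
    medians <- c(medians, upper_median(dv))
    if (is.na(tau)) {
      # derive the widest integer band staying within the exclusion cap
      dm <- medians[1L]
      tau_try <- 0
      repeat {
        frac <- mean(dm - (tau_try + 1) <= dv & dv < dm + (tau_try + 1))
        if (frac > m_cap) break
        tau_try <- tau_try + 1
        if (tau_try > env$k) break
      }
      tau <- tau_try
    }
    excl <- rep(FALSE, length(S))
    for (j in seq_along(pivots)) {
      excl <- excl | (medians[j] - tau <= dvecs[[j]] & dvecs[[j]] < medians[j] + tau)
    }
    frac <- mean(excl)
    if (frac <= m_cap || length(pivots) >= params$D) break
    # add a pivot, chained from the previous one by the configured strategy
    p <- .next_pivot(S, dv, params$pivot_strategy, env$tie_rank)
    if (is.na(p)) break
  }
  # When the band swallows every remaining point they are all deferred to
  # the next tree; the node keeps only its pivots (empty children), which
  # also guarantees the forest loop terminates.
  d <- length(pivots)
  keep <- which(!excl)
  labels <- integer(length(keep))
  for (j in seq_len(d)) {
    labels <- labels + as.integer(dvecs[[j]][keep] >= medians[j]) * 2L^(j - 1L)
  }
  children <- split(S[keep], factor(labels, levels = 0:(2L^d - 1L)))
  list(leaf = FALSE, pivots = pivots, medians = medians, tau = tau,
       excl_frac = frac, n_points = length(S),
       children = children, excluded = S[excl])
}

.next_pivot <- function(S, dv_prev, strategy, tie_rank) {
  if (strategy == "random") return(S[sample.int(length(S), 1L)])
  if (strategy == "optimal") {
    target <- upper_median(dv_prev)
    hits <- S[dv_prev == target]
  } else {
    pos <- dv_prev > 0
    if (!any(pos)) return(NA_integer_)
    hits <- S[pos][dv_prev[pos] == min(dv_prev[pos])]
  }
  hits[which.min(tie_rank[hits])]
}

.build_tree_rec <- function(idx, env) {
  if (length(idx) <= env$params$leaf_size) {
    return(list(is_leaf = TRUE, points = idx))
  }
  part <- .partition_node(idx, env)
  if (part$leaf) return(list(is_leaf = TRUE, points = idx))
  if (length(part$excluded)) {
    env$pool[[length(env$pool) + 1L]] <- part$excluded
  }
  children <- lapply(part$children, function(ch) {
    if (length(ch) == 0L) NULL else .build_tree_rec(ch, env)
  })
  list(is_leaf = FALSE, pivots = part$pivots, medians = part$medians,
       tau = part$tau, excl_frac = part$excl_frac, n_points = part$n_points,
       children = children)
}

#' Build one tree and return its exclusion pool
#'
#' Lower-level entry point used by [build_forest()]; exposed for structural
#' tests. Recursively partitions `points`, collecting every point that fell
#' in an exclusion band anywhere in the tree into a single pool.
#'
#' @inheritParams build_forest
#' @return list with `tree` (the root node), `size` (points retained in this
#'   tree) and `excluded` (integer indices of pooled exclusion points).
#' @export
build_tree <- function(points, params = apf_params(),
                       dist = hamming_distance()) {
  points <- .as_kmer_points(points)
  env <- .build_env(points, params, dist)
  res <- with_seed(params$seed, .build_tree_rec(seq_len(nrow(points)), env))
  excluded <- if (length(env$pool)) sort(unlist(env$pool)) else integer(0)
  list(tree = res, size = nrow(points) - length(excluded), excluded = excluded)
}

.build_env <- function(points, params, dist) {
  enc <- encode_seqs(points$seq)
  rank <- order(points$chrom, points$start, points$strand)
  tie_rank <- integer(nrow(points)); tie_rank[rank] <- seq_len(nrow(points))
  env <- new.env(parent = emptyenv())
  env$enc <- enc; env$params <- params; env$dist <- dist
  env$tie_rank <- tie_rank; env$k <- nrow(enc); env$pool <- list()
  env
}

#' Build an adaptive projection forest over k-mer points
#'
#' Builds excluded-middle vantage-point trees one after another: points
#' falling in any pivot's exclusion band are withheld from the tree being
#' built and pooled to seed the next tree, until the pool is empty. Every
#' input point ends up in exactly one leaf (or as a pivot) of exactly one
#' tree, and range queries on the forest are exact for any radius.
#'
#' @param points a [kmer_points()] table (or character vector of k-mers);
#'   duplicate `(seq, chrom, start, strand)` rows are rejected.
#' @param params an [apf_params()] object.
#' @param dist a `dist_fn`; default unweighted Hamming.
#' @return an object of class `apforest`.
#' @export
#' @examples
#' set.seed(1)
#' pts <- kmer_points(vapply(1:100, function(i)
#'   paste(sample(c("a","c","g","t"), 8, TRUE), collapse = ""), ""))
#' fst <- build_forest(pts, apf_params(tau = 1, seed = 7))
#' fst
build_forest <- function(points, params = apf_params(),
                         dist = hamming_distance()) {
  points <- .as_kmer_points(points)
  key <- paste(points$seq, points$chrom, points$start, points$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (seq, chrom, start, strand) points in input")
  }
  env <- .build_env(points, params, dist)
  trees <- list()
  sizes <- integer(0)
  remaining <- seq_len(nrow(points))
  with_seed(params$seed, {
    while (length(remaining) > 0L) {
      env$pool <- list()
      root <- .build_tree_rec(remaining, env)
      excluded <- if (length(env$pool)) unlist(env$pool) else integer(0)
      trees[[length(trees) + 1L]] <- root
      sizes <- c(sizes, length(remaining) - length(excluded))
      stopifnot(length(excluded) < length(remaining))  # termination guard
      remaining <- sort(excluded)
    }
  })
  structure(list(points = points, enc = env$enc, k = env$k, dist = dist,
                 params = params, trees = trees, tree_sizes = sizes,
                 n = nrow(points)),
            class = "apforest")
}

#' @export
print.apforest <- function(x, ...) {
  cat(sprintf("<apforest> %d points (k=%d), %d tree(s); tau=%s m=%g D=%d leaf_size=%d\n",
              x$n, x$k, length(x$trees), format(x$params$tau), x$params$m,
              x$params$D, x$params$leaf_size))
  cat(" tree sizes:", paste(x$tree_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.apforest <- function(object, ...) {
  st <- forest_stats(object)
  print(object)
  cat(sprintf(" nodes=%d leaves=%d pivots=%d max depth=%d\n",
              st$n_internal, st$n_leaves, st$n_pivots, st$max_depth))
  invisible(st)
}

#' Structural summary of a built forest
#'
#' Walks every tree and tallies nodes, leaves, pivots, depth, leaf point
#' counts and per-internal-node exclusion fractions, re-deriving the
#' conservation identity `sum(leaf points) + pivots == n`.
#'
#' @param forest an `apforest`.
#' @return list of counts plus a data frame `nodes` (one row per internal
#'   node: depth, n_pivots, exclusion fraction, tau applied).
#' @export
forest_stats <- function(forest) {
  stopifnot(inherits(forest, "apforest"))
  n_leaves <- 0L; n_internal <- 0L; n_pivots <- 0L; leaf_points <- 0L
  max_depth <- 0L
  rows <- list()
  walk <- function(node, depth) {
    max_depth <<- max(max_depth, depth)
    if (node$is_leaf) {
      n_leaves <<- n_leaves + 1L
      leaf_points <<- leaf_points + length(node$points)
    } else {
      n_internal <<- n_internal + 1L
      n_pivots <<- n_pivots + length(node$pivots)
      rows[[length(rows) + 1L]] <<- data.frame(
        depth = depth, n_pivots = length(node$pivots),
        excl_frac = node$excl_frac, tau = node$tau)
      for (ch in node$children) if (!is.null(ch)) walk(ch, depth + 1L)
    }
  }
  for (tr in forest$trees) walk(tr, 0L)
  nodes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(depth = integer(0), n_pivots = integer(0),
               excl_frac = numeric(0), tau = numeric(0))
  list(n_trees = length(forest$trees), n_internal = n_internal,
       n_leaves = n_leaves, n_pivots = n_pivots,
       points_in_leaves = leaf_points, total = leaf_points + n_pivots,
       max_depth = max_depth, tree_sizes = forest$tree_sizes, nodes = nodes)
}

#' Save / load a forest index
#'
#' Serializes the forest (points, encoded matrix, structure and build
#' parameters) to a single file; a reloaded index answers every query
#' identically to the original.
#'
#' @param forest an `apforest` (or `ref_index`).
#' @param path file path.
#' @return `load_index` returns the restored object.
#' @export
save_index <- function(forest, path) {
  stopifnot(inherits(forest, c("apforest", "ref_index")))
  saveRDS(list(format = "apforest-index", version = 1L, object = forest),
          file = path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "apforest-index")) stop("not an apforest index file")
  x$object
}
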