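#' Distance functions over fixed-length nucleotide strings
#'
#' The index and mapper operate on a *metric* over equal-length DNA strings:
#' a distance `d` satisfying non-negativity, symmetry, the triangle
#' inequality and identity of indiscernibles. The default metric is
#' unweighted Hamming distance — the count of mismatching positions — which
#' is what the read-mapping path uses throughout. A weighted Hamming variant
#' (e.g. pricing transitions and transversions differently) can be
#' constructed with [weight_scheme()]; its per-symbol cost table is validated
#' as a metric over the 4-letter alphabet at construction time, because the
#' correctness of triangle-inequality pruning in the index depends on it.
#'
#' @param a,b equal-length nucleotide strings (`acgt`, any case).
#' @param weights optional [weight_scheme()]; when supplied the distance is
#'   the sum of per-position substitution costs.
#' @return a non-negative number; 0 if and only if `a == b`.
#' @seealso [banded_nw()], [query_ball_size()], [check_metric_axioms()]
#' @export
#' @examples
#' hamming("aaaa", "aaca")  # 1
#' hamming("aaaa", "cccc")  # 4
hamming <- function(a, b, weights = NULL) {
  ea <- encode_seq(a)
  eb <- encode_seq(b)
  if (length(ea) != length(eb)) {
    stop("length mismatch: ", length(ea), " vs ", length(eb))
  }
  if (any(ea == 0L) || any(eb == 0L)) {
    stop("non-nucleotide character (alphabet is a, c, g, t)")
  }
  if (is.null(weights)) {
    sum(ea != eb)
  } else {
    stopifnot(inherits(weights, "weight_scheme"))
    sum(weights$cost[cbind(ea, eb)])
  }
}

#' Substitution weight scheme for weighted Hamming distance
#'
#' Prices each nucleotide substitution as either a transition or a
#' transversion. The `pairing` argument selects which two unordered pairs
#' count as transitions; the biochemical convention is `a<->g` and `c<->t`
#' (purine/purine, pyrimidine/pyrimidine). Both costs must be strictly
#' positive (identity of indiscernibles) and the resulting per-symbol cost
#' table must satisfy the triangle inequality over the alphabet, which is
#' checked exhaustively at construction.
#'
#' @param transition cost of a transition substitution (> 0).
#' @param transversion cost of a transversion substitution (> 0).
#' @param pairing list of two character vectors of length 2 naming the
#'   transition pairs; default `list(c("a","g"), c("c","t"))`.
#' @param validate check the metric axioms on the cost table (default TRUE).
#'   Disabling is only useful to construct deliberately broken schemes for
#'   testing [check_metric_axioms()].
#' @return an object of class `weight_scheme` with a 4x4 `cost` matrix.
#' @export
#' @examples
#' ws <- weight_scheme(transition = 1, transversion = 2)
#' hamming("aaaa", "gaaa", weights = ws)  # 1 (a->g transition)
#' hamming("aaaa", "caaa", weights = ws)  # 2 (a->c transversion)
weight_scheme <- function(transition = 1, transversion = 1,
                          pairing = list(c("a", "g"), c("c", "t")),
                          validate = TRUE) {
  if (transition <= 0 || transversion <= 0) {
    stop("costs must be strictly positive")
  }
  cost <- matrix(transversion, 4, 4, dimnames = list(.ALPHABET, .ALPHABET))
  diag(cost) <- 0
  for (p in pairing) {
    p <- tolower(p)
    if (length(p) != 2L || !all(p %in% .ALPHABET)) {
      stop("pairing entries must be two nucleotides each")
    }
    cost[p[1], p[2]] <- transition
    cost[p[2], p[1]] <- transition
  }
  ws <- structure(list(transition = transition, transversion = transversion,
                       cost = cost), class = "weight_scheme")
  if (validate) {
    viol <- .cost_table_violation(cost)
    if (!is.null(viol)) {
      stop("weight scheme is not a metric over {a,c,g,t}: ", viol)
    }
  }
  ws
}

# NULL if the 4x4 cost table is a metric, else a description of a violation.
.cost_table_violation <- function(cost) {
  for (x in 1:4) for (y in 1:4) {
    if (cost[x, y] != cost[y, x]) {
      return(sprintf("cost(%s,%s) != cost(%s,%s)",
                     .ALPHABET[x], .ALPHABET[y], .ALPHABET[y], .ALPHABET[x]))
    }
    if (x != y && cost[x, y] <= 0) {
      return(sprintf("cost(%s,%s) <= 0", .ALPHABET[x], .ALPHABET[y]))
    }
    for (z in 1:4) {
      if (cost[x, z] > cost[x, y] + cost[y, z] + 1e-12) {
        return(sprintf("cost(%s,%s) > cost(%s,%s) + cost(%s,%s)",
                       .ALPHABET[x], .ALPHABET[z], .ALPHABET[x], .ALPHABET[y],
                       .ALPHABET[y], .ALPHABET[z]))
      }
    }
  }
  NULL
}

#' Distance-function objects used by the index
#'
#' `hamming_distance()` returns the default unweighted Hamming metric;
#' `weighted_hamming()` wraps a [weight_scheme()]. Both return a `dist_fn`
#' object: a named metric with a scalar evaluator (`$pair`) plus internal
#' vectorised fast paths used during index construction and querying.
#'
#' @param weights a [weight_scheme()].
#' @return an object of class `dist_fn`.
#' @export
hamming_distance <- function() {
  structure(list(name = "hamming", type = "hamming",
                 pair = function(a, b) hamming(a, b)),
            class = "dist_fn")
}

#' @rdname hamming_distance
#' @export
weighted_hamming <- function(weights) {
  stopifnot(inherits(weights, "weight_scheme"))
  structure(list(name = "weighted_hamming", type = "weighted_hamming",
                 cost = weights$cost,
                 pair = function(a, b) hamming(a, b, weights = weights)),
            class = "dist_fn")
}

#' @export
print.dist_fn <- function(x, ...) {
  cat("<dist_fn>", x$name, "\n")
  invisible(x)
}

# Distances from encoded query q to columns idx of encoded matrix mat.
.dist_block <- function(fn, mat, idx, q) {
  if (length(idx) == 0L) return(numeric(0))
  if (fn$type == "hamming") {
    .hamming_block(mat, as.integer(idx), as.integer(q))
  } else if (fn$type == "weighted_hamming") {
    block <- mat[, idx, drop = FALSE]
    if (any(block == 0L) || any(q == 0L)) {
      stop("non-nucleotide character in weighted-distance path")
    }
    colSums(matrix(fn$cost[cbind(rep.int(q, length(idx)), as.vector(block))],
                   nrow = nrow(mat)))
  } else {
    vapply(idx, function(j) fn$pair(decode_enc(mat[, j]), decode_enc(q)),
           numeric(1))
  }
}

#' Banded Needleman-Wunsch edit distance
#'
#' Global alignment cost with the dynamic-programming matrix restricted to a
#' diagonal band of half-width `band`, i.e. at most `band` gaps on either
#' side of the main diagonal. With unit costs and `band >= max(nchar(a),
#' nchar(b))` this equals the unbanded Levenshtein distance. Provided as the
#' second classical metric over sequences; the default mapping path is
#' Hamming-only, so this function is not wired into the mapper.
#'
#' @param a,b nucleotide strings (lengths may differ by at most `band`).
#' @param band non-negative integer half-width of the diagonal band.
#' @param match,mismatch,gap costs (defaults 0/1/1, i.e. unit edit distance).
#' @return minimum alignment cost within the band.
#' @export
#' @examples
#' banded_nw("acgta", "acgt", band = 1)  # 1
#' banded_nw("acgt", "acct", band = 0)   # 1 (substitution only)
banded_nw <- function(a, b, band, match = 0, mismatch = 1, gap = 1) {
  band <- as.integer(band)
  if (band < 0L) stop("band must be non-negative")
  ea <- encode_seq(a); eb <- encode_seq(b)
  n <- length(ea); m <- length(eb)
  if (abs(n - m) > band) {
    stop("infeasible band: |len(a) - len(b)| = ", abs(n - m), " > ", band)
  }
  INF <- Inf
  # dp over rows i = 0..n, cells j restricted to i - band .. i + band
  prev <- rep(INF, m + 1L)
  for (j in 0:min(band, m)) prev[j + 1L] <- j * gap
  for (i in seq_len(n)) {
    cur <- rep(INF, m + 1L)
    jlo <- max(0L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      best <- INF
      if (j > 0L && i > 0L) {
        sub <- prev[j] + if (ea[i] == eb[j] && ea[i] != 0L) match else mismatch
        if (sub < best) best <- sub
      }
      if (prev[j + 1L] + gap < best) best <- prev[j + 1L] + gap  # delete a[i]
      if (j > 0L && cur[j] + gap < best) best <- cur[j] + gap    # insert b[j]
      cur[j + 1L] <- best
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Expected query-ball size for Hamming range queries
#'
#' Number of distinct strings at Hamming distance 1..`r` from any fixed
#' k-mer over an alphabet of `n` symbols: `sum_{i=1}^{r} C(k,i) (n-1)^i`.
#' This quantifies how the candidate neighbourhood grows with the query
#' radius and motivates short seeds with small per-seed radii.
#'
#' @param k k-mer length.
#' @param r query radius, `0 <= r <= k`.
#' @param n alphabet size (4 for DNA).
#' @return the neighbourhood size (0 when `r = 0`).
#' @export
#' @examples
#' query_ball_size(4, 1)      # 12
#' query_ball_size(2, 2)      # 15 = 4^2 - 1
query_ball_size <- function(k, r, n = 4) {
  if (r > k) stop("r must not exceed k")
  if (r < 0 || k < 0 || n < 2) stop("need 0 <= r <= k and n >= 2")
  if (r == 0) return(0)
  i <- seq_len(r)
  sum(choose(k, i) * (n - 1)^i)
}

#' Empirically check the metric axioms of a distance function
#'
#' Tests non-negativity, identity of indiscernibles, symmetry (all pairs of
#' the sample) and the triangle inequality (all triples, or a random subset
#' when the sample is large) for a distance over equal-length strings.
#' Unweighted Hamming passes on any sample; the report is mainly useful for
#' vetting user-supplied weighted or custom distances before indexing.
#'
#' @param fn a `dist_fn` or a plain `function(a, b)`.
#' @param sample character vector of equal-length strings (non-empty).
#' @param max_triples cap on the number of triples tested (random subset
#'   beyond this; seeded internally for reproducibility).
#' @return list with logical `ok` and a data frame `violations` (axiom,
#'   witness strings, values).
#' @export
check_metric_axioms <- function(fn, sample, max_triples = 20000L) {
  if (length(sample) == 0L) stop("sample must be non-empty")
  pair <- if (inherits(fn, "dist_fn")) fn$pair else fn
  n <- length(sample)
  viol <- list()
  add <- function(axiom, x, y, z = NA_character_, detail = "") {
    viol[[length(viol) + 1L]] <<- data.frame(
      axiom = axiom, x = x, y = y, z = z, detail = detail,
      stringsAsFactors = FALSE)
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- pair(sample[i], sample[j])
  for (i in seq_len(n)) {
    if (D[i, i] != 0) add("identity", sample[i], sample[i],
                          detail = sprintf("d(x,x) = %g", D[i, i]))
    for (j in seq_len(n)) {
      if (D[i, j] < 0) add("non-negativity", sample[i], sample[j],
                           detail = sprintf("d = %g", D[i, j]))
      if (i < j) {
        if (D[i, j] != D[j, i]) {
          add("symmetry", sample[i], sample[j],
              detail = sprintf("%g vs %g", D[i, j], D[j, i]))
        }
        if (D[i, j] == 0 && sample[i] != sample[j]) {
          add("identity", sample[i], sample[j], detail = "d = 0 but x != y")
        }
      }
    }
  }
  triples <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  if (nrow(triples) > max_triples) {
    keep <- with_seed(1L, sample.int(nrow(triples), max_triples))
    triples <- triples[keep, ]
  }
  for (t in seq_len(nrow(triples))) {
    i <- triples$i[t]; j <- triples$j[t]; k <- triples$k[t]
    if (D[i, k] > D[i, j] + D[j, k] + 1e-12) {
      add("triangle", sample[i], sample[k], sample[j],
          sprintf("d(x,z)=%g > d(x,y)+d(y,z)=%g", D[i, k], D[i, j] + D[j, k]))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(axiom = character(0), x = character(0), y = character(0),
               z = character(0), detail = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}
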