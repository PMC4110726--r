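# Shared fixture builders. All randomness is seeded at the call site.

ALPH <- c("a", "c", "g", "t")

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i) paste(sample(ALPH, k, TRUE), collapse = ""), "")
}

random_points <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kmer_points(random_kmers(n, k))
}

# plain R Hamming count, the independent oracle for the distance kernel
loop_hamming <- function(a, b) {
  x <- strsplit(tolower(a), "")[[1]]
  y <- strsplit(tolower(b), "")[[1]]
  stopifnot(length(x) == length(y))
  sum(x != y | !(x %in% ALPH))
}

# full (unbanded) Needleman-Wunsch with unit costs, the oracle for banded_nw
full_nw <- function(a, b) {
  x <- strsplit(tolower(a), "")[[1]]
  y <- strsplit(tolower(b), "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (x[i] != y[j]),
                           d[i, j + 1] + 1, d[i + 1, j] + 1)
  }
  d[n + 1, m + 1]
}

# brute-force sliding-window best placement over all positions and strands,
# in plain R (independent of the package's C kernel and of the index)
loop_best_placement <- function(genome_seqs, read) {
  best <- Inf; where <- NULL
  for (ch in names(genome_seqs)) {
    s <- genome_seqs[[ch]]
    for (st in c("+", "-")) {
      rd <- if (st == "+") tolower(read) else revcomp(read)
      L <- nchar(s); k <- nchar(rd)
      if (L < k) next
      for (pos in 0:(L - k)) {
        d <- loop_hamming(substr(s, pos + 1, pos + k), rd)
        if (d < best) { best <- d; where <- list(chrom = ch, pos = pos, strand = st) }
      }
    }
  }
  list(best = best, where = where)
}

hit_key <- function(df) sort(paste(df$seq, df$chrom, df$start, df$strand, df$distance))

# vectorised plain-R sliding-window scan (no C kernel, no index): best
# full-read placement over all positions and strands of a genome
vec_sliding <- function(genc, renc) {
  L <- length(genc); k <- length(renc)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  mism <- integer(n)
  for (i in seq_len(k)) {
    mism <- mism + (genc[i:(n + i - 1L)] != renc[i])
  }
  mism
}

vec_best_placement <- function(genome_seqs, read) {
  enc1 <- function(s) {
    m <- match(strsplit(tolower(s), "")[[1]], c("a", "c", "g", "t"))
    ifelse(is.na(m), 0L, m)
  }
  best <- Inf
  for (ch in names(genome_seqs)) {
    genc <- enc1(genome_seqs[[ch]])
    for (st in c("+", "-")) {
      rd <- if (st == "+") read else revcomp(read)
      dv <- vec_sliding(genc, enc1(rd))
      if (length(dv) && min(dv) < best) best <- min(dv)
    }
  }
  best
}
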