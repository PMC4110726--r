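# Seed-and-extend read mapping on the forest index, a deliberately crude
# hash-based first-stage aligner, and the MAPQ-driven rescue ensemble.
# Reference indexing defaults to the derived-tau rule (tau = "auto",
# m = 0.1): genomic k-mer distances are tightly concentrated around the
# median, so a fixed wide band would exile most points to later trees.

.genome_seqs <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$sequences)
  if (inherits(genome, "ref_index")) return(genome$genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(tolower(genome))
  }
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(tolower(as.character(genome)), names(genome)))
  }
  stop("cannot interpret `genome`")
}

#' Extract indexed k-mers from a reference genome
#'
#' Slides a window of width `k` along each reference sequence with the
#' given stride, on the requested strands. Windows containing characters
#' outside `acgt` (e.g. `N`) are skipped. Minus-strand points store the
#' reverse complement of the window; coordinates always refer to the
#' forward strand, 0-based.
#'
#' @param genome named character vector, `DNAStringSet`, or
#'   [simulate_genome()] output.
#' @param k k-mer length (>= 4).
#' @param stride sampling step between window starts (>= 1).
#' @param strands subset of `c("+", "-")`.
#' @return a [kmer_points()] table.
#' @export
#' @examples
#' extract_kmers(c(chr1 = "acgtacgt"), k = 4, strands = "+")
extract_kmers <- function(genome, k = 16L, stride = 1L,
                          strands = c("+", "-")) {
  k <- as.integer(k); stride <- as.integer(stride)
  if (k < 4L) stop("k must be >= 4")
  if (stride < 1L) stop("stride must be >= 1")
  strands <- match.arg(strands, several.ok = TRUE)
  seqs <- .genome_seqs(genome)
  out <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    if (L < k) {
      warning("sequence ", chrom, " shorter than k; skipped")
      next
    }
    starts <- seq.int(1L, L - k + 1L, by = stride)
    win <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("[^acgt]", win)
    starts <- starts[ok]; win <- win[ok]
    if (!length(win)) next
    if ("+" %in% strands) {
      out[[length(out) + 1L]] <- data.frame(
        seq = win, chrom = chrom, start = starts - 1L, strand = "+",
        stringsAsFactors = FALSE)
    }
    if ("-" %in% strands) {
      out[[length(out) + 1L]] <- data.frame(
        seq = revcomp(win), chrom = chrom, start = starts - 1L, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no k-mers extracted")
    return(structure(data.frame(seq = character(0), chrom = character(0),
                                start = integer(0), strand = character(0)),
                     class = c("kmer_points", "data.frame")))
  }
  df <- do.call(rbind, out)
  kmer_points(df$seq, df$chrom, df$start, df$strand)
}

#' Build a reference index for read mapping
#'
#' Extracts k-mers from the genome on both strands and builds the forest
#' over them; the returned object carries the genome itself so that seed
#' hits can be extended to full-read Hamming scores.
#'
#' @inheritParams extract_kmers
#' @param params an [apf_params()].
#' @param dist a `dist_fn`.
#' @return an object of class `ref_index`.
#' @export
reference_index <- function(genome, k = 16L, stride = 1L,
                            strands = c("+", "-"),
                            params = apf_params(tau = "auto"),
                            dist = hamming_distance()) {
  seqs <- .genome_seqs(genome)
  pts <- extract_kmers(seqs, k = k, stride = stride, strands = strands)
  forest <- build_forest(pts, params = params, dist = dist)
  structure(list(forest = forest, genome = seqs,
                 genome_enc = lapply(seqs, encode_seq),
                 k = as.integer(k), stride = as.integer(stride),
                 strands = strands),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> %d reference sequence(s), %s bp; k=%d stride=%d strands=%s\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              x$k, x$stride, paste(x$strands, collapse = "")))
  print(x$forest)
  invisible(x)
}

# mismatches of encoded read vs genome window starting at 0-based pos
.extend_score <- function(genc, pos, renc) {
  g <- genc[(pos + 1L):(pos + length(renc))]
  sum(g != renc | g == 0L)
}

.map_one <- function(read, index, r, rng_ready = TRUE) {
  k <- index$k
  len <- nchar(read)
  if (len < k) {
    return(data.frame(chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, distance = NA_real_,
                      n_candidates = 0L, status = "unmapped", mapq = 0L,
                      stringsAsFactors = FALSE))
  }
  read <- tolower(read)
  n_disjoint <- len %/% k
  offsets <- (seq_len(n_disjoint) - 1L) * k
  if (len %% k != 0L) offsets <- c(offsets, len - k)  # trailing seed overlaps
  rprime <- r %/% n_disjoint
  renc <- encode_seq(read)
  rc <- revcomp(read)
  rcenc <- encode_seq(rc)
  cand <- list()
  for (o in offsets) {
    q <- substr(read, o + 1L, o + k)
    hits <- range_query(index$forest, q, rprime)$hits
    if (!nrow(hits)) next
    pos <- ifelse(hits$strand == "+", hits$start - o,
                  hits$start - (len - k - o))
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = hits$chrom, pos = pos, strand = hits$strand,
      stringsAsFactors = FALSE)
  }
  if (length(cand)) {
    cand <- unique(do.call(rbind, cand))
    lens <- nchar(index$genome)[cand$chrom]
    cand <- cand[cand$pos >= 0L & cand$pos + len <= lens, , drop = FALSE]
  }
  if (!length(cand) || !nrow(cand)) {
    return(data.frame(chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, distance = NA_real_,
                      n_candidates = 0L, status = "unmapped", mapq = 0L,
                      stringsAsFactors = FALSE))
  }
  score <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    e <- if (cand$strand[i] == "+") renc else rcenc
    score[i] <- .extend_score(index$genome_enc[[cand$chrom[i]]], cand$pos[i], e)
  }
  best <- min(score)
  if (best > r) {
    return(data.frame(chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, distance = NA_real_,
                      n_candidates = 0L, status = "unmapped", mapq = 0L,
                      stringsAsFactors = FALSE))
  }
  ties <- which(score == best)
  second <- if (length(score) > length(ties)) min(score[-ties]) else r + 1
  if (length(ties) == 1L) {
    pick <- ties
    status <- "unique"
    mapq <- min(42L, 6L * as.integer(min(second, r + 1) - best))
  } else {
    pick <- ties[sample.int(length(ties), 1L)]
    status <- "tied_random"
    mapq <- 0L
  }
  data.frame(chrom = cand$chrom[pick], pos = as.integer(cand$pos[pick]),
             strand = cand$strand[pick], distance = best,
             n_candidates = length(ties), status = status, mapq = mapq,
             stringsAsFactors = FALSE)
}

#' Map reads with the exact seed-and-extend algorithm
#'
#' Each read is split into `floor(len/k)` non-overlapping seeds (plus one
#' trailing seed covering the last `k` bases when `k` does not divide the
#' read length). Every seed is queried against the forest with per-seed
#' radius `r' = floor(r / floor(len/k))`; by the pigeonhole principle a
#' read with at most `r` mismatches at some location must have a seed with
#' at most `r'` mismatches there, so the optimal location within the radius
#' budget is never missed. Each seed hit is projected to the implied
#' full-read location, candidates are deduplicated and scored by full-read
#' Hamming distance against the reference, and the minimal-distance
#' location is reported. Co-optimal locations are resolved by a seeded
#' uniform random pick (`status = "tied_random"`, MAPQ 0); unique hits get
#' a MAPQ that grows with the gap to the second-best candidate, capped at
#' 42.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids), or a data frame with `read_id` and `seq` columns.
#' @param read single read string for `map_read`.
#' @param index a [reference_index()].
#' @param r full-read Hamming radius budget (default 6).
#' @param seed RNG seed for tie-breaking.
#' @return data frame with one row per read: `read_id`, `chrom`, `pos`
#'   (0-based), `strand`, `distance`, `n_candidates`, `status`, `mapq`.
#' @export
map_reads <- function(reads, index, r = 6L, seed = 1L) {
  stopifnot(inherits(index, "ref_index"))
  if (is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  rows <- with_seed(seed, lapply(seqs, .map_one, index = index, r = r))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(read_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' @rdname map_reads
#' @export
map_read <- function(read, index, r = 6L, seed = 1L) {
  map_reads(setNames(read, "read1"), index, r = r, seed = seed)
}

#' Parameters of the two-stage rescue ensemble
#'
#' @param mapq_cutoff MAPQ strictly below which a first-stage alignment is
#'   considered uncertain and re-mapped (default 14).
#' @param r full-read Hamming radius for the rescue mapper.
#' @param seed RNG seed for tie-breaking in the rescue mapper.
#' @return an object of class `ensemble_params`.
#' @export
ensemble_params <- function(mapq_cutoff = 14L, r = 6L, seed = 1L) {
  if (mapq_cutoff < 0) stop("mapq_cutoff must be >= 0")
  structure(list(mapq_cutoff = as.integer(mapq_cutoff), r = as.integer(r),
                 seed = as.integer(seed)),
            class = "ensemble_params")
}

#' Rescue low-confidence alignments with the exact mapper
#'
#' Implements the two-stage ensemble: alignments whose MAPQ is at least the
#' cutoff pass through untouched; reads that the first-stage aligner left
#' unmapped or placed with MAPQ below the cutoff (the uncertain set) are
#' re-mapped with [map_reads()] and their records replaced. Rescued records
#' carry `rescued = TRUE` and a `PG:Z:apforest` tag when written to SAM.
#'
#' @param sam first-stage alignments: a path to a SAM file or a data frame
#'   from [read_sam()] / [heuristic_stub_align()].
#' @param reads the full read set (named character vector or data frame
#'   with `read_id`, `seq`, optionally `qual`); every SAM read id must be
#'   present here.
#' @param index a [reference_index()].
#' @param params an [ensemble_params()].
#' @return SAM-record data frame (see [write_sam()]) with one primary
#'   record per read and a logical `rescued` column.
#' @export
rescue_pipeline <- function(sam, reads, index, params = ensemble_params()) {
  stopifnot(inherits(index, "ref_index"))
  if (is.character(sam) && length(sam) == 1L) sam <- read_sam(sam)
  if (is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- setNames(reads$seq, ids)
    quals <- setNames(reads$qual %||% strrep("I", nchar(reads$seq)), ids)
  } else {
    seqs <- setNames(as.character(reads), names(reads))
    ids <- names(seqs)
    quals <- setNames(strrep("I", nchar(seqs)), ids)
  }
  missing <- setdiff(sam$qname, ids)
  if (length(missing)) {
    stop("read(s) in SAM but absent from the read set: ",
         paste(head(missing, 5), collapse = ", "))
  }
  unmapped <- bitwAnd(sam$flag, 4L) != 0L
  uncertain <- unmapped | sam$mapq < params$mapq_cutoff
  keep <- sam[!uncertain, , drop = FALSE]
  keep$rescued <- rep(FALSE, nrow(keep))
  rescue_ids <- sam$qname[uncertain]
  if (length(rescue_ids)) {
    mr <- map_reads(setNames(seqs[rescue_ids], rescue_ids), index,
                    r = params$r, seed = params$seed)
    resc <- mappings_to_sam(mr, seqs[rescue_ids], quals[rescue_ids])
    resc$rescued <- rep(TRUE, nrow(resc))
    out <- rbind(keep, resc)
  } else {
    out <- keep
  }
  out <- out[match(sam$qname, out$qname), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert mapper output to SAM records
#'
#' Minus-strand hits are written with the reverse-complemented read, the
#' reversed quality string and FLAG 16; positions become 1-based per the
#' SAM convention. Only Hamming (ungapped) alignments are produced, so the
#' CIGAR is always all-match.
#'
#' @param mappings output of [map_reads()].
#' @param seqs,quals named character vectors keyed by read id.
#' @return SAM-record data frame.
#' @export
mappings_to_sam <- function(mappings, seqs, quals = NULL) {
  if (is.null(quals)) quals <- setNames(strrep("I", nchar(seqs)), names(seqs))
  n <- nrow(mappings)
  out <- data.frame(qname = mappings$read_id,
                    flag = integer(n), rname = rep("*", n),
                    pos = integer(n), mapq = integer(n),
                    cigar = rep("*", n), seq = unname(seqs[mappings$read_id]),
                    qual = unname(quals[mappings$read_id]),
                    stringsAsFactors = FALSE)
  mapped <- mappings$status != "unmapped"
  out$flag[!mapped] <- 4L
  if (any(mapped)) {
    minus <- mapped & mappings$strand == "-"
    out$flag[mapped] <- ifelse(minus[mapped], 16L, 0L)
    out$rname[mapped] <- mappings$chrom[mapped]
    out$pos[mapped] <- mappings$pos[mapped] + 1L
    out$mapq[mapped] <- mappings$mapq[mapped]
    out$cigar[mapped] <- paste0(nchar(out$seq[mapped]), "M")
    if (any(minus)) {
      out$seq[minus] <- revcomp(out$seq[minus])
      out$qual[minus] <- vapply(out$qual[minus], function(q)
        paste(rev(strsplit(q, "")[[1]]), collapse = ""), "")
    }
  }
  out
}

#' Convert SAM records back to mapper-style 0-based placements
#'
#' @param sam SAM-record data frame or path.
#' @return data frame `read_id`, `chrom`, `pos` (0-based), `strand`,
#'   `mapq`, with `NA`s for unmapped records.
#' @export
sam_to_mappings <- function(sam) {
  if (is.character(sam) && length(sam) == 1L) sam <- read_sam(sam)
  unmapped <- bitwAnd(sam$flag, 4L) != 0L
  data.frame(read_id = sam$qname,
             chrom = ifelse(unmapped, NA_character_, sam$rname),
             pos = ifelse(unmapped, NA_integer_, sam$pos - 1L),
             strand = ifelse(unmapped, NA_character_,
                             ifelse(bitwAnd(sam$flag, 16L) != 0L, "-", "+")),
             mapq = sam$mapq, stringsAsFactors = FALSE)
}

#' Deliberately crude first-stage aligner
#'
#' An exact-seed hash aligner with first-hit reporting, standing in for an
#' external heuristic mapper so the ensemble can be exercised end to end.
#' Only the first `k` bases of each read are used as a seed and must match
#' the reference exactly; the first matching genomic location (in scanning
#' order) is reported, extended by full-read Hamming distance. MAPQ is high
#' for unique clean hits and low for ambiguous seeds or noisy extensions,
#' so error-laden reads end up unmapped or below typical rescue cutoffs —
#' by design.
#'
#' @param reads named character vector or data frame (`read_id`, `seq`,
#'   optional `qual`).
#' @param genome reference (named character vector or
#'   [simulate_genome()] output).
#' @param k exact seed length (default 16).
#' @return SAM-record data frame (one primary record per read).
#' @export
heuristic_stub_align <- function(reads, genome, k = 16L) {
  seqs_g <- .genome_seqs(genome)
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    rseq <- setNames(reads$seq, ids)
    rqual <- setNames(reads$qual %||% strrep("I", nchar(reads$seq)), ids)
  } else {
    rseq <- as.character(reads); ids <- names(reads)
    rqual <- setNames(strrep("I", nchar(rseq)), ids)
  }
  tab <- extract_kmers(seqs_g, k = k, stride = 1L, strands = c("+", "-"))
  dupseed <- tab$seq %in% tab$seq[duplicated(tab$seq)]
  genc <- lapply(seqs_g, encode_seq)
  n <- length(rseq)
  out <- data.frame(qname = ids, flag = rep(4L, n), rname = rep("*", n),
                    pos = rep(0L, n), mapq = rep(0L, n), cigar = rep("*", n),
                    seq = unname(rseq), qual = unname(rqual),
                    stringsAsFactors = FALSE)
  first_seed <- substr(tolower(rseq), 1L, k)
  hit <- match(first_seed, tab$seq)
  for (i in seq_len(n)) {
    h <- hit[i]
    if (is.na(h)) next
    len <- nchar(rseq[i])
    if (len < k) next
    strand <- tab$strand[h]
    pos <- if (strand == "+") tab$start[h] else tab$start[h] - (len - k)
    chrom <- tab$chrom[h]
    if (pos < 0L || pos + len > nchar(seqs_g[[chrom]])) next
    e <- if (strand == "+") encode_seq(tolower(rseq[i])) else
      encode_seq(revcomp(rseq[i]))
    d <- .extend_score(genc[[chrom]], pos, e)
    mapq <- if (dupseed[h]) 3L else max(0L, 40L - 4L * as.integer(d))
    out$flag[i] <- if (strand == "-") 16L else 0L
    out$rname[i] <- chrom
    out$pos[i] <- pos + 1L
    out$mapq[i] <- mapq
    out$cigar[i] <- paste0(len, "M")
    if (strand == "-") {
      out$seq[i] <- revcomp(rseq[i])
      out$qual[i] <- paste(rev(strsplit(rqual[i], "")[[1]]), collapse = "")
    }
  }
  out
}
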