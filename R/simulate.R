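# Synthetic genome / read simulation with a scalable position-dependent
# substitution-error profile and full truth tracking.

#' Simulate a reference genome with optional planted repeats
#'
#' Draws a uniform random ACGT background and optionally plants diverged
#' duplications: for each repeat row, the `len` bases starting at
#' `src_start` are copied to `dest_start` with each base substituted
#' independently with probability `divergence`. Planted repeats are what
#' make some simulated reads genuinely ambiguous or unrecoverable, the
#' phenomenon the evaluator's incorrect-vs-unrecoverable split measures.
#'
#' @param length genome length in bp (>= 1000).
#' @param repeats `NULL` or a data frame with columns `src_start`,
#'   `len`, `dest_start` (0-based) and `divergence` in `[0, 1]`.
#' @param seed RNG seed.
#' @param name sequence name.
#' @return object of class `synthetic_genome`: list with `sequences`
#'   (named character) and `repeats`.
#' @export
#' @examples
#' g <- simulate_genome(2000, seed = 1)
#' nchar(g$sequences)
simulate_genome <- function(length, repeats = NULL, seed = 1L,
                            name = "synth1") {
  length <- as.integer(length)
  if (length < 1000L) stop("length must be >= 1000")
  if (!is.null(repeats)) {
    need <- c("src_start", "len", "dest_start", "divergence")
    if (!all(need %in% names(repeats))) {
      stop("repeats needs columns: ", paste(need, collapse = ", "))
    }
    if (any(repeats$src_start + repeats$len > length) ||
        any(repeats$dest_start + repeats$len > length) ||
        any(repeats$src_start < 0) || any(repeats$dest_start < 0)) {
      stop("repeat interval exceeds genome length")
    }
  }
  codes <- with_seed(seed, {
    g <- sample.int(4L, length, replace = TRUE)
    if (!is.null(repeats)) {
      for (i in seq_len(nrow(repeats))) {
        src <- repeats$src_start[i] + seq_len(repeats$len[i])
        dst <- repeats$dest_start[i] + seq_len(repeats$len[i]) - 1L
        copy <- g[src]
        mut <- runif(repeats$len[i]) < repeats$divergence[i]
        if (any(mut)) {
          copy[mut] <- ((copy[mut] - 1L + sample.int(3L, sum(mut),
                                                     replace = TRUE)) %% 4L) + 1L
        }
        g[dst + 1L] <- copy
      }
    }
    g
  })
  seqs <- setNames(paste(.ALPHABET[codes], collapse = ""), name)
  structure(list(sequences = seqs, repeats = repeats, seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d sequence(s), %s bp, %d planted repeat(s)\n",
              length(x$sequences), format(sum(nchar(x$sequences)),
                                          big.mark = ","),
              if (is.null(x$repeats)) 0L else nrow(x$repeats)))
  invisible(x)
}

#' Position-dependent substitution-error profile
#'
#' Per-base substitution probabilities along a read, emulating the
#' Illumina-style pattern of quality degrading towards the 3' end: a
#' linear ramp from `p_start` at the first base to `p_end` at the last,
#' scaled by `multiplier` (1x/2x/10x in the accuracy experiments) and
#' capped.
#'
#' @param multiplier error-rate scaling factor (e.g. 1, 2, 10).
#' @param read_len read length in bp.
#' @param p_start,p_end substitution probability at the first/last base
#'   before scaling.
#' @param cap upper bound applied after scaling.
#' @return numeric vector of length `read_len`, class `error_profile`.
#' @export
#' @examples
#' round(error_profile(10)[c(1, 40, 80)], 3)
error_profile <- function(multiplier = 1, read_len = 80L, p_start = 0.001,
                          p_end = 0.01, cap = 0.75) {
  if (multiplier < 0) stop("multiplier must be >= 0")
  p <- seq(p_start, p_end, length.out = read_len) * multiplier
  structure(pmin(p, cap), class = "error_profile", multiplier = multiplier)
}

#' Simulate reads from known positions with truth tracking
#'
#' Draws read start positions and strands uniformly, copies the genomic
#' window (reverse-complemented for minus-strand reads), then substitutes
#' each base independently with the profile's position-specific
#' probability (substituted bases are drawn uniformly from the other three
#' nucleotides). The truth table records, for every read, its origin and
#' the number of planted errors; quality strings encode the profile's
#' per-position error probability on the Phred scale.
#'
#' @param genome a [simulate_genome()] result or named character vector.
#' @param n_reads number of reads.
#' @param read_len read length (default 80).
#' @param profile an [error_profile()].
#' @param seed RNG seed.
#' @return list with `reads` (data frame `read_id`, `seq`, `qual`) and
#'   `truth` (data frame `read_id`, `chrom`, `pos` 0-based, `strand`,
#'   `n_errors`, `seq`).
#' @export
simulate_reads <- function(genome, n_reads, read_len = 80L,
                           profile = error_profile(1), seed = 1L) {
  seqs <- .genome_seqs(genome)
  read_len <- as.integer(read_len)
  if (read_len > min(nchar(seqs))) stop("read_len exceeds a sequence length")
  if (length(profile) != read_len) {
    profile <- error_profile(attr(profile, "multiplier") %||% 1,
                             read_len = read_len)
  }
  lens <- nchar(seqs)
  phred <- pmax(2L, pmin(40L, as.integer(round(-10 * log10(pmax(profile, 1e-4))))))
  qual <- paste(intToUtf8(phred + 33L, multiple = TRUE), collapse = "")
  sim <- with_seed(seed, {
    chrom <- names(seqs)[sample.int(length(seqs), n_reads, replace = TRUE,
                                    prob = lens)]
    pos <- vapply(chrom, function(ch)
      sample.int(lens[[ch]] - read_len + 1L, 1L) - 1L, 0L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seq_out <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      win <- substr(seqs[[chrom[i]]], pos[i] + 1L, pos[i] + read_len)
      if (strand[i] == "-") win <- revcomp(win)
      enc <- encode_seq(win)
      mut <- which(runif(read_len) < profile)
      if (length(mut)) {
        enc[mut] <- ((enc[mut] - 1L + sample.int(3L, length(mut),
                                                 replace = TRUE)) %% 4L) + 1L
      }
      seq_out[i] <- paste(.ALPHABET[enc], collapse = "")
      n_err[i] <- length(mut)
    }
    list(chrom = chrom, pos = as.integer(pos), strand = strand,
         seq = seq_out, n_errors = n_err)
  })
  ids <- sprintf("read%0*d", nchar(n_reads), seq_len(n_reads))
  list(reads = data.frame(read_id = ids, seq = sim$seq, qual = qual,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids, chrom = sim$chrom, pos = sim$pos,
                          strand = sim$strand, n_errors = sim$n_errors,
                          seq = sim$seq, stringsAsFactors = FALSE))
}

#' Sliding-window Hamming distances of a read along a sequence
#'
#' Mismatch count of `read` against every full-length window of `sequence`
#' (one strand; callers scan the reverse complement for the other strand).
#' Characters outside `acgt` never match. This is the exhaustive scan
#' behind recoverability checks.
#'
#' @param sequence reference sequence (single string).
#' @param read read string.
#' @return integer vector of length `nchar(sequence) - nchar(read) + 1`.
#' @export
sliding_hamming <- function(sequence, read) {
  .sliding_hamming(encode_seq(sequence), encode_seq(read))
}

# Best placement(s) of a read over all sequences and strands.
# genc: list of encoded sequences. Returns list(best, at_origin, origins=df).
.global_best <- function(genc, read, truth_chrom = NULL, truth_pos = NULL,
                         truth_strand = NULL) {
  renc <- encode_seq(read)
  rcenc <- encode_seq(revcomp(read))
  best <- Inf
  origin_d <- NA_real_
  for (ch in names(genc)) {
    for (st in c("+", "-")) {
      dv <- .sliding_hamming(genc[[ch]], if (st == "+") renc else rcenc)
      if (!length(dv)) next
      b <- min(dv)
      if (b < best) best <- b
      if (!is.null(truth_chrom) && ch == truth_chrom && st == truth_strand) {
        origin_d <- dv[truth_pos + 1L]
      }
    }
  }
  list(best = best, origin = origin_d)
}

#' Classify one mapping against its simulated truth
#'
#' A mapping is `correct` when chromosome and strand match the truth and
#' the reported position is within `tolerance` of the true origin;
#' `skipped` when absent/unmapped; otherwise `incorrect`. Independently,
#' the read is *recoverable* when an exhaustive scan of the whole genome
#' (both strands) finds no location with strictly smaller full-read
#' Hamming distance than the true origin — an unrecoverable read's planted
#' errors have made some other location genuinely closer, so no exact
#' method can place it at its origin.
#'
#' @param mapping one row of [map_reads()] / [sam_to_mappings()] output, or
#'   `NULL` for an absent record.
#' @param truth the matching truth row (needs `chrom`, `pos`, `strand`,
#'   `seq`).
#' @param genome the reference.
#' @param tolerance positional slack in bp for calling a mapping correct
#'   (default 0).
#' @return list with `status` (`"correct"`, `"incorrect"`, `"skipped"`)
#'   and logical `recoverable`.
#' @export
classify_error <- function(mapping, truth, genome, tolerance = 0L) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  seqs <- .genome_seqs(genome)
  genc <- lapply(seqs, encode_seq)
  status <- if (is.null(mapping) || is.na(mapping$chrom)) {
    "skipped"
  } else if (mapping$chrom == truth$chrom && mapping$strand == truth$strand &&
             abs(mapping$pos - truth$pos) <= tolerance) {
    "correct"
  } else "incorrect"
  gb <- .global_best(genc, truth$seq, truth$chrom, truth$pos, truth$strand)
  list(status = status, recoverable = gb$origin <= gb$best)
}

#' Evaluate mapping accuracy against simulated truth
#'
#' Joins mappings to the truth table by read id and tabulates correct /
#' incorrect / skipped calls, plus — for the reads that were skipped or
#' placed incorrectly — whether each was *recoverable* (its true origin is
#' still a globally optimal placement; see [classify_error()]). The
#' headline `accuracy` counts correct reads over all reads, so unmapped
#' reads count against it; `accuracy_mapped` restricts the denominator to
#' mapped reads. The breakdown reports, for the skipped and wrong subsets
#' separately, the percentage an exact mapper could still place correctly
#' (their potential accuracy).
#'
#' @param mappings data frame from [map_reads()] or [sam_to_mappings()]
#'   (columns `read_id`, `chrom`, `pos`, `strand`); reads may be absent.
#' @param truth truth table from [simulate_reads()].
#' @param genome the reference the reads were simulated from.
#' @param tolerance positional slack in bp (default 0).
#' @return object of class `accuracy_report`.
#' @export
evaluate_mappings <- function(mappings, truth, genome, tolerance = 0L) {
  if (anyDuplicated(mappings$read_id)) stop("duplicate read ids in mappings")
  if (anyDuplicated(truth$read_id)) stop("duplicate read ids in truth")
  seqs <- .genome_seqs(genome)
  genc <- lapply(seqs, encode_seq)
  idx <- match(truth$read_id, mappings$read_id)
  n <- nrow(truth)
  status <- character(n)
  for (i in seq_len(n)) {
    j <- idx[i]
    status[i] <- if (is.na(j) || is.na(mappings$chrom[j])) {
      "skipped"
    } else if (mappings$chrom[j] == truth$chrom[i] &&
               mappings$strand[j] == truth$strand[i] &&
               abs(mappings$pos[j] - truth$pos[i]) <= tolerance) {
      "correct"
    } else "incorrect"
  }
  need_rec <- which(status != "correct")
  recoverable <- rep(NA, n)
  for (i in need_rec) {
    gb <- .global_best(genc, truth$seq[i], truth$chrom[i], truth$pos[i],
                       truth$strand[i])
    recoverable[i] <- gb$origin <= gb$best
  }
  n_correct <- sum(status == "correct")
  n_incorrect <- sum(status == "incorrect")
  n_skipped <- sum(status == "skipped")
  pot <- function(sel) {
    if (!any(sel)) NA_real_ else 100 * mean(recoverable[sel])
  }
  structure(list(
    n_reads = n, n_correct = n_correct, n_incorrect = n_incorrect,
    n_skipped = n_skipped,
    n_unrecoverable = sum(!recoverable[need_rec]),
    accuracy = 100 * n_correct / n,
    accuracy_mapped = if (n > n_skipped)
      100 * n_correct / (n - n_skipped) else NA_real_,
    breakdown = data.frame(
      subset = c("skipped", "wrong"),
      total = c(n_skipped, n_incorrect),
      potential_accuracy = c(pot(status == "skipped"),
                             pot(status == "incorrect"))),
    status = setNames(status, truth$read_id),
    recoverable = setNames(recoverable, truth$read_id)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d reads: %d correct, %d incorrect, %d skipped (%d unrecoverable)\n",
              x$n_reads, x$n_correct, x$n_incorrect, x$n_skipped,
              x$n_unrecoverable))
  cat(sprintf(" accuracy %.2f%% (all reads), %.2f%% (mapped reads)\n",
              x$accuracy, x$accuracy_mapped))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Write / read an accuracy report as TSV
#'
#' @param report an `accuracy_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  df <- data.frame(metric = c("n_reads", "n_correct", "n_incorrect",
                              "n_skipped", "n_unrecoverable", "accuracy",
                              "accuracy_mapped"),
                   value = c(report$n_reads, report$n_correct,
                             report$n_incorrect, report$n_skipped,
                             report$n_unrecoverable, report$accuracy,
                             report$accuracy_mapped))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @param truth truth table (see [simulate_reads()]).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character", chrom = "character",
                            strand = "character"))
}
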