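#' Indexed k-mer points
#'
#' Constructs the point table stored by the index: each row is one k-mer
#' together with its genomic origin. For minus-strand points `seq` is the
#' reverse complement of the genome window starting at `start` (coordinates
#' are always on the forward strand, 0-based).
#'
#' @param seq character vector of equal-length k-mer strings (`acgt`; case
#'   folded to lowercase).
#' @param chrom reference sequence name(s), recycled.
#' @param start 0-based start positions.
#' @param strand `"+"` or `"-"`, recycled.
#' @return a `data.frame` of class `kmer_points` with columns
#'   `seq`, `chrom`, `start`, `strand`.
#' @export
#' @examples
#' kmer_points(c("acgt", "ttca"), chrom = "chr1", start = c(0, 7))
kmer_points <- function(seq, chrom = "seq1", start = seq_along(seq) - 1L,
                        strand = "+") {
  seq <- tolower(as.character(seq))
  n <- length(seq)
  if (n == 0L) stop("no points supplied")
  k <- nchar(seq[1L])
  if (any(nchar(seq) != k)) stop("all k-mers must have equal length")
  if (!all(strsplit(paste(seq, collapse = ""), "")[[1]] %in% .ALPHABET)) {
    stop("non-nucleotide character in k-mers (alphabet is a, c, g, t)")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(seq = seq,
                   chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("kmer_points", "data.frame")
  df
}

.as_kmer_points <- function(points) {
  if (inherits(points, "kmer_points")) return(points)
  if (is.character(points)) return(kmer_points(points))
  if (is.data.frame(points)) {
    return(kmer_points(points$seq, points$chrom %||% "seq1",
                       points$start %||% (seq_len(nrow(points)) - 1L),
                       points$strand %||% "+"))
  }
  stop("cannot interpret `points` as k-mer points")
}
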