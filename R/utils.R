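# Internal helpers: nucleotide encoding, seeded evaluation, small utilities.

.ALPHABET <- c("a", "c", "g", "t")

# Encode a character vector of equal-length sequences as a k x n integer
# matrix (a=1, c=2, g=3, t=4, anything else 0). Case-folded to lowercase.
encode_seqs <- function(x, k = NULL) {
  x <- tolower(x)
  if (length(x) == 0L) {
    return(matrix(integer(0), nrow = if (is.null(k)) 0L else k, ncol = 0L))
  }
  lens <- nchar(x)
  if (is.null(k)) k <- lens[1L]
  if (any(lens != k)) stop("all sequences must have length ", k)
  codes <- integer(256)
  codes[utf8ToInt("a")] <- 1L
  codes[utf8ToInt("c")] <- 2L
  codes[utf8ToInt("g")] <- 3L
  codes[utf8ToInt("t")] <- 4L
  raw <- utf8ToInt(paste(x, collapse = ""))
  matrix(codes[raw], nrow = k)
}

encode_seq <- function(x) as.integer(encode_seqs(x)[, 1L])

decode_enc <- function(enc) {
  chars <- c("n", .ALPHABET)[enc + 1L]
  paste(chars, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' lowercase character vectors, used when indexing and mapping the minus
#' strand.
#'
#' @param x character vector of DNA strings (`acgtn`, any case).
#' @return character vector of lowercase reverse complements.
#' @export
#' @examples
#' revcomp(c("acgt", "aacc"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  tolower(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Evaluate expr with a private RNG stream seeded by `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Upper median: element at 0-based index floor(n/2) of the sorted values.
upper_median <- function(x) sort(x)[floor(length(x) / 2) + 1L]

`%||%` <- function(a, b) if (is.null(a)) b else a
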