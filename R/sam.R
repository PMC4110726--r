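# Minimal SAM text I/O. Only the 11 mandatory fields plus simple string
# tags are needed here: the mapper emits ungapped (all-match) alignments.

#' Write alignment records to a SAM file
#'
#' Emits `@HD`, one `@SQ` per reference sequence and an `@PG` line, then
#' the records. Rescued records (see [rescue_pipeline()]) get a
#' `PG:Z:apforest` tag.
#'
#' @param records SAM-record data frame (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, optional logical `rescued`).
#' @param genome reference the records refer to (for `@SQ` lines).
#' @param path output file.
#' @param extra_header optional extra header lines (character vector).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path, extra_header = character(0)) {
  seqs <- .genome_seqs(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)),
           "@PG\tID:apforest\tPN:apforest",
           extra_header)
  tags <- if (!is.null(records$rescued)) {
    ifelse(records$rescued, "\tPG:Z:apforest", "")
  } else ""
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                   records$qname, records$flag, records$rname, records$pos,
                   records$mapq, records$cigar, records$seq, records$qual,
                   tags)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into a record data frame
#'
#' Parses the 11 mandatory fields; any remaining fields are kept collapsed
#' in a `tags` column. Malformed lines (fewer than 11 fields) are skipped
#' with a warning.
#'
#' @param path SAM file path.
#' @return data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, `tags`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 11L
  if (any(bad)) {
    warning(sum(bad), " malformed SAM line(s) skipped")
    parts <- parts[!bad]
  }
  if (!length(parts)) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      tags = character(0), stringsAsFactors = FALSE))
  }
  get <- function(i) vapply(parts, `[[`, "", i)
  data.frame(qname = get(1), flag = as.integer(get(2)), rname = get(3),
             pos = as.integer(get(4)), mapq = as.integer(get(5)),
             cigar = get(6), seq = get(10), qual = get(11),
             tags = vapply(parts, function(p)
               paste(p[-(1:11)], collapse = "\t"), ""),
             stringsAsFactors = FALSE)
}

#' FASTA / FASTQ convenience I/O
#'
#' Thin wrappers over [Biostrings] readers plus a plain 4-line FASTQ
#' writer, operating on the package's lowercase character-vector
#' convention.
#'
#' @param path file path.
#' @param reads data frame (`read_id`, `seq`, `qual`) or named character
#'   vector.
#' @param genome named character vector of sequences.
#' @name seq-io
NULL

#' @rdname seq-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(tolower(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname seq-io
#' @export
write_fasta <- function(genome, path) {
  seqs <- .genome_seqs(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname seq-io
#' @export
read_fastq <- function(path) {
  # QualityScaledDNAStringSet construction warns about dropping its own
  # metadata columns; harmless here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = tolower(as.character(x)),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @rdname seq-io
#' @export
write_fastq <- function(reads, path) {
  if (!is.data.frame(reads)) {
    reads <- data.frame(read_id = names(reads), seq = as.character(reads),
                        qual = strrep("I", nchar(reads)),
                        stringsAsFactors = FALSE)
  }
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", reads$qual)), path)
  invisible(path)
}
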