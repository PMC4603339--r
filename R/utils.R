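# Shared helpers: rounding, phred encoding, FASTQ I/O.

#' Round half away from zero
#'
#' Table-style rounding (0.05 -> 0.1), as opposed to R's banker's rounding.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# decode a vector of quality strings to a list of integer phred vectors
phredDecode <- function(qual, offset = 33L) {
  lapply(qual, function(q) utf8ToInt(q) - as.integer(offset))
}

# encode integer phred vector(s) to character strings
phredEncode <- function(scores, offset = 33L) {
  if (is.numeric(scores)) scores <- list(scores)
  vapply(scores, function(s) intToUtf8(as.integer(s) + as.integer(offset)),
         character(1))
}

# reverse-complement for plain character vectors
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write paired reads to FASTQ mate files
#'
#' @param reads a library as returned by [simulateReads()]: a list with
#'   `id`, `seq1`, `qual1`, `seq2`, `qual2` character vectors.
#' @param prefix output path prefix; `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return invisibly, the two file paths.
#' @export
writeFastqPair <- function(reads, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", reads$id, "/1"), reads$seq1,
                             "+", reads$qual1)), f1)
  writeLines(as.vector(rbind(paste0("@", reads$id, "/2"), reads$seq2,
                             "+", reads$qual2)), f2)
  invisible(c(f1, f2))
}

#' Read paired FASTQ mate files
#'
#' @param file1,file2 mate FASTQ paths.
#' @return a list with `id`, `seq1`, `qual1`, `seq2`, `qual2`; mate ids are
#'   checked to match after stripping `/1`, `/2` suffixes.
#' @export
readFastqPair <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq",
                                     with.qualities = TRUE)
  strip <- function(x) sub("/[12]$", "", sub(" .*", "", x))
  id1 <- strip(names(r1)); id2 <- strip(names(r2))
  if (length(id1) != length(id2) || any(id1 != id2))
    stop("mate files disagree on read ids")
  list(id = unname(id1),
       seq1 = unname(as.character(r1)),
       qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
       seq2 = unname(as.character(r2)),
       qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}
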