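# Read cleaning with Trimmomatic semantics: adapter clip, LEADING,
# TRAILING, SLIDINGWINDOW, MINLEN -- in that order.

# position where the adapter starts in the read, or 0L if no hit:
# longest suffix of the read overlapping an adapter prefix by >= 8 bases
# with at most 1 mismatch
adapterClipPoint <- function(seqChars, adapterChars, minOverlap = 8L) {
  L <- length(seqChars)
  maxOv <- min(L, length(adapterChars))
  for (ov in seq(maxOv, minOverlap)) {
    if (ov < minOverlap) break
    p <- L - ov + 1L
    if (sum(seqChars[p:L] != adapterChars[seq_len(ov)]) <= 1L)
      return(p)
  }
  0L
}

#' Trim a single read
#'
#' Applies, in order: adapter clipping (longest read-suffix/adapter-prefix
#' overlap of at least 8 bases with at most 1 mismatch), LEADING (drop 5'
#' bases below `leadingQ`), TRAILING (drop 3' bases below `trailingQ`),
#' SLIDINGWINDOW (scanning 5' to 3', cut the read at the start of the
#' first `windowLen`-base window whose mean quality falls below `windowQ`),
#' and MINLEN (discard reads shorter than `minLen`).
#'
#' @param seq read bases (character scalar).
#' @param qual quality string, same length, encoded at
#'   `params@phredOffset`.
#' @param params a [TrimParams-class] object.
#' @return `NULL` when the read is discarded, otherwise
#'   `list(seq =, qual =)` with qualities aligned to the surviving bases.
#' @examples
#' p <- trimParams(adapters = character(0))
#' trimRead(strrep("ACGT", 15), strrep("I", 60), p)$seq
#' @export
trimRead <- function(seq, qual, params = trimParams()) {
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality strings differ in length")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  q <- utf8ToInt(qual) - params@phredOffset

  # adapter clip
  for (ad in params@adapters) {
    p <- adapterClipPoint(ch, strsplit(ad, "", fixed = TRUE)[[1]])
    if (p > 0L) {
      ch <- ch[seq_len(p - 1L)]
      q <- q[seq_len(p - 1L)]
    }
  }
  # LEADING
  while (length(q) && q[1] < params@leadingQ) {
    ch <- ch[-1]; q <- q[-1]
  }
  # TRAILING
  while (length(q) && q[length(q)] < params@trailingQ) {
    ch <- ch[-length(ch)]; q <- q[-length(q)]
  }
  # SLIDINGWINDOW: cut at the start of the first failing window
  w <- params@windowLen
  if (length(q) >= w) {
    cs <- cumsum(c(0, q))
    means <- (cs[(w + 1):(length(q) + 1L)] -
              cs[seq_len(length(q) - w + 1L)]) / w
    fail <- which(means < params@windowQ)
    if (length(fail)) {
      keep <- fail[1] - 1L
      ch <- ch[seq_len(keep)]; q <- q[seq_len(keep)]
    }
  }
  # MINLEN
  if (length(ch) < params@minLen) return(NULL)
  list(seq = paste(ch, collapse = ""),
       qual = intToUtf8(q + params@phredOffset))
}

#' Trim a read pair
#'
#' Both mates are trimmed with [trimRead()]; the pair is kept when both
#' survive, demoted to a singleton (with the surviving mate flagged) when
#' one survives, and dropped when neither does.
#'
#' @param seq1,qual1,seq2,qual2 mate sequences and quality strings.
#' @param params a [TrimParams-class] object.
#' @return list with `status` ("pair", "singleton", "dropped"), trimmed
#'   `seq1`/`qual1`/`seq2`/`qual2` (NA where discarded) and, for
#'   singletons, `survivor` (1 or 2).
#' @export
trimPair <- function(seq1, qual1, seq2, qual2, params = trimParams()) {
  t1 <- trimRead(seq1, qual1, params)
  t2 <- trimRead(seq2, qual2, params)
  if (!is.null(t1) && !is.null(t2))
    return(list(status = "pair", seq1 = t1$seq, qual1 = t1$qual,
                seq2 = t2$seq, qual2 = t2$qual))
  if (is.null(t1) && is.null(t2)) return(list(status = "dropped"))
  s <- if (is.null(t1)) 2L else 1L
  tt <- if (s == 1L) t1 else t2
  out <- list(status = "singleton", survivor = s,
              seq1 = NA_character_, qual1 = NA_character_,
              seq2 = NA_character_, qual2 = NA_character_)
  out[[paste0("seq", s)]] <- tt$seq
  out[[paste0("qual", s)]] <- tt$qual
  out
}

#' Trim a whole paired library
#'
#' @param reads a library (list with `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param params a [TrimParams-class] object.
#' @return a list with `reads` (same layout; NA entries mark discarded
#'   mates; fully dropped pairs removed) and `stats`: total reads, clean
#'   reads, kept pairs, singletons and dropped pairs, for a
#'   total-vs-clean accounting of the library.
#' @export
trimLibrary <- function(reads, params = trimParams()) {
  n <- length(reads$id)
  out <- list(id = reads$id,
              seq1 = rep(NA_character_, n), qual1 = rep(NA_character_, n),
              seq2 = rep(NA_character_, n), qual2 = rep(NA_character_, n))
  status <- character(n)
  for (i in seq_len(n)) {
    tp <- trimPair(reads$seq1[i], reads$qual1[i],
                   reads$seq2[i], reads$qual2[i], params)
    status[i] <- tp$status
    if (tp$status != "dropped") {
      out$seq1[i] <- tp$seq1; out$qual1[i] <- tp$qual1
      out$seq2[i] <- tp$seq2; out$qual2[i] <- tp$qual2
    }
  }
  keep <- status != "dropped"
  out <- lapply(out, `[`, keep)
  nPair <- sum(status == "pair")
  nSing <- sum(status == "singleton")
  list(reads = out,
       stats = data.frame(total_reads = 2L * n,
                          clean_reads = 2L * nPair + nSing,
                          kept_pairs = nPair, singletons = nSing,
                          dropped_pairs = sum(status == "dropped")))
}
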