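# Exact k-mer seed / ungapped extend fixture aligner. Deliberately simple:
# it exists so the MQS arbitration, counting and DE stages can be exercised
# on synthetic data without an external aligner. Not a production aligner.

# seed index: every k-mer position of every contig
buildSeedIndex <- function(ref, k) {
  refChar <- as.character(ref)
  lens <- nchar(refChar)
  usable <- lens >= k
  starts <- lapply(lens[usable], function(L) seq_len(L - k + 1L))
  contig <- rep(names(refChar)[usable], lengths(starts))
  pos <- unlist(starts, use.names = FALSE)
  kmers <- substring(refChar[contig], pos, pos + k - 1L)
  list(index = split(seq_along(kmers), kmers),
       contig = contig, pos = pos, refChar = refChar, lens = lens, k = k)
}

# candidate loci (contig, start) for one orientation of a set of reads
seedCandidates <- function(seqs, idx) {
  k <- idx$k
  L <- nchar(seqs)
  nSeeds <- 5L
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (L[i] < k) next
    offs <- unique(round(seq(1L, L[i] - k + 1L, length.out = nSeeds)))
    hits <- idx$index[substring(seqs[i], offs, offs + k - 1L)]
    ok <- !vapply(hits, is.null, logical(1))
    if (!any(ok)) next
    j <- unlist(hits[ok], use.names = FALSE)
    start <- idx$pos[j] - rep(offs[ok], lengths(hits[ok])) + 1L
    cand <- unique(data.frame(contig = idx$contig[j], start = start,
                              stringsAsFactors = FALSE))
    keep <- cand$start >= 1L &
      cand$start + L[i] - 1L <= idx$lens[cand$contig]
    out[[i]] <- cand[keep, , drop = FALSE]
  }
  out
}

countMismatches <- function(read, refsub) {
  sum(charToRaw(read) != charToRaw(refsub))
}

# align one mate set; returns per-read best hit or NA row
alignMates <- function(seqs, idx, mapqScale, maxMismatch) {
  n <- length(seqs)
  res <- data.frame(contig = rep(NA_character_, n), pos = NA_integer_,
                    rev = NA, mapq = NA_integer_, nBest = NA_integer_,
                    mm = NA_integer_, stringsAsFactors = FALSE)
  rc <- revComp(ifelse(is.na(seqs) | seqs == "", "A", seqs))
  candF <- seedCandidates(seqs, idx)
  candR <- seedCandidates(rc, idx)
  for (i in seq_len(n)) {
    if (is.na(seqs[i]) || nchar(seqs[i]) < idx$k) next
    cand <- rbind(
      if (!is.null(candF[[i]]) && nrow(candF[[i]]))
        cbind(candF[[i]], rev = FALSE, read = seqs[i]) else NULL,
      if (!is.null(candR[[i]]) && nrow(candR[[i]]))
        cbind(candR[[i]], rev = TRUE, read = rc[i]) else NULL)
    if (is.null(cand) || !nrow(cand)) next
    L <- nchar(seqs[i])
    refsub <- substring(idx$refChar[cand$contig], cand$start,
                        cand$start + L - 1L)
    mm <- mapply(countMismatches, cand$read, refsub, USE.NAMES = FALSE)
    best <- min(mm)
    if (best > maxMismatch) next
    nBest <- sum(mm == best)
    second <- if (length(mm) > 1L) sort(mm, partial = 2L)[2L] else maxMismatch
    second <- min(second, maxMismatch)
    b <- which.min(mm)
    res$contig[i] <- cand$contig[b]
    res$pos[i] <- cand$start[b]
    res$rev[i] <- cand$rev[b]
    res$mapq[i] <- min(60L, mapqScale * max(0L, second - best))
    res$nBest[i] <- nBest
    res$mm[i] <- best
  }
  res
}

#' Align paired reads to one subgenome with the fixture aligner
#'
#' Candidate loci are found by exact k-mer seeding and scored by ungapped
#' mismatch count. The best locus is reported with
#' `MAPQ = min(60, mapqScale * (second_score - best_score))`, where a read
#' with no second candidate takes `second_score = maxMismatch`; reads whose
#' best score exceeds `maxMismatch` (or shorter than `k`) are reported
#' unmapped. The `NH` tag records the number of equally best loci, so a
#' read matching two loci with equal score gets MAPQ 0 and NH 2.
#'
#' @param reads a library: list with `id`, `seq1`, `qual1` and optionally
#'   `seq2`, `qual2` (NA entries mark missing mates/singletons).
#' @param ref a [Biostrings::DNAStringSet-class] reference (one subgenome).
#' @param k exact seed length (default 21).
#' @param mapqScale MAPQ per unit of score gap (default 6, so a unique
#'   perfect hit with the default `maxMismatch = 10` scores MAPQ 60).
#' @param maxMismatch maximum mismatches for a reported alignment.
#' @return a data.frame of SAM-style records (qname, flag, rname, pos,
#'   mapq, cigar, rnext, pnext, tlen, seq, qual, NH) with the reference
#'   sequence dictionary in `attr(, "refLengths")`.
#' @export
fixtureAlign <- function(reads, ref, k = 21L, mapqScale = 6L,
                         maxMismatch = 10L) {
  if (length(ref) == 0L) stop("empty reference")
  idx <- buildSeedIndex(ref, as.integer(k))
  hasMate2 <- !is.null(reads$seq2)
  a1 <- alignMates(reads$seq1, idx, mapqScale, maxMismatch)
  a2 <- if (hasMate2) alignMates(reads$seq2, idx, mapqScale, maxMismatch)
        else NULL

  rec <- function(i, mate, a, seq, qual, aOther) {
    mapped <- !is.na(a$contig[i])
    mateMapped <- !is.null(aOther) && !is.na(aOther$contig[i])
    proper <- mapped && mateMapped && a$contig[i] == aOther$contig[i] &&
      a$rev[i] != aOther$rev[i]
    flag <- 1L + (if (proper) 2L else 0L) +
      (if (!mapped) 4L else 0L) + (if (!mateMapped) 8L else 0L) +
      (if (mapped && a$rev[i]) 16L else 0L) +
      (if (mateMapped && aOther$rev[i]) 32L else 0L) +
      (if (mate == 1L) 64L else 128L)
    list(qname = reads$id[i], flag = flag,
         rname = if (mapped) a$contig[i] else "*",
         pos = if (mapped) a$pos[i] else 0L,
         mapq = if (mapped) a$mapq[i] else 0L,
         cigar = if (mapped) paste0(nchar(seq[i]), "M") else "*",
         rnext = if (mateMapped) aOther$contig[i] else "*",
         pnext = if (mateMapped) aOther$pos[i] else 0L,
         tlen = 0L,
         seq = if (is.na(seq[i])) "*" else seq[i],
         qual = if (is.null(qual) || is.na(qual[i])) "*" else qual[i],
         NH = if (mapped) a$nBest[i] else 0L)
  }

  rows <- vector("list", 2L * length(reads$id))
  n <- 0L
  for (i in seq_along(reads$id)) {
    if (!is.na(reads$seq1[i])) {
      n <- n + 1L
      rows[[n]] <- rec(i, 1L, a1, reads$seq1, reads$qual1, a2)
    }
    if (hasMate2 && !is.na(reads$seq2[i])) {
      n <- n + 1L
      rows[[n]] <- rec(i, 2L, a2, reads$seq2, reads$qual2, a1)
    }
  }
  out <- do.call(rbind, lapply(rows[seq_len(n)], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "refLengths") <- setNames(idx$lens, names(idx$refChar))
  out
}
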