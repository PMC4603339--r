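# SAM serialisation for fixture-aligner records, and SAM ingest through
# Rsamtools (SAM -> BAM -> records), so external alignments can be fed to
# the arbitration stage.

#' Write alignment records to a SAM file
#'
#' Emits a valid name-grouped SAM: `@HD`/`@SQ` header built from the
#' reference dictionary, then one line per record with an `NH:i:` tag.
#'
#' @param records a record data.frame as produced by [fixtureAlign()].
#' @param path output SAM path.
#' @param refLengths named integer vector of reference sequence lengths;
#'   defaults to `attr(records, "refLengths")`.
#' @return invisibly, `path`.
#' @export
writeSam <- function(records, path, refLengths = attr(records, "refLengths")) {
  if (is.null(refLengths))
    stop("refLengths required (none attached to records)")
  hdr <- c("@HD\tVN:1.6\tGO:query",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                   as.integer(refLengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNH:i:%d",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, records$NH)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from a SAM or BAM file
#'
#' SAM input is converted with [Rsamtools::asBam()] and scanned; the fields
#' the arbitration and counting stages need (qname, flag, rname, pos, mapq,
#' cigar and the NH tag) are returned as a data.frame. Records missing an
#' NH tag are treated as single-best hits (NH = 1).
#'
#' @param path SAM or BAM path.
#' @return data.frame of records with `attr(, "refLengths")` set from the
#'   header.
#' @export
readSamRecords <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NH")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(x$qname))
  mapped <- !bitwAnd(x$flag, 4L)
  nh[is.na(nh)] <- ifelse(mapped[is.na(nh)], 1L, 0L)
  out <- data.frame(qname = x$qname, flag = x$flag,
                    rname = as.character(x$rname), pos = x$pos,
                    mapq = x$mapq, cigar = x$cigar, NH = nh,
                    stringsAsFactors = FALSE)
  out$pos[is.na(out$pos)] <- 0L
  out$mapq[is.na(out$mapq)] <- 0L
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  attr(out, "refLengths") <- hdr
  out
}

# coerce a records argument (path or data.frame) to records
asRecords <- function(x) {
  if (is.character(x)) readSamRecords(x) else x
}
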