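# MQS arbitration: decide, for every read pair, which subgenome (A or B)
# it belongs to. Read pairs beat singletons, uniquely mapped evidence
# beats ambiguous evidence, and among otherwise equal evidence the larger
# sum of mate MAPQs (MQS) wins; full ties are discarded.

STATUS_RANK <- c(UNMAPPED = 0L, SINGLETON = 1L, PAIR = 2L)

#' Build per-fragment evidence from one subgenome's alignment records
#'
#' Collapses the primary records of each read pair into one evidence row:
#' status (PAIR when both mates are mapped, SINGLETON when one is,
#' UNMAPPED otherwise), the MQS sum of mapped-mate MAPQs, and a uniqueness
#' flag (all contributing mates have NH = 1).
#'
#' @param records alignment record data.frame (or SAM/BAM path) for one
#'   subgenome.
#' @param subgenome label stored on the evidence ("A"/"B").
#' @param readIds optional read-id universe; ids absent from `records` get
#'   UNMAPPED evidence.
#' @param uniqueOnly when TRUE, mapped records with NH > 1 are dropped
#'   before evidence building (mirrors an aligner's report-unique-only
#'   mode).
#' @return data.frame: read_id, subgenome, status, mqs, unique.
#' @export
buildFragmentEvidence <- function(records, subgenome = NA_character_,
                                  readIds = NULL, uniqueOnly = FALSE) {
  records <- asRecords(records)
  primary <- bitwAnd(records$flag, 256L) == 0L &
    bitwAnd(records$flag, 2048L) == 0L
  mapped <- bitwAnd(records$flag, 4L) == 0L
  use <- primary & mapped
  if (uniqueOnly) use <- use & records$NH == 1L
  m <- records[use, , drop = FALSE]
  mate <- ifelse(bitwAnd(m$flag, 64L) > 0L, 1L, 2L)
  if (anyDuplicated(paste(m$qname, mate)))
    stop("duplicate primary record for a mate")
  if (is.null(readIds)) readIds <- unique(records$qname)

  nm <- integer(length(readIds)); names(nm) <- readIds
  mqs <- nm; namb <- nm
  if (nrow(m)) {
    t1 <- rowsum(rep(1L, nrow(m)), m$qname)
    t2 <- rowsum(as.integer(m$mapq), m$qname)
    t3 <- rowsum(as.integer(m$NH > 1L), m$qname)
    hit <- intersect(rownames(t1), readIds)
    nm[hit] <- t1[hit, 1]; mqs[hit] <- t2[hit, 1]; namb[hit] <- t3[hit, 1]
  }
  data.frame(read_id = readIds, subgenome = subgenome,
             status = c("UNMAPPED", "SINGLETON", "PAIR")[pmin(nm, 2L) + 1L],
             mqs = unname(mqs), unique = unname(nm > 0L & namb == 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise one read pair's evidence on both subgenomes
#'
#' @param recordsA,recordsB the pair's alignment records (data.frames with
#'   qname, flag, mapq, NH) on subgenome A and B; all records must share
#'   one read id.
#' @return list of two evidence rows (A then B), as in
#'   [buildFragmentEvidence()].
#' @export
summarizeFragment <- function(recordsA, recordsB) {
  ids <- unique(c(recordsA$qname, recordsB$qname))
  if (length(ids) != 1L) stop("records mix read ids: ",
                              paste(ids, collapse = ", "))
  list(A = buildFragmentEvidence(recordsA, "A", readIds = ids),
       B = buildFragmentEvidence(recordsB, "B", readIds = ids))
}

#' Arbitrate one read pair between the two subgenomes
#'
#' Lexicographic comparison of the two evidence rows: (1) status rank
#' PAIR > SINGLETON > UNMAPPED; (2) unique beats ambiguous; (3) larger MQS
#' sum. A strict winner at the first differing criterion is assigned with
#' that deciding rule; mapped on one side only is an ONLY_ONE assignment;
#' a full tie is DISCARD_TIE; both sides unmapped is UNMAPPED.
#'
#' @param evA,evB one-row evidence data.frames (or equivalent lists) with
#'   `status`, `mqs`, `unique` for the same read on subgenome A and B.
#' @return list: `read_id`, `outcome` (ASSIGN_A, ASSIGN_B, DISCARD_TIE,
#'   UNMAPPED) and `deciding_rule` (PAIR_PRIORITY, UNIQUE_PRIORITY, MQS,
#'   ONLY_ONE, NONE).
#' @examples
#' evA <- list(read_id = "r1", status = "PAIR", mqs = 70, unique = TRUE)
#' evB <- list(read_id = "r1", status = "SINGLETON", mqs = 55, unique = TRUE)
#' arbitrate(evA, evB)$outcome
#' @export
arbitrate <- function(evA, evB) {
  rid <- if (!is.null(evA$read_id)) evA$read_id else evB$read_id
  rA <- STATUS_RANK[[evA$status]]
  rB <- STATUS_RANK[[evB$status]]
  if (rA == 0L && rB == 0L)
    return(list(read_id = rid, outcome = "UNMAPPED",
                deciding_rule = "NONE"))
  if (rA == 0L || rB == 0L)
    return(list(read_id = rid,
                outcome = if (rA > 0L) "ASSIGN_A" else "ASSIGN_B",
                deciding_rule = "ONLY_ONE"))
  if (rA != rB)
    return(list(read_id = rid,
                outcome = if (rA > rB) "ASSIGN_A" else "ASSIGN_B",
                deciding_rule = "PAIR_PRIORITY"))
  uA <- isTRUE(evA$unique); uB <- isTRUE(evB$unique)
  if (uA != uB)
    return(list(read_id = rid,
                outcome = if (uA) "ASSIGN_A" else "ASSIGN_B",
                deciding_rule = "UNIQUE_PRIORITY"))
  if (evA$mqs != evB$mqs)
    return(list(read_id = rid,
                outcome = if (evA$mqs > evB$mqs) "ASSIGN_A" else "ASSIGN_B",
                deciding_rule = "MQS"))
  list(read_id = rid, outcome = "DISCARD_TIE", deciding_rule = "NONE")
}

# vectorised arbitration over aligned evidence tables (same read order)
arbitrateAll <- function(evA, evB) {
  stopifnot(identical(evA$read_id, evB$read_id))
  rA <- STATUS_RANK[evA$status]; rB <- STATUS_RANK[evB$status]
  uA <- evA$unique; uB <- evB$unique
  outcome <- rep("DISCARD_TIE", nrow(evA))
  rule <- rep("NONE", nrow(evA))

  bothUn <- rA == 0L & rB == 0L
  outcome[bothUn] <- "UNMAPPED"
  one <- xor(rA > 0L, rB > 0L)
  outcome[one] <- ifelse(rA[one] > 0L, "ASSIGN_A", "ASSIGN_B")
  rule[one] <- "ONLY_ONE"
  live <- !bothUn & !one

  d <- live & rA != rB
  outcome[d] <- ifelse(rA[d] > rB[d], "ASSIGN_A", "ASSIGN_B")
  rule[d] <- "PAIR_PRIORITY"
  live <- live & !d

  d <- live & uA != uB
  outcome[d] <- ifelse(uA[d], "ASSIGN_A", "ASSIGN_B")
  rule[d] <- "UNIQUE_PRIORITY"
  live <- live & !d

  d <- live & evA$mqs != evB$mqs
  outcome[d] <- ifelse(evA$mqs[d] > evB$mqs[d], "ASSIGN_A", "ASSIGN_B")
  rule[d] <- "MQS"

  data.frame(read_id = evA$read_id, outcome = outcome,
             deciding_rule = rule, stringsAsFactors = FALSE)
}

#' Partition a library's alignments between the two subgenomes
#'
#' Builds per-fragment evidence on each side, arbitrates every read pair,
#' and splits the records: a pair's records are kept only on its assigned
#' subgenome; DISCARD_TIE and UNMAPPED pairs appear on neither.
#'
#' @param samA,samB alignment record data.frames or SAM/BAM paths for the
#'   same read universe against subgenome A and B (name-grouped).
#' @param uniqueOnly drop ambiguous (NH > 1) records before evidence
#'   building.
#' @param cleanReads denominator for mapping ratios (clean read pairs);
#'   defaults to the read universe size.
#' @param outPrefix when given, assigned records are written to
#'   `<outPrefix>_A.sam` / `<outPrefix>_B.sam`.
#' @return list: `decisions` (read_id, outcome, deciding_rule),
#'   `recordsA`/`recordsB` (assigned records), and `stats` (mapped counts
#'   and [mappingRatio()] percentages per subgenome, assigned counts, tie
#'   and unmapped counts, combined assigned ratio).
#' @export
partitionLibrary <- function(samA, samB, uniqueOnly = FALSE,
                             cleanReads = NULL, outPrefix = NULL) {
  recA <- asRecords(samA)
  recB <- asRecords(samB)
  ids <- unique(c(recA$qname, recB$qname))
  missingA <- !(ids %in% recA$qname)
  missingB <- !(ids %in% recB$qname)
  if (any(missingA | missingB))
    warning(sum(missingA | missingB),
            " reads absent from one input; treated as unmapped there")
  evA <- buildFragmentEvidence(recA, "A", readIds = ids,
                               uniqueOnly = uniqueOnly)
  evB <- buildFragmentEvidence(recB, "B", readIds = ids,
                               uniqueOnly = uniqueOnly)
  dec <- arbitrateAll(evA, evB)

  keepA <- recA$qname %in% dec$read_id[dec$outcome == "ASSIGN_A"]
  keepB <- recB$qname %in% dec$read_id[dec$outcome == "ASSIGN_B"]
  outA <- recA[keepA, , drop = FALSE]
  outB <- recB[keepB, , drop = FALSE]
  attr(outA, "refLengths") <- attr(recA, "refLengths")
  attr(outB, "refLengths") <- attr(recB, "refLengths")

  clean <- if (is.null(cleanReads)) length(ids) else cleanReads
  nA <- sum(dec$outcome == "ASSIGN_A"); nB <- sum(dec$outcome == "ASSIGN_B")
  stats <- data.frame(
    total_pairs = length(ids), clean_pairs = clean,
    mapped_A = sum(evA$status != "UNMAPPED"),
    mapped_B = sum(evB$status != "UNMAPPED"),
    ratio_A = if (clean > 0) mappingRatio(sum(evA$status != "UNMAPPED"), clean) else NA,
    ratio_B = if (clean > 0) mappingRatio(sum(evB$status != "UNMAPPED"), clean) else NA,
    assigned_A = nA, assigned_B = nB,
    ties = sum(dec$outcome == "DISCARD_TIE"),
    unmapped = sum(dec$outcome == "UNMAPPED"),
    assigned_ratio = if (clean > 0) mappingRatio(nA + nB, clean) else NA)

  if (!is.null(outPrefix)) {
    writeSam(outA, paste0(outPrefix, "_A.sam"))
    writeSam(outB, paste0(outPrefix, "_B.sam"))
  }
  list(decisions = dec, recordsA = outA, recordsB = outB, stats = stats)
}

#' Mapping ratio as printed in read-accounting tables
#'
#' @param mapped mapped read count.
#' @param clean clean read count (denominator); must be positive and at
#'   least `mapped`.
#' @return `100 * mapped / clean`, rounded half-up to 1 decimal.
#' @examples
#' mappingRatio(17586172, 22088185)  # 79.6
#' @export
mappingRatio <- function(mapped, clean) {
  if (any(clean == 0)) stop("clean read count must be positive")
  if (any(mapped > clean)) stop("mapped cannot exceed clean")
  roundHalfUp(100 * mapped / clean, 1L)
}
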