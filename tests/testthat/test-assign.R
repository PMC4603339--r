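rec <- function(id, mate, mapped = TRUE, mapq = 0L, nh = 1L) {
  flag <- 1L + (if (mate == 1L) 64L else 128L) + (if (!mapped) 4L else 0L)
  data.frame(qname = id, flag = flag, rname = if (mapped) "c" else "*",
             pos = if (mapped) 1L else 0L, mapq = mapq, cigar = "*",
             NH = nh, stringsAsFactors = FALSE)
}

test_that("fragment evidence summarises pair status, MQS sum and uniqueness", {
  # both mates in A (MAPQ 40, 35), none in B
  recA <- rbind(rec("r1", 1, mapq = 40L), rec("r1", 2, mapq = 35L))
  recB <- rbind(rec("r1", 1, mapped = FALSE), rec("r1", 2, mapped = FALSE))
  sf <- summarizeFragment(recA, recB)
  expect_equal(sf$A$status, "PAIR")
  expect_equal(sf$A$mqs, 75)
  expect_true(sf$A$unique)
  expect_equal(sf$B$status, "UNMAPPED")
  expect_equal(sf$B$mqs, 0)

  # mate 1 only, MAPQ 30, 3 best hits -> ambiguous singleton
  s <- buildFragmentEvidence(rbind(rec("r2", 1, mapq = 30L, nh = 3L),
                                   rec("r2", 2, mapped = FALSE)), "B")
  expect_equal(s$status, "SINGLETON")
  expect_equal(s$mqs, 30)
  expect_false(s$unique)

  # nothing mapped either side
  sf0 <- summarizeFragment(rec("r3", 1, mapped = FALSE),
                           rec("r3", 1, mapped = FALSE))
  expect_equal(sf0$A$status, "UNMAPPED")
  expect_equal(sf0$B$status, "UNMAPPED")
})

test_that("mixed read ids and duplicate primaries are rejected", {
  expect_error(summarizeFragment(rec("r1", 1), rec("r2", 1)), "mix")
  expect_error(buildFragmentEvidence(rbind(rec("r1", 1), rec("r1", 1))),
               "duplicate")
})

test_that("arbitration follows pair > unique > MQS with tie discard", {
  # pair beats singleton regardless of MQS
  d <- arbitrate(ev("PAIR", 70, TRUE), ev("SINGLETON", 55, TRUE, sg = "B"))
  expect_equal(d$outcome, "ASSIGN_A")
  expect_equal(d$deciding_rule, "PAIR_PRIORITY")
  # unique beats ambiguous at equal status
  d <- arbitrate(ev("PAIR", 120, FALSE), ev("PAIR", 80, TRUE, sg = "B"))
  expect_equal(d$outcome, "ASSIGN_B")
  expect_equal(d$deciding_rule, "UNIQUE_PRIORITY")
  # higher MQS wins among equal status/uniqueness
  d <- arbitrate(ev("PAIR", 60, TRUE), ev("PAIR", 90, TRUE, sg = "B"))
  expect_equal(d$outcome, "ASSIGN_B")
  expect_equal(d$deciding_rule, "MQS")
  # equal everything is discarded
  d <- arbitrate(ev("PAIR", 80, TRUE), ev("PAIR", 80, TRUE, sg = "B"))
  expect_equal(d$outcome, "DISCARD_TIE")
  # one side only
  d <- arbitrate(ev("UNMAPPED"), ev("SINGLETON", 10, FALSE, sg = "B"))
  expect_equal(d$outcome, "ASSIGN_B")
  expect_equal(d$deciding_rule, "ONLY_ONE")
  # nothing anywhere
  expect_equal(arbitrate(ev("UNMAPPED"), ev("UNMAPPED"))$outcome,
               "UNMAPPED")
})

test_that("arbitrate agrees with the exhaustive rule-interpreter oracle", {
  grid <- expand.grid(status = c("PAIR", "SINGLETON", "UNMAPPED"),
                      unique = c(TRUE, FALSE), mqs = c(0, 30, 60),
                      stringsAsFactors = FALSE)
  n <- 0L
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    evA <- ev(grid$status[i], grid$mqs[i], grid$unique[i])
    evB <- ev(grid$status[j], grid$mqs[j], grid$unique[j], sg = "B")
    expect_equal(arbitrate(evA, evB)$outcome, oracleArbitrate(evA, evB),
                 info = paste(i, j))
    n <- n + 1L
  }
  expect_equal(n, 324L)
})

test_that("partition is complete and symmetric under A/B swap", {
  cfg <- simConfig(nGenes = 15, readsPerLibrary = 400, seqErrorRate = 0,
                   seed = 44)
  sg <- simulateSubgenomes(cfg)
  rd <- simulateReads(cfg, sg, simulateCounts(cfg))
  lib <- rd$libraries[[1]]
  samA <- fixtureAlign(lib, sg$refA)
  samB <- fixtureAlign(lib, sg$refB)
  p1 <- partitionLibrary(samA, samB)
  st <- p1$stats
  expect_equal(st$assigned_A + st$assigned_B + st$ties + st$unmapped,
               st$total_pairs)
  p2 <- partitionLibrary(samB, samA)
  expect_equal(p2$stats$assigned_A, st$assigned_B)
  expect_equal(p2$stats$assigned_B, st$assigned_A)
  expect_equal(p2$stats$ties, st$ties)
})

test_that("identical subgenomes force ties for everything mapped on both sides", {
  cfg <- simConfig(nGenes = 8, readsPerLibrary = 200, divergence = 0,
                   seqErrorRate = 0, seed = 45)
  sg <- simulateSubgenomes(cfg)
  rd <- simulateReads(cfg, sg, simulateCounts(cfg))
  samA <- fixtureAlign(rd$libraries[[1]], sg$refA)
  samB <- fixtureAlign(rd$libraries[[1]], sg$refB)
  p <- partitionLibrary(samA, samB)
  expect_equal(p$stats$assigned_A + p$stats$assigned_B, 0)
  expect_gt(p$stats$ties, 0)
})

test_that("an empty B input sends every mapped read to A", {
  cfg <- simConfig(nGenes = 5, readsPerLibrary = 100, seqErrorRate = 0,
                   seed = 46)
  sg <- simulateSubgenomes(cfg)
  rd <- simulateReads(cfg, sg, simulateCounts(cfg))
  samA <- fixtureAlign(rd$libraries[[1]], sg$refA)
  emptyB <- samA[0, ]
  p <- suppressWarnings(partitionLibrary(samA, emptyB))
  expect_equal(p$stats$assigned_B, 0)
  expect_equal(p$stats$assigned_A,
               sum(buildFragmentEvidence(samA)$status != "UNMAPPED"))
})

test_that("unique-only mode never assigns on ambiguous winning evidence", {
  set.seed(47)
  unit <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  # A carries the locus twice (ambiguous), B once with one mismatch
  refA <- Biostrings::DNAStringSet(c(x1 = unit, x2 = unit))
  mut <- unit
  substr(mut, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(unit, 150, 150))[1]
  refB <- Biostrings::DNAStringSet(c(y1 = mut))
  lib <- list(id = "r1", seq1 = substr(unit, 100, 200),
              qual1 = strrep("I", 101))
  samA <- fixtureAlign(lib, refA)
  samB <- fixtureAlign(lib, refB)
  pDefault <- partitionLibrary(samA, samB)
  pUnique <- partitionLibrary(samA, samB, uniqueOnly = TRUE)
  # default: A evidence is ambiguous, B unique -> B wins by uniqueness
  expect_equal(pDefault$decisions$outcome, "ASSIGN_B")
  # unique-only: ambiguous A records dropped entirely, B still wins
  expect_equal(pUnique$decisions$outcome, "ASSIGN_B")
  expect_true(all(buildFragmentEvidence(pUnique$recordsB)$unique))
})

test_that("assignment accuracy against truth is high and rises with divergence", {
  accAt <- function(div, seed) {
    cfg <- simConfig(nGenes = 12, readsPerLibrary = 300, divergence = div,
                     seqErrorRate = 0, seed = seed)
    sg <- simulateSubgenomes(cfg)
    rd <- simulateReads(cfg, sg, simulateCounts(cfg))
    lib <- names(rd$libraries)[1]
    samA <- fixtureAlign(rd$libraries[[1]], sg$refA)
    samB <- fixtureAlign(rd$libraries[[1]], sg$refB)
    dec <- partitionLibrary(samA, samB)$decisions
    tru <- rd$truth[rd$truth$library == lib, ]
    m <- merge(dec, tru, by = "read_id")
    keep <- m$outcome %in% c("ASSIGN_A", "ASSIGN_B")
    mean((m$outcome[keep] == "ASSIGN_A") == (m$origin[keep] == "A"))
  }
  acc <- vapply(c(0.01, 0.05, 0.1), accAt, numeric(1), seed = 48)
  expect_gte(acc[2], 0.95)
  expect_true(all(diff(acc) >= 0))
})

test_that("mapping ratios reproduce printed accounting and reject bad input", {
  expect_equal(mappingRatio(17586172, 22088185), 79.6)
  expect_equal(mappingRatio(13102552, 22088185), 59.3)
  expect_equal(mappingRatio(0, 1000), 0.0)
  expect_error(mappingRatio(1, 0), "positive")
  expect_error(mappingRatio(10, 5), "exceed")
})
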