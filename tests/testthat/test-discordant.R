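# build a minimal alignment_set by hand
fake_aln <- function(rows) {
  cols <- c("qname", "mate", "mapped", "chrom", "pos", "strand", "matchLength",
            "mismatches", "unique", "mateChrom", "matePos", "proper")
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df <- df[, cols]
  class(df) <- c("alignment_set", "data.frame")
  df
}

pair_rows <- function(qname, chrom1, pos1, strand1, chrom2, pos2, strand2,
                      unique1 = TRUE, unique2 = TRUE, mapped2 = TRUE) {
  list(list(qname = qname, mate = 1L, mapped = TRUE, chrom = chrom1,
            pos = pos1, strand = strand1, matchLength = 100L, mismatches = 0L,
            unique = unique1, mateChrom = chrom2, matePos = pos2, proper = FALSE),
       list(qname = qname, mate = 2L, mapped = mapped2, chrom = chrom2,
            pos = pos2, strand = strand2, matchLength = 100L, mismatches = 0L,
            unique = unique2, mateChrom = chrom1, matePos = pos1, proper = FALSE))
}

test_that("discordant extraction keeps exactly the unique inter-chromosomal pairs", {
  aln <- fake_aln(c(
    pair_rows("d1", "chr5", 100L, "+", "chr8", 900L, "-"),
    pair_rows("d2", "chr5", 150L, "+", "chr8", 950L, "-"),
    pair_rows("c1", "chr5", 100L, "+", "chr5", 400L, "-"),          # same chrom
    pair_rows("n1", "chr5", 100L, "+", "chr8", 900L, "-", unique2 = FALSE),
    pair_rows("u1", "chr5", 100L, "+", "chr8", 900L, "-", mapped2 = FALSE)))
  disc <- find_discordant(aln)
  expect_setequal(disc$qname, c("d1", "d2"))
  expect_true(all(disc$chromA == "chr5" & disc$chromB == "chr8"))

  # wild-type data: mapping a WT sample yields no discordant pairs
  ref <- small_ref(20000L, 20000L)
  win <- data.frame(chrom = c("chr5", "chr8"), start = 2000L, end = 8000L)
  reads <- simulate_paired_reads(ref, win, read_sim_config(depth = 10, seed = 5L))
  wt <- map_pairs(reads, build_index(ref))
  expect_equal(nrow(find_discordant(wt)), 0L)

  # unpaired stream errors
  expect_error(find_discordant(aln[-2L, ]), "unpaired")
})

test_that("single-linkage clustering joins and separates pairs as specified", {
  mk <- function(qname, pA, pB, sA = "+", sB = "-") {
    data.frame(qname = qname, chromA = "chr5", startA = pA, endA = pA + 100L,
               strandA = sA, chromB = "chr8", startB = pB, endB = pB + 100L,
               strandB = sB, stringsAsFactors = FALSE)
  }
  # 3 pairs within maxGap on both sides -> one cluster of support 3
  pairs <- rbind(mk("a", 100L, 5000L), mk("b", 300L, 5100L), mk("c", 500L, 5200L))
  class(pairs) <- c("discordant_pairs", "data.frame")
  cl <- cluster_discordant(pairs, maxGap = 455L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 3L)
  expect_equal(cl$startA, 100L)
  expect_equal(cl$endA, 600L)

  # separation of > maxGap on one side splits the cluster
  pairs2 <- rbind(mk("a", 100L, 5000L), mk("b", 1000L, 5050L))
  class(pairs2) <- c("discordant_pairs", "data.frame")
  cl2 <- cluster_discordant(pairs2, maxGap = 455L)
  expect_equal(nrow(cl2), 2L)
  expect_true(all(cl2$support == 1L))

  # opposite orientation consensus seeds separate clusters even when close
  pairs3 <- rbind(mk("a", 100L, 5000L), mk("b", 150L, 5050L, sA = "-", sB = "+"))
  class(pairs3) <- c("discordant_pairs", "data.frame")
  expect_equal(nrow(cluster_discordant(pairs3, maxGap = 455L)), 2L)

  # empty input -> empty output
  expect_equal(nrow(cluster_discordant(pairs[0, ], maxGap = 455L)), 0L)
})

test_that("clustering equals brute-force transitive closure on random pair sets", {
  maxGap <- 300L
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(2:20, 1L))
    pairs <- withr::with_seed(seed * 13L, data.frame(
      qname = sprintf("p%02d", 1:n),
      chromA = "chr5", startA = sample(0:3000, n, TRUE),
      endA = 0L, strandA = sample(c("+", "-"), n, TRUE),
      chromB = "chr8", startB = sample(0:3000, n, TRUE),
      endB = 0L, strandB = sample(c("+", "-"), n, TRUE),
      stringsAsFactors = FALSE))
    pairs$endA <- pairs$startA + 100L
    pairs$endB <- pairs$startB + 100L
    class(pairs) <- c("discordant_pairs", "data.frame")

    cl <- cluster_discordant(pairs, maxGap = maxGap)
    expect_equal(sum(cl$support), n)

    # oracle: reflexive-transitive closure of the pairwise join relation
    join <- outer(1:n, 1:n, function(i, j)
      pairs$strandA[i] == pairs$strandA[j] & pairs$strandB[i] == pairs$strandB[j] &
      abs(pairs$startA[i] - pairs$startA[j]) <= maxGap &
      abs(pairs$startB[i] - pairs$startB[j]) <= maxGap)
    reach <- join
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    oracleGroups <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
    gotGroups <- vapply(cl$members, function(m) paste(sort(m), collapse = ","), "")
    expect_setequal(gotGroups, oracleGroups)
  }
})

test_that("candidate calling filters by support and brackets the true breakpoints", {
  mk <- function(qname, pA, pB) {
    data.frame(qname = qname, chromA = "chr5", startA = pA, endA = pA + 100L,
               strandA = "+", chromB = "chr8", startB = pB, endB = pB + 100L,
               strandB = "-", stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk("a", 100L, 5000L), mk("b", 120L, 5020L), mk("c", 140L, 5040L),
                 mk("z", 9000L, 9000L))
  class(pairs) <- c("discordant_pairs", "data.frame")
  cl <- cluster_discordant(pairs, maxGap = 455L)
  cands <- call_candidates(cl, minSupport = 3L, insertMean = 350,
                           insertSd = 35, readLen = 100L, boundaryPad = 12L)
  expect_equal(nrow(cands), 1L)  # support-1 cluster dropped
  expect_equal(cands$support, 3L)
  # forward side: interval starts at (max read end - pad), extends the inner gap
  expect_equal(cands$startA, 240L - 12L)
  expect_equal(cands$endA, 240L + (350 - 200 + 4 * 35))
  # reverse side mirrors
  expect_equal(cands$startB, 5000L - (350 - 200 + 4 * 35))
  expect_equal(cands$endB, 5000L + 12L)

  expect_error(call_candidates(cl, minSupport = 3L), "insert")

  bedpe <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(cands, bedpe)
  back <- read.table(bedpe, sep = "\t")
  expect_equal(back$V2, cands$startA)
  expect_equal(back$V6, cands$endB)
})

test_that("a simulated event yields one candidate per junction containing the truth", {
  study <- simulate_study(seed = 314L, chromLen = 3e5, windowHalf = 2e4,
                          delA = 4L, delB = 2L, dup1 = 1L, wt = FALSE)
  res <- call_translocation(study$reads, study$ref)
  expect_equal(nrow(res$candidates), 2L)
  # the two junctions carry opposite orientation consensus
  expect_setequal(paste0(res$candidates$strandA, res$candidates$strandB),
                  c("+-", "-+"))
  rep <- recovery_report(res, study$truth)
  expect_true(rep$containment)
})
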