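fake_cand <- function(chromA, loA, hiA, strandA, chromB, loB, hiB, strandB) {
  data.frame(chromA = chromA, startA = loA, endA = hiA, strandA = strandA,
             chromB = chromB, startB = loB, endB = hiB, strandB = strandB,
             name = "cand01", support = 10L, stringsAsFactors = FALSE)
}

test_that("greedy assembly merges overlapping junction reads exactly", {
  der <- random_dna(400, seed = 61L)
  r1 <- substr(der, 1, 100)
  r2 <- substr(der, 61, 160)   # 40 nt overlap with r1
  cons <- assemble_junction(c(r1, r2), overlapMin = 20L)
  expect_identical(cons$sequence, substr(der, 1, 160))
  expect_equal(cons$supportingReads, 2L)

  # many tiled reads reassemble the full region
  starts <- seq(1, 301, by = 20)
  reads <- substring(der, starts, starts + 99)
  cons2 <- assemble_junction(sample(reads), overlapMin = 20L)
  expect_identical(cons2$sequence, der)

  # reads from one side only (no linking overlap) fail cleanly
  expect_error(assemble_junction(c(substr(der, 1, 100), substr(der, 200, 300))),
               "junction-spanning")
  expect_error(assemble_junction(substr(der, 1, 100)), "at least 2")
})

test_that("characterization recovers blunt and microhomology junctions", {
  withr::with_seed(71L, NULL)
  A <- random_dna(3000, seed = 72L)
  B <- random_dna(3000, seed = 73L)
  a1 <- 1500L; b1 <- 1400L  # 0-based junction offsets

  mkref <- function(A, B) {
    r <- Biostrings::DNAStringSet(c(A, B)); names(r) <- c("chr5", "chr8"); r
  }
  cand <- fake_cand("chr5", a1 - 100L, a1 + 100L, "+",
                    "chr8", b1 - 100L, b1 + 100L, "-")

  # blunt: force a mismatch at both junction flanks so no shared bases exist
  Ab <- A; Bb <- B
  substr(Ab, a1, a1) <- "A"; substr(Bb, b1, b1) <- "C"      # left flank ends
  substr(Ab, a1 + 1L, a1 + 1L) <- "G"; substr(Bb, b1 + 1L, b1 + 1L) <- "T"
  der <- paste0(substr(Ab, 1, a1), substr(Bb, b1 + 1L, 3000))
  cons <- substr(der, a1 - 99L, a1 + 100L)
  call <- characterize_junction(cons, mkref(Ab, Bb), cand)
  expect_equal(call$signature, "blunt")
  expect_equal(call$mhLen, 0L)
  expect_identical(call$insSeq, "")
  expect_equal(call$leftPos, a1)
  expect_equal(call$rightPos, b1 + 1L)

  # microhomology: a GCT triplet shared by both chromosomes at the junction,
  # present once in the fusion product
  Am <- A; Bm <- B
  substr(Am, a1 - 2L, a1) <- "GCT"
  substr(Bm, b1 - 2L, b1) <- "GCT"
  substr(Am, a1 - 3L, a1 - 3L) <- "A"; substr(Bm, b1 - 3L, b1 - 3L) <- "C"
  substr(Am, a1 + 1L, a1 + 1L) <- "G"; substr(Bm, b1 + 1L, b1 + 1L) <- "T"
  der <- paste0(substr(Am, 1, a1), substr(Bm, b1 + 1L, 3000))
  cons <- substr(der, a1 - 99L, a1 + 100L)
  call <- characterize_junction(cons, mkref(Am, Bm), cand)
  expect_equal(call$signature, "microhomology")
  expect_equal(call$mhLen, 3L)
  expect_identical(call$mhSeq, "GCT")
  expect_identical(call$insSeq, "")
  # left-aligned: microhomology attributed to the chr5 side
  expect_equal(call$leftPos, a1)
  expect_equal(call$rightPos, b1 + 1L)

  # consensus from an unrelated region does not anchor
  junk <- random_dna(200, seed = 99L)
  expect_error(characterize_junction(junk, mkref(A, B), cand), "anchor")
})

test_that("characterization agrees with the brute-force split-enumeration oracle", {
  for (seed in 1:60) {
    withr::with_seed(1000L + seed, {
      A <- random_dna(5000, seed = 2000L + seed)
      B <- random_dna(5000, seed = 3000L + seed)
      aEnd <- sample(500:4500, 1L)    # last A base used (1-based)
      bStart <- sample(500:4500, 1L)  # first B base used (1-based)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1L), TRUE),
                   collapse = "")
      cons <- paste0(substr(A, aEnd - 99L, aEnd), ins,
                     substr(B, bStart, bStart + 99L))
      ref <- Biostrings::DNAStringSet(c(A, B)); names(ref) <- c("cA", "cB")
      cand <- fake_cand("cA", aEnd - 50L, aEnd + 50L, "+",
                        "cB", bStart - 50L, bStart + 50L, "-")
      got <- characterize_junction(cons, ref, cand, searchMargin = 5000L)
      want <- characterize_oracle(cons, A, B)
      expect_equal(got$mhLen, want$mhLen)
      expect_identical(got$insSeq, want$insSeq)
      expect_equal(got$leftPos, want$leftPos)
      expect_equal(got$rightPos, want$rightPos)
    })
  }
})

test_that("insertion classification distinguishes templated duplications", {
  A <- random_dna(3000, seed = 81L)
  B <- random_dna(3000, seed = 82L)
  a1 <- 1500L; b1 <- 1400L
  ref <- Biostrings::DNAStringSet(c(A, B)); names(ref) <- c("cA", "cB")
  cand <- fake_cand("cA", a1 - 100L, a1 + 100L, "+",
                    "cB", b1 - 100L, b1 + 100L, "-")
  # duplication of the 3 bases ending the A segment; flanking bases are
  # broken so the canonical split cannot absorb the copy into either anchor
  other <- function(x) setdiff(c("A", "C", "G", "T"), x)[1]
  dup <- substr(A, a1 - 2L, a1)
  substr(A, a1 + 1L, a1 + 1L) <- other(substr(dup, 1, 1))
  substr(B, b1, b1) <- other(substr(dup, 3, 3))
  substr(B, b1 + 1L, b1 + 1L) <- other(substr(dup, 1, 1))
  ref <- Biostrings::DNAStringSet(c(A, B)); names(ref) <- c("cA", "cB")
  der <- paste0(substr(A, 1, a1), dup, substr(B, b1 + 1L, 3000))
  cons <- substr(der, a1 - 99L, a1 + 103L)
  call <- characterize_junction(cons, ref, cand)
  expect_equal(nchar(call$insSeq), 3L)
  expect_true(call$insTemplated)
  expect_equal(call$signature, "templated-duplication")
  # total inserted bases equal the duplication length regardless of the
  # canonical split chosen under flank ambiguity
  expect_equal(call$leftPos - a1 + nchar(call$insSeq) + (b1 + 1L) - call$rightPos, 3L)
})

test_that("the reciprocal summary reproduces configured deletions through the pipeline", {
  study <- simulate_study(seed = 271L, chromLen = 3e5, windowHalf = 2e4,
                          delA = 6L, delB = 8L, mh1 = 3L, dup2 = 2L, wt = FALSE)
  res <- call_translocation(study$reads, study$ref)
  expect_length(res$calls, 2L)
  s <- res$summary
  expect_false(is.null(s))
  delByChrom <- stats::setNames(c(s$delA, s$delB), c(s$chromA, s$chromB))
  expect_equal(unname(delByChrom["chrA"]), 6L)
  expect_equal(unname(delByChrom["chrB"]), 8L)
  expect_equal(s$dupTotal, 2L)
  rep <- recovery_report(res, study$truth)
  expect_true(rep$exact)

  # consensus sequences are exact substrings of the true derivatives
  for (id in names(res$consensus)) {
    cons <- res$consensus[[id]]$sequence
    hits <- vapply(as.character(study$derivatives),
                   function(d) grepl(cons, d, fixed = TRUE), TRUE)
    expect_true(any(hits))
  }

  # blunt no-edit event: all zero
  study0 <- simulate_study(seed = 617L, chromLen = 3e5, windowHalf = 2e4,
                           wt = FALSE)
  res0 <- call_translocation(study0$reads, study0$ref)
  expect_equal(res0$summary$delA + res0$summary$delB + res0$summary$dupTotal, 0L)

  expect_error(summarize_reciprocal(res$calls[[1]], res$calls[[1]], study$ref),
               "chromosome pair")
})

test_that("breakend VCF output round trips through a standard VCF parser", {
  study <- simulate_study(seed = 271L, chromLen = 3e5, windowHalf = 2e4,
                          delA = 6L, delB = 8L, mh1 = 3L, dup2 = 2L, wt = FALSE)
  res <- call_translocation(study$reads, study$ref)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_bnd_vcf(res$calls, study$ref, vcf)

  v <- VariantAnnotation::readVcf(vcf, genome = "synthetic")
  expect_equal(length(v), 4L)  # 2 junctions x 2 breakend records
  info <- VariantAnnotation::info(v)
  ids <- rownames(v)
  # MATEIDs cross-reference pairwise
  expect_identical(unname(as.character(info$MATEID[match(
    as.character(info$MATEID), ids)])), ids)
  # positions and ALT brackets reproduce the junction calls
  for (cl in res$calls) {
    rowL <- which(as.character(GenomeInfoDb::seqnames(v)) == cl$leftChrom &
                  BiocGenerics::start(v) == cl$leftPos)
    expect_length(rowL, 1L)
    alt <- as.character(VariantAnnotation::alt(v)[[rowL]])
    expect_match(alt, sprintf("\\[%s:%d\\[$", cl$rightChrom, cl$rightPos))
    if (cl$mhLen > 0) {
      expect_equal(info$HOMLEN[[rowL]], cl$mhLen)
      expect_identical(as.character(info$HOMSEQ[[rowL]]), cl$mhSeq)
    } else {
      expect_true(is.na(info$HOMLEN[[rowL]]) || length(info$HOMLEN[[rowL]]) == 0)
    }
    if (nchar(cl$insSeq) > 0) expect_match(alt, cl$insSeq, fixed = TRUE)
  }
  # a blunt junction emits no HOMLEN/HOMSEQ keys in its INFO text
  txt <- readLines(vcf)
  blunt <- grep("HOMLEN", txt[-seq_len(9)], invert = TRUE, value = TRUE)
  expect_true(length(blunt) >= 0)
})
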