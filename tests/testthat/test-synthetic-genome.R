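test_that("reference generation is deterministic with uniform composition", {
  ref <- make_reference(data.frame(name = "c5", length = 100000L, seed = 7L))
  expect_equal(Biostrings::width(ref), 100000L)
  ref2 <- make_reference(data.frame(name = "c5", length = 100000L, seed = 7L))
  expect_identical(as.character(ref), as.character(ref2))

  # GC fraction within the central 99.9% binomial interval around 0.5
  gc <- sum(Biostrings::alphabetFrequency(ref)[1, c("G", "C")])
  bounds <- qbinom(c(0.0005, 0.9995), 100000L, 0.5)
  expect_gte(gc, bounds[1])
  expect_lte(gc, bounds[2])

  expect_error(make_reference(data.frame(name = c("a", "a"),
                                         length = 1000L, seed = 1:2)),
               "duplicate")
  expect_error(make_reference(data.frame(name = "a", length = 0L, seed = 1L)),
               "positive")
})

test_that("derivative construction conserves and accounts for every base", {
  ref <- small_ref()
  # no edits: pure exchange conserves total length
  ev0 <- translocation_event("chr5", "chr8", 4000L, 4000L, 6000L, 6000L)
  d0 <- apply_translocation(ref, ev0)
  expect_equal(sum(Biostrings::width(d0$derivatives)), 20000L)

  # general base accounting: len(der1) + len(der2) =
  #   lenA + lenB - delA - delB + |ins1| + |ins2|, checked for a grid of edits
  for (delA in c(0L, 3L, 6L)) {
    for (delB in c(0L, 8L)) {
      ev <- translocation_event("chr5", "chr8", 4000L, 4000L + delA,
                                6000L, 6000L - delB,
                                ins1 = "TT", ins2 = "GCA")
      d <- apply_translocation(ref, ev)
      expect_equal(sum(Biostrings::width(d$derivatives)),
                   20000L - delA - delB + 5L)
      # the derivatives are literally prefix + insertion + suffix
      A <- as.character(ref[["chr5"]]); B <- as.character(ref[["chr8"]])
      expect_identical(as.character(d$derivatives[[1]]),
                       paste0(substr(A, 1, 4000), "TT",
                              substr(B, 6001, 10000)))
    }
  }
  expect_error(translocation_event("chr5", "chr8", 10L, 5L, 100L, 100L),
               "out of order")
  expect_error(apply_translocation(ref, translocation_event(
    "chr5", "chr8", 4000L, 20000L, 6000L, 6000L)), "range")
})

test_that("engineered events report the configured deletions and duplications", {
  ref <- small_ref(50000L, 50000L)
  # the headline configuration: 6 and 8 bp deletions, 1-3 nt duplications
  for (d in 1:3) {
    sim <- simulate_event(ref, "chr5", "chr8", delA = 6L, delB = 8L,
                          dup1 = d, dup2 = 4L - d, seed = 100L + d)
    tr <- sim$truth
    expect_equal(tr$a2 - tr$a1, 6L)
    expect_equal(tr$b1 - tr$b2, 8L)
    expect_equal(nchar(tr$ins1), d)
    expect_equal(nchar(tr$ins2), 4L - d)
    expect_equal(tr$mhLen1, 0L)
    expect_equal(tr$mhLen2, 0L)
  }
  # microhomology configurations canonicalize to the requested length
  sim <- simulate_event(ref, "chr5", "chr8", delA = 5L, delB = 6L,
                        mh1 = 3L, mh2 = 2L, seed = 9L)
  expect_equal(sim$truth$mhLen1, 3L)
  expect_equal(sim$truth$mhLen2, 2L)
  # microhomology must fit inside the resected flank
  expect_error(simulate_event(ref, "chr5", "chr8", delB = 1L, mh1 = 3L,
                              seed = 1L), "mh1")
})

test_that("truth records survive a JSON round trip losslessly", {
  ref <- small_ref(50000L, 50000L)
  sim <- simulate_event(ref, "chr5", "chr8", delA = 6L, delB = 8L,
                        mh1 = 2L, dup2 = 3L, seed = 5L)
  tr <- sim$truth
  tr$captureWindows <- data.frame(chrom = names(sim$derivatives),
                                  start = c(100L, 200L), end = c(5100L, 5200L),
                                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, path)
  back <- read_truth_json(path)
  expect_equal(back, tr)
})

test_that("paired-read simulation honours the coverage formula and no-error contract", {
  ref <- small_ref(120000L, 1000L)
  win <- data.frame(chrom = "chr5", start = 10000L, end = 110000L)
  cfg <- read_sim_config(depth = 30, readLen = 100L, seed = 21L)
  expect_equal(cfg$depth, 30)  # targeted-capture default depth
  reads <- simulate_paired_reads(ref, win, cfg)
  expect_length(reads$names, 15000L)  # round(30 * 1e5 / 200)

  # errorRate = 0: every mate 1 is an exact substring of the source window,
  # every mate 2 an exact substring of its reverse complement
  src <- substr(as.character(ref[["chr5"]]), 10001L - 500L, 110000L + 500L)
  rcsrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(src)))
  pick <- seq(1, 15000, by = 500)
  expect_true(all(vapply(reads$mate1[pick],
                         function(r) grepl(r, src, fixed = TRUE), TRUE)))
  expect_true(all(vapply(reads$mate2[pick],
                         function(r) grepl(r, rcsrc, fixed = TRUE), TRUE)))

  # placement truth matches the emitted sequences
  i <- 777L
  chrom <- as.character(ref[["chr5"]])
  expect_identical(reads$mate1[i],
                   substr(chrom, reads$truth$start1[i] + 1L,
                          reads$truth$start1[i] + 100L))

  # bit-reproducible under a fixed seed
  reads2 <- simulate_paired_reads(ref, win, cfg)
  expect_identical(reads$mate1, reads2$mate1)
  expect_identical(reads$mate2, reads2$mate2)

  expect_error(simulate_paired_reads(ref, data.frame(chrom = "chr8",
                                                     start = 0L, end = 400L),
                                     cfg), "shorter")
  expect_error(read_sim_config(depth = 30, seed = NA), "seed")
  expect_error(read_sim_config(insertMean = 150, readLen = 100, seed = 1L),
               "insertMean")
})

test_that("FASTQ round trip preserves pairs and names", {
  ref <- small_ref(5000L, 5000L)
  win <- data.frame(chrom = "chr8", start = 100L, end = 4900L)
  reads <- simulate_paired_reads(ref, win, read_sim_config(depth = 5, seed = 3L))
  f1 <- withr::local_tempfile(fileext = "_1.fq")
  f2 <- withr::local_tempfile(fileext = "_2.fq")
  write_fastq_pair(reads, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_identical(unname(back$mate1), reads$mate1)
  expect_identical(unname(back$mate2), reads$mate2)
  expect_identical(back$names, reads$names)
})
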