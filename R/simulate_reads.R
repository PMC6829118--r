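#' Configuration for paired-end read simulation
#'
#' Models a targeted-capture paired-end Illumina run: fold-coverage over the
#' capture windows, read length, a Gaussian insert-size distribution and an
#' optional per-base substitution error rate.
#'
#' @param depth fold coverage over each capture window (default 30).
#' @param readLen read length in nt (default 100).
#' @param insertMean,insertSd insert (fragment) size model in nt
#'   (defaults 350, 35); `insertMean >= 2 * readLen` is required.
#' @param errorRate per-base substitution probability in `[0, 1)` (default 0).
#' @param seed integer seed (required; simulation is bit-reproducible).
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(depth = 30, readLen = 100L, insertMean = 350,
                            insertSd = 35, errorRate = 0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("a seed is required")
  if (depth <= 0) stop("depth must be positive")
  if (insertMean < 2 * readLen) stop("insertMean must be at least 2 * readLen")
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  structure(list(depth = depth, readLen = as.integer(readLen),
                 insertMean = insertMean, insertSd = insertSd,
                 errorRate = errorRate, seed = as.integer(seed)),
            class = "read_sim_config")
}

sprinkle_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  L <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), L, rate)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L, nerr[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate targeted-capture paired-end reads
#'
#' Draws sequencing fragments from the given capture windows: fragment length
#' is Normal(`insertMean`, `insertSd`) truncated to `[2 * readLen, window
#' length]`, fragment start is uniform within the window, mate 1 is read
#' forward from the fragment start and mate 2 reverse-complement from the
#' fragment end. The number of pairs per window is
#' `round(depth * windowLength / (2 * readLen))`.
#'
#' @param seqs a [Biostrings::DNAStringSet] (e.g. derivative chromosomes).
#' @param windows data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open capture windows).
#' @param cfg a [read_sim_config()].
#' @return an object of class `read_set`: list with `names`, `mate1`,
#'   `mate2` (character vectors), `truth` (per-pair placement data.frame)
#'   and `cfg`.
#' @export
simulate_paired_reads <- function(seqs, windows, cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  windows <- as.data.frame(windows)
  if (!all(c("chrom", "start", "end") %in% names(windows)))
    stop("windows must have chrom, start, end columns")
  minW <- cfg$insertMean + 4 * cfg$insertSd
  L <- cfg$readLen

  out <- withr::with_seed(cfg$seed, {
    lapply(seq_len(nrow(windows)), function(w) {
      chromName <- as.character(windows$chrom[w])
      if (!chromName %in% names(seqs)) stop("window chromosome not in sequence set")
      chrom <- as.character(seqs[[chromName]])
      s0 <- as.integer(windows$start[w]); e0 <- as.integer(windows$end[w])
      if (s0 < 0 || e0 > nchar(chrom)) stop("capture window outside chromosome")
      W <- e0 - s0
      if (W < minW) stop("capture window shorter than insertMean + 4 * insertSd")
      n <- round(cfg$depth * W / (2 * L))

      fl <- round(stats::rnorm(n, cfg$insertMean, cfg$insertSd))
      bad <- which(fl < 2 * L | fl > W)
      while (length(bad) > 0) {
        fl[bad] <- round(stats::rnorm(length(bad), cfg$insertMean, cfg$insertSd))
        bad <- bad[fl[bad] < 2 * L | fl[bad] > W]
      }
      fl <- as.integer(fl)
      fs <- as.integer(s0 + floor(runif(n) * (W - fl + 1)))  # fragment start, 0-based

      m1 <- substring(chrom, fs + 1L, fs + L)
      m2 <- revcomp_chr(substring(chrom, fs + fl - L + 1L, fs + fl))
      m1 <- sprinkle_errors(m1, cfg$errorRate)
      m2 <- sprinkle_errors(m2, cfg$errorRate)
      nm <- sprintf("frag_w%d_%06d", w, seq_len(n))
      list(names = nm, mate1 = m1, mate2 = m2,
           truth = data.frame(name = nm, chrom = chromName,
                              start1 = fs, strand1 = "+",
                              start2 = fs + fl - L, strand2 = "-",
                              fragLen = fl, stringsAsFactors = FALSE))
    })
  })

  structure(list(
    names = unlist(lapply(out, `[[`, "names")),
    mate1 = unlist(lapply(out, `[[`, "mate1")),
    mate2 = unlist(lapply(out, `[[`, "mate2")),
    truth = do.call(rbind, lapply(out, `[[`, "truth")),
    cfg = cfg
  ), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pairs, readLen=%d\n", length(x$names), x$cfg$readLen))
  invisible(x)
}

#' Write a read set as a pair of FASTQ files
#'
#' Mate names carry "/1" and "/2" suffixes; qualities are constant Phred+33.
#'
#' @param reads a `read_set`.
#' @param file1,file2 output FASTQ paths for mate 1 / mate 2.
#' @export
write_fastq_pair <- function(reads, file1, file2) {
  q <- strrep("F", reads$cfg$readLen)
  for (m in 1:2) {
    seqs <- if (m == 1) reads$mate1 else reads$mate2
    path <- if (m == 1) file1 else file2
    writeLines(paste0("@", reads$names, "/", m, "\n", seqs, "\n+\n", q),
               con = path)
  }
  invisible(c(file1, file2))
}

#' Read a pair of FASTQ files into a read set
#'
#' @param file1,file2 FASTQ paths for mate 1 / mate 2.
#' @return a `read_set` (without placement truth or simulation config).
#' @export
read_fastq_pair <- function(file1, file2) {
  m1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(file2, format = "fastq")
  if (length(m1) != length(m2)) stop("FASTQ mate files have unequal length")
  nm <- sub("/[12]$", "", sub("\\s.*$", "", names(m1)))
  nm2 <- sub("/[12]$", "", sub("\\s.*$", "", names(m2)))
  if (!identical(nm, nm2)) stop("FASTQ mate names do not pair up")
  structure(list(names = nm, mate1 = as.character(m1), mate2 = as.character(m2),
                 truth = NULL, cfg = NULL),
            class = "read_set")
}
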