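#' Build a k-mer seed index over a reference set
#'
#' Complete occurrence index of every k-mer of the reference, queryable on
#' both strands (minus-strand occurrences are resolved through the reverse
#' complement, so each position is stored once).
#'
#' @param ref a [Biostrings::DNAStringSet].
#' @param k odd seed length, `1 < k <= 31` (default 31).
#' @return an object of class `seed_index`.
#' @export
build_index <- function(ref, k = 31L) {
  validate_reference(ref)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k > 31L || k < 3L) stop("k must be between 3 and 31")
  ptr <- cpp_build_index(names(ref), as.character(ref), k)
  structure(list(ptr = ptr, k = k, refnames = names(ref),
                 reflengths = stats::setNames(Biostrings::width(ref), names(ref))),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d over %d chromosome(s), %.0f positions\n",
              x$k, length(x$refnames), cpp_index_size(x$ptr)))
  invisible(x)
}

#' Query a seed index for one k-mer
#'
#' @param index a `seed_index`.
#' @param kmer a string of length `k`.
#' @return data.frame with `chrom`, `pos` (0-based) and `strand` for every
#'   occurrence on either strand.
#' @export
kmer_hits <- function(index, kmer) {
  hits <- cpp_index_query(index$ptr, kmer)
  hits$chrom <- index$refnames[hits$chrom]
  hits
}

#' Map paired-end reads with seed-and-extend alignment
#'
#' Each mate is seeded with its non-overlapping k-mers and extended ungapped
#' at every seed hit; the unique best (fewest-mismatch) full-length placement
#' within `maxMismatch` is reported. Equal-best ties keep the
#' lexicographically smallest placement and are flagged non-unique. Reads
#' spanning a novel junction have no tolerable full-length placement and are
#' reported unmapped, which is what the downstream discordant/assembly stages
#' rely on. Mate fields are cross-filled and a proper-pair flag is computed
#' from the FR orientation and the insert-size model.
#'
#' @param reads a `read_set` (see [simulate_paired_reads()],
#'   [read_fastq_pair()]).
#' @param index a `seed_index` built over the wild-type reference.
#' @param maxMismatch maximum substitutions tolerated per mate (default 3).
#' @param insertMean,insertSd insert-size model used for the proper-pair
#'   flag; defaults come from `reads$cfg` when present.
#' @return an `alignment_set`: data.frame with one row per mate (`qname`,
#'   `mate`, `mapped`, `chrom`, `pos` 0-based, `strand`, `matchLength`,
#'   `mismatches`, `unique`, `mateChrom`, `matePos`, `proper`).
#' @export
map_pairs <- function(reads, index, maxMismatch = 3L,
                      insertMean = NULL, insertSd = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(index, "seed_index"))
  if (length(reads$mate1) != length(reads$mate2))
    stop("mate vectors of unequal length")
  insertMean <- insertMean %||% (if (!is.null(reads$cfg)) reads$cfg$insertMean else 350)
  insertSd <- insertSd %||% (if (!is.null(reads$cfg)) reads$cfg$insertSd else 35)

  n <- length(reads$names)
  res <- lapply(1:2, function(m) {
    sq <- if (m == 1) reads$mate1 else reads$mate2
    df <- cpp_map_reads(index$ptr, sq, as.integer(maxMismatch))
    data.frame(qname = reads$names, mate = m, mapped = df$mapped,
               chrom = ifelse(is.na(df$chrom), NA_character_,
                              index$refnames[df$chrom]),
               pos = df$pos, strand = df$strand,
               matchLength = ifelse(df$mapped, nchar(sq), 0L),
               mismatches = df$mismatches,
               unique = df$mapped & df$nbest == 1L,
               stringsAsFactors = FALSE)
  })
  a1 <- res[[1]]; a2 <- res[[2]]
  a1$mateChrom <- a2$chrom; a1$matePos <- a2$pos
  a2$mateChrom <- a1$chrom; a2$matePos <- a1$pos

  samechrom <- a1$mapped & a2$mapped & a1$chrom == a2$chrom
  fr <- samechrom &
    ((a1$strand == "+" & a2$strand == "-" & a1$pos <= a2$pos) |
     (a1$strand == "-" & a2$strand == "+" & a2$pos <= a1$pos))
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$pos + a1$matchLength, a2$pos + a2$matchLength)
  insert <- hi - lo
  proper <- !is.na(fr) & fr &
    insert >= insertMean - 4 * insertSd & insert <= insertMean + 4 * insertSd
  proper[is.na(proper)] <- FALSE
  a1$proper <- proper; a2$proper <- proper

  aln <- rbind(a1, a2)
  aln <- aln[order(rep(seq_len(n), 2L), aln$mate), ]
  rownames(aln) <- NULL
  attr(aln, "refnames") <- index$refnames
  attr(aln, "reflengths") <- index$reflengths
  attr(aln, "insertMean") <- insertMean
  attr(aln, "insertSd") <- insertSd
  class(aln) <- c("alignment_set", "data.frame")
  aln
}

sam_flag <- function(aln) {
  other <- ifelse(aln$mate == 1L, 2L, 1L)
  key <- paste(aln$qname, other)
  self <- paste(aln$qname, aln$mate)
  mateRow <- match(key, self)
  mateMapped <- aln$mapped[mateRow]
  mateStrand <- aln$strand[mateRow]
  flag <- 1L +                                   # paired
    ifelse(aln$proper, 2L, 0L) +
    ifelse(!aln$mapped, 4L, 0L) +
    ifelse(!mateMapped, 8L, 0L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(mateMapped & mateStrand == "-", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  flag
}

#' Write alignments as SAM
#'
#' Emits a valid header (`@SQ` lines from the reference set used for mapping)
#' and the 11 mandatory fields plus an `NM` tag. Reverse-strand records store
#' the reverse-complemented read sequence, per convention.
#'
#' @param aln an `alignment_set` from [map_pairs()].
#' @param reads the `read_set` that was mapped (for sequences).
#' @param path output SAM path.
#' @export
write_sam <- function(aln, reads, path) {
  refn <- attr(aln, "refnames"); refl <- attr(aln, "reflengths")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refn, refl[refn]))
  seqs <- ifelse(aln$mate == 1L, reads$mate1[match(aln$qname, reads$names)],
                 reads$mate2[match(aln$qname, reads$names)])
  seqs <- ifelse(aln$mapped & aln$strand == "-", revcomp_chr(seqs), seqs)
  qual <- strrep("F", nchar(seqs))
  flag <- sam_flag(aln)
  rname <- ifelse(aln$mapped, aln$chrom, "*")
  pos <- ifelse(aln$mapped, aln$pos + 1L, 0L)
  mapq <- ifelse(!aln$mapped, 0L, ifelse(aln$unique, 60L, 0L))
  cigar <- ifelse(aln$mapped, paste0(aln$matchLength, "M"), "*")
  mateMapped <- !is.na(aln$mateChrom)
  rnext <- ifelse(!mateMapped, "*",
                  ifelse(aln$mateChrom == rname & aln$mapped, "=", aln$mateChrom))
  pnext <- ifelse(mateMapped, aln$matePos + 1L, 0L)
  tlen <- 0L
  same <- aln$mapped & mateMapped & aln$chrom == aln$mateChrom
  lo <- pmin(aln$pos, aln$matePos); hi <- pmax(aln$pos, aln$matePos) + aln$matchLength
  tlen <- ifelse(same, ifelse(aln$pos <= aln$matePos, hi - lo, lo - hi), 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                  aln$qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
                  seqs, qual, ifelse(is.na(aln$mismatches), 0L, aln$mismatches))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Accepts externally produced SAM interchangeably with [map_pairs()] output
#' for all downstream stages. Parsing goes through Rsamtools; uniqueness is
#' inferred from MAPQ > 0 and mismatch counts from the `NM` tag when present.
#'
#' @param path SAM file with header.
#' @return an `alignment_set`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  flag <- x$flag
  bit <- function(b) bitwAnd(flag, b) > 0L
  mlen <- ifelse(is.na(x$cigar), 0L,
                 suppressWarnings(as.integer(sub("M$", "", x$cigar))))
  mlen[is.na(mlen)] <- 0L
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  aln <- data.frame(
    qname = x$qname,
    mate = ifelse(bit(64L), 1L, 2L),
    mapped = !bit(4L),
    chrom = as.character(x$rname),
    pos = x$pos - 1L,
    strand = ifelse(bit(16L), "-", "+"),
    matchLength = mlen,
    mismatches = nm,
    unique = !bit(4L) & x$mapq > 0L,
    mateChrom = as.character(x$mrnm),
    matePos = x$mpos - 1L,
    proper = bit(2L),
    stringsAsFactors = FALSE)
  aln$chrom[!aln$mapped] <- NA_character_
  aln$strand[!aln$mapped] <- NA_character_
  attr(aln, "refnames") <- names(hdr)
  attr(aln, "reflengths") <- hdr
  class(aln) <- c("alignment_set", "data.frame")
  aln
}
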