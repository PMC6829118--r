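#' Extract inter-chromosomal discordant read pairs
#'
#' Returns exactly the pairs whose two mates are both uniquely mapped to
#' different chromosomes -- the raw evidence for a translocation. Proper
#' pairs are by construction excluded (mates on one chromosome), and any pair
#' with an unmapped or non-uniquely placed mate is discarded.
#'
#' @param aln an `alignment_set` ([map_pairs()] or [read_sam()]).
#' @return a `discordant_pairs` data.frame: `qname`, and per side (A = the
#'   lexicographically smaller chromosome) `chrom`, `start`, `end` (0-based
#'   half-open read footprint) and `strand`.
#' @export
find_discordant <- function(aln) {
  a1 <- aln[aln$mate == 1L, ]
  a2 <- aln[aln$mate == 2L, ]
  if (nrow(a1) != nrow(a2) || !identical(a1$qname, a2$qname))
    stop("unpaired alignment stream: every read needs both mates")
  keep <- a1$mapped & a2$mapped & a1$unique & a2$unique &
    a1$chrom != a2$chrom
  a1 <- a1[keep, ]; a2 <- a2[keep, ]
  swap <- a1$chrom > a2$chrom
  eA <- ifelse(swap, a2$chrom, a1$chrom)
  eB <- ifelse(swap, a1$chrom, a2$chrom)
  pA <- ifelse(swap, a2$pos, a1$pos); pB <- ifelse(swap, a1$pos, a2$pos)
  lA <- ifelse(swap, a2$matchLength, a1$matchLength)
  lB <- ifelse(swap, a1$matchLength, a2$matchLength)
  sA <- ifelse(swap, a2$strand, a1$strand); sB <- ifelse(swap, a1$strand, a2$strand)
  out <- data.frame(qname = a1$qname,
                    chromA = eA, startA = pA, endA = pA + lA, strandA = sA,
                    chromB = eB, startB = pB, endB = pB + lB, strandB = sB,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("discordant_pairs", "data.frame")
  out
}

#' Cluster discordant pairs by genomic proximity
#'
#' Single-linkage clustering: two pairs join iff they share the chromosome
#' pair and the strand (orientation) consensus on both sides, and both their
#' A-side and B-side positions are within `maxGap`. This is exactly
#' single-linkage agglomeration under the Chebyshev (max-coordinate) distance,
#' computed with `hclust(method = "single")` cut at `maxGap`.
#'
#' @param pairs a `discordant_pairs` data.frame.
#' @param maxGap join distance in nt (default `insertMean + 3 * insertSd` for
#'   the package's default insert model).
#' @return a `discordant_clusters` data.frame, one row per cluster, sorted by
#'   support (descending) then A-side footprint: `chromA`, `startA`, `endA`,
#'   `strandA`, likewise for B, `support`, and a list-column `members` of row
#'   indices into `pairs`.
#' @export
cluster_discordant <- function(pairs, maxGap = 350 + 3 * 35) {
  if (maxGap <= 0) stop("maxGap must be positive")
  if (nrow(pairs) == 0) {
    out <- data.frame(chromA = character(), startA = integer(), endA = integer(),
                      strandA = character(), chromB = character(),
                      startB = integer(), endB = integer(), strandB = character(),
                      support = integer(), stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("discordant_clusters", "data.frame")
    return(out)
  }
  key <- paste(pairs$chromA, pairs$chromB, pairs$strandA, pairs$strandB)
  rows <- split(seq_len(nrow(pairs)), key)
  clusters <- list()
  for (idx in rows) {
    sub <- pairs[idx, ]
    if (length(idx) == 1) {
      grp <- 1L
    } else {
      dA <- dist(sub$startA); dB <- dist(sub$startB)
      d <- pmax(dA, dB)  # Chebyshev over the two footprint coordinates
      grp <- cutree(hclust(d, method = "single"), h = maxGap)
    }
    for (g in unique(grp)) {
      m <- idx[grp == g]
      sm <- pairs[m, ]
      clusters[[length(clusters) + 1L]] <- data.frame(
        chromA = sm$chromA[1], startA = min(sm$startA), endA = max(sm$endA),
        strandA = sm$strandA[1],
        chromB = sm$chromB[1], startB = min(sm$startB), endB = max(sm$endB),
        strandB = sm$strandB[1],
        support = length(m), stringsAsFactors = FALSE)
      clusters[[length(clusters)]]$members <- list(m)
    }
  }
  out <- do.call(rbind, clusters)
  out <- out[order(-out$support, out$chromA, out$startA), ]
  rownames(out) <- NULL
  class(out) <- c("discordant_clusters", "data.frame")
  out
}

#' Convert clusters into candidate breakpoint interval pairs
#'
#' Clusters with support below `minSupport` are dropped (read pairs must map
#' "repeatedly" to the same region pair to count). For each retained cluster
#' the breakpoint is predicted to lie in the unsequenced inner gap of the
#' straddling fragments: on a forward-consensus side the interval starts at
#' the rightmost read end and extends `insertMean - 2*readLen + 4*insertSd`
#' to the right; on a reverse-consensus side it ends at the leftmost read
#' start and extends the same amount to the left. A small `boundaryPad`
#' widens the interval on the read-facing edge because the mapper tolerates
#' reads overrunning the junction by a few (mismatch-budget) bases.
#'
#' @param clusters a `discordant_clusters` data.frame.
#' @param minSupport minimum pair support (default 3).
#' @param insertMean,insertSd,readLen insert-size model of the library.
#' @param boundaryPad extra nt on the read-facing interval edge (default 12).
#' @return an `sv_candidates` data.frame in BEDPE column order (`chromA`,
#'   `startA`, `endA`, `chromB`, `startB`, `endB`, `name`, `support`,
#'   `strandA`, `strandB`), 0-based half-open.
#' @export
call_candidates <- function(clusters, minSupport = 3L, insertMean, insertSd,
                            readLen, boundaryPad = 12L) {
  if (missing(insertMean) || missing(insertSd) || missing(readLen))
    stop("insert statistics (insertMean, insertSd, readLen) are required")
  m <- insertMean - 2 * readLen + 4 * insertSd
  if (m <= 0) stop("insert model leaves no inner gap: insertMean too small")
  keep <- clusters[clusters$support >= minSupport, , drop = FALSE]
  side <- function(strand, start, end) {
    lo <- ifelse(strand == "+", end - boundaryPad, start - m)
    hi <- ifelse(strand == "+", end + m, start + boundaryPad)
    data.frame(lo = as.integer(pmax(lo, 0)), hi = as.integer(hi))
  }
  sa <- side(keep$strandA, keep$startA, keep$endA)
  sb <- side(keep$strandB, keep$startB, keep$endB)
  out <- data.frame(chromA = keep$chromA, startA = sa$lo, endA = sa$hi,
                    chromB = keep$chromB, startB = sb$lo, endB = sb$hi,
                    name = sprintf("cand%02d", seq_len(nrow(keep))),
                    support = keep$support,
                    strandA = keep$strandA, strandB = keep$strandB,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sv_candidates", "data.frame")
  out
}

#' @export
print.sv_candidates <- function(x, ...) {
  cat(sprintf("%d candidate junction(s):\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: %s:%d-%d (%s) <-> %s:%d-%d (%s), support %d\n",
                x$name[i], x$chromA[i], x$startA[i] + 1L, x$endA[i], x$strandA[i],
                x$chromB[i], x$startB[i] + 1L, x$endB[i], x$strandB[i],
                x$support[i]))
  }
  invisible(x)
}

#' Write candidates as BEDPE
#'
#' @param cands an `sv_candidates` data.frame.
#' @param path output file.
#' @export
write_bedpe <- function(cands, path) {
  write.table(as.data.frame(cands)[, c("chromA", "startA", "endA", "chromB",
                                       "startB", "endB", "name", "support",
                                       "strandA", "strandB")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
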