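#' Collect junction-spanning reads near a candidate
#'
#' Junction-spanning reads fail to map to the wild-type reference; their
#' mates map uniquely next to the breakpoint with the cluster's strand
#' consensus. This selects exactly those unmapped mates and orients each one
#' to derivative-forward (the strand on which the candidate's `+` side is the
#' derivative prefix): a read whose anchor mate mapped `+` was sequenced from
#' the fragment end and is reverse-complemented.
#'
#' @param cand one row of an `sv_candidates` data.frame.
#' @param aln the `alignment_set` the candidate came from.
#' @param reads the mapped `read_set`.
#' @param margin how far (nt) around the candidate interval anchor mates may
#'   map (default `2 * insertMean` under the default library model).
#' @return character vector of derivative-forward read sequences.
#' @export
collect_junction_reads <- function(cand, aln, reads, margin = 700L) {
  a1 <- aln[aln$mate == 1L, ]
  a2 <- aln[aln$mate == 2L, ]
  grab <- function(anchor, other, otherSeq) {
    onA <- anchor$mapped & anchor$unique & anchor$chrom == cand$chromA &
      anchor$strand == cand$strandA &
      anchor$pos >= cand$startA - margin & anchor$pos < cand$endA + margin
    onB <- anchor$mapped & anchor$unique & anchor$chrom == cand$chromB &
      anchor$strand == cand$strandB &
      anchor$pos >= cand$startB - margin & anchor$pos < cand$endB + margin
    sel <- which((onA | onB) & !other$mapped)
    if (length(sel) == 0) return(character())
    sq <- otherSeq[match(anchor$qname[sel], reads$names)]
    plus <- anchor$strand[sel] == "+"
    sq[plus] <- revcomp_chr(sq[plus])
    sq
  }
  c(grab(a1, a2, reads$mate2), grab(a2, a1, reads$mate1))
}

#' Assemble a junction consensus from spanning reads
#'
#' Greedy maximal-exact-overlap merging (longest overlap first, ties by input
#' order; duplicate and contained reads absorbed) of junction-spanning reads
#' into a single consensus contig. Fails cleanly when fewer than two reads
#' are available or when no overlap of at least `overlapMin` links the reads
#' into one contig.
#'
#' @param jreads character vector of derivative-forward read sequences.
#' @param overlapMin minimum exact overlap (default 20 nt).
#' @return a `junction_consensus`: list with `sequence` and
#'   `supportingReads`.
#' @export
assemble_junction <- function(jreads, overlapMin = 20L) {
  if (length(jreads) < 2L)
    stop("no junction-spanning reads: need at least 2 reads to assemble")
  res <- cpp_assemble_greedy(jreads, as.integer(overlapMin))
  if (length(res$contigs) != 1L)
    stop("no junction-spanning reads: overlaps of >= ", overlapMin,
         " nt do not link the two sides (", length(res$contigs),
         " contigs remain)")
  structure(list(sequence = res$contigs[[1]],
                 supportingReads = res$counts[[1]]),
            class = "junction_consensus")
}

#' @export
print.junction_consensus <- function(x, ...) {
  cat(sprintf("junction consensus: %d nt from %d reads\n",
              nchar(x$sequence), x$supportingReads))
  invisible(x)
}

#' Characterize a junction consensus against the wild-type references
#'
#' Anchors the consensus with its maximal exact prefix match to the
#' candidate's forward-consensus ("left") chromosome and its maximal exact
#' suffix match to the reverse-consensus ("right") chromosome, searching only
#' around the candidate intervals. If prefix and suffix overlap, the shared
#' bases are microhomology (attributed to the left side -- the single
#' canonical representation); if they leave a gap, the intervening bases are
#' an insertion, classified as a templated duplication when they copy the
#' `<= 3` nt immediately flanking the junction. The resulting signature
#' (`blunt`, `microhomology`, `templated-duplication`,
#' `untemplated-insertion`) is the classic NHEJ repair footprint readout.
#'
#' @param consensus a `junction_consensus` (or a plain DNA string).
#' @param ref the wild-type reference set.
#' @param cand the candidate row the consensus was assembled from.
#' @param floor minimum anchoring match length (default 30 nt); below this
#'   the consensus does not represent the junction.
#' @param searchMargin how far (nt) beyond the candidate intervals to search
#'   for anchors (default 700, i.e. twice the default mean insert).
#' @return a `junction_call`: list with `derivativeId`, `leftChrom`,
#'   `leftPos`, `rightChrom`, `rightPos` (1-based, last/first reference base
#'   used), `mhLen`, `mhSeq`, `insSeq`, `insTemplated`, `signature`,
#'   `supportingReads`.
#' @export
characterize_junction <- function(consensus, ref, cand, floor = 30L,
                                  searchMargin = 700L) {
  supporting <- NA_integer_
  if (inherits(consensus, "junction_consensus")) {
    supporting <- consensus$supportingReads
    consensus <- consensus$sequence
  }
  L <- nchar(consensus)
  if (cand$strandA == "+" && cand$strandB == "-") {
    leftChrom <- cand$chromA; rightChrom <- cand$chromB
    leftReg <- c(cand$startA, cand$endA); rightReg <- c(cand$startB, cand$endB)
  } else if (cand$strandA == "-" && cand$strandB == "+") {
    leftChrom <- cand$chromB; rightChrom <- cand$chromA
    leftReg <- c(cand$startB, cand$endB); rightReg <- c(cand$startA, cand$endA)
  } else {
    stop("unsupported orientation consensus (inversion-type junctions are out of scope)")
  }
  refL <- as.character(ref[[leftChrom]]); refR <- as.character(ref[[rightChrom]])

  # the consensus extends up to its own length beyond the breakpoint interval
  ap <- cpp_anchor_prefix(consensus, refL,
                          as.integer(leftReg[1] - searchMargin - L),
                          as.integer(leftReg[2] + searchMargin))
  as_ <- cpp_anchor_suffix(consensus, refR,
                           as.integer(rightReg[1] - searchMargin),
                           as.integer(rightReg[2] + searchMargin + L))
  p <- ap[2]; s <- as_[2]
  if (is.na(ap[1]) || p < floor)
    stop("consensus prefix does not anchor to ", leftChrom,
         " near the candidate (match ", p, " < floor ", floor, ")")
  if (is.na(as_[1]) || s < floor)
    stop("consensus suffix does not anchor to ", rightChrom,
         " near the candidate (match ", s, " < floor ", floor, ")")

  j <- junction_arithmetic(p, s, L, ap[1], as_[1] - s, consensus)
  templ <- is_templated_insertion(j$insSeq, refL, j$leftPos, refR, j$rightPos)
  structure(list(
    derivativeId = derivative_name(leftChrom, rightChrom),
    leftChrom = leftChrom, leftPos = j$leftPos,
    rightChrom = rightChrom, rightPos = j$rightPos,
    mhLen = j$mhLen, mhSeq = j$mhSeq,
    insSeq = j$insSeq, insTemplated = templ,
    signature = junction_signature(j$mhLen, j$insSeq, templ),
    supportingReads = supporting
  ), class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("%s: %s:%d | %s:%d  [%s]\n", x$derivativeId,
              x$leftChrom, x$leftPos, x$rightChrom, x$rightPos, x$signature))
  if (x$mhLen > 0) cat(sprintf("  microhomology: %s (%d nt)\n", x$mhSeq, x$mhLen))
  if (nchar(x$insSeq) > 0)
    cat(sprintf("  insertion: %s (%stemplated)\n", x$insSeq,
                if (x$insTemplated) "" else "un"))
  invisible(x)
}

#' Summarize the two junctions of a reciprocal event
#'
#' Combines the der(A;B) and der(B;A) junction calls into per-chromosome
#' deletion totals and the total inserted/duplicated length, and verifies the
#' base-accounting identity
#' `len(der1) + len(der2) = lenA + lenB - delA - delB + dupTotal`
#' against the reference lengths.
#'
#' @param callAB,callBA the two `junction_call`s of one event (in either
#'   order; they are matched by chromosome roles).
#' @param ref the wild-type reference set.
#' @return a `reciprocal_summary`: list with `chromA`, `chromB`, `delA`,
#'   `delB`, `dupTotal`.
#' @export
summarize_reciprocal <- function(callAB, callBA, ref) {
  if (!(callAB$leftChrom == callBA$rightChrom &&
        callAB$rightChrom == callBA$leftChrom))
    stop("junction calls do not reference the same chromosome pair")
  chromA <- callAB$leftChrom; chromB <- callAB$rightChrom
  delA <- callBA$rightPos - callAB$leftPos - 1L
  delB <- callAB$rightPos - callBA$leftPos - 1L
  dupTotal <- nchar(callAB$insSeq) + nchar(callBA$insSeq)
  lenA <- nchar(as.character(ref[[chromA]]))
  lenB <- nchar(as.character(ref[[chromB]]))
  der1 <- callAB$leftPos + nchar(callAB$insSeq) + (lenB - callAB$rightPos + 1L)
  der2 <- callBA$leftPos + nchar(callBA$insSeq) + (lenA - callBA$rightPos + 1L)
  if (der1 + der2 != lenA + lenB - delA - delB + dupTotal)
    stop("internal error: length accounting identity violated")
  structure(list(chromA = chromA, chromB = chromB,
                 delA = as.integer(delA), delB = as.integer(delB),
                 dupTotal = as.integer(dupTotal)),
            class = "reciprocal_summary")
}

#' @export
print.reciprocal_summary <- function(x, ...) {
  cat(sprintf("reciprocal event %s;%s: del %d bp (%s), %d bp (%s), +%d bp inserted\n",
              x$chromA, x$chromB, x$delA, x$chromA, x$delB, x$chromB, x$dupTotal))
  invisible(x)
}

#' Write junction calls as a VCF with breakend (BND) records
#'
#' Emits VCF 4.2 with one breakend pair per junction call, bracket-notation
#' ALT alleles, cross-referencing MATEID and a shared EVENT key; HOMLEN and
#' HOMSEQ are set for microhomology junctions, and inserted bases appear in
#' the ALT strings.
#'
#' @param calls a list of `junction_call`s.
#' @param ref the wild-type reference set (for REF bases and contig headers).
#' @param path output VCF path.
#' @param eventId EVENT identifier shared by all records (default "TRA1").
#' @export
write_bnd_vcf <- function(calls, ref, path, eventId = "TRA1") {
  if (inherits(calls, "junction_call")) calls <- list(calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=translocatr",
           sprintf("##contig=<ID=%s,length=%d>", names(ref), Biostrings::width(ref)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
           "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"ID of associated event\">",
           "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Length of breakpoint microhomology\">",
           "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Sequence of breakpoint microhomology\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character()
  for (i in seq_along(calls)) {
    cl <- calls[[i]]
    refL <- as.character(ref[[cl$leftChrom]])
    refR <- as.character(ref[[cl$rightChrom]])
    baseL <- substr(refL, cl$leftPos, cl$leftPos)
    baseR <- substr(refR, cl$rightPos, cl$rightPos)
    id1 <- sprintf("bnd_%d_1", i); id2 <- sprintf("bnd_%d_2", i)
    hom <- if (cl$mhLen > 0)
      sprintf(";HOMLEN=%d;HOMSEQ=%s", cl$mhLen, cl$mhSeq) else ""
    alt1 <- sprintf("%s%s[%s:%d[", baseL, cl$insSeq, cl$rightChrom, cl$rightPos)
    alt2 <- sprintf("]%s:%d]%s%s", cl$leftChrom, cl$leftPos, cl$insSeq, baseR)
    info1 <- sprintf("SVTYPE=BND;MATEID=%s;EVENT=%s%s", id2, eventId, hom)
    info2 <- sprintf("SVTYPE=BND;MATEID=%s;EVENT=%s%s", id1, eventId, hom)
    rows <- c(rows,
              sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                      cl$leftChrom, cl$leftPos, id1, baseL, alt1, info1),
              sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                      cl$rightChrom, cl$rightPos, id2, baseR, alt2, info2))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write junction calls as JSON
#'
#' @param calls a list of `junction_call`s.
#' @param path output file.
#' @export
write_junction_json <- function(calls, path) {
  if (inherits(calls, "junction_call")) calls <- list(calls)
  jsonlite::write_json(lapply(calls, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
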