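#' Describe a reciprocal translocation event
#'
#' A reciprocal translocation between `chrA` and `chrB` producing two
#' derivative chromosomes:
#' \itemize{
#'   \item der(A;B) = `chrA[0:a1] + ins1 + chrB[b1:]`
#'   \item der(B;A) = `chrB[0:b2] + ins2 + chrA[a2:]`
#' }
#' All offsets are 0-based inter-base positions; `a1 <= a2` and `b2 <= b1`, so
#' `a2 - a1` bases of chrA and `b1 - b2` bases of chrB are lost from the
#' genome, and `ins1`/`ins2` are novel (typically short, templated) bases
#' gained at the two fusion junctions -- the classic small-deletion /
#' small-duplication footprint of non-homologous end joining.
#'
#' @param chrA,chrB chromosome names (must differ).
#' @param a1,a2 0-based offsets on `chrA`, `a1 <= a2`.
#' @param b1,b2 0-based offsets on `chrB`, `b2 <= b1`.
#' @param ins1,ins2 DNA strings (possibly empty) inserted at the der(A;B) and
#'   der(B;A) junctions.
#' @return an object of class `translocation_event`.
#' @export
translocation_event <- function(chrA, chrB, a1, a2, b1, b2, ins1 = "", ins2 = "") {
  if (identical(chrA, chrB)) stop("chrA and chrB must differ")
  a1 <- as.integer(a1); a2 <- as.integer(a2)
  b1 <- as.integer(b1); b2 <- as.integer(b2)
  if (a1 > a2) stop("offsets out of order: need a1 <= a2")
  if (b2 > b1) stop("offsets out of order: need b2 <= b1")
  if (min(a1, b2) < 0) stop("offsets must be non-negative")
  for (s in c(ins1, ins2)) {
    if (nchar(s) > 0 && grepl("[^ACGT]", s)) stop("insertions must be A/C/G/T only")
  }
  structure(list(chrA = chrA, chrB = chrB, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 ins1 = ins1, ins2 = ins2),
            class = "translocation_event")
}

#' @export
print.translocation_event <- function(x, ...) {
  cat(sprintf("reciprocal translocation t(%s;%s)\n", x$chrA, x$chrB))
  cat(sprintf("  der(%s;%s): %s:1-%d + [%s] + %s:%d-end\n",
              x$chrA, x$chrB, x$chrA, x$a1, x$ins1, x$chrB, x$b1 + 1L))
  cat(sprintf("  der(%s;%s): %s:1-%d + [%s] + %s:%d-end\n",
              x$chrB, x$chrA, x$chrB, x$b2, x$ins2, x$chrA, x$a2 + 1L))
  cat(sprintf("  deletions: %d bp (%s), %d bp (%s); insertions: %d + %d bp\n",
              x$a2 - x$a1, x$chrA, x$b1 - x$b2, x$chrB,
              nchar(x$ins1), nchar(x$ins2)))
  invisible(x)
}

derivative_name <- function(left, right) paste0("der_", left, "_", right)

# Canonical representation of one fusion junction. The maximal exact prefix
# match to the left reference and maximal exact suffix match to the right
# reference uniquely resolve the representational ambiguity that
# microhomology (and flank-templated insertion) creates: overlap of the two
# matches is the microhomology, attributed to the left (A) side; a gap between
# them is the inserted sequence.
junction_arithmetic <- function(p, s, L, leftAnchor0, rightSuffixStart0, consensus) {
  if (p + s >= L) {
    mh <- p + s - L
    ins <- ""
  } else {
    mh <- 0L
    ins <- substr(consensus, p + 1L, L - s)
  }
  list(
    leftPos = leftAnchor0 + p,                    # 1-based last base used from left ref
    rightPos = rightSuffixStart0 + mh + 1L,       # 1-based first base used from right ref
    mhLen = as.integer(mh),
    mhSeq = if (mh > 0) substr(consensus, p - mh + 1L, p) else "",
    insSeq = ins,
    p = as.integer(p), s = as.integer(s)
  )
}

# Does insSeq look copied from a <=3 nt flank immediately adjacent to the
# junction (last used bases of the left ref, or first used bases of the right
# ref)? Longer perfect flank copies trigger a warning but are not "templated"
# for signature purposes.
is_templated_insertion <- function(insSeq, refLeft, leftPos, refRight, rightPos) {
  d <- nchar(insSeq)
  if (d == 0) return(FALSE)
  leftFlank <- substr(refLeft, leftPos - d + 1L, leftPos)
  rightFlank <- substr(refRight, rightPos, rightPos + d - 1L)
  hit <- (insSeq == leftFlank) || (insSeq == rightFlank)
  if (d > 3L) {
    if (hit) warning("insertion longer than 3 nt matches a junction flank; ",
                     "classified as untemplated-insertion")
    return(FALSE)
  }
  hit
}

junction_signature <- function(mhLen, insSeq, insTemplated) {
  if (mhLen > 0) "microhomology"
  else if (nchar(insSeq) == 0) "blunt"
  else if (insTemplated) "templated-duplication"
  else "untemplated-insertion"
}

#' Apply a reciprocal translocation to a reference set
#'
#' Builds the two derivative chromosomes defined by `event` and returns them
#' together with a ground-truth record holding the canonical (left-aligned)
#' junction coordinates and microhomology lengths. Canonicalization follows
#' the maximal prefix/suffix matching convention used by
#' [characterize_junction()], so downstream recovery can be compared by
#' strict equality.
#'
#' @param ref a [Biostrings::DNAStringSet] containing `event$chrA` and
#'   `event$chrB`.
#' @param event a [translocation_event()].
#' @param seed optional integer recorded in the truth record.
#' @param captureWindows optional data.frame (`chrom`, `start`, `end`;
#'   0-based half-open) recorded in the truth record.
#' @return a list with `derivatives` (a 2-entry `DNAStringSet`) and `truth`
#'   (class `truth_record`).
#' @export
apply_translocation <- function(ref, event, seed = NA_integer_, captureWindows = NULL) {
  validate_reference(ref)
  if (!all(c(event$chrA, event$chrB) %in% names(ref)))
    stop("event chromosomes not present in reference set")
  A <- as.character(ref[[event$chrA]])
  B <- as.character(ref[[event$chrB]])
  lenA <- nchar(A); lenB <- nchar(B)
  if (event$a2 > lenA || event$b1 > lenB)
    stop("event offsets out of chromosome range")

  der1 <- paste0(substr(A, 1L, event$a1), event$ins1, substr(B, event$b1 + 1L, lenB))
  der2 <- paste0(substr(B, 1L, event$b2), event$ins2, substr(A, event$a2 + 1L, lenA))

  # canonical truth, junction 1 (A-prefix | B-suffix)
  p1 <- cpp_lcp(der1, A); s1 <- cpp_lcs(der1, B)
  j1 <- junction_arithmetic(p1, s1, nchar(der1), 0L, lenB - s1, der1)
  # canonical truth, junction 2 (B-prefix | A-suffix)
  p2 <- cpp_lcp(der2, B); s2 <- cpp_lcs(der2, A)
  j2 <- junction_arithmetic(p2, s2, nchar(der2), 0L, lenA - s2, der2)

  ders <- Biostrings::DNAStringSet(c(der1, der2))
  names(ders) <- c(derivative_name(event$chrA, event$chrB),
                   derivative_name(event$chrB, event$chrA))

  truth <- structure(list(
    chrA = event$chrA, chrB = event$chrB,
    a1 = j1$leftPos,          # 0-based canonical offsets (leftPos is a count of used bases)
    a2 = j2$rightPos - 1L,
    b1 = j1$rightPos - 1L,
    b2 = j2$leftPos,
    ins1 = j1$insSeq, ins2 = j2$insSeq,
    mhLen1 = j1$mhLen, mhLen2 = j2$mhLen,
    seed = as.integer(seed),
    captureWindows = captureWindows
  ), class = "truth_record")

  list(derivatives = ders, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth record t(%s;%s)\n", x$chrA, x$chrB))
  cat(sprintf("  junction 1: %s:%d | %s:%d  mh=%d ins='%s'\n",
              x$chrA, x$a1, x$chrB, x$b1 + 1L, x$mhLen1, x$ins1))
  cat(sprintf("  junction 2: %s:%d | %s:%d  mh=%d ins='%s'\n",
              x$chrB, x$b2, x$chrA, x$a2 + 1L, x$mhLen2, x$ins2))
  cat(sprintf("  delA=%d delB=%d\n", x$a2 - x$a1, x$b1 - x$b2))
  invisible(x)
}

#' Serialize a truth record to JSON
#'
#' @param truth a `truth_record`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$captureWindows)) x$captureWindows <- as.data.frame(x$captureWindows)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a truth record from JSON
#'
#' @param path JSON file written by [write_truth_json()].
#' @return a `truth_record`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("a1", "a2", "b1", "b2", "mhLen1", "mhLen2", "seed"))
    x[[f]] <- as.integer(x[[f]])
  if (!is.null(x$captureWindows)) {
    x$captureWindows <- as.data.frame(x$captureWindows)
    x$captureWindows$start <- as.integer(x$captureWindows$start)
    x$captureWindows$end <- as.integer(x$captureWindows$end)
  }
  structure(x[c("chrA", "chrB", "a1", "a2", "b1", "b2", "ins1", "ins2",
                "mhLen1", "mhLen2", "seed", "captureWindows")],
            class = "truth_record")
}

#' Simulate a reciprocal translocation with configurable junction edits
#'
#' Draws random breakpoint positions on two chromosomes and engineers the
#' requested junction features into the reference before fusing it: per-side
#' deletion sizes, per-junction microhomology (written into the resected,
#' i.e. deleted, segment flanking the junction -- microhomology-mediated
#' joins consume at least their homology), and short templated duplications
#' copied from a randomly chosen junction flank. Positions are resampled
#' until the canonical (maximal prefix/suffix) representation of both
#' junctions coincides with the requested configuration, so the returned
#' truth record equals the configuration exactly.
#'
#' @param ref a reference set containing `chrA` and `chrB`.
#' @param chrA,chrB chromosome names.
#' @param delA,delB deletion sizes (nt) on each chromosome.
#' @param mh1,mh2 microhomology lengths at junction 1 / junction 2
#'   (`mh1 <= delB`, `mh2 <= delA`; a junction with microhomology cannot also
#'   carry an insertion).
#' @param dup1,dup2 templated duplication lengths (nt, 0-3) at each junction.
#' @param seed integer seed (required).
#' @param margin minimum distance of breakpoints from chromosome ends.
#' @param maxTries resampling attempts before giving up.
#' @return a list with `ref` (possibly base-edited reference), `event`,
#'   `derivatives` and `truth`.
#' @export
simulate_event <- function(ref, chrA, chrB, delA = 0L, delB = 0L,
                           mh1 = 0L, mh2 = 0L, dup1 = 0L, dup2 = 0L,
                           seed, margin = 2e5, maxTries = 100L) {
  if (missing(seed)) stop("a seed is required")
  if (mh1 > 0 && dup1 > 0) stop("junction 1: microhomology and duplication are exclusive")
  if (mh2 > 0 && dup2 > 0) stop("junction 2: microhomology and duplication are exclusive")
  if (mh1 > delB) stop("mh1 must not exceed delB (homology lies in the resected chrB flank)")
  if (mh2 > delA) stop("mh2 must not exceed delA (homology lies in the resected chrA flank)")
  A0 <- as.character(ref[[chrA]]); B0 <- as.character(ref[[chrB]])
  lenA <- nchar(A0); lenB <- nchar(B0)
  margin <- as.integer(min(margin, floor(min(lenA, lenB) / 3)))

  withr::with_seed(as.integer(seed), {
    for (try in seq_len(maxTries)) {
      A <- A0; B <- B0
      a1 <- sample(seq(margin, lenA - margin), 1L)
      b1 <- sample(seq(margin, lenB - margin), 1L)
      a2 <- a1 + as.integer(delA)
      b2 <- b1 - as.integer(delB)

      if (mh1 > 0) substr(B, b1 - mh1 + 1L, b1) <- substr(A, a1 - mh1 + 1L, a1)
      if (mh2 > 0) substr(A, a2 - mh2 + 1L, a2) <- substr(B, b2 - mh2 + 1L, b2)
      ins1 <- ""
      if (dup1 > 0) {
        ins1 <- if (sample(c(TRUE, FALSE), 1L)) substr(A, a1 - dup1 + 1L, a1)
                else substr(B, b1 + 1L, b1 + dup1)
      }
      ins2 <- ""
      if (dup2 > 0) {
        ins2 <- if (sample(c(TRUE, FALSE), 1L)) substr(B, b2 - dup2 + 1L, b2)
                else substr(A, a2 + 1L, a2 + dup2)
      }

      refi <- Biostrings::DNAStringSet(stats::setNames(
        replace(as.character(ref), match(c(chrA, chrB), names(ref)), c(A, B)),
        names(ref)))
      ev <- translocation_event(chrA, chrB, a1, a2, b1, b2, ins1, ins2)
      res <- apply_translocation(refi, ev, seed = seed)
      tr <- res$truth
      ok <- tr$a1 == a1 && tr$a2 == a2 && tr$b1 == b1 && tr$b2 == b2 &&
        tr$mhLen1 == mh1 && tr$mhLen2 == mh2 &&
        identical(tr$ins1, ins1) && identical(tr$ins2, ins2)
      if (ok) {
        return(list(ref = refi, event = ev,
                    derivatives = res$derivatives, truth = tr))
      }
    }
    stop("could not place an event with the requested canonical form; ",
         "try a different seed or configuration")
  })
}
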