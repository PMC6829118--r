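# Small deterministic fixtures shared across test files. Everything is
# generated in code; no data files.

small_ref <- function(lenA = 10000L, lenB = 10000L, seedA = 11L, seedB = 12L,
                      names = c("chr5", "chr8")) {
  make_reference(data.frame(name = names, length = c(lenA, lenB),
                            seed = c(seedA, seedB)))
}

# A hand-built reference from explicit strings (for exact-arithmetic cases).
manual_ref <- function(...) {
  x <- c(...)
  ref <- Biostrings::DNAStringSet(x)
  names(ref) <- names(x)
  ref
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Exhaustive-position oracle for probe-panel localization: test every
# inter-base position on the chromosome against every classification.
localize_oracle <- function(probes, labels, chromLen) {
  bp <- 0:chromLen
  ok <- rep(TRUE, length(bp))
  for (i in seq_len(nrow(probes))) {
    lab <- ifelse(probes$end[i] <= bp, "proximal",
                  ifelse(probes$start[i] >= bp, "distal", "split"))
    ok <- ok & lab == labels[i]
  }
  bp[ok]
}

# Brute-force anchoring oracle for junction characterization: longest
# consensus prefix occurring anywhere in refA (fixed-string search), longest
# suffix occurring in refB, then the same overlap arithmetic recomputed
# independently.
characterize_oracle <- function(cons, refA, refB, floor = 30L) {
  L <- nchar(cons)
  p <- 0L; pPos <- NA_integer_
  for (l in seq(L, floor)) {
    hit <- regexpr(substr(cons, 1L, l), refA, fixed = TRUE)
    if (hit > 0) { p <- l; pPos <- as.integer(hit) - 1L; break }
  }
  s <- 0L; q <- NA_integer_
  for (l in seq(L, floor)) {
    hit <- regexpr(substr(cons, L - l + 1L, L), refB, fixed = TRUE)
    if (hit > 0) { s <- l; q <- as.integer(hit) - 1L + l; break }
  }
  if (p < floor || s < floor) return(NULL)
  if (p + s >= L) {
    mh <- p + s - L; ins <- ""
  } else {
    mh <- 0L; ins <- substr(cons, p + 1L, L - s)
  }
  list(p = p, s = s, mhLen = as.integer(mh), insSeq = ins,
       leftPos = pPos + p, rightPos = (q - s) + mh + 1L)
}
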