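#' Classify a probe relative to a breakpoint
#'
#' A metaphase-FISH probe (e.g. a BAC clone) hybridizing to `[start, end)` on
#' the breakpoint chromosome is `split` by an inter-base breakpoint strictly
#' inside its interval, `proximal` when it lies entirely at or before the
#' breakpoint, and `distal` when entirely at or after it. A breakpoint
#' exactly at a probe boundary does not split the probe (FISH cannot resolve
#' boundary touching; interiors are open).
#'
#' @param start,end 0-based half-open probe coordinates (vectorized).
#' @param bp 0-based inter-base breakpoint position.
#' @return character vector over `{"proximal", "distal", "split"}`.
#' @export
classify_probe <- function(start, end, bp) {
  if (any(start >= end)) stop("probe intervals must satisfy start < end")
  ifelse(end <= bp, "proximal", ifelse(start >= bp, "distal", "split"))
}

#' Invert probe classifications into a breakpoint interval
#'
#' Returns the exact set of breakpoint positions consistent with every
#' classification: the intersection of all split-probe interiors, further
#' clipped to `[max proximal end, min distal start]`. The result is
#' guaranteed to contain any true breakpoint that generated the panel;
#' an empty consistent set signals a mis-scored panel and is an error.
#'
#' Also reported is the plain overlap of the split probes
#' (`[max split start, min split end)`), the interval a cytogeneticist would
#' quote as the "BAC overlap region".
#'
#' @param probes data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open), all on one chromosome.
#' @param labels character vector (parallel to `probes`, or named by probe
#'   name) over `{"proximal", "distal", "split"}`.
#' @return a `probe_interval`: list with `chrom`, `interval` (0-based
#'   half-open vector of length 2), `nPositions`, and `splitOverlap`.
#' @export
localize_breakpoint <- function(probes, labels) {
  probes <- as.data.frame(probes)
  if (length(unique(probes$chrom)) != 1L)
    stop("all probes in a panel must lie on one chromosome")
  if (!is.null(names(labels))) labels <- labels[probes$name]
  if (length(labels) != nrow(probes) || anyNA(labels))
    stop("every probe needs a classification")
  if (!all(labels %in% c("proximal", "distal", "split")))
    stop("labels must be proximal, distal or split")
  if (!any(labels == "split")) stop("at least one split probe is required")

  sp <- probes[labels == "split", ]
  lo <- max(sp$start) + 1L                 # open interiors
  hi <- min(sp$end) - 1L                   # last consistent position
  if (any(labels == "proximal")) lo <- max(lo, max(probes$end[labels == "proximal"]))
  if (any(labels == "distal")) hi <- min(hi, min(probes$start[labels == "distal"]))
  n <- hi - lo + 1L
  if (n <= 0L)
    stop("contradictory panel: no breakpoint position is consistent with all classifications")
  structure(list(chrom = probes$chrom[1],
                 interval = c(lo, hi + 1L),
                 nPositions = as.integer(n),
                 splitOverlap = c(max(sp$start), min(sp$end))),
            class = "probe_interval")
}

#' @export
print.probe_interval <- function(x, ...) {
  cat(sprintf("breakpoint localized to %s:%d-%d (%d consistent positions)\n",
              x$chrom, x$interval[1] + 1L, x$interval[2], x$nPositions))
  cat(sprintf("  split-probe overlap: %s:%d-%d (%.1f kb)\n",
              x$chrom, x$splitOverlap[1] + 1L, x$splitOverlap[2],
              (x$splitOverlap[2] - x$splitOverlap[1]) / 1000))
  invisible(x)
}

#' Simulate a probe panel around a hidden breakpoint
#'
#' Draws random probes on a chromosome and classifies them against a hidden
#' breakpoint; at least one probe is guaranteed to span the breakpoint
#' (panels without a split clone cannot localize).
#'
#' @param chromLen chromosome length (nt).
#' @param bp hidden 0-based breakpoint position (`0 < bp < chromLen`).
#' @param nProbes number of probes (default 6).
#' @param probeMin,probeMax probe length range (defaults 2000-8000 nt).
#' @param seed integer seed (required).
#' @param chrom chromosome name.
#' @return list with `probes` (data.frame) and `labels`.
#' @export
simulate_probe_panel <- function(chromLen, bp, nProbes = 6L, probeMin = 2000L,
                                 probeMax = 8000L, seed, chrom = "chrS") {
  if (missing(seed)) stop("a seed is required")
  if (bp <= 0 || bp >= chromLen) stop("breakpoint must be inside the chromosome")
  withr::with_seed(as.integer(seed), {
    len <- sample(probeMin:probeMax, nProbes, replace = TRUE)
    start <- vapply(len, function(l) sample(0:(chromLen - l), 1L), 0L)
    # force one probe to strictly contain the breakpoint
    l1 <- len[1]
    loMin <- max(0L, bp - l1 + 1L)
    loMax <- min(bp - 1L, chromLen - l1)
    if (loMin > loMax) stop("chromosome too short for a spanning probe")
    start[1] <- if (loMin == loMax) loMin else sample(loMin:loMax, 1L)
    probes <- data.frame(name = sprintf("probe%02d", seq_len(nProbes)),
                         chrom = chrom, start = as.integer(start),
                         end = as.integer(start + len),
                         stringsAsFactors = FALSE)
    list(probes = probes,
         labels = classify_probe(probes$start, probes$end, bp))
  })
}

#' Read a probe table from BED
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.frame with `name`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_probe_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = gr$name,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Read probe classifications from a two-column table
#'
#' @param path whitespace-delimited file with columns (name, label).
#' @return named character vector of labels.
#' @export
read_probe_classes <- function(path) {
  x <- read.table(path, header = FALSE, col.names = c("name", "label"),
                  stringsAsFactors = FALSE)
  stats::setNames(x$label, x$name)
}

#' Write a localized interval as BED
#'
#' @param interval a `probe_interval` from [localize_breakpoint()].
#' @param path output BED path.
#' @param name feature name.
#' @export
write_interval_bed <- function(interval, path, name = "breakpoint_interval") {
  gr <- GenomicRanges::GRanges(interval$chrom,
                               IRanges::IRanges(interval$interval[1] + 1L,
                                                interval$interval[2]))
  gr$name <- name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
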