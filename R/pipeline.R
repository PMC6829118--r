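#' Run the full breakpoint-calling pipeline on a read set
#'
#' Chains mapping, discordant-pair extraction, clustering, candidate interval
#' construction, junction consensus assembly and characterization, and --
#' when both junctions of a reciprocal event are recovered -- the
#' per-chromosome deletion/duplication summary.
#'
#' @param reads a `read_set`.
#' @param ref the wild-type reference set.
#' @param k seed length (default 31).
#' @param maxMismatch per-mate mismatch allowance (default 3).
#' @param minSupport minimum discordant-pair support per candidate
#'   (default 3).
#' @param maxGap cluster join distance; default `insertMean + 3 * insertSd`.
#' @param overlapMin minimum assembly overlap (default 20 nt).
#' @param index optionally, a prebuilt `seed_index` over `ref`.
#' @return a `translocation_result`: list with `alignments`, `discordant`,
#'   `clusters`, `candidates`, `consensus` (list), `calls` (list of
#'   `junction_call`), `failures` (character), and `summary` (a
#'   `reciprocal_summary` or `NULL`).
#' @export
call_translocation <- function(reads, ref, k = 31L, maxMismatch = 3L,
                               minSupport = 3L, maxGap = NULL,
                               overlapMin = 20L, index = NULL) {
  cfg <- reads$cfg
  insertMean <- if (!is.null(cfg)) cfg$insertMean else 350
  insertSd <- if (!is.null(cfg)) cfg$insertSd else 35
  readLen <- if (!is.null(cfg)) cfg$readLen else nchar(reads$mate1[1])
  maxGap <- maxGap %||% (insertMean + 3 * insertSd)

  if (is.null(index)) index <- build_index(ref, k)
  aln <- map_pairs(reads, index, maxMismatch = maxMismatch,
                   insertMean = insertMean, insertSd = insertSd)
  disc <- find_discordant(aln)
  clusters <- cluster_discordant(disc, maxGap = maxGap)
  cands <- call_candidates(clusters, minSupport = minSupport,
                           insertMean = insertMean, insertSd = insertSd,
                           readLen = readLen,
                           boundaryPad = 4L * maxMismatch)

  consensus <- list(); calls <- list(); failures <- character()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    res <- tryCatch({
      jr <- collect_junction_reads(cand, aln, reads,
                                   margin = as.integer(2 * insertMean))
      cons <- assemble_junction(jr, overlapMin = overlapMin)
      call <- characterize_junction(cons, ref, cand,
                                    searchMargin = as.integer(2 * insertMean))
      list(cons = cons, call = call)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cand$name, conditionMessage(res)))
    } else {
      consensus[[cand$name]] <- res$cons
      calls[[cand$name]] <- res$call
    }
  }

  summary <- NULL
  if (length(calls) == 2) {
    ids <- vapply(calls, `[[`, "", "derivativeId")
    chroms1 <- c(calls[[1]]$leftChrom, calls[[1]]$rightChrom)
    chroms2 <- c(calls[[2]]$rightChrom, calls[[2]]$leftChrom)
    if (!identical(ids[1], ids[2]) && identical(chroms1, chroms2)) {
      summary <- summarize_reciprocal(calls[[1]], calls[[2]], ref)
    }
  }
  structure(list(alignments = aln, discordant = disc, clusters = clusters,
                 candidates = cands, consensus = consensus, calls = calls,
                 failures = failures, summary = summary),
            class = "translocation_result")
}

#' @export
print.translocation_result <- function(x, ...) {
  cat(sprintf("translocation result: %d discordant pairs, %d cluster(s), %d candidate(s)\n",
              nrow(x$discordant), nrow(x$clusters), nrow(x$candidates)))
  for (cl in x$calls) print(cl)
  if (!is.null(x$summary)) print(x$summary)
  if (length(x$failures)) cat("failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Simulate one complete translocation study
#'
#' Builds two random chromosomes, engineers a reciprocal translocation with
#' the requested junction edits, and simulates targeted-capture paired-end
#' reads from windows centred on each derivative junction (the homozygous
#' mutant sample). Optionally simulates a matched wild-type sample from the
#' corresponding windows of the intact chromosomes.
#'
#' @param seed integer seed driving every random choice (required).
#' @param chromLen chromosome length (default 1e6 nt).
#' @param windowHalf half-width of each capture window (default 5e4 nt, i.e.
#'   100 kb windows).
#' @param delA,delB,mh1,mh2,dup1,dup2 junction edits, see [simulate_event()].
#' @param depth,readLen,insertMean,insertSd,errorRate read simulation
#'   parameters, see [read_sim_config()].
#' @param wt also simulate the matched wild-type sample (default TRUE).
#' @param chromNames names for the two chromosomes.
#' @return list with `ref`, `derivatives`, `event`, `truth` (capture windows
#'   filled in), `reads` (mutant), and `wtReads` (or `NULL`).
#' @export
simulate_study <- function(seed, chromLen = 1e6, windowHalf = 5e4,
                           delA = 0L, delB = 0L, mh1 = 0L, mh2 = 0L,
                           dup1 = 0L, dup2 = 0L,
                           depth = 30, readLen = 100L, insertMean = 350,
                           insertSd = 35, errorRate = 0, wt = TRUE,
                           chromNames = c("chrA", "chrB")) {
  if (missing(seed)) stop("a seed is required")
  seed <- as.integer(seed)
  ref <- make_reference(data.frame(name = chromNames, length = chromLen,
                                   seed = c(seed, seed + 1L)))
  sim <- simulate_event(ref, chromNames[1], chromNames[2],
                        delA = delA, delB = delB, mh1 = mh1, mh2 = mh2,
                        dup1 = dup1, dup2 = dup2, seed = seed + 2L)

  tr <- sim$truth
  j1 <- tr$a1 + nchar(tr$ins1)              # junction offset in der(A;B)
  j2 <- tr$b2 + nchar(tr$ins2)              # junction offset in der(B;A)
  dn <- names(sim$derivatives)
  win <- data.frame(chrom = dn,
                    start = as.integer(c(j1, j2) - windowHalf),
                    end = as.integer(c(j1, j2) + windowHalf),
                    stringsAsFactors = FALSE)
  tr$captureWindows <- win
  cfg <- read_sim_config(depth = depth, readLen = readLen,
                         insertMean = insertMean, insertSd = insertSd,
                         errorRate = errorRate, seed = seed + 3L)
  reads <- simulate_paired_reads(sim$derivatives, win, cfg)

  wtReads <- NULL
  if (wt) {
    wtWin <- data.frame(chrom = c(tr$chrA, tr$chrB),
                        start = as.integer(c(tr$a1, tr$b1) - windowHalf),
                        end = as.integer(c(tr$a1, tr$b1) + windowHalf),
                        stringsAsFactors = FALSE)
    wtCfg <- read_sim_config(depth = depth, readLen = readLen,
                             insertMean = insertMean, insertSd = insertSd,
                             errorRate = errorRate, seed = seed + 4L)
    wtReads <- simulate_paired_reads(sim$ref, wtWin, wtCfg)
  }
  list(ref = sim$ref, derivatives = sim$derivatives, event = sim$event,
       truth = tr, reads = reads, wtReads = wtReads)
}

#' Compare a pipeline result against a truth record
#'
#' Checks candidate-interval containment of both canonical breakpoints and
#' exact recovery of all junction fields (positions, microhomology,
#' insertions) and of the per-chromosome deletion totals.
#'
#' @param result a `translocation_result`.
#' @param truth the matching `truth_record`.
#' @return list of logicals: `containment`, `exact`, plus `nCandidates` and
#'   per-field detail in `detail`.
#' @export
recovery_report <- function(result, truth) {
  cands <- result$candidates
  der1 <- derivative_name(truth$chrA, truth$chrB)
  der2 <- derivative_name(truth$chrB, truth$chrA)

  contains <- function(cand, chrom, bp) {
    # bp as 0-based inter-base position; candidate intervals 0-based half-open
    (cand$chromA == chrom & cand$startA <= bp & bp <= cand$endA) |
    (cand$chromB == chrom & cand$startB <= bp & bp <= cand$endB)
  }
  cont1 <- any(contains(cands, truth$chrA, truth$a1) &
               contains(cands, truth$chrB, truth$b1))
  cont2 <- any(contains(cands, truth$chrA, truth$a2) &
               contains(cands, truth$chrB, truth$b2))

  c1 <- result$calls[[match(der1, vapply(result$calls, `[[`, "", "derivativeId"))]]
  c2 <- result$calls[[match(der2, vapply(result$calls, `[[`, "", "derivativeId"))]]
  detail <- list()
  exact <- FALSE
  if (!is.null(c1) && !is.null(c2) && !is.null(result$summary)) {
    s <- result$summary
    detail <- list(
      j1_left = c1$leftPos == truth$a1, j1_right = c1$rightPos == truth$b1 + 1L,
      j2_left = c2$leftPos == truth$b2, j2_right = c2$rightPos == truth$a2 + 1L,
      mh1 = c1$mhLen == truth$mhLen1, mh2 = c2$mhLen == truth$mhLen2,
      ins1 = identical(c1$insSeq, truth$ins1),
      ins2 = identical(c2$insSeq, truth$ins2),
      delA = (if (s$chromA == truth$chrA) s$delA else s$delB) == truth$a2 - truth$a1,
      delB = (if (s$chromA == truth$chrA) s$delB else s$delA) == truth$b1 - truth$b2)
    exact <- all(unlist(detail))
  }
  list(containment = cont1 && cont2, exact = exact,
       nCandidates = nrow(cands), detail = detail)
}

#' Run a seeded multi-event recovery study
#'
#' Simulates `n` reciprocal translocations with randomly drawn junction
#' edits (deletions 0-10 nt per side; per junction one of blunt join,
#' microhomology 1-4 nt -- bounded by the resected flank -- or templated
#' duplication 1-3 nt), runs the full pipeline on each mutant sample and on
#' the matched wild-type sample, and tabulates recovery.
#'
#' @param n number of events.
#' @param seed base seed; event i uses `seed + 1000 * i` derived seeds.
#' @param chromLen,windowHalf,depth see [simulate_study()].
#' @param ... further arguments passed to [simulate_study()].
#' @return data.frame with one row per event: seed, the drawn edit sizes,
#'   `containment`, `exact`, `nCandidates`, `wtCandidates`, and the two
#'   retained candidate supports (`support1`, `support2`, NA when missing).
#' @export
run_recovery_study <- function(n = 100L, seed = 1L, chromLen = 1e6,
                               windowHalf = 5e4, depth = 30, ...) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    evSeed <- as.integer(seed + 1000L * i)
    par <- withr::with_seed(evSeed, {
      delA <- sample(0:10, 1L); delB <- sample(0:10, 1L)
      draw <- function(del) {
        type <- sample(c("blunt", "mh", "dup"), 1L)
        if (type == "mh" && del >= 1L) c(mh = sample(seq_len(min(4L, del)), 1L), dup = 0L)
        else if (type == "dup") c(mh = 0L, dup = sample(1:3, 1L))
        else c(mh = 0L, dup = 0L)
      }
      e1 <- draw(delB); e2 <- draw(delA)
      list(delA = delA, delB = delB, mh1 = e1[["mh"]], mh2 = e2[["mh"]],
           dup1 = e1[["dup"]], dup2 = e2[["dup"]])
    })
    study <- simulate_study(seed = evSeed, chromLen = chromLen,
                            windowHalf = windowHalf, depth = depth,
                            delA = par$delA, delB = par$delB,
                            mh1 = par$mh1, mh2 = par$mh2,
                            dup1 = par$dup1, dup2 = par$dup2, ...)
    index <- build_index(study$ref)
    res <- call_translocation(study$reads, study$ref, index = index)
    rep <- recovery_report(res, study$truth)

    wtRes <- call_translocation(study$wtReads, study$ref, index = index)
    sup <- sort(res$candidates$support, decreasing = TRUE)
    rows[[i]] <- data.frame(
      seed = evSeed, delA = par$delA, delB = par$delB,
      mh1 = par$mh1, mh2 = par$mh2, dup1 = par$dup1, dup2 = par$dup2,
      containment = rep$containment, exact = rep$exact,
      nCandidates = rep$nCandidates,
      wtCandidates = nrow(wtRes$candidates),
      support1 = if (length(sup) >= 1) sup[1] else NA_integer_,
      support2 = if (length(sup) >= 2) sup[2] else NA_integer_)
  }
  do.call(rbind, rows)
}
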