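#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' Standard comparative threshold-cycle quantification with amplification
#' efficiency fixed at 2: technical replicates are first averaged per
#' (sample, gene); each sample's delta-Ct is `Ct(gene) - Ct(refGene)`;
#' delta-Ct is averaged per group; and each group's relative expression is
#' `2^-(mean dCt(group) - mean dCt(calibrator))`, so the calibrator group
#' reports exactly 1 by construction. Adding a constant to every Ct of a
#' sample (a plate/efficiency offset) cancels in delta-Ct, so results are
#' scale invariant.
#'
#' @param table data.frame with columns `sample`, `group`, `gene`, `ct`
#'   (cycles, in `(0, 40]`).
#' @param refGene the normalization control gene (must be measured in every
#'   sample).
#' @param calibratorGroup group whose mean sets the baseline (default
#'   `"WT"`).
#' @return data.frame with one row per (gene, group): `gene`, `group`,
#'   `dCtMean`, `relExpr`, plus `foldChange` repeated per gene (relative
#'   expression of the non-calibrator group; `NA` when there are more than
#'   two groups).
#' @export
ddct <- function(table, refGene = "Pgk1", calibratorGroup = "WT") {
  table <- as.data.frame(table)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(table))) stop("table needs columns: ",
                                         paste(need, collapse = ", "))
  if (any(table$ct <= 0 | table$ct > 40))
    stop("Ct values must lie in (0, 40] cycles")
  if (!calibratorGroup %in% table$group)
    stop("calibrator group has zero samples")

  # average technical replicates per (sample, gene)
  avg <- aggregate(ct ~ sample + group + gene, data = table, FUN = mean)
  ref <- avg[avg$gene == refGene, c("sample", "ct")]
  names(ref)[2] <- "refCt"
  samples <- unique(avg$sample)
  if (!all(samples %in% ref$sample))
    stop("reference gene '", refGene, "' missing in sample(s): ",
         paste(setdiff(samples, ref$sample), collapse = ", "))

  tgt <- avg[avg$gene != refGene, ]
  if (nrow(tgt) == 0) stop("no target genes in table")
  tgt <- merge(tgt, ref, by = "sample")
  tgt$dCt <- tgt$ct - tgt$refCt
  out <- aggregate(dCt ~ gene + group, data = tgt, FUN = mean)
  names(out)[3] <- "dCtMean"

  res <- do.call(rbind, lapply(split(out, out$gene), function(g) {
    cal <- g$dCtMean[g$group == calibratorGroup]
    if (length(cal) == 0)
      stop("gene ", g$gene[1], " has no calibrator-group measurements")
    g$relExpr <- 2^-(g$dCtMean - cal)
    other <- g$relExpr[g$group != calibratorGroup]
    g$foldChange <- if (length(other) == 1) other else NA_real_
    g
  }))
  rownames(res) <- NULL
  res
}

#' Simulate a Ct table with a known true fold change
#'
#' Generates per-sample reference-gene and target-gene Ct values with
#' Gaussian measurement noise; mutant samples shift the target delta-Ct by
#' `-log2(fold)`, so `fold` is the true mutant/WT expression ratio.
#'
#' @param fold true fold change (mutant relative to WT).
#' @param nPerGroup samples per group (default 3).
#' @param sdCt per-measurement Ct noise, cycles (default 0.2).
#' @param seed integer seed (required).
#' @param gene,refGene gene labels.
#' @param refCt,baseDct reference-gene Ct level and baseline target
#'   delta-Ct in the WT group (defaults 18 and 5 cycles).
#' @return data.frame in [ddct()] input format.
#' @export
simulate_ct_table <- function(fold, nPerGroup = 3L, sdCt = 0.2, seed,
                              gene = "geneX", refGene = "Pgk1",
                              refCt = 18, baseDct = 5) {
  if (missing(seed)) stop("a seed is required")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (grp in c("WT", "mutant")) {
      shift <- if (grp == "mutant") -log2(fold) else 0
      for (i in seq_len(nPerGroup)) {
        sm <- paste0(grp, i)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sm, group = grp,
          gene = c(refGene, gene),
          ct = c(refCt + rnorm(1, 0, sdCt),
                 refCt + baseDct + shift + rnorm(1, 0, sdCt)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns sample, group, gene, ct.
#' @return data.frame in [ddct()] input format.
#' @export
read_ct_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write relative-expression results as TSV
#'
#' @param res result of [ddct()].
#' @param path output file.
#' @export
write_relative_expression <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
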