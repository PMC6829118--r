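#' Define a PCR primer pair
#'
#' @param name assay name.
#' @param fwd,rev primer sequences, both written 5'-to-3' as synthesized
#'   (the reverse primer anneals to the plus strand via its reverse
#'   complement). Lengths 15-35 nt, unambiguous A/C/G/T only.
#' @param maxProduct largest reportable amplicon (default 2000 nt).
#' @return a `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, maxProduct = 2000L) {
  for (p in c(fwd, rev)) {
    if (grepl("[^ACGT]", p)) stop("primers must not contain ambiguity codes")
    if (nchar(p) < 15L || nchar(p) > 35L) stop("primer lengths must be 15-35 nt")
  }
  structure(list(name = name, fwd = fwd, rev = rev,
                 maxProduct = as.integer(maxProduct)),
            class = "primer_pair")
}

#' Predict PCR amplicons on a set of templates
#'
#' Exact-match in-silico PCR: the forward primer must match the plus strand
#' and the reverse complement of the reverse primer must match the plus
#' strand downstream; every such site pair within `maxProduct` yields a
#' product. No mismatch or thermodynamic model is applied -- this validates
#' assay logic (junction vs wild-type specificity), not chemistry.
#'
#' @param pair a [primer_pair()].
#' @param templates a [Biostrings::DNAStringSet] (wild-type chromosomes
#'   and/or derivatives).
#' @return data.frame with `template`, `start`, `end` (1-based inclusive)
#'   and `length`, one row per predicted product (zero rows when none).
#' @export
predict_amplicons <- function(pair, templates) {
  stopifnot(inherits(pair, "primer_pair"))
  out <- list()
  rcrev <- revcomp_chr(pair$rev)
  for (tn in names(templates)) {
    subject <- templates[[tn]]
    fhits <- BiocGenerics::start(Biostrings::matchPattern(pair$fwd, subject))
    rhits <- BiocGenerics::end(Biostrings::matchPattern(rcrev, subject))
    if (length(fhits) == 0 || length(rhits) == 0) next
    for (f in fhits) {
      ok <- rhits[rhits >= f + nchar(pair$fwd) + nchar(pair$rev) - 1L &
                  rhits - f + 1L <= pair$maxProduct]
      if (length(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          template = tn, start = f, end = ok, length = ok - f + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(template = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call a genotype from amplicon presence
#'
#' Given the presence/absence of the wild-type assay product and the
#' junction assay product on the same sample, returns the genotype label:
#' wild-type only -> `WT`, both -> `T/+` (heterozygous), junction only ->
#' `T/T` (homozygous). Neither product is an assay failure.
#'
#' @param wtPresent,jxnPresent logicals.
#' @return one of `"WT"`, `"T/+"`, `"T/T"`.
#' @export
genotype_call <- function(wtPresent, jxnPresent) {
  if (!wtPresent && !jxnPresent)
    stop("assay failure: neither the wild-type nor the junction amplicon is present")
  if (wtPresent && jxnPresent) "T/+" else if (wtPresent) "WT" else "T/T"
}

#' Genotype a sample's template set with a WT and a junction assay
#'
#' Runs both assays by in-silico PCR on the sample templates (a heterozygote
#' is the union of wild-type chromosomes and derivatives) and calls the
#' genotype from the presence pattern.
#'
#' @param wtPair,jxnPair [primer_pair()]s for the wild-type-spanning and
#'   junction-spanning assays.
#' @param templates a [Biostrings::DNAStringSet] of the sample's
#'   chromosomes.
#' @return list with `genotype`, `wtProducts`, `jxnProducts`.
#' @export
genotype_sample <- function(wtPair, jxnPair, templates) {
  wt <- predict_amplicons(wtPair, templates)
  jx <- predict_amplicons(jxnPair, templates)
  list(genotype = genotype_call(nrow(wt) > 0, nrow(jx) > 0),
       wtProducts = wt, jxnProducts = jx)
}

#' Design breakpoint genotyping primers from a truth record
#'
#' Picks exact-match primers flanking the canonical breakpoints: the
#' wild-type assay amplifies across the chrA breakpoint on the intact
#' chromosome (and cannot amplify from either derivative, whose two primer
#' sites are separated onto different molecules), while the junction assay
#' spans the der(A;B) fusion (and has no co-linear site pair on wild-type
#' chromosomes).
#'
#' @param ref the wild-type reference set.
#' @param truth a `truth_record`.
#' @param primerLen primer length (default 22 nt).
#' @param gap distance between each primer and the breakpoint (default 150
#'   nt; total products stay well under the default `maxProduct`).
#' @return list with `wt` and `jxn` [primer_pair()]s.
#' @export
design_genotyping_primers <- function(ref, truth, primerLen = 22L, gap = 150L) {
  A <- as.character(ref[[truth$chrA]])
  B <- as.character(ref[[truth$chrB]])
  # WT assay: both primers on chrA, straddling [a1, a2]
  fwdWT <- substr(A, truth$a1 - gap - primerLen + 1L, truth$a1 - gap)
  revWTsite <- substr(A, truth$a2 + gap + 1L, truth$a2 + gap + primerLen)
  # junction assay: forward on the chrA side, reverse on the chrB side of der(A;B)
  fwdJx <- substr(A, truth$a1 - gap - primerLen + 1L, truth$a1 - gap)
  revJxSite <- substr(B, truth$b1 + gap + 1L, truth$b1 + gap + primerLen)
  list(wt = primer_pair("wt_assay", fwdWT, revcomp_chr(revWTsite)),
       jxn = primer_pair("jxn_assay", fwdJx, revcomp_chr(revJxSite)))
}

#' Write a primer table as TSV
#'
#' @param pairs list of [primer_pair()]s.
#' @param path output file.
#' @export
write_primer_tsv <- function(pairs, path) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(name = p$name, fwd = p$fwd, rev = p$rev,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer table from TSV
#'
#' @param path TSV with columns name, fwd, rev.
#' @param maxProduct passed to [primer_pair()].
#' @return list of [primer_pair()]s.
#' @export
read_primer_tsv <- function(path, maxProduct = 2000L) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$fwd[i], df$rev[i], maxProduct))
}
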