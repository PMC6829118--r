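#' Generate random reference chromosomes
#'
#' Produces a set of named chromosomes with i.i.d. uniform A/C/G/T composition.
#' The same (length, seed) pair always yields the identical sequence, so the
#' reference doubles as a reproducible ground-truth substrate for simulation
#' studies.
#'
#' @param spec a data.frame with columns `name`, `length`, `seed` (one row per
#'   chromosome), or a list of `list(name=, length=, seed=)` entries.
#' @return a [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' ref <- make_reference(data.frame(name = c("chrA", "chrB"),
#'                                  length = 5000, seed = c(1, 2)))
#' @export
make_reference <- function(spec) {
  if (is.data.frame(spec)) {
    spec <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, , drop = FALSE]))
  }
  nm <- vapply(spec, function(e) as.character(e$name), "")
  if (anyDuplicated(nm)) stop("duplicate chromosome names in reference spec")
  seqs <- vapply(spec, function(e) {
    len <- as.integer(e$length)
    if (is.na(len) || len <= 0) stop("chromosome length must be positive")
    if (is.null(e$seed) || is.na(e$seed)) stop("a seed is required for every chromosome")
    withr::with_seed(as.integer(e$seed), {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    })
  }, "")
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- nm
  validate_reference(ref)
  ref
}

#' Validate a reference set
#'
#' Checks the invariants every reference set used by the pipeline must hold:
#' unique names, non-empty sequences, alphabet restricted to A/C/G/T.
#'
#' @param ref a [Biostrings::DNAStringSet].
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_reference <- function(ref) {
  if (!methods::is(ref, "DNAStringSet")) stop("reference must be a DNAStringSet")
  if (is.null(names(ref)) || any(names(ref) == "")) stop("all chromosomes must be named")
  if (anyDuplicated(names(ref))) stop("chromosome names must be unique")
  if (any(Biostrings::width(ref) == 0)) stop("chromosome sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(ref, baseOnly = TRUE)
  if (any(freq[, "other"] > 0)) stop("sequences must use the A/C/G/T alphabet only")
  invisible(ref)
}

#' Write a reference set to FASTA
#'
#' @param ref a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref, path, width = 60L)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA file.
#' @return a validated [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  validate_reference(ref)
  ref
}
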