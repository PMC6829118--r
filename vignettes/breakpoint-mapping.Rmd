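---
title: "Mapping reciprocal translocation breakpoints from targeted paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping reciprocal translocation breakpoints from targeted paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translocatr)
```

## The problem

A reciprocal translocation t(A;B) exchanges the distal segments of two
non-homologous chromosomes, producing two derivative chromosomes,
der(A;B) and der(B;A). In a classic mouse mutant of this kind the two
junctions were localized in three steps: metaphase FISH with large-insert
(BAC) probes narrowed each breakpoint to the overlap of the clones "split"
by it; targeted capture and ~30X paired-end sequencing of windows around
those intervals produced read pairs whose mates map to different
chromosomes, and the clusters of such pairs pinpoint the junctions; finally
the junction-spanning sequence itself reveals the repair signature --
small per-chromosome deletions, optional microhomology, and short templated
duplications, the classic footprint of non-homologous end joining (NHEJ).
Junction PCR assays then genotype animals, and comparative-Ct (delta-delta-Ct)
qRT-PCR quantifies expression of genes flanking the breakpoints relative to
a reference gene such as *Pgk1*.

`translocatr` implements this entire computational chain, together with a
fully synthetic test-bed that emits ground-truth records for every stage, so
each step can be validated by exact parameter recovery.

## Simulation model

`make_reference()` draws i.i.d. uniform A/C/G/T chromosomes; the default
study uses two 1 Mb chromosomes. Random sequence of this length is
essentially repeat-free at the 31-mer scale, which is the regime the
targeted-capture experiment operated in (unique mapping near the
breakpoints). Real genomes add repeats, capture-efficiency bias, indel
errors and PCR duplicates, none of which are modelled -- passing tests show
the algorithms are correct under clean mapping conditions, not that the
pipeline is robust to repeat-rich loci.

`translocation_event()` describes the rearrangement as
`der(A;B) = chrA[0:a1] + ins1 + chrB[b1:]` and
`der(B;A) = chrB[0:b2] + ins2 + chrA[a2:]` (0-based half-open internally;
all human-facing reports are 1-based). `a2 - a1` and `b1 - b2` are the
per-chromosome deletions; `ins1`/`ins2` the junction insertions.

`simulate_event()` engineers the NHEJ anatomy into the sequence:

* **Microhomology** of length *k* is written into the resected flank
  (`chrB[b1-k:b1] := chrA[a1-k:a1]` for junction 1), so it requires
  `k <= delB`. Biologically, microhomology-mediated joining consumes at
  least the homology it uses; technically, the constraint keeps the two
  junctions' engineered regions disjoint.
* **Duplications** are templated copies of the 1-3 bases immediately
  flanking the junction on a randomly chosen side, matching the short
  flank-templated duplications seen at real NHEJ junctions.

`simulate_paired_reads()` draws fragments with Normal(350, 35) length
truncated to `[2*readLen, window]`, uniform starts inside each 100 kb
capture window, and `round(depth * W / (2*readLen))` pairs per window
(15,000 pairs at 30X over 100 kb). Mate 1 reads the fragment start forward,
mate 2 the fragment end on the reverse strand. The error model is
substitution-only (default rate 0); indel and chimera errors are out of
scope. Seeds are mandatory everywhere; nothing defaults to the clock.

## Canonical junction representation

A junction with microhomology (or with an insertion copying a flank) has
several equivalent coordinate representations. The package uses one canon
everywhere: the **maximal exact prefix** match to the left reference and
the **maximal exact suffix** match to the right reference. If prefix and
suffix overlap by `m` bases, `mhLen = m` and the microhomology is
attributed to the left (A) side; if they leave a gap, the gap is `insSeq`.
This mirrors VCF-style left alignment and makes recovery testable: truth
records are computed by running the same arithmetic (longest common
prefix/suffix against each reference) on the full derivative, and
`simulate_event()` resamples breakpoint positions until the canonical form
equals the requested configuration, so pipeline output can be compared to
truth by strict equality. A consequence worth knowing: a perfect 3 nt flank
duplication can canonicalize as a shifted blunt join -- total inserted bases
are preserved, but the split point moves. The resampling step excludes such
ambiguous placements from the truth set.

## Mapping and clustering

The mapper (`build_index()`, `map_pairs()`) is a seed-and-extend aligner:
non-overlapping 31-mers seed candidate placements, which are scored by
full-length ungapped Hamming comparison with at most `maxMismatch = 3`
substitutions per mate. Ties keep the lexicographically smallest placement
and are flagged non-unique; downstream stages use only unique-unique pairs.
Extension is deliberately ungapped: the simulator emits substitution-only
errors, and junction-spanning reads are *meant* to fail mapping -- they are
the assembly substrate, not an alignment problem. `k` is odd so a k-mer
cannot be its own reverse complement.

`find_discordant()` keeps exactly the unique-unique inter-chromosomal
pairs. `cluster_discordant()` joins two pairs iff they share chromosome
pair and strand consensus and both sides are within `maxGap`
(default `insertMean + 3*insertSd = 455`); this join rule is single-linkage
agglomeration under the Chebyshev distance, so it is computed with
`hclust(method = "single")` cut at `maxGap`.

`call_candidates()` drops clusters below `minSupport = 3` (pairs must map
"repeatedly" to count; at 30X the expectation is ~22 pairs, so 3 rejects
sporadic mismapping without risking the signal) and converts each cluster
to a breakpoint interval pair. The breakpoint lies in the unsequenced inner
gap of the straddling fragments: on a forward-consensus side the interval
runs from the rightmost read end rightwards by
`insertMean - 2*readLen + 4*insertSd` (290 nt at defaults), mirrored on
reverse sides. Because the mapper tolerates up to 3 mismatches, a read can
overrun the junction by a few bases and still map, pushing the rightmost
read end slightly past the true breakpoint; the read-facing edge is
therefore padded by `boundaryPad = 4 * maxMismatch` (12 nt). The number of
cleanly straddling fragments is Poisson with
`lambda = depth * (insertMean - 2*readLen) / (2*readLen) = 22.5`
at defaults, which is the model the support-distribution check uses.

## Junction assembly and characterization

`collect_junction_reads()` selects unmapped reads whose mate maps uniquely
near the candidate with the cluster's strand consensus -- the orientation
filter matters because the two junctions of a reciprocal event can lie
within a few bases of each other on each chromosome, and mate strand is
what separates their read populations. Each read is oriented
derivative-forward using the mate's strand. `assemble_junction()` merges
them greedily by maximal exact overlap (ties by input order, contained
reads absorbed, minimum overlap 20 nt); with 30X error-free data the result
is a single contig that is an exact substring of the derivative. Assembly
is exact-overlap by design; at nonzero error rates the mapper still feeds
the stage, but consensus accuracy degrades and a mismatch-tolerant merge
would be the natural extension.

`characterize_junction()` anchors the consensus in the candidate regions
(prefix scan on the `+`-consensus side, suffix scan on the `-` side; both
scans extend the candidate interval by `searchMargin = 2*insertMean` and by
the consensus length on the outward edge) and applies the canonical
arithmetic. Anchors below `floor = 30` nt are rejected: on desk-scale
references, shorter matches anchor spuriously (a 15 nt match has expected
frequency 5000/4^15 per strand of a 5 kb reference, and the scan maximizes
over ~2000 offsets). Insertions of 1-3 nt matching either junction flank
are classified `templated-duplication`; longer flank-matching insertions
warn and classify `untemplated-insertion`. `summarize_reciprocal()`
combines the two calls into per-chromosome deletion totals and verifies the
length-accounting identity
`len(der1) + len(der2) = lenA + lenB - delA - delB + dupTotal`.

`write_bnd_vcf()` emits VCF 4.2 breakend pairs (bracket ALTs, MATEID/EVENT,
HOMLEN/HOMSEQ for microhomology junctions, inserted bases inline in the
ALT); the tests round-trip the file through `VariantAnnotation` as an
independent parser.

## Probe localization

`classify_probe()` implements the three-way partition (split iff
`start < bp < end`, with open interiors: a breakpoint touching a probe
boundary is not resolvable as a split by FISH). `localize_breakpoint()`
inverts a panel into the exact consistent set: intersection of split
interiors clipped to `[max proximal end, min distal start]`, returned
half-open with a position count; a contradictory panel is an error rather
than an empty interval. The split-clone overlap
(`[max split start, min split end)`) is reported alongside, since that is
the interval cytogeneticists quote. Against the published clone-overlap
endpoints this reproduces the ~130 kb (chr5) and ~193 kb (chr8) intervals,
and the sequenced chr8 breakpoint falls inside its interval.

## In-silico genotyping and expression

`predict_amplicons()` does exact-match PCR (forward primer on the plus
strand, reverse-complemented reverse primer downstream, products up to
`maxProduct`); no thermodynamics -- the point is assay logic: a
junction-spanning pair amplifies only from der(A;B), a WT-spanning pair
only from the intact chromosome, and `genotype_call()` maps the presence
pattern to WT / T/+ / T/T (a heterozygote is the union of both template
sets).

`ddct()` implements comparative Ct with efficiency fixed at 2: technical
replicates are averaged per (sample, gene) *before* computing
`dCt = Ct(gene) - Ct(ref)` (the replicate-order choice, documented here
because protocols differ), group means give
`fold = 2^-(dCt_mut - dCt_cal)`, and the calibrator group reports exactly 1.
Adding any per-sample constant to Ct cancels. For a known fold *f* with
per-measurement noise sd sigma and *n* samples per group, the estimator
satisfies `log2(f-hat) ~ Normal(log2 f, 4 sigma^2 / n)`; the recovery tests
use this closed-form interval (sigma = 0.2 cycles, n = 3).

## Problem sizes and numerical choices

The validation study runs 100 seeded events at the conditions above
(1 Mb chromosomes, 100 kb windows, 30X, 2x100 reads, insert 350 +/- 35)
plus 100 matched wild-type runs, ~4 minutes on one core; localization
soundness uses 1,000 random panels on 50 kb chromosomes against an
exhaustive-position oracle, and characterization is checked against a
brute-force enumeration oracle on 500 random consensi over 5 kb references.
Tie-breaks are deterministic throughout (lexicographic placements, smallest
anchor offset, input order in assembly), and every stochastic routine takes
an explicit seed, so all results in the test suite and acceptance script
are bit-reproducible.

## Known limitations

Inversion-type junctions (same-strand consensus) are out of scope, as are
intra-chromosomal SV classes, gapped alignment, indel read errors,
capture-efficiency modelling, PCR-duplicate simulation, primer
thermodynamics, and qPCR efficiency correction. The synthetic reference is
repeat-free by construction; on repeat-rich real loci the unique-mapping
filter would thin discordant support and the candidate intervals would
widen accordingly.

## A short worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 42L, delA = 6L, delB = 8L, mh1 = 3L, dup2 = 2L)
res <- call_translocation(study$reads, study$ref)
print(res)
recovery_report(res, study$truth)$exact
```
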