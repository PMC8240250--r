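---
title: "Detecting reverse-transcription splicing artifacts with falsitronr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reverse-transcription splicing artifacts with falsitronr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falsitronr)
library(dplyr)
```

## The problem

Exitrons are intron-like segments excised from within annotated exons.
Their hallmark in sequencing data is a split read whose gap lies entirely
inside an exon. The trouble is that reverse transcriptase produces the
same signature artifactually: when a transcript region folds into a
hairpin flanked by two copies of a short direct repeat, the enzyme can
slip from one repeat copy to the other, deleting one copy plus the
intervening sequence from the cDNA. Downstream, the deletion is
indistinguishable from a clean splice junction — except that it is absent
from direct RNA sequencing (dRNA-seq) of the same sample, because native
RNA molecules never passed through reverse transcription.

`falsitronr` implements this dRNA-vs-cDNA contrast as a reusable
pipeline. Junctions supported only by RT-based protocols, passing a set
of coverage and context filters, are nominated as *falsitrons* —
questionable exitrons that are likely RT artifacts. The package also
provides the two companion analyses that characterise such loci: a
direct-repeat search anchored at the splice-site dinucleotides, and
position-wise splice-site nucleotide profiles.

## The detection model

Let `J` be a junction (a genomic interval skipped by split reads),
observed in a cDNA-type dataset with matched dRNA-seq from the same RNA.
`J` is nominated iff all of the following hold:

1. **Support.** At least `min_coverage` (default 5) cDNA reads skip
   exactly `J`.
2. **Absence.** No dRNA read skips exactly `J`.
3. **Coverage.** At least `min_coverage` dRNA reads overlap the interval
   of `J` by one or more bases — absence must be informative, not a
   sampling artifact. A read skipping `J` counts as overlapping: its
   aligned span includes the skip. We count junction-local read coverage
   directly from the alignments rather than relying on an assembler's
   per-transcript coverage estimate; it is the quantity the threshold is
   meant to bound and removes an external-tool dependency.
4. **Exonic context.** `J` lies fully within one exon of a dRNA
   transcript model (filter path *1a*, boundaries inclusive), or its two
   ends lie in two *adjacent* exons of one model (filter path *1b*). 1a
   is checked first; a junction passing both is recorded as 1a, the
   stricter, exitron-like case. The host transcript also supplies the
   strand for all sequence-level annotation, since cDNA reads themselves
   are not reliably stranded.
5. **Non-canonical splice sites.** The junction's donor–acceptor
   dinucleotide pair, read in transcript orientation, is not in the
   canonical set (`GT–AG` by default; `GC–AG` can be added). A genuine
   novel intron should look like an intron; an RT-slippage junction has
   no reason to.

Conditions are evaluated at the read level against exact junction
coordinates. Working with reads rather than assembled isoform
comparisons is stricter and better defined: a junction either is or is
not present in the dRNA alignments. An exact-coordinate absence test is
the default; coordinate ambiguity caused by flanking repeats is handled
explicitly by the shift-tolerant matcher (below) rather than by fuzzing
the detector.

The long-read **relative abundance** of a candidate is the number of
split reads supporting the junction divided by the number of reads
overlapping its coordinates; it is undefined (`NA`), not zero, when no
read overlaps. For short-read junction tables a second estimator is
provided: spliced-read count over the mean per-base coverage of the
junction region (`short_read_abundance()`).

## Direct repeats at splice sites

RT slippage requires a template: two identical sequence copies flanking
the deleted segment. `annotate_repeats()` searches, for each junction,
for the longest k-mer (k from `k_min = 4` to `k_max = 20`) that occurs in
a 40-nt window centred on each splice-site boundary (20 exonic + 20
intronic nt), with each occurrence overlapping at least 1 nt of that
site's boundary dinucleotide motif. The motif anchoring is what makes
the search specific to repeats that can explain the junction register
rather than any repeat in the vicinity. `k_min` may be lowered to 3 to
also capture the shortest repeats observed at real artifact loci,
at the cost of more chance matches.

Ties among equal-length k-mers are broken by the smallest total distance
of the occurrence centres to their motif centres, then lexicographically
— both occurrences must overlap their motifs regardless, so the
tie-break only selects among near-equivalent placements. The search is
validated against a brute-force enumeration of every substring pair of
the two windows.

Catalogue-level statistics (`repeat_summary()`) report the fraction of
intervals with a repeat of length ≥ 4 and the median repeat length among
those, using the lower-median convention for even counts so the
statistic is always an observed value.

## Shift-tolerant junction matching

A junction ending inside a repeat has no unique register: external
datasets may record the same event shifted into the repeat copies. When
looking a candidate up in an external junction table,
`shifted_junction_match()` accepts an observed junction iff it is an
*outward* enlargement of the query by at most one repeat length `r` on
each side, and its length differs from the query length by at most `r`.
Both clauses are applied — per-side shifts bounded by `r` *and* the
total length change bounded by `r` — which is the conjunction of the two
stated constraints; inward shifts never qualify, because repeat
ambiguity can only extend the apparent intron into the repeat copies.
The exact match always qualifies.

## Splice-site profiles

`splice_profile()` computes the numeric substrate of a splice-site
sequence logo: per-position nucleotide counts and frequencies in 15-nt
windows, 3 exonic + 12 intronic nt at each splice site. Positions are
labelled `-3..-1, +1..+12` at the 5' site and `-12..-1, +1..+3` at the
3' site (negative = before the splice-site boundary in transcript
orientation; there is no position 0). Ambiguous bases are excluded from
the denominator position-wise instead of discarding whole sequences.
Genuine introns show fixed `G/T` at 5' positions +1/+2, fixed `A/G` at
3' positions −2/−1, and a pyrimidine-rich tract upstream of the
acceptor; RT-artifact junctions show none of this — the package's
testable analogue of the observation that questionable exitrons lack
splice-site character.

## The synthetic study

Every claim above is exercised against `sim_genome()`/`sim_reads()`,
which embed the slippage mechanism with known truth:

* **Genes.** Multi-exon genes (defaults: 10 genes, 3–5 exons of 250–400
  nt, introns of 150–300 nt), each on its own contig with 150-nt
  flanking pads, random strand. Introns are canonical: `GT` donor,
  `AG` acceptor, pyrimidine-rich 3' end.
* **Planted loci.** A subset of genes (default 5) carries, inside an
  exon, a segment `R · I · R`: two identical repeat copies `R` (default
  lengths 4, 6, 8, 12, 16 nt — spanning the range seen at real artifact
  loci) around an interior `I` (60–140 nt) that contains an
  inverted-repeat stem (8 nt by default) as hairpin decoration. The
  bases adjacent to each copy are forced to differ so the planted repeat
  length is exact, and the donor is forced non-canonical unless
  `canonical_boundaries = TRUE` is requested for filter-effectiveness
  experiments.
* **Junction register.** Slippage deletes one repeat copy plus the
  interior. The resulting gap is coordinate-ambiguous across the repeat;
  the simulator registers the truth junction one base into the repeat,
  so that each repeat copy overlaps its splice-site dinucleotide motif —
  the geometry required for a motif-anchored repeat search to see the
  repeat at all, and the register real artifact junctions must
  effectively occupy for their flanking repeats to be reported. At the
  extreme (leftmost/rightmost) registers the second copy merely abuts
  the motif, and no motif-overlapping search can qualify it.
* **QC.** Each planted locus is verified by exhaustive substring
  enumeration to have its repeat as the unique longest motif-overlapping
  shared k-mer in the 40-nt windows; genes failing the check (by chance
  collisions in flanking sequence) are resampled. This keeps
  "planted repeat length" an exact, testable truth value.
* **Reads.** All modes emit full-length, pre-aligned reads of each
  transcript (mapping is out of scope), with true introns as `N` skips.
  `cDNA`/`dcDNA` molecules additionally slip at each planted locus with
  probability `p_slip` (default 0.3), adding the truth-interval skip;
  `dRNA` never does, and warns if `p_slip > 0` to make the contrast
  explicit. Sequencing noise is substitution-only (default 0.5%),
  applied away from block edges so junction coordinates stay exact —
  indel noise would perturb CIGARs without exercising any additional
  logic. PCR amplification is modelled only as an optional duplication
  factor on slipped molecules in `cDNA` mode, since the artifact arises
  at the RT step shared by both cDNA protocols.

What the simulator does *not* emulate: realistic ONT error profiles,
truncated or partial reads, multi-isoform genes, alignment ambiguity,
and expression variation. Passing tests therefore demonstrate the
correctness of the pipeline's logic under ideal alignment, not its
robustness to mapper artifacts on real data.

## Numerical and interface choices

* Internal coordinates are 0-based half-open everywhere (BED
  convention); GFF/GTF and printed region strings (1-based inclusive)
  are converted at the I/O boundary only. Printed coordinates such as
  `chr5:126625543-126625746:+` are treated as 1-based inclusive intron
  spans.
* Secondary and supplementary alignments are excluded by default —
  artifact junctions must come from primary placements.
* Junctions extracted from reads are unstranded and match either strand
  in set operations; stranded annotation comes from the host transcript.
* Containment ties (a junction inside exons of several transcripts) are
  broken by the smallest transcript identifier, keeping output
  deterministic and order-invariant.
* Validation problem sizes are chosen for exactness of the checks, not
  scale: 20 simulated studies for recovery, 1000 window pairs for the
  repeat-search oracle, 100 seeds × three slippage probabilities for
  abundance recovery, exhaustive enumeration for the shift matcher.
* This package is an R library; its interface is the exported functions
  and `run_pipeline()`, which orchestrates detection, repeat annotation,
  abundance and profiling with per-stage logging and deterministic
  TSV outputs.

## Worked example

```{r example}
sim <- sim_genome(sim_config(seed = 42))
cdna <- sim_reads(sim, "cDNA")
drna <- suppressWarnings(sim_reads(sim, "dRNA"))

result <- detect_falsitrons(
  extract_junctions(cdna, dataset = "cDNA"),
  drna, sim$annotation, sim$genome
) |>
  annotate_repeats(sim$genome)

tidy(result) |>
  select(chrom, start, end, strand, filter_path,
         repeat_length, repeat_kmer, relative_abundance)
glance(result)
```

All five planted loci are recovered with their exact coordinates and
repeat lengths; the estimated abundances scatter around the configured
`p_slip`.

## Known limitations

* Absence in dRNA is exact-coordinate; a real artifact registered at a
  shifted coordinate by the aligner would need the shift-tolerant
  matcher applied upstream.
* No statistical test or FDR control is attached to candidate calls:
  the cascade is a deterministic filter, as defined.
* Single-sample pairs only; cohort-level aggregation ("N events across
  M cell lines") is bookkeeping left to the caller.
* The repeat search is exact-match only; mismatch-tolerant repeats and
  hairpin thermodynamics are out of scope.
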