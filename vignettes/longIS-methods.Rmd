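---
title: "Integration-site detection from Cas9-enriched long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integration-site detection from Cas9-enriched long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longIS)
```

## The problem and the read geometry

Lentiviral vectors integrate semi-randomly into host chromosomes, and
integration-site (IS) analysis is a safety checkpoint for gene-therapy
products. Amplification-free Cas9 enrichment produces a characteristic read
structure that longIS exploits: high-molecular-weight DNA is end-protected
(dephosphorylated), cut by Cas9 RNPs at guide sites placed *inside* the
integrated provirus near both ends, and only the fresh cut ends receive
sequencing adapters. Because SpCas9 stays bound to the cleaved end 5&prime;
of the PAM, the A-tailable (sequenceable) fragment is the PAM-side one, and
guides are oriented so that sequencing proceeds from the cut, across the
vector terminus, into flanking host DNA.

A productive ("outward") read therefore looks like:

```
cut site .... vector arm .... terminus | host sequence ................
read start                             junction          ~11 kb of host
```

The pipeline identifies the junction on every such read, clusters per-read
junctions into unique integration sites, estimates the target-site
duplication (TSD), annotates sites against a gene model, and reports a
fold-enrichment statistic.

## Coordinate and junction conventions

All internal coordinates are 0-based, half-open. The guide `cut_position`
is the index of the first base of the right-hand fragment (SpCas9 blunt-cut
model, 3 bp 5&prime; of the PAM; the 1-nt staggered-end refinement is far
below read-level resolution).

Integrase duplicates `t` bp of host sequence (typically 5&ndash;6 bp)
around the insertion. With the duplicated motif starting at host
coordinate `p`, the modified locus is
`host[0, p+t) + provirus +/- + host[p, L)`. Junction calls record the host
coordinate of the first host base adjacent to the vector, with the side of
the host sequence made explicit:

* host on the **right** of the vector (host span on the `+` strand of the
  read's host segment): position `p`, the start of the 5&prime;-most
  duplicated copy;
* host on the **left** (host span `-`): position `p + t`.

A bidirectional site therefore shows its two junction populations offset by
exactly the TSD, and `estimate_tsd()` returns
`median(left-side positions) - median(right-side positions)`, clipped to
`[0, tsd_max]`. The sign rule is deliberately expressed on *host sides*
rather than vector ends: which vector terminus abuts the 5&prime; copy
flips with the provirus strand, so a vector-end-based rule would only be
correct for one orientation. The cluster representative position is the
minimum member coordinate, i.e. the start of the 5&prime;-most duplicated
copy.

### Why the junction is anchored on the vector span

The provirus reference ends at the terminus, so the vector-side (LV) span
of a read can never extend past the junction &mdash; alignment simply runs
out of target. Its read-side end `q*` is therefore an exact junction marker
on error-free reads. The host-side span, in contrast, can creep a few bases
back across the junction on coincidental matches (each flanking host base
matches the adjacent vector base with probability 1/4), which during
development shifted called positions by 1&ndash;6 bp *at error rate 0*.
Two consequences in the implementation:

* phase-2 host alignment is masked to start exactly at `q*`, so the host
  span can never overlap the LV span on the read;
* the reported position is taken at the host span boundary and any residual
  read-side gap (junction-adjacent sequencing errors) is extrapolated as
  diagonal.

## The two-phase triage

Reads are first aligned to the proviral construct only; reads without a
vector hit are never host-aligned (they are presumed host background
&mdash; the pipeline cannot distinguish "host_only" from "unmapped" without
aligning, and does not pay for the alignment). Reads with an LV span have
their remainder aligned to the host genome. Host uniqueness uses a
best/second-best score ratio (default 1.2) instead of a mapper-specific
MAPQ, because both references contain genuine repeats &mdash; notably the
two LTR copies of the construct, which the aligner is required to surface
as near-equal-scoring secondary spans rather than hide.

`min_host_anchor` (default 200 bp) is the smallest host segment accepted as
a mapping anchor; with ~10&ndash;15% per-base error a shorter anchor is not
reliably unique even in a random genome.

## Episome (LTR-circle) elimination

Non-integrated circular vector DNA produces reads that cross a
terminus-to-terminus junction and contain no host sequence. A read is
flagged episomal when (a) two vector spans are adjacent on the read with
one exiting a terminus and the next entering a terminus (the circle
junction), or (b) the read is vector-only after crossing a terminus:
if the tail beyond the terminus is at least `min_host_anchor` it failed to
find a unique host anchor, and if it is shorter the read is excluded
conservatively with the distinct reason `ends_at_terminus`. Wrong-direction
(inward) reads never reach a terminus and fall into `no_structure` instead.

## The internal aligner

The aligner exists so the package tests itself without an external binary;
real genome-scale runs should use a production long-read mapper and enter
the pipeline through the PAF/SAM import path (`read_alignments()` into
`triage_reads(lv_alignments=, host_alignments=)`).

Numerical choices, all configurable:

* canonical minimizers with `k = 15`, `w = 10` (the usual genomic-DNA
  regime for long-read mappers); strand-symmetric k-mers are skipped;
* seeds occurring more than 200 times are ignored (repeat filter);
* O(n&sup2;) colinear chaining with a 64-anchor lookback and a
  5 kb maximum anchor gap; chains need &ge; 4 anchors;
* base-level refinement by piecewise banded DP (linear scores: match +1,
  mismatch &minus;2, gap &minus;2; band 50) between anchors, with x-drop 50
  end extension that stops at the best-scoring cell &mdash; this is what
  clips the LV span exactly at the terminus and the host span near the
  junction;
* reported identity is `matches / block_length` with gap columns counted in
  the block; spans below 0.8 identity are dropped;
* ties in span ordering break deterministically by lowest target
  coordinate, then target name.

## Clustering

Single-linkage per chromosome: same-side calls within `merge_window`
(default 10 bp, above Nanopore indel jitter and far below the collision
scale of independent sites) merge; opposite-side calls merge when the
left-side coordinate exceeds the right-side coordinate by 0..`tsd_max`
(default 7) bp &mdash; the duplication geometry. A site is `bidirectional`
when both vector ends are observed; the TSD estimate is only defined then.

## The simulator: what the stated world is, and is not

The generator encodes the stated experimental regime:

* mean read length 12 kb (truncated normal, sd 2 kb &mdash; the sd is not
  stated anywhere and is a simulator choice);
* TSD default 6 bp (the documented 5&ndash;6 bp integrase duplication; 6 is
  the value shown in the worked junction example this package reproduces);
* `outward_bias = 0.9`: A-tailing of the Cas9-bound end is *reduced*, not
  eliminated; the residual wrong-direction fraction is not a quantified
  protocol parameter, so 0.9 is a free choice. Inward reads terminate at the
  opposite arm's nearest cut site (the molecule is cleaved there too) and
  never reach host;
* constant per-read Phred quality `Q = -10 log10(error_rate)` (capped at
  40), sufficient for the mean-quality filter it feeds;
* errors are i.i.d. substitutions (60%), insertions (20%), deletions (20%);
* `background_fraction = 0.3`, `circle_fraction = 0.1` by default. These
  are *testing* proportions chosen so every read class is exercised at
  small n; in the real protocol the on-target fraction is far smaller
  (hundreds of LV reads among ~200k total) &mdash; recovery statistics,
  which are per-site, do not depend on the background proportion, but
  wall-clock realism does;
* the synthetic construct duplicates its first 600 bp at the right end, so
  the LTR multi-mapping problem is genuinely present; guides are drawn from
  the construct's own PAM scan under the panel design rules (two guides
  per arm, opposite strands per arm role, &ge; 500 bp from the served
  terminus, &ge; 50 bp spacing).

Not emulated: homopolymer-biased and signal-level Nanopore errors,
basecaller artifacts, chimeric/concatemer reads, diploidy, and a realistic
repeat landscape (host chromosomes are i.i.d. random DNA, so host
uniqueness is easier than in a mammalian genome). A green round-trip test
therefore establishes the correctness of the junction arithmetic, the
filters and the clustering under the stated noise model &mdash; not mapper
performance on real genomes, for which the external-aligner import path
exists.

## Annotation choices

"Transcriptional unit" means the annotated gene body; a site in any exon is
`exon`, else in any gene body `intron`, else `intergenic` (exon wins over
intron for overlapping genes). A site inside two overlapping gene bodies is
*classified* once but *attributed* to both genes for gene-level analyses
(multiple-integration detection, cross-sample overlap), which are
membership analyses. Nearest-gene ties break by smaller gene start, then
name. The cross-sample shared fraction is Jaccard by default; the
denominator convention of a Venn shared-gene percentage is not spelled
out anywhere standard, so `|A&cap;B| / min(|A|,|B|)` is available via
`method = "min"`. The chromosome-level regression is ordinary least squares
of IS density on gene density (both normalised to chromosome length), with
an `exclude=` hook for absent chromosomes (e.g. chrY in female-origin
lines); a zero-variance predictor returns `NA` rather than a crash.

## Enrichment statistic

`fold_enrichment(observed, a, b, c, d, e)` returns
`observed / ((a*b) * (c*d) / e)`: the observed count of vector-mapped reads
over the count expected if `a*b` vector genomes were sequenced at random at
depth `c*d / e`. Reads (not bases) are counted because a junction read
carries a fixed amount of vector sequence regardless of its host tail
length. `e` is an explicit input rather than always being computed from `a`; `input_bases(a, genome_size)` covers the common `e = a*G` case.
Reproducing any particular experiment's fold values exactly requires its
own measured constants (`a`, `d`, `e`); the
formula itself is pinned by a hand-derivable case
(`observed = 1, a = 1000, b = 2, c = 100, d = 10^4, e = 6.4*10^12`
&rArr; 3200) and the identity `observed = expected` &rArr; 1.

## Degenerate inputs and edge behaviour

Empty read sets flow through the whole pipeline and produce an all-zero
summary with an absent fold enrichment. Empty gene models classify
everything intergenic with absent nearest genes. The per-read decision log
partitions the input exactly into
`{dropped_quality, dropped_size, episome, no_structure, ambiguous,
member_of_site}`; the CLI `call` subcommand exits non-zero if the partition
does not balance. The mean-quality cut-off is strict (`> 9`): a read at
exactly Q9 is dropped. The size-selection threshold is
`min(arm lengths) + min_host_anchor`; per-arm sufficiency is enforced at
calling time by requiring the LV span to reach within `end_slack`
(default 50 bp, tolerant of terminal adapter trimming) of the terminus.

## Known limitations

* Aligner accuracy is adequate for the simulated noise model, not
  competitive with production mappers on real data; use the PAF import for
  real genomes.
* Clonal abundance is reported as raw support counts; there is no
  sonication-fragment deduplication because the protocol is
  amplification-free.
* One design decision was consciously not followed: there is no global
  TOML/YAML config file; every tunable is an explicit function argument and
  CLI flag instead, which is the R-native equivalent and keeps the
  dependency set closed.
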