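---
title: "Mining immune DNA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining immune DNA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idnaseq)
```

# The problem

Mature T cells carry a somatically rearranged T-cell receptor beta (TCRB)
locus: one V and one J gene joined with trimmed ends and non-templated
insertions, forming the hypervariable CDR3 junction that defines a
clonotype. Bulk tumor exomes are sequenced from all cells in a specimen,
so a small fraction of reads in a T-cell-infiltrated tumor derives from
rearranged TCRB molecules. Those reads map poorly to the unrearranged
germline reference — they end up soft-clipped inside the TCRB locus or
unmapped — but they are recoverable, and their abundance is a direct,
DNA-level measure of T-cell infiltration ("immune DNA", iDNA). `idnaseq`
implements the whole chain: harvesting candidate reads from a BAM, calling
CDR3 junctions against a germline V/J reference, normalizing to reads per
million (RPM), scoring cohorts into iDNA deciles, summarizing clonal
diversity, and checking the detection limits with both a closed-form model
and simulation.

# Anchor-based junction calling

## Reference conventions

Every V segment carries the conserved cysteine codon near its 3' end and
every J segment the conserved phenylalanine/tryptophan of the [FW]-G-x-G
motif. The CDR3 is delimited IMGT-style: from the V cysteine codon through
the J F/W codon, both inclusive. This is the convention of the repertoire
tools this package's outputs are meant to be comparable with. References
are user-supplied (FASTA plus a three-column anchor table); anchors are
validated at load time, with the J motif checked at codon positions 2 and
4 after the anchor. Genomic coordinates are 1-based inclusive (the default
harvest window is the hg19 TCRB locus, chr7:142,000,817–142,510,993);
offsets within a sequence are 0-based. D segments are carried but never
aligned: short D remnants in 100 bp reads almost never retain enough
sequence to assign, and the V+J anchoring is what the comparable tools
use.

## The caller

Candidate reads are aligned to every V and every J segment by seed-and-
extend: shared 12-mers define diagonals, each run of seed matches is
extended outward under +1/−1 scoring, and among extension end points that
can participate in an optimum (the Pareto frontier of score versus
mismatches on each side) the caller keeps the best-scoring interval whose
aligned length reaches the class minimum (V: 20, J: 12 bases) and whose
mismatch fraction stays within `max_mismatch_rate` (default 0.1). The
alignment is deliberately ungapped — substitutions only. V/J flanks of a
junction inside a 100 bp read essentially never require gaps, and the
restriction keeps an exact brute-force oracle cheap enough to test
against.

A call requires a V hit and a J hit on the same strand, the V interval
ending before the J interval ends, and both anchor codons projected inside
the read through their alignment diagonals; the CDR3 is the read substring
between the projected anchors. Both strands are attempted and the higher
combined score wins. A junction is productive when its length is divisible
by three, its translation is stop-free, and it is bounded by C and F/W.
Non-productive junctions are dropped by default; with
`rescue_out_of_frame = TRUE` they are returned flagged `rescued`, matching
the permissive counting mode some published tools use.

Within a sample, clonotype identity is the exact (CDR3 nucleotide, V, J)
triple — nucleotide-level identity preserves the most information at
exome depth, where nearly every clonotype is supported by a handful of
reads. Across samples, sharing defaults to amino-acid identity, the usual
unit in repertoire studies because convergent recombination produces the
same amino-acid junction from different nucleotide rearrangements; the
nucleotide key remains available. Error collapse merges a clonotype
supported by exactly one read into a clonotype with two or more reads when
their CDR3s have equal length, the same V/J, and Hamming distance at most
one — a minimal, deterministic stand-in for the quality-aware error
correction of amplicon-based tools (largest neighbor wins; ties break
lexicographically).

## Harvesting and normalization

Candidates are every primary, non-duplicate record overlapping the TCRB
window by at least one base, plus every primary unmapped record;
reverse-strand alignments are reverse-complemented back to the original
read. The RPM denominator is the count of primary records (secondary and
supplementary excluded); duplicate-flagged records are excluded by default
(`denominator = "primary-nodup"`) on the assumption that duplicates were
marked upstream, with `"primary"` available because published totals do
not always say whether they were counted before or after deduplication.
The clipped-read fraction — window reads carrying at least `min_clip`
soft/hard-clipped bases — is reported separately, as the mapping signature
of rearranged molecules forced onto the germline reference.

# The synthetic-data generator

The simulator emulates a captured tumor exome at a chosen T-cell fraction
`f`, coverage, read length, and per-base substitution error rate. It emits
`exome_len × coverage / read_length / (1 − off_target)` single-end reads
(default exome 50 Mb, off-target 0.2, the configuration of the detection
model below) drawn from three pools:

* **T-cell reads.** The total count is binomial with per-read probability
  `f × mean_footprint / exome_len`, where a clone's footprint is
  `|template| + read_length − 1` start positions; clone assignment is
  multinomial in the clone frequencies, and the start position is uniform
  over the footprint, so only the geometric fraction
  `(read_length − |CDR3| + 1) / footprint` of a clone's reads fully spans
  its junction.
* **Germline background** drawn from a contig of the unrearranged V and J
  segments separated by long spacers — deliberately included so that a
  naive V-only matcher would false-positive while the V+J caller must not.
* **Decoy background** standing in for the rest of the exome.

Clone mixtures follow a rank power law (frequency ∝ rank^−α), which
reproduces oligoclonal tumor repertoires with one parameter; α = 0 gives a
uniform repertoire. Sampled clones are always productive with distinct
junctions. No background read ever contains a clone's CDR3 (re-drawn on
collision), so simulator truth is unambiguous. Reads are single-end with
substitution errors only: mate structure and indels add nothing to the
detection logic under test. In the BAM emission, CDR3-spanning reads are
written unmapped or soft-clipped at the window start (the two signatures
the harvester must capture), germline reads map inside the window on
alternating strands, and FASTQ/BAM/manifest always contain the same reads;
identical seeds give byte-identical FASTQ.

What the generator does *not* emulate: capture-probe thermodynamics, PCR
duplicates and amplification bias, indel errors, paired-end rescue, allele
diversity within a V family, and genuinely mappable rearranged reads that
exome aligners sometimes place with partial matches. Green tests therefore
demonstrate the correctness of the detection logic and count statistics
under the stated model, not performance on any particular real capture
kit.

# The detection-sensitivity model

The expected CDR3 RPM at T-cell fraction `f` is

```
E[RPM] = f × s × (cdr3_len / exome_len) × 1e6
```

with defaults `cdr3_len` = 50 bp, `exome_len` = 50 Mb, and a bundled
detection sensitivity `s` = 0.5 that lumps together capture of rearranged
fragments (only a subset of TCRB exons have probes) and read-geometry
losses (a read must span the junction with enough flank on both sides).
Total yield at coverage `c` is `exome_len × c / read_length /
(1 − off_target)`: off-target reads inflate the denominator of RPM and the
total yield equally, so they cancel in RPM space — the only
parameterization consistent with both an expected RPM of order 10⁻¹ at
20–40% infiltration and a ~3% detection floor at 100-fold coverage. At the
defaults the minimum detectable infiltration (expected one detected read)
is 3.2% at 100-fold coverage, algebraically independent of exome length at
fixed coverage.

`monte_carlo_detection()` closes the loop: it runs the simulator and the
caller end to end and compares the frequency of detecting at least one
CDR3 read against the Poisson prediction `1 − exp(−λ)`. Because `s` is a
bundled constant while the simulator realizes geometry explicitly, the
per-clone capture probability is calibrated so that the expected number of
caller-detectable reads equals the analytic λ
(`q_c = s × cdr3_len × footprint_c / (mean_footprint ×
detectable_positions_c)`, with detectable start positions brute-force
enumerated under the caller's flank minima). The Monte-Carlo check
therefore validates the count statistics and the end-to-end pipeline, not
the bundled constant itself — which is exactly its role, since `s`
absorbs capture behavior no simulation of ours could derive. Simulations
run at a down-scaled exome: λ depends on exome length only through
coverage, so a small exome with the same coverage leaves the expected
count unchanged while keeping run times in seconds. The test suite uses
simulated exomes of 20–50 kb, coverages of 20–400, and 32–48 Monte-Carlo
replicates per grid point.

A note on stochastic test design: a 95% confidence-interval check per grid
point has a 5% false-failure rate by construction even when the model is
exact, so the grid is checked at a family-wise 5% level
(Bonferroni-adjusted per-point intervals).

# Cohort metrics

* **iDNA score**: 0 for samples with no CDR3 reads — "absence" is a
  category of its own, keeping `score = 0 ⇔ RPM = 0` exact — and deciles
  1–10 of the positive-RPM distribution otherwise, computed over the
  positive samples only, ties sharing the lower bin. With fewer than ten
  positive samples the bins degrade gracefully to proportional quantile
  bins (with a warning).
* **Diversity ratio**: clonotypes divided by CDR3 RPM, defined only for
  samples with CDR3 reads; a shallow-depth proxy for clonal diversity.
* **Clonality**: `1 − H / ln R` with `H` the Shannon entropy (natural
  log) of the clone frequencies and `R` the clone count — the de facto
  repertoire standard; a single clone scores 1 by convention. One caution:
  because the normalizer `ln R` changes with the number of clones, the
  metric is only monotone under concentration at *fixed* `R` (Schur
  concavity); comparisons across very different clone counts inherit the
  usual caveats of normalized entropy.
* **DNA/RNA classes**: D±R± by presence of CDR3 reads in each source; the
  TCRB expression value (region reads per million total) uses the same
  scale as RPM for comparability.

# Benchmarking against other detectors

`overlap_stats()` reproduces multi-tool comparisons from per-clone
evidence tables. Rescued out-of-frame evidence is encoded as a `>0`
marker (present, count unknown) and is counted as a detection under
`rescued_policy = "count"` but not under `"ignore"`; the packaged
OX1285 table needs the `count` policy to reproduce the per-tool union and
overlap fractions and the `ignore` policy to reproduce the
two-or-more-tools clone count, and the dual policy is documented in the
fixture header. "Sensitivity" (fraction of a tool's clones present in the
deep repertoire) and "specificity" (fraction shared with another tool) are
kept with their informal meanings and surfaced as overlap fractions.
Read-level matching between two detectors goes by read id when available
and falls back to exact substring recovery (both strands) when a tool does
not report ids, reporting ambiguous matches rather than assigning them.

# Numerical choices and degenerate inputs

* Alignment ties break by score, then lexicographic segment id, then read
  position — repertoires are invariant to read order and to
  reverse-complementing the input.
* `seed_k = 12` must not exceed `min_j_match`: the J flank of a junction
  read can be as short as the J minimum, and it must still be seedable.
* Clone frequencies must sum to 1 within 1e-9; clonality rejects
  non-distributions rather than renormalizing silently.
* Empty inputs: an empty candidate set yields an empty repertoire with
  RPM 0; a window with no reads makes `clipped_fraction()` warn and
  return 0; absence of a junction in a read is a `NULL` call, never an
  error.
* The toy reference generator places V anchors three codons from the 3'
  end and J anchors four codons from the 5' end, giving junctional
  trimming room on both sides while keeping every segment valid.

# Known limitations

The caller is tethered to the supplied germline segments, so rearrangements
using alleles far from the reference lose sensitivity — the same
limitation as the reference-based tools it mirrors; de novo assembly of
rearranged receptors is out of scope. Exome-depth repertoires are
shallow: most positive samples show a handful of reads and one or two
clonotypes, so diversity measures are order-of-magnitude tools, not
estimates of true clonal richness. The bundled detection sensitivity is an
empirical constant, not a mechanistic capture model.
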