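# idnaseq — immune DNA signatures from bulk tumor exomes

Bulk tumor exomes are sequenced from every cell in a specimen, including
infiltrating T cells. Each mature T cell carries a somatically rearranged
T-cell receptor beta (*TCRB*) locus whose V(D)J junction — the CDR3 —
does not exist in the germline reference, so reads spanning it surface as
soft-clipped or unmapped reads around the TCRB locus. `idnaseq` recovers
those reads and turns them into quantitative immunology: a DNA-level
measure of T-cell infiltration and a shallow view of the clonal
repertoire, from data that was never generated for immunology.

The package is aimed at cancer genomicists reanalyzing exome/RNA-seq
cohorts (e.g., TCGA-style collections) who want T-cell infiltration and
clonotype summaries without a dedicated repertoire assay.

## What it computes

For a sample with $n$ CDR3-supporting reads among $N$ total primary
reads, the normalized infiltration signal is

```
CDR3 RPM = n / N × 10⁶
```

and the cohort-level **iDNA score** is 0 for samples with no CDR3 reads
and the decile (1–10) of the positive CDR3-RPM distribution otherwise.
Clonal structure is summarized by the diversity ratio (clonotypes per
CDR3 RPM) and clonality `1 − H/ln R` (Shannon entropy over clone
frequencies). The expected signal follows the closed-form detection
model

```
E[CDR3 RPM] = f × s × (L_CDR3 / L_exome) × 10⁶
```

with `f` the T-cell fraction, `s = 0.5` a bundled detection sensitivity,
`L_CDR3 = 50` bp and `L_exome = 50` Mb; at 100-fold coverage the minimum
detectable infiltration (one expected read) is **3.2%**.

Modules: germline V/J reference handling with conserved-anchor validation
(`read_reference`, `make_toy_reference`), a VDJ read simulator with
ground-truth manifests (`sample_mixture`, `simulate_reads`), BAM
harvesting (`harvest`, `clipped_fraction`), the anchor-based CDR3 caller
(`detect_sample`, `call_cdr3`), cohort metrics (`idna_scores`,
`clonality`, `shared_clonotypes`, `classify_dna_rna`), the detection
model (`expected_cdr3_rpm`, `min_detectable_infiltration`,
`monte_carlo_detection`), and multi-detector benchmarking
(`overlap_stats` with the packaged OX1285 three-tool table). A thin CLI
lives at `exec/idna` (`idna harvest|detect|score|share|model|benchmark|simulate`).

## Worked example

Simulate a 30%-infiltrated tumor exome, harvest the TCRB window from the
BAM, and call the repertoire:

```r
library(idnaseq)

ref <- make_toy_reference(n_v = 6, n_j = 3, seed = 42)
mix <- sample_mixture(n_clones = 4, alpha = 1, ref, seed = 42)
cfg <- sim_config(t_cell_fraction = 0.3, coverage = 80,
                  error_rate = 0.001, seed = 42, exome_len = 5e4)
sim <- simulate_reads(mix, cfg, ref, bam = "tumor.bam")

cand <- harvest("tumor.bam", window = ref$locus_window, sample_id = "demo")
#> CandidateReadSet 'demo': 1981 candidate reads (1968 locus-mapped, 13 unmapped) of 50,000 total

rep <- detect_sample(cand, ref)
#> SampleRepertoire 'demo': 4 clonotypes, 19 CDR3 reads / 50,000 total = 380 RPM

rep$clonotypes[, c("cdr3_nt", "cdr3_aa", "v_id", "j_id", "read_count")]
#>                       cdr3_nt   cdr3_aa  v_id  j_id read_count
#> 1    TGCCTTTCCGTCGGAAAGCAGTTC  CLSVGKQF TRBV1 TRBJ1         11
#> 2       TGCAACTCCGGAAGCACTTTT   CNSGSTF TRBV1 TRBJ3          4
#> 3 TGCATCTTGCACTCGGAGAGCACTTTT CILHSESTF TRBV1 TRBJ3          3
#> 4    TGCCCATATCTCCTGCGCAAGTTC  CPYLLRKF TRBV6 TRBJ2          1
```

All four simulated clonotypes (true frequencies 0.48/0.24/0.16/0.12) are
recovered, with supporting read counts tracking abundance. The 380 RPM
reflects the deliberately tiny 50 kb simulated exome; at a real 50 Mb
exome the same infiltration gives the model's expected
`expected_cdr3_rpm(0.3)` = 0.15 RPM — a handful of reads per hundred
million, which is why harvesting unmapped and clipped reads matters.

The packaged three-tool comparison table reproduces the published
overlap statistics:

```r
overlap_stats(read_tool_table(), "count")
#> OverlapStats (rescued policy: count )
#>   per tool:  clonotyper=6  imseq=18  mitcr=24
#>   union 26 | in deep repertoire 15 | detected by >=2 tools 17
#>   clonotyper: in-deep 50%, shared-with-another-tool 100%
#>   imseq: in-deep 72%, shared-with-another-tool 94%
#>   mitcr: in-deep 58%, shared-with-another-tool 67%
```

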