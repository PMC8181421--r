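# atacmem

Identification and tracking of epigenetically primed chromatin in
antigen-specific memory T cells from ATAC-seq.

When naive T cells differentiate into resting memory cells, a set of
regulatory elements stays transposase-accessible without active
transcription — *primed* chromatin thought to underlie the rapid recall
response. `atacmem` is an R package implementing the full genome-wide
procedure for finding and following such elements across a
naive → memory → antigen-recall design:

* **Peak-set construction** — a local-Poisson peak caller on
  strand-separated Tn5 cut tracks, replicate concordance by intersecting
  each replicate's top 35,000 peaks, and a merged master summit set.
* **Normalization** — per-sample correction factors from the median of
  each sample's top 30,000 summit-window counts (±200 bp around summits),
  with median-of-ratios as an alternative mode.
* **Differential accessibility** — an in-package negative-binomial Wald
  test (method-of-moments dispersion with shrinkage, per-group NB mean
  MLEs with size-factor offsets, observed-information standard errors,
  Benjamini–Hochberg adjustment).
* **DHS classification** — per contrast, a peak is *up* when
  FC > 3, padj < 0.05, and its normalized count exceeds 20 in both
  replicates of the condition where it is claimed present; this yields the
  four categories mDHS (memory-gained), nDHS (naive-lost), iDHS
  (antigen-induced) and dDHS (antigen-diminished), plus stability,
  transience and cross-timepoint consistency summaries.
* **Integration** — nearest-gene assignment (summit-to-TSS), exclusive
  gene classes (mDHS-only / iDHS-only / mDHS+iDHS / dDHS-only), mean
  expression fold changes with bootstrap CIs, and primed-inducible gene
  detection (≥3-fold induced on recall *and* ≥3-fold elevated in resting
  memory).
* **Motifs and footprints** — IUPAC consensus scanning in ±100 bp summit
  windows, hypergeometric enrichment, strand-aware binomial footprint
  scores (pass at combined −log10 p ≥ 10), average cut profiles and
  2000 bp / 10 bp tag-density matrices.
* **Synthetic data** — a deterministic generator that plants all of the
  above (NB counts with condition multipliers, cut tracks with protected
  footprints, coupled expression), so every stage is tested against known
  truth.

The statistical model and all defaults are described in
`vignettes/atacmem-methods.Rmd`.

## Worked example

A complete run on a reduced synthetic design (200 peaks on 2 × 1 Mb;
seconds on a laptop):

```r
library(atacmem)
cfg <- sim_config(n_peaks = c(mDHS = 30, nDHS = 30, iDHS = 30, dDHS = 30,
                              constitutive = 80),
                  genome = c(chr1 = 1e6, chr2 = 1e6), seed = 42)
run_pipeline(cfg, outdir = "demo")
pipeline_report("demo")
```

```
atacmem run (seed 42): 200 master peaks
DHS categories: mDHS=30, nDHS=29, iDHS=30, dDHS=30
mDHS stability at 3-fold: 30 (100%)
mDHS stability at 2-fold: 30 (100%)
transient early-suppressed fraction: 0/29 (0%)
primed-inducible genes: 3/26 (12%)
mean log2FC [dDHS-only]: -1.43 (95% CI -1.67..-1.14, n=30)
mean log2FC [iDHS-only]: 1.86 (95% CI 1.55..2.12, n=26)
mean log2FC [mDHS-only]: -0.11 (95% CI -0.28..0.06, n=26)
mean log2FC [mDHS+iDHS]: 2.42 (95% CI 1.33..3.27, n=4)
top motif enrichments: ETS, RUNX, NFAT
ETS footprints passing: 27/28
truth recovery:
  mDHS sensitivity: 1.000 (30/30)
  nDHS sensitivity: 0.967 (29/30)
  iDHS sensitivity: 1.000 (30/30)
  dDHS sensitivity: 1.000 (30/30)
  constitutive false-labelling: 0.000
```

Reading the report: of the 120 planted differential peaks, 119 were
re-identified from raw cut tracks with the correct category and no
constitutive peak was mislabelled. Genes linked to both an mDHS and an
iDHS show the strongest recall induction (mean log2FC 2.42), exceeding
iDHS-only genes (1.86) — the planted priming–inducibility synergy. The
planted ETS and RUNX consensi are the top enrichments in mDHS peaks, and
27/28 footprinted ETS instances pass the protection score. Every
table the report summarizes (master BED, per-contrast results, gene
classes, enrichment, footprints) is written as plain TSV in the run
directory, along with a `manifest.json` recording all thresholds and file
checksums; a rerun with the same seed is byte-identical.

The same functions run standalone on user data at any entry point:
`read_bed()` / bedGraph cut tracks → `call_peaks_all()`,
`count_in_windows()` → `size_factors_topn()`, `nb_wald_test()` →
`classify_dhs()`, `stability_summary()` and onwards.

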