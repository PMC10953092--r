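---
title: "Methods: models, parameters and design choices in dmmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dmmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmmrkit)
```

# Scope

`dmmrkit` re-implements, as reusable and tested components, the analysis
stack used to characterize sporadic, naturally occurring colorectal cancer in
rhesus macaques — a model system in which every tumor loses MLH1/PMS2
mismatch-repair function through promoter hypermethylation rather than
mutation. The package covers microsatellite-instability (MSI) calling,
MethyLight-style methylation quantification with CIMP classification, tumor
mutational burden (TMB), SBS96 mutational spectra with signature matching,
cross-species hotspot codon mapping, methylation-aware DNA-shape analysis,
cohort statistics, and seeded synthetic-data generators. Upstream read
alignment, variant calling, copy-number segmentation and RNA-seq model
fitting are out of scope: the package consumes their tabular outputs.

# MSI calling

A locus is typed from paired healthy/tumor electropherograms of
microsatellite amplicons (panel of six rhesus loci, `msi_panel()`).

* **Peak detection** (`detect_peaks()`): a trace point is a peak if it is at
  least as intense as the trace points 1 bp to either side (polymerase
  stutter climbs toward the allele in 1-bp steps, so ladder shoulders are
  never peaks, while alleles separated by a gap stand alone) and reaches a
  fraction `rel_threshold` (default 0.10) of the trace maximum.
* **Locus call** (`call_locus()`): the tumor is unstable iff it shows a
  *novel* amplicon length — a peak farther than `tol_bp` (default 1 bp, the
  sizing resolution of chip electrophoresis) from every normal peak. Loss of
  a normal allele alone is *not* scored as instability; whether the original
  manual overlay counted allele loss is unstated, so this is a documented
  package choice, and both parameters are configurable.
* **Classification** (`classify_msi()`): 0, 1, or ≥ 2 unstable loci of 6 give
  MSS, MSI-low, MSI-high. Partial panels are classified but flagged.

# Methylation quantification and CIMP

Percent methylation from bisulfite methylation-specific qPCR follows the
MethyLight "percent of methylated reference" (PMR) convention, because the
source analysis reports percent methylation without stating its formula:

$$\%\,\mathrm{meth} = 100 \cdot 2^{-\left(\Delta Ct_\mathrm{sample} -
\Delta Ct_\mathrm{calibrator}\right)},\qquad
\Delta Ct = Ct_\mathrm{meth\ assay} - Ct_\mathrm{control\ assay}$$

where the control assay probes a CpG-free region (ACTB) to normalize
bisulfite-converted input and the calibrator is fully methylated DNA. An
alternative `"paired-normal"` mode expresses the tumor relative to its
matched normal, matching paired overlay plots; the mode is recorded in the
output. Conventions, all stated explicitly because they are convention and
not physics: replicate Cts are averaged on the Ct scale; an undetermined
methylation-specific Ct means no detectable methylated template and maps to
0 %; an undetermined control Ct invalidates the well (error, never silently
0); values above 100 % are clipped with the raw value retained.

A marker is *methylated* when tumor minus paired normal exceeds 20
percentage points (strict), a cutoff chosen in the original assay to absorb
30–80 % tumor cell content; no tumor-purity correction is applied. CIMP on
the five-marker panel (MLH1 probe 1, CACNA1G, CDKN2A, CRABP1, NEUROG1):
≤ 2 / 3 / ≥ 4 methylated markers give negative / low / high. The second MLH1
probe is confirmation-only (`dual_probe_concordance()`) and never enters the
CIMP count. Relative expression uses the standard ΔΔCt method
(`relative_expression()`).

# Mutation analytics

* **SBS96 spectrum** (`compute_spectrum()`): each SNV is assigned to one of
  96 pyrimidine-centered trinucleotide categories (COSMIC layout,
  `sbs96_contexts()`); purine-centered variants are reverse-complemented.
  Counts conserve the SNV total; contig-edge variants are skipped and
  counted in an attribute.
* **Signature matching** (`best_signature()`): cosine similarity, the
  community convention, since the original claim of resemblance states no
  metric. Ties are broken lexicographically and flagged. The packaged
  signature matrix is *synthetic* (an SBS6-like C>T-at-NCG pattern plus
  decoys); real COSMIC matrices in the same TSV schema are accepted.
* **TMB** (`compute_tmb()`): mutations per callable megabase; the numerator
  includes indels by default (SNV-only behind a flag) because the original
  per-tumor TMB provenance is unstated; `callable_mbp` is a required user
  input because the capture size is not published. TMB-high is strictly
  above 10 mut/Mbp.
* **Hotspot mapping** (`match_hotspots()`): because the published "similar
  amino acid" statistic is not precisely defined, three nested statistics
  are always reported — exact amino-acid change, same residue at the same
  codon, and any catalog entry within ± 5 codons — so any of the printed
  fractions can be compared.

# Methylation-aware DNA shape

Sequences carry symmetric CpG methylation in an extended alphabet: `M` is
5-methylcytosine and `W` the guanine paired to a methylated cytosine on the
opposite strand (`encode_methylation()`; hemimethylation is not modeled).
Shape features — minor groove width (MGW, Å), propeller twist (ProT, °),
helix twist (HelT, °), roll (°) — come from pentamer query-table lookup
(`predict_shape()`). Base-centered features take the pentamer centered on
each base (defined for positions 3..L−2, 1-based); each pentamer contributes
its two central steps, interior steps average the two covering pentamers and
boundary steps keep the single value (defined steps 2..L−3). This
aggregation is the standard sliding-pentamer convention, restated here
because the tables are consumed, not derived: deriving tables from
crystallography/NMR simulation is explicitly out of scope, and the packaged
table is a synthetic construction (`gen_shape_table()`) whose methylated
pentamers equal their demethylated twins plus declared shifts — ProT −3°,
Roll +3°, MGW/HelT 0 by default, mirroring the qualitative physics
(methylation lowers propeller twist and raises roll while barely affecting
groove width and twist). A loader (`read_shape_table()`) accepts externally
obtained real tables in the same schema; the qualitative conformance check
on real tables is optional and not part of acceptance.

Reference envelopes (`build_envelope()`) summarize a JASPAR-style aligned
binding-site set as per-position mid-rank percentiles (5/25/50/75/95) of
each feature, with a floor of 20 sites (override available). The departure
of a query profile (`departure_score()`) reports, per feature, the mean
normalized mid-rank deviation `mean(|rank − 50|/50)` and the fraction of
positions strictly outside [P5, P95]. Both are package-defined statistics —
the original work shows overlays without a score — and both components are
reported so thresholds can be chosen later. With tied reference values
(inevitable with a finite pentamer vocabulary) the mid-rank of the median
can differ from 50, so the "zero at the median" identity holds exactly only
for tie-free references; tests use tie-free constructions for that identity.
Whether JASPAR sites were flank-extended before shape prediction is
unstated; profiles of flank-extended sequences are supported by slicing the
central window.

# Cohort statistics

Spearman correlation is computed as Pearson correlation of average ranks on
pairwise-complete observations; p-values use the t approximation with n − 2
degrees of freedom (the original tool's internals are unstated), with an
exact permutation option for n ≤ 8. Constant columns and pairs with n < 3
are reported missing, never as 0. Because it is unstated whether the
original correlation p-values were multiplicity-adjusted, raw and
Benjamini–Hochberg-adjusted p-values are both reported. The
differential-expression filter applies BH across all rows and then the
|log2 FC| > 1, adjusted p < 0.05 partition.

# Synthetic data: the stated world

Generators are pure functions of (configuration, seed) and each emits a
ground-truth sidecar. Defaults encode the cohort structure being emulated,
chosen once and not revisited:

* Cohort: 16 tumor/normal pairs; MLH1 (both probes) hypermethylated in
  16/16 tumors (tumor fraction 0.55–0.9 vs normal ≤ 0.03); the other four
  markers mixed to target 5 CIMP-high, 4 CIMP-low, 7 CIMP-negative — so the
  dissociation of MLH1 status from CIMP status is a structural property of
  the generated world, not a tuned outcome.
* qPCR: perfect-doubling Ct model `Ct = intercept − log2(fraction) + N(0, σ)`
  with σ = 0.2 cycles and 2 wells per measurement; fraction 0 yields an
  undetermined Ct. Real assay efficiencies are undisclosed and not claimed.
* MSI traces: geometric stutter (ratio 0.35, 4 rungs), tumor-novel alleles
  shifted ± 2–4 bp with 60 % residual germline signal; locus-level
  instability probability is the dial that the classification invariants
  exercise at 0 and 1.
* Variants: categories drawn from declared SBS96 weights, positions uniform
  over matching genomic contexts of a random 41 %-GC genome (the GC of a
  mammalian exome neighborhood), REF always consistent with the genome.
* Promoters/motifs: a CpG-bearing consensus embedded at a recorded offset in
  a 2 kb, 55 %-GC (CpG-island-like) background, spanning the −1500..+500
  promoter scan convention.

What a green test on this world does **not** establish: concordance with the
embargoed sequencing data, real assay efficiencies or stutter chemistry, or
the published shape curves (which depend on external query tables and a
specific JASPAR release).

# Numerical choices and degenerate inputs

1-based inclusive coordinates everywhere in R (Biostrings/VCF convention).
Strict inequalities at every clinical cutoff (TMB > 10; marker delta > 20).
Signature columns renormalize only within 1e-3 of 1, else error. Envelope
percentiles use the mid-rank (type 5) definition for deterministic tie
handling. Classification boundaries (0/1/2 unstable; 2/3/4 methylated) are
tested exactly. Empty cohorts, all-zero traces, zero vectors, unknown
pentamers, undetermined control Cts, and out-of-range stages all fail loudly
with named offenders.

# Known limitations

* A known-red acceptance check: with σ = 0.2 cycles per well the
  replicate-averaged ΔΔCt has a standard deviation near 0.28 cycles, a
  ± 18 % relative error at 1 σ, so per-replicate recovery within ± 10
  percentage points cannot reach 95 % coverage for fractions ≥ 0.5
  (measured ≈ 78 % pooled). The mean over replicates does recover the truth
  (within ± 5 points at f = 0.8), which is what the generator's own oracle
  asserts. The per-replicate criterion is asserted as stated and fails.
* The hand-transcribed staging table computes a mean age at arrival of
  20.3292 y, printed as 20.32 (truncated); and the table's 15 biopsy rows
  disagree with the text's 14/24 — the table is shipped as printed.
* The flattened published variant table is column-ambiguous in two cells;
  the shipped transcription satisfies every printed per-gene count and is
  flagged in the fixture header.
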