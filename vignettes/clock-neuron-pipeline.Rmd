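---
title: "Detecting cycling transcripts and annotating clock-neuron clusters"
author: "clockcells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cycling transcripts and annotating clock-neuron clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockcells)
```

## The problem

The ~150 clock neurons of the adult *Drosophila* brain keep circadian time
as a heterogeneous network of anatomically defined classes (s-LNv, l-LNv,
LNd, LPN, DN1a, DN1p, DN2, DN3).  Single-cell RNA-seq of these neurons
sampled around the clock — six timepoints spaced 4 h apart, under a 12:12
light:dark cycle (LD) and in constant darkness (DD), with two replicate
plates per condition — makes it possible to ask, per neuron class, which
transcripts oscillate with a 24-h period, and to assign transcriptomic
clusters to anatomical classes from marker expression alone.

`clockcells` implements the post-alignment arm of such a study: cell
quality control, normalization, per-cluster rhythmicity detection, marker
detection, and rule-based anatomical annotation.  Upstream steps (alignment,
UMI counting, integration, clustering) are out of scope: the pipeline
consumes a UMI count matrix, per-cell metadata and a cluster assignment.
Because the interesting guarantees are about *recovering known signal*, the
package ships a first-class synthetic-data module whose ground-truth ledger
drives every test.

## Cell quality control

A cell passes QC when all three criteria hold, with the failing side
exclusive (so boundary values are kept):

* detected genes (at least one UMI) in `[1000, 6000]`;
* total UMIs in `[6000, 75000]`;
* expression entropy at least 5.5 nats.

Entropy here is the Shannon entropy of the cell's gene-frequency
distribution, $H = -\sum_g p_g \ln p_g$ with $p_g$ the fraction of the
cell's UMIs in gene $g$, computed on raw counts because filtering precedes
normalization.  A cell spreading its UMIs over $G$ genes equally scores
$\ln G$ — about 7.9 nats for a typical 2,600-gene cell, comfortably above
the 5.5 cutoff, while an empty-well-like cell dominated by a handful of
genes falls far below it.  We note the cutoff's unit and normalization are
a deliberate reading: an *unnormalized* count-weighted form would sit in
the thousands and could not discriminate at 5.5, so the frequency-weighted
entropy in nats is the only self-consistent interpretation; both the
formula and the cutoff are exposed as parameters.

Counts are then normalized to TP10K (transcripts per 10,000): each cell's
counts scaled to sum to $10^4$.  Pseudo-bulk profiles are plain group means
of TP10K over cells, and cluster similarity is the Pearson correlation of
$\ln(\mathrm{TP10K}+1)$ profiles.

## Rhythmicity detection

Per cluster and condition, every gene passing a detectability floor
(expressed in at least 5% of the stratum's cells, configurable) is scored
four ways; all four gates must pass for a "cycler" call:

1. **JTK q-value < 0.05.** The JTK statistic treats every cell as a
   replicate of its timepoint: for each candidate peak phase
   $\varphi \in \{0, 4, \dots, 20\}$ h, the tie-corrected Kendall
   correlation $\tau_b$ between per-cell expression and the reference
   $\cos(2\pi(t-\varphi)/24)$ is computed, and the statistic is
   $T = \max_\varphi \tau_b(\varphi)$.  Significance comes from a
   permutation null — random reassignment of timepoint labels to cells,
   $p = (\#\{T^{perm} \ge T\} + 1)/(B+1)$ — rather than Harding's
   normal approximation: with hundreds of tied, zero-inflated cells the
   approximation is unreliable, while permutation is exact in expectation
   under any tie structure, and taking the max over phases absorbs the
   phase scan without a multiplicity factor.  q-values are
   Benjamini–Hochberg within each cluster × condition stratum.  The
   permutation engine runs in compiled code; because the cosine reference
   takes one value per timepoint, the Kendall numerator decomposes over
   timepoint-group pairs and each permutation costs
   $O(T \cdot K)$ rather than $O(n^2)$.
2. **F24 > 0.5.** Cells at each timepoint are randomly split into two
   halves (a seeded, balanced partition shared by all genes, mirroring how
   two pseudo-replicates are built for Fourier analysis) and each
   half-series of timepoint means is scored by the fraction of its non-DC
   spectral power at the 24-h frequency,
   $F_{24} = 2|F_1|^2 / (2|F_1|^2 + 2|F_2|^2 + |F_3|^2)$
   (conjugate bins folded; the Nyquist bin counts once), the two scores
   averaged.  A pure 24-h cosine scores exactly 1, a constant series 0,
   and iid noise 0.4 in expectation — the 24-h component's share (2) of
   the five non-DC degrees of freedom of a six-point series.  An
   alternative that concatenates the halves into one two-cycle series is
   available behind `f24_method = "concatenated"`; the averaged form is
   the default because the halves are exchangeable replicates of the same
   cycle, not consecutive days.
3. **Amplitude ≥ 1.5.** Peak over trough of the timepoint-mean TP10K
   profile (all cells, not the pseudo-replicate halves).  A zero trough
   yields an infinite sentinel amplitude; such genes pass the amplitude
   gate if and only if they meet the expression requirement, so sparse
   genes are judged on expression, not on a division by zero.
4. **Peak ≥ 0.8 TP10K.** Maximal timepoint-mean expression.

Phases are reported two ways: the argmax phase of the JTK scan (4-h
resolution, ties broken toward the smaller offset) and a cosinor estimate —
least squares of $a + b\cos\omega t + c\sin\omega t$, acrophase
$\hat\varphi = \frac{24}{2\pi}\mathrm{atan2}(c, b) \bmod 24$ — which is
continuous and is what the DD-antiphase criterion uses.  Both are
equivariant under clock shifts of the timepoint labels.

Per-gene permutation streams are seeded from a hash of the gene name, so
results are independent of gene order and reproducible gene-by-gene.

## Marker detection

One-vs-rest differential expression per cluster: a two-sided Wilcoxon
rank-sum test (normal approximation with tie correction) on
$\ln(\mathrm{TP10K}+1)$, Bonferroni correction within each cluster's tested
family, and a natural-scale fold-change gate
$(\bar x_{in} + 0.1)/(\bar x_{out} + 0.1) > 1.25$ with both gates strict.
The covariate-adjusted negative-binomial model used by integrated
single-cell toolchains is deliberately replaced by the rank-sum test: this
package's target is recovery of truly enriched genes on data with unknown
dispersion, where the rank statistic is robust and assumption-free.  Genes
expressed in fewer than 10% of both populations are not tested (and do not
enter the Bonferroni family): the normal approximation is badly
anticonservative for a gene seen in a handful of cells — its exact tail
probability can exceed the approximation by four orders of magnitude — so
near-undetected genes are excluded, matching standard practice in
single-cell marker detection.

`dot_stats()` reports the standard dot-plot pair per gene × cluster: the
fraction of cells with nonzero counts and the mean TP10K.

## Anatomical annotation

Identity assignment is a plain, user-editable rule table evaluated in
priority order; the first satisfied rule wins.  "Positive" means at least
50% of the cluster's cells express the gene and mean expression is at
least 1 TP10K (inclusive, configurable per call).  The default table
encodes the published marker logic of the fly clock network:

| priority | rule | identity |
|---|---|---|
| 1 | AstA⁺ ∧ AstC⁺ | LPN |
| 2 | Pdf⁺ ∧ sNPF⁺ | s-LNv |
| 3 | Pdf⁺ ∧ sNPF⁻ | l-LNv |
| 4 | ITP⁺ | LN_ITP |
| 5 | Trissin⁺ | LNd_Trissin |
| 6 | AstC-R2⁺ ∧ NPF⁺ | LNd_NPF |
| 7 | AstC-R2⁺ ∧ NPF⁻ | LNd |
| 8 | CCHa1⁺ | DN1a |
| 9 | tim antiphase in DD | DN2 |
| 10 | CNMa⁺ ∧ (gl⁺ ∨ Dh31⁺) | DN1p_CNMa |
| 11–12 | gl⁺, or Dh31⁺ ∧ CNMa⁺ | DN1p |
| 13 | correlation fallback | DN3 |

Three special behaviors:

* **NPF is read from LD cells only** — NPF rises broadly in DD, so its
  positivity for cluster classification is evaluated on the LD dot table.
* **The DN2 rule is not a marker rule.**  DN2s are the one class whose
  clock runs antiphase in constant darkness: the rule fires when the
  cosinor phases of *tim* in LD and DD differ by 12 ± 4 h (circularly),
  with two guards — a relative-amplitude floor (0.1) so non-rhythmic
  profiles never fire, and a mesor floor (1 TP10K) so the meaningless
  phase of a barely expressed gene never fires either.
* **The fallback labels marker-poor clusters DN3**, optionally inheriting
  the identity of their best-correlated already-annotated cluster when
  that identity is fallback-eligible.  This mirrors how DN3s — missing all
  canonical markers — are identified in practice.  Clusters that real
  studies resolve with external evidence (e.g. a gl-negative DN1p
  identified via a reporter line) cannot be derived from expression rules
  and will land in the fallback; the rule table is data, so users with
  such evidence simply edit it.

`clock_gene_screen()` supports the upstream judgement of which clusters are
clock neurons at all: mean *tim*/*vri* expression, *tim* cosinor amplitude
and phase, and *Clk* near its morning peak, per cluster.

## The synthetic-data generator

`simulate_scdata()` draws negative-binomial UMI counts
($\mathrm{Var} = \mu + \phi\mu^2$, shared overdispersion $\phi$) around a
per-cluster × condition × timepoint mean structure:

* background gene abundances are lognormal (sdlog 1.9), rescaled so each
  expected TP10K profile sums to ~$10^4$; library sizes are lognormal
  (CV 0.35) around 20,000 UMIs — together these reproduce the target
  regime of roughly 2,400–2,600 detected genes per cell and cell entropy
  well above the QC cutoff;
* a planted cycler multiplies its baseline by
  $1 + \frac{f-1}{f+1}\cos\frac{2\pi(t-\varphi)}{24}$, so the noise-free
  peak/trough ratio is exactly its fold amplitude $f$ and the mesor is its
  baseline; DD reuses the LD phase except `antiphase_in_DD` cyclers,
  which shift by 12 h;
* a planted marker multiplies a low out-of-cluster baseline
  (default 0.1 TP10K) by its fold enrichment in its clusters, with a
  per-cell Bernoulli expressing fraction;
* planted QC violators (too few genes, too few/many UMIs, low entropy)
  and Poisson-leakage empty wells emulate the failure modes the filter
  must catch;
* everything planted is recorded in a ground-truth ledger
  (`truth$cell_labels`, `cyclers`, `markers`, `identities`, `bad_cells`).

`sim_clock_panel()` assembles the full 17-cluster study: unequal cluster
sizes (24–600 cells across the sampling design, ~2,800 cells total), the
marker combinations of the table above, one unique marker per cluster,
core clock genes cycling with an evening *tim* peak (ZT14), one
antiphase-in-DD cluster (the DN2 analogue), and one *tim*-poor cluster so
the clock-gene screen has a negative control.

What the generator does *not* emulate — and hence what passing tests do
not certify on real data: batch and plate effects, ambient RNA and
doublets, gene–gene correlation beyond the planted structure, mean–variance
relationships beyond a single shared dispersion, and uncertainty in the
cluster assignment itself (labels are taken as given).  The paper-scale
headline numbers of a real study (thousands of cells passing QC, the
percentage of all transcripts cycling) depend on the deposited dataset and
on the upstream clustering and are deliberately not regenerated here.

## Numerical choices and edge cases

* Permutation p-values use the add-one estimator, so the minimum
  attainable p is $1/(B+1)$; `n_permutations` defaults to 20,000 (tests
  and the acceptance script use 1,000–2,000, which bounds the minimum
  q-value well below the 0.05 gate at their problem sizes).
* Constant genes: JTK returns $p = 1$ with an undefined phase; F24 of a
  constant series is defined 0; a constant gene can never be a cycler.
* Reference ties (cosine values equal across timepoints) are handled by
  the tau-b denominator per phase; degenerate phases are skipped.
* All-zero cells have entropy 0 by convention and fail QC on the UMI
  floor; zero-total cells are a hard error in TP10K normalization.
* Pseudo-replicate splits at a single-cell timepoint reuse the cell in
  both halves with a warning rather than failing the stratum.
* JTK phase ties break toward the smaller offset; a peak planted midway
  between two grid offsets (e.g. 14 h against a 12/16 grid) resolves to
  the smaller one, still within the 2-h grid resolution.
* The fold-change pseudocount (0.1 TP10K) keeps ratios finite for
  undetected out-groups without drowning genuine enrichment.

## Problem sizes used in the tests

The shipped suite exercises: a 100-cell QC fixture (90 conforming, 10
planted violators), a 500-gene × 120-cell permutation-null calibration, a
1,000-gene × 300-cell power fixture (30 strong cyclers, 10 low-peak
cyclers), a 400-gene × 600-cell phase-recovery fixture over all six grid
phases, the full ~2,800-cell panel for markers and annotation, and a
quarter-scale panel for the end-to-end determinism check.  These sizes were
chosen as the smallest at which the binomial error bands of the measured
rates (type-I error, sensitivity, false-positive fraction) are tight enough
to be meaningful.

## Known limitations

* The JTK permutation null assumes cells are exchangeable within a
  cluster × condition; plate effects would violate this and are neither
  simulated nor corrected.
* The rank-sum marker test ignores covariates (time, batch); strongly
  cycling genes can appear as markers of clusters where they are
  cluster-restricted — in validation they are scored against the planted
  truth, not treated as background.
* Amplitude is a ratio of noisy timepoint means: for genes near the
  detection limit its sampling error is large, which is why the expression
  gate, not the amplitude gate, carries genes with zero troughs.
* Period is fixed at 24 h — appropriate for a 6 × 4 h design; there is no
  multi-period scan and no support for uneven sampling.
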