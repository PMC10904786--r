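---
title: "Models and methods behind bdnascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bdnascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdnascreen)
```

# The screening problem

Pooled barcoded screening asks a simple question at scale: when dozens of
lipid nanoparticle (LNP) formulations are injected into the same animal as a
single pool, which formulations accumulate preferentially in which organ?
Each formulation carries a short barcoded DNA oligo (b-DNA) with a
formulation-identifying barcode and a unique molecular identifier (UMI).
After systemic administration, organs are harvested, b-DNA is extracted,
PCR-amplified and deep sequenced. Comparing each barcode's within-tissue
abundance to its abundance in the uninjected pool ("basemean" normalization)
reveals organ tropism — typically with five organs (heart, liver, spleen,
lung, kidney) across a cohort of five mice, a 96-formulation pool, and a
spiked-in naked (unencapsulated) b-DNA as a negative control.

`bdnascreen` implements this analysis end to end, together with a
ground-truthed simulator of the whole measurement chain and a
structure–activity (SAR) module for the combinatorial cationic degradable
(CAD) lipid library behind the formulations.

# The generative model

`biodistribution_model()` states the world the simulator draws from:

* **Pool composition.** Barcode $b$ has pool fraction $f_b$ (default
  uniform over the whitelist, including the naked control).
* **Tropism.** A barcode × organ matrix of multiplicative affinities
  $a_{bo} > 0$, all 1 under neutrality. The expected pre-PCR molecule count
  for barcode $b$ in organ $o$ of one mouse is
  $$\lambda_{bo} = M \cdot \frac{f_b\,a_{bo}}{\sum_{b'} f_{b'}\,a_{b'o}}
    \cdot e^{\varepsilon},\qquad
    \varepsilon \sim \mathcal N(0, \sigma_m^2),$$
  realized as a Poisson draw. $M$ is `molecules_per_organ` (default
  $2\times10^5$) and $\sigma_m$ (`mouse_sd`, default 0.3) captures
  biological mouse-to-mouse variability on the log scale. Note the
  renormalization: planting an 8-fold lung affinity on one barcode at
  $f = 1/96$ yields an expected lung fraction of $8/103 \approx 0.078$, not
  $8/96$ — enrichment of one member depletes all others.
* **UMI attachment.** Each captured molecule receives one UMI uniformly at
  random over $4^{L_u}$ ($L_u = 8$ by default), *before* amplification, so
  UMI collapsing estimates molecules.
* **PCR.** Each copy duplicates independently with probability
  `pcr_efficiency` (default 0.9) in each of `pcr_cycles` (default 16)
  rounds — a branching process without chimera or jackpot effects
  (a documented simplification).
* **Sequencing.** `reads_per_sample` reads (default $2M$) are drawn from
  the amplified pool with probability proportional to copy number; each
  read is `prefix + barcode + UMI + suffix` with i.i.d. per-base
  substitution errors at `seq_error_rate` (default $10^{-3}$). Qualities
  are constant `"I"` and nothing downstream is quality-aware. Indels are
  not modelled; extraction is positional.

The default read layout (20 nt constant prefix, 8 nt barcode, 8 nt UMI,
20 nt constant suffix) is a declared convention of this package — the real
assay's oligo design is vendor- and study-specific — and every piece of it
is configurable through `read_layout()` and recorded in run metadata.

**Seeding.** One root seed; child seeds for the whitelist, the model, and
each sample are derived by a fixed affine counter scheme
(`child_seed()` in the sources), so outputs are byte-identical across runs
and independent of evaluation order.

## What the simulator does not emulate

Serum protein corona and particle chemistry, dose–response, PCR chimeras
and amplification jackpots, indels, quality-score structure, index
hopping/demultiplexing, and any functional readout (mRNA expression,
luminescence, cell-type tropism). A green recovery test therefore
establishes that the *statistical pipeline* recovers planted compositional
enrichment through the barcode/UMI/PCR/error channel — not that any
particular chemistry is lung-tropic.

# Quantification

Per sample: positional extraction (prefix anchor allows ≤ 2 mismatches, an
`N` counts as a mismatch), mismatch-tolerant whitelist assignment (exact
match wins; otherwise the unique entry within Hamming distance 1;
equidistant hits are discarded as ambiguous rather than randomly assigned),
then directional UMI collapse per barcode: distinct UMIs are nodes with
read counts, with an edge $u \to v$ iff $\mathrm{Hamming}(u,v) = 1$ and
$c_u \ge 2c_v - 1$; nodes are visited by decreasing count (lexicographic
tie-break for determinism) and each unvisited node seeds one molecule,
absorbing everything reachable. A `unique` (distinct-UMI) method is kept
for comparison; directional ≤ unique always holds.

Whitelists designed with `design_whitelist()` guarantee a minimum pairwise
Hamming distance of 3 (rejection sampling, homopolymer runs > 3 rejected),
which makes 1-mismatch correction unambiguous ($d_{\min} \ge 2\cdot 1+1$).

Two subtleties worth knowing:

* The directional rule is *not* invariant to duplicating every read:
  doubling all counts turns borderline $c_u = 2c_v - 1$ edges off. That is
  a property of the established scheme itself; the distinct-UMI count is
  exactly invariant and is the one asserted for duplication idempotence.
* With ~2,000 molecules per barcode in a $4^8$ UMI space, random Hamming-1
  UMI pairs are common enough that the directional method merges an
  appreciable fraction of true molecules. This deflates absolute molecule
  counts roughly uniformly across barcodes and cancels in the
  fraction-based enrichment statistics.

# Enrichment statistics

Counts become within-sample fractions with a pseudocount of 0.5 (sensitivity
switch available), then normalized accumulation = tissue fraction / pool
fraction, the pool fraction being the mean over uninjected-pool replicates.
The per-(barcode, organ) log2 fold-change is the **median over mice** of
log2 normalized accumulation — robust to a single outlier mouse.

Significance uses a two-sided Wilcoxon rank-sum test. The comparison group
is genuinely ambiguous in this kind of assay; the default `one_vs_rest`
tests barcode $b$'s per-mouse values against all other (non-control)
barcodes' per-mouse values within the organ, which is always feasible with
$n = 5$ mice. `vs_pool_replicates` (tissue fractions against pool-replicate
fractions) is available when ≥ 3 pool replicates exist. The exact
permutation null is used when $n + m \le 20$ without ties (two-sided by
doubling the smaller tail, capped at 1); otherwise the normal approximation
with tie and continuity corrections. Benjamini–Hochberg adjustment is
applied per organ across barcodes (matching per-organ volcano panels; a
global switch exists). The naked control is kept in every denominator,
reported with its own record, but excluded from BH and from candidate
calling.

`classify_tropism()` calls a barcode a candidate for the organ of interest
iff it is enriched there (log2 FC ≥ 1 and $q \le 0.05$ by default) and not
enriched in any off-target organ (liver and spleen by default). The
off-target veto makes the candidate set deliberately *non*-monotone in the
thresholds: a stricter fold-change bar can release a liver veto and admit a
barcode. The monotonicity property holds, and is tested, for the pure
enrichment rule.

# Numerical and design choices

* **Hit calling (SAR).** Replicate RLU values are aggregated by mean
  (configurable to median) and compared strictly (`> 100`). The default
  "relative hit rate" denominator is the whole library, so rates across
  the levels of one feature partition the overall hit rate; a within-group
  denominator is available. The per-core secondary-amine annotation is
  registry data shipped as an editable synthetic default.
* **PCR sampling.** Per-molecule copy trajectories are i.i.d. and Markov,
  so the first nine cycles are drawn in one vectorized step from the exact
  copy-number distribution (computed by convolving binomials) —
  distribution-identical to simulating them cycle by cycle. Later cycles
  use exact binomial draws while the per-cycle variance is ≤ 25 and a
  clamped normal approximation above that; the approximation error is
  orders of magnitude below the depth-subsampling noise. Together these
  keep multi-seed calibration runs tractable.
* **Calibration at scale.** The planted-recovery acceptance check runs the
  full read-level pipeline on all 10 seeds (via the fused per-sample
  driver `simulate_and_quantify()`, seed-identical to writing and
  re-reading FASTQ). The 20-seed neutral null check runs at the
  molecule-count level: under neutrality the read channel is
  barcode-symmetric and cannot create enrichment, and 20 read-level seeds
  would not fit a desk-scale time budget.
* **Degenerate inputs.** All-zero samples are excluded with a warning;
  empty FASTQ gives a zero column with QC; an empty UMI set collapses to
  0; capacity-infeasible whitelist requests fail fast with a clear error.

# Worked example

```{r example, eval = FALSE}
wl <- design_whitelist(n = 96, barcode_len = 8, min_dist = 3, seed = 7)
aff <- plant_tropism(wl, sprintf("BC%03d", 1:10), "lung", 8)
model <- biodistribution_model(wl, organ_affinity = aff, seed = 1)
sq <- simulate_and_quantify(model, n_mice = 5)
norm <- normalize_to_pool(normalize_within_sample(sq$counts))
rec <- enrichment_analysis(norm)
classify_tropism(rec)
```

On this configuration the candidate set equals the ten planted barcodes;
the same computation runs inside `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which are the package's only sources of empirical
claims.

# Known limitations

* One-vs-rest significance ranks each barcode against the rest of the
  pool, so a pool where *most* members share a tropism would mask itself;
  the pool-replicate comparison is the escape hatch.
* The simulator's log-normal mouse effect is independent per (mouse,
  barcode, organ); correlated per-mouse capture efficiency (which pool
  normalization would absorb) is not modelled separately.
* Candidate thresholds are configuration, not biology; the package makes
  no claim that any specific threshold reproduces a published candidate
  count.
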