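---
title: "Methods: codon occupancy profiles and elongation-disruption waves"
author: "ribowaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon occupancy profiles and elongation-disruption waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribowaves)
```

## The problem

Ribosome profiling reads out the positions of translating ribosomes as
~28-nt nuclease-protected footprints. If cells are flash-frozen so that
elongation stops instantly, the expected footprint density over a codon is
proportional to the mean time a ribosome spends with that codon in its
A-site, so per-codon "occupancies" estimate relative decoding times.
Translation inhibitors such as cycloheximide (CHX), however, are often added
to the culture minutes before harvesting. If ribosomes keep elongating after
the drug arrives — but with codon-specific rates that differ from the
undisturbed ones — then every measured occupancy reflects the drug-modified
dynamics, and the relaxation from the old to the new steady state is
imprinted on the data as transient *waves* of excess or depleted density
downstream of each codon identity.

`ribowaves` implements the complete analysis chain for this phenomenon:
footprint-to-A-site assignment, per-gene relative enrichments, per-codon
offset profiles, wave-area quantification and its conservation test against
tRNA-binding-site changes, corrected aggregate enrichments, a stochastic
elongation simulator, an analytic relaxation model, and a synthetic-data
generator so that every stage is testable without external sequencing data.

## Model of elongation

A ribosome with codon $c$ in its A-site waits an exponentially distributed
time with mean dwell $\tau_c$ (rate $k_c = 1/\tau_c$) before advancing one
codon. Initiation is a Poisson process with per-gene rate $J$; termination
at the stop codon is instantaneous. With steric exclusion disabled,
particles are independent and the open-boundary steady state is exact:

$$\rho_i \;=\; J\,\tau_{c(i)}.$$

All simulation times are in *mean-dwell units* (mean dwell $\equiv 1$ over
codon usage); to express a duration in seconds one would multiply by the
natural per-codon elongation time (roughly $1/7$–$1/9$ s at 7–9 aa/s), which
the package deliberately does not hard-code.

Two perturbation models are provided:

* **Continued elongation with switched rates** (`simulate_rate_switch()`):
  at $t = 0$ every codon's dwell switches from $\tau^{\mathrm{pre}}_c$ to
  $\tau^{\mathrm{post}}_c$ and elongation continues for a duration $T$
  before the snapshot. The initial condition ($\rho_i = J\tau^{\mathrm{pre}}$)
  is out of equilibrium under the new rates; the excess
  $J(\tau^{\mathrm{pre}}_c - \tau^{\mathrm{post}}_c)$ stored at each codon
  travels downstream, spreading as it goes.
* **Instantaneous arrest** (`simulate_exponential_arrest()`): each ribosome
  elongates under *unchanged* rates until its own exponential arrest time,
  then freezes. Because the position of a stationary Markov process at an
  independent random time is still stationary, this null model predicts no
  waves and no occupancy changes — the package reproduces that prediction,
  which is what rules it out as an explanation for the observed data.

### Analytic relaxation model

`evolve_density()` integrates the master equation of the independent-particle
model,

$$\frac{d\rho_i}{dt} = k_{i-1}\rho_{i-1} - k_i\rho_i, \qquad
  \rho_1' = J - k_1\rho_1,$$

from the old steady state with `deSolve::lsoda` (relative tolerance
$10^{-8}$, absolute $10^{-12}$). When only the initial condition is
perturbed and the downstream rates are uniform at $k_f$, the excess packet
at time $t$ is exactly the Poisson($k_f t$) displacement kernel, so its
centroid advances as $k_f t$ and its width grows as $\sqrt{k_f t}$ — the
package's wave summaries are tested against this closed form, and the
stochastic simulator against the ODE (centroid agreement within 5%).

### Simulation engines

With `exclusion_footprint = 0` (the default) the stationary law is known in
closed form, so `simulate_steady_state()` draws snapshots directly from it
(a perfect sampler); transient evolution after a rate switch or under
arrest is always a genuine per-ribosome exponential jump process, including
Poisson-distributed new initiations during the window at the stationary
flux. An exact event-driven (Gillespie) engine is also provided; it is the
only option when steric exclusion is enabled (`exclusion_footprint > 0`,
default 10 codons when used) and serves in the test suite as the
non-circular dynamic oracle for the stationary law. The arrest model does
not inject new ribosomes after drug arrival: its defining snapshot is taken
"after all ribosomes arrested", which an ever-initiating system never
reaches. Exclusion-aware (TASEP) analytics and collision-dependent kinetics
are out of scope.

## From footprints to statistics

**A-site assignment.** Reads of length 28/29 nt are assigned to the
in-frame codon closest to the nucleotide at 0-based offset +15 from the 5'
end; length 30 uses +16. "Closest" is formalized as nearest codon start:
in-codon distances 0 and 1 round down, distance 2 rounds up (no ties are
possible over a 3-nt period). A canonical 28-nt read starting at CDS
position 0 therefore maps to the sixth codon. Other lengths are rejected
and tallied — the library preparations behind such data select 27–29 nt
fragments, but no offset rule is defined for 27-mers, so they are counted,
not guessed at. Retained plus rejected counts always reconcile with the
input.

**Relative enrichment.** Within each gene, counts at interior positions are
divided by their interior mean, so the included-position mean is exactly 1
and expression differences between genes cancel. The first and last
`edge_exclusion` codons are excluded: 90 by default (density near CDS ends
has poorly understood structure), raised to 200 whenever downstream wave
areas are computed, because composition biases near gene starts accumulate
when enrichments are summed over a wide offset range. Whether the
normalizing mean should use the full CDS or only the trimmed interior is
genuinely open; the package uses the interior only, keeping the mean-1
invariant exact on the positions that enter every downstream statistic.

**Offset profiles.** $E[X, d]$ is the mean relative enrichment at included
positions exactly $d$ codons downstream ($+$) or upstream ($-$) of an
occurrence of codon identity $X$, with both the position and the anchor
inside the inclusion mask. Offsets 0/+1/+2 are the A-, P- and E-site
occupancies. The optimized implementation is tested for exact equality
against a literal triple loop.

**Wave analysis.** For each codon, `wave_analysis()` computes
$\Delta\mathrm{bind} = \sum_{d \in \{0,1,2\}} (E_{\mathrm{test}} -
E_{\mathrm{ref}})$ and the downstream area
$\sum_{d \in [d_{lo}, d_{hi}]} (E_{\mathrm{test}} - E_{\mathrm{ref}})$.
If downstream peaks are conserved waves, area $= -\Delta\mathrm{bind}$ and
the OLS regression across codons has slope $-1$. The *corrected aggregate
enrichment* (CAE) adds the wave area back to the summed binding-site
enrichments, estimating the codon's total decode-time signature before the
perturbation. Window presets: 6–65 for matched pairs, 7–90 for
deletion-strain style comparisons; $d_{lo} \ge 3$ is enforced so the window
can never overlap the binding sites. A robustness flag excludes named
codons (e.g. the few extreme shifters) from the regression.

**tAI.** `compute_tai()` builds the tRNA adaptation index from genomic tRNA
copy numbers with penalties for wobble codon–anticodon pairings,
$W_X = \sum_a (1 - s) \cdot \mathrm{tGCN}_a$, normalized to $\max W = 1$.
The shipped default penalties are the conventional empirical values
(Watson–Crick 0; G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, treating
anticodon A as inosine); they are an input table, not a constant of the
method, and the toy tests use synthetic penalty schemes.

## The synthetic-data generator

`generate_transcriptome()` draws genes of 450–550 sense codons (uniform
lengths, i.i.d. codons). The length default leaves a usable interior after
the 200-codon edge exclusion without requiring genome-scale data.
`generate_rate_scheme()` anchors pre-switch dwells to $1/\mathrm{tAI}$ with
lognormal noise and mirrors their centred log-values by an
`anticorrelation` coefficient to produce the post-switch regime; both
tables are normalized to mean dwell 1. `generate_experiment_pair()` then
yields a matched reference/perturbed pair of 28-nt read sets whose A-site
assignment recovers the simulated positions exactly on interior positions.

Study conditions used by the acceptance analyses (chosen once as realistic
desk-scale analogues of the real study designs): 200 genes, synthetic tAI
log-uniform on $[0.1, 1]$ (an order-of-magnitude spread, as in real
genomes), `anticorrelation = -1`, `noise_sd = 0.25`, continued elongation
for 15 mean-dwell units, $10^6$ footprints per sample. For the
duration-proportionality analysis the two pretreatment durations are 18 and
8 mean-dwell units — the stated 9:4 ratio, scaled so that the measurement
window (offsets $\ge 3$, skipping the binding sites) truncates neither
wave's left tail (a Poisson(4) packet has ~24% of its mass below offset 3;
Poisson(8) only ~1.4%).

What the generator does *not* emulate: UTRs, uneven nuclease digestion,
ligation and amplification biases, multi-mapping, non-uniform codon usage
along genes, P-/E-site dwell contributions, and ribosome collisions under
exclusion. Passing tests on synthetic data therefore validate the
statistical machinery and the wave model's internal consistency, not the
biases of any particular real library.

## Numerical and design choices

* **Windows for corrected aggregates.** With unit-baseline CAE the
  downstream sum is taken over the offsets the wave actually occupies
  (6–65 for a 15-unit switch). Per-gene interior normalization makes each
  anchor's excess come at the expense of its gene's other interior
  positions, a bias of relative size (window width)/(interior length);
  extending the window to 90 on 50–150-codon interiors mostly adds this
  bias plus sparsely-populated strata. In matched-pair analyses the bias
  cancels exactly between the two profiles, which is why the conservation
  regression tolerates wide windows.
* **Peak localization.** `peak_center()` is the excess-weighted centroid of
  the positive part of $E - \mathrm{baseline}$. Over a wide window,
  rectified sampling noise pulls the centroid toward the window midpoint,
  so `support = "contiguous"` (the positive run containing the maximum) is
  used for localization; the default remains the full window.
* **Determinism.** Every stochastic function takes a seed and restores the
  caller's RNG state; child streams are derived by hashing the master seed
  with a stream label, so adding a stage never perturbs another stage's
  draws. Identical inputs and seed give bit-identical outputs.
* **UPGMA.** Average-linkage clustering on Euclidean distances between
  correlation-matrix rows; rows are ordered lexicographically first so tie
  handling is platform-independent.
* **Degenerate inputs.** Genes with empty interiors or fewer interior reads
  than `min_included_reads` (default 1) are dropped and logged; empty
  offset strata carry $n = 0$ and undefined $E$; all-zero excess makes
  wave summaries and peak centers flagged as undefined rather than NaN.

## Problem sizes and what the tests show

The unit suite runs toy genes (3–300 codons) against closed forms, brute
force, and the event-driven engine; the end-to-end checks run the full
desk-scale conditions above ($10^6$ footprints per sample), where the
conservation regression returns slope $\approx -1$ (within $\pm 0.1$) with
$r^2 \approx 0.85$, raw perturbed A-site occupancies rank-correlate
*negatively* with $1/\mathrm{tAI}$ while corrected aggregate enrichments
restore the positive correlation, arrest-null occupancies stay within
4 SE of the steady state with flat downstream profiles, and doubling the
continued-elongation time slightly more than doubles peak centers. The
slope's tendency to run slightly steeper than $-1$ (here up to
$\approx -1.1$) is expected: wave mass still sitting at offsets 3–5 at
sampling time is counted by neither the binding sites nor the window.

## Limitations

Dwell times depend only on the A-site codon; sequence context, dicodon
effects and nascent-chain interactions are not modelled. The analytic model
and the default simulator ignore steric exclusion (the event-driven engine
supports it for robustness checks but no exclusion-aware analytics are
provided). SAM input must be aligned directly against the CDS FASTA; no
genome/spliced alignment, adapter trimming or rRNA filtering is included.
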