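---
title: "Models and methods behind peatmox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peatmox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatmox)
```

peatmox implements the computational chain used to characterise
methane-oxidizing bacteria (MOB) in Arctic peat: closed-bottle CH₄ oxidation
kinetics, absolute *pmoA* transcript quantification, *pmoA* amplicon
community processing, indicator-OTU analysis, and distance phylogenetics.
This vignette explains each model, its assumptions, the defaults and their
units, the numerical conventions, and what the synthetic-data generators do
and do not emulate.

## Closed-bottle gas mass balance

A sealed serum bottle (`bottle_spec()`) holds a headspace of volume
$V_g$ (mL) at pressure $P$ (atm, assumed 1 throughout: no overpressure data
are available for typical incubations, and injections are handled only as
volume dilution) and, for culture experiments, a liquid volume $V_l$. For
soil microcosms the peat volume is treated as negligible and $V_l = 0$, so
all CH₄ is assumed to reside in the headspace; whether pore-water CH₄ should
be added is genuinely open, and the headspace-only convention is the
configurable default.

Headspace CH₄ at mixing ratio $x$ (ppm v/v) amounts to
$n = P V_g x / (R T)$ via the ideal gas law, with
$R = 0.082057$ L·atm·mol⁻¹·K⁻¹. The dissolved concentration follows Henry's
law with a van 't Hoff temperature correction:

$$C_{aq} = k_H(T)\, p_{CH_4}, \qquad
  k_H(T) = k_{H,ref} \exp\!\left[B\left(\tfrac{1}{T} -
  \tfrac{1}{T_{ref}}\right)\right]$$

The defaults, $k_{H,ref} = 1.4\times10^{-3}$ mol·L⁻¹·atm⁻¹ at 298.15 K and
$B = 1750$ K, are mid-range literature values for CH₄ in water; they
reproduce the four benchmark dissolved concentrations (≈2 and 1.7 µM under a
0.1 % headspace at 8 and 15 °C; ≈20 and 17 µM under 1 %) to within a few per
cent. Both constants are user-configurable (`henry_params()`).

`headspace_after_injection()` assumes the injected gas mixes ideally into
the expanded gas phase, $x = 10^6 \cdot v_{inj}\,\phi / (V_g + v_{inj})$
with purity $\phi$; this reproduces the printed culture headspace series
(≈1900/5400/13,000/25,000 ppm for 0.2/0.6/1.5/3 mL of a 95 % mixture) within
10 %.

### Sampling corrections

Each measurement removes a gas aliquot (and, in culture experiments, a
medium aliquot). `apply_sampling_corrections()` uses the convention that a
gas sample drawn at uniform mixing leaves the mixing ratio unchanged while
the remaining CH₄ pool shrinks by $v_g/V_g$; medium sampling removes the
corresponding share of dissolved CH₄ (and cells) and shrinks $V_l$. Between
measurements the phases are assumed to re-equilibrate, so the gas/liquid
split of the pool is fixed by geometry and temperature, and first-order
consumption scales the pool by the measured concentration ratio. The
"oxidized" column is then defined by mass balance —
initial − removed − residual — which is exactly conserved by construction,
is zero for a constant-concentration series, and reduces to
initial − mass(t) when nothing is sampled. Note that material removed by
sampling escapes later oxidation, so this bookkeeping is an accounting
convention, not a counterfactual no-sampling trajectory.

## First-order oxidation kinetics

CH₄ consumption is modelled as first order: $C(t) = C_0 e^{-kt}$. The rate
constant is estimated by ordinary least squares of $\ln(\text{ppm})$ on time
(`fit_first_order()`); $k$ (h⁻¹) is minus the slope and the fit reports the
ordinary coefficient of determination. Conventions:

* all mixing ratios must be strictly positive (the log is otherwise
  undefined) and at least two time points are required;
* a constant series returns $k = 0$ with $R^2 = 0$ and a `degenerate` flag
  rather than an undefined $R^2$;
* negative fitted $k$ (net production) is reported as-is with a warning, not
  clamped, because production can exceed oxidation in real incubations;
* a 95 % confidence interval for $k$ from the slope's standard error is
  attached when there are more than two points.

Rates are normalised two ways. For soils, µmol·h⁻¹ is converted to µg CH₄
per g dry soil per day (×16.04 g·mol⁻¹, ×24 h·d⁻¹, ÷ dry mass from the
gravimetric water content). For cultures, rates are scaled per 10⁸ cells
using an OD₄₁₀-to-cell-count linear standard (`fit_cell_standard()`), with
negative predicted counts clamped to zero with a warning. Comparisons across
temperatures at equal *dissolved* CH₄ use `equivalent_ppm()`: the mixing
ratio at the target temperature whose dissolved concentration matches the
reference, i.e. scaled by the ratio of Henry constants (≈1.16 from 8 to
15 °C with the defaults).

## qPCR quantification

The standard curve is ordinary least squares of Cq on $\log_{10}$(copies)
over a dilution series (the emulated default spans seven decades,
7.15×10⁶ down to 7.15 copies per reaction). Replicate Cq values are averaged
per level before fitting — for balanced replication the fitted line is
identical either way. Amplification efficiency is $10^{-1/\text{slope}}-1$;
a slope of $-1/\log_{10} 2 \approx -3.32$ means perfect doubling. Curves
with non-negative slope are flagged invalid and refuse quantification.
Unknowns are inverted at their replicate-mean Cq and scaled by a
user-supplied elution-and-dilution factor (the extract-to-reaction chain is
not derivable from the assay itself, so it is an explicit argument) and by
the aliquot's dry mass. Cq values outside the standard's range are still
inverted but flagged `extrapolated`. Negative controls can be screened with
`check_negative_controls()` (non-detect or beyond a late-cycle cutoff,
default Cq 35).

## Amplicon post-processing

The filters operate on primer-trimmed reads (merging, chimera removal and
OTU clustering are upstream tools whose outputs the package consumes):

* **Quality window** — a read is discarded iff any 50-nt sliding window
  (step 1) has mean Phred below 20; reads shorter than 50 nt are judged on
  their full length.
* **Frame/stop screen** — coding amplicons must have length divisible by 3
  and no in-frame stop codon (TAA/TAG/TGA, bacterial code). The codon phase
  of primer-trimmed *pmoA* amplicons is taken as 0 by default and is
  configurable.
* **Length windows** — representative lengths must fall inside the
  primer-set windows, 465–474 nt (mb661R) or 492–495 nt (A682R). The windows
  are treated as inclusive: both bounds are multiples of 3 and are observed
  amplicon lengths, so excluding them would be inconsistent with the
  frame rule.
* **Taxonomy** — global (Needleman–Wunsch) alignment of each OTU's dominant
  sequence against every reference entry; the best score wins, percent
  identity is matches over alignment columns, and score ties fall to the
  first database entry with an explicit tie flag.

Community matrices are normalised to relative abundance per sample; OTUs
whose within-sample relative abundance is strictly below 10⁻³ are set absent
("less than a thousandth" is read as a strict inequality) and the surviving
entries renormalised, with the removed read fraction reported. The
`log_normalize()` transform maps $x > 0$ to $\log_b x + 1$ (default base 2)
and keeps zeros at zero. It is applied to whatever matrix is supplied —
counts or relative abundances; whether the original analysis transformed
counts or proportions is not determinable, so the choice is left to the
caller, and values in (0, 1) trigger a warning because they map to negative
numbers.

Denoising is not idempotent in general: renormalisation can push an entry
below the threshold on a second pass. The tests check the stable case and
the implementation reports how many entries were zeroed so crossings are
visible.

## Indicator-value analysis

For OTU $i$ and group $j$ (the two CH₄ levels; temperatures are pooled, as
community composition showed no temperature response in the motivating
system):

$$A_{ij} = \frac{\bar{x}_{ij}}{\sum_k \bar{x}_{ik}}, \qquad
  B_{ij} = \frac{\#\{x_{i\cdot} > 0 \text{ in } j\}}{n_j}, \qquad
  \mathrm{IndVal}_{ij} = A_{ij} B_{ij}$$

The statistic per OTU is the maximum over groups. Significance comes from
shuffling group labels: by default
$p = (\#\{\mathrm{IndVal}^{perm} \ge \mathrm{IndVal}^{obs}\} + 1)/(N+1)$
with $N$ = 10,000 shuffles — the add-one correction avoids $p = 0$ and is
standard Monte Carlo practice; whether the original test used $\ge$ or $>$
and any correction is not stated, so a `strict` flag switches the
comparison and an `exhaustive` mode enumerates all distinct label
arrangements (two groups) with the plain count fraction, which is what the
tests use for closed-form cases. Fixed seeds give bit-identical p-values.

Responding bioindicators are OTUs with $p < 0.01$ (uncorrected, as in the
motivating analysis), labeled by their best group. Unconditional
bioindicators combine the two grazing treatments: OTUs responding to the
same CH₄ level in both treatments ("peat soil independent"), plus OTUs
responding in one treatment while absent — zero abundance in every sample
after denoising — from the other (labeled by the treatment where they
respond).

## Distance phylogenetics

Pairwise mismatch proportions $p$ (gap/N columns excluded pairwise by
default; complete deletion by flag) are corrected with the Jukes–Cantor
transform $d = -\tfrac34 \ln(1 - \tfrac43 p)$; pairs at $p \ge 0.75$ have no
finite JC distance and raise an error by default (bootstrap replicates cap
them instead, with a count). Trees are built with classic neighbor joining
(Saitou–Nei agglomeration on the Studier–Keppler $Q$ criterion), which is
exact on additive matrices. Ties in $Q$ are broken by the lowest index pair
and negative branch-length estimates are clamped to zero with a count, both
for reproducibility. Bootstrap support resamples alignment columns with
replacement (default 500 replicates), rebuilds the tree, and annotates each
internal bipartition of the point-estimate tree with its replicate
percentage; supports above 80 can be flagged for presentation
(`high_support_edges()`). Newick serialisation goes through ape, with an
explicit balanced-parenthesis check that reports the offset of the first
imbalance. Alignment length is whatever the input provides (the generators
default to 452 columns, a typical analysed *pmoA* section).

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its seed and parameters and returns a
ground-truth record, so each downstream stage can be scored without
re-deriving the truth.

* `gen_gas_series()` — exponential decay with multiplicative Gaussian noise
  (GC measurement error scales with concentration); default scenarios use
  four measurements over 24 h and σ = 5 %, under which a mixed-rate batch of
  192 bottles reproduces the qualitative fit-quality profile of real
  incubations (roughly three quarters of fits with $R^2 > 0.9$).
* `gen_community()` — Dirichlet-multinomial counts over a 1/rank power-law
  base composition with total concentration 200 and depth 5000 reads per
  sample, 8 samples per group. The concentration was calibrated once, as
  part of the generator's design, so that a planted `fold_effect` is
  actually realised as a comparable enrichment in relative abundance:
  stronger overdispersion (e.g. concentration 50) destroys even genuine
  8-fold effects at this sample size, and planting large effects on the
  dominant taxa deflates the whole composition, which is why the demo
  scenarios plant the 7-vs-1 indicator structure on mid-rank taxa
  (ranks 21–28). One consequence worth knowing: planting enrichment in one
  group necessarily depresses every other OTU's relative share there, so a
  few non-planted OTUs can become genuine (weak) indicators of the opposite
  group — a compositional property of relative-abundance analysis, not an
  error.
* `gen_amplicons()` — reads copied from stop-free reference ORFs with
  planted, mutually exclusive defect classes (in-frame stop, 1-nt deletion,
  50-nt Phred-10 window) at stated rates; the filters must recover the
  planted partition exactly. No attempt is made to emulate Illumina error
  profiles, chimeras, or length variation beyond the planted deletion.
* `gen_dilution_cq()` — log-linear Cq over the seven-decade default series
  with Gaussian cycle noise.
* `evolve_sequences()` — exact JC transition probabilities along a given
  tree from a uniform root sequence.

Passing tests on these generators demonstrates that the estimators recover
the structure they assume. Real peat data differ in ways the generators do
not model — non-exponential kinetics near substrate depletion,
amplification bias, chimeras, rate variation across sites, non-Dirichlet
community covariance — so test results bound implementation correctness,
not field performance.

## Problem sizes and numerical conventions

The shipped analyses and tests use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: 24 simulated bottles,
200-series rate-recovery batches, 1,000 null OTUs for p-value calibration,
20 seeds × 10,000 permutations for the planted-indicator scenario, and
10 × 500-replicate bootstraps on 6-taxon alignments. Degenerate inputs are
handled explicitly rather than silently: empty samples stay zero and are
flagged, constant series get a degenerate-fit flag, saturated distance pairs
error or are capped and logged, invalid standard curves refuse
quantification, and all clamping (branch lengths, cell counts) is counted or
warned about.
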