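---
title: "Allotype calling and enzyme kinetics for ERAP1/ERAP2: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allotype calling and enzyme kinetics for ERAP1/ERAP2: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
library(dplyr)
```

## The problem

ERAP1 and ERAP2 are endoplasmic-reticulum aminopeptidases that trim
N-terminally extended peptide precursors into the 8--11mer ligands that MHC
class I molecules present to T cells. ERAP1 carries nine common coding SNPs
(amino-acid positions 56, 127, 276, 346, 349, 528, 575, 725, 730) which
travel together on chromosomes as a small set of *allotypes* -- multi-site
haplotypes at the protein level. Individuals carry an unordered pair of
allotypes (a diplotype), and because allotypes differ strongly in catalytic
behaviour, diplotypes imply a wide landscape of per-individual trimming
capacity.

`allokin` implements that analysis end to end as composable, tested
tibble-in/tibble-out functions:

* **popgen** -- calling allotypes from phased haplotypes, population
  frequency and diplotype tables, random-pairing expectations, ERAP2
  (rs2549782, rs2248374) calling with the expression-null flag, and
  ERAP1-by-ERAP2 cross-tabulation;
* **kinetics** -- calibration curves, initial rates, the low-substrate
  linear-regime efficiency estimator, Michaelis--Menten and allosteric
  (Hill) fits with AIC model selection, and fold-ratio summaries;
* **trimming** -- internal-standard quantification, fraction-of-total and
  maximal-accumulation summaries of sequential digestions, a LOWESS display
  smoother, and model-based recovery of per-step efficiencies;
* **inhibition** -- turnover computation, high/low-control normalisation,
  four-parameter logistic (4PL) titration fits, and correlation summaries;
* **landscape** -- combining diplotype frequencies with per-allotype
  efficiencies into a genotype-activity table;
* **synthdata** -- seeded generators for every input the other modules
  consume, so the full pipeline runs and is tested without any download.

## Allotype calling and population statistics

A phased panel is a tibble with one row per sample and two residue-string
haplotypes in canonical position order. Classification is a pure catalog
lookup: the shipped catalog (`allotype_catalog()`) holds the 16 allotypes
that reach appreciable frequency in the five continental population groups
of the 2504-sample phased reference panel, and any string not in the catalog
is labelled `"unassigned"` rather than guessed.

```{r}
classify_haplotype(c("ERIGMKDRQ", "EPIGVRNQE", "EPIGMKDRE"))
```

Frequencies are chromosome counts over total chromosomes, computed at full
precision; one-decimal rounding is applied only by report writers
(`write_report_tsv()`). Two published frequency cutoffs coexist in this
literature -- 1% "in all populations" and 0.5% "in at least one population".
The catalog deliberately contains the union (entries 1--16) and
`filter_polymorphic_sites()` exposes the cutoff as a parameter
(default 0.01) instead of hard-coding either convention.

For a pair of haplotype frequencies $p, q$ the expected frequency of the
unordered diplotype under random pairing is $2pq$ for distinct allotypes
and $p^2$ for homozygotes. `expected_cooccurrence()` defaults to this
Hardy--Weinberg mode; the plain product $pq$ is retained as
`mode = "product"` because the arithmetic sometimes quoted for the "random
expectation" of the common 8-2 combination is the plain product (25.6% x
21.8% = 5.6%), which for distinct allotypes is half the Hardy--Weinberg
value ($2pq$ = 11.2%, matching the observed ~11%). The package computes
both and takes no position on which was intended;
`random_pairing_simulation()` settles the question empirically for any
frequency vector.

ERAP2 haplotypes over (rs2549782, rs2248374) are labelled A = [G, A] and
B = [T, G]; the rs2248374 G allele abolishes protein expression, so B/B
individuals (and any "other" haplotype carrying G there) are flagged
expression-null.

## Enzyme kinetics

All internal units are molar and seconds; `to_molar()`/`to_seconds()`
convert the µM/min dialects common in assay exports.

**Initial rates.** `initial_rate()` fits a line to the initial contiguous
run of points with accumulated product at most 10% of the starting
substrate (minimum four points). The window keeps the linear-regime
assumption explicit: on a progress curve the least-squares slope
underestimates the true initial rate by roughly half the relative rate drop
across the window (about 3% under the default settings at $S = K_M/2$), a
bias the tests quantify against an ODE-integrated oracle.

**Linear-regime efficiency.** Below saturation, $v/E = (k_{cat}/K_M)\,S$,
so the through-origin slope of specific activity versus $S$ estimates the
catalytic efficiency directly. The default fit weights points by $1/S^2$ --
the generalised-least-squares choice when measurement error is a constant
coefficient of variation, which also stops the top of the assayed range
(where mild saturation bends the curve) from dominating the slope. A
weighted $R^2$ below 0.98 raises a nonlinearity flag; `strict = TRUE`
escalates it to an error.

**Rate-law fits.** `fit_mm()` fits $v = k_{cat} E S/(K_M + S)$ and
`fit_hill()` fits $v = V_{max} S^h/(K_{half}^h + S^h)$, both by
Levenberg--Marquardt with data-driven starts ($K_M$ or $K_{half}$ at the
median substrate level, rate scale at the maximum response, $h = 1$).
Optional $1/v$ weighting serves constant-CV noise. Standard errors come
from the local curvature; the efficiency's uncertainty uses the delta
method. Fits that fail to converge return all-`NA` flagged results --
downstream summaries (e.g. `fold_ratios()`) exclude flagged entries with a
message and never extrapolate a number. This is the designed path for
enzymes too sluggish to characterise on a given substrate, such as the
low-activity outlier allotype on the chromogenic dipeptide.

**Model selection.** The criterion for preferring the cooperative model is
AIC with a parsimony tie-break: the Hill fit must beat the
Michaelis--Menten fit by more than 2 AIC units, otherwise the simpler model
is reported. The threshold is a package choice (the standard
"$\Delta$AIC < 2 is indistinguishable" rule); it is exposed as an argument.

## Sequential trimming

The digestion of the 14mer ovalbumin epitope precursor GLEQLESIINFEKL
through six intermediates to SIINFEKL is summarised by two descriptive
statistics computed straight from the measured concentrations: each
species' trajectory as a fraction of total peptide, and each species'
maximal accumulation (in both molar and fraction units -- the published
heat maps do not state which, so both are reported). Maxima are taken over
the sampled grid without interpolation, matching how discrete time courses
are summarised. LOWESS curves (`lowess_smooth()`, tricube local-linear via
`stats::lowess`, no robustness iterations) are a display aid only and never
feed statistics.

`simulate_cascade()` provides a mechanistic stand-in for such digestions:
a shared-enzyme competitive Michaelis--Menten cascade,
$$v_i = \frac{k_{cat,i}\,E\,(S_i/K_{M,i})}{1 + \sum_j S_j/K_{M,j}},$$
the simplest mechanism consistent with one enzyme digesting co-present
substrates; the terminal product is not consumed and total peptide is
conserved (to integrator precision, < 1e-6 relative). Free amino acids are
not tracked, as they are not measured. This model and the rate recovery
below are a package extension beyond the descriptive statistics.

**Identifiability.** `recover_cascade_rates()` fits the cascade to all
species jointly in log-parameters. Profiling the fit shows that with the
precursor near or below $K_M$, trajectories are nearly invariant to a joint
rescaling of all $k_{cat}$ and $K_M$: the data pin the efficiency *ratios*
strongly but the absolute scale weakly (at 5% noise the flat direction
dwarfs the curvature by ~10^3). The default fit therefore estimates one
shared $K_M$ (profiled over a coarse grid before the joint polish, so the
optimiser cannot wander down the valley) and reports honest, wide
uncertainties on noisy data; passing independently measured Michaelis
constants via `KM =` reduces the problem to per-step turnover numbers,
which noisy data determine well (tests: within 20% at 5% noise with
triplicate series sampled every 300 s). Noiselessly the unconstrained fit
round-trips the generator essentially exactly.

## Inhibitor titrations

Turnover is $100\,[P]/([P]+[S])$ after converting both signals through
their own calibration curves (correcting the detection-sensitivity
difference between analytes). Turnover above 35% raises a flag -- the
published quality bound is treated as an observed QC criterion, not an
automatic exclusion. Activities are normalised to percent between
uninhibited (high) and fully inhibited (low) controls; values above 100
are legitimate for activators.

The 4PL model is parameterised on log10 dose for conditioning:
$r = A_0 + (A_\infty - A_0)/(1 + 10^{\,h\,(-p - \log_{10} x)})$ with
$p = \mathrm{pXC_{50}}$. After fitting, the sign convention is normalised
(slope positive; `top`/`bottom` are the larger/smaller plateau) and the
direction tag is `"inhibition"` when the saturating plateau lies below the
zero-dose plateau, `"activation"` otherwise -- so the same machinery fits
potency of active-site inhibitors (pIC50 ~7.2--7.6 in the emulated
titrations) and regulatory-site activators (pXC50 ~4.8--6.5). A midpoint
outside the dosed range is flagged. Because the published figures do not
state the correlation flavour used to relate allotype activity to inhibitor
response, `correlate()` reports Pearson and Spearman side by side.

## The genotype-activity landscape

`landscape_table()` scores each observed diplotype by the sum of its two
allelic efficiencies -- the no-interaction, equal-expression assumption.
Expression-level modulation by regulatory variants is deliberately out of
scope, and entries inherit that assumption; the 9mer-epitope efficiency
profile is the default substrate basis since it is the one with reliable
full Michaelis--Menten characterisation. Useful invariants follow directly:
the pair-level spread equals $(2\max_a e_a)/(2\min_a e_a)$, ranking is
invariant to rescaling the profile, and with the low-activity allotype at
the profile minimum its homozygote ranks last. No numeric activity "bands"
are hard-coded; banding thresholds in published figures are presentation
choices, so plotting leaves them to the caller.

## What the generators emulate -- and what they do not

`gen_phased_panel()` reproduces a phased diploid panel from haplotype
frequencies: exact-count mode assigns largest-remainder counts (totals are
exactly $2n$ chromosomes) and pairs chromosomes randomly or per an explicit
joint diplotype table; sampling mode draws i.i.d. `table1_panel()` rebuilds
the shipped frequency table as a concrete panel (for the pooled panel,
counts are `round(pct/100 * 5008)` with the remainder assigned to an
off-catalog haplotype, reproducing the published rounding structure
including its ~0.3% unassigned remainder). The generators do **not**
imitate linkage-disequilibrium structure beyond the haplotype frequencies
and any joint table supplied, nor admixture within samples -- passing tests
says nothing about phasing or imputation quality on real cohorts, which
must arrive already phased.

Kinetic ground truths (`default_activity_profile()`,
`default_hill_params()`, `cascade_spec()`) are package defaults in the
ranges typical of ERAP1 in-vitro work. Their *absolute* values are design
choices; what is anchored to the published record are the fold
relationships: a 60-fold 9mer efficiency ratio between the most and least
active allotypes (the latter ~10-fold down in $k_{cat}$, with a < 6-fold
$K_M$ spread and the two tightest binders being the most active pair), an
18-fold dipeptide efficiency ratio, dipeptide response linear past 150 µM,
and digestion conditions of 25 µM precursor with 10 nM enzyme (the
sluggish allotype assayed at 10x enzyme, which all summaries normalise per
enzyme). Noise is multiplicative log-normal of given CV (mean-one), the
plate-reader-like default; an additive option exists. All generators are
pure functions of (spec, seed).

## Numerical and testing choices

* Exact-count rounding: largest remainder, so chromosome totals are exact.
* Display rounding: one decimal, confined to report writers.
* ODE integration: `lsoda` at rtol 1e-9 with state-scaled atol; an
  integrator failure at an extreme trial point during fitting is treated
  as a very poor fit rather than an error, letting the optimiser retreat.
* Degenerate inputs fail loudly and early: empty site sets, alphabet
  violations, unphased VCF records, zero internal standards (named time
  point), equal controls, constant correlation inputs.
* Test problem sizes keep the suite quick at desk scale: 2504-sample
  panels, 200-seed pairing simulations, 100-seed recovery studies for the
  Michaelis--Menten and 4PL estimators, 13--25-point digestion grids.
  The acceptance script re-runs the same computations from scratch at the
  same sizes.

## Limitations

Beyond the generator caveats above: no association testing or LD
estimation; no phasing; no mechanistic model of the regulatory-site
coupling (the 4PL is purely descriptive); dipeptide progress curves are
not fit globally; and per-step Michaelis constants of a cascade are not
identifiable from a single digestion -- the package will fit them on
request, but the uncertainties say what the data cannot.
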