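# allokin

Population genetics and enzyme kinetics of ERAP1/ERAP2 allotypes, in one
tested R package.

ERAP1 is the endoplasmic-reticulum aminopeptidase that trims N-terminally
extended peptide precursors into the 8–11mers presented by MHC class I.
Its nine common coding SNPs (positions 56, 127, 276, 346, 349, 528, 575,
725, 730) travel together as a small set of **allotypes** — multi-site
protein haplotypes — and individuals carry an unordered pair of them.
Because allotypes differ up to 60-fold in catalytic efficiency, and the
ranking is substrate dependent, a person's ERAP1 diplotype implies a
specific point on a wide genotype–activity landscape, with consequences
for antigen presentation and inflammatory-disease risk.

`allokin` covers that analysis end to end, tidyverse-style (tibbles in,
tibbles out, pipe-friendly, `tidy()`/`glance()`/`autoplot()` on fitted
objects):

* **Allotype calling & population statistics** — classify phased
  haplotypes against the shipped 16-entry catalog; chromosome-level
  frequency tables per population with subtotals; unordered diplotype
  tables; Hardy–Weinberg and plain-product co-occurrence expectations and
  seeded random-pairing simulation; ERAP2 (rs2549782/rs2248374) calling
  with the expression-null flag; ERAP1×ERAP2 cross-tabulation.
* **Enzyme kinetics** — calibration curves, initial rates with an explicit
  depletion window, low-substrate linear-regime efficiency, Michaelis–
  Menten and allosteric (Hill) fits with AIC model selection, pairwise
  fold-ratio summaries. Rate laws:
  `v = kcat·E·S/(KM+S)` and `v = Vmax·S^h/(K_half^h + S^h)`.
* **Sequential trimming** — internal-standard MS quantification,
  fraction-of-total and maximal-accumulation heat-map summaries of the
  14mer→8mer ovalbumin digestion, LOWESS display smoothing, and model-based
  per-step efficiency recovery from a shared-enzyme competitive cascade.
* **Inhibitor titrations** — percent turnover with analyte-sensitivity
  correction (35% QC flag), high/low-control normalisation, four-parameter
  logistic fits reporting pIC50/pXC50 with a direction tag, and
  Pearson+Spearman correlations.
* **Landscape** — diplotype frequency × summed allelic efficiency tables
  with ranks and spread, plus scatter/bubble plots.
* **Synthetic data** — seeded generators for every input (phased panels,
  rate datasets, progress curves, digestion cascades, titrations), so the
  whole pipeline runs without any external download.

## Worked example

```r
library(allokin)
library(dplyr)

# a 2504-sample panel reconstructed from the shipped frequency table
panel <- table1_panel("ALL")
allotype_frequencies(panel) |> filter(population == "ALL") |> head(3)
#>   allotype population n_chrom freq_pct is_subtotal
#> 1 1        ALL            305      6.1 FALSE
#> 2 2        ALL           1282     25.6 FALSE
#> 3 3        ALL            426      8.5 FALSE

dip <- diplotype_table(panel)
head(dip, 3)
#>   allotype_a allotype_b     n freq_pct
#> 1 2          8            264    10.5
#> 2 2          2            160     6.39
#> 3 2          10           130     5.19
```

The most common combination pairs the two most frequent allotypes, and at
about twice the plain-product "random" expectation — because the right
expectation for a distinct unordered pair is `2pq`, not `pq`:

```r
100 * expected_cooccurrence(0.256, 0.218, mode = "product")  # 5.6
100 * expected_cooccurrence(0.256, 0.218)                    # 2pq = 11.2
```

Kinetic fits on generated data (here an allotype-2-like enzyme on the 9mer
epitope substrate: kcat 0.60 /s, KM 20 µM, 5% noise, triplicate wells):

```r
d <- gen_rate_dataset(list(model = "mm", kcat = 0.60, KM = 20e-6),
                      S = rep(c(5, 10, 20, 40, 60, 90, 120, 160,
                                220, 300, 400, 500) * 1e-6, 3),
                      E = 1e-9, noise_cv = 0.05, seed = 42)
fit <- fit_mm(d, E = 1e-9)
tidy(fit)
#>   term            estimate     std.error
#> 1 kcat           0.609        0.00945
#> 2 KM             0.0000213    0.00000163
#> 3 efficiency 28624.        1892.
```

`kcat` and `KM` come back within a few percent of truth; `efficiency` is
kcat/KM in 1/M/s with a delta-method standard error. Combining a
per-allotype efficiency profile with the diplotype table gives the
landscape:

```r
ls <- landscape_table(dip, default_activity_profile(), "9mer")
head(ls, 3); attr(ls, "spread")
#>   allotype_a allotype_b     n freq_pct activity  rank
#> 1 2          2            160    6.39     60000     1
#> 2 1          2             69    2.76     55000     2
#> 3 1          1              8    0.319    50000     3
#> [1] 60
```

The allotype-2 homozygote tops the table, the allotype-10 homozygote
(~1.2% of samples) ranks last, and expected per-individual activity spans
60-fold — individuals at the bottom are near-functional knockouts for this
substrate. `plot_landscape(ls)` draws the activity-vs-frequency scatter.

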