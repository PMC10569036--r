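---
title: "Partition fingerprints: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition fingerprints: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

partprint turns non-targeted LC-MS peak areas from solvent–water partition
experiments into *physicochemical fingerprints* — vectors of log solvent–water
partition ratios over a panel of organic solvents — and uses them to predict
substructure-count descriptors of unknown compounds. This vignette records
the underlying model, the assumptions baked into each stage, the main
parameters and why they default to what they do, what the bundled simulator
does and does not cover, and the numerical choices made along the way.

```{r load}
library(partprint)
```

## 1. The measurement model

A compound is spiked into water, shaken against an organic solvent, and the
**aqueous phase** is measured by LC-MS. Two peak areas per solvent enter the
calculation:

* $A_T$ — the area in a *water control* (no partitioning): total analyte.
* $A_W$ — the area in the aqueous phase after equilibration.

The solvent-phase area is taken by difference, $A_S = A_T - A_W$, and the
partition ratio is

$$\log K_{SW} = \log_{10}\!\left(\frac{A_T - A_W}{A_W}\cdot
\frac{V_W}{V_S}\right),$$

with $V_W/V_S$ the water-to-solvent volume ratio. Because both areas come
from the *same* (aqueous) matrix, the relative response factor of the
instrument cancels; no calibration is needed. The assumptions are:

* linear detector response over the relevant area range;
* negligible losses other than partitioning (no adsorption, degradation);
* equilibrium reached before sampling.

When $A_S \le 0$ (the compound barely partitions, or noise dominates), the
entry is treated as **missing** and routed to imputation rather than forced
into the logarithm.

For an ionizable compound at a working pH, the measured quantity is the
distribution ratio $D_{SW} = K_{SW} \cdot f_u$, where $f_u$ is the
un-ionized fraction in water. On the log scale this is an **additive offset
that is identical for every solvent**:

$$\log D_{SW} = \log K_{SW} + \log_{10} f_u.$$

## 2. Standardization

Fingerprints are compared after per-compound z-scoring (population variance):

```{r std}
fp <- tibble::tibble(
  compound_id = "demo", solvent = default_solvents(),
  value = rnorm(10, mean = 2), imputed = FALSE, standardized = FALSE
)
standardize_fingerprints(fp)$value |> round(3)
```

Standardization has two consequences that the package leans on:

1. Any per-compound additive offset cancels. In particular the ionization
   offset $\log_{10} f_u$ vanishes, so the standardized $D$ fingerprint is
   *identical* to the standardized $K$ fingerprint — measured fingerprints
   of ionized compounds can be compared directly against neutral-species
   reference values.
2. Ordinary least squares between two standardized vectors has intercept
   exactly 0 and slope equal to the Pearson correlation, which makes the
   slope/intercept diagnostics of `compare_fingerprints()` interpretable at
   a glance.

Compounds with fewer than two observed solvents, or zero variance across the
panel, cannot be standardized and raise an error naming the compound.

## 3. Read-across imputation

Missing entries are imputed from a reference database of compounds with
complete fingerprints. For a target solvent and a random triplet of observed
solvents, a multilinear law

$$K_{target} = c + a K_1 + b K_2 + d K_3$$

is fitted on the database rows by least squares and applied to the compound's
observed values. This is repeated for `n_iter = 100` random triplets and the
predictions are averaged. The default of 100 draws keeps the seed-to-seed
spread of the average small while remaining fast; the spread shrinks roughly
as $1/\sqrt{n}$ and the test suite checks it directly.

The approach is exact when fingerprints have low-rank structure (each
compound's profile is a linear mixture of a few latent interaction scales) —
which is also how the simulator constructs its panels, giving an oracle the
tests can hold the code to at tolerance $10^{-6}$. Compounds with fewer than
three observed solvents cannot be imputed and are returned untouched with a
warning. Rank-deficient triplets raise a typed condition and the draw is
resampled.

## 4. Fragment priors

For candidate structures sharing a molecular formula, a per-formula prior
over substructure counts is computed as a weighted sum of each isomer's
counts, with weights `data_sources / max(data_sources)` — the
better-documented isomers dominate. If every isomer has zero recorded data
sources the weights fall back to 1 (an unweighted sum). A min–max variant is
available behind `normalization = "minmax"`.

## 5. The substructure-count network

`train_fragment_net()` trains a multilayer perceptron mapping the
standardized fingerprint plus formula information (monoisotopic mass, element
counts, fragment priors) to the vector of substructure counts:

* 10 hidden ReLU layers of 500 units each;
* dropout (rate 0.2) after the last ReLU layer;
* one exponential-activation layer of 500 units (counts are non-negative and
  multiplicative structure helps);
* a linear output layer, one unit per fragment in the catalog.

Optimization is Adamax (step size 0.001) on mean absolute error, 200 epochs,
an 80/20 train/test split, and 5-fold shuffle-split cross-validation. The
network is implemented in base R matrix algebra; weights initialize with He
scaling for the ReLU stack, the exponential pre-activation is clipped at 30
to keep the forward pass finite, and inverted dropout keeps train- and
test-time scales identical. Inputs and the per-fold z-scoring statistics are
computed on the training portion only. Predictions are clamped at zero but
**never rounded**: they behave like expected counts, and rounding discards
information before any downstream similarity calculation.

MAE was chosen as the loss to match the reporting metric and because count
targets are sparse: absolute error does not let a few large counts dominate.

### Problem sizes

The unit tests exercise reduced widths/depths for speed; the acceptance-level
checks train the full 500×10 architecture on 2,000 simulated compounds with
30 epochs, a single shuffle-split fold and batch size 128. These sizes are
this package's own choice of demonstration scale: they are large enough that
the network separates real structure from a shuffled-target control by a wide
margin, while a desk machine trains both models in a few minutes. Nothing in
the code limits larger runs — `epochs`, `cv_folds`, `hidden`, `n_relu` and
`batch_size` are ordinary arguments.

## 6. The simulator

`simulate_panel()` generates a fully synthetic study so that every stage is
testable offline:

* **Compounds** get unique molecular formulas over a 10-element alphabet and
  integer fragment counts (0–4).
* **Fingerprints** are built from a rank-3 latent model: fragment counts map
  to 3 latent interaction scales (plus latent noise), and each solvent's
  log K is a fixed affine function of the latents. Consequence: any 3
  generic solvents linearly determine the rest — the imputation oracle.
* **Ionization**: a fraction of compounds get $f_u < 1$, producing the
  solvent-independent log-offset between $D$ and $K$.
* **Areas** are rendered through the mass-balance model
  $A_W \propto 1/(V_W + D V_S)$, $A_T \propto 1/V_W$, with lognormal
  multiplicative noise (default 5 %), three volume ratios, duplicate
  injections, and blanks at $10^{-3}$ of the median control area — a
  realistic instrument dynamic range that leaves most entries observable
  while still exercising the blank filter and the missing-data path.
* **Saturation**: an optional log-logistic detector response
  $2L/(1+(L/A)^s)$ — identity at the onset level $L$ (by default the 60th
  area percentile), asymptote $2L$ — mimics a narrow intrascan dynamic
  range and lets tests show that saturation degrades recovered fingerprints.

The simulator deliberately does **not** model retention-time drift,
co-elution, adduct diversity beyond a single species, in-source
fragmentation, or matrix effects; it is a test harness for the numerical
pipeline, not an instrument model. All stages draw from seeds derived
deterministically from `sim_config(seed = ...)`.

## 7. Other numerical and design choices

* **Blank filter**: a feature is kept iff its *maximum* water-control area is
  at least 1.3× the *mean* blank area (inclusive; zero-blank features are
  kept). The water control is the reference because it is the sample with
  the full analyte amount.
* **ppm matching** uses the theoretical mass in the denominator,
  $10^6\,|\Delta m|/m$, with a 10 ppm default (QTOF) and 5 ppm for Orbitrap
  configurations; adduct correction subtracts (adds) one proton mass for
  [M+H]+ ([M−H]−). A relative slack of $10^{-9}$ on the boundary keeps the
  inclusive window robust to floating-point rounding.
* **Replicate aggregation** averages duplicate injections in area space
  (same physical sample), then takes log K per replicate, then averages in
  log space across volume-ratio replicates (different equilibria).
* **Cross-platform selection** keeps compounds whose fingerprint comparison
  reaches $R^2 \ge 0.8$ (inclusive).
* The solvent panel defaults to 10 solvents (`default_solvents()`); panels
  are an argument everywhere, not a constant.

## 8. Limitations

* The imputation guarantee is tied to (approximately) low-rank fingerprint
  structure; strongly specific solute–solvent interactions outside the
  latent span will impute poorly.
* $D = K \cdot f_u$ neglects ion-pair partitioning into the organic phase.
* The network predicts the fragments of its training catalog only, and its
  accuracy is demonstrated on simulated panels; transfer to measured data
  should be validated per instrument and panel.
* Area-difference log K estimates lose precision as $A_W \to A_T$ (weak
  partitioning): small relative area noise becomes large log-scale noise.
  This is inherent to the aqueous-only design, not to the implementation.
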