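---
title: "Methods: dose-response, Bliss synergy, transwell transport and expression QC for efflux-mediated resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, Bliss synergy, transwell transport and expression QC for efflux-mediated resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effluxr)
library(dplyr)
```

effluxr implements the quantitative chain used to establish that an efflux
transporter (P-glycoprotein/ABCB1) drives acquired taxane resistance in vitro
and that a P-gp inhibitor such as ritonavir reverses it: sigmoid
dose-response fitting with relative-resistance ratios, checkerboard Bliss
independence scoring, bidirectional Caco-2 permeability analysis, and a
count-matrix QC/differential-expression screen. This vignette documents the
models, the defaults and why they were chosen, the simulators that make the
chain testable without external data, and the known limitations.

## Dose-response model

Viability or clonogenic signals are normalized to treated-over-control (T/C)
fractions against the mean of untreated wells on the same plate
(`tc_fraction()`); normalization makes the fit invariant to the raw signal
units. The response model is the four-parameter logistic

$$\mathrm{T/C}(c) \;=\; b + \frac{t - b}{1 + (c/\mathrm{IC_{50}})^h},$$

fitted by unweighted least squares in $\log_{10}$-concentration space
(`fit_dose_response()`, Levenberg-Marquardt with box constraints via
minpack.lm). The reported IC50 is the *relative* IC50 — the inflection
point, halfway between the fitted plateaus — not the absolute 50%-of-control
crossing.

Numerical choices, all tunable through the function arguments:

* **Replicates** are averaged at the T/C level before fitting, matching the
  duplicate-well plate designs the package targets.
* **Initialization**: top = max observed T/C, bottom = min observed T/C,
  IC50 from the linear-interpolation crossing of the plateau midpoint, and a
  multi-start over Hill slopes $\{0.5, 1, 2, 4\}$; the lowest-RSS converged
  start wins. This avoids the local minima that plague one-shot sigmoid
  fits on noisy or partial curves.
* **Bounds**: relative to the maximum observed T/C $m$, bottom
  $\in [-0.1, 0.5]\,m$, top $\in [0.5, 1.2]\,m$, Hill $\in [0.1, 10]$, IC50
  within two decades of the tested range. The bottom/top bounds prevent
  runaway plateaus when only part of the sigmoid was sampled.
* **Censoring**: if the fitted inflection lies outside the tested range the
  IC50 is reported as a bound at the range limit (`"> 30.0000 uM"` via
  `format_ic50()`) with `censored = "above_max"`/`"below_min"`. A curve so
  flat that no start converges is censored likewise (span below `min_span`)
  rather than declared a failure; anything else non-convergent raises a
  fit-failure error with per-start diagnostics. Censored fits refuse to
  enter `ic50_ratio()` — a bound, not a ratio, is the honest summary.

`ic50_ratio()` computes relative resistance (resistant over parental IC50)
and fold-sensitization (IC50 without over with inhibitor); the conventional
report rounds to one decimal.

## Bliss independence on checkerboards

For a drug-A $\times$ drug-B concentration grid whose zero row/column holds
the single-agent effects measured on the same plate, the Bliss expectation
of each combination cell is $E_{12} = E_1 E_2$ (fractions unaffected
multiply under independence) and the Bliss index is
$\mathrm{BI} = E_{12} - \mathrm{T/C_{combo}}$: positive means more
inhibition than independence predicts. Design points:

* $E_1, E_2$ come from the measured margins, never from fitted curves; the
  expectation inherits the same plate normalization as the observation.
* T/C values above 1 (apparent stimulation) enter $E_1 E_2$ unclipped so the
  algebraic identity holds; clipping to $[0,1]$ is only applied to the
  display copy of the heat map (`clip_tc()`, `autoplot()`).
* Cells are flagged synergistic at $\mathrm{BI} \ge 0.15$ and antagonistic
  at $\mathrm{BI} \le -0.15$; a tie at the threshold counts as flagged.
* The assay-level call counts flagged cells against
  $k = \lceil 0.12\,n \rceil$ of the $n$ evaluable combination cells:
  more than $k$ in one direction calls synergy (or antagonism), exactly $k$
  calls the "slight" variant, and anything else is additive; if both
  directions fire the package emits `mixed` rather than invent a precedence.
  For the 5 × 5 grid ($n = 25$, $k = 3$) this reproduces the familiar
  "> 3/25", "= 3/25", "> 22/25" rules exactly, and the fraction form makes
  8 × 2 reversal designs ($n = 16$, $k = 2$) classifiable on the same
  footing. We deliberately define *additive* as "neither direction reaches
  $k$ flags": a grid with, say, one synergy and one antagonism flag out of
  16 is additive, not mixed — split noise flags are not evidence of a mixed
  interaction.
* Cells with no surviving replicate are excluded from $n$ (with a note);
  a cell with one surviving replicate uses it.

Heat-map grids round-trip through CSV bit-for-bit (`write_tc_matrix()` /
`read_tc_matrix()` write 17-significant-digit doubles), so archived grids
re-analyze to identical BI matrices.

## Transwell permeability

Apparent permeability is $P_\mathrm{app} = (dQ/dT)/(A\,C_0)$ (cm/s) from the
receiver-side quantity at a single sampling time — a slope approximation
valid in the linear transport regime the standard 60/120-minute designs stay
within. The efflux ratio is
$\mathrm{ER} = P_\mathrm{app}(B\to A)/P_\mathrm{app}(A\to B)$; recovery is
the percent of the applied amount found across apical, basolateral and
cellular compartments. Defaults: membrane area 0.7 cm² (24-well insert),
ER decision cutoff 2. A compound is an efflux substrate when ER > 2 with the
B→A direction dominating; an inhibitor arm of a substrate is called
`inhibited` when its ER drops below 2.

Both ER aggregation orders are reported, because they differ when replicate
noise is asymmetric: the ratio of mean Papps (`er`, the display default) and
the mean of per-replicate ratios (`er_replicate`). ER uncertainty is
propagated to first order from the directional SEMs. Wells failing monolayer
QC (Lucifer-Yellow / TEER flags supplied as a `qc_pass` column) are dropped
with a note; the package treats monolayer QC as pass/fail only.

## Expression screen

The screen is a deliberately transparent stand-in for moderated count
models: `log_cpm()` (log2 counts-per-million with pseudocount 0.5), per-gene
Welch t-tests (`two_group_test()`, vectorized, with a small variance floor
for degenerate genes), Benjamini-Hochberg adjustment (`bh_adjust()`, a
validated wrapper over `stats::p.adjust`), and the DEG rule *q* < 0.05 AND
fold $\ge$ 2 in either direction (`deg_filter()`). TMM normalization and
voom precision weights are intentionally not reimplemented; biological DEG
lists from real studies are not reproducible without their raw data, and the
stand-in keeps every step auditable. Consequence: with n = 3 per group the
Welch degrees of freedom can drop to 2, so borderline genes near the FDR
boundary are less reliably called than a moderated model would call them.

Sample QC computes four per-sample statistics: sum of Euclidean distances to
the other samples; Hoeffding's D against the per-gene median
pseudo-reference; mean Pearson correlation with the other samples; and the
two-sample Kolmogorov-Smirnov statistic against the pooled remaining
samples. The KS comparison uses the pooled *empirical* distribution of the
other samples (not a theoretical reference). A sample is flagged when a
statistic departs from the across-sample median in its adverse direction
(high distance, low D, low correlation, high KS) by more than 3 robust
z-units (MAD scale) **and** by a minimum practical margin (25% of the median
distance sum; 0.1, 0.05 and 0.05 absolute for D, correlation and KS). The
floor matters: with a dozen samples the MAD itself is noisy, and a pure
3-MAD fence flags clean replicate sets almost half the time, while genuine
outliers (a permuted sample, a swapped library) depart by an order of
magnitude and clear both fences easily. Zero-variance samples correlate as 1
with identical twins and are otherwise dropped from the correlation mean
with a note.

`hoeffding_d()` is the classical rank-form estimator with midrank tie
corrections, reported on the 30-scaled convention (about $[-0.5, 1]$;
1 for monotone dependence of distinct values, ~0 under independence). The
test suite verifies it against an independent order-5 U-statistic oracle,
exhaustively over all permutations of $n = 5..7$.

## Simulators and what passing tests mean

Every generator attaches its exact generating parameters to the dataset
(`synthetic_truth()`), and all randomness flows from one seed per call —
same seed, byte-identical output.

**Viability plates** (`gen_viability_plate()`): well signal is
`control_mean * f(C_eff) * g(c_inh) * noise`, where `f` is the drug's 4PL
survival curve, `g` the inhibitor's own (weak) 4PL, noise is multiplicative
log-normal (plate-reader error scales with signal), and the efflux mechanism
enters only through the effective intracellular concentration

$$C_\mathrm{eff} = \frac{c}{1 + E\,(1 - c_i/(c_i + K_i))}.$$

With efflux factor $E = 0$ the combination is exactly multiplicative — a
Bliss-null plate by construction; with $E \gg 1$ the apparent IC50 shifts
$(1+E)$-fold and saturating inhibitor restores parental potency, producing
genuine mechanism-based synergy. Defaults emulate the target regime:
parental IC50 1 nM, Hill 2 (taxane curves are steep), inhibitor-alone IC50
22 µM, $K_i$ 5 µM, duplicate wells, six controls, 10% CV. The one-site
occupancy term is a modeling convenience: the studies this emulates report
endpoints, not transporter kinetics, so the generator targets the observed
fold-shifts rather than Michaelis-Menten parameters.

**Transwell** (`gen_transwell()`): directional permeability
$P_{AB} = p/(1 + Mu)$, $P_{BA} = p(1 + Mu)$ with unoccupied fraction
$u = 1 - c_i/(c_i + K_i)$, so the noiseless ER is $(1+Mu)^2$; the default
$M = \sqrt{31.8} - 1$ reproduces the ER ≈ 32 regime of a strong P-gp
substrate at 10 µM, collapsing toward 1 under a tight-binding reference
inhibitor (10 µM, $K_i$ 0.1 µM) or a weaker clinical inhibitor (50 µM,
$K_i$ 1 µM). Compartment quantities are constructed mass-conserving, so the
noiseless recovery is exactly 100% — an oracle for the `recovery()`
computation; measurement noise is applied per measured quantity.

**Counts** (`gen_counts()`): negative-binomial counts over a shared
log-normal baseline. Defaults: 2,000 genes, dispersion 0.01 (biological CV
10%, the conventional scale for triplicate cultures of a clonal line),
library size 2 × 10⁶, and a DE specification with one transporter-like gene
up ~3000-fold from a pinned low-but-quantifiable baseline (~25 CPM — the
parental lines express almost none, yet the induction is finite and
measurable) plus ~5% of genes changed 2-64-fold in both directions, the DEG
burden reported for acquired-resistance sublines. Problem sizes throughout
(2,000 genes, 200-500 simulation seeds, 10-concentration curves) are desk
scale: large enough for stable rates, small enough to re-run casually.

What the simulators do *not* emulate: spatial plate effects and edge wells,
carry-over between concentrations, transporter saturation kinetics,
count-level batch effects, library-composition artifacts beyond what the DE
spec itself induces, and read-level sequencing noise. Passing tests
therefore demonstrate that the analysis chain is correct under its stated
assumptions and calibrated against its own mechanism — not that it would
rescue pathological real-world data.

## End-to-end run

`run_study_pipeline(out_dir, seed)` simulates a full study (parental and
resistant dose-response plates and checkerboards, a transwell dataset, a
12-sample count matrix) and runs every stage, writing the fit table, BI
grids and calls, the transwell table, the QC report, the DEG table and a
`summary.json` that embeds the seed and a hash of the configuration; reruns
with equal seed and config are byte-identical. The expected qualitative
pattern — additive in the parental checkerboard, synergy in the resistant
one, ER > 2 collapsing below 2 under inhibition, the transporter-like gene
as top-fold DEG, no QC flags — is asserted in the test suite.

```{r pipeline, eval = FALSE}
summary <- run_study_pipeline("results/study", seed = 1)
summary$relative_resistance
summary$bliss_call_resistant
```

## Known limitations

* Relative IC50 only; absolute IC50 is intentionally out of scope.
* The Welch/log-CPM screen approximates, but does not reproduce, moderated
  pipelines; DEG *counts* from real studies are outside its reach.
* BI values carry no confidence intervals — the classification is a count
  rule over thresholded point estimates, as in the assay convention it
  mirrors.
* Plate-level normalization error (finite control wells) shifts every BI
  cell coherently; at high noise this can masquerade as weak antagonism or
  synergy. More control wells, or lower CV, is the remedy — the classifier
  does not attempt to model it.
* The transwell analysis assumes sink conditions and linear transport; it
  does not fit transporter kinetics.
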