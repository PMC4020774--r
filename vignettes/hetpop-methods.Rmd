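---
title: "Characterizing heterogeneous receptor populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing heterogeneous receptor populations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics and its
compartment model: what is computed, under which assumptions, which knobs
matter, and where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The statistical procedure

### Candidate families and estimation

Per-cell surface receptor counts are positive, strongly right-skewed, and
often heavy-tailed. Three two-parameter families cover the shapes seen in
practice: Weibull (shape $a$, scale $b$; a generalized-extreme-value
special case), Gamma (shape $a$, scale $b$; the maximum-entropy choice),
and lognormal ($\mu$, $\sigma$ of log-counts). A Gaussian of the counts is
carried strictly as a baseline — it is never selectable, and on
heavy-tailed data its histogram SSE is far worse than the best family
(asserted qualitatively in the tests; the magnitude is data-specific).

Parameters are estimated by maximum likelihood on the **raw, unbinned**
values: the lognormal and Gaussian MLEs are closed-form; Gamma and Weibull
use the standard one-dimensional profile reductions (Newton on
$\log a - \psi(a) = \log \bar x - \overline{\log x}$; bracketed root of the
Weibull shape equation), with a three-start quasi-Newton search in
log-parameter space as fallback. Estimating parameters from the histogram
instead would couple them to the bin count and undermine the bin-number
search below; the binned SSE is reserved for *model selection* and
*binning*, never for estimation. Optimizer failure is an error, never a
silent `NaN`.

### SSE, family selection and the optimal bin number

Against a $k$-bin equal-width histogram (right-open bins, last bin closed,
spanning the data range) with centers $c_i$ and counts $n_i$,

$$\mathrm{SSE}(k) = \sum_{i=1}^{k} \left( \frac{n_i}{N\,w} - f(c_i)
\right)^2 .$$

The observed heights are density-normalized ($n_i/(N w)$) so that observed
and expected values are commensurable and the SSE is comparable across bin
numbers within one data set — the property the $k$-scan needs. Note the
consequence: the SSE carries units of density squared, so its numeric value
scales roughly as $1/\mathrm{range}^2$ and is **not** comparable across
data sets with different ranges (section 5).

The best family is the SSE minimizer among the three candidates, evaluated
once at a *reference bin number* (default 20, configurable via
`low_bin_config(reference_k = )`). The best family is insensitive to the
bin number over a wide range, but selection at the very coarse end of the
scan (near the 5-bin minimum) is unreliable: the density evaluated at the
center of a very wide bin is a poor stand-in for the bin's average density,
and the comparison degenerates. Twenty bins is comfortably inside the
stable region for samples of a few thousand cells and up; this choice is a
deliberate deviation from selecting at the scan minimum.

The optimal bin number is $k^\* = \arg\min_{k \in [k_\min, k_\max]}
\mathrm{SSE}(k)$ with parameters held at the raw-data MLE, ties broken
toward smaller $k$. Defaults $k_\min = 5$ (fewer bins cannot represent the
data) and $k_\max = 200$ (comfortably above optimal bin numbers seen in
practice, which reach ~100 for very broad populations).

### The outlier cutoff

On the $k^\*$ histogram, the cutoff bin is the leftmost bin strictly right
of the largest bin satisfying, with $f = 1\%$ by default:

* $n_j < f \cdot n_{\max}$ (low occurrence probability), and
* $n_{j-1} < f \cdot n_{\max}$ and $n_{j+1} < f \cdot n_{\max}$
  (uniqueness: not an isolated dip in a populated region).

The bin and everything right of it is removed; the family is refitted on
the kept cells. Three deliberate boundary rules:

* **Largest-bin ties** go to the leftmost maximal bin, keeping the
  candidate region deterministic.
* **The last bin's missing right neighbor counts as 0 cells** — otherwise
  the final bin could never qualify and the extreme tail could never be
  trimmed, defeating the method's purpose.
* **Only right-of-maximum bins are candidates.** Low/zero expression is a
  real biological state (receptor down-regulation), so the left tail is
  never touched. The tests assert this as an invariant.

The eligibility fraction is configurable (e.g. 2% for extremely heavy
tails); lowering it can only shrink the set of eligible bins, so it never
removes more cells — also asserted as an invariant.

### Representative statistics and mixtures

Geometric mean $\exp(\overline{\log x})$, arithmetic mean, mode and median
are computed on the cleaned, **unbinned** values (so the mode need not lie
in the largest bin). The mode of continuous data needs a precision rule:
values are rounded to the nearest integer receptor count — the data's
physical resolution — and ties break toward the smaller value, making the
mode deterministic and unit-meaningful. The geometric mean is the preferred
single-value representation for lognormal-like data: it acknowledges the
tail without being dominated by it (arithmetic mean) or ignoring it
(mode/median).

Multimodal tumor-derived populations are decomposed by a tri-modal Gaussian
mixture fitted by EM (convergence: relative log-likelihood change
$< 10^{-8}$ or 500 iterations; best of 10 seeded k-means initializations; a
component collapsing below $10^{-6}$ of the data SD invalidates the run).
Components are ordered by descending weight ("Density 1" is the most
frequent subpopulation). Per-component statistics are computed on the cells
hard-assigned by maximum posterior responsibility — not from the fitted
Gaussian parameters, because a Gaussian's support includes nonpositive
values where the geometric mean is undefined. Mixture-level values are the
density-weighted sums $\sum_m w_m \cdot \mathrm{stat}_m$, always inside the
component range. Weighted geometric/arithmetic means decompose almost
exactly on overlapping components (the EM weights track the assignment
fractions); median and mode do not decompose additively, so the unimodal
invariance test asserts the means only.

### Bootstrap protocols

Two robustness protocols, each rerunning the *entire* low bin search per
trial and recording the cutoff value and post-removal geometric mean:

* **Subsampling**: without-replacement subsamples of stated sizes
  (deliberately not a with-replacement bootstrap — the protocol models
  "what if we had acquired fewer cells", not resampling noise).
* **20% perturbation**: a chosen number of distinct cells have their values
  multiplied by 1.2, emulating calibration error in a subset of events;
  the geometric mean of the result can exceed the unperturbed one by at
  most a factor 1.2, which the tests assert.

Baseline comparators are included: the mean-plus-3-SD rule (single pass)
and size-only bin-count rules, `ceiling(sqrt(n))` and `floor(n^(1/3))`
(the latter exponent configurable). The exact formulas used by the
commercial packages they caricature are not public in our sources; both are
documented approximations whose point is that they ignore the data's shape.

## 2. The synthetic-data generators

The generators are first-class, tested code; they define the package's
"stated world":

* `generate_population()`: lognormal/Gamma/Weibull draws at the scales seen
  in endothelial receptor data (default lognormal $\mu = 7.83$,
  $\sigma = 0.57$, i.e. a geometric mean of ~2,500 receptors/cell), default
  $n = 20{,}000$ cells — the order of a gated cytometry acquisition; the
  data sets motivating this package all exceeded 20,000 events.
  Contamination is a tight cluster, uniform over $[0.95, 1.05] \times$
  center, placed at a multiplier (default 10) of the clean 99th percentile:
  any tight, detached right-tail artifact cluster suffices to exercise the
  cutoff, and the uniform shape keeps the planted/clean boundary crisp for
  ground-truth scoring. Exactly
  $\lfloor \text{fraction} \times n \rfloor$ cells are planted and labeled.
* `generate_mixture()`: tri-modal Gaussian draws with strictly descending
  weights; negative draws are rejected and redrawn (truncation would bias
  component means); true labels are kept as a side channel.

What the generators do **not** emulate: raw fluorescence, bead-calibration
curves, scatter gating, FCS files, instrument noise floors, or continuum
heavy-tail contamination blending into the physiological tail. A green
outlier-removal test therefore establishes that the cutoff finds *detached*
artifact clusters without touching the bulk — not that it optimally
resolves contamination overlapping the genuine tail.

## 3. The compartment model

Three well-mixed compartments — normal tissue, blood, diseased tissue —
carry free VEGF, free anti-VEGF, their 1:1 complex, GAG-bound VEGF in the
tissue compartments, and free/occupied receptors (VEGFR1, VEGFR2, NRP1) on
six cell surfaces: healthy endothelium (luminal surface in blood, abluminal
in normal tissue), tumor endothelium (luminal in blood, abluminal in
diseased), tumor cells and myocytes (interstitial). Structural assumptions:

* Receptors are pre-dimerized homodimers: one binding site per counted
  receptor, no dimerization kinetics or heterodimers. NRP1 is a pure
  VEGF-binding sink (no co-receptor coupling).
* Luminal and abluminal endothelial surfaces carry equal receptor levels; a
  whole-cell update of $L$ receptors/cell puts $L/2$ on each surface.
* Receptor turnover is insertion at $s_R$ (pM/s in compartment units) and
  internalization of free *and* bound receptor at $k_{int}$, so the total
  surface level obeys $d(R + RV)/dt = s_R - k_{int}(R + RV)$ and relaxes to
  $s_R / k_{int}$ independent of ligand. Updating a receptor level rescales
  $s_R = \text{level} \times k_{int}$, so the requested level *is* the
  drug-free steady state. (The unoccupied level alone equals
  $s_R/k_{int}$ only when ligand is absent; the tests check both the total
  in the full model and the free level in a secretion-free configuration.)
  Internalization of the bound complex is what makes free VEGF sensitive to
  receptor levels — without it, receptors would be inert decorations at
  steady state.
* VEGF is secreted in all three compartments, permeates the vessel wall
  (bidirectional, flow conductances in L/s), drains via lymph from tissue
  to blood, and is cleared from plasma. Antibody and complex share the
  transport structure scaled by a macromolecular permeability factor (0.3)
  and a slow plasma clearance. All binding is mass-action.

The anchored constants — control levels of 1,100 VEGFR1 and 700 VEGFR2 per
cell, the 50/50 surface split, a $t = 0$ bolus into blood, a 3-week
horizon, and $K_d(\mathrm{VEGFR1}) < K_d(\mathrm{VEGFR2})$ (10 vs 100 pM
here; VEGFR1 binds VEGF more tightly) — are wired exactly. Everything else
(volumes, cell counts, rate constants, secretion) is an order-of-magnitude
literature-plausible choice declared once in `default_model_config()`,
tuned only so that drug-free steady states land at physiological scales
(free VEGF of order 1–100 pM, interstitial above plasma). Consequently
**absolute pM outputs are illustrative**; directions and structure are the
claims: the tests assert that the bolus lowers diseased free VEGF, that
steady-state free VEGF is monotone decreasing in local receptor level, and
that an equal-fold VEGFR1 increase depresses free VEGF more than the same
VEGFR2 increase.

The efficacy readout is the fold change
$FC = (V(3\,\mathrm{wk}) - V(0^-))/V(0^-)$ per compartment, where $V(0^-)$
is the pre-injection steady state; increases are positive. Against a
control run, $FC/FC_{\mathrm{control}}$ is reported (the defining formula
in our sources is redacted; this form reproduces the stated sign
convention). The insertion-rate sensitivity scan uses the
$s_R = \text{level} \times k_{int}$ convention as a declared substitute for
an unpublishable geometry-dependent relationship.

### Numerics

No stiff ODE solver package is assumed: integration uses a package-internal
adaptive Rosenbrock 2(3) scheme (the method behind MATLAB's `ode23s`) with
forward-difference Jacobians refreshed every step, relative tolerance
$10^{-8}$. The drug-free steady state is found by a logarithmically spaced
long integration ($\sim$46 days) followed by damped-Newton refinement and
is *verified* (relative residual $< 10^{-9}$) before dosing; failure to
verify is an error. Concentrations more negative than $10^{-4}$ of the
state scale abort the run; smaller negative round-off is clamped to zero at
output. The closed-form anchors — the binding quadratic of
$L + R \rightleftharpoons C$ in a closed compartment and the
$s_R/k_{int}$ receptor fixed point — are checked to 0.1% against the
integrator in the acceptance tests.

## 4. Degenerate inputs and tie rules (summary)

* All-equal samples: histogram construction and MLE refuse (zero range /
  degenerate likelihood); the 3-SD rule keeps everything (threshold equals
  the common value).
* Nonpositive values: `receptor_sample()` drops and counts them at
  ingestion (they are physical impossibilities in calibrated data); raw
  numeric vectors passed directly to fitting or statistics functions
  instead raise an error naming the offending count, since silent dropping
  would hide a support violation the caller should know about.
* Samples below 100 cells are rejected by `low_bin_search` — binning is
  meaningless there.
* SSE ties in the $k$-scan go to fewer bins; largest-bin ties to the
  leftmost bin; mode ties to the smaller value.

## 5. Known limitations

* **Cross-range SSE comparisons are not meaningful.** Because the SSE is a
  sum of squared *densities*, its numeric value scales as
  $1/\mathrm{range}^2$. Comparing the minimum SSE before and after removing
  a detached outlier cluster (which shrinks the range several-fold)
  therefore shows an *increase* even when the fit demonstrably improves on
  a common histogram. One acceptance expectation encodes the literal
  before/after comparison and is intentionally red, with the
  fit-improvement statement asserted on a common histogram alongside it.
* Family selection runs on the *contaminated* sample (by construction —
  selection precedes removal), so heavy contamination can flip the selected
  family even when removal then succeeds; the refit is performed within the
  selected family rather than re-selecting.
* The mixture component count is fixed at three; no information-criterion
  selection, and no non-Gaussian mixture families.
* The compartment model omits intracellular signaling, receptor trafficking
  beyond insertion/internalization, tumor growth dynamics, and any per-cell
  compartment expansion; it is a vehicle for propagating representation
  choices, not a calibrated pharmacokinetic predictor.
* The bin-count baselines are stand-ins for undisclosed commercial
  formulas and should not be quoted as those products' behavior.
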