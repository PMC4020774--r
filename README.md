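# hetpop

Statistical characterization of heterogeneous single-cell surface-receptor
populations, and propagation of the chosen representation into a
compartmental model of anti-VEGF therapy.

## The problem

Calibrated flow cytometry yields tens of thousands of per-cell surface
receptor counts (receptors/cell) for receptors such as VEGFR1, VEGFR2 and
NRP1. These populations are strongly right-skewed — usually lognormal- or
Gamma-like with heavy right tails — and contain a small number of
non-physiological events (debris, doublets, saturated signal). Deterministic
models of ligand–receptor pharmacokinetics need a *single* receptors/cell
value per cell type, so two questions arise:

1. How should outliers be removed from a heavy-tailed population without a
   presupposed distribution and without discarding genuine tail biology?
2. Which single-value representation (geometric mean, arithmetic mean, mode,
   median, or a mixture decomposition) should be injected into the model —
   and how much do model predictions depend on that choice?

`hetpop` answers both with the **low bin search** procedure plus a
three-compartment VEGF/anti-VEGF kinetic-transport model.

## The method

For a sample x₁…x_N, candidate two-parameter densities f are Weibull(a, b),
Gamma(a, b) and lognormal(μ, σ), fitted by maximum likelihood on the raw
values. Against a k-bin equal-width histogram with centers cᵢ and counts
nᵢ, a fit is scored by

    SSE(k) = Σᵢ ( nᵢ/(N·w) − f(cᵢ) )² ,  w = bin width,

and low bin search proceeds in three steps:

1. **Family selection** — the family with the lowest SSE (Gaussian is kept
   only as a baseline; it is never selected).
2. **Optimal bin number** — k\* = argmin over k ∈ [5, 200] of SSE(k), with
   parameters held at the raw-data MLE.
3. **Outlier cutoff** — on the k\*-histogram, the leftmost bin strictly
   right of the largest bin whose own count *and* both neighbors' counts are
   below 1% of the largest bin's count (a 500-cell largest bin demands
   "fewer than 5 cells"); that bin and everything to its right is removed,
   and the family is refitted on the kept cells.

Representative statistics (geometric mean exp(mean(log x)), arithmetic
mean, mode, median) are computed on the cleaned, unbinned values. Multimodal
tumor populations are decomposed by a tri-modal Gaussian mixture (EM, best
of 10 seeded k-means starts); mixture-level values are the density-weighted
sums Σ w_m·stat_m. Two bootstrap protocols (random subsampling; 20% value
perturbation of a random subset) quantify robustness.

The compartment model tracks free VEGF, free anti-VEGF, their complex,
GAG-bound VEGF, and free/occupied VEGFR1, VEGFR2 and NRP1 on six cell
surfaces across normal tissue, blood and diseased tissue. Endothelial
receptors split 50/50 between luminal (blood) and abluminal (tissue)
surfaces; receptor insertion s_R and internalization k_int fix the surface
level at s_R/k_int. An anti-VEGF bolus enters blood at t = 0 and the stiff
ODE system is integrated for 3 weeks; the fold change
FC = (V(3 wk) − V(0⁻))/V(0⁻) per compartment, optionally normalized to a
control run, is the efficacy readout.

## Worked example

```r
library(hetpop)
s <- generate_population(population_spec(
  family = "lognormal", param1 = 7.83, param2 = 0.57,
  n_cells = 20000, contamination_fraction = 0.003,
  contamination_location = 10, seed = 7))
res <- low_bin_search(s)
print(res)
#> low_bin_result: best family gamma, k* = 12
#>   cutoff bin 4 (>= 2.535e+04 receptors/cell): 60 cells removed
representative_stats(res$kept)
#> geometric mean 2523 | arithmetic mean 2974 | mode 1934 | median 2521 receptors/cell
```

All 60 planted contaminant cells (0.3% of 20,000, placed at 10× the clean
99th percentile) are removed and no more: the cutoff lands at ~25,350
receptors/cell, between the physiological tail and the artifact cluster.
The geometric mean (2,523) sits between the mode (1,934) and the
tail-inflated arithmetic mean (2,974), which is why it is the preferred
single-value representation for lognormal-like receptor data.

Propagating that value into the model:

```r
m <- apply_receptor_update(vegf_model(), "healthy_ec", "VEGFR1",
                           representative_stats(res$kept)$geometric_mean)
fold_change(simulate_model(m, dose_schedule()),
            simulate_model(vegf_model(), dose_schedule()))
#>   compartment        pre       post          fc fc_normalized
#> 1      normal 11.7546256 11.5282059 -0.01926217     0.8850847
#> 2       blood  0.7526776  0.9693639  0.28788733     0.9004309
#> 3    diseased 21.9210579 18.8286830 -0.14106869     1.0231974
```

Raising healthy-endothelial VEGFR1 from the control 1,100 to ~2,523
receptors/cell lowers pre-treatment free VEGF in the normal-tissue and
blood compartments (`pre` here is already the updated steady state) and
changes the post-bolus fold change relative to control — the
data-representation choice visibly moves the predicted drug response.
Absolute pM values are illustrative: the model is structurally faithful but
re-parameterized with order-of-magnitude literature values (see the methods
vignette).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "hetpop.R", package = "hetpop"))') \
  synth --n 20000 --contamination 0.003 --seed 7 --out sample.csv
# then: lowbin / stats / mixture / bootstrap / simulate / scan / run / init-config
```

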