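# factorlens

Interpretability tooling for deep non-linear tensor factorizations of fMRI.
A 4D scan compressed into three mode factor matrices and a fixed core tensor,

```
X = G ×₁ f(A) ×₂ f(S) ×₃ f(C),
```

is informative but opaque. `factorlens` makes it legible along two routes:

* **Formula distillation.** A factor matrix is re-encoded as coordinate
  triplets `(i, j, value)` and an *equation-learner* network — hidden units
  apply elementary operators (`sin`, `cos`, product, safeguarded quotient,
  `log|·|`, …) to linear combinations of their inputs — is trained to
  regress the value on the normalized coordinates under the smoothed-L1/2
  penalty

  ```
  L = ‖y − ŷ‖² + λ Σ L½*(w),   L½*(w) = |w|^½ for |w| ≥ a,
                                smooth quartic surrogate for |w| < a
  ```

  and then pruned at a coefficient threshold (0.01), after which the
  surviving network is read off as a closed-form formula.  Fit quality is
  reported as *verification accuracy*: the percentage of held-out matrix
  elements predicted within 5% of the observed value range.

* **Brain-network comparison.** Frames rebuilt from the factors form a 4D
  reference tensor; regional signals are averaged over a labeled
  parcellation (116 ROIs in eight subnetworks); dependence between regions
  is histogram mutual information `I = H(R₁) + H(R₂) − H(R₁,R₂)`; and the
  116×116 connectivity matrices are compared between groups edge by edge
  with ANCOVA and Benjamini–Hochberg FDR control at q = 0.05.

Seeded synthetic generators (six built-in closed-form factor surfaces,
random factorized tensors, phantom parcellations, two-group time series
with planted connectivity differences) make every stage runnable and
testable with no imaging data.  Intended users: methods researchers who
need a transparent, fully reproducible desk-scale reference for this
interpretability stack.

## Worked example

Distill a formula from a synthetic factor surface:

```r
library(factorlens)

s   <- formula_surface("sagittal-normal", 100, 100, noise_frac = 0.01, seed = 11)
fit <- fit_surface_formula(s$triplets, seed = 11, restarts = 2, epochs = 1500)
fit$report
#> <accuracy_report> 100.00% within 0.05 of range (n = 2000, MAE 0.0005611, NRMSE 0.009824)
formula_text(fit$formula)   # one restart's distilled expression (seed-dependent)
```

The report says every held-out matrix element was predicted within 5% of
the observed value range (accuracy 100%), with a normalized RMSE under 2%.

Compare two simulated groups with one planted edge:

```r
spec <- planted_difference_spec(n_rois = 8, n_time = 100, n_per_group = 20,
                                edges = cbind(2, 5), effect_size = 5, seed = 1)
g    <- group_timeseries(spec)
conn <- function(subjects) lapply(subjects, \(x) build_connectivity(x$series, bins = 16))
cmp  <- edgewise_group_comparison(conn(g$groupA), conn(g$groupB))
cmp
#> <edge_comparison> 8 ROIs, 28 edges, 1 significant at FDR q = 0.05
subset(cmp$edges, significant)
#>   roi_a roi_b diff_mean statistic      p_value      q_value significant
#> 8     2     5 0.5935357  199.0122 1.097312e-16 3.072473e-15        TRUE
```

The single edge whose dependence was strengthened in group B (2–5) is the
one flagged after FDR correction; its mean MI difference is the `diff_mean`
column, in bits.

A full simulate → connectome → compare run, with a JSON manifest recording
seeds, parameters and artifact digests, is available as
`run_pipeline(config)` (R list or YAML) and through the thin CLI at
`inst/cli/factorlens`.

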