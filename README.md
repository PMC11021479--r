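# piriform

Tools for comparing the odor representations carried by the two axonal
pathways that converge on the olfactory bulb (OB): the feedforward input
from olfactory sensory neurons (OSNs) and the feedback projections from
piriform-cortex (PC) neurons, imaged as axonal boutons in the bulb. The
central empirical contrast is that OSN activity scales strongly with
stimulus drive (mixture complexity, odorant concentration) while cortical
feedback activity is equalized — similar density and sparseness for every
stimulus, with nonmonotonic concentration tuning in single boutons.

The package provides, as tested reusable components:

- **Response analysis pipeline** for ΔF/F response tensors
  (ROI × stimulus × trial): significance classification against blank-trial
  noise (mean ± 3 SD per ROI), response-polarity classes, effective-odorant
  counts, lifetime and population sparseness, ranked-normalized tuning
  curves and their spread, Pearson representational similarity at trial or
  stimulus level, within-stimulus trial reliability, hierarchical ordering
  of correlation matrices, and mixture-overlap group comparisons.
- **Polarity null model**: the Monte-Carlo chance level for purely
  enhanced / purely suppressed / mixed ROIs under independent draws from
  the pooled response-label distribution, with an exact closed form
  (pure-enhanced = (p_N + p_E)^n − p_N^n, and symmetrically).
- **Bulb-to-cortex rate model** with global activity-dependent inhibition:
  glomerular output x_i(c) = η_i κ_i c / (1 + κ_i c); cortical voltages
  τ du_j/dt = −u_j − w_inh σ(β(v − v_thr)) + Σ_i W_ji x_i with rectified
  outputs y_j = max(u_j, 0); interneuron voltage τ dv/dt = −v + Σ_j y_j.
  The model yields rise–dip–recover dose–response curves in individual
  cortical neurons and monotonically decreasing response latencies.
- **Synthetic data generators** that emulate both populations' statistics
  (sublinear OSN density scaling, stimulus-independent bouton density,
  higher bouton trial variability, a minority of suppressed responses),
  so the full pipeline is exercisable without any imaging data.

## Worked example

Chance-level polarity fractions for 16 odorants at the pooled label
distribution (72.2% non-responsive, 12.4% enhanced, 15.4% suppressed):

```r
library(piriform)
simulate_polarity_null(c(0.722, 0.124, 0.154), n_odors = 16,
                       n_boutons = 10000, seed = 1)
#> <polarity_null_result> 10000 ROIs x 16 draws (p = 0.722/0.124/0.154 N/E/S)
#>   pure_enhanced      6.52% +/- 0.64%  (analytic   6.34%)
#>   pure_suppressed   11.19% +/- 0.81%  (analytic  11.48%)
#>   mixed             81.85% +/- 0.99%  (analytic  81.64%)
#>   silent             0.44% +/- 0.17%  (analytic   0.55%)
```

If response polarity were assigned independently per odorant, more than
80% of ROIs would show mixed polarity; observed populations are far more
polarity-conserved than that, which is the point of the null model.

Feedforward vs feedback contrast on synthetic tensors (100-stimulus
mixture panel: 16 odorants, 24/20/20/20 mixtures of sizes 2/4/8/12):

```r
panel  <- make_mixture_panel(seed = 1)
osn    <- simulate_osn_tensor(panel, osn_params(seed = 1))
bouton <- simulate_bouton_tensor(panel, bouton_params(seed = 1))

summarize <- function(tensor) {
  cl   <- classify_responses(tensor, n_sd = 3)
  keep <- filter_rois(cl)
  ps   <- sparseness_report(cl$trial_mean[keep, ])$population_sparseness
  rel  <- within_stimulus_reliability(
    representational_similarity(tensor, "trial", rois = keep))
  c(retained = length(keep),
    vapply(c(1, 2, 4, 8, 12),
           function(sz) mean(ps[panel$n_components == sz]), numeric(1)),
    reliability = mean(rel, na.rm = TRUE))
}
round(rbind(OSN = summarize(osn), bouton = summarize(bouton)), 3)
#>        retained PS_size1 PS_size2 PS_size4 PS_size8 PS_size12 reliability
#> OSN         345    0.367    0.422    0.538    0.720     0.837       0.801
#> bouton      712    0.466    0.467    0.467    0.463     0.473       0.539
```

OSN population sparseness climbs from 0.37 (single odorants) to 0.84
(12-part mixtures) — activity becomes denser and more uniform as more
glomerular channels are recruited — while bouton sparseness stays flat
near 0.47 at every mixture size, and bouton trial-to-trial reliability
(0.54) is lower than OSN reliability (0.80).

Nonmonotonic concentration tuning from the circuit model:

```r
spec <- circuit_spec(sample_glomerular_panel(400, seed = 1),
                     sample_projection(5000, 400, seed = 2),
                     interneuron_population(w_inh = 1, beta = 2,
                                            v_thr = 2000))
dr <- dose_response(spec, default_concentration_grid(24))
sum(detect_nonmonotonicity(dr$responses)$nonmonotonic)  # e.g. ~1500 of 5000
```

A command-line dispatcher over the same functions lives in
`inst/scripts/piriform-cli.R` (subcommands `simulate-circuit`,
`dose-response`, `make-synthetic`, `analyze`, `polarity-null`).

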