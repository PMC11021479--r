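---
title: "Feedforward and feedback odor representations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedforward and feedback odor representations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piriform)
```

# The scientific problem

The olfactory bulb receives two very different axonal inputs that can be
imaged with calcium indicators: feedforward afferents from olfactory
sensory neurons (OSNs), whose activity tracks stimulus drive, and feedback
axons from piriform-cortex neurons, imaged as boutons. When stimulus drive
is varied — by mixing more monomolecular odorants into a blend, or by
raising concentration — OSN population activity becomes denser in a
stimulus-dependent way, whereas feedback activity stays at a similar
density and sparseness for every stimulus, and individual boutons show
nonmonotonic concentration tuning. This package implements three things:
the analysis pipeline that quantifies those contrasts from ΔF/F response
tensors, a Monte-Carlo null model for response-polarity classes, and a
minimal bulb-to-cortex rate model in which global activity-dependent
inhibition produces the nonmonotonic tuning.

# The rate model

## Equations

The output of glomerulus $i$ to an odorant at concentration $c$ is a
saturating receptor-binding curve

$$x_i(c) = \eta_i \frac{\kappa_i c}{1 + \kappa_i c},$$

where $\kappa_i$ is the binding affinity and $\eta_i \in \{0, 1\}$ the
activation efficacy. Log-affinities are i.i.d. $N(0, 3^2)$ (natural log),
so affinities span roughly three orders of magnitude; efficacies are
i.i.d. Bernoulli(0.2), so an odorant activates about 20% of glomeruli at
saturation. Concentration is expressed in affinity-relative (inverse
median-$\kappa$) units.

Cortical (principal-cell) voltages $u_j$ and interneuron voltages $v_k$
integrate

$$\tau \frac{du_j}{dt} = -u_j
  - \left\langle w_{inh}^{(k)}\,
     \sigma\!\left(\beta^{(k)} (v_k - v_{thr}^{(k)})\right)\right\rangle_k
  + \sum_{i} W_{ji} x_i, \qquad
  \tau \frac{dv_k}{dt} = -v_k + \sum_j y_j,$$

with rectified outputs $y_j = \max(u_j, 0)$ and the logistic
$\sigma(z) = 1/(1+e^{-z})$ (the sigmoid is not further specified by the
circuit hypothesis; the logistic is the standard bounded choice). The
angle bracket is the interneuron-population mean, which reduces to the
single-interneuron term for a homogeneous population — chosen so the
heterogeneous variant reproduces the homogeneous model exactly at zero
jitter. All times are in units of the membrane time constant $\tau$, so
$\tau$ never appears in the integrator.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $N_g$ | 400 | count | glomeruli |
| $N_p$ | 5000 | count | cortical neurons |
| $\mathrm{sd}(\log \kappa)$ | 3 | natural log | affinity spread |
| $P(\eta_i = 1)$ | 0.2 | probability | active glomeruli per odor |
| $W$ density | 0.1 | probability | non-zero projection entries |
| $W$ scale | 0.5 | — | half-normal scale of non-zero entries |
| $w_{inh}$ | 1 | voltage | global inhibitory weight |
| $\beta$ | 2 | 1/voltage | sigmoid steepness |
| $v_{thr}$ | 2000 | voltage | inhibition threshold |
| $dt$ | 0.01 | $\tau$ | Euler step |
| duration | 20 | $\tau$ | integration window |

At these values the mean bulbar drive per cortical neuron at saturating
concentration is $N_g \cdot 0.1 \cdot 0.2 \cdot 0.5\sqrt{2/\pi} \approx
3.2$, which the tests verify by direct Monte Carlo conditional on the
realized active-glomerulus set. Because the saturating drive (≈ 3.2)
exceeds $w_{inh} = 1$, the model has the full three-phase behaviour:
activity rises until the summed cortical output reaches $v_{thr}$, global
inhibition subtracts up to $w_{inh}$ from every neuron (the dip), and at
high concentration excitation overcomes the bounded inhibition (the
recovery). Test circuits that shrink $N_p$ scale $v_{thr}$ proportionally
($v_{thr} \propto N_p$, i.e. 2000 at $N_p = 5000$) and keep $N_g = 400$
when the recovery phase matters, since shrinking $N_g$ lowers the
saturating drive below $w_{inh}$ and removes the second rising phase.

For heterogeneous inhibition, 500 interneurons each scale
$(w_{inh}, \beta, v_{thr})$ by independent $1 + \varepsilon$ factors,
$\varepsilon \sim N(0, 0.2^2)$. A negative product is unphysical and is
clipped at zero (probability $\approx 5\times 10^{-7}$ per draw). An
exactly-zero $\beta$ after clipping would be degenerate and is nudged to
the smallest positive double.

## Numerical choices

- **Integration**: forward Euler at $dt = 0.01\tau$ over $20\tau$. The
  dynamics are first order and smooth; tests verify that halving $dt$
  changes steady states by less than $10^{-3}$ relative, and that frozen-
  inhibition fixed points ($u_j = \sum_i W_{ji} x_i - w_{inh} g$ for
  constant $g \in \{0, 1\}$) are met within $10^{-3}$.
- **Stimulus protocol**: $x$ is switched on at $t = 0$ and held constant,
  from zero initial conditions.
- **Steady-state readout**: mean of $y$ over the final 20% of the trace,
  robust to residual oscillation of the inhibitory loop near threshold.
- **Latency**: first crossing of 50% of the steady state, which gives the
  closed form $\tau \ln 2$ for the inhibition-free step response (verified
  within one $dt$); neurons with zero steady state get `NA`.
- **Nonmonotonicity**: a neuron is flagged when some response falls below
  the running maximum by more than 10% of the curve's peak; the dip index
  is the deepest such point. An all-zero curve is never flagged.
- **Instability guard**: the integrator aborts with an explicit error if
  any $|u_j|$ exceeds $10^6$.
- **Concentration grid**: 24 points log-spaced over $10^{-3}$–$10^{3}$
  (affinity-relative), mirroring the three orders of magnitude of affinity
  spread on both sides.

## What the model does and does not claim

Two behaviours deserve care when interpreting "nonmonotonic":

- Individual responsive neurons are nonmonotonic in a substantial
  fraction (the tests require a non-empty set at the default parameters
  and exactly zero when $w_{inh} = 0$). The *population-mean* curve,
  however, is monotone: while inhibition is interior the loop pins the
  summed output near $v_{thr}$, producing a plateau, not a dip. The
  smoothing effect of heterogeneous inhibition is therefore tested on
  single-neuron curves (mean maximum concentration-step drop), where
  jittered thresholds recruit inhibition gradually.
- Median response latency *decreases* steeply up to the inhibition onset
  and then partially rebounds, because the half-max criterion tracks a
  steady state that inhibition has reduced. The monotone-decrease claim
  therefore holds as an overall trend (Spearman $\rho \le 0$ across the
  grid), which is what the tests assert, not as a strict step-by-step
  decrease.

The model deliberately omits spiking, conductances, plasticity, and a
mitral-cell intermediate layer (the bulb-to-cortex transform is taken as
linear), and it is not fitted to any imaging data — it is a plausibility
argument, exercised here only for its qualitative signatures.

# The response pipeline

Inputs are ΔF/F response amplitudes (the mean signal in a fixed window
after odorant onset), organized ROI × stimulus × trial, plus blank
(no-odorant) trials.

- **Classification**: each ROI's thresholds are its blank mean ± $n$ blank
  SDs (default $n = 3$), applied to the across-trial mean amplitude with
  strict inequalities. Thresholds are per-ROI because noise levels differ
  across ROIs; an ROI with zero blank variance falls back to the pooled
  blank distribution and is flagged. Only ROIs with at least one
  significant response (enhanced *or* suppressed) are retained.
- **Sparseness**: the activity-ratio form
  $\left(\sum r/n\right)^2 / \sum (r^2/n)$, applied across ROIs for one
  stimulus (population sparseness) or across stimuli for one ROI (lifetime
  sparseness); bounded in $(0, 1]$, equal to 1 for uniform vectors and
  $1/n$ for one-hot vectors, invariant to positive scaling, and
  transpose-dual. Inputs are absolute magnitudes by default so suppressed
  responses contribute; a signed mode is available
  (`sparseness_report(..., signed = TRUE)`). All-zero vectors return `NA`
  with a warning.
- **Ranked tuning curves**: absolute responses sorted descending and
  normalized to the maximum; ties keep stimulus order. The per-stimulus
  population curves' mean absolute deviation from their across-stimulus
  mean curve quantifies how stimulus-dependent the activity distribution
  is.
- **Similarity**: Pearson correlation between population vectors at trial
  or trial-mean level; zero-variance vectors yield `NA` entries that are
  excluded from block averages. Trial-level matrices collapse to stimulus
  level by averaging trial-pair blocks (off-diagonal pairs on the
  diagonal blocks — that average is also the within-stimulus reliability).
- **Hierarchical ordering**: average linkage on distance $1 - r$;
  the leaf order derived from one population (e.g. OSNs) can be applied
  to the other population's matrix. `NA` entries enter as zero
  correlation. Linkage is not dictated by the analysis; average linkage
  is the common choice for correlation matrices.
- **Mixture overlap**: $|a \cap b| / \max(|a|, |b|)$, so the single 75%
  criterion means ≥ 6 shared of 8 and ≥ 9 shared of 12, and is
  conservative for 8-vs-12 pairs; Jaccard is available behind a flag.
  The overlap comparison partitions all pairs among size-8 and size-12
  mixtures at the threshold and compares the two correlation samples.

# The polarity null model

Under the null that an ROI's 16 response labels are independent draws
from the pooled label distribution $(p_N, p_E, p_S)$, the category
probabilities are closed-form: silent $= p_N^{16}$, pure-enhanced
$= (p_N + p_E)^{16} - p_N^{16}$, pure-suppressed symmetric, mixed the
remainder. The Monte-Carlo version draws 10,000 simulated ROIs
(multinomial label counts) and reports fractions with 99% binomial
half-widths $2.576\sqrt{\hat p(1-\hat p)/n}$. "10,000 simulations" is
interpreted as 10,000 simulated ROIs: at the reference label distribution
(72.2/12.4/15.4%) the binomial half-widths at $n = 10^4$ are ±0.63 and
±0.99 percentage points for the enhanced and mixed categories,
matching the published ±0.6 and ±1.0 — while the published ±0.3 for the
suppressed category is narrower than any binomial interval consistent
with the other two, so the package reports its own binomial CI for that
category rather than matching it. The exact form is verified against
exhaustive enumeration of all $3^3$ outcomes at $n = 3$, and the
Monte-Carlo against the exact form within 4 standard errors across random
probability triples. Fractions are reported over *all* simulated ROIs;
silent ROIs (~0.5% at the reference distribution) form their own
category, which is why the three named categories sum to slightly less
than 100%.

# The synthetic generators

The generators provide tensors with the statistical structure the
analyses assume, so every pipeline stage is testable without imaging
data. They are statistical emulators, not biophysical models.

**OSN generator.** Each ROI gets a sparse per-component sensitivity
profile (each of 16 components is sensed with probability 0.15, with
log-normal magnitudes, meanlog $\log 0.6$, sdlog 0.8). A mixture's drive
is the sum of component sensitivities passed through a saturating
nonlinearity $s/(1+s)$ (`additive_saturating`, default), or through a
competitive-binding rule in which a component can bind without activating
(`antagonistic`, agonist probability 0.6) — both produce the sublinear
density scaling with mixture size that the analyses require; neither is a
claim about mechanism. Concentration series use per-ROI Hill functions
(coefficient 1.5, midpoints log-uniform over 0.003–0.3 relative
concentration) so recruitment spreads across the 3-decade series. A
random 10% of ROIs carry sign-flipped (suppressed) tuning. Trials add
i.i.d. Gaussian noise; blank trials are the same noise around zero.

**Bouton generator (direct mode).** Every stimulus independently recruits
ROIs at the same target density 0.278 (the pooled responding fraction per
odorant, 12.4% enhanced + 15.4% suppressed), with log-normal magnitudes
and a conserved per-ROI polarity (enhanced with probability
0.446 = 12.4/27.8). Density, sparseness and mixture-mixture similarity
are therefore stimulus-independent by construction. In circuit mode the
responses are steady-state outputs of the rate model across a
concentration series, rescaled to ΔF/F-like units, and inherit its
nonmonotonic tuning.

**Noise calibration.** Trial noise is set from the variance decomposition
$r = V_{signal}/(V_{signal} + \sigma^2)$ to the target within-stimulus
trial reliabilities — about 0.78 for OSNs ($\sigma = 0.13$) and about
0.53 for boutons ($\sigma = 0.25$); the tests assert the ordering and
approximate levels on the default mixture panel.

**Default sizes.** 400 OSN ROIs and 800 bouton ROIs, 3 trials per
stimulus, 6 blank trials — the scale of the reference datasets while
staying fast on a laptop; the acceptance checks run the full 100-stimulus
mixture panel at these sizes and the full-size circuit
($N_p = 5000$, 24 concentrations).

**What the generators do *not* emulate**, and hence what passing tests do
not show about real data: no temporal dynamics within a trial (amplitudes
only), no correlated trial-to-trial variability across ROIs (the
"correlated variability" correction applied to real recordings is
deliberately not implemented; an optional blank-drift subtraction would
be its nearest simple analogue), no photon/indicator noise model, no
spatial structure, and blank-trial noise equals response-trial noise. A
consequence of that last simplification: at reliability 0.53 and design
density 0.278 many true bouton responses sit below the 3-SD detection
threshold, so the *measured* significant-response density is well below
the design density (the real data's blank noise is evidently smaller than
its trial-to-trial response variability). The pipeline contrasts —
rising vs flat sparseness, overlap effects, reliability ordering — are
unaffected, and the construction-level density is what the tests check
against its binomial CI.

**Classification operating characteristics** are checked under the
conditions where they are nominal: the false-positive rate equals
$2\Phi(-3) \approx 0.27\%$ when the tested statistic has the same noise
as the blank trials (single-trial responses, well-estimated thresholds),
and planted responses of 5 blank-SDs are detected at ≥ 99% sensitivity
with three trials (trial averaging shrinks the test statistic's noise by
$\sqrt{3}$). With few blank trials per ROI the realized false-positive
rate is mildly inflated by threshold-estimation error — that is a
property of the 3-SD procedure itself, not of the implementation.

# Reproducibility

Every sampling function takes a `seed`; one user-facing seed expands into
independent named streams (panel, projection, interneurons, mixtures,
osn, bouton, polarity) so components can be regenerated independently,
and all functions restore the caller's RNG state. `scripts/acceptance.R`
recomputes the polarity-null chance levels from scratch for any seed.
Tensors serialize to a plain-text container (full-precision CSV + JSON
sidecars) that round-trips bitwise.

# Known limitations

- The rate model's concentration units are affinity-relative; mapping to
  liquid-dilution percentages would require a calibration the model does
  not attempt.
- Population-mean dose-response curves can be reported over all neurons
  or responsive neurons only; both are trivially obtained from the
  per-neuron matrix, and the package takes no position on which average
  is the right summary.
- The pipeline starts at response amplitudes: no motion correction, ROI
  segmentation or trace extraction.
- Real-data values (e.g. lifetime sparseness levels, trial reliabilities,
  effective-odorant counts) depend on the imaging data and are exercised
  here only as qualitative orderings on synthetic tensors.
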