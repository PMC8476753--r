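---
title: "Quantifying motion differences with movement primitives and symmetric KL divergence"
author: "prompkl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion differences with movement primitives and symmetric KL divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prompkl)
```

## The problem

Non-invasive brain stimulation studies ask whether a stimulation condition
(tDCS, tACS, tRNS, or a Sham placebo) changes how people move. A common
protocol records repetitive finger tapping between two instrumented pads
with inertial sensors on the hand and wrist (six acceleration channels),
before stimulation (the `Prae` baseline) and at several time points after
(`Post1`–`Post3`), across several tapping patterns and participants.

Hand-crafted kinematic features (peak velocities, onset times, frequency
bands) require domain-specific post-processing and transfer poorly across
tasks. `prompkl` instead learns features directly from the data: each cell
of the study is summarized by a *Probabilistic Movement Primitive* (ProMP) —
a Gaussian distribution over whole trajectories — and two cells are compared
with a closed-form symmetric Kullback–Leibler divergence between the induced
trajectory distributions.

## The model

**Phase normalization.** Each stroke (one pad-to-pad movement) is resampled
onto a common phase grid $z \in [0, 1]$ by rescaling its own duration, so
trajectory *shape* is modeled independently of duration
(`normalize_time()`, `phase_grid()`).

**Basis.** The regression features are $M$ Gaussian bumps with centers $c_i$
uniform on $[0,1]$ and common bandwidth $h = 0.2\,(c_{i+1}-c_i)^2$,
normalized per phase point so each row of the basis matrix
$\Phi \in \mathbb{R}^{T \times M}$ sums to one (`make_basis()`). The
bandwidth rule ties the overlap of neighboring bumps to their spacing, so
$M$ is the only free model-capacity parameter.

**Ridge weights.** With $D = 6$ channels the feature matrix
$A = I_D \otimes \Phi$ is block diagonal, and each stroke, vectorized
channel-major into $\tau \in \mathbb{R}^{TD}$, gets a weight vector by
damped least squares:
$$ W^\star = (A^\top A + \lambda I)^{-1} A^\top \tau, $$
with $\lambda = 10^{-6}$ by default (`fit_weights()`). The ridge term
matters: duplicated or barely varying demonstrations make $A^\top A$
ill-conditioned.

**Distribution over trajectories.** Collapsing the per-stroke weight columns
gives a weight mean $\mu_w$ and unbiased sample covariance $\Sigma_w$
(`fit_weight_distribution()`). Marginalizing the weights yields a Gaussian
over trajectories; per channel $d$ and phase point $t$,
$$ y_{t,d} \sim \mathcal{N}\!\left(\phi_t^\top \mu_w^{(d)},\;
   \phi_t^\top \Sigma_w^{(dd)} \phi_t + \sigma_{y,d}^2\right), $$
where $\sigma_{y,d}$ is the per-channel residual RMS of the ridge
reconstruction (`estimate_noise()`, `marginal_distribution()`).

**Divergence.** For univariate Gaussians the symmetric KL divergence has the
closed form
$$ D_{KLS} = \tfrac14\left(\tfrac{\sigma_1^2}{\sigma_2^2} +
   \tfrac{\sigma_2^2}{\sigma_1^2} +
   (\mu_1-\mu_2)^2\left(\tfrac1{\sigma_1^2}+\tfrac1{\sigma_2^2}\right)
   - 2\right), $$
(`kls_gaussian()`). Two trajectory distributions are compared by applying
this to every (phase point, channel) marginal and averaging over the $T$
points and the six axes (`trajectory_kls()`). A sliding window (default
width $1/10$ of the phase) localizes *where* in the movement two
distributions differ (`sliding_window_kls()`).

The multivariate alternative — a full 6-dimensional Gaussian KL per phase
point — is deliberately not implemented: the analysis averages univariate
per-channel divergences, which keeps the measure interpretable per axis and
avoids estimating $6 \times 6$ covariances from 20 strokes.

## The study pipeline

`run_pipeline()` chains the stages: per-cell preprocessing
(`detect_taps()` → `segment_strokes()` → `select_strokes()` →
`normalize_time()`), one ProMP fit per cell and movement direction,
baseline-versus-post divergences
$D_{KLS}(\tau'_{\text{Prae}} \| \tau'_{\text{Post}k})$ per participant,
stimulation, experiment and direction (`compare_phases()`), 3σ outlier
exclusion (`detect_outliers()`), and aggregation (`aggregate_results()`).
The familiarization phase `Erst` is fitted but never enters statistics —
participants explore during it — and requesting otherwise is refused.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `M` | 20 | basis functions; capacity of the trajectory model |
| `T` (`phase_grid`) | 100 | phase resolution of the common grid |
| `lambda` | 1e-6 | ridge regularizer |
| `n_select` | 20 | strokes fitted per cell and direction |
| `threshold` | 0.5 | tap threshold, fraction of the pad-channel maximum |
| `refractory` | 0.1 s | dead time between taps on one pad |
| `window_fraction` | 0.1 | sliding-window width in phase |

`M` is selected by the reconstruction loss: the mean $D_{KLS}$ between each
cell's empirical per-phase distribution and its ProMP reconstruction
(`reconstruction_loss()`, `select_basis_size()`). The loss falls steeply
from $M = 5$ to $M = 20$ on smooth tapping data; pushing $M$ far higher
starts fitting sensor noise.

### Stroke selection

Of the $K$ strokes per direction, positions $K-20$ through $K-1$ are fitted
(1-based). The final stroke is always excluded because the stop signal
contaminates it; the earliest strokes are excluded because they still carry
tempo-settling transients. At least 21 strokes per direction are therefore
required, and cells that fall short are logged as missing rather than
aborting the run.

### Outlier rule

A comparison unit (participant × stimulation × experiment × comparison) is
excluded when its divergence exceeds $\mu_D + 3\sigma_D$ in either movement
direction; only the high side is excluded, since unusually *small*
divergences are valid. $\mu_D$ and $\sigma_D$ describe the non-corrupted
data, so for each unit they are computed from the pooled values of all
*other* units. This matters in small studies: a sensor misplacement (axis
flip) corrupts both direction rows of its unit, and if those rows entered
the statistics they would inflate $\sigma_D$ enough to hide themselves (with
16 rows, two equal gross outliers can never exceed a pooled 3σ threshold —
the maximal attainable $z$ is about 2.7).

The flip side is honest to state: with few rows the $3\sigma$ threshold is
itself estimated from ~14 skewed values, so the false-alarm probability per
small study is appreciable (we measure roughly 25% for a 16-row study under
the null; it vanishes at full study scale where thousands of rows stabilize
the threshold). The rule is a screening device, not a hypothesis test.

## The synthetic-data generator

No raw recordings are distributed with this kind of study, so the package
generates its own (`generate_study()`), with the statistical structure the
analysis assumes:

* **Template.** Strokes follow a minimum-jerk acceleration profile
  $a(z) \propto 60z - 180z^2 + 120z^3$ — smooth, biphasic, antisymmetric
  about mid-phase — scaled per channel; outward strokes are the
  time-reversed, sign-negated counterpart of inward strokes. This is a
  declared stand-in for real stroke waveforms, not a claim about them.
* **Variability.** Per-stroke, per-channel Gaussian amplitude multipliers
  (CV 10%), log-normal stroke durations (5%), and a smooth per-stroke shape
  perturbation built from 8 Gaussian bumps per channel with coefficient
  standard deviation 10% of the channel amplitude. The shape term is
  essential, not cosmetic: phase normalization removes duration variability
  entirely, so without it all normalized variability collapses onto six
  amplitude degrees of freedom and the null distribution of downstream
  divergences becomes unrealistically heavy-tailed — human stroke-to-stroke
  variability is high-dimensional in shape.
* **Acquisition.** 2000 Hz sampling, 30 tap cycles at 1.5 taps/s, a 0.1 s
  dwell on each pad, a 20 ms rectangular pulse on the pad channel at every
  contact, and additive Gaussian sensor noise (sd 0.05 in units of the
  unit-peak template) on all motion channels.
* **Design.** 10 participants × 4 stimulations × 5 phases × 8 experiments
  = 1600 recordings; each cell owns a random substream hashed from the root
  seed, so any cell is reproducible in isolation.
* **Effects and anomalies.** `stimulation_effect()` shifts and/or scales
  the template, optionally confined to a phase sub-interval and to chosen
  recording phases; `anomaly_spec()` plants axis flips/swaps that emulate
  sensor misplacement.

What the generator does *not* emulate: gravity components and orientation
drift, tremor spectra, fatigue trends within a recording, cross-channel
noise correlation, and any true stimulation physiology. Passing tests on
synthetic data therefore validate the *pipeline machinery* — segmentation,
fitting, divergence arithmetic, exclusion logic — not claims about real
stimulation effects.

## Numerical choices

* Standard deviations entering the divergence are floored at $10^{-8}$ of
  the channel RMS (and empirical/noise estimates at $10^{-6}$ absolute) so
  duplicated strokes cannot divide by zero.
* $\Sigma_w$ receives a diagonal jitter of $10^{-9}\,\mathrm{tr}/(MD)$;
  with 20 strokes and $MD = 120$ weights the sample covariance is rank
  deficient, which is benign because only per-channel marginal variances
  are consumed downstream.
* `kls_gaussian()` is written so that every term is symmetric at the
  floating-point level: swapping the arguments returns bit-identical values.
* Double contacts on one pad are reduced to their first event with a
  warning; vectorization is channel-major (all phase points of channel 1,
  then channel 2, ...); interpolation is linear.
* The optional zero-phase 20 Hz low-pass (`lowpass_filter()`) is off by
  default: a limited number of smooth basis functions already suppresses
  high-frequency noise in the fitted means.

## Problem sizes used by the tests and the acceptance script

Counting checks run the full 1600-cell design at 150 Hz (the counts do not
depend on the rate); distribution-level checks use 250–500 Hz, 60–100
phase points and $M$ = 10–20, chosen so the whole suite completes in about
a minute while leaving every statistical conclusion unchanged at full
resolution (spot-checked at 2000 Hz / $T = 100$ / $M = 20$).

## Known limitations

* The ProMP ignores stroke duration by construction; a stimulation effect
  expressed purely in timing would be invisible after phase normalization.
* $\sigma_y$ is per-channel and diagonal; cross-channel noise correlation
  is not modeled. Whether a shared noise term would be preferable is
  unresolved — per-channel is the conservative choice.
* Expectation–maximization fitting of the weights is not implemented;
  ridge regression is the operative estimator.
* The 3σ rule's small-sample false-alarm behavior discussed above.
* Conditioning on via-points, mixtures of primitives and task
  parameterization are out of scope.
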