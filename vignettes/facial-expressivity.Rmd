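---
title: "Quantifying facial expressivity from action-unit classifier scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial expressivity from action-unit classifier scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(facexpr)
library(dplyr)
```

## The measurement problem

Parkinson's disease attenuates spontaneous facial expression ("facial
masking", hypomimia). Clinician rating scales capture this only coarsely, so
this package implements an automated alternative: per-video-frame outputs of
binary action-unit (AU) classifiers — signed distances to an SVM decision
boundary for eleven FACS AUs — are converted into calibrated intensity time
series, and the dynamics of those series are summarized into a small set of
expressivity statistics per 30 s stimulus window. Companion physiological
channels (single-lead ECG, two facial EMG channels over the levator labii
superioris and orbicularis oculi) provide an independent check that the
emotional stimulus engaged the same musculature.

The pipeline deliberately starts *after* face tracking and AU
classification: its input contract is the per-frame decision-value table,
not video. That keeps the package testable end to end with synthetic inputs
whose ground truth is known exactly.

## From decision values to intensities

A decision value $h$ is mapped to a posterior probability with the Platt
sigmoid

$$P(y = +1 \mid h) = \frac{1}{1 + \exp(A h + B)},$$

with $(A, B)$ fitted by maximum likelihood on labelled scores
(`fit_platt()`; Newton iterations with backtracking on the regularized
targets $t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$, the standard
smoothing that keeps the likelihood bounded). Note the sign convention of
the exponent: a fitted slope is *negative* whenever larger scores mean
stronger evidence, and all downstream code relies on "probability increases
with the decision value". A decision value of exactly zero is classified
positive; the tie has probability zero under any continuous score
distribution, it just needs one documented rule.

One sigmoid is fitted (or supplied) per AU. The per-AU choice is an
interpretation — a single shared sigmoid is equally expressible by passing
the same coefficients for every AU — but per-AU score distributions differ
enough in practice that per-AU calibration is the safer default.

The per-frame probability series $I_t$ is smoothed with a Gaussian kernel
(`smooth_intensity()`, reflective boundaries, kernel truncated at four
standard deviations and renormalized so constants pass through exactly).
The default bandwidth of 3 frames at 25 fps suppresses single-frame
classifier flicker without erasing sub-second AU events; it is a
convention, not a recorded property of any particular camera, and both the
frame rate and the bandwidth are configurable.

## Activity, phases, and the expressivity statistics

A frame is **active** when the smoothed intensity $\tilde I_t$ reaches the
activation threshold, 0.5 by default — the natural decision boundary of a
calibrated classifier. The comparison is inclusive ($\ge$), so a series
sitting exactly at the threshold is active. An alternative rule that takes
the raw binary decision $\operatorname{sign}(h)$ as the activity mask is
available (`au_intensity(..., activation = "decision")`) because the
underlying construct ("the AU is displayed") could be read either way.

Maximal runs of active frames form activation episodes, labelled
neutral → onset → apex → offset: the apex plateau is every frame within 5
percent of the episode maximum around the peak, frames before it are onset,
after it offset, and a single-frame episode is pure apex.

Per window, with $T_i$ the active-frame set of AU $i$ and
$N_i' = |T_i|$:

* **TFA** — the number of displayed AUs (those with
  $N_i' \ge$ `min_active_frames`, default 1);
* **AI** $= \sum_{i \in \mathrm{DAUs}} \frac{1}{N_i'} \sum_{t \in T_i}
  \tilde I_t(\mathrm{AU}_i)$ — summed mean active intensity;
* **AMC** $= \sum_{i \in \mathrm{DAUs}} \frac{1}{N_i'} \sum_{t \in T_i}
  \left| \tilde I_t - \tilde I_{t+1} \right|$ — summed mean absolute first
  difference. The absolute value is a deliberate reading: a signed sum
  telescopes to a boundary difference and cannot measure movement. By
  default the difference is only taken between consecutive frames of the
  same active run — the frame after a run's last active frame is not part
  of the displayed behavior — with the literal all-active-frames variant
  behind `within_runs = FALSE`;
* **FE** $= \mathrm{AMC}_e + \mathrm{AI}_e$ over the emotional window;
* **EFE** $= (\mathrm{AMC}_e + \mathrm{AI}_e) - (\mathrm{AMC}_n +
  \mathrm{AI}_n)$, the same statistic corrected by the subject's own
  neutral window. The correction is what separates two phenotypes of
  masking: attenuated emotional response lowers FE and EFE alike, whereas
  *failure to relax* (tonic activity during neutral viewing) leaves FE
  high and pulls EFE down. EFE may legitimately be negative.

The canonical disgust signature — brow lowerer AU4, cheek raiser AU6, lid
tightener AU7 and nose wrinkler AU9 simultaneously active — is counted per
frame by `disgust_pattern_frames()`. Blink (AU45) is outside the
formulation because the upstream classifier set does not include it.

Metrics are kept in raw probability units; multiplying by 100 for display
is a formatting choice (`scale_pct = TRUE` in `run_pipeline()`) and never
feeds back into computation.

```{r}
scores <- generate_au_scores(archetype_params("C"), n_frames = 300, seed = 2)
intens <- au_intensity(scores$scores, c(A = -2, B = 0))
window_metrics(intens)
```

## Physiological branch

**Denoising.** Signals are decomposed by empirical mode decomposition
(cubic-spline envelopes through mirrored extrema, Cauchy-type sifting
stop). Each intrinsic mode function is thresholded at its universal
threshold $\tau_k = \sqrt{2 E_k \log N}$ with the per-IMF noise energy
taken from the white-noise cascade $E_k = (E_1/0.719)\,2.01^{-(k-1)}$. The
anchor $E_1$ is estimated robustly as the square of
$\min\{\mathrm{MAD}(\mathrm{IMF}_1),\ \mathrm{MAD}(\Delta x)/\sqrt 2\}$:
both statistics read the noise scale off the finest scale, and the minimum
protects a clean slow oscillation that lands in IMF 1 from being mistaken
for noise. Thresholding operates on whole zero-crossing intervals (an
interval is kept when its extremum exceeds $\tau_k$, zeroed otherwise);
per-sample soft shrinkage is available for comparison
(`method = "soft"`) but clips every oscillation near its zero crossings
and measurably loses SNR on ECG-like signals.

**R peaks.** Candidate change points come from bottom-up merging of
degree-1 least-squares segments (initial segments ≈ 16 ms; adjacent
segments merge while the cost increase stays below a penalty of
$6\hat\sigma^2\log n$, with $\hat\sigma$ from the MAD of the first
difference). Candidates are refined to the local maximum within ±30 ms,
scored by prominence (peak height above the ±200 ms local median), kept
when prominence exceeds the threshold — by default 60 percent of the 99th
percentile of candidate prominences, making the rule amplitude-scale-free —
and deduplicated by a 0.3 s refractory rule that keeps the more prominent
peak. RR intervals outside 0.3–2.0 s are discarded as non-physiologic
before rate statistics.

**HR/HRV/AMV.** Each RR interval gives an instantaneous rate $60/RR$ in
bpm; HR is its mean and HRV its sample standard deviation ("variation of
beat-to-beat heart rate" is not a single canonical estimator; RMSSD is
offered as an alternative). EMG amplitude is the rectified mean
$\mathrm{AMV} = \frac1N \sum |x_t|$ — rectification is required for a
zero-mean signal; the literal signed mean is available for audit — and is
reported as a percentage of the subject's own 30 s neutral baseline, which
cancels inter-individual amplitude differences and any global gain.
Stimulus windows are always the *trailing* 30 s thin slice of a record
(`extract_thin_slice()`).

## The synthetic cohort

`simulate_cohort_data()` / `generate_cohort()` draw four groups — control
(C) and three Parkinson severity archetypes (least/intermediate/most
severe: LP, IP, MP) — with three windows each (two disgust, one neutral).
AU activations are trapezoids in intensity space (linear onset ramp, flat
apex, linear offset) over a baseline, placed by a Poisson episode count per
AU and window; intensities are pushed through the *inverse* of a known
Platt sigmoid so that the decision values handed to the pipeline calibrate
back to the intended profile, then perturbed with Gaussian score noise
(SD 0.25 decision units). ECG is a PQRST Gaussian template train with
Normal instantaneous heart rate; EMG is Gaussian noise with a burst-
modulated envelope. Every generated file carries its ground truth (episode
boundaries and apexes, beat times, burst ratios) so tests never re-derive
truth from the data.

The archetype defaults encode the two masking phenotypes and were fixed
once from an expected-value calculation, before any test was run, so that
the qualitative group orderings hold in expectation with margins of at
least a few subject-level standard errors at 20 subjects per group:

| group | episodes/AU/window | apex mean | tonic neutral level (AUs) |
|---|---|---|---|
| C  | 1.5 | 0.85 | 0.02 (none) |
| LP | 0.9 | 0.65 | 0.30 (AU4, AU25 — below threshold) |
| IP | 1.0 | 0.80 | 0.75 (AU4, AU6, AU25) |
| MP | 0.5 | 0.62 | 0.55 (AU4, AU25, AU9) |

Neutral windows draw episodes at 0.3 times the stimulus rate. With AI
approximately (number of displayed AUs) × (mean active intensity), the
expectations are FE ≈ 6.7 (C) > 5.1 (IP) > 3.7 (LP) > 2.3 (MP) and EFE ≈
4.1 (C) > 2.3 (LP) > 1.4 (IP) > ≈0 (MP): the LP archetype expresses masking
as attenuation (low FE, moderate EFE), the IP archetype as failure to relax
(high FE, low EFE), so FE ranks IP above LP while the baseline-corrected
EFE inverts them — precisely the behavior the correction exists to capture.
The frame rate defaults to 25 fps; the window length to 30 s (750 frames).
The 25 fps value is a video convention, not a measured property.

What the generator does *not* emulate: correlated classifier errors across
AUs (scores are conditionally independent given the profile), head-pose and
illumination artifacts, EMG crosstalk between adjacent muscles, ECG
baseline wander and electrode artifacts, and any within-subject coupling
between facial and autonomic responses beyond the group labels. Passing
tests therefore demonstrate that the *computational chain* is correct and
that the statistics separate the encoded phenotypes — not that the pipeline
is robust to every artifact of real recordings.

## Group statistics

`rank_sum_test()` is the two-sided Wilcoxon rank-sum with an exact branch
for combined samples up to 20 (closed-form null distribution when tie-free,
complete enumeration of group assignments under ties, using the tail mass
of $|W - \mathbb E W|$) and a tie-corrected normal approximation with
continuity correction beyond. `mixed_anova()` is the classical two-way
mixed design (group between subjects, stimulus within) via error-strata
sums of squares; subjects missing a stimulus level are dropped with a
warning that names them, and with three or more within levels a
Greenhouse–Geisser epsilon (pooled within-group covariance, capped at 1)
accompanies the within-subject terms. Post-hoc stimulus contrasts are
paired t tests with Bonferroni adjustment — a deliberately conservative
default since no particular post-hoc procedure is canonical here.
Significance language throughout uses $\alpha = 0.05$.

## Numerical choices and degenerate inputs

* Sigmoid evaluation uses the sign-split stable form; probabilities can
  saturate to exactly 0/1 in double precision at extreme arguments, which
  downstream code tolerates.
* Inverting the sigmoid in the generator needs probabilities away from
  $\{0, 1\}$: profiles are floored at 0.02 and capped at 0.98.
* `fit_platt()` refuses single-class input (unbounded likelihood) and
  non-finite scores; the Newton step carries a $10^{-12}$ ridge.
* Zero/constant signals: `emd_denoise()` returns them unchanged; the peak
  detector raises an error (no events; RR undefined), as does a detection
  yielding fewer than two peaks.
* `rank_sum_test()` on two samples with no variation returns p = 1.
* Frames are 0-based and episode bounds half-open `[start, end)` in every
  table that leaves the package.
* Problem sizes in the test-suite simulations (for example 400 null ANOVA
  replicates in the unit test and 1000 in the acceptance script; 20-seed
  detector and denoiser sweeps; 10 cohort seeds at 20 subjects per group)
  were chosen as the smallest sizes at which the binomial/Monte-Carlo error
  of each check is comfortably below its decision margin.

## Known limitations

* The expressivity statistics inherit any bias of the upstream AU
  classifiers; calibration fixes the probability scale, not classifier
  errors.
* AMC depends on the smoothing bandwidth: heavier smoothing deflates it.
  Comparisons are only meaningful at a fixed configuration, which the
  pipeline records in its provenance block.
* The EMD noise model assumes approximately white broadband noise; highly
  colored interference (mains hum) would need a notch stage this package
  does not provide.
* The change-point R detector assumes a dominant upright R deflection;
  inverted-QRS leads would need a sign flip upstream.
* With only a handful of subjects per group the mixed ANOVA is fragile;
  the rank-sum tests are the more defensible summary at pilot scale.
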