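---
title: "Topological EEG features and intentional time binding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological EEG features and intentional time binding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`topobind` implements an end-to-end analysis of how self-reflection styles
relate to the implicit sense of agency: Libet-clock intentional-binding
scoring on the behavioral side, and spectral, complexity-theoretic and
topological features of four-channel EEG on the neural side, joined by a
nonparametric statistical battery.  Because no human recordings ship with
the package, a first-class synthetic-data module generates EEG-like
signals and clock-judgment trials with known ground truth, so that every
stage of the pipeline has a recoverable target and every claim in the test
suite is checked against an independent oracle.

# The behavioral model: intentional time binding

In a Libet-clock task a dot rotates with period $T$ (default
$T = 2560$ ms, the standard convention; the period is configurable and all
millisecond outputs scale with it).  The subject reports the dot angle at
which an event (a voluntary keypress or a tone) occurred.  The signed
judgment error is the wrapped angular difference mapped to time,

$$ \Delta = \left(((\theta_{rep} - \theta_{act} + 180) \bmod 360) - 180\right)
   \frac{T}{360}, $$

positive when the event is reported *later* than it occurred.  Four
conditions are run (20 trials each, 80 total): action-only and tone-only
baselines, and two agency conditions in which a keypress is followed by a
tone after 250 ms, judged either on the action or on the tone.  Binding
scores per subject are

* action binding = mean agency action error − mean action-only error,
* tone binding = mean agency tone error − mean tone-only error,
* **total binding = action binding − tone binding**,

so that mutual attraction of action and tone (action perceived later,
tone earlier) gives a positive total.  The sign convention is printed with
every report (`binding_convention()`); with an injected action shift of
+40 ms and tone shift of −40 ms the total is 80 ms.  Judgment noise is
modeled as Gaussian on the reported time — an explicit assumption, since
no empirical error model is available; reported angles wrap onto
$[0, 360)$.

# The EEG feature stack

## Preprocessing

Raw 256 Hz four-channel recordings (TP9, AF7, AF8, TP10, the Muse-S
montage) are band-pass filtered 0.1–45 Hz with a 50 Hz notch.  A
meaningful "fourth-order" FIR does not exist at a 0.1 Hz edge, so the
kernel length follows the Hamming transition-bandwidth rule
($\approx 3.3 f_s / \Delta f$, capped at 8193 taps) and is applied
zero-phase by compensating the linear-phase group delay; the notch is a
narrow FIR band-stop at 49–51 Hz.  The passband (1–40 Hz) is flat to well
under 1 dB and 50 Hz is attenuated by more than 20 dB (both asserted in
tests on pure tones).

Muscle-artifact screening decomposes the recording with a deterministic
symmetric FastICA (tanh contrast, seeded initialisation, sign fixed by
the largest mixing weight).  Per component we report

* `slope_7_45`: the slope of a log–log fit to the component PSD over
  7–45 Hz.  The fit uses 12 log-spaced bins, each summarised by its lower
  quartile, and is refit after dropping the two most peak-inflated bins —
  this estimates the *spectral floor*, robust to narrowband rhythms
  leaking through the unmixing;
* `focality`: max |mixing weight| / Σ|mixing weights|;
* `smoothness`: the $R^2$ of that trimmed fit.

A component is flagged when slope > 0 and focality > 0.6 (both
configurable).  The smoothness threshold defaults to 0 (reported, not
gating): calibration on synthetic mixtures showed that with only four
channels the floor fit of a genuinely broadband component is degraded by
rhythm leakage, while clean brain components fit *better* — $R^2$ does
not separate the classes, whereas slope and focality do with wide
margins.  Reconstruction excludes flagged components; with nothing
flagged it reproduces the input to numerical tolerance.

TP9/TP10 and AF7/AF8 are pooled by averaging into TP and AF channels.
Reflection sessions consist of eight 30 s questions; the analysis uses
the **last 25 s** of each question, while control sessions contribute the
**central 25 s** of the 240 s block (offset 107.5 s, symmetric about the
midpoint; half-open sample intervals, 0-based offsets).  Before
topological and complexity analysis, segments are decimated by 4 (FIR
anti-aliasing) to 64 Hz.

## Spectral features

Welch PSDs use 4 s Hann windows with 50 % overlap (configurable; the
frequency resolution is $1/\text{window}$).  Relative band power over the
six bands delta (0.5–5), theta (5–8), alpha (8–13), sigma (13–16), beta
(16–30) and gamma (30–45 Hz) is the **mean PSD per band divided by the
sum of the six band means** — deliberately *not* the integrated-power
fraction; a regression test pins this variant, which differs measurably
on non-flat spectra.  Band edges are half-open $[low, high)$.  Features
of the eight questions are averaged element-wise per subject and channel.

## Topological features

Each 64 Hz segment is delay-embedded (Takens), row $j$ being
$(x_j, x_{j+\tau}, \dots, x_{j+(m-1)\tau})$.  Defaults: $m = 3$; $\tau$
from the first local minimum of time-delayed mutual information (16
quantile bins) — for noiseless periodic signals this estimator is noisy,
which is expected and documented, so tests probe it with realistic noise.
Clouds are reduced by deterministic farthest-point subsampling (seeded at
the point farthest from the centroid) to at most `subsample_to` points;
full Rips filtrations to dimension 2 on the raw 1584-point clouds are not
tractable, and the subsample bound is part of the reported configuration.

Vietoris–Rips persistence is computed over $\mathbb{Z}/2$ by boundary-
matrix reduction with the clearing (twist) optimisation, in compiled
code: H0 via union–find (its finite deaths are exactly the MST edge
lengths — an oracle test), H1/H2 via reduction of the dimension-2 and
dimension-3 boundary matrices.  Simplices enter at their diameter; the
filtration is capped at `max_radius` (default twice the median pairwise
distance); bars alive at the cap are recorded with death $\infty$.  The
test suite validates whole diagrams against an independent brute-force
GF(2) persistent-homology oracle (persistent Betti numbers from dense
rank computations) on hundreds of small random clouds.

From the diagram of dimension $k$ we compute

* **Betti curves** $\beta_k(s)$ — bars alive on $[b, d)$ at each grid
  radius (default 100 radii over $[0, \text{max\_radius}]$);
* **persistence entropy** — Shannon entropy (natural log) of normalised
  finite lifetimes; infinite bars are excluded, and a diagram with no
  finite bars has entropy 0 with a warning;
* **Wasserstein amplitude** — distance to the empty diagram, each bar
  matched to the diagonal at L2 ground-metric cost
  $(d_i - b_i)/\sqrt{2}$, i.e.
  $\left(\sum_i ((d_i - b_i)/\sqrt2)^p\right)^{1/p}$ with $p = 2$ by
  default.  The $\sqrt2$ diagonal factor is a fixed, documented
  convention.

## Hodge spectral entropy

At a chosen filtration radius the Rips complex yields oriented boundary
matrices $B_n$; the order-$n$ Hodge Laplacian is
$L_{[n]} = B_n^{\top} B_n + B_{n+1} B_{n+1}^{\top}$ (for $n = 0$, the
graph Laplacian of the 1-skeleton).  With eigenvalues $\lambda_i$ and
damping $\alpha$ (default 1; natural logs make the identity exact), the
spectral entropy is the Gibbs entropy

$$ S^{hs}_n = \alpha \langle \lambda \rangle + \ln Z_n, \qquad
   Z_n = \sum_i e^{-\alpha \lambda_i}, \quad
   \langle \lambda \rangle = \frac{1}{Z_n} \sum_i \lambda_i
   e^{-\alpha\lambda_i}, $$

which equals $-\sum q_i \ln q_i$ for $q_i = e^{-\alpha\lambda_i}/Z_n$ and
therefore lies in $[0, \ln N_n]$, approaching $\ln N_n$ as
$\alpha \to 0$.  `build_hodge_laplacian()` defaults to the radius at
which the 1-skeleton first becomes connected (the largest MST edge).
The *pipeline*, however, evaluates spectra at **1.5× the connectivity
radius** (`hodge_radius_mult`): at the bare connectivity radius the
2-skeleton is barely populated and the order-2 entropy was empirically
flat in signal bandwidth, whereas at 1.5× it separates oscillatory from
broadband segments strongly and monotonically.  A guard refuses
complexes beyond `max_simplices` order-$n$ simplices rather than
attempting an infeasible dense eigendecomposition.

## Complexity features

Sample entropy uses pattern length $m = 2$ and tolerance
$r = 0.2 \times \mathrm{SD}$ with Chebyshev template distance, templates
starting at $1..N{-}m$ for both lengths and self-matches excluded; zero
match counts yield an undefined (`NA`) value rather than an error.
Multiscale entropy coarse-grains by non-overlapping window means
(scales 1–20 by default) and — following the common convention — keeps
the tolerance fixed from the *original* series SD across scales
(per-scale SD is available behind a flag).  The implementation is
checked against a brute-force $O(N^2)$ double-loop oracle on every test
series up to $N = 300$.

# The synthetic-data module

The generator is the package's study-conditions contract, not a tuning
knob:

* **EEG**: per band, a quasi-sinusoidal oscillation — carrier at the band
  centre with slow Brownian phase drift (linewidth
  $\max(0.05, 0.02 \cdot \text{bandwidth})$ Hz) and 20 % slow amplitude
  modulation — mixed across channels with non-focal weights; an
  independent $1/f^{\gamma}$ background per channel (spectral shaping of
  white noise, $\gamma = 1$ by default); an optional common 50 Hz
  sinusoid; and an optional muscle artifact: noise with PSD rising as
  $f^2$ between 5 and 60 Hz under a bursting log-normal envelope,
  injected into a single channel.  The envelope matters twice over — it
  matches the intermittency of postural EMG, and it makes the source
  super-Gaussian, hence actually identifiable by ICA (spectrally shaped
  Gaussian noise is not).  Band-passed-noise "rhythms" were rejected as
  the oscillation model because their embedded clouds are topologically
  indistinguishable from broadband background.
* **Fixtures**: a pure sine (period 32 samples), a two-tone mixture, the
  first coordinate of the standard Lorenz trajectory
  ($\sigma = 10, \rho = 28, \beta = 8/3$, `deSolve`), and white noise.
* **Trials**: the 4 × 20 randomized schedule with uniform event angles,
  Gaussian judgment noise, and injectable per-condition shifts.

Everything is bit-reproducible given the seed, with RNG state isolated
per call.

What the generator does **not** emulate: volume conduction or electrode
geometry (no forward model), eye blinks (reflection happens eyes-closed),
non-stationary drift across a session, or realistic cross-channel
correlation structure beyond shared band sources.  Passing tests
therefore demonstrate correctness of the *computations* and
recoverability of *injected* structure — not that the features behave
identically on human EEG.

## The built-in TTB–entropy coupling

In the end-to-end study simulation each subject's true total binding is
drawn from their group's distribution (SCR 123 ± 75, SLR 51 ± 41,
CTR 82 ± 54 ms), drives their trial simulation (action shift $+TTB/2$,
tone shift $-TTB/2$, 70 ms judgment noise), and is mapped to an EEG
irregularity $c = \mathrm{clip}(0.5 - 0.4\,(TTB - 85)/60,\ 0.05,\ 0.95)$:
larger binding ⇒ more dominant alpha rhythm and weaker broadband
background ⇒ loop-like embedded clouds with fewer high-order simplicial
degrees of freedom ⇒ lower order-2 Hodge entropy.  This induces the
negative TTB–$S^{hs}_2$ correlation that the pipeline's Pearson stage
must recover; the recovery rate over seeded replicate runs is part of the
acceptance checks.  The reference scale (85 ± 60 ms) is the grand mean
and spread of the three group means.

# Statistical battery

* Shapiro–Wilk per group gates the choice of nonparametric tests
  (`normal` ⇔ p > 0.05); degenerate constant samples are reported
  non-normal instead of erroring.
* Mann–Whitney U, one-tailed as designed (SCR > SLR, SLR < CTR,
  SCR > CTR), exact for small untied samples and normal-approximated
  with tie correction otherwise (delegated to `stats::wilcox.test`, and
  verified against full enumeration for $n \le 6$).
* Kruskal–Wallis with $\varepsilon^2 = H (n+1)/(n^2-1)$ and the
  conventional magnitude cut-offs (small .01–.06, medium .06–.14,
  large ≥ .14).  This $\varepsilon^2$ variant is fixed; it is bounded by
  $H/(n-1) \le 1$ and invariant under monotone transforms.
* Pearson correlation with the two-sided t-based p-value; zero-variance
  inputs yield an `NA` flag.
* Power analysis for a paired Wilcoxon signed-rank design by two routes:
  the ARE correction of the one-sample t size ($n_t / 0.955$, rounded
  up) and a direct Monte-Carlo search over $n$.  At $d = 0.6$,
  $\alpha = 0.05$ one-tailed and power 0.95 the ARE route gives
  $n = 33$.  The power analysis uses a *paired* test although the study
  design is between-subjects; it is implemented as specified and the
  mismatch is noted here.
* No multiple-comparison correction is applied by default (pilot-style
  analysis); a Holm flag exists and every manifest states which mode
  ran.

# Problem sizes and numerical choices

The full study configuration (eight 30 s questions at 256 Hz, 100-point
clouds, all features) is the default of `study_config()`.  The test and
acceptance harnesses run structurally identical reduced studies
(`mini_study_config()`: one 30 s question at 128 Hz, decimation by 2,
40-point clouds, order-2 Hodge entropy only, 5 subjects per group) and
state these sizes as their configuration; noise levels, group effects and
the coupling are unchanged.  Other fixed numerical choices: eigenvalues
clipped at 0 before entropy; zero-persistence pairs dropped from
diagrams; the infinite H0 bar excluded from entropy and amplitude;
diagrams never averaged across questions (scalar features are).

# Known limitations

* Four synthetic channels cannot exercise re-referencing, interpolation
  or realistic ICA mixing ranks; the screener is calibrated on this
  generator and its thresholds should be re-examined on real data.
* The Rips reduction is exact but dense in spirit; clouds beyond a few
  hundred points at dimension 2 are out of scope by design.
* The mutual-information delay estimator is unreliable on noiseless
  periodic inputs (an intrinsic property of binned MI), so `embed_tau`
  is exposed for explicit control and always logged.
* Published Libet-clock group tables sometimes report binding totals
  that are not the arithmetic difference of the printed action/tone
  means (per-subject computation with differing exclusions can cause
  this); this package therefore treats group-level totals strictly as
  simulation inputs and never asserts that identity.
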