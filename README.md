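# topobind

Topological EEG features and intentional time binding: an analysis
workflow for studying how self-reflection styles relate to the implicit
sense of agency.

## The problem

The *sense of agency* — the experience of controlling one's actions and
their outcomes — can be measured implicitly through **intentional
binding**: in a Libet-clock task, a voluntary action and the tone it
triggers are perceived as compressed toward each other in time.  The
analysis implemented here asks whether self-centered reflection (SCR),
selfless reflection (SLR), or no reflection (CTR) modulates that
compression, and whether the **topology** of concurrently recorded
four-channel EEG carries a neural signature of it.

For a signed judgment error
`Δ = (((θ_rep − θ_act + 180) mod 360) − 180) · T/360` (clock period
`T = 2560` ms), per-subject binding scores are

```
action binding = mean(agency action error) − mean(action-only error)
tone binding   = mean(agency tone error)   − mean(tone-only error)
total binding  = action binding − tone binding     (TTB)
```

On the EEG side, each 25 s channel segment is delay-embedded
(`x_j, x_{j+τ}, …, x_{j+(m−1)τ}`), filtered through a Vietoris–Rips
complex, and summarised by persistence diagrams, Betti curves,
persistence entropy `S_k = −Σ p_i ln p_i` over normalised bar lifetimes,
Wasserstein amplitude, and the **Hodge spectral entropy**

```
S_n = α⟨λ⟩ + ln Z,   Z = Σ exp(−α λ_i),  λ_i eigenvalues of
L[n] = Bₙᵀ Bₙ + Bₙ₊₁ Bₙ₊₁ᵀ
```

— the Gibbs entropy of the damped Laplacian spectrum of order-n
simplices.  Conventional features (Welch relative band power in six
bands, multiscale sample entropy) and a nonparametric battery
(Shapiro–Wilk gating, one-tailed Mann–Whitney, Kruskal–Wallis with ε²,
Pearson TTB–feature correlations, Wilcoxon power analysis) complete the
stack.  The Rips reduction, boundary matrices and Hodge Laplacians are
implemented in compiled code inside this package and validated against
brute-force GF(2) homology and MST oracles in the test suite.

Because the underlying human data are not deposited, the package ships a
first-class synthetic-data module: EEG-like signals (quasi-sinusoidal
band rhythms, 1/f background, 50 Hz line noise, optional bursting muscle
artifact for the ICA screener) and Libet-clock trials with injectable
perceptual shifts — every pipeline stage has a recoverable ground truth.

## Worked example

```r
library(topobind)

# trials with a known +40 / −30 ms action/tone shift, no judgment noise
trials <- generate_trials(trial_sim_config(action_shift_ms = 40,
                                           tone_shift_ms = -30,
                                           judgment_noise_sd_ms = 0))
binding_scores(trials, "demo")[, 2:4]
#>   action_binding_ms tone_binding_ms total_binding_ms
#> 1                40             -30               70

# a reduced but complete synthetic study: 5 subjects/group, EEG +
# trials simulated per subject, preprocessing, Hodge entropy, statistics
b <- run_pipeline(mini_study_config(n_per_group = 5, seed = 42))
b$binding_table[b$binding_table$measure == "total", ]
#>   group measure      mean       sd n
#> 3   SCR   total 178.53808 46.19057 5
#> 6   SLR   total  -5.59938 70.11577 5
#> 9   CTR   total  67.66258 39.10051 5
b$correlations
#>   channel feature          r           p  n
#> 1      TP   hse_2 -0.5824617 0.022701444 15
#> 2      AF   hse_2 -0.6796477 0.005315304 15
```

The group totals recover the injected group structure (SCR high, SLR
low), and the order-2 Hodge spectral entropy correlates negatively with
total binding — the coupling built into the generator.

The `analysis/` directory holds the same workflow as numbered thin
drivers (`01_simulate.R` … `05_stats.R`) that write their tables under
`results/`.

## Layout

```
R/                  package code (one file per analysis stage)
src/                Rips persistence / simplex enumeration / SampEn (Rcpp)
analysis/           numbered workflow drivers
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests + oracles
vignettes/          methods vignette (models, parameters, design choices)
```
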