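---
title: "Multi-window weighted CPPopt: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-window weighted CPPopt: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

After severe traumatic brain injury, cerebral autoregulation — the
vasomotor mechanism that keeps cerebral blood flow roughly constant across
perfusion-pressure changes — is often impaired, and the degree of
impairment varies with the cerebral perfusion pressure (CPP = ABP − ICP)
itself. The pressure-reactivity index (PRx) quantifies this state as the
moving Pearson correlation between 10-s averages of arterial blood
pressure (ABP) and intracranial pressure (ICP) over a trailing 5-min
window: near-zero or negative PRx indicates intact reactivity, positive
PRx indicates impairment. Plotting PRx against CPP over a period of hours
typically traces a U-shape; the CPP at its nadir — the "optimal CPP",
CPPopt — is the candidate individualized perfusion target this package
estimates continuously.

The estimator is the multi-window weighted approach. Once a minute:

1. CPP is pre-filtered with a trailing 5-min statistic (median in the
   fine-tuned algorithm, mean in the predecessor) and PRx is Fisher
   transformed (`atanh`) to unbound and approximately normalize it.
2. For each of 36 look-back windows from 2 h 10 min to 8 h in 10-min
   steps, the pairwise-valid (CPP, PRx) samples are grouped into 16
   half-open 5-mmHg CPP bins over 40–120 mmHg; bins holding less than a
   minimum fraction of the window's data are excluded.
3. A quadratic is least-squares fitted to the included bins' (mean CPP,
   mean PRx) and judged by a fixed acceptance stack: enough included
   data (≥ 50%), parabolic shape, minimum fitted PRx span (0.2), overlap
   with the informative PRx band (−0.3 to 0.6), and — in the fine-tuned
   algorithm only — a minimum coefficient of determination computed over
   *all* non-empty bins, `R²_full ≥ 0.2`.
4. Accepted nadirs are combined by a weighted average (weights below) and
   the minute-by-minute result is smoothed with a 2-h exponentially
   weighted average (EWA), weights `(1 − α)^k`, `α = 0.1`.

The two weighting schemes are run from one code path, selected by
configuration: the fine-tuned scheme weights an accepted parabolic fit by
`R²_full` (0 otherwise); the predecessor scheme uses
`exp(−L) · exp(−RMSE) · w_NP` with `L` the window length and `w_NP` 1 for
parabolic, 0 for non-parabolic fits.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| PRx window / cadence | 300 / 60 | s | 30 sample pairs per estimate; 1-min updates of a 5-min window is the established neuromonitoring convention |
| PRx `min_pairs` | 15 | pairs | 50% of 30, mirroring the global missing-data philosophy |
| CPP prefilter | median, 300 s | — | robust to short spikes/drops; the predecessor used the mean |
| bins | 16 over 40–120 | mmHg | 5-mmHg resolution; candidate optima cannot leave this range |
| `min_bin_count_frac` | 0.03 (prev 0.02) | fraction | discards bins fed only by transient excursions |
| `min_included_frac` | 0.5 | fraction | the curve must describe at least half of the window's data |
| `min_y_span` | 0.2 | PRx (ft) | flatter curves carry no optimum information |
| Y region | (−0.3, 0.6) | PRx (ft) | uniformly very high or very low PRx admits no optimum |
| `r2_full_min` | 0.2 (prev: disabled) | fraction | confidence gate evaluated against all non-empty bins, including excluded ones |
| windows | 36, 7800–28800 by 600 | s | multi-window consensus across time scales |
| EWA | α = 0.1 over 7200 s | — | recent estimates dominate; smooths tick-to-tick jitter |
| `missing_data_limit` | 0.5 | fraction | with an 8-h maximal buffer this makes 4 h of valid data the warm-up before the first output |

## The synthetic world

`virtual_patient_spec()` / `simulate_patient()` generate a ground-truth
world for parameter-recovery testing. The target correlation is a
programmable U-shape `ρ(CPP) = curvature·(CPP − opt)² + ρ_min`, clipped to
[−0.99, 0.99]; defaults (`ρ_min = −0.3`, `curvature = 0.004 /mmHg²`) put
ρ at −0.3 at the optimum and +0.6 at ±15 mmHg, spanning exactly the PRx
band the acceptance criteria treat as informative. CPP follows a bounded
reflecting random walk (default 60–90 mmHg, 3 mmHg drift SD per 5 min —
enough to traverse the band several times in a 10-h recording). Signals
are synthesized in 5-min blocks: a standardized AR(1)-smoothed ABP
slow-wave fluctuation (5 mmHg SD) is mixed into the ICP fluctuation
(2 mmHg SD around a 10 mmHg baseline) as
`ρ·z_abp + √(1−ρ²)·z_noise` with the noise orthogonalized in-block, so
the in-block sample correlation — the very quantity PRx estimates — equals
ρ(CPP) exactly before sensor noise (0.5 mmHg SD) is added. Because the
clip bounds ρ away from ±1, a "deterministic linkage" configuration
yields in-block correlation exactly 0.99, not 1; the tests assert the
clipped value.

What the generator emulates: minute-scale slow-wave dynamics, a CPP-
dependent ABP–ICP coupling with a known optimum, gaps, sensor noise.
What it does not: waveform-frequency content (pulse, respiration),
artefacts, therapy-driven nonstationarity, ICP plateau waves, or any
hemodynamically mechanistic coupling. A green parameter-recovery test
therefore establishes that the estimator finds the optimum of the stated
correlation structure — not that it is robust to everything real
recordings contain.

`phase_randomize()` produces pure-noise surrogates with the original
amplitude spectrum but uniformly random phases (conjugate-symmetric, DC
and Nyquist untouched), destroying the ABP–ICP relationship; each signal
is randomized independently, per realization seed.

## Numerical choices and degenerate inputs

* All trailing filters are causal; a bedside algorithm must not peek
  ahead. The output at `t` covers `(t − window, t]`.
* Even-count medians are midpoints of the two central values.
* PRx over a zero-variance window is invalid rather than 0 — silent zeros
  would bias the curve fit toward "intact reactivity".
* Fisher transform clips at `1 − 10⁻⁶` before `atanh`.
* The quadratic is fitted on a centered/scaled abscissa and mapped back;
  singular normal equations yield a "no-fit" verdict, not an error.
* `R²_full` is floored at 0, and defined as 0 when the across-bin
  variance is 0.
* Empty windows, short recordings, and inputs that never clear the
  warm-up produce all-invalid trends with `warmed_up = FALSE`, never
  exceptions; every curve-fit failure is a recorded verdict.
* The engine's per-tick multi-window pass accumulates bin statistics over
  10-min age chunks and cumulates across chunks (all default window
  lengths are multiples of the 10-min step); a direct per-window fallback
  covers non-multiple configurations, and both paths are tested against
  the one-window `bin_window()` contract.

## Design choices where the design was open

* **36 windows, not 37.** "2 h to 8 h in 10-min steps" arithmetically
  yields 37 lengths; the established count is 36. Enumeration is anchored
  at the 8-h window (7800 s up to 28800 s), keeping the longest window —
  which also anchors the 4-h warm-up — exact. The constructor validates
  the (min, max, step, n) quadruple and reports the arithmetic on error.
* **Warm-up.** The 50% missing-data limit is read against the maximal
  8-h buffer: output begins once 4 h of valid input time have
  accumulated in it. Each window additionally skips itself when more
  than 50% of its own span is missing. The EWA output is valid whenever
  its 2-h buffer holds at least one valid raw sample.
* **Criteria order** (data count → shape → span → region → R²) is fixed;
  it affects only the recorded rejection reason, never the verdict.
* **"Parabolic"** means the fit opens upward *and* its vertex lies within
  the included bins' mean-CPP range: a nadir outside the observed CPP
  range is not an observed optimum.
* **Span and region are evaluated on the fitted curve** over the included
  CPP range, not on raw bin means, and all PRx thresholds are applied on
  the Fisher-transformed scale throughout.
* **Bin mean CPP** (not the bin center) is the fit abscissa.
* **Predecessor weight units** (unstated historically): window length in
  hours, fit error as included-bin residual RMSE in Fisher-transformed
  PRx units, `w_NP ∈ {0, 1}`.
* **Configs are JSON**, keys named as the snake_cased parameter names;
  unknown keys are errors.

## Known limitations

* The smoothed-yield metric saturates: because the EWA emits for up to
  2 h after the last accepted window, two variants with different raw
  acceptance rates can tie in yield once both accept something in most
  2-h buffers. The false-positive comparison between variants is
  therefore sharper at the raw (pre-EWA) level than in smoothed yield,
  and the corresponding acceptance check is sensitive to this (see the
  test suite: the strict per-realization yield inequality does not hold
  on every surrogate realization, while the aggregate
  surrogate-vs-structured contrast does).
* With exactly three included bins the quadratic interpolates them, so
  the span criterion and `R²_full` lose discriminating power unless
  excluded bins contradict the fit; this is the main false-positive
  channel left open on pure-noise input.
* Minute-cadence PRx samples share 4/5 of their correlation window;
  bin means are therefore far less precise than independent-sample
  arithmetic suggests. The simulator reproduces this property, which is
  why surrogate runs do produce occasional accepted curves.
* Statistics in the evaluation module are deliberately minimal: the
  univariate logistic-regression AUC is computed as its rank-statistic
  equivalent, and no confidence intervals or AUC-comparison tests are
  provided.
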