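---
title: "Models and methods: murine cardiac electrophysiology under anesthesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: murine cardiac electrophysiology under anesthesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murineEP)
```

# The problem

Invasive electrophysiology (EP) studies in mice require anesthesia, and
anesthetics act on the autonomic nervous system that governs sinus-node
and AV-node behaviour. Comparing regimens therefore requires a complete
quantitative chain: surface-ECG interval measurement, heart rate
variability (HRV) analysis of the RR tachogram, rule-based screening for
spontaneous rhythm disorders, and extraction of invasive
programmed-stimulation parameters, all followed by a consistent group
statistics layer. `murineEP` implements this chain, together with a
synthetic data generator and a virtual heart whose ground truth makes
every stage testable by recovery — no animal data are required to
validate the mathematics.

# The synthetic RR generator

The generator uses a point-process construction in the interval domain.
With cumulative beat time $t_i$ (the time of the beat opening interval
$i$), each interval is

$$RR_i = \bar{RR}\,\bigl(1 + a_{LF}\sin 2\pi f_{LF} t_i
  + a_{HF}\sin 2\pi f_{HF} t_i + a_{W}\sin 2\pi f_{W} t_i\bigr)
  + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

and the next beat is placed $RR_i$ ms later. Amplitudes are fractions of
the mean RR and must sum below 1 so intervals stay positive; modulation
frequencies are constrained to the murine bands (VLF 0–0.15 Hz,
LF 0.15–1.5 Hz, HF 1.5–5 Hz). We chose direct interval modulation over an
integral-pulse-frequency-modulation oscillator: it is simpler, exactly
reproducible, and preserves spectral peak locations at the tolerances
that matter here.

The three named presets emulate the autonomic states of interest:

| preset | mean RR (ms) | LF amp/freq | HF amp/freq | wander | noise (ms) |
|--------|-------------:|------------:|------------:|-------:|-----------:|
| awake  | 126.1 | 0.045 @ 0.40 Hz | 0.050 @ 2.5 Hz | 0.060 @ 0.05 Hz | 3.0 |
| mmf    | 227.3 | 0.040 @ 0.40 Hz | 0.410 @ 2.5 Hz | 0.010 @ 0.05 Hz | 5.0 |
| if     | 157.5 | 0.040 @ 0.40 Hz | 0.045 @ 2.5 Hz | 0.050 @ 0.05 Hz | 2.5 |

The MMF (medetomidine/midazolam/fentanyl) preset encodes deep vagal
dominance: its HF amplitude is sized so that RMSSD comes out near 130 ms
and the successive-difference distribution pushes pRR50 far above the
other groups, while HF captures most spectral power and LF/HF collapses.
The awake and IF (isoflurane/fentanyl) presets keep modest, balanced
modulation. These constants are calibration targets chosen once; the
test suite checks that the full pipeline recovers the intended ordering
and median RR values from generated data, which demonstrates internal
consistency of generator and analysis — not correctness on real mouse
recordings.

# ECG synthesis and delineation

`synthesize_ecg()` renders one stylized complex per beat: squared-sine
(Hann) lobes whose supports are exactly the ground-truth fiducial
intervals (P over `[p_onset, p_offset]`, R over `[qrs_onset,
qrs_offset]`, T over `[qrs_offset, t_end]` — murine T merges with the
terminal QRS, so the T lobe starts at QRS offset). Morphology is
cosmetic; fiducials are the authoritative truth. No Q/S separation is
modeled. Default sampling is 2 kHz; 1 kHz is the enforced minimum so a
~10 ms murine QRS stays resolvable.

Delineation choices, all of which the paper trail of LabChart-era manual
reading leaves open and we therefore fixed explicitly:

* **R detection** — 10–300 Hz zero-phase Butterworth band-pass, squared
  derivative smoothed over 10 ms, adaptive threshold (a fraction of the
  99.9th percentile of smoothed energy), 20 ms refractory lockout
  (murine rates reach 800 bpm, RR ≥ 75 ms, so 20 ms is safe).
* **QRS boundaries** — threshold crossing of the lightly smoothed signal
  at 2% of the local R amplitude (or 2.5 noise SDs, whichever is
  larger), refined by tangent extrapolation to baseline.
* **P search** — a window 12–80 ms before QRS onset. The P wave must be
  an *interior* local maximum of the window: the decaying tail of the
  previous T wave can exceed the amplitude threshold at the window edge
  but never forms an interior peak there. Onset/offset come from a
  noise-adapted crossing plus tangent extrapolation.
* **T end** — tangent method: a straight line fitted to the central
  descending limb (25–80% of the T peak) and extrapolated to baseline.
  This is the variant of the classical tangent rule that stays stable
  under noise; interval tests use a widened 5 ms tolerance for QT.
* **Classification** — QRS without a P in the search window is called
  ventricular; a P-like deflection with no QRS within 100 ms becomes a
  non-conducted atrial event. Fusion labels are only transferred from
  synthetic truth; automatic fusion calling from morphology is out of
  scope.
* **Conventions** — all times in ms from record start, fiducials at
  sample centers, analysis windows half-open `[start, end)`.

`measure_intervals()` averages conducted sinus beats only; RR is taken
between sinus beats that are consecutive in the record. Heart rate is
`60000 / mean(RR)` so HR–RR reciprocity is exact by construction. QT is
corrected with the murine Mitchell normalization
$QTc = QT / \sqrt{RR / 100\,\mathrm{ms}}$ — the constant 100 ms (not the
human 1 s) is deliberate and exposed as `qtc_rr0`.

# HRV analysis

Time domain: mean/median RR, SDRR and SDSD with the sample ($n-1$)
convention, RMSSD, and pRR50 with a *strict* inequality
(|successive difference| > 50 ms). Intervals adjacent to non-sinus beats
can be mask-excluded (`included`); the default in the pipeline is to
exclude them.

Frequency domain: the classical Lomb normalized periodogram of the
unevenly sampled tachogram ($RR_i$ against $t_i$), mean-subtracted and
normalized by twice the sample variance, evaluated on a uniform
0.005 Hz grid over (0, 5] Hz. The test suite proves the implementation
equal (to $10^{-8}$ relative) to an independent least-squares route: at
each frequency the Lomb power is the chi-square reduction of fitting
$a\cos\omega t + b\sin\omega t$. Band percentages integrate the
periodogram by the trapezoidal rule, assign each panel to the band
holding its midpoint, and normalize to the VLF+LF+HF total, so the three
percentages sum to 100 by construction and LF/HF is their ratio. A
constant series yields a degenerate spectrum, which is flagged and
refused downstream rather than silently producing 0/0.

One aliasing subtlety is worth recording: the tachogram is sampled at
the beat rate. At a mean RR of 150 ms (6.7 beats/s) the spectral mirror
of a 3 Hz modulation falls at ≈3.7 Hz — inside the HF band — so the band
integral of an HF tone double-counts while an LF tone's mirror lands
above the 5 Hz table and is lost. Equal-amplitude tones at 0.5 and 3 Hz
therefore only balance LF/HF when the beat rate is high enough
(mean RR ≲ 125 ms) to push the mirror out of the table; the peak heights
themselves balance at any rate. This is a property of band-integrating a
beat-sampled spectrum up to 5 Hz, and applies to any such analysis of
bradycardic mice.

Poincaré analysis: $SD1 = SD\bigl((RR_n - RR_{n+1})/\sqrt2\bigr)$,
$SD2 = SD\bigl((RR_n + RR_{n+1})/\sqrt2\bigr)$, with the population
variance convention by default so the identities
$SD1 = SDSD_{pop}/\sqrt2$ and $SD1^2 + SD2^2 = 2\,SDRR_{pop}^2$ (on the
paired subseries) hold exactly; the sample convention is available.

# Rhythm-disorder detection

The reference screening was a visual call by two cardiologists; the
package necessarily operationalizes it.

* **Sinus arrhythmia** — "visibly irregular sinus rhythm" becomes: any
  10-beat sliding window of the conducted-sinus RR stream whose
  coefficient of variation exceeds 0.15 (config-exposed; this threshold
  is a package definition, not a literature value). Intervals
  interrupted by non-conducted P waves or ventricular beats are removed
  first, so AV-block pauses are never attributed to sinus irregularity.
* **Wenckebach (second-degree type I)** — at least two conducted beats
  with strictly increasing PR (by more than 3 ms per beat, a tolerance
  for measurement noise) ending in exactly one non-conducted P, with
  conduction resuming. The two-beat minimum is the shortest run in
  which "increasing PR" is observable.
* **Intermittent third-degree block** — two or more consecutive
  non-conducted P waves. The boundary between high-grade second-degree
  and intermittent third-degree block is not sharply defined anywhere;
  the ≥ 2 rule is a documented choice. Each dropped P belongs to at most
  one episode, so the two block classes are disjoint by construction. A
  single isolated dropped P without PR prolongation counts under
  neither subtype by default (a toggle reports it as unspecified block).
* **Ventricular activity** — maximal runs of ≥ 4 consecutive
  ventricular beats (the definition of abnormal spontaneous ventricular
  activity; 3-beat runs are deliberately rejected). Fusion beats are
  transparent: they neither break a run nor count toward it.

Prevalence is the fraction of animals per group with at least one
episode of a kind, feeding the chi-square comparison.

# The virtual heart and EP analysis

Conduction in the virtual heart is threshold-deterministic: an extra
stimulus captures iff its coupling exceeds the tissue's true refractory
period; atrial pacing conducts 1:1 iff CL > WB CL (a Wenckebach drop
pattern between WB and 2:1 thresholds, 2:1 at or below); ventricular
pacing conducts retrogradely iff CL > VA CL; the first sinus return
after overdrive arrives exactly `snrt_true` ms after the last stimulus.
Only induction success (Bernoulli per maneuver) and episode duration
are stochastic. This split makes refractory-period and cycle-length
recovery exact up to the protocol grid while preserving inducibility
statistics.

The default protocol mirrors standard murine practice: 30 s overdrive
drives at 120 and 100 ms; a decremental atrial ramp (130→40 ms, 5 ms
steps) for WB and 2:1 cycle lengths; an ascending ventricular ramp
(50→160 ms) for retrograde conduction; S1/S2 scans (couplings 80→15 ms,
5 ms decrements) for AERP, AVERP and VERP at both drive CLs; S1/S2/S3
induction at couplings 40–20 ms in 5 ms decrements; and 3 s and 6 s
bursts at cycle lengths 40–10 ms.

Analysis conventions fixed here (and used identically by the simulator,
so round-trips are exact):

* **ERP** is the *longest failing* coupling (equivalently
  last-captured + step). The AV-nodal ERP considers only couplings that
  captured the atrium.
* **VA CL** is the longest ventricular pacing CL with retrograde block
  on the incremental ramp, so a larger value means worse retrograde
  conduction.
* **2:1 CL** is the longest CL at which a 2:1 pattern is observed
  (first occurrence, not demanded stable).
* **Censoring** — endpoints outside the tested range are always
  censored (`below_range` / `above_range`), never extrapolated; a
  missing sinus return within 5 s is reported as sinus arrest.
  Non-monotonic capture scans resolve to the longest failing coupling
  with a warning.
* **Corrected SNRT** = (first sinus return − last stimulus) − basic
  cycle length, with the basic CL measured from the intrinsic-rhythm
  block the simulator emits before pacing.
* **Inducibility** = successful maneuvers / all maneuvers; **burden** =
  summed episode durations. Because per-animal burden can be normalized
  by all animals or by inducible animals only — and the two answers
  differ — the cohort summary reports both denominators.

Atrial episodes qualify at ≥ 3 s of rapid ectopic atrial activity;
ventricular episodes at ≥ 4 consecutive ventricular beats. The virtual
heart emits only qualifying episodes (atrial draws truncated at 3 s,
ventricular runs at 4 beats): its Bernoulli probability is the
probability of inducing a *qualifying* arrhythmia.

# Group statistics

Each group is gated through the D'Agostino–Pearson omnibus normality
test (implemented from the standard $Z(g_1)$/$Z(g_2)$ transforms, since
no installed package provides it; validated against an independent
implementation). Both groups passing at α = 0.05 routes to the pooled
two-sided t-test, otherwise to the two-sided Mann–Whitney test; the gate
is applied per group, a documented choice. Groups below the test's
minimum of n = 8 fall back to Mann–Whitney, the conservative option —
relevant because group sizes here are 7–12. Three-group comparisons use
one-way ANOVA with Tukey's HSD; proportions use Pearson chi-square
without continuity correction (the common Prism default; a Yates toggle
exists). No correction is applied across the many parameters compared,
matching the reference analysis style. Simulation tests hold the
empirical type-I error of both gated procedures to 3.5–6.5% at nominal
5%.

# Study orchestration and problem sizes

`run_study()` simulates the default cohort (7 awake, 10 MMF, 12 IF),
analyzes every animal through the full chain, and assembles tidy result
tables plus a manifest (config, seeds, package version) sufficient to
reproduce the run; re-runs under the same configuration are
bit-identical. Per-animal problem sizes were chosen to keep a full run
around twenty seconds on one core while leaving every estimate
well-conditioned: 300 s tachograms for HRV (≈1400–2400 beats), a 30 s
rendered ECG segment at 2 kHz for delineation and rhythm screening, and
the complete stimulation protocol per narcosis animal.

Two study-level generator decisions deserve explanation:

* The MMF disorder roster places sinus arrhythmia in 9/10 animals,
  Wenckebach plus intermittent third-degree block in 5/10 and
  ventricular runs in 3/10, the observed prevalences; the Wenckebach
  and third-degree findings co-locate in the same five animals under
  the umbrella of high-grade AV block.
* The rendered ECG segment for MMF animals uses a damped HF amplitude
  (0.12 instead of 0.41). At the full tachogram amplitude every 10-beat
  window exceeds the sinus-arrhythmia criterion, which would make the
  discrete visual finding indistinguishable from baseline respiratory
  modulation; damping the rendered segment lets the injection roster
  govern prevalence while the HRV tachogram keeps the full vagal
  dynamics. This is a deliberate separation of the two phenomena the
  study reports.

# What passing tests do and do not show

The synthetic generator emulates autonomic interval modulation,
template-based murine morphology, discrete conduction disorders and
threshold-deterministic EP behaviour. It does not emulate baseline
wander or electrode artifact, beat-to-beat morphology variability,
ectopic atrial foci, escape rhythms during third-degree block, rate
adaptation of refractory periods, or drug pharmacokinetics. Recovery
results therefore certify the analysis mathematics and the internal
consistency of the pipeline; performance on real recordings — in
particular delineation thresholds tuned to the template amplitudes —
must be expected to degrade and should be revalidated against annotated
data. Detection of fusion beats, multi-lead reconstruction and
AF/flutter subclassification are out of scope.
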