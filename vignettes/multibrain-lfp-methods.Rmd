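---
title: "Methods: multi-brain LFP band-power, huddling and interbrain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-brain LFP band-power, huddling and interbrain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblfp)
```

## The problem

When several mice share an arena, their prefrontal local field potentials
(LFPs) are shaped not only by each animal's own behavioural state but by the
social context: who is huddling with whom, whose activity precedes whose.
`mblfp` implements the full analysis chain for such multi-animal
("hyperscanning") recordings:

1. decoding the wireless telemetry text format and behavioural annotations;
2. per-second spectral summaries, in particular the high-to-low-power ratio
   (HLR);
3. behavioural state modelling (locomotive states, huddle episodes,
   immobility-defined sleep, time budgets, state-conditioned HLR cell
   means);
4. interbrain statistics: HLR cross-correlation against shuffled-pair
   permutation nulls, locomotion-residualised correlation, and lag-1
   Granger-causality directionality graphs.

Because no public recordings exist for this design, the package ships a
first-class synthetic cohort generator with planted ground truth. Every
statistical claim the test suite makes is a claim about recovery of planted
structure, not about any particular animal.

## Spectral model

Traces are sampled at 1024 Hz (configurable). Preprocessing applies a
4th-order Butterworth low-pass at 200 Hz and second-order IIR notches at 60
and 120 Hz (Q = 30), all forward–backward. Zero-phase filtering matters
here: every downstream statistic is aligned to a per-second behavioural
clock, and a causal filter would shift signal energy across 1-s segment
boundaries.

Each trace is segmented into 1-s blocks and each block summarised by a
Hamming-windowed Welch PSD whose window spans the whole block. With 1-s
blocks this is the modified periodogram on an exact 1 Hz grid — the coarsest
grid that still resolves the 0–3 Hz delta band; averaging shorter
sub-windows within a second would destroy delta resolution. The
implementation is validated against an independent brute-force $O(n^2)$ DFT
periodogram to $10^{-6}$ relative error, and satisfies the Parseval identity
for the windowed signal.

Band powers are the mean PSD *density* inside closed intervals on the 1 Hz
grid: delta 0–3, theta 4–7, alpha 8–12, beta 13–30, gamma 31–80, high gamma
81–150 Hz, plus the composites low = 0–12 and high = 31–150 Hz. Two
numerical conventions:

* **DC exclusion.** The 0 Hz bin is excluded from delta and low: it
  reflects amplifier offset, not neural activity. It is configurable but on
  by default.
* **Mean density vs integrated power.** Whether a band "average" means mean
  density or integrated power is a free convention; mean density is used
  everywhere, consistently, so ratio statistics are unaffected as long as
  the same convention enters numerator and denominator.

The HLR of a segment is its high-band mean power divided by its low-band
mean power, always computed from *unnormalised* powers. Segments with zero
low-band power are marked invalid — invalidity is data, not an exception —
and are skipped pairwise by every correlation downstream. The robust-scaled
spectrogram ((x − median)/IQR per frequency row over time) exists for
display only and never feeds the HLR; rows with zero IQR are flagged
invalid.

## Behavioural rules

Locomotive states (`inactive`, `active_still`, `active`) arrive as
per-second manual annotations; the package treats annotation as an input,
not a vision problem. Huddling likewise arrives as per-second contact
labels, and the package applies only the formal rules:

* a contact run must persist **strictly more than 10 s** to be an episode;
* any interruption of contact, however short, splits the run *before* the
  persistence rule is applied (strict contiguity);
* a label with fewer than two members at a given second is no huddle at
  that second — a lone animal cannot huddle;
* a subject is "huddled" at a second iff it is a member of a surviving
  episode at that second.

Immobility-defined sleep flags inactive runs of at least `min_immobile_s`
seconds (default 40 s, a common immobility-defined-sleep convention; the
threshold is an assumption, exposed as a parameter, and not a substitute for
polysomnography). Sleep seconds are by construction a subset of inactive
seconds, which the tests assert as an invariant.

Cell means aggregate per-second HLR by locomotive state × social context,
where context is `single`, `group_huddled` or `group_non_huddled`. Seconds
whose HLR is invalid are excluded and counted; empty cells are reported with
n = 0 rather than dropped.

## Interbrain statistics

"Cross-correlation" means the lag-0 Pearson coefficient over pairwise-valid
seconds; a lag-scan utility exists but no default analysis uses it. Pairs
are classified by provenance into four combination classes: `group`
(same cohort, both group condition — the only socially co-present class),
`group_shuffled` (different cohorts, group condition),
`group_single_shuffled` (same cohort, one group and one single session) and
`single_shuffled` (same cohort, both single condition, i.e. simultaneously
recorded but socially separated animals). The last three are negative
controls by construction.

The permutation null draws 10,000 random pairs of distinct series from the
pooled HLRs of all cohorts and conditions and summarises them by mean ± 1.96
SD. An important subtlety, visible in both real and synthetic data: the pool
*contains* the in-class (same-cohort group) pairs, so when coupling is real
the null distribution is a contaminated mixture and its extreme empirical
percentiles land inside the in-class distribution itself. The decision
criterion is therefore the ±1.96 SD band — the criterion actually used in
this analysis tradition — not an empirical percentile of the mixture. The
calibration experiment (all couplings zero) checks that the in-group mean
falls inside the band at its nominal rate; the planted-modulation experiment
checks that it exceeds the band's upper edge.

### Locomotion residualisation

Interbrain HLR correlation could be a trivial consequence of shared
locomotion. To isolate the part it cannot explain, sessions are segmented
into 15-min windows; per pair and window the HLR correlation and the
correlation of ordinally encoded locomotive states (inactive = 0,
active_still = 1, active = 2 — the encoding preserves the mobility ordering
that drives the HLR) are computed, a least-squares line of HLR-correlation
on state-correlation is fitted, and residuals are compared between group and
single sessions.

The regression is fitted **pooled across conditions** by default. Fitting
per condition would force each condition's mean residual to zero by OLS
construction and erase the group-vs-single contrast that is the point of the
analysis; the per-condition option (`fit_scope = "condition"`) exists for
inspecting the within-condition relationship. The ablation tests confirm
both directions: with locomotion-mediated coupling only (shared huddle
gating, no direct HLR modulator) the group mean residual is ≈ 0; adding a
direct shared modulator raises the group residual above the single residual.

### Granger causality

For each ordered pair the package fits the lag-1 restricted autoregression
$y_t \sim 1 + y_{t-1}$ and the full model adding $x_{t-1}$, and compares
residual sums of squares with an F-test — the standard SSR form, verified in
the tests against `lmtest::grangertest`. The raw HLR series (not
log-transformed) is used. Invalid seconds are bridged by linear
interpolation when the gap is ≤ 2 s; longer gaps trigger a fall-back to the
longest contiguous valid run, since AR models need contiguity.

Per-cohort directionality graphs use raw p < 0.05 per direction with no
multiplicity correction, matching the convention of the analysis this
package reproduces; `p_adjust` offers Bonferroni/BH when wanted. A pair is
unidirectional iff exactly one direction is significant, bidirectional iff
both, none iff neither.

Two caveats are worth stating plainly because the synthetic experiments
quantify them:

* **Common input confounds pairwise GC.** When all animals load on a shared
  modulator (or on shared huddle gating), past values of any animal help
  predict any other, and bidirectional "influence" appears everywhere. On
  default synthetic cohorts with strong shared coupling the GC graph is
  dense and bidirectional — correctly reflecting the generative structure,
  but not the planted directed edges. Exact graph recovery is only
  identifiable when directed influence is the sole coupling.
* **Family-wise error vs exact recovery.** Exact recovery of an edge set
  over three cohorts entails ~36 ordered tests of which most are null; at
  raw α = 0.05 the probability of at least one false edge is
  $1 - 0.95^{33} \approx 0.82$, so exact-set recovery at raw α is
  arithmetically hopeless regardless of power. The planted-edge recovery
  experiment therefore controls the familywise level across the
  experiment's 36 ordered tests (α = 0.05/36). Per-cohort descriptive
  graphs keep the raw convention.

The recovery experiment accordingly uses an influence-isolation
configuration: state-independent band gains, no huddle process, no shared
modulator, and white (non-autoregressive) directed latents. With
influence weight 0.7 at lag 1 this recovers the planted three-cohort edge
set exactly in ≥ 90% of seeds.

## The synthetic cohort generator

The generator is layered so that every downstream stage has ground truth at
the timescale it works on.

**Behaviour.** Each subject follows a 3-state Markov chain per second. In
group condition a shared huddle process alternates non-huddled gaps
(geometric, mean 600 s) with episodes (10 s minimum persistence + geometric
excess, mean 1200 s); each subject joins an episode with probability 0.9
(at least two members always). Huddled seconds bias transitions toward
`inactive`, non-huddled seconds toward `active`, reproducing the
inactive-enriched/active-enriched split of huddled vs non-huddled time.
Leader→follower edges make followers adopt the leader's state at the
configured lag with the configured probability, outside huddled seconds.

**Per-second band powers.** Log low- and high-band powers are
$\log P_{high} = g_{high}(state) + d/2 + \varepsilon$,
$\log P_{low} = g_{low}(state) - d/2 + \varepsilon$, where the planted
log-HLR driver $d$ is the sum of a context offset (single 0, group-huddled
0.05, group-non-huddled 0.35), `coupling_strength` × a cohort-shared AR(1)
modulator (AR 0.9, unit variance), and a per-subject directed latent
(AR 0.3, innovation SD 0.2) coupled along the leader map. State gains
default to log-HLR separations of −3.6 (inactive), −1.0 (active-still) and
+0.3 (active), chosen once to reproduce the qualitative orderings reported
for this design (HLR increasing with mobility; huddled ≈ single <
non-huddled) — the source reports effect sizes only as ANOVA F statistics,
so magnitudes are the package's own calibration, not reproductions. Named
bands jitter around their composite (beta loads half on the low composite),
reproducing the observed band-correlation sign structure.

**Raw traces.** Each subject's voltage trace is low-band (FIR 0–12 Hz) plus
high-band (FIR 31–150 Hz) filtered noise, amplitude-modulated per second so
each segment's measured in-band PSD density matches its planted band power,
plus a 1/f background (flat below 1 Hz) and a white floor. Envelopes are
smoothed with a ~50 ms raised-cosine kernel at segment boundaries; the
analysis is blind to sub-second nonstationarity because every statistic is
per-1-s-segment, so segment-wise stationarity is an adequate model. Samples
are scaled, rounded and clipped to the 16-bit ADC range so traces are
representable in the hexadecimal dialect.

Because all planted interbrain structure lives at the 1 Hz driver timescale,
Monte-Carlo experiments run at the band-power level
(`simulate_cohort(cfg, signal = "band")`); the raw-trace layer is exercised
separately by the spectral tests and the end-to-end determinism check. What
the generator does **not** emulate: spikes, cross-frequency coupling, volume
conduction, electrode artefacts, thermoregulatory physiology of huddling,
or any behavioural microstate beyond the three locomotive states. Passing
tests therefore demonstrate correct recovery of the planted statistical
structure, not validity on arbitrary real recordings.

## Problem sizes and determinism

Defaults model the study design: cohorts of 4 animals, 3-h sessions
(10,800 s) at 1024 Hz, three cohorts recorded on a group day and a single
day. The validation suite chooses smaller sizes where the property under
test allows it: 30-min sessions for the null-calibration replicates, full
10,800-s sessions for residualisation and Granger experiments (whose
effects live at lag 1 on the 1 Hz series), and a 15-min, 512 Hz, 4-animal
session for the byte-level determinism check of the raw-trace pipeline —
512 Hz keeps the Nyquist margin above the 200 Hz low-pass while halving the
sample count. `scripts/acceptance.R` re-runs the same experiments from
scratch at comparable sizes and writes the resulting rates as JSON.

All randomness is seeded: a `cohort_sim_config` with a non-`NULL` seed
yields bit-identical bundles, session seeds of multi-cohort experiments
derive deterministically from a master seed, and the permutation null takes
its own seed. Ties and degenerate inputs are handled explicitly: constant
series flag correlations as undefined rather than erroring; empty cells
report n = 0; huddle labels in single condition, unknown vocabulary,
annotation gaps and malformed hex tokens are hard errors that name the
offending subject, second or token.

## Known limitations

* Lag-1 bivariate GC cannot distinguish direct influence from common input;
  conditional/multivariate GC is out of scope.
* The HLR collapses the spectrum to one number; analyses needing phase,
  coherence or cross-frequency structure need different tools.
* The hexadecimal dialect's bit width and signedness are conventions
  (16-bit two's-complement by default, configurable); stored samples are
  unitless ADC integers and are never converted to volts.
* The huddle persistence rule is applied to per-second labels; behaviour
  between annotation ticks is invisible.
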