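---
title: "Kinetic modelling of stepwise nucleosome sliding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of stepwise nucleosome sliding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remkin)
```

## The kinetic model

ATP-dependent chromatin remodellers slide histone octamers along DNA in a
stepwise fashion.  The mechanistic picture implemented here is: after the
enzyme engages a nucleosome, each remodelling *round* consists of `N`
sequential ~1-bp translocations of DNA from the entry side (each an
exponential waiting time with per-step rate `k_N`), after which the
accumulated strain is released by a concerted, effectively instantaneous
ejection of `n_eject` (~4-6, default 5) bp of DNA from the exit side.  In
single-molecule FRET recordings, each ejection appears as a sharp drop in
FRET efficiency, and the dwell between two successive drops — the *pause
time*, `tau_p` — is the experimental observable.

If the pause comprises `N` identical rate-determining steps, `tau_p` is a
sum of `N` i.i.d. exponentials, i.e. gamma-distributed:

    f(t) = k^N t^(N-1) exp(-k t) / Gamma(N)

The fitted shape `N_app` counts the rate-determining steps and the fitted
rate `k_app` is the per-step rate; `k_overall = k_app / N_app` is the
effective rate to traverse the whole pause.  With `N = 1` this is the
exponential distribution.

A round may additionally contain one kinetically *distinct* step with
rate `k_X` (before or after the translocations; the pause-time
distribution, a sum of independent waits, is order-invariant, so the
position is a labelling choice only).  The pause is then hypoexponential,
and the apparent shape of a gamma fit depends on the rate ratio:

* `k_N << k_X`: the distinct step is invisible; `N_app = N`, `k_app = k_N`.
* `k_N >> k_X`: the distinct step is rate-determining; `N_app = 1` and the
  distribution is exponential.
* `k_N ~ k_X`: intermediate `N_app`.  Exactly at `k_N = k_X` the distinct
  step is an (N+1)-th identical step, so the apparent count *peaks* at
  `N + 1` before collapsing towards 1 as `k_N` rises further.  The
  apparent-step-count curve over the rate ratio is therefore not globally
  monotone: it is flat at `N` for small ratios, bumps to `N + 1` near
  ratio 1, and decreases monotonically beyond it.

`unmasking_sweep()` exposes this behaviour: raising `k_N` relative to a
fixed `k_X` (experimentally, raising ATP concentration) "unmasks" the
distinct step, driving `N_app` from `N` down to 1 and the selected model
from gamma to exponential.

## Fitting choices

**Unbinned maximum likelihood is the primary path.**  The gamma MLE is
computed by a 1-D profile likelihood over the shape: for uncensored data
the rate that maximizes the likelihood at fixed shape is `shape / mean`
in closed form, and with censored data it is found by an inner 1-D
optimization.  The profile is smooth and unimodal, so this is markedly
more robust than a joint 2-D search (which showed line-search failures on
some samples).  The shape is bounded to `[1, 50]` and initialized at the
method-of-moments value `mean^2 / variance`.  A binned least-squares path
(`method = "histogram"`, Freedman-Diaconis widths by default) mirrors
fits performed on histograms; the two agree within the ~25% parameter
uncertainty typical of such fits on synthetic data.

**Shape is continuous during optimization; rounding is a reporting
convention.**  Values at or above 2 are reported to the nearest whole
number, values below 2 to the nearest 0.5 (so that shapes around 1.5 are
distinguishable from a pure exponential in reports).

**Censoring.**  A pause is right-censored when the observation ends
(acceptor photobleaching or end of movie) before the second FRET drop.
Censored values are excluded by default; `use_censored = TRUE` adds them
through the gamma survival function.  Because bleaching preferentially
censors *long* pauses, excluding them biases the shape and rate upward —
the censoring-aware likelihood is the recommended path whenever censored
intervals are available, and it is what the end-to-end recovery analyses
use.

**Model selection.**  The exponential is the nested `N = 1` case.
`select_model()` combines a practical-equivalence guard with an
information criterion: when the fitted shape is below 1.5 — the smallest
value distinguishable from 1 at the reporting resolution — the
exponential is chosen outright; otherwise BIC (default) or a
likelihood-ratio test arbitrates.  The guard matters: with thousands of
pause times, a pure likelihood criterion flags deviations that are real
but kinetically unresolvable.  In the regime `k_N = 100 k_X`, for
example, the fitted shape is ~1.25 and BIC still prefers the gamma model
by ~50 points, yet no analysis would report a quarter of an extra step —
the distribution *reads* as exponential at any attainable resolution.

## The synthetic-data generator

`synth_population()` emulates a TIRF single-molecule FRET experiment:

* **Frame rate** 5 frames/s; movies default to 300 s (the end-to-end
  recovery analyses use 900 s, see below).
* **Calibration** 0.05 FRET-efficiency change per bp ejected, linear,
  floored at E = 0.05.
* **Populations** three molecule classes with mean FRET 0.78 (acceptor on
  both histone copies), 0.67 (acceptor proximal; the only
  remodelling-competent class in the generator) and 0.42 (acceptor
  distal); default weights (0.3, 0.4, 0.3).
* **Channels** donor and acceptor are anti-correlated shares of a
  constant total intensity (default 1000 a.u.) with additive Gaussian
  noise per channel (default 30 a.u., i.e. 3% of total).  This is an
  idealization: no EMCCD noise model, no spectral crosstalk or gamma
  factor, no photoblinking, no donor bleaching (selection in the
  emulated protocol keys on acceptor bleaching only).
* **Bleaching** a single acceptor bleach step at an exponential time
  (default rate 1/150 s^-1); afterwards the acceptor sits at background
  and the donor is fully dequenched.

Because the generator omits those instrumental effects, passing
round-trip tests demonstrates correctness of the *analysis logic* —
segmentation, selection, censoring bookkeeping, likelihoods — not
robustness to every artefact of real recordings.

## Trace analysis choices

* **Proximity ratio** `E = acceptor / (donor + acceptor)`, uncorrected;
  frames with nonpositive total are flagged invalid and skipped.
* **Segmentation** is penalized binary segmentation minimizing squared
  error, with the per-trace penalty `8 sigma^2 log(n)` where `sigma` is
  the median absolute deviation of first differences (divided by
  sqrt(2)).  A 0.25-efficiency ejection step between segments of tens of
  frames reduces the cost by orders of magnitude more than the penalty,
  while the penalty sits well above the spurious-gain scale of pure
  noise; a floor of 1e-8 keeps exactly-constant noiseless segments from
  splitting on rounding error.  Minimum segment length is 3 frames
  (0.6 s); more than 20 change points triggers a suspicious-trace
  warning.
* **Bleach detection** counts acceptor-level transitions whose relative
  drop is at least 0.8 of the pre-step level.  Single 5-bp ejections
  produce relative acceptor drops of ~0.37-0.6 and even a compound
  double ejection ~0.75, whereas photobleaching drops to background
  (relative drop ~1), so the classes are well separated.  Levels below
  10% of the maximum are ignored as post-bleach background.
* **Selection** retains molecules whose *starting* FRET (median over the
  first 25 pre-bleach frames, i.e. the initial dwell) lies in
  [0.55, 0.7] and that show exactly one bleach step.  A whole-trace mean
  would be dragged down by remodelling itself and reject exactly the
  molecules of interest.
* **Pause extraction** takes `tau_p` as the time between the first and
  second downward level changes of at least 0.15 efficiency units.  One
  drop followed by bleach/end is censored at the window end; a single
  drop of 0.4 or more is classified "no intermediate state" (a compound
  ejection) and contributes no pause; the analysis window ends at the
  bleach frame.
* **Reversals** are upward level transitions of at least +0.1 sustained
  for 5 or more frames — both thresholds are tunable, as "significant
  reversal" is not a sharply defined quantity.  In the simulator a
  reversal restores `reversal_bp` (default `n_eject`) at a uniformly
  random time within the following round (a reversal after the final
  round follows the last ejection immediately and spans no frames).
  This is a deliberately phenomenological knob: no mechanism or rate law
  is asserted for reversals.

## Bulk assays

Real-time remodelling curves follow `y = F_lim (1 - exp(-k_RTFA t))`
with `t` measured from ATP injection (default 5-min baseline, 0.5-min
sampling, 30-min duration); fitting is Levenberg-Marquardt least squares
and is exact on noiseless input.  Binding titrations are fit as
`response = baseline + amplitude x fraction bound` with the fraction
bound taken by default from the exact 1:1 equilibrium with probe
depletion (quadratic solution).  The depletion-aware form is the default
because the dissociation constants of interest (tens of nM) are
comparable to the 25 nM labelled-probe concentration; the hyperbolic
isotherm is available and agrees with the quadratic form within 1% when
probe << K_D.  Replicates are fitted jointly with shared parameters.

## Crosslink scoring

Crosslink tables are deduplicated on unordered residue pairs.  A
crosslink is *satisfied* when the C-alpha--C-alpha distance in the model
is strictly below the cutoff (default 35 Angstroms).  Crosslinks with an
unresolved endpoint are excluded from the satisfaction denominator —
models routinely omit disordered regions, and counting missingness as
violation would conflate the two — but the fraction over all crosslinks
is also reported.  Residue numbering is full-length throughout; both
intervals in circulation for the auto-inhibitory region ship as named
regions (`C1a` 1231-1380 and `C1a_xl` 1201-1340) and counts are reported
per region name.  BS3 site chemistry is not validated on input (the
deposited lists are trusted); `lint_bs3_sites()` is an opt-in check.

The deposited crosslink list and the native protein sequence are
*optional* inputs.  The package ships synthetic stand-ins
(`synth_xl_table()`, `synth_idr_sequence()`, `synth_structure()`) that
emulate their structure and scale — 579 unique intra-protein pairs with
127 touching residues 1201-1340, and a 136-residue IDR with 32 basic
residues — so that every counting and scoring path is exercisable
without network access.  They are labelled synthetic and are not the
native data.

## Composition conventions

Positive = Lys + Arg; negative = Asp + Glu; polar = \{S, T, N, Q, C, Y,
H\}.  Histidine is not counted positive (charge-neutral at assay pH, and
the emulated mutagenesis exchanged charged residues against Ala/Ser/Thr,
implying a K/R-vs-D/E convention); Gly/Ala/Pro are counted neither.  The
sets are arguments, so other conventions are one call away.  Charge
editing substitutes alanine when removing charge (keeping the polar count
unchanged) and replaces small/apolar residues when adding charge.

## Problem sizes and determinism

The validation analyses use 2000 pause times per fitted condition,
20-seed replication for recovery medians, and a 500-molecule population
(900-s movies at 5 fps, 1/250 s^-1 bleach rate) for the end-to-end round
trip — sizes at which the shape estimate has a standard error of ~0.6
steps and ~180 complete pauses survive selection and censoring, so the
recovery tolerances are statistically meaningful.  Every stochastic
operation takes a `seed`; multi-part operations derive per-part child
streams deterministically from it (a Lehmer-style hash kept below 2^31),
so identical configurations reproduce byte-identical outputs, which
`run_pipeline()` records as MD5 checksums in its manifest.

## Known limitations

* The simulator does not model entry-side DNA bookkeeping, octamer
  position thermodynamics, or ATP-binding sub-steps; `k_X` is a single
  lumped distinct step, drawn once per round.
* Ejection is instantaneous; no rate is assigned to the concerted
  release.
* The FRET calibration is assumed linear over the full range.
* Reversal kinetics are phenomenological (see above).
* Segmentation recovers step positions to +/- 2 frames under the
  generator's noise model; heavy-tailed or correlated noise in real
  recordings would require retuning the penalty.
* Thermophoresis is treated as a generic binding response; no
  temperature-jump physics.
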