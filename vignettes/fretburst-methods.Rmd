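---
title: "Burst analysis of single-molecule FRET photon streams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst analysis of single-molecule FRET photon streams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretburst)
```

# Scope

`fretburst` analyzes photon streams from confocal, solution-based
single-molecule FRET measurements of freely diffusing molecules under pulsed
interleaved excitation (PIE/ALEX). Its motivating application is conformational
dynamics of membrane-anchored substrate-binding domains (SBDs) of ABC
importers such as OpuA, where two tethered domains transiently approach each
other and the question is whether a broad FRET distribution reflects a
mixture of static molecules or millisecond interconversion within single
bursts. The pipeline covers:

1. photon-stream I/O (a plain-text photon table dialect),
2. a generative simulator with full ground truth,
3. background estimation and the all-photon burst search (APBS),
4. apparent FRET efficiency / stoichiometry and species filtering,
5. photon-by-photon hidden Markov modeling (H2MM) with ICL model selection,
6. leakage / direct-excitation / gamma correction factors,
7. burst variance analysis (BVA),
8. a geometric interpretation layer (Förster distances, tether radius,
   local concentration, steady-state anisotropy).

# Data model

Photons arrive time-stamped on the sync clock of the pulsed laser (40 MHz, so
one tick is 25 ns) and are classified into three streams: donor
excitation/donor emission (`DexDem`), donor excitation/acceptor emission
(`DexAem`) and acceptor excitation/acceptor emission (`AexAem`).
Acceptor-excitation/donor-emission photons carry no FRET information and are
dropped at ingest. From the three burst counts
$F_{DD}, F_{DA}, F_{AA}$, the apparent FRET efficiency and stoichiometry are

$$E^* = \frac{F_{DA}}{F_{DA} + F_{DD}}, \qquad
  S = \frac{F_{DA} + F_{DD}}{F_{DA} + F_{DD} + F_{AA}}.$$

Doubly labeled molecules sit at intermediate $S$; donor-only molecules at
$S \approx 1$ and acceptor-only molecules at $S \approx 0$. The thresholds
used to partition species ($S < 0.2$ acceptor-only, $S > 0.8$ donor-only)
are a package convention — practice in the field fixes only the qualitative
$S \approx 0$ / $S \approx 1$ signatures — and are exposed in
`filter_species()` and `pipeline_settings()`.

# The synthetic-data generator

`simulate_experiment()` is first-class, tested code: it produces photon
streams with the statistical structure the analysis assumes, plus the full
ground truth, so every downstream stage is testable without access to raw
experimental data. The generative model:

* molecule transits arrive as a Poisson process (`burst_rate_hz`, default
  5 s⁻¹) with exponential transit durations (`transit_ms_mean`, default
  3 ms) and a top-hat emission profile at `peak_rate_khz` (default 50 kHz);
* a hidden conformational state follows a continuous-time Markov chain
  (exact Gillespie simulation); the default two states at corrected
  E = 0.18 and 0.63 interconvert at 42 s⁻¹ (low→high) and 173 s⁻¹
  (high→low), the kinetics typical of SBD docking under high ionic
  strength (600 mM KCl);
* a one-way bleaching/blinking transition (default 50 s⁻¹) sends the
  molecule mid-burst into a donor-only or acceptor-only emission regime
  (equal probability), reproducing the S≈1/S≈0 states that the hidden Markov
  model finds inside otherwise doubly-labeled bursts;
* species fractions default to 70% doubly labeled, 20% donor-only, 10%
  acceptor-only — typical double-labeling yields;
* per-stream Poisson background (defaults 600/400/500 Hz, a realistic
  1.5 kHz total for a confocal setup);
* instrument distortions are applied at the per-photon level: the stream
  probabilities of a state with true efficiency $E$ and designed
  stoichiometry $S$ are the exact algebraic inverse of the correction
  equations (see below), so applying the true correction set recovers
  $(E, S)$ in expectation by construction.

Choices and what they mean for the tests: nanodisc-reconstituted membrane
proteins diffuse slowly enough that their bursts last several milliseconds
(which is also what makes 40–200 s⁻¹ interconversion visible within single
bursts), so the default 3 ms mean transit puts most bursts in the
single-digit-millisecond range; burst brightness varies widely between
setups, so the 50 kHz peak rate is a convention. The top-hat transit profile (rather than a Gaussian diffusion
profile through the detection volume) keeps the ground truth exact; it means
burst-duration and brightness *distributions* are not realistic, but every
statistic the pipeline tests — stream proportions, interphoton statistics,
state kinetics, correction algebra — is unaffected by the profile shape.
Multi-molecule coincidence and lifetime/IRF effects are not modeled.
Consequently, passing tests demonstrate correctness of the estimators under
the assumed model, not robustness to diffusion-profile artifacts.

The master seed drives three fixed sub-generators (burst layout, background,
per-burst emission), so a run is bit-reproducible.

# Background and burst search

The background rate is a simple count/duration estimator per 30 s window
(per stream and total); the final partial window uses its actual duration.
No exponential-tail fit is attempted: the plain estimator is unbiased for
Poisson background and exactly testable.

The all-photon burst search slides a window of $m = 10$ consecutive photons;
a window starting at photon $i$ qualifies when
$m / (t_{i+m-1} - t_i) \ge F \times$ (total background rate of the 30 s
window containing $t_i$), with $F = 6$. The comparison is inclusive, and the
total (all-stream) background is used — both conventions fixed so a
brute-force oracle can reproduce the search exactly. Overlapping qualifying
windows merge into bursts; any non-qualifying gap separates bursts. Note
that the number of bursts is *not* monotone in $F$ (raising $F$ can split a
merged burst in two); the monotone invariant, which the tests assert, is
that the set of photons covered by bursts shrinks as $F$ grows.

Bursts with fewer than 35 photons (counting both excitation periods) are
discarded; in the corrected re-selection pass the same cut-off is applied to
the corrected total signal $F_{DA}^{cc} + \gamma F_{DD} + F_{AA}/\beta$.

# Photon-by-photon hidden Markov model

The hidden chain is parameterized in discrete time on the sync clock: a
$K \times K$ per-tick transition matrix $A$, a prior $\pi$, and per-state
emission probabilities over the three streams. Between photons separated by
$\Delta$ ticks the transition operator is $A^\Delta$, computed through the
spectral decomposition $A = R\,\mathrm{diag}(\lambda)\,R^{-1}$ (with a
repeated-squaring fallback when the eigenbasis reconstructs $A$ poorly, and
a real-arithmetic fast path when the spectrum is real, which it always is in
the physical rate regime).

The EM fit is exact, not approximate: the E-step accumulates
interval-resolved expected transition counts over every unobserved tick
inside each gap, using the closed form

$$\sum_{d=0}^{\Delta-1} \lambda_p^{\,d}\, \lambda_q^{\,\Delta-1-d}
  = \frac{\lambda_p^\Delta - \lambda_q^\Delta}{\lambda_p - \lambda_q}
  \quad (\lambda_p \neq \lambda_q),$$

rather than the "one transition per gap" approximation. The test suite
validates the E-step, the forward likelihood, the posteriors and the Viterbi
path against exhaustive enumeration over all hidden tick paths on tiny
bursts; the EM log-likelihood is asserted non-decreasing.

Numerical conventions: scaled forward variables floored at $10^{-300}$;
emission rows floored at $10^{-12}$ in the M-step; Viterbi ties broken
toward the lower state index; EM stops when the absolute log-likelihood
improvement drops below `tol` (default $10^{-7}$ for `h2mm_fit()`,
$10^{-6}$ in `pipeline_settings()` where two full selections are run) or at
`max_iter`, returning `converged = FALSE` rather than erroring.

The Viterbi state sequence is defined at the photon times with $A^\Delta$
gap weights; dwells are maximal constant-state runs, with boundaries at the
midpoint of the separating gap (burst edges at the edge photons) and a
position class (`whole`, `initial`, `mid`, `terminal`). Transition rates are
read off the fitted matrix as $k_{ij} = A_{ij}/\delta$ with $\delta$ the
tick length — valid while $A_{ij} \ll 1$, which the code checks — and a
dwell-duration-based estimate (`dwell_rates()`) is available as a
cross-check. Rates are reported from the optimized $A$, not from dwell
statistics, because Viterbi dwell durations are censored at burst edges.

## Model selection

For each $K$ the fit starts from a deterministic grid of (E, S) emission
targets (two FRET-like states first, then donor-only-like and
acceptor-only-like states, then intermediate E values) plus optional seeded
jittered starts; the best final log-likelihood wins. Scores use
$d_K = (K-1) + K(K-1) + 2K$ free parameters and $N$ = photon count:

* $\mathrm{BIC} = -2\,\ell + d_K \ln N$,
* $\mathrm{ICL} = -2 \ln P(\text{photons, Viterbi path}) + d_K \ln N$,
* $\mathrm{BIC}' = (\mathrm{BIC}_{K-1} - \mathrm{BIC}_K)/\mathrm{BIC}_{K-1}$
  (diagnostic, reported with the conventional 0.05 threshold).

The adopted model is the ICL minimum; at $K = 1$ ICL equals BIC exactly
(single path). The $d_K$ and BIC' definitions are explicit package choices,
stated here because conventions differ between implementations.

# Correction factors

With leakage `lk`, direct excitation `dir`, and detection imbalance
`gamma` (plus optional excitation imbalance `beta`, default 1):

$$F_{DA}^{cc} = F_{DA} - lk\,F_{DD} - dir\,F_{AA}, \qquad
  E = \frac{F_{DA}^{cc}}{F_{DA}^{cc} + \gamma F_{DD}}, \qquad
  S = \frac{F_{DA}^{cc} + \gamma F_{DD}}
           {F_{DA}^{cc} + \gamma F_{DD} + F_{AA}/\beta}.$$

`lk` is the pooled $\sum F_{DA} / \sum F_{DD}$ of the donor-only bursts,
`dir` the pooled $\sum F_{DA} / \sum F_{AA}$ of the acceptor-only bursts.
Background photons mixed into bursts bias these pooled ratios upward (the
donor-only population has almost no true DexAem signal, so even a few
background DexAem photons per burst matter), so the pipeline feeds them
background-corrected counts: `subtract_background()` removes each burst's
expected per-stream background (local rate × burst duration) before
pooling, the standard practice in burst-analysis software. Raw burst counts
everywhere else — E*/S histograms, selection, the HMM — remain raw.

`gamma` and `beta` come from the line $1/S = \Omega + \Sigma E$ fitted
through exactly the two FRET-state centroids after lk/dir correction:
$\beta = \Omega + \Sigma - 1$, $\gamma = (\Omega - 1)/\beta$. The centroids
are computed from *photon-pooled* per-state counts rather than dwell-mean
ratios: pooling weights the long, reliably classified dwells and avoids the
small-sample ratio bias that dwell averaging introduces. When the model does
not contain exactly two FRET states, the pipeline falls back to
$\gamma = \beta = 1$ and logs the fact.

`run_pipeline()` chains the passes: (1) raw search/selection/species split,
(2) H2MM on the FRET bursts, lk/dir from the donor-only/acceptor-only
populations and gamma from the FRET-state centroids, (3) re-selection with
the same cut-offs applied to corrected counts, a fresh model selection
(warm-started from the first-pass fits), Viterbi dwells, corrected dwell
E/S, state classification and BVA. Applying the unchanged cut-off to
*corrected* counts in the re-selection pass is a package convention, applied
consistently and logged.

# Burst variance analysis

Each burst is cut into consecutive non-overlapping windows of $n = 5$
donor-excitation photons; the burst's mean window efficiency is plotted
against the standard deviation of the window values and binned at 0.1 E. A
static molecule's window efficiency is binomial, so
$\sigma_{shot}(\bar E) = \sqrt{\bar E (1-\bar E)/n}$; binned standard
deviations above that curve indicate within-burst dynamics. The window size
and the use of non-overlapping windows are package conventions; both are
exposed as arguments. When a
correction set is supplied the window efficiency is the corrected E of the
window counts (windows contain only donor-excitation photons, so the
direct-excitation term is inactive within windows). The comparison is
qualitative by design; no dynamic fraction is quantified from BVA.

# Geometry and interpretation

`fret_to_distance()` applies $R = R_0 (1/E - 1)^{1/6}$. The default Förster
radius is $R_0 = 5.1$ nm, appropriate for the Alexa Fluor 555 / Alexa Fluor
647 pair (it reproduces the reference conversions asserted in the test
suite: 4.1 nm at E = 0.781 and 4.9 nm at E = 0.568). `tether_radius()` models the sampling
radius of a tethered domain as domain radius (2 nm) plus 0.35 nm per
extended linker residue, reported half-up to one decimal (half-up, not
banker's rounding, so 5.85 → 5.9). `halfsphere_concentration()` converts
that radius into the apparent concentration of one molecule confined to a
half-sphere, $c = 1/(N_A \cdot \tfrac{2}{3}\pi r^3)$ — about 4 mM at
5.9 nm — with a full-sphere option. Steady-state anisotropy uses
$G = I_{HV}/I_{HH}$ and $r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$.

`summarize_conditions()` lays out per-condition state summaries as one row
per measurement condition (S, E, % dwells for the low- and high-FRET states,
the two rate constants, and the number of FRET dwells).

# Problem sizes used in the test suite

Unit tests run on simulations of seconds to a minute (hundreds of bursts).
The end-to-end kinetics recovery uses a 400 s simulated acquisition
(~2000 molecule transits, ~10⁵ burst photons) with model selection over
K = 1…5 from the deterministic start; correction recovery uses 150 s; BVA
discrimination 60 s per condition. These sizes were chosen so that the
statistical tolerances (state efficiencies within ±0.05, rates within ±25%,
correction factors within ±0.01/±5%) are comfortably resolvable from the
information content of the data.

# Known limitations

* No lifetime/nanotime information: states separable only through stream
  proportions and kinetics.
* No Gaussian diffusion profile, no multi-molecule coincidence: burst-shape
  statistics are not realistic and no burst-shape filtering is offered.
* Transition rates approaching the inter-photon rate are not identifiable;
  the per-tick parameterization warns when $A_{ij} > 10^{-3}$.
* Dwell-averaged state efficiencies carry a small classification bias for
  short dwells (photon-pooled centroids are used where it matters, in the
  gamma fit).
* BVA is qualitative; deviations from the shot-noise curve flag dynamics
  but do not quantify them.
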