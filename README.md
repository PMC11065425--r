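# fretburst

Burst analysis of confocal single-molecule FRET photon streams with
photon-by-photon hidden Markov modeling.

## The problem

In solution-based smFRET, single labeled molecules diffuse through a confocal
spot and emit millisecond photon bursts under pulsed interleaved excitation.
When the FRET histogram of such bursts is broad, the question is whether it
reflects a mixture of static conformations or states that interconvert
*within* single bursts — for example, the two substrate-binding domains of a
membrane transporter that transiently dock onto each other on the
millisecond timescale. `fretburst` implements the full analysis chain needed
to answer that question, plus a generative simulator with ground truth so
every stage is testable:

* **Burst search.** Background is estimated per 30 s window; the all-photon
  burst search (APBS) keeps windows of m = 10 consecutive photons whose
  local rate is at least F = 6 times the background, merges them into
  bursts, and applies a 35-photon minimum.
* **E and S.** From the burst counts F_DD, F_DA, F_AA (donor-excited donor
  emission, donor-excited acceptor emission, acceptor-excited acceptor
  emission): E\* = F_DA/(F_DA+F_DD), S = (F_DA+F_DD)/(F_DA+F_DD+F_AA).
  Donor-only (S ≈ 1) and acceptor-only (S ≈ 0) bursts are split off and
  reused to estimate leakage and direct excitation; gamma (and beta) come
  from the line 1/S = Ω + Σ·E through the two FRET-state centroids.
* **Photon-by-photon HMM.** A K-state hidden Markov model on the 25 ns sync
  clock, with transition operator A^Δt across inter-photon gaps, exact
  interval-resolved EM (validated against brute-force enumeration), Viterbi
  dwell segmentation, and model selection by the integrated complete
  likelihood (ICL); transition rates are read off the fitted matrix as
  k = A/δ.
* **Burst variance analysis.** Within-burst standard deviation of windowed
  E against the binomial shot-noise curve sqrt(E(1−E)/n).
* **Interpretation.** Förster distance conversion R = R0·(1/E−1)^(1/6),
  tether geometry of membrane-anchored domains, apparent local
  concentration in a half-sphere sampling volume, steady-state anisotropy.

## Worked example

Simulate the high-ionic-strength condition (two FRET states at E = 0.18 and
0.63 interconverting at 42 and 173 s⁻¹, donor-only/acceptor-only species,
within-burst bleaching, 1.5 kHz background), then run the three-pass
pipeline:

```r
library(fretburst)

cfg <- sim_config(seed = 7, duration_s = 120)
sim <- simulate_experiment(cfg)
sim$stream
#> <photon_stream> 283570 photons, 120 s @ 25 ns/tick
#>   DexDem: 121135  DexAem: 56608  AexAem: 105827

res <- run_pipeline(sim$stream,
                    pipeline_settings(k_range = 1:4, n_starts = 1, seed = 1))
glance(res)
#> # A tibble: 1 × 7
#>   n_bursts chosen_K     lk     dir gamma  beta n_fret_dwells
#>      <int>    <int>  <dbl>   <dbl> <dbl> <dbl>         <int>
#> 1      614        4 0.0127 0.00460  1.01 0.978           405

tidy(res)
#> # A tibble: 4 × 6
#>   state class          mean_E mean_S n_dwells pct_fret_dwells
#>   <int> <chr>           <dbl>  <dbl>    <int>           <dbl>
#> 1     1 fret_low      0.178   0.506       317            78.3
#> 2     2 fret_high     0.619   0.503        88            21.7
#> 3     3 donor_only    0.00320 0.981        21            NA
#> 4     4 acceptor_only 0.190   0.0172       27            NA
```

The ICL-selected model has four states: the two genuine FRET states
(recovered at E 0.178 and 0.619, with 78/22% of FRET dwells) plus the
donor-only and acceptor-only states produced by within-burst
bleaching/blinking. The estimated correction factors are near identity, as
simulated. Condition tables collect the kinetics:

```r
summarize_conditions(list("600 mM KCl (synthetic)" = res$summary))
#> # A tibble: 1 × 10
#>   condition       S_low E_low pct_low S_high E_high pct_high k_LH_s k_HL_s
#> 1 600 mM KCl (s…  0.506 0.178    78.3  0.503  0.619     21.7   46.6   153.
```

i.e. recovered rate constants of ~47 s⁻¹ (low→high) and ~153 s⁻¹
(high→low) against the simulated 42 and 173 s⁻¹ from a 2-minute synthetic
acquisition. Geometry helpers interpret the states:

```r
fret_to_distance(0.63, R0_nm = 5.1)   # high-FRET inter-dye distance, nm
#> [1] 4.667099
halfsphere_concentration(tether_radius(11))  # mM for an 11-residue tether
#> [1] 3.860419
```

A domain tethered by 11 extended residues samples a half-sphere of radius
5.9 nm, in which one molecule corresponds to an apparent concentration of
about 4 mM — the regime where weak, transient protein–protein interactions
become significant.

`autoplot()` methods produce the standard figures: corrected dwell E–S
scatter (`autoplot(res)`), ICL versus K (`autoplot(res$selection)`), and the
BVA plot with the shot-noise curve (`autoplot(res$bva)`).

## Package layout

* `R/photon_stream.R` — photon-stream container and plain-text I/O
* `R/simulate.R` — generative simulator (Gillespie kinetics, distorted
  emission, background, ground truth)
* `R/burst_search.R` — background, APBS, E\*/S, selection, species filter
* `R/h2mm.R`, `src/h2mm.cpp` — photon-by-photon HMM (exact EM, Viterbi,
  model selection)
* `R/corrections.R` — leakage/direct-excitation/gamma estimation and
  application, background subtraction
* `R/bva.R` — burst variance analysis
* `R/geometry.R` — distances, tether geometry, concentration, anisotropy
* `R/pipeline.R` — the three-pass orchestrator
* `vignettes/fretburst-methods.Rmd` — models, assumptions, conventions and
  limitations
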