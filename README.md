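# impactchain

Simulation of surgical impaction force transmission for total hip
arthroplasty instrumentation: a lumped-parameter model of the chain
mallet → impactor → polymer tip → femoral head → stem taper → responding
tissue, with the signal conditioning, feature extraction,
parameter-estimation and extrapolation tooling that goes with it.

## Who this is for

Biomechanics groups that measure impaction forces with instrumented
mallets, impactors or stem load cells, and need to relate what a sensor at
one *position of measurement* (PoM) reports to the force at an
inaccessible *position of interest* (PoI) such as the head–taper junction.
Because a blow lasts a fraction of a millisecond, the inertia and
compliance between sensor and PoI attenuate the force substantially —
setups with different instruments are not directly comparable, and a model
of the whole transmission path is the way to translate between them.

## The model

Six masses in series along the impaction axis, anchored to ground through
the responding tissue (the patient's femur and soft tissue, or its bench
surrogate). Between consecutive masses sit:

* linear spring–dampers (impactor shaft, measurement cell, stem), whose
  forces at the two load-cell positions are the reported PoM signals;
* a **one-sided hard stop** between polymer tip and head: compression
  only, stiffness and damping ramping linearly from zero over a 50 µm
  transition region;
* a **stick–slip friction element** at the taper junction with a
  clamping normal force quadratic in the insertion depth `d`,

  `N(d) = N0 + β d²`,  transmitted force ≤ μs·N(d) (stick), = μk·N(d) (slip);

* gravity on every node, with the simulation starting from the exact
  static equilibrium (preloaded springs, closed contact, seated taper).

The stiff ODE system is integrated with a compiled right-hand side via
`deSolve` on the 800 kHz acquisition grid over 0.8 ms. Default parameters
are the fitted values for a DePuy Emphasys head impactor driving a 28 mm
CoCr head onto a 12/14 stem taper replica, with a 4.0 N/mm / 0.52 kg
tissue surrogate.

## Worked example

```r
library(impactchain)

sim <- simulate_chain(chain_config(), pulse_half_sine())  # 9247 N, 0.140 ms
sim
#> <impact_sim> 641 samples at 800 kHz
#>   pulse peak: 9247 N
#>   impactor PoM peak: 2705.6 N at 0.1462 ms
#>   stem PoM peak:     5122.7 N at 0.4938 ms

glance(sim)[, c("normalized_peak_impactor", "normalized_peak_stem",
                "final_insertion_depth")]
#>   normalized_peak_impactor normalized_peak_stem final_insertion_depth
#> 1                    0.293                0.554              0.000205
```

A 9.2 kN mallet blow arrives at the impactor cell as a 2.7 kN peak — 29%
of what the mallet sensor saw — and the head advances about 0.2 mm onto
the taper. Features of the conditioned impactor trace (10 kHz zero-phase
Butterworth, normalized to the mallet peak):

```r
trace <- lowpass_zerophase(sim$data$force_impactor, 800e3, 10e3)
signal_features(trace, 800e3, mallet_peak = 9247, mallet_peak_time = 0.070e-3)
#>   first_peak second_peak first_peak_time second_peak_time    period     delay
#> 1     0.2909      0.2551       0.0001463          0.00046 0.0003138 7.625e-05
```

i.e. a damped oscillation at `1/period ≈ 3.2 kHz`, peaking 0.076 ms after
the mallet. `autoplot(sim)` draws the normalized traces;
`run_impactor_sweep()`, `run_tissue_sweep()` and `run_experiment_presets()`
produce the extrapolation tables; `sensitivity_mc()` and
`fit_parameters()` implement the screening and estimation pipeline; and
`inst/cli/impactchain` wraps all of it for the shell. The methods
vignette (`vignettes/impaction-model.Rmd`) documents the model,
assumptions and numerical choices.

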