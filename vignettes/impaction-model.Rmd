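---
title: "A lumped-parameter model of surgical impaction force transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of surgical impaction force transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(impactchain)
```

## The problem

Uncemented implant components are seated by mallet blows: femoral ball
heads are driven onto stem tapers, stems are driven into the femur. The
force that matters clinically acts at a *position of interest* (PoI) — the
head–taper junction or the implant–bone interface — which cannot host a
load cell. Sensors therefore sit at nearby *positions of measurement*
(PoM): in the mallet, above the impactor's polymer tip, below the stem. In
a process this fast (a blow lasts well under a millisecond) the inertia
and compliance between PoM and PoI attenuate and reshape the force, so
different instrumented setups report very different "impaction forces" for
the same blow.

`impactchain` models the whole transmission path as a one-dimensional
serial chain of lumped masses and idealized elements, so that the force at
any position — accessible or not — can be computed from the applied mallet
pulse, and so that the effect of exchanging instruments or tissue
conditions can be explored without new experiments.

## The chain

Six point masses are connected in series along the impaction axis
(positive downward), anchored to ground below:

| node | mass [kg] | element below |
|---|---|---|
| impactor handle | 0.508 | spring 85×10³ N/mm |
| measurement cell | 0.137 | spring 2.3×10⁶ N/mm (impactor PoM) |
| polymer tip | 0.084 | one-sided hard stop, 13×10³ N/mm, 240 Ns/mm |
| femoral head | 0.062 | taper friction element |
| stem taper | 0.043 | spring 130×10³ N/mm (stem PoM) |
| responding tissue | 0.52 / 0.89 | spring 0.6–5.0 N/mm + damper to ground |

The mallet itself is not a modeled mass: the measured (or synthesized)
mallet force pulse acts directly on the impactor node, which mirrors how
an instrumented mallet records the interface force at its striking
surface. The two PoM signals are the forces carried by the springs at the
physical load-cell positions, reported as deviations from their static
preload. The responding tissue — the patient's femur and soft tissue, or
the spring stack standing in for it on the bench — is a mass on a
spring–damper whose damping defaults to 10% of the spring stiffness
(numerically, in N/mm and Ns/mm).

Three element laws carry the physics that a plain spring chain misses:

* **One-sided hard stop** (tip–head contact). The head rests loosely on
  the polymer tip, so the contact transmits compression only. Its
  stiffness ramps linearly from zero over a transition depth δ = 50 µm,
  which regularizes contact onset; the damping uses the same ramp factor
  and the total force is clamped non-negative so the contact can neither
  pull nor push "backwards" through its damper. A `contact_bilateral`
  switch replaces the stop by an ordinary spring–damper for
  conservative-limit checks.
* **Taper friction** (head–stem junction). The junction transmits axial
  force by Coulomb friction under a clamping normal force that grows with
  the contact area, modeled as `N(d) = N0 + β d²` in the insertion depth
  `d` (no linear term), with N0 = 5 N, β = 140×10⁹ N/m², μ_static = 0.79,
  μ_kinetic = 0.49. While the head–stem relative velocity is below a
  threshold and the demanded shear is inside the static cone, the junction
  sticks (transmits the demand); otherwise it slides at μ_kinetic·N(d).
  Insertion is reversible here: `d` follows the relative displacement, and
  `d < 0` (pull-off) leaves the junction free. Whether the physical
  junction ratchets instead is unknown; the reversible reading is the
  simpler assumption and the blow of interest is dominated by forward
  sliding anyway.
* **Gravitational preload.** The bench is vertical, so every element
  carries the weight above it before the blow. `steady_state_preload()`
  solves this equilibrium in closed form — spring compressions, the
  hard-stop penetration (inverting the ramp law), and the smallest
  insertion depth whose static friction cone holds the supported weight —
  and the simulation starts exactly there, at rest.

## Numerics

The equations of motion are integrated by `deSolve`'s stiff solver
(`lsoda`) with a compiled C right-hand side and the mallet pulse supplied
as an interpolated forcing. The output grid is fixed at 800 kHz over
0.8 ms (641 samples), matching the acquisition used for the recordings the
model was built against; the solver's maximum internal step equals the
1.25 µs output interval because the load-cell spring (2.3×10⁶ N/mm) and
the tip damping create time constants far below it.

Stick–slip is the delicate part. A literal Coulomb law is discontinuous at
breakaway and at the stick boundary, which stalls any adaptive integrator.
The implementation is a Karnopp-style regularization made continuous
everywhere: inside a stick band (relative speed below `v_eps = 1e-4` m/s,
far below impact speeds) the transmitted force is the stick demand clamped
to the static cone; beyond twice the threshold it is kinetic friction; in
between the two laws are blended linearly. The transmitted force therefore
never exceeds μ_static·N(d), which is also asserted as a test invariant.

Four structural checks pin the integrator down: a zero pulse leaves the
preloaded chain motionless to better than 10⁻⁶ of the total weight; a
reduced configuration (upper chain detached, stem spring rigid) reproduces
the closed-form period 2π√(m/k) of the stem+tissue oscillator to 0.5%;
the conservative limit (no damping, no friction, bilateral contact)
conserves energy to 1% after the pulse; and the one-sided contact never
reports a tensile force along the reference blow.

## Signals and features

Measured forces are conditioned by 4th-order zero-phase Butterworth
low-passes (20 kHz mallet, 10 kHz impactor, 15 kHz stem — each about five
times the dominant signal frequency) and normalized to the peak of the
corresponding mallet blow. "4th order, zero phase" is read as: design a
4th-order filter, run it forward and backward, so the magnitude response
is effectively squared and peak times are unshifted. The implementation
initializes each pass at its steady state for the first sample and pads by
odd reflection, so a constant passes through exactly and edge transients
are suppressed. Features (`signal_features()`) are the first and second
positive local maxima — found with a hysteresis rule at 1% of the global
maximum, so numerical ripple is ignored and a peak is only reported once
the signal has confirmed it by falling again — plus the period between
them and the delay behind the mallet peak. Simulated traces are passed
through the same filters before features are compared with measured ones.

Goodness of fit is a windowed RMSE in percent of the mallet peak: the
window runs from the zero crossing before the first positive peak of the
measured trace to the zero crossing after its second — two positive
half-waves and the negative one between — and is located on the measured
signal, then applied to both.

## The synthetic mallet blow

The canonical input is a half-sine lobe with peak 9247 N and base width
0.140 ms, the mean of the recorded blows; `random_blow()` draws peak and
width from the reported blow-to-blow variability (SD 1513 N and 0.008 ms,
normal truncated at zero) for pseudo-experiments. A real recording can be
used instead: `extract_first_peak()` isolates the lobe between the 0.5%
threshold crossings around the global maximum and zero-pads it, since only
the first peak of the mallet force drives the impaction.

What the synthetic stand-in does *not* reproduce: the measured blow's
slight asymmetry and its rebound lobes, sensor noise, and any off-axis
component of a manual blow. Tests built on it therefore validate the
chain's dynamics and the pipeline's bookkeeping, not the fidelity of any
particular in vitro recording.

## Parameter estimation

Ten parameters cannot be measured directly. Monte-Carlo screening
(`sensitivity_mc()`: uniform sampling over the declared ranges, Spearman
rank correlation of each parameter against normalized peaks and windowed
RMSEs) rates the hard-stop transition depth, the constant normal-force
term and the tissue damping as weakly influential; they are fixed at
50 µm, 5 N and the 10% rule. The remaining seven are fitted by minimizing
the summed squared error of both PoM traces over their RMSE windows across
all datasets (`fit_parameters()`).

The optimizer is bounded least squares rather than a direct search: the
objective is an explicit residual vector with a zero-residual optimum for
pseudo-measurements, which Gauss–Newton exploits far better than a simplex
in seven dimensions. Scale-type parameters are optimized on log axes.
Two structural difficulties shape the scheme:

* the printed tip damping (240 Ns/mm) is roughly forty times critical for
  the tip mass, so the contact force is damping-dominated and the contact
  *stiffness* barely enters the objective — its Jacobian column is mostly
  solver noise;
* the slip force μ·N(d) couples the friction coefficients and β, so
  compensated parameter combinations track the data closely.

`fit_parameters()` therefore alternates well-conditioned sub-problems —
bounded Levenberg–Marquardt over the five strongly identified parameters
with the contact pair frozen, then a two-level grid profile of each
contact parameter — for three cycles before a joint polish, and repeats
the whole descent from a few jittered starts, keeping the best sum of
squares. Finite-difference steps are set well above the ODE solver's noise
floor (`epsfcn`), and the initial trust region is kept small so the flat
directions cannot overshoot to their bounds.

With three noise-free pseudo-measurement datasets of deliberately
different amplitude (2, 9.247 and 16 kN — amplitude diversity reaches
different insertion depths and is what separates μ_kinetic from β), the
two spring stiffnesses are recovered to better than 0.1% and the friction
trio to a few percent. The contact pair is the known exception: at the
sum-of-squares resolution the scheme can reach, contact stiffness is not
identifiable — estimates tens of percent off change the objective less
than the descent can resolve. This is a property of the model as
parameterized (a heavily overdamped contact), not of the optimizer, and it
is the reason the package reports per-parameter bounds and diagnostics
rather than point estimates alone.

An optional screen (`screen_datasets()`) drops recordings whose dominant
impactor frequency deviates more than 25% from the group median,
mirroring the exclusion of assemblies with distinctly different
oscillatory behaviour; the threshold is a choice, as no quantitative rule
was reported.

## Extrapolation sweeps

Two sweeps explore conditions beyond the bench. `run_impactor_sweep()`
crosses 5 impactor masses (0.1–2 kg, linear — a handful of discrete
instruments) with 26 impactor stiffnesses (100–10⁶ N/mm, log-spaced over
four decades): 130 simulations. Cells whose impactor force never develops
a confirmable peak within 0.8 ms (heavy, compliant impactors) are flagged,
not dropped. `run_tissue_sweep()` crosses 8 tissue masses (0.1–20 kg) with
8 stiffnesses (0.1–50 N/mm), both log-spaced since the ranges span
decades: 64 simulations. `run_experiment_presets()` reruns the five bench
configurations (reference 4.0 N/mm / 0.52 kg; 1.9, 5.0, 0.6 N/mm; 0.89 kg
added weight).

```{r presets}
run_experiment_presets()
```

Three robust behaviours emerge, and are asserted as acceptance-level
tests: the normalized impactor first peak is insensitive to the responding
tissue (it varies by under 1% across the whole 64-cell grid, mean ≈ 29%);
lighter impactors transmit a larger share of the mallet peak; added mass
below the stem raises the stem force while leaving the impactor force
unchanged.

```{r sim-plot}
autoplot(simulate_chain(chain_config(), pulse_half_sine()))
```

## Problem sizes and defaults used by the test suite

The suite simulates the standard 0.8 ms window throughout. Parameter
recovery uses 3 datasets and 5 optimizer starts; sensitivity screening is
exercised at 60 samples (its null-parameter behaviour is tested on the
correlation backbone directly at n = 500, where the null |ρ| bound of 0.1
is meaningful); the reference-group pipeline is demonstrated on 32
pseudo-recordings with 1% sensor noise. These sizes make every stochastic
check reproducible under fixed seeds while keeping the full suite within
a coffee break on one core.

## Known limitations

* The model is strictly one-dimensional: no off-axis blows, no bending,
  no taper-strength or pull-off prediction. The junction is a force
  transmission element only.
* The stem-PoM amplitude is reproduced less faithfully than the impactor
  trace under the half-sine stand-in: the simulated normalized stem peak
  exceeds the reported in vitro one substantially. The exact hard-stop
  force law and the provenance of the 240 Ns/mm tip damping are the
  suspected structural causes; both are flagged as open readings of the
  source material and both sit exactly where the estimation problem is
  sloppy.
* Contact stiffness is practically unidentifiable from PoM traces alone
  (see above); conclusions about the polymer tip's stiffness should come
  from component tests, not from this fit.
* The tissue element is a single mass–spring–damper; resonance effects
  at high tissue stiffness with light masses are captured, but
  distributed-tissue dynamics are not.
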