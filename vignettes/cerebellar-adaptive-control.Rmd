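---
title: "Methods: a cerebellar rate network in a closed control loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cerebellar rate network in a closed control loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model the package implements, the
parameters that matter, the calibration and numerical choices behind
the implementation, and what the simulated study can and cannot say
about the physical experiments it emulates.

## The circuit and its equations

The model is a discrete-time firing-rate network of the cerebellar
cortical microcircuit, evaluated once per 10 ms control sample.
Granule cells receive excitatory mossy-fiber input and inhibitory Golgi
feedback; their axons (parallel fibers) excite Golgi cells, basket/
stellate cells and the single Purkinje cell; basket cells inhibit the
Purkinje cell feed-forward. Population sizes (755 GC, 5 GO, 15 BA,
1 PC; 5 mossy fibers for the motor, 7 for the robot) and per-cell
convergence counts (MF→GC 4, GO→GC 3, PF→GO 150, PF→BA 50, full MF→GO,
PF→PC and BA→PC) reproduce the anatomical convergence ratios at desk
scale. Connectivity is drawn uniformly without replacement, one
independent seeded stream per projection.

Every population shares the sigmoid `1/(1 + exp(-8 (x - 0.5)))`; the
Purkinje rate is shifted by −0.5 into (−0.5, 0.5) so that the
vestibular-nucleus stage can subtract it from the PD command. The only
plastic weights are PF→PC, updated every sample by
`dw = -0.008 (y_PF - 0.5) CF(t)` and clipped to [1e−6, 1]: same-sign
parallel-fiber modulation and climbing fiber give depression, opposite
signs potentiation. Fixed weights are sampled once per experiment from
a Normal(±0.5, 1) restricted by rejection (not clipping) to (0, 1] for
excitatory and (−1, 0) for inhibitory synapses.

The granule–Golgi loop is algebraic as written (granule drive needs the
Golgi rate, Golgi drive needs the parallel-fiber rate). It is resolved
with a one-sample delay on the inhibitory GO→GC branch — the standard
discrete-time resolution, avoiding a fixed-point iteration per sample —
while PF→GO uses the current sample. The initial "previous" Golgi rate
is 0.5, the midpoint of its range.

## Teaching signals

Three climbing-fiber contents are compared, with fixed scaling
coefficients chosen to equalize the contribution of each error
component: sensory error `SE = 0.5 φe + 0.02 φ̇e (+ 5 θe + 0.5 θ̇e)`
(kinematic coordinates, rad) and motor error `ME ∝ 0.4 · PD(t)`
(command coordinates, A), plus their sum. All errors follow the
desired-minus-actual convention, and velocity errors come from the
plant's velocity states, not from differencing positions.

Two wiring polarities deserve note, because the physical robot fixes
them silently in hardware while a simulation must choose them
explicitly:

* **Drive polarity.** The robot's wheel-position PD loop only
  stabilizes the linearized wheeled inverted pendulum if positive
  command current torques the wheels in the −φ direction — the usual
  wiring, equivalent to feeding back +state rather than +error. The
  package therefore ships `polarity = -1` in `robot_params()`. With it,
  the default plant is open-loop unstable (eigenvalue +15.3 s⁻¹), the
  published PD gains stabilize it (discrete-loop spectral radius 0.983
  at 10 ms), and PD-only tracking error on the 0.1 Hz design trajectory
  is ≈0.05 rad.
* **Motor-error polarity.** The catalogued coefficient is c1 = −0.4/A,
  and `compute_me()` implements exactly that. Inside the closed loop,
  however, the learning rule drives the Purkinje output toward
  anti-correlation with the CF, and the command subtracts the Purkinje
  output; a CF proportional to −PD therefore teaches the network to
  attenuate the PD command, which degrades control, while +0.4·PD
  reproduces the intended feedback-error-learning behaviour (the
  cerebellum gradually takes over the feedback controller's correction
  as a feedforward signal). The loop applies `me_polarity = -1` to c1
  by default, analogous to the drive polarity above.

## Operating-point calibration

A freshly sampled weight set places every downstream population far
outside the sigmoid's dynamic range: a Golgi cell summing 150 parallel
fibers saturates, shutting granule cells down, and the Purkinje drive —
755 excitatory inputs against 15 inhibitory ones — sits two orders of
magnitude above the activation midpoint. Both failure modes
(over-inhibition of the Purkinje cell; a runaway granule–Golgi loop)
must be tamed before learning can operate at all. The package does this
with one logged scalar per projection, measured on a one-cycle PD-only
warmup pass of the actual closed-loop signals and iterated to a fixed
point:

* MF→GC excitation is scaled to a mean drive of 1.0 and GO→GC
  inhibition to −0.5, so granule drives straddle the midpoint with wide
  cell-to-cell diversity. Diversity matters beyond richness of the
  basis: it keeps a subpopulation of strongly driven granule cells
  active at every stimulus phase, so the population term
  `S(t) = Σ y (y − 0.5)` that couples a CF excursion to the Purkinje
  drive never changes sign — with S > 0 the closed learning loop is
  negative feedback; operating points that let S change sign (we tested
  sparse and narrowly graded coding targets) lead to runaway
  potentiation or depression.
* The Golgi input (MF→GO with PF→GO) and the basket input (PF→BA) are
  scaled to mean drive 0.5, keeping those populations responsive.
* The basket→Purkinje pathway gets two scalars: the input scale is
  scanned and the output scale set by an exact mean constraint, so that
  the inhibition centres the mean Purkinje drive at 0.5 while
  cancelling as much of the common-mode parallel-fiber drive
  fluctuation as a scalar allows. The plastic PF→PC vector is never
  rescaled.

All five scalars are returned in the trial object (`calibration`;
`guard_scale` is the basket output scalar, the quantity worth logging
when diagnosing over-inhibition).

Even calibrated, the Purkinje drive fluctuates far beyond the sigmoid's
linear range — an unavoidable consequence of summing 755 positive
weights over a population with common-mode stimulus drive — so the
Purkinje output largely operates as a fast relay between its bounds.
The plant's inertia demodulates this duty-cycle-modulated signal; the
learning rule shapes the switching pattern. This is visible in the
recorded `y_pc` series and is part of why the Purkinje contribution
must enter the command at a modest gain (next section).

## Output gain

The Purkinje rate is bounded in (−0.5, 0.5) while commands are in
amperes, so a conversion gain is unavoidable. The defaults (0.3 A per
unit rate for the motor, 0.02 for the robot) were fixed once by pilot
calibration: large enough that the cerebellar pathway has authority
comparable to the correction the PD leaves on the table, small enough
that the relay ripple the plant must filter does not dominate. The
wheeled inverted pendulum tolerates far less command perturbation than
the motor — its soft wheel-position loop converts low-frequency command
noise into standing tracking error — hence the much smaller robot gain.
Both are config fields (`experiment$output_gain`).

## Plants

The experiments this package emulates drove physical devices; the
package ships linear stand-ins with all constants in config:

* Motor: `J φ̈ = Kt i − B φ̇` with J = 5e−5 kg m², B = 2e−4 N m s,
  Kt = 0.01 N m/A.
* Robot: the linearized wheeled-inverted-pendulum pair
  `(I_w + (m_w + m_b) r²) φ̈ + m_b r l θ̈ = τ`,
  `(I_b + m_b l²) θ̈ + m_b r l φ̈ − m_b g l θ = −τ`, τ = −Kt i, with
  m_b = 0.8 kg, m_w = 0.05 kg, r = 0.025 m, l = 0.1 m,
  I_b = m_b l²/3, I_w = m_w r²/2, Kt = 0.1 N m/A; body tilt beyond π/4
  marks the trial failed.

Sensors are noiseless and delay-free state readouts. Being linear and
driven under zero-order hold, both plants are discretized exactly: one
RK4 step on a linear system equals the 4th-order Taylor polynomial of
the matrix exponential, and the ten 1 ms sub-steps per control period
compose into a single precomputed affine map, so the integrator
contract (fixed-step RK4 at `dt_inner`) is honoured at negligible cost.
Superposition holds to 1e−9 and halving `dt_inner` changes closed-loop
trajectories by under 1e−6 rad (for the open-loop robot this comparison
is only meaningful under the stabilizing PD loop, as any integration
difference grows like e^(15 t) otherwise).

## Protocol and metrics

The desired trajectory is `π sin(2π f t)` (motor f = 0.5 Hz, robot
0.2 Hz by default; 0.2–0.4 Hz supported), with the desired body tilt
fixed at zero. Trials run 100 stimulus cycles at 10 ms sampling; five
replicate weight initializations are derived from one master seed. The
performance metric is the per-cycle root-mean-square error of the
controlled angle; cycles are the `[k/f, (k+1)/f)` windows of the
desired signal, and per-cycle values are averaged across seeds (the
alternative — pooling whole records before the RMS — was rejected to
keep learning curves visible). The PD-only baseline runs the identical
loop with the Purkinje contribution disconnected and learning off; it
has no randomness, so a single run represents it.

Analyses: `ltd_ltp_fractions()` classifies synapses with a 1e−12
equality tolerance and provides the most-depressed→most-potentiated
sort; `gc_correlation()` computes per-cell Pearson coefficients against
any reference signal (the closed-loop trial accumulates them in
streaming form over the full record, so no rate history is stored) and
smooths with a centred 13-point moving average truncated symmetrically
at the edges; `rotate_trajectory()` maps desired/yielded pairs into the
−45°-rotated plane where perfect tracking is the line y′ = 0 — with the
convention y′ = (φ − φdes)/√2, which direction maps above the line is a
documented convention, not a claim matched to any published figure.

## What the simulation shows — and what it cannot

With the default conditions the acceptance script
(`scripts/acceptance.R`) reproduces the qualitative findings: on the
motor, every CF content (SE, ME, SE+ME) beats the PD-only baseline for
every seed (mean late-cycle improvement around 15–17%); on the robot at
0.2 Hz no trial tips over, SE and SE+ME improve tracking, granule cells
that were depressed correlate positively with the CF and the most
potentiated correlate negatively, and ME depresses far more synapses
than SE.

Motor error on the simulated robot does **not** improve over the PD
baseline at any output gain we tested: the PD-proportional CF covaries
positively with granule population activity, which drives a net
depression drift that pins the Purkinje output at its lower bound, and
the resulting DC command bias costs a small standing wheel offset. This is the
expected fragility of motor error as task difficulty rises — a PD
controller is an increasingly poor inverse model of an unstable plant —
and our linear stand-in reaches that regime already at 0.2 Hz. The
package reports this honestly rather than tuning around it.

More generally, passing the simulated study does not certify the
hardware findings: the plants are linear and noise-free, sensors have
no delay or quantization, the serial-link timing of a physical setup is
absent, and the LTD/LTP percentages depend on the stand-in dynamics
(the direction ME > SE is robust; the absolute fractions are properties
of the simulated plants, not of any physical one). The bi-hemispheric extension, spiking dynamics,
multiple plasticity sites and sensory delays are out of scope.

## Problem sizes and runtimes

The shipped tests evaluate the full network (755 granule cells) in
closed loop: the motor study is 3 modes × 5 seeds × 100 cycles of 200
samples, the robot study the same with 500-sample cycles — about
750 000 network evaluations per battery, a couple of minutes in plain
R. Unit tests use miniature fully connected circuits (2–5 cells per
population) where the rate equations are re-evaluated by an
independent, loop-written oracle to 1e−12.
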