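# flocculus

A firing-rate model of the cerebellar cortical microcircuit embedded in a
closed motor-control loop, built to ask one question: **what error signal
should the climbing fiber carry for cerebellar motor learning to work?**

Two candidates have long competed. *Sensory error* (SE) is the kinematic
mismatch between desired and actual movement, in radians. *Motor error*
(ME), the teaching signal of feedback-error-learning theory, is the
corrective command of a feedback controller, in amperes. The package
simulates a cerebellar network driving two plants — a brushed DC motor
shaft (easy task) and a two-wheeled balancing robot, i.e. a wheeled
inverted pendulum (hard task) — and compares SE, ME and their sum as the
climbing-fiber input, by tracking performance and by the synaptic and
population changes each induces. It is intended for computational
neuroscientists and control engineers studying cerebellar adaptive
filters.

## The model

Four populations are simulated at a 10 ms control period: 755 granule
cells (GC), 5 Golgi cells (GO), 15 basket/stellate cells (BA) and one
Purkinje cell (PC), wired with the convergence ratios of the real
circuit (4 mossy fibers per granule cell, 3 Golgi cells per granule
cell, 150 parallel fibers per Golgi cell, 50 per basket cell, full
parallel-fiber and basket convergence on the Purkinje cell). Every cell
uses the same sigmoidal activation

    y = 1 / (1 + exp(-sigma (x - mu))),   sigma = 8, mu = 1/2

applied to its masked, weighted synaptic drive; the Purkinje rate is
shifted by −1/2 so it can be subtracted from the motor command at the
vestibular-nucleus stage. Mossy fibers carry the desired motion, the
error components and an efference copy of the previous command, each
scaled by a fixed pre-cerebellar gain and sigmoid-encoded.

The sole plastic site is the parallel fiber → Purkinje cell weight
vector `w`, updated every sample by the climbing-fiber (CF) gated rule

    dw = -gamma (y_PF - 1/2) CF(t),   gamma = 0.008

so that same-sign parallel-fiber activity and CF depress a synapse (LTD)
and opposite signs potentiate it (LTP). The CF carries SE, ME, or
SE + ME:

    SE = a1 phi_e + a2 phi_e' (+ b1 theta_e + b2 theta_e' on the robot)
    ME = c1 PD(t)

with the PD controller (the non-cerebellar pathway) also supplying the
baseline command: plant current = PD − gain · y_PC.

Both plants are linear ODE systems integrated exactly under zero-order
hold (a fixed-step 4th-order scheme at 1 ms sub-steps); the robot model
is the standard linearized wheeled-inverted-pendulum pair, open-loop
unstable and stabilized by the published PD gains.

## Worked example

A single experiment is one call; the returned object behaves like a
fitted model (`coef()` is the learned weight vector, `residuals()` the
tracking error, `plot()` the learning curve):

```r
library(flocculus)
trial <- cnn_control("motor", cf = "SE", cycles = 100, seed = 1)
summary(trial)
#> motor plant, CF = SE: 100 cycles
#>   RSE(phi): cycle 1 = 0.3201 rad, late mean = 0.1941 rad
#>   PF-PC weights: 24.0% depressed, 76.0% potentiated (guard scale 39.6)
```

The root-mean-square tracking error (RSE) falls from 0.32 rad to
0.19 rad as the PF–PC weights adapt; the guard scale is the logged
basket-pathway calibration factor (see the vignette).

The full protocol — five random weight initializations per CF mode plus
the PD-only baseline — is one more call:

```r
bat <- cnn_battery("motor", cycles = 100, n_seeds = 5, seed = 1)
bat
#> Cerebellar control battery: motor plant at 0.5 Hz, 100 cycles, 5 seeds
#>   PD-only late RSE: 0.2349 rad
#>   CF = SE     late RSE: 0.1991 rad (-15.3% vs PD)
#>   CF = ME     late RSE: 0.1949 rad (-17.0% vs PD)
#>   CF = SE+ME  late RSE: 0.1987 rad (-15.4% vs PD)
plot(bat)
```

On the easy task every teaching signal clearly beats the PD controller
alone. On the balancing robot (`cnn_battery("robot", ...)`) SE and
SE + ME still improve tracking while ME does not — motor error degrades
as the task gets harder, because the PD controller is a poor inverse
model of an unstable plant (the vignette analyses this).

Post-hoc analyses mirror the network-level statistics:
`ltd_ltp_fractions()` classifies depressed/potentiated synapses,
`gc_correlation()` correlates each granule cell's rate with the CF or
any mossy-fiber signal in the plasticity sort order, and
`rotate_trajectory()` gives the −45°-rotated desired-vs-yielded view.

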