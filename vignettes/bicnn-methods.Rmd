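---
title: "The bicnn model: circuit, plasticity, plants and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bicnn model: circuit, plasticity, plants and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bicnn` simulates a bi-hemispheric firing-rate model of the cerebellar
cortex used as an adaptive feedforward element next to a fixed PD feedback
controller. Each hemisphere contains five populations: mossy fibers (MF,
the inputs), granule cells (GC, whose axons are the parallel fibers, PF),
Golgi cells (GO), basket/stellate cells (BC) and a Purkinje cell (PC, the
output). Per hemisphere the experimental configuration keeps 257 MFs, 27
GOs, 267 BCs and 1 PC fixed while the GC population starts at 4000 and is
knocked down in graded numbers — the scientific question being what the
abundance of GCs buys during motor control.

### Anatomy in a cube

Construction is 3D: every neuron of every population is placed uniformly
at random in a cube of edge 100 µm, then wired by a nearest-neighbour rule
under anatomical convergence ratios — each GC receives exactly its 4
closest MFs and 4 closest GOs, and likewise for the other projections
(MF→GO 66, PF→GO 1639, BC→GO 28, PF→BC 41, PC→BC 3, BC→PC 110).
Distance ties resolve to the lowest source index so a rebuild under the
same seeds is bit-identical.

Two configurations are supported: the anatomical whole-network totals
(562 MF / 56 GO / 8192 GC / 548 BC / 30 PC), for which PF→PC keeps its
1024:1 convergence, and the per-hemisphere experimental configuration
above. The two are not a factor-of-two of each other and their relation is
left open; with a single PC we let that PC receive *all* parallel fibers.
That choice is forced by the knockdown design: compensation rescales the
surviving GC drive by total/active so the expected excitation of
downstream cells is preserved, and weight-trajectory analyses rank all
active GCs by their PF–PC weight — both of which presuppose every GC
synapses on the PC. Fan-ins larger than a source population are capped at
the population size (e.g. PC→BC becomes 1:1 with a single PC).

Synaptic magnitudes are drawn from a normal distribution (mean 0.9, sd
0.1) truncated to [0.8, 1] — by resampling, not clipping, so no
probability mass piles up at the bounds — and multiplied by a cell-wise
normalizer *d*, the inverse of the number of same-nature (excitatory or
inhibitory) inputs of the target cell. Consequently each cell's
excitatory and inhibitory input weights each sum to ≈0.9 regardless of
fan-in, and the sum of *d* over same-sign inputs is exactly 1.

### Rate dynamics

All populations are memoryless sigmoid units, `y = 1/(1 + exp(-σ(x−µ)))`
with σ = 8 and µ = 1/2, where `x` is the signed, *d*-normalized weighted
sum of inputs (inhibitory projections enter with negative sign). The PC
alone subtracts 0.5 from its sigmoid, giving a centred rate in
(−0.5, 0.5); the left hemisphere's PC rate is inverted and added to the
right one, so the combined cerebellar output lives in [−1, 1] and
identical bi-hemispheric modulation cancels exactly.

Two numerical choices deserve note:

* **Recurrence.** The loops GC↔GO, BC↔GO and BC↔PC have no within-step
  fixed-point procedure in a discrete-time rate model, so recurrent terms
  (PF→GO, BC→GO, GO→GC, PC→BC) use the previous control step's rates — a
  one-step (10 ms) delay — while feedforward terms use the current step.
* **PC→BC feedback.** The BC population sees the *nonnegative* part of
  the PC activation (the sigmoid before centring, in [0, 1]). Feeding the
  centred rate into an inhibitory synapse would act as excitation whenever
  the PC rate is negative; numerically this latches both PCs at −0.5 and
  freezes the circuit. The centred value is used, exactly as defined, for
  the hemisphere's output.

### Plasticity

PF–PC synapses are the sole plastic site. Each hemisphere receives one
climbing fiber (CF) with spontaneous rate `cf_spont = 0.05` encoding a
preferred direction of task error: per control step, if `cf > cf_spont`
every PF synapse is depressed by `γ_LTD · cf · y_pf` (γ_LTD = 4×10⁻⁶),
otherwise potentiated by `γ_LTP · y_pf` (γ_LTP = 0.3×10⁻⁶); equality
routes to potentiation, weights are floored at 0 and not capped above
(LTD is the opposing force in closed loop). The CF encoding is a clipped
linear map, `cf = clip(cf_spont + g_pref·max(e,0) − g_np·max(−e,0))`,
mirrored between hemispheres; its exact form is not fixed by the model
definition and this stand-in is the package's own, with `g_pref` sized so
a plant's typical peak error maps to a CF rate near 0.5 and
`g_np = g_pref/10`.

The CF's error source is the *tracked variable* of each plant (shaft
angle, wheel angle, horizontal position). An alternative — the
stabilization-critical variable (robot tilt, quad pitch) — was
implemented and tested first: under a stabilizing PD those errors are
essentially uncorrelated with the task phase, the two hemispheres depress
symmetrically, and no tracking improvement can emerge. The
motion-direction reading also keeps one chain property uniform across
plants: a persistent forward tracking error raises `cf_left` above
spontaneous and depresses left-hemisphere PF–PC weights.

### Knockdown

`knockdown_gcs()` silences all but *n* uniformly chosen GCs (a silenced
GC emits exactly 0 everywhere and its synapses never change) and rescales
surviving GC-originating drive by total/active — equivalently, recomputes
the excitatory normalizer over active inputs — preserving expected
downstream excitation. The compensation multiplies the whole synaptic
efficacy including its learned part, so the effective per-step weight
excursion scales with the compensation too; this keeps the learning
timescale roughly size-independent, and what small GC counts lose is
representational diversity, not learning speed.

## Plants and the control loop

The control loop runs at 10 ms: read sensors → form errors against the
analytic reference → encode MF rates (the efference copy is the previous
step's command) → step both hemispheres → encode the CFs → apply
plasticity → command `u = u_PD + g_cb · output` → integrate the plant
(RK4 at 1 ms sub-steps; Euler at 10 ms destabilizes the pendulum
independently of control). Each signed plant signal feeds two rectified
MF channels (positive/negative) scaled by its printed gain and clipped to
[0, 1]; the 257 fibers are interleaved near-evenly across the
signal × polarity channels, and both hemispheres receive the identical MF
vector — hemispheres differ only in CF preference.

The three plants are simulations; their physical constants are this
package's own, chosen once so that (a) the printed PD gains stabilize the
printed simple tasks and (b) reference amplitudes/frequencies are
trackable but demanding:

* **DC motor** (1 DOF): armature-voltage model with back-EMF
  (J = 0.002, b = 0.01, kt = 0.5, ke = 0.02, R = 1, L = 0.005); PD
  kp = 0.8, kd = 0.01 tracks `π sin(2π·0.5t)` with an untrained cycle RSE
  of ≈0.2–0.4 rad.
* **Two-wheel robot** (2 DOF): nonlinear wheeled inverted pendulum
  (body 0.7 kg with COM 0.13 m above the axle, wheel radius 0.03 m,
  motor constant 0.05 N·m per unit, command saturation ±1.5), upright
  equilibrium open-loop unstable, fall threshold π/4 rad. The printed
  body PD (−18.017, −2.511) plus wheel PD (−0.553, −0.197) balances the
  0.25 Hz single-sinusoid wheel task; the sum-of-sines task
  `π sin(2π·0.2t) + sin(2π·0.7t)` exceeds the saturated authority and the
  PD alone falls — the qualitative contrast the model exploits.
* **Planar quadcopter subsystem** (pitch + horizontal position of the 6
  DOF vehicle; the other loops are held ideal): tilt-to-translate
  dynamics `m·ẍ = m·g·tanθ − c_x·ẋ`, `I·θ̈ = u − c_th·θ̇`, with a
  position PD (0.5, 0.9) setting the pitch reference (clipped at ±0.35
  rad) and a pitch PD (4, 0.8) setting torque; these cascade gains are
  package choices.

The cerebellar gain `g_cb` converts the [−1, 1] output to actuator units:
dc_motor 20, robot 2, quad 2. The DC-motor value is deliberately larger
than the PD's peak command: at the printed activation constants the
learned PC differential expresses only a few percent of the output range,
and the gain is sized so the full cerebellar pathway can carry the
plant's actuation demand. With it, the 182-cycle protocol reproduces the
expected learning phenomenology (trained RSE ≈ 0.11–0.12 rad on the
simulated motor, ≈55% below untrained).

A caveat stated plainly: with the printed MF scaling gains at these
plants' signal ranges, the robot and quadcopter encode rather weak MF
modulation, and their closed-loop learning is correspondingly weak. The
DC motor — the plant all quantitative properties are asserted on — has
healthy MF drive and shows the full effect. Trends across plants
(stability contrasts, bookkeeping, falls) are unaffected.

## The experiment harness

`experiment_config()` encodes the protocol: twelve GC sizes (4…4000),
five weight seeds × five connectivity tables ("Nets") = 25
initial-condition permutations, hence 300 runs per plant; untrained
window cycles 5–6, trained window 90–91 (robot/quad) or 180–181 (DC
motor), rescaled proportionally for reduced desk-scale grids.
`gc_sweep()` shares construction across the factorial (each Net is placed
and wired once). Analyses: per-size box statistics pooling 25 × 2 = 50
RSE values (type-7 quantiles — the convention is unspecified upstream, so
the most common default is used and recorded here), one-way ANOVA of
trained model vs PD-only with a 0.05 flag and no multiplicity correction,
the Net-wise variability decomposition (bar = mean over weight seeds,
error bar = their sd), and the best-GC analysis ranking GCs by PF–PC
weight and matching 4-MF input patterns and GO afferents. Fallen trials
are excluded from moments and counted separately.

Sizes used by the shipped checks: the learning property uses 1000 active
GCs, 60 cycles and 10 seeded builds; the robustness property uses sizes
{4, 80, 1000} × 5 × 5 seeds at 60 cycles and asserts the
across-initialization sd of final RSE is non-increasing in size (Spearman
ρ ≤ 0). These are the package's desk-scale study conditions; the full
300-run grid is available through `gc_sweep()` / the CLI.

## What the simulations do and do not show

All inputs are generated internally — reference trajectories, plant
states and seeds; there is no external data. Sensor noise is off by
default (noiseless simulation mode; a seeded Gaussian noise option
exists), so every run is exactly reproducible from its manifest, and all
stochasticity enters through the seeded build streams (placement,
connectivity, weights, knockdown mask), as in the 5 × 5 design. Passing
properties on these simulated plants demonstrates the circuit-level
mechanisms — structural contract, gated LTD/LTP, bi-hemispheric
differential learning, knockdown robustness trends — not the performance
of any physical motor or robot, whose constants are not part of the
model definition.

Known limitations: no spiking dynamics, conductances or PF conduction
delays (outside the abstraction level); plasticity only at PF–PC; the
quadcopter is reduced to its planar pitch/horizontal subsystem; and the
robot/quad learning magnitudes are limited as discussed above.
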