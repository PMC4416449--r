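# bicnn

A bi-hemispheric firing-rate model of the cerebellar microcircuit for
closed-loop adaptive motor control, with a granule-cell knockdown
experiment harness.

## The problem

The cerebellar granule cells (GCs) are the most numerous neurons in the
vertebrate brain, yet only a fraction of them appears necessary for any
single motor task. This package is for computational neuroscientists and
neurorobotics engineers who want to ask, in silico, what the *abundance*
of GCs buys: it builds an anatomically structured two-hemisphere
cerebellar network, couples it to simulated motor plants next to a fixed
PD controller, silences GCs in graded numbers while keeping the rest of
the circuit intact, and measures the behavioral (tracking error, falls)
and neural (Purkinje rates, synaptic weight trajectories) consequences.

## The model

Each hemisphere holds mossy fibers (MF), granule (GC), Golgi (GO),
basket/stellate (BC) and Purkinje (PC) cells, placed uniformly in a
100 µm cube and wired by a nearest-neighbour rule under anatomical
convergence ratios (each GC receives its 4 closest MFs and 4 closest
GOs). All cells are sigmoidal rate units; the PC obeys

    x_PC = y_PF · W_PF–PC + y_BC · W_BC–PC
    y_PC = 1 / (1 + exp(−σ (x_PC − µ))) − 0.5,      σ = 8, µ = 1/2

and the left PC rate is inverted and added to the right one, giving a
cerebellar output in [−1, 1] that joins the PD command. Each hemisphere's
climbing fiber (CF) carries one direction of task error around a
spontaneous rate cf_spont = 0.05 and gates plasticity at the PF–PC
synapses, the sole plastic site:

    ΔW_PFi–PC = −γ_LTD · cf · y_PFi   if cf > cf_spont
    ΔW_PFi–PC = +γ_LTP · y_PFi        otherwise

with γ_LTD = 4×10⁻⁶ and γ_LTP = 0.3×10⁻⁶ per 10 ms step. Initial weights
are Normal(0.9, 0.1) truncated to [0.8, 1], times a cell-wise normalizer
d = 1/(number of same-nature inputs). Knocking the 4000-GC population
down to n active cells rescales surviving GC drive by 4000/n, preserving
expected downstream excitation.

Three simulated plants are included: a DC motor (1 DOF), a two-wheel
inverted-pendulum robot (2 DOF, falls past ±π/4 tilt), and a planar
quadcopter pitch/horizontal subsystem. See the methods vignette
(`vignettes/bicnn-methods.Rmd`) for the full account of dynamics,
parameters and design choices.

## Worked example

Build the experimental network (257 MF / 27 GO / 4000 GC / 267 BC / 1 PC
per hemisphere), knock it down to 1000 active GCs, and run 60 cycles of
the DC-motor tracking task (shaft reference π·sin(2π·0.5·t)):

```r
library(bicnn)

model <- build_bicnn(seeds = list(placement = 11L, connectivity = 11L,
                                  weights = 21L))
model <- knockdown_bicnn(model, 1000, seed = 3L)
print(model$left)
#> <hemisphere_net> MF=257 GO=27 GC=4000 BC=267 PC=1
#>   cube edge: 100 um; active GCs: 1000 / 4000 (compensation x 4 )

trial <- run_trial(model, dc_motor_params(), control_config("dc_motor"),
                   default_trajectory("dc_motor"), n_cycles = 60)
print(trial)
#> <trial_record> dc_motor : 60 / 60 cycles
#>   RSE first: 0.4011  last: 0.1428

r <- trial$cycles$rse
mean(r[5:6])    # untrained window: 0.269 rad
mean(r[59:60])  # trained window:   0.143 rad
```

The cycle-wise root-mean-square error of the shaft angle falls from
0.269 rad (untrained, cycles 5–6) to 0.143 rad after learning — the PD
controller alone stays at 0.378 rad. The same harness sweeps GC counts
across seeded initial conditions:

```r
cfg <- experiment_config("dc_motor", gc_sizes = c(4L, 80L, 1000L),
                         n_weight_sets = 2L, n_net_tables = 2L,
                         n_cycles = 30L)
sw <- gc_sweep(cfg, base_seed = 2L)
trained_vs_untrained(sw)        # per-size box statistics + PD reference
variability_decomposition(sw)   # Net-wise mean / weight-seed sd
```

A thin command-line surface wraps the same functions:

```sh
Rscript inst/cli/bicnn.R run --plant dc_motor --gcs 1000 --cycles 182 \
    --seed 1 --out out/
Rscript inst/cli/bicnn.R sweep --plant dc_motor --grid reduced --seed 1 \
    --out sweep/
Rscript inst/cli/bicnn.R analyze --in sweep/ --report boxes
Rscript inst/cli/bicnn.R replay --manifest out/manifest.json --out out2/
```

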