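# locustcompass

A computational model of heading and angular-velocity integration in the
desert locust central complex.

Desert locusts, unlike fruit flies, appear to carry a **single 360° compass
representation** across the 16 columns of the protocerebral bridge (PB).
`locustcompass` implements a firing-rate circuit model built on that
topography: 16 CL1a (compass) neurons, 16 CL2 neurons, a constant-rate bias
neuron, and two angular-velocity neurons that update the compass not by
feed-forward input but by **multiplicative neuromodulation** of the
recurrent synapses. The package is aimed at computational neuroscientists
studying insect navigation and ring-attractor dynamics.

## The model in brief

Neurons are steady-state rate units (`tau_s >> tau_m`): the membrane sits at
its conductance-based equilibrium

```
U = sum(g_tot * P_s * E) / (1 + sum(g_tot * P_s)),    r(U) = r_max / (1 + exp(-k (U - U_1/2)))
```

with `r_max = 99.6 Hz`, `k = 0.19 /mV`, `U_1/2 = 17.8 mV`. Only synapses
have dynamics: channel-open probabilities follow
`dP_s/dt = P_max r - (r + 1/tau_s) P_s`, and each angular-velocity neuron's
release probability `P_rel` relaxes towards its normalised rate. The
effective weight of every synapse is

```
g_tot = g_s + P_rel_cw * g_mod_cw + P_rel_ccw * g_mod_ccw ,
```

so clockwise/counterclockwise rotation tilts the effective connectivity and
pushes the activity bump around the ring. Synapses are restricted to an
anatomically derived boolean mask; all weights on the mask (324
feed-forward + 2 × 292 modulatory) are fitted by L-BFGS with an analytic
adjoint gradient through the RK4 integrator, against cosine activity
targets: maintenance (hold a heading at zero velocity) and shift (track a
random constant velocity over 200 ms), plus a diagonal-variance
regulariser (weight 0.1).

Evaluation follows three protocols: 4-s angular-velocity integration under
membrane / synaptic / weight noise, attractor clean-up of perturbed bump
states, and a closed-loop walking agent steered towards a fixed goal
through an adapted goal-directed steering circuit (CL1a → TB1 → CPU1-style
comparator), with optional wind gusts.

## Worked example

```r
library(locustcompass)

mask <- build_columnar_mask()              # anatomical connectivity mask
fit  <- optimize_weights(mask, seed = 20, maxit = 1200)
fit
#> Fitted heading-circuit weights: final loss 0.0201 after 1324 evaluations (seed 20)

# integrate a meandering walking trajectory for 4 s
av  <- generate_av_trajectory(4000, dt = 1, seed = 7)   # deg/s, AR(1)
sim <- simulate_circuit(fit$weights, av, phi0 = 120, dt = 1)
sim
#> Circuit simulation: 4000 steps of 1 ms
#>   final true heading 224.6 deg, decoded 241.1 deg (error 16.42 deg)

# accuracy over 200 fresh trials
run_integration_suite(fit$weights, noise_config(seed = 101), n_trials = 200)
#> Integration suite: mean absolute heading error 12.36 deg +/- 0.63 (SEM), n = 200 trials of 4 s
```

The final loss is the mean-squared rate error (Hz²) plus the regulariser;
`~0.02` corresponds to sub-Hz deviations from the target bumps. The suite's
mean error is the wrapped absolute difference between the decoded and true
heading at the end of each 4-s trial — the model's headline accuracy
number. A matching agent run:

```r
interface <- optimize_cl1a_tb1_map(seed = 2)
run_agent_trials(fit$weights, interface, wind_config(p_rotation = 0.02),
                 n_trials = 200, seed = 8)
#> Agent suite: n = 200 trials of 200 steps; median |final deviation| 15.0 deg (mean 18.1)
```

A thin command-line wrapper with subcommands `optimize`, `simulate`,
`evaluate-noise`, `evaluate-attractor` and `run-agent` is installed at
`inst/cli/locustcompass.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/locustcompass.R", package="locustcompass"))')" \
    optimize --seed 1 --out fits/
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/neuron.R`, `R/simulate.R` | rate/synapse equations, batched RK4 engine |
| `R/circuit.R`, `R/weights.R` | masks, bump init, decoder, weight sets |
| `R/training.R` | objective, adjoint gradient, L-BFGS driver |
| `R/evaluation.R` | integration & attractor suites, AV generator |
| `R/agent.R` | steering interface and closed-loop agent |
| `R/io.R`, `R/constants.R` | config, weight files, seeds, manifests |
| `vignettes/heading-circuit-model.Rmd` | the methods vignette |

See the vignette for the model's assumptions, parameter choices (including
the synaptic time constants and the mask conventions), and known
limitations.
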