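# qpdnet

Agent-based co-evolution of a **classical prisoner's dilemma (PD)** on one
scale-free network and a **simplified quantum prisoner's dilemma (QPD)** on
a second one, coupled node-to-node through a shared utility. The package is
for researchers in evolutionary game theory who want to study how quantum
entanglement on one layer and economic coupling between layers reshape the
evolution of cooperation — and to reproduce, at reduced scale, the reported
stationary strategy fractions of this model.

## The model in brief

* **Layer 1** plays the weak PD with every neighbour: R = 1, T = b ∈ [1, 2],
  S = P = 0.
* **Layer 2** plays the three-strategy QPD over cooperation (C), defection
  (D) and super cooperation (Q), with row-player payoffs

  |   | C | D | Q |
  |---|---|---|---|
  | **C** | 1 | 0 | cos²γ |
  | **D** | b | 0 | b·cos²γ |
  | **Q** | cos²γ | b·sin²γ | 1 |

  where γ ∈ [0, π/2] is the entanglement degree. At γ = 0, Q collapses onto
  C; for b·cos²γ < 1, Q is the unique strict Nash equilibrium and ESS.
* Both layers are Barabási–Albert graphs (N nodes, attachment m); a random
  bijection matches nodes across layers. Partners share utility
  U_x = P_x + α·P_x′ with coupling factor α ∈ [0, 1] (α = 0: independent
  layers), but never play games across layers.
* Dynamics: asynchronous Fermi imitation — a focal node adopts a random
  neighbour's strategy with probability 1/(1 + exp((U_x − U_y)/K)), K = 0.1;
  one Monte Carlo step (MCS) updates N players per layer on average.
  Stationary fractions are trailing-window averages over ensembles of
  independent realizations.

See `vignettes/coupled-pd-qpd.Rmd` for the full methods account, including
the calibration of the utility convention and the bistability analysis at
maximum entanglement.

## Worked example

```r
library(qpdnet)

# the QPD at intermediate entanglement, b = 1.5
qpd_matrix(game_spec(b = 1.5, gamma = pi / 4))
#> payoff_matrix (3 strategies: C, D, Q), row-player payoffs
#>     C    D    Q
#> C 1.0 0.00 0.50
#> D 1.5 0.00 0.75
#> Q 0.5 0.75 1.00

q_equilibrium_analysis(game_spec(1.5, pi / 2))
#> Q (super cooperation) equilibrium analysis
#>   strict NE / ESS:          TRUE
#>   gamma threshold (rad):    0.615480
#>   Q dominates D in subgame: TRUE

# a desk-scale ensemble (N = 1000, 1e4 MCS, 10 realizations)
cfg <- scale_profile(simulation_config(b = 1.5, gamma = pi / 2, alpha = 0.8,
                                       seed = 1), "desk")
ens <- simulate_ensemble(cfg)
ens
#> ensemble_result over 10 realization(s)
#>   b = 1.5, gamma = 1.5707963267949, alpha = 0.8, n = 1000, m = 2, k_noise = 0.1
#>      rho_C_1 rho_D_1 rho_C_2 rho_D_2 rho_Q_2
#> mean  0.7944  0.2056  0.1942  0.0067  0.7991
#> se    0.0492  0.0492  0.1265  0.0033  0.1290

whole_network_cooperation(ens$mean)
#> [1] 0.8939
```

Reading: on the PD layer ~79% of players cooperate; on the QPD layer
defection is nearly extinct and super cooperation holds ~80% while ordinary
cooperation persists at ~19% — C and Q coexist instead of Q sweeping the
population as the well-mixed replicator baseline would predict
(`replicator_trajectory()`). The large per-strategy standard errors on
layer 2 reflect genuine bistability: single runs fixate to all-Q or all-C
and the ensemble mean is the quantity of interest.

Figure-layout sweeps come as presets, e.g.
`run_sweep(figure_preset("fig2"))`, and `inst/cli/qpdnet` wraps
simulate/sweep/figure/analyze for shell use.

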