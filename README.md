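# embryosim

An agent-based simulator of early *Caenorhabditis elegans* embryogenesis.
The worm's embryo develops through an invariant, fully mapped cell
lineage inside a rigid ellipsoidal eggshell (~50 µm × 30 µm), and modern
automated lineaging delivers every nucleus's identity and 3D position at a
one-minute cadence. embryosim is for modelers who want to turn that kind
of observation data into a runnable, testable cell-level simulation:

* **Lineage module** — the invariant lineage (Sulston naming, binary
  divisions, fate labels for pharynx / neuron / hypodermis / muscle / gut)
  drives each cell's fate and division time. Trees load from delimited
  tables and export to Newick.
* **Mechanics module** — cells are point masses joined to contacting
  neighbors by springs (rest length = sum of radii); the eggshell is a
  one-sided quadratic penalty on the normalized ellipsoid coordinate
  `g(x) = sqrt((x/a)² + (y/b)² + (z/c)²)`. On the one-minute observation
  timescale the network is in quasi-equilibrium, so positions minimize

  `E = Σ_edges ½k(|xᵢ−xⱼ|−L₀)² + Σ_cells ½k_shell max(0, g(xᵢ)+r̃ᵢ−1)²`.

* **Division-direction module** — a division axis is the normalized
  weighted sum `d = normalize(K_p·p + K_s·s + K_e·e)` of cell polarity,
  the composite cell–cell squeeze, and the cell–eggshell squeeze. The
  coefficients `K` (non-negative, summing to 1) are fitted to observed
  axes by minimizing the summed sign-invariant angle
  `Σᵢ arccos|d(K;cᵢ)·dᵢ|`.
* **Movement module** — directed single-cell migration (the anterior
  intercalation of Cpaaa) as tabular Q-learning on a lattice of occupied
  neighbor-cell sites, with ordered sub-goals (rosette way-points) before
  the destination.
* **Synthetic-data module** — generators for lineages, observed-division
  tables with known `K` and controlled angular noise, and migration
  scenarios, so everything here runs without external data.

The methods vignette (`vignettes/embryo-simulation-methods.Rmd`) documents
the models, parameter defaults, and limitations.

## Worked example

Fit the division-direction model to (synthetic) observed axes, then
simulate a 4-generation embryo:

```r
library(embryosim)

tree <- synth_lineage(generations = 4, division_interval = 10)
tree
#> <lineage_tree> 31 cells (16 terminal), root R, t = [0, 40]

obs <- synth_divisions(c(0.6, 0.3, 0.1), n = 200, noise_angle_deg = 5, seed = 2)
fit <- fit_coefficients(obs, seed = 1)
fit
#> <division_direction_model> K = (0.6019, 0.3026, 0.0955) [polarity, cell-cell, eggshell]
#>   fitted on 200 observations, objective 18.4397 rad

traj <- run_simulation(sim_config(division_K = fit, seed = 1), tree)
traj
#> <embryo_trajectory> t = [0, 41] (42 steps), 15 division(s), final 16 cells
head(traj$events[, 1:4], 3)
#>   time mother daughter_a daughter_p
#> 1   10      R         Ra         Rp
#> 2   20     Ra        Raa        Rap
#> 3   20     Rp        Rpa        Rpp
```

The fitted `K = (0.6019, 0.3026, 0.0955)` recovers the generating
coefficients `(0.6, 0.3, 0.1)` from 200 noisy axes; the objective,
18.44 rad over 200 observations, is a mean angular error of ~5.3°,
consistent with the 5° generative noise. The trajectory holds one
snapshot per minute; divisions fire exactly at the lineage's scheduled
times, daughters are named by the a/p convention, and total cell volume
is conserved to machine precision.

Migration with hierarchical sub-goals:

```r
env <- synth_migration_scenario("cpaaa_like")   # 4 sub-goals + destination
pol <- train_q_learning(env, episodes = 2000, seed = 1)
ro <- greedy_rollout(env, pol)
ro$moves; ro$success; ro$goal_times
#> [1] 10
#> [1] TRUE
#> [1]  3  5  7  9 11
```

The learned policy intercalates through the channel in 10 moves — the
breadth-first shortest path — passing the four sub-goals in order
(path rows 3, 5, 7, 9) before the destination.

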