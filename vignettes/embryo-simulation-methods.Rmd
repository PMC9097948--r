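---
title: "Modeling early C. elegans embryogenesis: lineage, mechanics, division axes, and migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early C. elegans embryogenesis: lineage, mechanics, division axes, and migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryosim)
```

The early C. elegans embryo is a uniquely favorable system for
cell-resolved simulation: its lineage is invariant and fully mapped, the
embryo is transparent and small (roughly 50 µm long with a 30 µm
diameter), and automated lineaging of 3D time-lapse microscopy yields the
identity and position of every nucleus at a one-minute cadence. embryosim
treats each cell as an agent whose *fate* and *division time* are imposed
by the observed lineage, whose *division orientation* follows a fitted
geometric model, and whose *position* follows a quasi-equilibrium
mechanical model. A separate module learns *directed single-cell
migration* as a path-optimization problem. This vignette describes each
model, its assumptions, the tunable parameters, and the limits of what the
accompanying tests demonstrate.

## Lineage as the driver of fate and timing

A `lineage_tree` is a table of cells with `name`, `parent`, `birth_time`,
`division_time`, and `fate` (pharynx, neuron, hypodermis, muscle, gut,
other, or unassigned). Division is strictly binary: each cell has zero or
two children, each child is born exactly at its mother's division time,
and times are minutes on the observation clock. Fate labels are inert
annotations — they have no mechanical effect — reflecting their role as
predefined observations rather than dynamical variables. The fate column
is a pluggable slot: a model that predicts fate under genetic perturbation
could populate it, but only the table-driven provider is implemented.

Daughters are named by Sulston-style suffixing restricted to
anterior/posterior: the daughter in the hemisphere where the division axis
points along the AP axis gets `a`, the other `p`. Only the a/p pair is
generated because the simulator resolves division axes against the AP axis
alone; left/right and dorsal/ventral suffixes would require an oriented
reference frame the model does not maintain. Founder cells of the P
lineage (P0 through P4, EMS) keep their fixed historical names via a
lookup table. When two cells are scheduled to divide at the same minute,
they are processed in lexicographic name order; the observation data do
not dictate an order, and a deterministic convention is required for
reproducibility.

Trees serialize to Newick (via ape) with branch lengths equal to cell
lifetimes in minutes and a root edge for the root's lifetime; terminal
cells, whose division is unobserved, carry length 0. Because Newick has no
standard per-node annotation field, fates ride along in node labels as
`name&fate`; `import_newick()` splits them back out. The delimited
lineage-table format is the primary interchange format and round-trips all
fields exactly.

## Quasi-equilibrium spring-mass mechanics

Each cell is a point mass at position $x_i$ with radius $r_i$. Two cells
are *neighbors* when $\lVert x_i - x_j\rVert \le
f\,(r_i + r_j)$ with contact factor $f$ (default 1.2) — a
distance-threshold contact rule, standard in particle-based tissue models;
the neighbor graph is rebuilt after every division. Each neighbor pair is
joined by a harmonic spring with rest length $L_0 = r_i + r_j$ and a
single global stiffness $k$ (default 1 energy/µm²). The eggshell is an
axis-aligned ellipsoid with semi-axes $(a,b,c) = (25, 15, 15)$ µm by
default; writing $g(x) = \sqrt{(x/a)^2 + (y/b)^2 + (z/c)^2}$ for the
normalized ellipsoid coordinate, the shell contributes a one-sided
quadratic penalty

$$E_{\text{shell}} = \tfrac12\,k_{\text{shell}}
  \max\!\bigl(0,\; g(x_i) + \tilde r_i - 1\bigr)^2,$$

where $\tilde r_i = r_i\,g(x_i)/\lVert x_i\rVert$ is the cell radius
expressed in normalized units along the local radial direction and
$k_{\text{shell}} = 10k$ by default. The penalty is smooth, zero inside
the shell, and convex outside — the simplest functional form consistent
with a rigid confining shell felt only on contact.

Because imaging is at one-minute intervals while mechanical relaxation is
fast, inertia and damping are neglected and the network is assumed to be
in quasi-equilibrium at every observation step: positions are obtained by
minimizing the total potential energy. `relax_to_equilibrium()` runs
L-BFGS-B with the analytic gradient until the gradient max-norm is at most
`tol_grad` (default 1e-6 energy/µm, up to 10,000 iterations with
restarts); failure to converge raises a condition carrying the last state.
Without a shell the energy is invariant under rigid motions, so the
minimum is made unique for testing by pinning the first free cell and
restricting the second to the line joining the pair (any residual rotation
about that line is energy-flat and harmless to the optimizer). Coincident
positions — possible only through degenerate input — are separated by a
1e-6 µm seeded jitter and logged.

Division replaces the mother by two daughters at
$x \pm \phi\, r\, \hat d$ along the division axis $\hat d$ with offset
fraction $\phi$ (default 0.5), each with radius $r/2^{1/3}$, so volume is
conserved exactly; growth is not modeled, matching the constant-volume
cleavage-stage embryo. The default initial radius of 15 µm makes the
16-cell stage occupy ~60% of the default shell volume.

One known limitation follows from the soft shell: when the embryo is
densely packed (e.g. 16 cells at 60% fill), spring compression can balance
the penalty at a small positive protrusion, so the containment condition
$g + \tilde r \le 1$ holds only approximately. Real cells deform; point
masses cannot. At moderate fill the residual is below 1e-4 and the
containment property is tested there.

## The division-direction model

The division axis of a mother cell is modeled as the normalized weighted
sum of three unit vectors:

$$\hat d \;=\; \mathrm{normalize}\bigl(K_p\,p + K_s\,s + K_e\,e\bigr),$$

* $p$ — the dominant polarity of the cell. Polarity provenance is not an
  output of lineaging, so the package defaults to inheritance: a
  daughter's polarity is its mother's division axis, and the root's
  polarity is the AP axis.
* $s$ — the composite cell–cell squeeze: overlap-weighted repulsion
  $\mathrm{normalize}\bigl(\sum_j w_j (x - x_j)/\lVert x - x_j\rVert\bigr)$
  with $w_j = \max(0, (r + r_j) - \lVert x - x_j \rVert)$, zero when no
  neighbor overlaps.
* $e$ — the cell–eggshell squeeze: the inward ellipsoid normal at the
  cell's position when it presses on the shell, zero otherwise.

The squeeze components are named in the conceptual model but have no
canonical functional form; the overlap-weighted and inward-normal choices
are this package's, chosen to be smooth in the geometry and zero exactly
when the named contact is absent.

Division axes from microscopy are undirected lines, so all angles are
computed sign-invariantly, $\theta = \arccos\lvert \hat d_1 \cdot \hat
d_2\rvert \in [0, \pi/2]$. `fit_coefficients()` minimizes
$\sum_i \theta\bigl(\hat d(K; c_i),\, d_i^{\text{obs}}\bigr)$ over the
coefficient simplex. Since the composition is invariant to positive
rescaling of $K$, the gauge $K \ge 0$, $\lVert K\rVert_1 = 1$ is imposed
for identifiability. The simplex is parametrized by squared coordinates
($K = v^2/\sum v^2$) and searched by multi-start Nelder–Mead — the three
pure single-component strategies plus `n_starts` (default 16) seeded
random points — followed by restart polishing, because the objective is
cone-shaped rather than smooth at an exact fit. The three pure strategies
are always evaluated as candidate solutions, so the fit can land exactly
on the simplex boundary and never does worse than any single component
alone. Whether one coefficient vector should apply to all cells and
stages, or vary per stage, is an open modeling question; a single global
$K$ is implemented and per-stage fitting is left to the caller (fit on a
stage-restricted observation table).

Coefficient recovery is validated generatively: `synth_divisions()` draws
components uniformly on the sphere (zeroing squeeze components with
probability 0.3, since many cells touch nothing), composes the axis with a
known $K^\*$, and perturbs it by a rotation about a random transverse
axis. The rotation angle is half-normal, scaled so its *mean* equals
`noise_angle_deg` — the parameter reads directly as the expected angular
deviation. With 200 observations at 5° mean noise, the fitted $K$ has
cosine similarity ≥ 0.98 to $K^\*$ in at least 95% of seeded replicates;
with zero noise recovery is essentially exact (objective below 1e-6 rad).
These synthetic components are isotropic and independent across cells,
which real embryos are not: correlated geometry across successive
divisions could make $K$ harder to identify than the tests suggest.

## Directed migration as tabular reinforcement learning

Directed single-cell migration — the anterior intercalation of Cpaaa is
the motivating scenario — is cast as path optimization on a bounded
integer lattice: neighboring cells are static occupied sites, the lattice
boundary stands in for the eggshell, and the migrating agent must visit an
ordered list of sub-goals (rosette way-points along the intercalation
path) before its destination. Actions are axis-aligned unit moves plus
"stay"; a move into an occupied or off-lattice site leaves the agent in
place and costs a collision penalty. The reward per step is
$-c_{\text{step}} - c_{\text{coll}}\,[\text{blocked}] +
R_{\text{goal}}\,[\text{goal reached}]$ with defaults
$(c_{\text{step}}, c_{\text{coll}}, R_{\text{goal}}) = (1, 5, 100)$ —
chosen so that one goal outweighs any plausible detour cost, making
shortest free paths optimal.

The learner is tabular Q-learning over the state
(site relative to the current goal, occupancy mask of adjacent sites, goal
index); with static obstacles and fixed goal sites this state is
equivalent to (site, goal index), so the table is exact, and a
function-approximation learner (a deep network) could be swapped in
against the identical environment contract at larger scale. Defaults are
$\alpha = 0.5$, $\gamma = 0.95$, epsilon decaying linearly from 1 to 0.05
over the first 80% of episodes. Training is bit-reproducible per seed, an
unreachable goal sequence is rejected up front by breadth-first search,
and greedy rollouts break ties toward the lowest action index and detect
policy loops. On corridor, open-grid, and detour fields the greedy path
length equals the breadth-first shortest path; on the Cpaaa-like field
(a band of cells with a single open channel and four sub-goals) rollouts
visit the sub-goals in order. Path summaries follow the repeated-runs
protocol: the mean trajectory over 50 seeded rollouts with a
one-standard-deviation band, ragged paths padded with their final
position. Rosette way-points are supplied explicitly in the scenario, not
detected from geometry; detection would require cell-shape information the
point-mass model does not carry.

## The simulation loop

`run_simulation()` advances in `time_step` (default 1-minute) increments.
Per step: (1) every cell whose scheduled division time has arrived divides,
in lexicographic order — the axis is composed from the current geometry,
daughters are named against the lineage (whose child names are
authoritative) and placed along the axis with polarity set to that axis;
(2) the contact network is rebuilt and relaxed to equilibrium once, after
the whole division batch — re-equilibration is what the quasi-static
assumption licenses per observation interval, and one relaxation per step
is both cheaper and better-defined than interleaving; (3) the snapshot is
recorded. Exact collinear geometry can cancel the axis composition (the
reason the default $K$ is $(0.6, 0.3, 0.1)$ rather than a vector with
$K_p = K_s + K_e$); if it still happens, the mother's polarity is used and
the event logged. Trajectories carry per-step cell snapshots and a
division event log, and write to the `time,name,x,y,z,radius` nuclei
table format.

```{r example}
tree <- synth_lineage(generations = 4, division_interval = 10)
traj <- run_simulation(sim_config(seed = 1), tree)
tail(cell_counts(traj), 3)
range(tapply(traj$snapshots$radius^3, traj$snapshots$time, sum))
```

## Numerical choices and problem sizes

All tolerances are defaults, exposed in the relevant constructors:
relaxation gradient tolerance 1e-6 energy/µm; shell containment checked at
1e-4; volume conservation at 1e-9 relative per event; coefficient-fit
polishing until the objective improves by less than 1e-13. Validation
uses problem sizes a reviewer can re-run in about a minute: 10-cell random
spring networks (with 1,000-draw perturbation sampling of the minimum),
100-network energy cross-checks, 50 fit replicates of 200 observations,
lattices up to 13×7, and a 16-cell (4-generation) simulated embryo —
large enough to exercise every code path, small enough to keep the whole
suite interactive.

## What the synthetic data do and do not show

The generators reproduce the *structure* of the observation data —
invariant binary lineages with uniform timing, division axes from a known
generative model with controlled angular noise, migration fields with an
intercalation channel — but none of its biological irregularity: real
division intervals vary by sublineage, real axes correlate across
divisions, real neighbors move during migration, and tracking output
contains identity errors. Green tests therefore demonstrate correctness
of the algorithms under the stated models, not fidelity to any particular
embryo. Fitting the division model to real lineaging output and comparing
simulated to observed positions is the intended next use: the file
formats (lineage tables, nuclei tables, observation tables) are designed
to accept automated-lineaging exports directly.
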