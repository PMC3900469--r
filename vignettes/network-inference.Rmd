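---
title: "Inferring S-system gene networks with the island-model hybrid GA-PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring S-system gene networks with the island-model hybrid GA-PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igapso)
```

## The model

An S-system describes the expression dynamics of an $N$-gene regulatory
network by one power-law rate equation per gene:

$$\frac{dx_i}{dt} \;=\; \alpha_i \prod_{j=1}^{N} x_j^{g_{ij}}
\;-\; \beta_i \prod_{j=1}^{N} x_j^{h_{ij}},$$

where $x_i > 0$ is the concentration of gene $i$'s product, the rate
constants $\alpha_i, \beta_i \ge 0$ scale synthesis and degradation, and the
kinetic orders $g_{ij}, h_{ij} \in \mathbb{R}$ encode the sign and strength
of gene $j$'s influence on gene $i$'s production and degradation. Fitting
the coupled system means estimating all $2N(N+1)$ parameters jointly, which
is intractable for realistic $N$.

The package therefore fits the *decoupled* form: gene $i$'s single equation
is integrated with the *observed* profiles substituted for all $x_j$,
$j \ne i$, reducing the problem to $N$ independent sub-problems of
$2(N+1)$ parameters each ($\alpha_i, g_{i1..N}, \beta_i, h_{i1..N}$ --
the particle position space of the optimizer). Between measured time points
the observed profiles are linearly interpolated; this is a modelling choice
(the decoupling device itself does not prescribe one), and it is the
dominant error term of the decoupled forward model when sampling is sparse.

The objective for gene $i$ is the sum over the $T$ time points of squared
relative errors,

$$F_i \;=\; \sum_{t=1}^{T}
\left(\frac{x_i^{a}(t) - x_i^{d}(t)}{x_i^{d}(t)}\right)^2,$$

a sum rather than a mean -- "fitness per gene" values are therefore
comparable across datasets with equal $T$. A normalized variant (divide by
$T$) is available via `fitness_mse(..., normalize = TRUE)`. Relative errors
require strictly positive observations, which the data validators enforce.

## Search ranges

Kinetic orders are searched in $[-3, 3]$ and rate constants in $[0, 10]$,
the standard box for evolutionary S-system fitting. These bounds are also
the hard clamp applied by every operator, so every individual at every
iteration is feasible by construction.

## The hybrid optimizer

Each iteration of `run_gapso()`:

1. **Rank** the evaluated population ascending by fitness (ties broken by
   particle id, so ranking is deterministic).
2. **Partition**: the best $\lfloor p \cdot pop \rfloor$ particles are
   *elites* (default $p = 0.7$); the rest are discarded.
3. **PSO refinement** of the elites with the constriction-factor velocity
   update
   $$v' = \chi\left(w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)\right),
   \qquad \chi = \frac{2}{\left|2 - \varphi - \sqrt{\varphi^2 - 4\varphi}\right|},$$
   with $\varphi = c_1 + c_2 > 4$ (defaults $c_1 = c_2 = 2.05$, so
   $\chi \approx 0.7298$) and fresh per-dimension uniforms $r_1, r_2$.
   The inertia weight defaults to $w = 1$: $\chi$ multiplies the whole
   bracket, and a $w < 1$ would damp momentum twice. Positions are clamped
   to the violated bound; velocities to $\pm(UB - LB)$.
4. **GA reproduction** refills the discarded slots from a parent pool of
   the same size: a fraction $r$ of the population (default $0.1$, optionally
   on a linear ramp) is regenerated uniformly at random, the remainder drawn
   without replacement from the PSO-refined elites. Parents are chosen by
   tournament (size 2, with replacement); crossover places both children at
   the parents' midpoint displaced by the *other* parent's velocity scaled
   by a fresh uniform, so children sit between the parents but accelerate
   away from the current location; out-of-range coordinates are set to the
   bound, and children start with zero velocity. Non-uniform mutation then
   perturbs each coordinate with probability $0.1$ by
   $\Delta(t, y) = y\,(1 - u^{(1 - t/T_{iter})^b})$ (shape $b = 5$): early
   perturbations span the whole feasible interval, late ones shrink to fine
   tuning and vanish at the final iteration.

The best-so-far position (`gbest`) is a sticky run-level memory refreshed
from the surviving personal bests; it can only improve, which is what makes
the reported fitness trace non-increasing. Personal-best memories of
discarded particles are dropped with them.

### Iteration phases and the execution backend

The loop is organised as a *map* phase (PSO update of the flagged elites,
fitness evaluation of every stale particle, personal-best update -- all
strictly per-particle) followed by a *reduce* phase (ranking, partition,
best-update, migration, GA reproduction -- all requiring the group).
Relative to the description above, the loop boundary is rotated so that
every per-particle operation lands in one phase; the sequence of operations
over a whole run is the same. The random individuals that enter the parent
pool are generated and evaluated in the map phase of the iteration that
consumes them.

This split is exactly the contract of a mapper/reducer deployment, and the
package's worker-pool backend (`workers = k`, a fork pool) executes the same
phase functions as the sequential loop. Bit-identical results for any worker
count are guaranteed by the random-number design: every draw comes from a
counter-based stream keyed by (run seed, iteration, gene, island, particle,
operation), so a draw's value depends only on *what* it is for, never on
execution order. The particle-record text format (`serialize_records()`,
one tab-separated line per particle with the gene/island/particle identifier
triple and the full state at 17 significant digits) can be spilled each
iteration (`spill_dir =`) to mirror the intermediate-file flow of a
distributed deployment; a cluster port would replace only the scheduler,
not the algorithm.

## The island model

`run_igapso()` splits the population across $2^n$ islands placed on a binary
hypercube (non-power-of-two counts fall back to a bidirectional ring).
Islands evolve independently; every `migration_interval` iterations
(default 10) a synchronized communication phase sends
$k = \mathrm{round}(0.05 \cdot subpop)$ migrants -- drawn uniformly from each
island's top 20% -- to every immediate neighbor, where copies (position,
velocity, fitness, and personal best; the donor keeps its particle) replace
the currently worst $k$ particles. Incoming batches apply in ascending
neighbor-id order, recomputing the worst slots before each batch, so the
outcome is deterministic. Migration runs strictly between iterations, after
ranking and before reproduction. With one island the procedure reduces
*exactly* (bit-identically) to the single-swarm run.

## Synthetic benchmarks

`generate_benchmark()` stands in for external benchmark generators so every
part of the pipeline is testable without downloads. It samples a sparse
S-system -- each off-diagonal kinetic order nonzero with probability
$k/(2(N-1))$ for a target mean in-degree $k$ (default 2), magnitudes in
$[0.5, 3]$ with random sign (near-zero edges would be unidentifiable),
$\alpha, \beta \sim U[1, 5]$, guaranteed self-degradation
$h_{ii} \in [0.5, 3]$, and $g_{ii} = 0$ -- and integrates it from random
initial states $U[0.2, 1.2]$ over 31 equally spaced points in $[0, 2]$ time
units (long enough, at these rate constants, to span both transient and
near-steady behaviour). Optional multiplicative log-normal noise
(default sd 0.05; microarray-like) and per-gene max-normalization emulate
expression-profiling artefacts; both are off for the noise-free recovery
benchmarks.

Because data are generated *from* S-systems, a perfect fit exists and
parameter recovery is well-posed -- deliberately stronger than benchmarks
generated from a different kinetic model. The generator does **not**
emulate module extraction from real interactomes, realistic noise
covariance, or the identifiability pathologies of under-sampled large
networks, so passing recovery tests here shows the optimizer works, not
that real expression data determine a unique network.

## Expected cost and speed-up accounting

Repeating independent runs (cost $C$ each, success probability $P$) until
one succeeds has expected cost $C/P$. Given $M$ observed successes and $N$
failures, the package reports the closed form

$$E[x] \;=\; C\,\frac{M + N + 2}{M + 1}.$$

`success_posterior_density()` exposes the uniform-prior posterior
$P^M (1-P)^N / B(M+1, N+1)$. Note that integrating $C/P$ against *that*
density gives $C (M+N+1)/M$, not the closed form above: the closed form is
the expectation under $\mathrm{Beta}(M+2,\, N+1)$, i.e. with the terminal
successful run of the try-until-success sequence counted as one further
success. The brute-force check `expected_cost_mc()` therefore integrates
against $\mathrm{Beta}(M+2, N+1)$ (adaptive quadrature by default;
Monte-Carlo sampling retained for convergence checks), and agrees with the
closed form to numerical precision. The estimator is undefined at $M = 0$
and raises rather than extrapolating. The success threshold that defines
$M$ is always an input (`cost_analysis(runs, threshold)`), never inferred.

`amdahl_speedup(f, S)` evaluates $1/((1-f) + f/S)$ and its $S \to \infty$
bound $1/(1-f)$; `parallel_fraction(t_{seq}, t_{par})` recovers
$f = 1 - t_{par}/t_{seq}$ from wall-clock pairs. Platform overheads (job
latency, distributed-filesystem reads) are not simulated; they enter only
through measured times supplied by the user.

## Numerical choices

* **Integrator**: fixed-step classical RK4 with 10 substeps per observed
  interval (configurable). The systems in bounds are small and non-stiff;
  a fixed step keeps runs deterministic and cheap. Halving the step cuts
  the trajectory error about 16-fold (4th order), which the tests assert.
* **State floor** $\varepsilon = 10^{-6}$, applied to every stage state and
  after every substep, keeps negative kinetic orders defined.
* **Divergence**: any state above $10^6$ or non-finite aborts integration;
  the fitness layer maps divergence to a penalty of $10^9$ so ranking stays
  total.
* **Ties**: ranking ties break by particle id; equal-fitness tournament
  entrants resolve to the lowest index; personal bests update only on
  strict improvement.
* **Rounding of fractional partition counts**: floor for the elite and
  random counts; the remainder of the pool comes from the elites. Migrant
  counts round half-up with a minimum of one when migration is enabled.

## Problem sizes used by the test-suite

The suite exercises the operators at toy sizes and the full pipeline at
desk scale: a noise-free 5-gene benchmark fitted with population 500 per
gene for 200 iterations (recovery), the same benchmark under 10 paired
seeds comparing one population of 500 against 4 islands of 125 with
migration interval 10 (island-versus-panmictic direction), and a 3-gene toy
for the backend-equivalence replay. These sizes were chosen so the whole
suite runs on a single CPU in minutes while still leaving the optimizer a
genuinely high-dimensional search (12 parameters per gene, 31 data points).

## Limitations

* The decoupled fit bounds each sub-problem's quality by the interpolation
  of the other genes' observed profiles; with sparse or very noisy sampling
  the assembled model can re-simulate (coupled) worse than its per-gene
  fitness suggests.
* Expression data rarely identify a unique S-system; equally fit models
  with different topologies exist, and nothing here penalizes extra edges.
  Structure-aware objectives are an extension hook, not implemented.
* The worker pool parallelizes fitness evaluation and islands on one
  machine; it preserves the record format and phase contract of a cluster
  deployment but does not implement one.
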