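---
title: "Branching clinical trajectories and pseudo-time from mixed-type tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching clinical trajectories and pseudo-time from mixed-type tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotree)
```

## The problem

Large clinical registries are snapshots: each patient contributes one row of
mixed-type measurements (binary complications, ordinal severity grades,
categorical diagnoses, continuous labs), observed at one moment of an
unobserved disease course.  If the population covers all stages of the
disease, the rows collectively trace the course itself — usually not a single
line but a bouquet of bifurcating trajectories with a shared mild-state stem.
`pseudotree` recovers this structure: it quantifies the mixed table into a
numeric point cloud, learns an **elastic principal tree** through the cloud,
and reads off each patient's **pseudo-time** (geodesic progression along the
tree) and trajectory membership, which then support association statistics
and pseudo-time survival analysis.

## Quantification of mixed-type variables

Ordinal and binary variables are scored under a latent-Gaussian model: the
ordered levels are assumed to bin a standard-normal latent variable, and
level $i$ with proportion $p_i$ receives the score at the centre of its
cumulative mass,

$$x_i = \Phi^{-1}\Big(\sum_{j<i} p_j + p_i/2\Big).$$

Binary variables are 2-level ordinals; categorical variables are dummy
(one-hot) encoded; continuous variables pass through and everything is
finally z-scored with the population ($1/N$) convention, matching the
probability convention of the latent-Gaussian scores.

Because multivariate quantification needs complete rows while imputation
needs quantified values, the pipeline is deliberately hybrid: univariate
scores → SVD imputation → optimal scaling → z-scores.

**Optimal scaling.**  After imputation, ordinal scores are refined by
maximising $J = \sum_{i<j} \mathrm{cor}(x_i, x_j)^2$ over monotone re-scorings
of each ordinal variable.  The update is alternating least squares: for one
variable at a time, the candidate scores are the per-level means of the
projection of all other (standardised) columns on their first principal
direction, made monotone by weighted isotonic regression and standardised.
Because an isotonic projection of that target can in principle lower $J$, a
candidate is accepted **only if $J$ does not decrease**; this makes the
objective trace non-decreasing by construction rather than by hope.  The
sweep stops when $|\Delta J| < 10^{-6}$ (default) or after 100 sweeps.

## Missing values

Rows and columns with intolerable missingness are removed first by the greedy
two-pass rule (columns with missing fraction $> \delta_{\text{column}}$, then
rows recomputed on the remaining columns with fraction
$> \delta_{\text{row}}$; strict inequalities; defaults 0.3 and 0.2).  The
optimal largest-submatrix search is intentionally not attempted.

Two multivariate low-rank imputers fill what remains, both parameterised by
an SVD order $k$:

* **SVDComplete** fits the rank-$k$ PCA basis on the fully observed rows and
  maps each incomplete row to the nearest point of that affine hyperplane,
  measuring nearness only over the row's observed coordinates.  It needs a
  healthy fraction of complete rows.
* **SVDFull** iterates: fill missing cells (initially with column means),
  take the rank-$k$ approximation of the whole matrix, overwrite only the
  missing cells, repeat until the largest change is below $10^{-6}$ (at most
  200 iterations).  Its observed-cell Frobenius error is non-increasing
  across iterations.

The default $k$ is the PCA intrinsic dimension of the complete-row submatrix:
the number of covariance eigenvalues exceeding $\lambda_0 / C$ with $C = 10$.
Imputed ordinal/binary cells can be snapped to the nearest admissible level
score, and a dummy group whose cells were all missing in a row is resolved to
a single 1 at its largest imputed coordinate.  Observed cells are never
modified.

## The elastic principal tree

The tree is a graph with nodes embedded in data space by
$\phi: V \to \mathbb{R}^m$, chosen to minimise

$$U = \mathrm{MSD} + U_E + U_R,$$

where MSD is the mean squared distance of points to their nearest node
(trimmed at $R_0^2$), $U_E$ penalises squared edge lengths with modulus
$\lambda + \alpha\,(\max(2, \deg) - 2)$ (so edges at branchings of degree
$> 2$ cost extra), and $U_R = \mu \sum_{\text{stars}} \|\phi(\text{centre}) -
\overline{\phi(\text{neighbours})}\|^2$ penalises non-harmonic stars.

* **Node positions** are optimised by a splitting algorithm: alternate
  nearest-node partition and the exact quadratic minimisation of $U$ at fixed
  partition (one linear system shared by all coordinates).  Both half-steps
  can only lower $U$, so convergence is monotone.
* **Topology** is searched with two grammar operations, *add a node to a
  node* and *bisect an edge*.  From a deterministic 2-node seed on the first
  principal direction, every candidate one operation away is fitted cheaply
  (tolerance $10^{-4}$, 20 iterations) and the lowest-energy candidate is
  accepted until the node budget is reached; the final tree is polished at
  tolerance $10^{-6}$.  Bisecting an edge at its midpoint never raises the
  energy, which makes the accepted-energy sequence non-increasing.
* **Post-processing** prunes single-edge terminal segments (a grammar
  artefact) and extends each terminal edge to the orthogonal projection of
  its farthest assigned point, so branch-end data project onto edge
  interiors.

Defaults are $\lambda = 0.05$, $\mu = 0.1$, $\alpha = 0.01$, $R_0 = \infty$,
50 nodes — suitable for z-scored clinical data of a few hundred to tens of
thousands of rows.  Ties (equidistant nodes or edges) always resolve to the
lowest index; the only randomness is a jitter fallback when a grammar
candidate has no data-driven placement, governed by the run seed.

A consequence of $\alpha > 0$ worth knowing: star centres of degree 4 or
more are penalised, so data radiating in four directions from one point are
typically represented as two adjacent bifurcations — measurably lower energy
than the degree-4 star on such data.  This is the intended bias: the
underlying clinical model is a cascade of bifurcations, and raising
$\alpha$ monotonically removes branchings.

## Segments, trajectories, pseudo-time

Non-branching **segments** (maximal paths whose interior nodes have degree 2)
are extracted by a depth-first walk over *edges*, which also handles cycles
and isolated nodes in arbitrary graphs.  Observations are partitioned by the
segment of their nearest node; at a branching node the tie goes to the
candidate segment containing the second-nearest node.

Given a root (chosen by per-node 2×2 chi-squared enrichment for a
user-named mild class, or supplied explicitly — selection is advisory),
**trajectories** are the root-to-leaf paths, and the **pseudo-time** of an
observation projecting onto edge $p$ at fraction $\epsilon$ is

$$\mathrm{Pt}(x) = \begin{cases} d_0 + \epsilon & d_0 < d_1\\
d_0 - \epsilon & d_0 > d_1\end{cases}$$

with $d_0, d_1$ the graph distances from the root to the edge's ends,
measured in edge units (a Euclidean-length option exists but edge units are
the default and what the statistics downstream assume, e.g. the default
kernel bandwidth).

## Associations and survival

Segment labels are tested against categorical variables by the independence
chi-squared test with per-cell deviation scores $(E - O)/E$, and against
numeric/ordinal variables by one-way ANOVA with the largest segment as
reference.  Along each trajectory, continuous/ordinal variables are regressed
on pseudo-time by Gaussian-kernel (Nadaraya–Watson) regression
($R^2 = 1 - SS_{res}/SS_{tot}$; bandwidth default 0.25 edge units) and binary
variables by logistic regression, where $R^2$ is defined as the squared
correlation of fitted probability with outcome (a package choice — no
standard $R^2$ exists for this case; separation triggers a small-ridge refit
and a flag).  Screening keeps trajectory pairs with $R^2 > 0.3$ and segment
effects from Benjamini–Hochberg-significant tests (level 0.05 across
variables, per test family) with absolute effect above 0.3.

For survival, pseudo-time replaces physical time: along **one trajectory at
a time** (the API refuses pooled trajectories — risk sets across trajectories
are incomparable), the Nelson–Aalen estimator
$H(t) = \sum_{t_i \le t} d_i / n_i$ (variance $\sum d_i / n_i^2$,
log-transformed bands) gives cumulative hazards, optionally per cause with
all other outcomes censored; Kaplan–Meier gives group survival curves; and
Cox regression (Breslow ties) relates covariates to progression hazard, with
a ridge-stabilised fallback under monotone likelihood.

## Layout

The tree is drawn with the Kamada–Kawai stress layout (per connected
component, tiled); each observation sits at its projection abscissa on its
embedded edge, displaced perpendicularly on a seeded random side by
*scattering* × its projection residual.  The default scattering makes the
median displacement 25% of the median embedded edge length; full
distance-preservation optimisation of the scattering is out of scope.
Per-edge variable means (normalised to $[0,1]$) encode trends as edge
widths, and per-node class proportions are emitted as tables for pie-chart
style summaries.

## What the synthetic generator emulates — and what it does not

`tree_spec()` / `generate_branching_dataset()` produce points uniform along
the arms of an embedded tree (seeded well-separated arm directions, isotropic
Gaussian noise), record the true branch and arc-length pseudo-time, then
optionally degrade columns to ordinal/binary levels by order-preserving
binning and inject missingness (uniform, or concentrated in chosen columns).
This exercises every pipeline stage with known ground truth.

It does **not** emulate: correlated or heteroscedastic noise, non-uniform
patient density along the course (real registries oversample severe states),
informative missingness correlated with severity, measurement batch effects,
or label noise in outcomes.  Passing tests therefore certify the machinery —
quantification, completion, tree recovery, pseudo-time, statistics — under
the stated noise model, not clinical validity on any particular registry.

## Numerical choices and edge cases

* Tolerances: node optimisation $10^{-6}$ (candidates $10^{-4}$), optimal
  scaling $10^{-6}$, SVDFull $10^{-6}$.
* Zero-variance columns: z-scored to 0 with a warning; excluded from optimal
  scaling.
* Empty grammar nodes keep their elastic terms, so the linear system stays
  non-singular whenever $\lambda, \mu > 0$.
* Pruning a bare star would delete every edge; the collapse is stopped at a
  single node with a warning.
* Quantification of a level with zero count places it at its cumulative
  position (consecutive zero-count levels tie).
* Fully missing rows under SVDComplete fall back to column means.

The test-suite study conditions are sized for a workstation: recovery runs
use trees of 20–28 nodes on 300–420 points in 5 dimensions with noise at 7%
of arm length, 20 seeded replicates; null calibrations use 1000 replicates
of $n = 120$; survival recovery uses 50 replicates of $n = 500$.

## Worked example

```{r example, eval = FALSE}
spec <- tree_spec_star(
  3, arm_lengths = 1, m = 6, sigma = 0.06, n_per_branch = 80,
  degrade = lapply(1:3, function(j) list(column = j, kind = "ordinal",
                                         n_levels = 5)),
  missing = list(mechanism = "uniform", fraction = 0.03))
gen <- generate_branching_dataset(spec, seed = 81)
res <- run_pipeline(run_config(dataset = gen$dataset, n_nodes = 16,
                               n_components = 4, seed = 81))
res$graph
res$report
head(res$pseudotime)
```

## Known limitations

* Tree topologies only: no loops, no disconnected principal graphs (the
  segment decomposition handles them, the grammar does not build them).
* The grammar search is greedy per step; it is not guaranteed to find the
  global optimum over all trees of the target size.
* Root selection is a heuristic 2×2 enrichment scan; all downstream
  functions take an explicit root for exactly this reason.
* Kernel-regression $R^2$ is computed on fitted values at the observed
  points; with very small bandwidths it approaches an interpolation score.
* The intrinsic-dimension rule is a scree cutoff; datasets with slowly
  decaying spectra deserve a manually chosen $k$ and reduction dimension.
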