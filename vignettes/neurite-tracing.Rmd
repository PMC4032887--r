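---
title: "Tracing neurites with Fast Marching and active learning of branch topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing neurites with Fast Marching and active learning of branch topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritrace)
```

## The problem

Light-microscopy stacks of fluorescently labeled neurons show axons and
dendrites as bright tubular structures over a noisy background. Recovering
their geometry is largely a solved problem; recovering their *topology* is
not. Two failure modes dominate. Imperfect labeling leaves dark gaps along
a neurite, so one branch appears as several disconnected pieces. And the
anisotropic resolution of confocal or two-photon imaging — the z extent of
the point-spread function is several times the lateral one — makes
neurites of *different* cells that pass within a voxel of each other
appear fused, so a tracer routes one axon onto another ("stolen"
branches). `neuritrace` grows a geometrically accurate initial trace,
refines it, then deliberately dismantles its connectivity and reassembles
it with a classifier trained on morphological features, querying the user
only about the clusters it is least certain about.

## Initial tracing

The arrival-time map $T(\mathbf r)$ of fronts propagating at speed equal
to the normalized image intensity $I \in [0,1]$ obeys the Eikonal
boundary-value problem $|\nabla T|\, I = 1$ with $T = 0$ on the current
boundary $\partial S$. Because bright voxels are fast, fronts race along
neurites. We solve the problem with the Fast Marching method: voxels are
accepted in nondecreasing $T$ order from a min-heap, each update solving
the upwind quadratic in which, per axis, only the smaller *accepted*
neighbor contributes, weighted by $1/s_x^2, 1/s_y^2, 1/s_z^2$ for the
anisotropic voxel dimensions. Zero-intensity voxels are hard barriers (the
equation is singular there) and are never accepted.

`grow_initial_trace()` iterates: march all fronts until the next voxel to
accept lies farther than `D_max` (Euclidean distance to the nearest
boundary voxel; default $15\,s_x$ — larger than a neurite caliber, not
much larger than the shortest branch worth resolving); extract the
gradient-descent path from the farthest accepted voxel back to $T = 0$
over the 26-neighborhood (discrete steps guarantee termination on a valid
upwind map; sub-voxel accuracy is restored later by optimization); add
the path to the boundary and re-solve. Fronts of distinct seeds carry
labels; the first voxel whose accepted neighborhood spans two labels is a
collision, joined by two back-propagated descent paths, one per colliding
region (ties broken by lowest arrival time; the step *into* the other
region may be non-strict because fronts meet at equal times).

Two stopping details matter in practice:

* **Reference intensity.** Growth stops when the newest path's mean raw
  intensity falls below `stop_fraction` (default 0.2) of the trace's
  reference intensity. We use the *median* node intensity as the
  reference: a mean decays with every accepted borderline path, which
  lets the threshold chase the background down and the trace crawl over
  the whole stack. The median stays at the bright-structure level.
  Interactive use can hook `on_stop` to continue past the stop, mirroring
  a tracer that pauses for the user.
* **Dim collisions.** Fronts creeping through nonzero background
  eventually collide even between unrelated neurites. The same intensity
  rule is applied to the joining paths (trimmed of their last two voxels,
  which necessarily touch bright structure); a rejected front pair is
  remembered and never re-joined. Genuinely dark separations (zero
  intensity) are barriers and never collide at all.

Seed points are local maxima of a Gaussian-smoothed copy of the stack
($\sigma = 1$ voxel, with a 0.02 near-maximum tolerance so noise does not
thin the ridge) whose raw intensity exceeds 0.3, greedily thinned to a
minimum separation of $10\,s_x$. The generation rule is this package's
own; only "automatic, intensity-based" is inherited from the field.

## Trace optimization

A trace is a graph of nodes $k$ with positions $\mathbf r^k$ and calibers
$R^k$ and an arbitrary symmetric adjacency — loops are allowed, which is
why the native format is a JSON node/edge graph and SWC (which encodes
rooted trees) is an export with an explicit cycle refusal.

`optimize_trace()` maximizes

$$F = \sum_k L_k \;-\; \alpha_r \lambda\, E_{\text{pos}}
      \;-\; \alpha_R \lambda \sum_{(k,k')} (R^k - R^{k'})^2$$

over all positions and calibers simultaneously. $L_k$ is the
scale-normalized Laplacian-of-Gaussian response of the image at node $k$:
the kernel $-\sigma_e^2 \nabla^2 G_{\sigma_e}$ (unit-mass Gaussian),
evaluated by explicit summation over voxels within 4 standard deviations.
Two numerical choices deserve note:

* The kernel width is $\sigma_e^2 = R_k^2 + \bar s^2/12$, where
  $\bar s^2/12$ is the variance of a voxel footprint. The discrete sum
  point-samples the kernel, and without this term it diverges like
  $R^{-3}$ as $R \to 0$, creating a spurious attractor that collapses
  calibers; with it, the response of a tube with Gaussian cross-section
  of radius $t$ peaks at $\sigma_e = t$, so calibers are recovered with a
  small, known negative bias ($\sqrt{t^2 - \bar s^2/12}$), well under the
  sampling error at realistic calibers. Calibers are clamped at half the
  smallest voxel dimension — sub-voxel kernels are not resolvable.
* $\lambda$ is the average node density of the trace — nodes per voxel
  width of trace *length* (about 1 for voxel-spaced traces). Read as
  nodes per stack voxel it would be $10^{-3}$ or less and the
  regularizers would be irrelevant.

The position penalty $E_{\text{pos}}$ (default `"elastic"`) is the sum of
a spring term — every edge keeps the length it had on input — and a
discrete curvature term (squared umbrella operator at nodes of degree at
least 2). This combination was arrived at the hard way. The intensity
term is *flat* along a tube's axis: a first-difference penalty contracts
the chain (nothing opposes shrinking edges), springs alone let the chain
fold back onto the bright centerline like a concertina (edge lengths
unchanged), and curvature alone lets nodes slide axially and bunch onto
bright noise ripples, harvesting micro-improvements for hundreds of
iterations. Springs plus curvature pin the sampling pattern while leaving
lateral centering — the quantity that matters — completely free. The pure
forms remain available as `regularizer = "curvature"` and `"spacing"`.

Maximization uses a damped Newton method on the full variable set. The
intensity term's Hessian is exactly $4\times4$ block-diagonal (each
node's response depends only on its own position and caliber), computed
analytically in C++ alongside the gradient; each block is made negative
definite by flipping positive eigenvalues (saddle-free Newton) with a 5%
relative eigenvalue floor — a single node sitting on a convex-ascent
direction (a caliber collapsing onto a noise spike, say) would otherwise
force global damping that freezes every other node. The regularizer
Hessians (exact for the quadratic parts, Gauss-Newton for the springs)
are added, the assembled matrix is damped to definiteness if needed, and
the step is scaled by $\beta = 0.5$ with halving whenever the fitness
would decrease, so accepted fitness is monotone. A trust cap of 2 voxels
per node per iteration keeps near-flat background nodes from wild jumps.
Iteration ends when the relative changes of all three fitness terms drop
below $10^{-8}$ (measured against the total fitness scale). On clean
synthetic tubes this converges in 10–30 iterations with centerline error
around 0.02 voxels; occasional noisy draws take about 60.

## Branch merging as classification

`decompose_branches()` cuts the trace at every node of degree $\neq 2$
(each branch keeps its own copy of a shared junction, so junctions
dissolve), and `cluster_terminals()` forms single-linkage clusters of
branch endpoints closer than $10\,s_x$ — above the labeling-gap scale,
below the typical branch length; results are insensitive over roughly
$5s_x$–$15s_x$. Every set partition of a cluster's endpoints is one
merging scenario: blocks of two become an edge, blocks of three or more a
junction node, singletons stay free. Scenario counts are Bell numbers,
which is exactly what makes the approach data-efficient: one labeled
cluster of 4 endpoints yields 14 informative comparisons.

Each scenario gets a 9-component feature vector (per merged pair,
averaged over blocks): endpoint distance; overrun
$\max(0, -(\mathbf r_b - \mathbf r_a)\cdot \mathbf u_a)$ over ordered
pairs, where $\mathbf u_a$ is the outward tangent fitted to the last five
nodes of the branch; perpendicular offset; tangent alignment
$-\mathbf u_a \cdot \mathbf u_b$; absolute difference of branch mean
intensities; intensity standard deviation along the straight bridge;
absolute caliber difference; tortuosity of a tangent-following Bezier
bridge; and the number of free terminals. The exact formulas are this
package's own definitions — the field's literature names the feature
*kinds* but not closed forms — and the extractor is deliberately a single
function (`scenario_features()`) so alternatives can be swapped without
touching the learners. Features 1–4, 8, 9 are rigid-motion invariant;
within-cluster subtractive normalization
$\Delta\mathbf x = \mathbf x_{\text{erroneous}} - \mathbf x_{\text{correct}}$
cancels any per-cluster additive offset, normalizing out local intensity
and neurite density.

Two linear learners consume the $\Delta\mathbf x$ (lower score = better
scenario; the argmin is the chosen merge):

* a **sign-constrained perceptron**: examples drawn with probability
  proportional to cluster weights $Q_\mu$ (all 1 by default); an example
  with margin $\frac1N \mathbf w^\top \Delta\mathbf x < \kappa/N$
  triggers $\mathbf w \mathrel{+}= \Delta\mathbf x/N$, after which
  weights violating their sign constraint are zeroed. The constraint
  vector $g = (1,1,1,0,0,0,0,0,1)$ forces the distance, overrun, offset,
  and free-terminal weights positive; $\kappa = 1$. Initialization is
  $\mathbf w = g$, a feasible start (the field does not specify one).
  Convergence is a clean deterministic pass; an update cap flags
  non-separable data honestly.
* a **cluster-weighted SVM**: maximize
  $\frac1m\sum_i \alpha_i - \frac{1}{2Nm^2}\sum_{ij}
  (\Delta\mathbf x_i^\top \Delta\mathbf x_j)\alpha_i\alpha_j$ under
  $0 \le \alpha_i \le C Q_i$, $C = 2^{20}$, by projected coordinate
  ascent — with no equality constraint, single-coordinate updates are
  exact — to a $10^{-6}$ KKT residual;
  $\mathbf w = \frac1m\sum\alpha_i \Delta\mathbf x_i$.

Active learning ranks unlabeled clusters by the confidence
$e^{-s_{\text{best}}/T} / \sum_i e^{-s_i/T}$ and queries the lowest
first. $T$ rescales the spread and never reorders scenario probabilities
*within* a cluster; the ranking *across* clusters can in principle shift
with $T$ (different gap profiles), which is why $T = 1$ is fixed
throughout. Clusters the annotator declines are skipped permanently —
mislabeled training clusters hurt far more than missing ones.
Generalization error is counted at the cluster level: the whole partition
must match.

## The synthetic generator, and what passing tests mean

`render_stack()` renders tubes with Gaussian cross-sections
($I = \text{background} + \sum A\, e^{-d^2/2\sigma^2} + \text{noise}$,
clipped to $[0,1]$) from centerline polylines, with sharp labeling gaps
(fluorescence zeroed where the nearest centerline point's arc position
falls in a gap interval) and a ground-truth trace that spans the gaps —
the neurite exists even where the label fails. Coincident endpoints of
different tubes are welded into true junctions. The bundled conditions
are a single bright axon (`straight_tube_spec()`: amplitude 0.9 over
background 0.05, noise 0.02, $\sigma = 1.5$ voxels), a bifurcation
(`y_tube_spec()`), and a multi-axon condition (`multi_axon_spec()`: four
axons, two near-crossings at one voxel approach in z, three gaps of five
voxel widths) that reliably reproduces the two error classes of interest
— crossing-induced false branch points and gap-induced breaks.
`planted_clusters()` builds geometric merge clusters labeled by a planted
weight vector, rejecting clusters whose best-vs-runner-up score gap is
below 0.5 so the pool has a controlled margin.

The Gaussian tube profile matches the LoG fitness optimum, so caliber
recovery is well-defined; real image stacks differ in ways the generator
does not emulate — a structured point-spread function, depth-dependent
attenuation, autofluorescent debris, varicosities and spines. Passing
tests therefore demonstrate the *algorithms* (solver correctness against
an independent fixed-point oracle, convergence behavior, separable
learning, topology repair under the modeled error classes), not
performance on any particular microscope's data.

`make_truth_oracle()` stands in for the human annotator on synthetic
stacks: it attributes each branch to the tube its interior nodes hug
(skipping the three nodes nearest the junction) and declines clusters
with any ambiguous attribution, exactly as a careful annotator skips
uncertain cases. On the multi-axon condition this declines the genuinely
ambiguous bridge stubs at crossings; the classifier trained on the
remaining clusters still removes essentially all false positive branch
points on held-out stacks while healing gap breaks.

## Comparison suite

Before comparison, traces are prefiltered — terminal branches shorter
than 12 voxel widths and branches with mean trilinear-sampled intensity
below 0.12 are removed, one branch per pass until stable (simultaneous
removal over-prunes: deleting a twig merges its neighbors into a branch
that may no longer qualify) — and resampled to edges of at most 0.25
voxels by subdividing each edge individually, which preserves total
length exactly and keeps every sample on the original geometry.
Correspondence is a bi-directional nearest-neighbor search: a node
corresponds if its nearest neighbor on the other trace lies within
$h = 10$ voxels, evaluated independently in both directions. (A strict
mutual-NN pairing was tried first and discarded: between two
independently resampled curves the NN relation is almost never
symmetric, so it pairs a quarter of the nodes even when nearly all of
the geometry corresponds.) False positive/negative lengths attribute
half of each incident edge to a node; the Miss-Extra-Score is
$(L_{\text{gold}} - L_{FN})/(L_{\text{gold}} + L_{FP})$, with terminal-
and branch-point analogs on counts. `comparison_plan()` /
`compare_set()` enumerate the multi-user protocol in which every manual
trace serves once as the gold standard (with $U$ users and one automated
trace per stack: $U(U-1)$ inter-user and $U$ automated-to-user
comparisons per stack).

## Problem sizes and limitations

The shipped tests and the acceptance script run on stacks of roughly
$10^5$ voxels, traces of 100–700 nodes, pools of 200 planted clusters,
and 20-tube optimization ensembles — sizes chosen so the full suite
completes in a few minutes on one CPU while still exercising multi-seed
collisions, crossings, gaps, and both learners end to end. Known
limitations: the front-travel check uses the distance to the *nearest*
boundary point (the alternative — distance to the originating point — is
not distinguishable from the field's descriptions); erroneous-collision
suppression beyond the dim-join rule is deliberately left to branch
merging; scenario enumeration refuses clusters above 8 terminals
(B(8) = 4140) unless the cap is raised explicitly; and the classifier is
linear by design — the combinatorial scenario space, not the classifier,
carries the expressive power.
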