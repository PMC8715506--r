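---
title: "Methods: models, parameters and design choices in allokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in allokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

allokit analyses labelled conformational ensembles of a protein — for
example a receptor simulated with and without an intracellular binding
partner — and asks two questions: *which residues distinguish the
conditions* (importance profiling) and *along which residue chains does the
perturbation propagate* (dynamical network analysis). This vignette states
the models each stage implements, the tunable parameters with their
defaults and units, what the synthetic generator does and does not emulate,
and the design decisions taken where the methodology left genuine freedom.

## 1. The adaptive single-state sampling controller

The controller emulates "kinetically trapped" sampling of the metastable
state nearest to a starting structure. Each iteration launches a fixed
count of replicas (`n_replicas = 24`), takes each replica's endpoint in
collective-variable (CV) space, and computes the swarm center $c$
(arithmetic mean per CV). Replica $i$ gets a distance $x_i = \lVert e_i -
c\rVert$ and the mean distance is $d$. Weights follow

$$w_i = \exp(-x_i / d),$$

a scale-free, strictly decreasing law that is maximal at the center, so
center-proximal replicas multiply. The original description leaves the
exact weight and copy-number formulas unspecified; the law is therefore a
pluggable strategy (`law = "rational"` gives $1/(1 + x_i/d)$) and the
default is a documented stand-in, not a reconstruction. Copy counts are the
largest-remainder (Hamilton) apportionment of 24 by $w_i/\sum w$,
deterministic with ties broken by replica index; replicas may receive zero
copies (termination), and children of one parent restart from the parent's
endpoint with fresh RNG streams derived from `(seed, iteration, replica)`.

Convergence is declared when the center-to-center displacement between
subsequent iterations is smaller than the standard error of the replica
distances, $\mathrm{sd}(x_i)/\sqrt{n}$ (an exactly zero drift also counts,
so a deterministic zero-temperature backend can converge). Two properties
of this criterion matter for interpretation:

* It is intrinsically stochastic. In a purely diffusive basin the typical
  center increment per iteration is $\approx 0.36\,\delta$ ($\delta$ the
  per-segment diffusion length) while the SE grows as
  $\approx 0.11\,\delta\sqrt{t}$, so the expected crossing sits near
  iteration 11 and any individual run converges earlier only through
  favourable fluctuations. Roughly 85–90% of seeds converge within 8
  iterations in the toy's default regime; the physically meaningful
  assertion — the swarm never crosses a barrier $\gg kT$ — holds for every
  seed we have run.
* It presumes segments shorter than the intra-basin relaxation time. The
  real protocol uses nanosecond segments inside states whose internal
  relaxation is slower still, so consecutive swarms are strongly
  correlated and the center stops drifting while the spread accumulates.
  The toy defaults reproduce that regime: a double well with minima at
  $(\pm 2, 0)$, barrier $8\,kT$, friction $\gamma = 20$, timestep $0.01$
  and 50 steps per segment (segment $\ll \gamma/U''$).

The backend interface is a plain function `(start, n_steps, seed) ->
trajectory`, so an external engine can be hooked in; only the bundled
overdamped-Langevin double well (Euler–Maruyama, reduced units, exactly
two minima — more would need a different potential parameterisation) is
tested.

## 2. Features and microswitches

Inverse closest-heavy-atom distances $1/d_{ij}$ (Å$^{-1}$) over all residue
pairs with sequence separation $\ge$ `min_sep = 3` are the classifier
input; plain Cα distances are the second supported transform. Both are
internal coordinates and need no frame alignment. The separation cutoff
skips trivially constant neighbour pairs and is configurable.

The GPCR activation microswitches follow the field's conventions: TM6–TM3
is the Cα distance between generic (Ballesteros–Weinstein) positions 3.50
and 6.34; the Y–Y motif is the closest-heavy distance between 5.58 and 7.53
(the water-mediated character of that interaction is deliberately
approximated by the bare heavy-atom distance); the NPxxY motif (7.49–7.53,
heavy atoms) is reported as RMSD against a reference structure after
Kabsch superposition of each frame on a core selection. Defaults where the
methodology is silent: the core is all Cα atoms, and the reference is frame
1 of the ensemble unless a starting active structure is supplied. RMSF is
the per-residue root-mean-square Cα deviation from the time-average
position after two-pass superposition (align to frame 1, then to the frame
average).

Kabsch superposition itself is the standard SVD construction restricted to
proper rotations (det $= +1$); collinear or coincident fit sets (rank $<
2$) are rejected.

## 3. Dimensionality reduction

PCA is the eigendecomposition of the feature covariance (mean-centred, not
scaled), with component signs fixed so each component's largest-magnitude
loading is positive — this makes results bit-reproducible. The pipeline
default of `n_components = 4` matches the practice of reading
conformational landscapes as (PC1, PC2) and (PC3, PC4) panels. Unsupervised
importance back-projects the components onto features,
$\mathrm{imp}_f = \sum_k \lambda_k \lvert V_{kf}\rvert$, min–max normalised;
absolute loadings are used because loading signs are arbitrary for this
purpose.

Metric MDS minimises the raw stress $\sum_{i<j}(d_{ij} - \delta_{ij})^2$ by
SMACOF majorization, initialised from the deterministic classical
(Torgerson) solution. Majorization only finds local optima; `n_starts`
adds seeded random restarts and keeps the lowest-stress solution (the
worked failure case is four points with square geometry embedded in 1-D,
where the symmetric Torgerson start is a saddle). Nonmetric MDS is out of
scope.

## 4. Importance profiling

*KL route.* Each feature is histogrammed per class on shared edges spanning
the pooled range (Freedman–Diaconis bin count capped at 50, or a fixed
`n_bins`), a pseudo-count of 1 is added to every bin, and the symmetrised
divergence $\tfrac12[\mathrm{KL}(P\|Q) + \mathrm{KL}(Q\|P)]$ (natural log)
is computed. Constant features score 0 by convention. Binning and
pseudo-count are documented choices; the methodology does not state them.

*MLP+LRP route.* A softmax-output feed-forward network with one hidden
ReLU layer of 64 units is trained by mini-batch Adam on z-scored features
until the loss plateaus. The network carries **no bias terms**: with the
epsilon-stabilised LRP rule ($\varepsilon = 10^{-9}$), a bias-free network
conserves relevance exactly — the per-sample input relevances sum to the
propagated output score — which we assert to $10^{-4}$ relative tolerance.
Inputs are standardized, so the expressiveness lost is minor. Relevance is
propagated from the true-class logit, averaged over frames within each
class and then across classes. Because relevance on a converged,
over-parameterised classifier still depends on initialisation,
`importance_profiles()` averages |relevance| over `n_models = 3`
independently initialised networks (derived seeds) — the stabilisation the
field's feature-importance tooling uses. A stratified 20% held-out split
is always evaluated and reported to flag overfitting, although relevance
is interpreted on the training distribution.

*PCA route.* `importance_profiles()` computes the PCA importance on **Cα
distance** features rather than inverse distances. This follows the
source's own convention for PCA projections, and has a numerical reason:
in a Gaussian toy without excluded volume, $1/d$ for near-contact pairs is
heavy-tailed, and an unsupervised covariance decomposition chases that
variance instead of the class signal. Cα distances keep feature noise
commensurate. The supervised routes keep the inverse-distance convention.

*Aggregation.* A residue's score is the **maximum** absolute score over
the pair features it participates in (mean available via `agg`), then
min–max normalised; max is chosen so one sharp contact change is not
diluted across a residue's many quiet pairs. Note the structural corollary:
a pairwise feature belongs to both of its residues, so the contact partners
of a genuinely discriminative residue legitimately inherit part of its
signal. Perfect separation of "planted" from "partner" residues is only
measurable when effects are not saturated (see §6).

## 5. Dynamical network analysis

Nodes are residues. An edge joins residues $i, j$ (sequence separation
$\ge 2$; backbone neighbours are excluded so they cannot dominate paths)
whose minimum heavy-atom distance is within `cutoff = 4.5` Å in strictly
more than `occupancy = 0.75` of frames. Correlations are the classic
dynamical-network estimator over Cα displacement vectors,

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}},$$

computed after superposing frames on the core (`superpose = TRUE`; see §6
for why synthetic analyses disable it). Edge weights are $w_{ij} =
-\ln\lvert C_{ij}\rvert$ — natural log by the convention of the originating
network-analysis literature, capped at `w_max = 20` so uncorrelated
contacts become effectively non-conductive rather than infinite.

Girvan–Newman repeatedly removes the edge of highest weighted betweenness
(weights as distances; floating ties broken lexicographically by edge id)
and returns the nested partition maximizing modularity. Since $w$ is a
distance, modularity is evaluated with $\lvert C_{ij}\rvert$ as connection
strength — using $w$ itself would reward weak edges. Critical nodes are
the endpoints of the maximum-betweenness edge between each pair of
communities. Optimal paths come from a hand-rolled Floyd–Warshall with
path reconstruction (weight ties resolved toward fewer hops, then by node
order); suboptimal paths are enumerated by depth-first search pruned with
the all-pairs distances (an admissible completion bound) up to a
combinatorial cap (`max_paths = 1e5`, an error when exceeded). The
suboptimal tolerance is a required, user-chosen parameter in weight units;
no scientific default is claimed. igraph supplies graph containers,
betweenness and modularity; shortest paths are additionally cross-checked
against igraph's independent implementation in the test suite.

## 6. The synthetic generator: what it emulates, and what a green test shows

`generate_two_state_ensembles()` builds a coarse helical pseudo-protein
(Cα on an ideal helix — 2.3 Å radius, 1.5 Å rise, 100°/residue — plus a
radial CB and a CG bridging toward residue $i{+}3$, so an $i \to i{+}3$
contact ladder exists at the 4.5 Å threshold). Frames are the base
geometry plus correlated Gaussian residue displacements drawn i.i.d. per
frame from a block correlation structure: `rho_in` within planted
communities, `rho_out` between, and a shared latent factor raising
planted-chain pairs to `rho_path` (factor loadings solved so cross-block
chain pairs hit the target after renormalisation; the construction is
positive definite for $0 \le \rho_{out} < \rho_{in} < 1$). Class B shifts
the mean position of planted discriminative residues radially by `shift` Å.
Side-chain atoms inherit the residue displacement plus 0.2 Å independent
jitter, so closest-heavy and Cα features correlate without being
identical.

Defaults are `rho_in = 0.5`, `rho_out = 0.05`, `rho_path = 0.9`,
`sigma = 0.4` Å per axis (Cα RMSF $\approx 0.7$ Å, a folded-core scale that
keeps the contact ladder's occupancy above 75%).

What the generator does **not** emulate: temporal autocorrelation (the
downstream analyses are distributional; only the Langevin toy is
sequential), excluded volume (displacements can transiently clash, which
is why unsupervised PCA uses Cα distances, §4), solvent and membrane,
and any real force field. Consequently a green recovery test establishes
that the estimators recover *planted distributional structure* — not that
they would resolve the subtler signals of real trajectories.

Two scenario-level choices deserve emphasis:

* **Superposition.** The generator's frames share one global frame by
  construction, so network analyses of synthetic data pass
  `superpose = FALSE`. Aligning such frames *manufactures* spurious
  structure: superposition on a toy with block displacements drops
  within-block $|C|$ from 0.80 to 0.34 and raises between-block $|C|$ from
  0.01 to 0.41. Real trajectories, which do undergo global rotation and
  translation, need `superpose = TRUE`.
* **The importance-recovery scenario** (50 residues, 2000 frames/class,
  3 Å shift) plants the shift on a coherently displaced helix face
  (residues 20, 23, 26, 29, 32 — one $i{+}3$ ladder), emulating the
  displacement of a transmembrane-helix face, and uses `sigma = 1.0` Å
  (Cα RMSF $\approx 1.7$ Å, realistic for a flexible receptor). Both are
  forced by measurement logic, not preference: with noise far below the
  shift, every feature touching a planted residue saturates its divergence
  (the z-scaled effect tends to its ceiling of 2), so planted residues and
  their contact partners tie and no method can order them; and a lone
  shifted residue hands its strongest features to its $i\pm3$ contacts.
  A benchmark in the saturated regime measures nothing. In the resolvable
  regime all three methods rank every planted residue above the 90th
  percentile of non-planted residues with comfortable margins.

## 7. Numerical and degenerate-input conventions

* Weight law at $d = 0$ (all replicas at the center): all weights 1.
* Distances for betweenness are floored at $10^{-8}$ (a $|C| = 1$ edge has
  $w = 0$, and path counting needs positive costs); path lengths
  themselves use the exact weights.
* Zero-fluctuation residues get off-diagonal correlation 0 with a warning;
  constant features get KL divergence 0; features with zero variance are
  excluded from z-scoring by setting their scale to 1.
* Floyd–Warshall tie-breaks: fewer hops, then smallest intermediate index
  (deterministic, $k$ ascending); Girvan–Newman and critical-node ties:
  lexicographic by (residue_a, residue_b).
* GRO coordinates are converted nm → Å on load; all thresholds are in Å.
  Insertion codes and residue numbers reused across chains are rejected.
  Binary trajectory formats (XTC/DCD) are not readable here; convert to
  multi-model PDB first.
* The min–max normalisation of an all-zero profile returns zeros (no
  signal) rather than NaN.

## 8. Pipeline and reproducibility

`run_pipeline()` drives synth → sample → features → dimred → importance →
network → paths from one config (R list or JSON). A single top-level seed
is hashed with the stage name (and iteration/replica indices inside the
controller) into independent substreams, so stages are individually
reproducible and an identical config reproduces byte-identical outputs;
every output file's MD5 is recorded in `manifest.json`. Stage failures
halt the run with the stage name attached. The package's functions (plus
the thin Rscript front-end in `inst/cli/allokit.R`) are the supported
interface.

## 9. Known limitations

* The weight/copy-number law of the sampling controller is a documented
  stand-in (the original formulas are not printed in the source text);
  conclusions about the controller are conditional on that choice.
* Replicas restart from parent endpoints; restarting from resampled frames
  of the parent segment is a plausible alternative the source leaves
  unspecified.
* The convergence criterion is stochastic (§1); treat the converged flag
  as a stopping rule, not a statistical test.
* Importance aggregation cannot fully separate a discriminative residue
  from its persistent contact partners — that ambiguity is intrinsic to
  pairwise features.
* The MLP is a single-hidden-layer, bias-free network; it is a relevance
  vehicle, not a production classifier.
* Only two-minima toy potentials are provided; the controller, however,
  accepts any backend.
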