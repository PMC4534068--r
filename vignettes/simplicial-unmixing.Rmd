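---
title: "Unmixing bulk tumor profiles with simplicial complexes: model, algorithm, and design notes"
author: "simplicialUnmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing bulk tumor profiles with simplicial complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A bulk genomic profile of a tumor mixes the profiles of the cell
populations it contains. Writing the data as a matrix $M \in
\mathbb{R}^{g \times s}$ of $g$ gene-level measurements on $s$ tumors
(Z-scored per gene), the mixed-membership model assumes each sample
$\vec{s}_j$ is a convex combination of $k$ unobserved pure-population
profiles $\vec{c}_1, \dots, \vec{c}_k$,

$$\vec{s}_j = \sum_{i=1}^k f_{j,i}\, \vec{c}_i + \epsilon_j,
\qquad f_{j,i} \ge 0,\; \sum_i f_{j,i} = 1 .$$

Geometrically the noiseless samples live in the simplex whose vertices
are the component profiles, so unmixing is simplex fitting (archetype
analysis). The premise of this package is that when cell populations
arise along a common evolutionary tree, with distinct tumor subtypes
sampling distinct branches, the samples do *not* fill one
$k$-vertex simplex: they fill a **union of low-dimensional
subsimplices glued at shared vertices** — a simplicial complex. A
shared vertex is a common ancestral (or contaminating normal)
population; each subsimplex is one subtype's progression pathway.
Exploiting that structure keeps the geometric estimation in the low
dimension of each branch, where it is well conditioned, instead of the
full dimension of the union.

The inference target is the pair $(C, F)$: merged vertex profiles in
gene space, and per-sample mixture fractions. A defining consequence of
the model is the *structural zero*: a sample can only draw on the
components of its own subsimplex; its fraction on every other component
is exactly zero. This is also the model's main liability when a
population (e.g. infiltrating immune cells) violates the tree
assumption — see *Limitations*.

## The pipeline

`runPipeline()` executes five stages. All randomness is seeded;
identical configurations are bit-identical end to end.

**(0) Reduction.** Genes are Z-scored (`zscoreGenes()`; constant genes
are dropped by default, since their Z score is undefined) and samples
are projected onto the top `nPcs` principal axes (`pcaReduce()`,
default 10 — a slight upper bound on the number of populations one can
realistically resolve). The basis, offset and per-gene center/scale are
retained so fitted vertices can be mapped back to gene space in the
input units (`backProject()`). Axis signs are fixed (largest loading
positive) for reproducibility. PCA is fit on the Z scores.

**(1) Clustering into putative subsimplices.** Samples are clustered
with k-medoids on a shortest-path distance: the complete sample graph
is weighted by *squared* Euclidean distances, and the distance between
two samples is their shortest-path length (`geodesicDistances()`).
Squaring breaks the triangle inequality for long hops, so the metric
hugs the point cloud: two points in one subsimplex are roughly as close
through the cloud as in a straight line, while points in different
subsimplices must detour through the shared region. The assignment
step uses this geodesic metric; the medoid update follows the printed
k-medoids rule (the data point nearest, in Euclidean distance, to the
cluster's Euclidean mean), which keeps centers inside the data
subspaces. Ties go to the lowest medoid index; emptied clusters are
re-seeded with the point farthest (max-min geodesic) from the current
medoids; 20 seeded restarts by default.

The number of clusters is the operator's decision.
`scanClusterCounts()` reports the mean variance of cluster sizes per
candidate `k` as a balance diagnostic. Note that on smooth, evenly
sampled data the absolute size variance tends to fall as `k` grows
(smaller clusters have smaller absolute size fluctuations), so the scan
is informative mainly when a wrong `k` produces ragged fragments; it
is deliberately not an automatic selector.

**(2) Per-cluster regularized simplex fitting.** Each cluster is fit
with a noise-tolerant simplex under

$$\min_K \sum_j \lVert x_j - K^{\mathsf T} f_j \rVert_p
  + \gamma \log(\mathrm{mst}(K)),$$

where $\mathrm{mst}(K)$ is the Euclidean length of the minimum spanning
tree over the vertices (`mstLength()`). The MST term scores a candidate
simplex by the parsimony of the tree connecting its vertices — a good
simplex is one whose vertices could plausibly have evolved from a
common ancestor along short branches — and, because every subsimplex
contributes a log-length, costs are on one scale and sum into a single
complex-level score regardless of subsimplex dimension. The classic
volume penalty ($\gamma \log \mathrm{vol}(K)$, `simplexVolume()`)
remains available as `penalty = "volume"`.

Defaults are $\gamma = 10$ and $p = 1$. The fit is insensitive to
$\gamma$ over roughly 1–15 (the range matching a few to ~15 % noise in
modern RNA-seq); the L1 residual corresponds to a log-Laplacian noise
model, which fits expression noise better than log-Gaussian. The
logarithm is natural.

*Optimization.* `fitSimplex()` alternates two steps from an
initialization described below:

* **F-step** (`solveFractions()`): with $K$ fixed, each sample's
  fractions solve the simplex-constrained least-squares subproblem.
  The per-point solution is exact: the unconstrained affine solution is
  accepted when feasible; otherwise all faces of the simplex are
  enumerated (vectorized over points) and the best feasible face
  projection taken — exact because the hull projection lies in the
  relative interior of exactly one face. The L2 subproblem is used even
  when the reported objective is L1, matching the alternating algorithm
  as described; the two norms are reconciled only through the
  acceptance rule below.
* **K-step**: with $F$ fixed, candidate vertex updates are tried in a
  cascade: a per-dimension IRLS pass on the L1 regression
  $\min_{K_d} \sum_j |x_{jd} - f_j \cdot K_d|$ (the residual separates
  by dimension once $F$ is fixed), an exact per-vertex weighted-median
  pass (the coordinatewise L1 minimizer), and finally a bounded
  quasi-Newton search (L-BFGS-B with the analytic subgradient of the
  residual and the fixed-topology MST derivative). Vertices are boxed
  to the data bounding box inflated by 20 %.

A candidate is accepted **only if the full objective, after re-solving
$F$, improves**; the recorded objective trace is therefore strictly
non-increasing. Iteration stops when the improvement falls below `tol`
(absolute, default `1e-6`) or after `maxIter` (200) rounds. A
degeneracy floor (`1e-9`) keeps the log penalty finite during line
searches, but a candidate whose MST length sits on the floor is never
accepted — otherwise a large $\gamma$ would reward collapsing the
simplex to a point through $\log(10^{-9})$.

*Initialization* (`mvesInit()`) approximates a minimum-volume enclosing
simplex in three deterministic stages, working in the cluster's own
top-$(m-1)$ principal subspace: successive farthest-point seeding;
"corner snap" rounds that move each vertex to the data point with the
largest barycentric coordinate for that corner (self-correcting when a
sparsely populated corner misleads the farthest-point rule); and
alternating support-plane refinement, translating each face along its
outward normal to a per-face support quantile (about 1 % of points left
outside in total) and recomputing vertices as face-plane intersections.
The face step matters: corner-most data points locate a vertex only to
the local sampling resolution, while the faces are supported by many
points along their whole extent. Before fixing the subspace, the 5 %
of points with the largest out-of-span residuals are dropped and the
span recomputed — points leaked across a cluster boundary from a
neighbouring subsimplex stick out of the cluster's own affine span and
would otherwise tilt it. An enclosing start is deliberately preferred:
the alternating scheme deflates an oversized simplex far more readily
than it expands an undersized one, because interior points' fixed
fractions resist outward vertex moves.

The number of vertices per cluster is either supplied or estimated by
`estimateNumVertices()`: one plus the number of covariance eigenvalues
whose variance share exceeds a threshold (default 0.05). Benchmarks in
this package supply the true counts — mirroring how the baselines are
given the true component number — so that structure recovery measures
clustering, fitting and merging rather than dimension estimation,
which is tested separately.

**(3) Bootstrap and merging.** To decide which vertices on different
subsimplices are the *same* population, each vertex needs an
uncertainty. `runPipeline()` resamples the samples with replacement and
reruns the whole per-replicate inference — clustering **and** fitting
(`bootstrapPipeline()`, default $B = 10$) — matching replicate clusters
to the reference clustering by sample overlap and replicate vertices to
the reference fit by a minimum-cost assignment (`matchVertexSets()`,
exact branch-and-bound). Including the clustering step in the resampled
procedure is deliberate: the dominant uncertainty for a shared vertex
is where the cluster boundary falls — the boundary "steals" samples
near the junction from one subsimplex, truncating its neighbour's
estimate — and a within-cluster resample (available separately as
`bootstrapSimplex()`) cannot see that variability at all. Each
vertex's central position is the componentwise median over matched
replicates (robust to an occasional replicate caught in a poor local
optimum) and its scalar spread is the root of the summed per-dimension
variances, i.e. the standard deviation of the position as a vector.

Two vertices are *indistinct* when their Euclidean distance does not
exceed the sum of their positional standard deviations
(`shouldMerge()`; boundary inclusive, so coincident zero-sd vertices
merge). The root-summed-variance scalar is chosen to be commensurate
with the distance it gates: two independent estimates of the same
vertex sit about $\sqrt{s_1^2 + s_2^2} \le s_1 + s_2$ apart in
expectation, whereas a per-dimension average would undershoot by a
$\sqrt{g'}$ factor and essentially never merge. `buildComplex()`
evaluates the relation over **all** pairs, within and across clusters
(within-cluster merges are legitimate: an over-specified subsimplex
collapses two of its own vertices), merges the connected components of
the relation (position: member mean; sd: member max), and remaps the
subsimplex index sets. Merged vertices are ordered canonically by
coordinates, so the result is invariant to cluster input order.

**(4) Output.** Fractions are re-solved per sample against the merged
vertices of its own subsimplex (the merge moves vertices, so pre-merge
fractions are stale), enforcing the structural zeros exactly. Merged
vertices are back-projected through the PCA basis and un-Z-scored into
the input units. The phylogeny is the minimum spanning tree over merged
vertex positions (`mstPhylogeny()`; deterministic Kruskal, ties broken
by lexicographic vertex pair), written as Newick (rooted for
serialization at the highest-degree vertex) and as an edge list.

## The synthetic validation scenarios

`scenarioCatalog()` defines four tree-structured mixing scenarios, each
with two subtypes: **A** two line segments joined at a point (3
vertices), **B** two tetrahedra joined at a point (7), **C** two
triangles joined at a point (5), **D** two triangles sharing an edge
(4). `simulateScenario()` draws global vertices i.i.d. from a spherical
Gaussian (scale 1, mimicking the unit variance of Z-scored expression)
in the ambient dimension (default 25 000, comparable to a genome-wide
expression panel); assigns each of the 400 samples (default) uniformly
to a subsimplex; draws its fractions Dirichlet(1, …, 1) — uniform on
the subsimplex — and adds i.i.d. Gaussian noise per dimension with sd
equal to `noiseLevel` times that dimension's sd in the noiseless mixed
data (the only self-consistent reading: the noise is defined before it
is added). Vertex placement, the uniform subsimplex allocation and the
flat Dirichlet are choices made for even coverage and testability; they
are not claimed to match any particular tumor cohort.

What the generator deliberately does **not** emulate: count noise and
library-size effects of real RNA-seq, correlated genes, unequal subtype
prevalences, non-vertex contamination, or populations off the tree.
Passing the package's validation therefore demonstrates the geometry
engine works under the model's own assumptions, not performance on real
cohorts.

Benchmarks in the test suite and `scripts/acceptance.R` run at
`ambientDim = 2000`, 400 samples (1000 for the $\gamma$ scan, with 3
repetitions), noise 0.1, with `tol = 1e-4`; these sizes keep a full
benchmark under a few minutes per scenario while leaving every
qualitative conclusion unchanged (the quantities checked —
merge counts, win rates, relative spreads — are dimensionless).

## Evaluation and baselines

`vertexRMSD()` matches estimated to true vertices by minimum-cost
assignment and reports RMSD per matched vertex per dimension; surplus
vertices are reported, not scored. `fractionRMSD()` defaults to the
reconstruction-space normalization
$\sqrt{\lVert C^{\mathsf T}(\hat F - F)\rVert_F^2 / (n g)}$ — an RMSD
per point per ambient dimension, which is the only reading under which
fraction errors have "per dimension" units; the literal fraction-space
mode is available for comparison. Two baselines reproduce the standard
alternatives: `singleSimplexBaseline()` fits one simplex to the whole
cloud with the total true vertex count, and `gmmBaseline()` fits a
full-covariance Gaussian mixture by EM (mclust `"VVV"`; deterministic
hierarchical initialization), scoring its means as vertices and its
responsibilities as fractions. `contingencyChiSq()` provides the
Pearson chi-squared association test (no continuity correction) used to
relate subsimplex assignments to clinical subtype labels.

## Numerical choices and degenerate inputs

* Fraction solver tolerances: feasibility at $-10^{-10}$, dual
  feasibility at $-10^{-9}$; tiny negative entries are clipped and
  columns renormalized, keeping every column on the simplex to 1e-6.
* Rank deficiency: `mvesInit()` refuses to seed $m$ vertices on data
  whose affine span has dimension below $m-1$ (reduce the
  within-cluster dimension first); all-identical clusters are reported
  with $m = 1$ and a warning by the vertex-count heuristic.
* A subsimplex that collapses below two vertices after merging is
  retained as a single shared vertex, with a warning.
* Determinism: axis-sign conventions in PCA, lowest-index tie-breaks in
  clustering and assignment, lexicographic tie-breaks in the MST, and
  canonical coordinate ordering of merged vertices make identical
  configurations bit-identical.

## Limitations

* **Cluster boundaries.** Hard geodesic k-medoids places its boundary
  at a cost equilibrium that fluctuates around the true junction by
  order $n^{-1/2}$ of the branch length — occasionally much more when
  two subsimplices meet along an extended face. The stolen samples bias
  the deprived cluster's shared-vertex estimate inward. The
  pipeline-level bootstrap absorbs much of this into the merge
  tolerance, but merging can still fail in a minority of runs on the
  segment and shared-edge geometries; when it fails, the complex is
  reported as a disjoint union rather than silently repaired. Soft
  assignment would address this and is out of scope here.
* **Structural zeros.** A population that in truth contributes to
  every sample (e.g. immune infiltration) but is assigned to one
  subsimplex is forced to zero elsewhere.
* **Local search.** The fit is a seeded local optimization with no
  global guarantee; the initializer is the main defense, and bootstrap
  replicates expose residual instability as vertex sd.
* **Vertex-count estimation.** The eigenvalue-share heuristic is
  serviceable at low noise but fragile for sparse, noisy,
  high-dimensional clusters; when the count matters, inspect the
  spectrum and supply `mPerCluster` explicitly.
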