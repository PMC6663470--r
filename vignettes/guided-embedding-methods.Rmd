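---
title: "Guided graph spectral embedding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided graph spectral embedding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slepianEmbed)
```

## The model

`slepianEmbed` works on an undirected weighted graph with no self-loops,
raw adjacency $\tilde{A}$ and degree matrix $D$. All spectral machinery
uses the symmetrically normalized operators
$A = D^{-1/2}\tilde{A}D^{-1/2}$ and $L = I - A$, whose eigenvalues lie in
$[0, 2]$; the eigendecomposition $L = U \Lambda U^\top$ defines the graph
Fourier transform, with $\lambda_1 = 0$ and first eigenvector proportional
to $D^{1/2}\mathbf{1}$ on a connected graph. Normalization makes the
analysis reflect topology rather than raw degree, which is why every
downstream operator is built from $A$ and $L$ rather than $\tilde{A}$.

Two classical graph Slepian designs are implemented for a binary selection
matrix $S$ and bandlimit $W$ (signals restricted to the first $W$ Fourier
modes):

* **energy concentration**: eigenvectors of $C = W^\top U^\top S U W$,
  eigenvalues $\mu_k \in [0, 1]$ sorted decreasingly — the fraction of the
  signal's energy inside the selected subset;
* **modified embedded distance**: eigenvectors of the $W\times W$ block of
  $U^\top L^{1/2} S L^{1/2} U$, eigenvalues $\xi_k \ge 0$ sorted
  increasingly — a smoothness ("localized frequency") measure confined to
  the subset. For $S = I$, $L^{1/2} S L^{1/2} = L$.

Both degenerate at full bandwidth ($W = N$): $C$ becomes similar to $S$,
so its spectrum is exactly the multiset of diagonal entries of $S$; and
$L^{1/2} S L^{1/2} = \sum_{k} s_{i_k} l_{i_k} l_{i_k}^\top$ has rank at
most $N - z_S$ (with $z_S$ the number of zero selections), with equality
of the zero-eigenvalue count $z_\lambda = z_S$ on connected graphs because
any proper subset of columns of $L^{1/2}$ is linearly independent. These
two closed forms are the package's main quantitative invariants and are
exercised at $N = 279$ in the test suite and the acceptance script.

The guided criterion removes the bandlimit, generalizes $S$ to a diagonal
*cooperation matrix* $M$ with arbitrary nonnegative weights, and combines
the two objectives:

$$\zeta \;=\; \mu - \xi \;=\;
\frac{g^\top\!\left(M - L^{1/2} M L^{1/2}\right) g}{g^\top g}.$$

Because concentration and localized frequency are opposing goals, the
full-bandwidth problem is well-conditioned: its eigenvalues satisfy
$m_{\max} \ge \zeta_1 \ge \dots \ge \zeta_N \ge -2\,m_{\max}$ (from
$\lambda \in [0,2]$), and for $M = I$ the criterion matrix *equals* $A$,
so the unguided limit is the adjacency eigendecomposition. Each guided
eigenvector is additionally scored by its equivalent $\mu_k = g_k^\top M
g_k$ and $\xi_k = g_k^\top L^{1/2} M L^{1/2} g_k$; for the exact criterion
$\zeta_k = \mu_k - \xi_k$ identically, and for approximated criteria the
same exact operators are used, so approximation quality is always measured
in one fixed frame.

## Taylor approximations

From $L^{1/2} = (I - A)^{1/2}$ and the scalar series of $\sqrt{x}$ about 1,

$$L^{1/2} = I - \sum_{k\ge1} c_k A^k,\qquad
c_k = \frac{(2k)!}{2^{2k}(k!)^2(2k-1)},$$

with $c_1 = 1/2$, $c_2 = 1/8$, $c_3 = 1/16$. Coefficients are evaluated by
the multiplicative recurrence $c_{k+1} = c_k\,(2k-1)/(2k+2)$: each factor
is an exact rational, so the floating-point recurrence is accurate to
$O(k\,\varepsilon)$ and free of the factorial overflow that the closed
form hits near $k \approx 85$. The tests cross-check the recurrence
against a log-gamma evaluation of the closed form up to $k = 50$.

The order-$K$ criterion is computed as $M - Q_K M Q_K$ with
$Q_K = I - \sum_{k \le K} c_k A^k$ (square-root-first truncation, then
symmetrization). Truncating the double series of the expanded criterion
directly would drop different cross terms of total order $> K$; the
square-root-first form is unambiguous and matches how the approximation
error of $L^{1/2}$ itself is defined. Two named special cases have
path-reweighting interpretations: the **linear** criterion
$(MA + AM)/2$ multiplies each edge $a_{ij}$ by $(m_i + m_j)/2$ — an edge
with a single zero-weight endpoint survives at half weight, which is why
de-emphasized nodes never vanish from the analysis — and the
**quadratic** criterion adds $(MA^2 + A^2M)/8 - AMA/4$, reweighting
length-2 paths by their endpoint weights and penalizing them by the
intermediate node's weight. Note that the linear form is the $K=1$
truncation *without* its cross term $AMA/4$.

Approximation error is tracked at two levels: $d_K$, the Frobenius
distance of $Q_K$ to the exact $L^{1/2}$, and $d_{K,M}$, the distance
between exact and approximated criterion matrices. Both are non-increasing
in $K$ (asserted on seeded fixtures), and $d_K$ is bounded by the summed
Lagrange remainders $\sum_i |R_K(\lambda_i)|$. The remainder's evaluation
point is not unique; we bound $|f^{(K+1)}|$ by its supremum over the
closed interval between each $\lambda_i$ and 1, the conservative reading.
At $\lambda = 0$ that supremum diverges, so there the exact scalar
remainder $1 - \sum_{k\le K} c_k$ is used instead (it equals the true
pointwise error at 0, so the bound remains valid). Because near-zero
eigenvalues dominate the remainder, graphs with a larger low-band eigengap
approximate better — the tests compare a ring lattice against a dense
modular graph to exercise exactly this.

## Focus sweeps, alignment, clustering

A focus sweep keeps a focus set at cooperation weight 1 and lowers all
other weights from 1 to 0 over `seq(1, 0, length.out = nSteps)`; the
default is 51 steps, a grid fine enough that successive embeddings change
smoothly while a full sweep on a 279-node graph still takes seconds. At
each step, nodes are projected on the eigenvectors with the second and
third largest $\zeta$ (the leading eigenvector is a near-constant "DC"
pattern, as in Laplacian embedding where the analogous convention is the
second and third *smallest* eigenvalues).

Successive frames are aligned by orthogonal Procrustes — the SVD solution
of $\min_R \|XR - Y\|_F$ over orthogonal $R$, reflections allowed. Two
deliberate restrictions: **no centering and no scaling**, because the
origin of a spectral embedding is meaningful (eigenvector sign conventions
aside, distance from the origin carries concentration information), and
only the rotational/reflective ambiguity of eigendecompositions needs
removing. Alignment is **chained** (each step to the previous step's
aligned frame) rather than all-to-first: with a fine grid the neighboring
embeddings are closest, so chaining follows the continuous deformation and
cannot lock onto a stale reference; the figures of interest are invariant
to either choice up to a single global transform. Step 1 ($t = 1$, $M=I$)
is the unguided reference frame with an identity transform.

End-point clustering of focus nodes uses `stats::kmeans` with 50 restarts
under a fixed seed, and the number of clusters is chosen by maximal mean
silhouette width (`cluster::silhouette`) over `kRange` (default 2..10).
The silhouette criterion is our choice — any "optimal cell groups" rule
needs an explicit model-selection statistic, and silhouette is the
standard one for small k-means problems; it is undefined at $k = 1$, which
is why `kRange` must start at 2.

## Numerical conventions

* **Eigensolver**: dense `eigen(symmetric = TRUE)` everywhere; the package
  targets $N \lesssim 5000$ and makes no attempt at sparse/iterative
  solvers.
* **Sign convention**: every eigenvector column is flipped so its
  largest-magnitude entry is positive, ties broken at the lowest index;
  this makes all outputs reproducible byte for byte.
* **Degeneracy**: repeated eigenvalues make individual eigenvectors
  non-unique. Tests compare subspace projectors or Procrustes residuals in
  that case, and `embedCoords` warns when a requested component sits in a
  degenerate cluster (e.g. a triangle's paired $\zeta = -1/2$).
* **Clamping**: Laplacian eigenvalues in $(-10^{-10}, 0)$ are set to 0,
  and magnitudes below $10^{-12}$ are snapped to 0 before square-rooting —
  $\sqrt{\cdot}$ amplifies an eigenvalue error of $10^{-16}$ at zero into
  $10^{-8}$ in $L^{1/2}$. Anything below $-10^{-6}$ is treated as an
  invalid basis and raises an error.
* **Zero/one classification** in degeneracy reports uses tolerance
  $10^{-8}$, matching double-precision symmetric eigensolver accuracy at
  $N \le 10^3$; it is overridable.
* **Bound checks**: `guidedSpectrum` verifies
  $\zeta_1 \le m_{\max} + 10^{-6}$ and $\zeta_N \ge -2m_{\max} - 10^{-6}$
  and treats violations as numerical failure rather than data.

## Input handling

The loader accepts edge lists (undirected; an exact duplicate edge is an
error, a mirrored pair is accepted only with equal weights), dense CSV
(symmetry enforced to $10^{-12}$), and Matrix Market files. Node order
follows first appearance in the file, with no hidden sorting. Zero-degree
nodes are rejected by name rather than silently dropped; removal is an
explicit `dropIsolated = TRUE`. Binarization (`binarize = TRUE`) maps any
positive weight to 1 — a logical OR, the natural convention when a
connectome combines several connection types (chemical synapses and gap
junctions) into one binary matrix; users who prefer summed weights can
simply skip binarization, since the loader always keeps the raw weights.

## The synthetic generator

`synthModularGraph` draws a three-class planted-partition (stochastic
block model) graph: independent Bernoulli edges with probability `pWithin`
inside classes and `pBetween` across, regenerated until connected (at most
100 attempts), bit-reproducible under a fixed seed. The default sizes
76/75/128 mirror a 279-node somatic connectome's split into sensory
neurons, interneurons and a 128-node motoneuron class, with `pWithin =
0.3` and `pBetween = 0.05` giving the clear-but-noisy modular structure
typical of neural wiring diagrams at this scale. What it emulates: size,
class structure, connectedness, binary symmetric adjacency. What it does
not: degree heterogeneity and hubs, bilateral (left/right) symmetry pairs,
spatial/somatic organization, and the correlated placement of chemical and
electrical synapses. Consequently, passing tests demonstrate the
*algebraic and numerical* behavior of the method — degeneracy counts,
identities, bounds, approximation order — not the biological cluster
memberships or trajectory shapes one would obtain on a real connectome;
those depend on the actual wiring and on clustering settings, and are
deliberately out of the test surface. One behavioral check is retained on
the packaged fixture (focused nodes ending farther from the origin than
de-focused ones); it is an empirical property of that fixture, not a
theorem.

## Problem sizes

The test suite runs dense eigendecompositions up to $N = 279$ (a few
seconds) and property loops over 20–50 fixtures at $N \le 45$; the
acceptance script runs a single $N = 279$ analysis. These sizes keep a
full check-and-test cycle interactive while exercising every code path at
the scale the method is intended for.

## Known limitations

* Dense linear algebra only; memory and time scale as $O(N^2)$–$O(N^3)$.
* Undirected, nonnegative, loop-free graphs; no multigraphs or signed
  edges.
* The bandlimited *guided* criterion is not implemented (the method's
  point is that the bandlimit can be dropped); bandlimits apply only to
  the two classical Slepian designs.
* Chained Procrustes alignment accumulates an arbitrary global orthogonal
  transform over a sweep; only relative geometry within and across nearby
  steps is interpretable.
* The criterion-level error bound $d_{K,M}$ is reported empirically; no
  analytic bound is asserted beyond its monotone behavior.
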