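---
title: "Mapping structural to functional brain connectivity with polynomial models and persistence barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structural to functional brain connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyconn)
```

## The model

Anatomical (structural) connectivity constrains but does not equal
functional connectivity: two regions without a direct white-matter tract can
still show correlated resting-state activity through polysynaptic routes.
`polyconn` models the functional connectivity matrix $F$ as a polynomial in
the structural matrix $S$ plus a global shared input:

$$
\hat F \;=\; G\,\mathbf{1}\mathbf{1}^\top \;+\; \sum_{k=0}^{K} c_k S^k ,
$$

where $S^k$ aggregates walks of length $k$ through the anatomical graph.
The $k=0$ term is a diagonal offset capturing local recurrent self-coupling;
$k=1$ is the direct pathway; $k \ge 2$ are indirect pathways. $G$ models a
brain-wide common signal added to every entry — resting-state BOLD exhibits
global coherence, and absorbing it into one free scalar keeps it out of the
path-length coefficients. By the Cayley–Hamilton theorem any analytic matrix
function of $S$ reduces to a polynomial of degree at most $N-1$, so
$K \le N-1$ is enforced as a hard bound.

The coefficients solve a Tikhonov-regularized least-squares problem,

$$
\hat c = \arg\min_{c,\,G} \;\bigl\lVert F - \textstyle\sum_k c_k S^k - G \bigr\rVert^2
  + \mu \lVert c \rVert^2 ,
$$

with three practical choices that matter:

* **Only unique entries enter the fit.** All matrices are symmetric, so the
  regression runs over the vectorized diagonal-plus-lower-triangle
  ($N(N+1)/2$ rows), giving each unordered node pair one vote instead of
  two.
* **Per-power max-abs normalization.** Matrix powers blow up quickly; each
  $S^k$ is divided by $m_k = \max_{ij} |S^k_{ij}|$ before fitting and the
  fitted coefficient is divided by the same $m_k$ afterwards, so reported
  coefficients live on the original power scale. This keeps the design
  numerically well scaled whatever the spectral radius of $S$; a spectral
  radius $\ge 1$ still triggers a diagnostic warning because the infinite
  Taylor series would not converge there.
* **$G$ is not penalized.** The penalty is $\mu\lVert c\rVert^2$ over the
  path-length coefficients only; shrinking the global offset would bias
  every entry uniformly for no stabilization benefit.

The solver works through the SVD of the augmented system
($\sqrt\mu$-scaled identity rows appended for penalized columns), never
normal equations. With $\mu = 0$ an all-zero design column is refused with
advice to set $\mu > 0$.

## Choosing the regularization weight

$\mu$ is selected by generalized cross-validation,
$\mathrm{GCV}(\mu) = n\,\lVert(I-H(\mu))y\rVert^2 / \mathrm{tr}(I-H(\mu))^2$,
evaluated on a 30-point log-spaced grid over $[10^{-8}, 10^{2}]$ by default.
That span runs from effectively unregularized to heavily shrunk for
max-abs-normalized designs; the grid is a default, not a constraint. Grid
ties are broken toward the larger $\mu$ (the more conservative model). On an
identity design GCV is analytically constant in $\mu$ — a degeneracy the
implementation reproduces to $10^{-10}$ and the tie-break then resolves.
When scanning path lengths, $\mu$ is re-selected at every $K$ by default
(each $K$ is its own model); a fixed numeric $\mu$ can be passed instead to
freeze it globally.

## Coefficient uncertainty

95% intervals come from a percentile bootstrap (default 1000 replicates;
at least 100 enforced) that resamples the $N(N+1)/2$ vectorized
(design-row, response) node-pair entries with replacement and refits at
fixed $\mu$. The resampling unit is the node-pair entry: the fit itself
treats entries as exchangeable observations, so resampling them matches the
model's own error structure. Resampling nodes or subjects would be the
natural alternatives when per-subject matrices are available; that is out of
scope here and the choice is documented rather than asserted as canonical.

## Comparing networks without a threshold

Binarizing a functional matrix at one correlation threshold discards the
filtration structure, and different thresholds tell different stories.
`polyconn` instead converts connectivity to dissimilarity,
$D = 1 - |\mathrm{corr}|$, sweeps a filtration value $\lambda$, and tracks
the zeroth Betti number $\beta_0(\lambda)$ — the number of connected
components of the graph whose edges are pairs with $D_{ij} < \lambda$. The
resulting barcode starts at $N$ components and steps down at exactly the
single-linkage merge heights, which `betti0_barcode()` computes via a
sorted-edge union-find (Kruskal order). Two conventions are fixed:

* **Strict inequality** $D_{ij} < \lambda$: at $\lambda$ equal to a merge
  height the merge has *not yet* happened. This affects only
  measure-zero points of the integral below but makes point evaluation
  deterministic.
* **Exact integration.** Two barcodes are compared by
  $\mathrm{SSE}_\beta = \tfrac{1}{N^2}\int_0^1 (\hat\beta_0 - \beta_0)^2
  \,d\lambda$, computed exactly by merging breakpoint lists and summing
  piecewise-constant contributions — no quadrature grid, hence no
  resolution knob. The $1/N^2$ factor makes the measure comparable across
  network sizes, and the integration limits are exactly $[0,1]$.

A model prediction is not itself a correlation matrix, so before the
$1-|\mathrm{corr}|$ conversion any matrix with entries exceeding 1 in
magnitude is rescaled by its maximum absolute value (with a warning in
interactive use). The conventional comparisons — Frobenius SSE and the
Pearson correlation over strict lower triangles — are reported alongside.
The Pearson measure excludes the diagonal deliberately: correlation matrices
carry a trivially matched unit diagonal that would inflate $r$.

## Selecting the maximum path length

`scan_path_lengths()` fits $K = 1, \dots, K_{\max}$ and records
$\mathrm{SSE}_\beta$, Frobenius SSE and Pearson $r$ per $K$.
$\mathrm{SSE}_\beta$ typically descends steeply until the true path depth is
reached and then flattens; `select_elbow()` automates the visual rule by
returning the smallest $K$ whose *next* step improves the curve by less than
`rel_tol` (default 5%) in relative terms. A flat curve yields the first
index; a curve that never flattens yields the last index flagged
`converged = FALSE`. The full curve is always returned so users can override
the automatic choice.

## Null models

Two randomizations probe whether an observed structure–function mapping is
attributable to the specific wiring:

* **Degree-preserving rewiring** (`rewire_degree_preserving()`): repeated
  double-edge swaps — $(a,b), (c,d) \to (a,d), (c,b)$ with four distinct
  endpoints, rejecting self-loops and duplicate edges — leave every node's
  degree exactly intact. The default of 10 accepted swaps per edge is this
  package's convention (the procedure itself has no canonical count), with
  an attempt budget of $100\times$ the target before returning a flagged
  partial result; a triangle graph, which admits no valid swap, exercises
  that path. Connectedness is not enforced; the report flags disconnection.
* **Gaussian rank resampling** (`resample_matrix()`): fiber-strength
  distributions are heavy-tailed, spanning orders of magnitude. Replacing
  the sorted weights with sorted draws from $\mathcal N(0.5, 0.1)$
  compresses the dynamic range while preserving the full weak ordering.
  Draws are not clipped: at these parameters values outside $[0,1]$ are
  vanishingly rare, and clipping would distort the target moments.

## What the synthetic generators emulate — and what they do not

`generate_modular_sc()` produces planted-partition binary graphs: community
structure is the dominant mesoscale feature of tractography connectomes and
is what the mapping and null models respond to. It does not reproduce
spatial embedding, hemispheric symmetry, distance-dependent wiring cost, or
weighted streamline counts. `forward_model()` generates functional matrices
from the polynomial model itself plus symmetric Gaussian noise (drawn on the
unique entries and mirrored, so symmetry is exact) — by construction the
model is well specified on these data, so recovery tests certify the
estimator, not the biological adequacy of the polynomial form.
`generate_correlation_matrix()` mixes latent signals into channels and
correlates them, yielding genuine positive-semidefinite correlation matrices
for barcode tests, but with none of the temporal autocorrelation or
anti-correlated network structure of real BOLD. Passing tests therefore
demonstrate correctness of the machinery under the stated generative
assumptions; they do not validate the polynomial model on empirical
connectomes.

Default study conditions used across the test suite: $N = 66$ nodes (a
common low-resolution cortical parcellation size), four modules with
within/between connection probabilities $0.6 / 0.05$, true coefficients
$(-0.3, 0.05, 0.01, 0.0005)$ — direct path dominant, higher orders smaller,
negative self-coupling — global input $0.01$, and noise at 1% of the signal
standard deviation. Replicated simulations (coverage, null-model
discrimination, elbow recovery) use 100 replicates with 200-replicate
bootstraps; these sizes give stable rates while keeping the suite quick to
run.

## Worked example

```{r example}
s <- generate_modular_sc(66, 4, 0.6, 0.05, seed = 101)
f <- forward_model(s, c(-0.3, 0.05, 0.01, 0.0005),
                   global_input = 0.01, noise_sd = 0.02, seed = 102)

scan <- scan_path_lengths(s, f, k_max = 5, mu = "gcv")
scan
k_selected(scan)

fit <- fit_mapping(s, f, k_max = k_selected(scan), mu = "gcv",
                   n_boot = 200, seed = 103, warn_spectral = FALSE)
tidy(fit)
glance(fit)
```

```{r plots, fig.width = 6, fig.height = 3}
autoplot(scan)
autoplot(betti0_barcode(dissimilarity_from_connectivity(f, quiet = TRUE)))
```

## Numerical choices and degenerate inputs

* Symmetry on construction: asymmetries up to $10^{-9}$ (absolute) are
  averaged out; anything larger is an error naming the worst entry pair.
  The tolerance accommodates text-file rounding without masking genuine
  asymmetry.
* An all-zero matrix power gets scale factor 1 by convention, leaving the
  normalized power all-zero rather than dividing by zero.
* `binarize()` forces the diagonal to zero: self-connections are not
  anatomical edges, and the $c_0 I$ term already models diagonals.
* Barcode breakpoints are stored distinct; tied merge heights collapse into
  one breakpoint whose component count drops by the number of tied merges.
* Rank resampling breaks weight ties by stable original order, so the map
  from input to output positions is deterministic.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state afterwards; the CLI derives all submodule seeds from
  one `--seed`.

## Known limitations

* The polynomial acts on a single subject-averaged pair $(S, F)$; no
  subject-level or hierarchical modeling.
* Only $\beta_0$ homology is computed — no loops ($\beta_1$) or voids
  ($\beta_2$), no persistence diagrams or landscapes.
* The penalty is $\ell_2$ only; sparse ($\ell_1$) variants and the inverse
  mapping $F \to S$ are out of scope.
* Rewiring operates on binary graphs; weighted-graph rewiring is not
  provided.

## Package shape

Core containers are lightweight matrix-based S3 classes — connectivity data
are square symmetric matrices, not tidy tables — while every naturally
tabular result is a tibble: `scan_path_lengths()` returns one, fitted
models expose `tidy()`/`glance()` methods, and `autoplot()` methods cover
barcodes and diagnostic curves.
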