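---
title: "Methods: evidence maps, bibliometric networks and altmetrics for meta-analytic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence maps, bibliometric networks and altmetrics for meta-analytic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

A meta-analytic evidence base carries two kinds of information. The
quantitative side — effect sizes and their sampling variances — is what the
meta-analytic model consumes. The qualitative side — study characteristics
(moderators), bibliographic metadata (authors, countries, cited references),
and alternative impact metrics — is usually reported in prose, if at all.
`evimap` turns that qualitative side into computed summaries and
publication-style figures: evidence-gap-map grids with pooled effects per
cell, alluvial moderator flows, phylogenetically annotated per-species
forests, co-authorship and country bibliographic-coupling networks, and
altmetric orchard plots. The statistical machinery underneath (effect-size
computation and pooling) is deliberately small and fully specified here.

# Effect sizes and pooling

## Hedges' g

When a study reports two-group summaries $(m_1, s_1, n_1)$ and
$(m_2, s_2, n_2)$, the standardized mean difference is

$$s_p = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}, \qquad
  d = \frac{m_1 - m_2}{s_p}, \qquad
  g = J\,d, \quad J = 1 - \frac{3}{4\,\mathrm{df} - 1},$$

with $\mathrm{df} = n_1+n_2-2$, and sampling variance

$$v_g = J^2\left(\frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2\,\mathrm{df}}\right).$$

$J$ is the usual linear approximation of the exact gamma-function
correction; the two differ by less than 0.1% for $\mathrm{df} \ge 10$, and
the linear form keeps every quantity closed-form and hand-checkable.
Identical constant groups ($s_p = 0$) are a degenerate input and an error,
not a zero.

## Sampling variance–covariance under an assumed correlation

Effects that share a study typically share design elements — most commonly a
control arm — so their sampling errors are correlated. The exact correlation
is rarely recoverable from reports, so the toolkit follows the common
convention of a single assumed within-cluster sampling correlation $\rho$:

$$\mathrm{Cov}(y_i, y_j) = \rho \sqrt{v_i v_j} \quad \text{(same cluster)},
  \qquad 0 \text{ otherwise.}$$

The default $\rho = 0.5$ is a guesstimate in the literature's sense — it
should be overridden when ancillary data inform it, and every pooling
function takes it as an argument. $\rho$ must lie in $[0, 1)$; at
$\rho = 1$ the matrix is singular for tied variances.

## Fixed-effect GLS pooling

With the full matrix $V$, the pooled mean is generalized least squares with
an intercept-only design:

$$\hat\mu = \frac{\mathbf{1}^\top V^{-1} y}{\mathbf{1}^\top V^{-1}\mathbf{1}},
  \qquad \mathrm{se}^2 = \frac{1}{\mathbf{1}^\top V^{-1}\mathbf{1}},$$

with a Wald 95% CI using $z_{0.975} = 1.959964$. With diagonal $V$ this is
the classic inverse-variance weighted mean. A useful exact identity used in
the tests: $n$ effects with common variance $v$ in one cluster at
correlation $\rho$ give $\mathrm{se}^2 = v\,(1 + (n-1)\rho)/n$, which is
also why the standard error is non-decreasing in $\rho$.

## Random effects (DerSimonian–Laird)

The conventional random-effects option uses the method-of-moments
between-study variance
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$
with $w = 1/v$, followed by inverse-variance weighting at $1/(v+\hat\tau^2)$.
DL was chosen over REML because it is closed-form, deterministic, and
directly testable against hand computation; REML is out of scope.

## Cluster-robust (sandwich) variance

The point estimate is the GLS mean; the variance tolerates unmodeled
dependence within clusters (studies, research groups):

$$\widehat{\mathrm{se}}^2 = \frac{m}{m-1}\,
  \frac{\sum_c \big(\sum_{i \in c} w_i e_i\big)^2}{(\sum_i w_i)^2},$$

with $w_i$ the row sums of $V^{-1}$, $e_i = y_i - \hat\mu$, $m$ clusters,
and a $t_{m-1}$ reference distribution. This is a CR1-type estimator — the
small-sample factor $m/(m-1)$ with $t(m-1)$ degrees of freedom — chosen as
the simplest member of the robust-variance-estimation family; CR2 with
Satterthwaite degrees of freedom is a documented non-goal. For an
intercept-only model with $V$ block-diagonal by cluster this coincides with
the standard sandwich formula, which the tests verify against metafor's
cluster-robust machinery. When every residual is zero the standard error is
exactly zero; the result is flagged `degenerate` rather than silently
reported.

Critical values: $z$ for fixed and random pooling, $t_{m-1}$ for the robust
estimator. These are the dominant conventions for each estimator; the
per-species CIs in the phylogenetic forest use $z$, consistent with the
fixed-GLS pooling they come from.

## Leave-one-cluster-out

To quantify the influence of a dominant research group, each cluster is
held out in turn and both the complement and the cluster alone are pooled
with the configured method. With two clusters, each row's complement equals
the other cluster's own estimate — an identity the tests assert.

# Evidence maps

`cross_tabulate()` counts distinct studies and effect rows at every
intersection of two moderators, *including* schema-declared empty cells —
the gaps are the point of an evidence-gap map. A study contributing effects
to several cells is counted in each cell's `n_studies`; consequently cell
study counts sum to at least the number of distinct studies, with equality
when each study occupies one cell. Missing moderator values are retained as
an explicit `"Unknown"` level so that maps and alluvial diagrams display
missingness instead of silently dropping rows.

`pool_cells()` pools each non-empty cell with fixed GLS on a
study-clustered VCV, upgrading to the cluster-robust variance when the cell
spans at least two studies; single-effect cells pass through their own
effect and $\sqrt{v}$. A failing cell is reported with `NA`s and a warning,
never fatally. Cell ordering follows the moderator schema (first-appearance
or user-declared), not alphabetical order, so outputs diff cleanly. When a
third moderator is mapped to shape, a cell mixing labels reports the modal
label plus a `mixed` flag, since a single glyph cannot show a mixture.

`alluvial_flows()` counts effects per unique tuple of moderator labels; the
per-axis marginals are equal by construction and asserted per axis.

# Phylogenetic annotation

Trees enter as Newick (any input branch lengths are ignored). The basal
node of the string is taken as the root, so a basal polytomy is a rooted
star rather than an "unrooted" tree. Grafen's method assigns each node the
raw height

$$h(u) = \left(\frac{\text{tips}(u) - 1}{N - 1}\right)^{p},$$

with tips at 0 and the root at 1; branch length is parent height minus
child height. The default power $p = 1$ matches standard practice; $p$
rescales depth without changing topology-induced structure. Under Brownian
trait evolution the covariance of two tips is the root-to-MRCA depth, so
after Grafen scaling the correlation matrix has unit diagonal, entries in
$[0,1]$, and is positive semidefinite — all asserted on random topologies.
Note that the *normalized* heights rescale when tips are added or removed
(the denominator changes), so a pruned tree's correlation matrix is not a
principal submatrix of the full one; the submatrix identity holds on the
unnormalized heights and only for tips whose removal leaves the remaining
MRCAs' tip counts unchanged.

`species_means()` pools each species' effects with fixed GLS on a
within-species VCV at the assumed $\rho$, ordered to match tree tip order
for forest display; species present in only one of data/tree are reported,
not dropped silently.

# Bibliometric networks

Co-authorship is the textbook incidence-product construction: with the
binary Author × Paper matrix $M$, the weight matrix is the off-diagonal of
$M^\top M$ — the number of papers each pair of authors shares — and the
diagonal (papers per author) becomes a node attribute. Bibliographic
coupling is the same construction on Paper × Cited-reference: the
off-diagonal of $CC^\top$ counts shared references. Country-level coupling
sums paper couplings over country pairs; a multi-country paper contributes
to every listed country by default (a `"first"` flag restricts to the first
affiliation), and within-country coupling is kept as a node attribute
rather than a self-loop. Edge weights stay integers end-to-end; any scaling
is the renderer's concern.

Author identity is the normalized name string (lower-cased, accents
stripped, `"Surname, Initials"` collapsed to `"surname initials"`). This
matches common bibliometric practice and is a documented limitation: two
people with the same collapsed name merge, and the same person under
different spellings splits. No ORCID disambiguation is attempted.
Reference keys are compared as exact normalized strings; fuzzy citation
matching is out of scope.

Clustering defaults to connected components — deterministic, and exactly
what "research groups that never share an author" means. Louvain modularity
communities are available behind a recorded seed for networks whose giant
component hides substructure. Cluster ids are assigned by decreasing size
with ties broken by the smallest member label, so partitions are invariant
to node relabeling.

# Altmetrics

The metric client is offline-first: a fixture table (CSV: `doi, score,
policy_citations, patent_citations`) or a per-DOI JSON cache resolves every
request, and the offline path never touches the network. The live client
targets the public Altmetric details endpoint keyed by DOI with caching and
a rate limit, and is intentionally the only code path the test suite does
not exercise. A DOI unknown to the source yields a zero record flagged
`not_found` rather than a missing row. Joins to the evidence base are
study-level left joins on the lower-cased DOI: one output row per study
regardless of match rate, with unmatched studies counted in a message.

The orchard plot pools each moderator group (robust variance when the group
spans two or more studies) and sizes each effect's bubble by the chosen
metric of its study — the attention score, policy citations, patent
citations, or their sum, since reports differ in which they emphasize.
Bubbles above a configurable cap are flagged as overflow and rendered grey,
keeping one extreme score from flattening the size scale.

# Synthetic evidence bases

The generator exists so every pipeline is testable offline with known
truth. Defaults describe a mid-sized evidence base: 30 studies, 1–3 effects
each, true mean 0.5 on the standardized-mean-difference scale, no
between-study heterogeneity ($\tau^2 = 0$), per-arm sizes 20–40, two
crossed study-level moderators, three disjoint research groups of 4–8
authors, and log-normal attention scores with Poisson policy/patent counts.

Three design choices deserve explanation:

* **Raw outcomes, not effect sizes.** Group summary statistics are drawn
  from their exact sampling distributions (means normal, variances scaled
  $\chi^2$), so `hedges_g()` is exercised end-to-end and recovers the true
  study effect in expectation.
* **A shared control arm induces the correlation.** All effects of a
  multi-effect study compare separate treatment arms against the study's
  single control arm. The within-study sampling correlation therefore
  arises mechanistically — approximately $n_2/(n_1+n_2)$, about 0.5 at
  equal arm sizes — instead of being injected as ad-hoc correlated noise.
  This is the structure the pooling default $\rho = 0.5$ assumes.
* **Clusters are recoverable by construction.** Every paper draws all its
  authors from exactly one research group, with a group hub on every paper
  and remaining members rotated in, so the true co-authorship components
  equal the declared groups for every seed — giving clustering a sharp
  ground truth.

One master seed drives a named pseudo-random substream per generator
(effects, species signal, tree, bibliography, altmetrics), so adding a
generator never perturbs existing fixtures.

What the generator does **not** emulate: publication bias, realistic
citation-graph topology, author-name ambiguity, reporting errors, or
moderators that vary within study. Passing tests therefore demonstrate
correctness of the computations, not robustness to those real-data
pathologies.

## Calibration checks and problem sizes

The packaged checks use problem sizes chosen to make Monte Carlo error
small while keeping a default test run fast: 1,000 random instances for the
GLS-versus-direct-inversion comparison (tolerance $10^{-10}$ relative);
1,000 seeded replicates of 30 independent single-effect studies for Wald
coverage at $\tau^2 = 0$, $\mu = 0.5$ — the independence condition under
which nominal 95% coverage is the theoretical claim, accepted within
[93%, 97%]; 200 random bibliographies (up to 30 papers) for exact
integer equality of network weights against brute-force set intersections;
100 random topologies for positive semidefiniteness (minimum eigenvalue
$\ge -10^{-10}$); and 100 seeds for exact recovery of three generated
author clusters.

# Numerical notes

* $V$ is inverted via Cholesky; a failure is reported as
  non-positive-definiteness with the advice to reduce $\rho$.
* Tie-breaks are deterministic everywhere: schema order for grid cells and
  strata, descending count then label order for flows and chord edges,
  cluster size then smallest member for cluster ids.
* Renderers compute nothing: every number in a figure's JSON sidecar is
  taken verbatim from the input tables, and sidecars — not pixels — are
  the testing surface, since font and rasterizer output is not
  deterministic across systems.
* Degenerate inputs are explicit: zero pooled SD errors, a single cluster
  refuses the robust estimator with the violated assumption named, an
  all-zero-residual robust fit is flagged rather than hidden.

# Known limitations

Author disambiguation by normalized string only; country lists must be
explicit (no affiliation-string parsing); the Grafen/Brownian matrix is
displayed and exported but not yet used as a random-effect structure in a
phylogenetic meta-analytic model; no meta-regression, network
meta-analysis, or publication-bias machinery — the toolkit enriches, and
deliberately does not replace, the meta-analysis itself.
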