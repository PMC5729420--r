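---
title: "Modeling regulatory network state transitions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling regulatory network state transitions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monster)
```

## The problem

Case-control expression studies are often summarized as two co-expression or
regulatory networks, one per phenotype, which are then compared edge by edge.
Individual edge weights, however, are estimated with so much noise that
edge-difference rankings rarely replicate between independent cohorts of the
same disease.  This package takes a different view: it models the *transition*
between the two phenotype-specific networks as a linear map on transcription
factors (TFs), and asks which TFs must re-target their genes to turn the
baseline network into the disease network.  That TF-level summary aggregates
over thousands of noisy edges and is correspondingly more stable.

The pipeline has three stages.

### 1. Phenotype-specific bipartite network inference

For each phenotype separately we estimate a bipartite network from the $m$
TFs to the $p$ genes, anchored on a binary motif prior $M \in \{0,1\}^{p
\times m}$ ($M_{ij} = 1$ when TF $i$ has a sequence motif near gene $j$).
Two complementary sources of evidence are computed for every (gene $j$, TF
$i$) pair, motif or not:

* **Direct evidence** $\hat d_{ij}$: the squared partial correlation between
  the TF's encoding-gene expression $g_i$ and the target's expression $g_j$,
  conditioning on the expression of the gene's *other* motif-predicted
  regulators,
  $\hat d_{ij} = \mathrm{cor}\!\left(g_i,\, g_j \mid \{g_k : k \ne i,\,
  k \in \mathbf{TF}_j\}\right)^2 .$
  With an empty conditioning set this is the plain squared Pearson
  correlation.  Conditioning removes the shared variation contributed by
  co-regulators, so $\hat d_{ij}$ reads as the $R^2$ uniquely attributable to
  TF $i$.
* **Indirect evidence** $\hat\theta_{ij}$: one logistic regression per TF,
  with the motif indicator column $M_{\cdot i}$ as the response over the $p$
  genes and each gene's expression profile across the $N$ samples of the
  phenotype as the predictors.  The fitted probability that gene $j$ looks
  like a motif target of TF $i$ is the evidence.  This borrows the central
  premise that co-targeted genes co-express: a gene whose profile resembles
  the known targets is plausibly a target itself even if its individual
  correlation with the TF is weak.

The two scores live on different scales (an $R^2$ versus a probability), so
they are combined non-parametrically.  Within each TF column the $p$ genes
are ranked (ascending, average ties) on each evidence type, ranks are divided
by $p$, and the edge weight is the convex combination

$$w_{ij} = (1-\alpha)\,\mathrm{rank}_p(\hat d_{ij}) +
           \alpha\,\mathrm{rank}_p(\hat\theta_{ij}),$$

with $\alpha = 0.5$ by default, i.e. equal contribution.  Because only ranks
enter, any strictly increasing per-column transform of either evidence
matrix leaves the network unchanged, and all weights lie in $(0, 1]$.

### 2. The transition matrix

Given the initial-state network $A$ and the final-state network $B$ (both
$p \times m$), the transition model is $B = A\,T + E$ with $T$ an $m \times m$
matrix and $E$ the residual.  Column $i$ of $T$ expresses TF $i$'s
final-state targeting as a linear combination of all initial-state targeting
columns.  The fit regresses the *change* per TF,

$$\mathbb{E}[\,b_i - a_i\,] = \tau_{1i}\,a_1 + \dots + \tau_{mi}\,a_m,$$

whose least-squares solution per column is the normal-equations estimand
$\hat\tau_i = (A^\top A)^{-1} A^\top (b_i - a_i)$; the reported transition is
$T_{\mathrm{full}} = T_{\mathrm{diff}} + I$.  When $A$ has full column rank
this equals the direct regression of $b_i$ on $A$ exactly (the projection of
$a_i$ onto the column space of $A$ has coefficient vector $e_i$);
`equivalence_check()` audits that identity numerically.  Two identical
states therefore give $T_{\mathrm{full}} = I$, and rewiring shows up as
off-diagonal mass.

The regression has no intercept — the model is a homogeneous linear map.
Optional penalties extend the estimand: `method = "ridge"` adds
$\lambda\lVert\tau\rVert_2^2$ and `method = "lasso"` adds
$\lambda\lVert\tau\rVert_1$, the latter yielding exactly sparse transitions
for large $\lambda$.  A sparse transition is appropriate when few TFs are
expected to re-target; for complex phenotypes the unpenalized default is the
better-matched assumption, and no penalty-selection procedure is built in —
$\lambda$ is a required user input when a penalty is requested.

### 3. Differential TF involvement and its null

The per-TF statistic is the off-diagonal share of each column's sum of
squares,

$$\mathrm{dTFI}_j = \frac{\sum_{i \ne j} \hat\tau_{ij}^2}
                         {\sum_{i} \hat\tau_{ij}^2} \in [0, 1],$$

zero for a TF that keeps its targets and one for a TF whose column mass sits
entirely off the diagonal.  Significance is calibrated by permuting the
sample-to-phenotype labels (preserving the two group sizes) and rerunning
the *entire* pipeline — both network inferences, the transition fit and dTFI
— for each of `n_perm = 400` permutations by default, so the null carries
the full variability of network inference.  Each TF's observed dTFI is
converted to $z_j = (\mathrm{dTFI}_j - \bar q_j)/s_j$ using the permutation
mean $\bar q_j$ and sample SD $s_j$, then to a one-sided upper-tail normal
p-value $1 - \Phi(z_j)$, with Benjamini–Hochberg FDR across the $m$ TFs.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | weight of indirect evidence in the rank combination; 0 = partial correlation only, 1 = logistic evidence only |
| `method` | `"ols"` | transition solver; `"ridge"`/`"lasso"` add an L2/L1 penalty |
| `penalty` | 0 | $\lambda$, on the scale of the summed squared error (unitless weights) |
| `n_permutations` | 400 | label permutations behind the dTFI null |
| `seed` | 1 | master seed; every permutation uses a child seed derived from it |
| `workers` | 1 | forked workers over permutations; never changes any number |

## Numerical and design choices

Several points are underdetermined by the estimands themselves; the package
resolves them as follows.

* **Partial-correlation solver.**  Both vectors are residualized on an
  intercept plus the conditioning block.  After centering, the residual
  cross-moments are computed from cross-product matrices with a symmetric
  eigendecomposition standing in for the inverse, which equals the
  minimum-norm least-squares residualization whenever the block is
  rank-deficient or wider than $n - 2$ (a warning counts affected genes).
  Projection residuals are identical for every least-squares solution, so
  the choice is about defined behavior, not about the value.
* **Zero-variance residuals.**  A residual whose variance falls below
  $10^{-12}$ of the centered original is numerically zero; the evidence
  entry becomes 0 (no evidence), never `NaN`, keeping the downstream
  logistic design finite.
* **Logistic stabilization.**  The per-TF logistic regressions can be
  perfectly separated when $N$ approaches $p$.  Predictors are standardized
  internally and a fixed quadratic penalty of $10^{-6}$ on the non-intercept
  coefficients keeps the optimum finite; fitting is Newton/IRLS with step
  halving, converged at $10^{-10}$ on the coefficient scale.  The intercept
  is unpenalized, so fitted columns reproduce the motif prevalence exactly.
  An all-0 or all-1 motif column short-circuits to its mean with a warning.
* **Rank dialect.**  Ascending ranks (more evidence, larger rank), average
  ties, normalized by $p$, per TF column — making $\alpha$ interpolation
  scale-free and weights bounded in $(0,1]$.  Ranking per column rather than
  globally reflects that each TF's target list is ranked on its own.
* **Self-edges and missing motifs.**  A TF's encoding gene may appear among
  its own potential targets, and evidence is emitted for all pairs whether
  or not a motif exists; the prior shapes the conditioning sets and the
  logistic responses, not the output support.
* **Transition solver.**  QR factorizations (augmented QR for ridge), never
  an explicit inverse; singular $A^\top A$ falls back to the minimum-norm
  SVD solution with a prominent warning instead of failing.  The lasso is a
  cyclic coordinate descent on $\lVert y - A\tau\rVert_2^2 +
  \lambda\lVert\tau\rVert_1$ without re-standardization, matching the
  written objective exactly (the test suite cross-checks it against an
  independent solver of the same objective).
* **dTFI on `T_full`.**  The statistic is computed on the identity-anchored
  matrix, so identical states give dTFI $= 0$ rather than $0/0$; a column
  with zero sum of squares returns 0 with a warning.
* **p-values from the permutation moments.**  The z-score uses the
  permutation mean — not an assumed null mean of zero — and the $n-1$ SD.  A
  normal tail was chosen over the empirical permutation rank because the
  empirical tail of a few hundred permutations is too coarse below
  $p \approx 10^{-3}$, which is where the interesting FDR statements live.
  The trade-off is honesty about the other end: dTFI is bounded below, its
  null distribution is right-skewed, and a normal tail on a right-skewed
  null is mildly anti-conservative at moderate thresholds such as 0.05 (the
  calibration check in the validation suite measures the fraction of null
  p-values below 0.05 and shows the excess).  Treat p-values near 0.05 as
  indicative; the permutation-mean centering and FDR adjustment carry the
  ranking, and strong drivers sit many SDs out.  The test is one-sided
  upper-tail: only an excess of dTFI is evidence of rewiring.
* **Group direction.**  The first label encountered in the phenotype file is
  the initial state; a config/CLI flag overrides it.  Reversing direction
  changes the transition (the map is not symmetric), which is intended.
* **Determinism.**  Inference contains no randomness.  Permutation $k$ draws
  its own child seed from the master seed, so serial and forked execution,
  in any order, give bit-identical results.
* **Missing data.**  Genes with any missing expression value are dropped
  with a logged count at read time; imputation is out of scope because the
  model assumes complete matrices.
* **Identifier matching** is exact-string; symbol aliasing is data
  preparation, not method.  Harmonization keeps every expression gene
  (all-zero motif rows for genes absent from the prior), drops prior TFs
  without an expression row, and orders genes and TFs byte-wise so results
  are platform-independent.

## The synthetic generator, and what passing tests mean

`simulate_regulatory_data()` draws a linear regulatory model: TF expression
is i.i.d. standard normal, each non-TF gene gets `targets_per_gene` random
regulators and expression `effect_size * sum(regulators) + N(0, noise_sd)`,
and between states `n_drivers` disjoint TF pairs either swap their entire
target columns or transfer half of one column to the other.  The motif prior
handed to the pipeline describes the *initial* state only — the rewiring is
visible only through expression, as in real use where one motif map serves
both phenotypes.  Defaults (`p = 200`, `m = 10`, 30 + 30 samples,
`effect_size/noise_sd = 2`, one swapped pair) describe a moderately sized
cohort with a clear but noisy signal.

The generator is deliberately minimal: regulation is linear and additive,
noise is homoscedastic Gaussian, TF activity equals TF mRNA, and there are
no batch effects, heavy tails, count-type mean–variance coupling, or hidden
confounders.  Recovery of the planted drivers under this model shows the
estimators and the permutation calibration are correct; it does not show
robustness to the biological and technical pathologies of real cohorts.

The validation suite runs at these sizes: exact-algebra and oracle checks on
50 seeded instances each; end-to-end driver recovery on 20 replicates of the
default generator with 100 permutations per replicate; and null calibration
on 20 driver-free replicates, pooling 200 p-values against the exact
binomial band around 0.05.  One hundred permutations is the package's
routine validation depth; published analyses should keep the 400 default.

## Known limitations

* The transition model is linear; genuinely combinatorial rewiring (a TF
  pair acting only jointly) appears only through its linear shadow.
* dTFI is a *column* summary: a TF whose targets are taken over by others
  (row involvement) is flagged only through the affected columns.
* The permutation null is built from the observed samples, so under a strong
  alternative the label-shuffled groups still mix the two regulatory
  programs: the null mean and SD are inflated by the very signal being
  tested, which costs z-score power for moderately rewired TFs (their dTFI
  rank is unaffected).  Conversely, the right-skew of the null makes normal
  p-values near 0.05 slightly optimistic (see above).  Both are properties
  of the SE-based permutation test itself, not of its implementation.
* The permutation null reruns the full pipeline and therefore costs
  `n_perm` times the base inference; for genome-scale inputs use forked
  `workers`.
* With $p < m$ or duplicated TF columns the transition is underdetermined;
  the minimum-norm answer is returned with warnings, and dTFI should then be
  read qualitatively.
* The method was described on continuous (microarray-scale) expression;
  counts should be transformed to a roughly homoscedastic scale first (e.g.
  log-CPM), which is the user's responsibility.
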