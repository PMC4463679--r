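---
title: "Predicting protein-protein interactions with reduced alphabets and weighted sparse representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions with reduced alphabets and weighted sparse representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsrcppi)
```

## The problem

Experimental screens for protein-protein interactions (PPIs) are slow and
noisy, so sequence-based computational predictors are used to triage
candidate pairs. `wsrcppi` implements one such predictor: protein pairs are
encoded by n-peptide composition over a *reduced amino acid alphabet*
(RAAA), and classified with a *weighted sparse representation classifier*
(WSRC). The package provides the full pipeline — FASTA and pair-list input,
feature extraction, the classifier, an evaluation harness (ACC/SN/PE/MCC,
ROC/AUC, stratified k-fold cross-validation), a synthetic benchmark
generator, and a command-line front end.

## Reduced amino acid alphabets

Counting all length-n windows of a protein over the 20-letter alphabet
costs $20^n$ features, which for $n = 3$ (8000 features) invites
overfitting on data sets of a few thousand pairs. The RAAA idea is to
first partition the 20 residues into $k$ physico-chemically coherent
groups and rewrite the sequence over group symbols, so that an n-peptide
vector has only $k^n$ cells. The package ships the five cluster profiles
derived from the protein blocks structural alphabet:

```{r}
raaa_profiles()
```

`CP(k)` means "$k$ groups"; e.g. under `CP(5)`, I and V (both in group 2)
are counted together:

```{r}
reduce_sequence("GIV", raaa_profile("CP(5)"))
npeptide_composition("GIV", raaa_profile("CP(5)"), n = 1)
```

The per-protein feature dimension is $k^n$ (so 512 for `CP(8)` with
$n = 3$), and a pair is encoded by ordered concatenation of the two
protein vectors, giving $2k^n$ features. Concatenation is the dominant
convention in sequence-based PPI work; the symmetrised alternative
$[a+b;\,|a-b|]$ is available via `combine = "symmetric"` for users who
want order-invariant pairs, but concatenation is the default. Counts are
normalised by the number of windows $L - n + 1$, so each composition
vector sums to exactly 1 — the standard k-mer frequency definition.

Cells are ordered row-major over group indices (the window
$(g_1, \dots, g_n)$ sits at $\sum_j (g_j - 1)k^{n-j} + 1$); the ordering
is arbitrary but fixed, and classifier behaviour does not depend on it.
Group indices are 1-based throughout, matching R indexing and the "first
group" phrasing conventional in the field.

**Ambiguity codes.** Real FASTA files contain B, Z, X, U, O and J. The
default policy drops them before reduction (they are rare, and dropping
perturbs the composition minimally while keeping real files usable); an
`"error"` policy is available for strict pipelines. Any other unexpected
character is always an error. Input is uppercased first.

**Length filter.** `filter_short()` implements the conventional
pre-filter: sequences of *fewer than* 50 residues are removed, so length
exactly 50 is kept; pairs touching a removed protein are dropped with
`drop_pairs_of()`.

## The classifier

Let $X \in \mathbb{R}^{d \times n}$ hold the training pairs as columns,
normalised to unit $\ell_2$ norm, with class labels $1..K$. A query $y$ is
sparse-coded by basis pursuit denoising (BPDN),

$$\hat\alpha = \arg\min \|\alpha\|_1
  \quad \text{s.t.} \quad \|y - X'\alpha\|_2 \le \epsilon,$$

and assigned the class $k$ minimising the class-restricted residual
$g_k(y) = \|y - X'\delta_k(\hat\alpha)\|_2$, where $\delta_k$ zeroes all
coefficients outside class $k$. Ties are broken towards the lowest class
index (deterministic and documented). In the weighted variant (WSRC),
$X'$ is the dictionary with column $j$ scaled by its Gaussian similarity
to the query,

$$w_j = \exp\!\left(-\|x_j - y\|^2 / 2\sigma^2\right) \in (0, 1],$$

so distant training samples become expensive to use and the code
concentrates on the query's neighbourhood — this is what rescues sparse
coding in the low-dimensional feature spaces that reduced alphabets
produce. With all weights equal to 1 (or $\sigma \to \infty$) WSRC reduces
exactly to plain SRC, a property the test suite checks.

Two points where the formulation is genuinely ambiguous, and the choices
made:

* **Weighted dictionary in the residuals.** The weighted matrix $X'$ is
  used consistently in both the coding program and the residuals
  $g_k$. Using the unweighted $X$ in either place would make the weights
  inert, defeating the purpose of the weighting.
* **Distances for the weights** are computed against the unit-normalised
  dictionary columns (the matrix the solver actually sees), and the query
  itself is never rescaled — composition features are already bounded.

### Tunable parameters

| parameter  | meaning                               | default | notes |
|-----------|----------------------------------------|---------|-------|
| `sigma`   | Gaussian kernel width (feature units)  | 50      | the method's standard operating point; predictions are insensitive over a wide range because composition distances are $\ll \sigma$ |
| `epsilon` | BPDN residual tolerance (feature units)| 0.05    | standard operating point; larger values code more loosely and can blur class residuals |
| `weighted`| WSRC (`TRUE`) vs SRC (`FALSE`)         | `TRUE`  | |
| `k` folds | cross-validation folds                 | 5       | |

If every weight underflows to zero (a query astronomically far from the
training set at a tiny `sigma`), the classifier falls back to unweighted
coding for that query and warns, rather than coding against an all-zero
dictionary.

### Numerical realisation of the solver

`solve_bpdn()` solves the constrained program through its penalised
(lasso) form: the residual norm along the lasso path is monotone in the
penalty, so the path is swept one decade at a time (11 penalties per
decade, computed with `glmnet`, `thresh = 1e-14`) until the residual
crosses $\epsilon$, the bracketing interval is refined twice (30 penalties
each), and — because the lasso path is piecewise linear in the
coefficients — the solution with residual exactly $\epsilon$ is obtained
by solving a scalar quadratic for the convex combination of the two
bracketing path points. The returned solution is feasible by
construction; on batches of random instances its $\ell_1$ objective agrees
with an independent sequential-quadratic-programming solution of the
constrained program to better than $10^{-4}$ (part of the test suite).
Degenerate cases are exact: $\|y\|_2 \le \epsilon$ returns
$\alpha = 0$; a single-atom dictionary is solved in closed form. A query
further than $\epsilon$ from the dictionary's column span makes the
program infeasible; this raises a classified error
(`"wsrc_solver_error"`), never a silent zero vector.

## Evaluation harness

`classification_metrics()` reports ACC, SN (sensitivity/recall), PE
(precision) and MCC, all as percentages. A metric whose denominator is
zero (e.g. precision with no positive predictions) is reported as `NA`
with an explanatory attribute — never silently as 0, which would make
degenerate folds look meaningfully bad rather than undefined.

WSRC has no native probability, so the ROC score is the residual margin
$g_{\text{neg}} - g_{\text{pos}}$: it is monotone in decision confidence
and reproduces the argmin decision at threshold 0. ROC/AUC are computed
with `pROC` (trapezoidal AUC; tied scores handled by its threshold
sweep). `cross_validate()` uses seeded *stratified* folds — the data sets
this method targets are class-balanced, and stratification preserves that
in every fold; fold sizes differ by at most one overall and within each
class, and the assignment is a pure function of `(labels, k, seed)`.

## The synthetic benchmark

The method's published evaluations used curated interaction data sets
(DIP *S. cerevisiae*; *H. pylori*) that are not redistributable with the
package, so `simulate_ppi_pairs()` provides a controlled stand-in for
development and testing. Two residue emission distributions are built at
an exact total-variation distance $s$ ("separation"):
$D_1 = (1-s)U_{20} + sV_1$ and $D_2 = (1-s)U_{20} + sV_2$, with $V_1, V_2$
uniform over disjoint 10-residue halves. Interacting pairs draw both
proteins i.i.d. from $D_1$; non-interacting pairs draw protein A from
$D_1$ and protein B from $D_2$. At $s = 0$ the classes are statistically
identical (any classifier is at chance); at $s = 1$ the supports are
disjoint and composition separates the classes almost perfectly, with
accuracy rising monotonically in between — properties the acceptance
suite verifies. Defaults: 200 pairs per class, lengths uniform on
[50, 150] (typical desk-scale protein lengths that respect the 50-residue
filter), separation 0.8. Output is byte-reproducible for a fixed seed.

What the generator deliberately does *not* emulate: domain architecture,
motif grammar, phylogenetic correlation between proteins, shared proteins
across pairs, and class-imbalanced sampling. Passing tests on this
benchmark therefore demonstrate that the pipeline is correct and that the
classifier recovers composition-level signal at the advertised operating
point — not that it attains any particular accuracy on real interactome
data. On the published curated sets the method is reported to reach
around 91% accuracy (yeast) at its best profile; the printed best-MCC
value differs between sections of the original report (84.43 vs 83.43),
an inconsistency we record here rather than arbitrate, and neither number
is reproducible without the original curated data.

## Problem sizes used in the checks

The acceptance suite runs five-fold WSRC cross-validation at 200 pairs
per class for the recovery and chance-level checks, and at 100 pairs per
class across the four-point separation grid {0, 1/3, 2/3, 1}; the solver
oracle comparison uses 100 random instances with $d \le 10$, $n \le 8$.
These sizes give stable statistics (binomial noise on a 400-sample
accuracy is about ±2.5 percentage points at one standard deviation) while
keeping the whole suite comfortably quick on a laptop.

## Known limitations

* Prediction cost is one BPDN solve per query (a handful of lasso paths);
  scoring very large pair lists is linear in queries and benefits from
  the low-dimensional profiles — which is exactly the regime the weighted
  classifier is designed for.
* The redundancy filter at 40% sequence identity used in the original
  data curation requires an external clustering tool and is out of scope;
  apply it upstream if needed.
* Negative-pair construction from subcellular localisation annotation is
  likewise an upstream concern; the package consumes whatever labelled
  pair list it is given.
* For $K > 2$ classes the machinery works (residuals and decisions are
  per-class) but the ROC score and the pair semantics are binary.
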