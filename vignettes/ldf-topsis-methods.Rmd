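---
title: "Methods: linear Diophantine fuzzy copula aggregation and extended TOPSIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear Diophantine fuzzy copula aggregation and extended TOPSIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldftopsis)
```

## The model

A linear Diophantine fuzzy number (LDFN) is a quadruple
$L = \langle(\varphi, \psi), (\varrho, \sigma)\rangle$ with exponent
$q \ge 1$: a membership grade $\varphi$ and non-membership grade $\psi$,
weighted by reference parameters $(\varrho, \sigma)$ under the constraints

$$\varrho^q + \sigma^q \le 1, \qquad
  \varphi\,\varrho^q + \psi\,\sigma^q \le 1.$$

The reference parameters decouple the grades from the classical
intuitionistic budget $\varphi + \psi \le 1$: an expert may assert
$\varphi = 0.9$ and $\psi = 0.9$ simultaneously, provided the reference
weights are small enough. Intuitionistic, Pythagorean and q-rung orthopair
numbers are all recovered by particular reference choices, but get no
dedicated types here — they are just LDFNs. Note that the mixed constraint
is implied by the reference constraint whenever both grades lie in
$[0,1]$; the constructor nevertheless checks both and reports whichever is
violated, because user-supplied cells can fail either first.

Ranking LDFNs needs a score function. We use

$$S(L) = \tfrac12\left[(\varphi - \psi) + (\varrho^q - \sigma^q)\right]
  \in [-1, 1],$$

the convention of the LDF aggregation-operator literature, together with
an accuracy function $A(L) = \tfrac12[(\varphi + \psi) + (\varrho^q +
\sigma^q)]$ and a final lexicographic tie-break on the four components.
This makes `ldf_compare()` a *total* order, so every argmax/argmin in the
decision pipeline (ideal-solution picks, ordered aggregation) is
deterministic. The complement swaps both pairs,
$L^c = \langle(\psi, \varphi), (\sigma, \varrho)\rangle$: it is an
involution, negates the score, and preserves both constraints — properties
that simpler complements (swapping only the grades) do not all share.

## Copula operational laws

Aggregation needs a t-norm/t-conorm pair. Instead of fixing the product
norm, the package parameterizes it by an Archimedean copula: a strictly
decreasing generator $\vartheta : (0,1] \to [0,\infty)$ with
$\vartheta(1) = 0$ defines

$$C(x, y) = \vartheta^{[-1]}(\vartheta(x) + \vartheta(y)), \qquad
  C^*(x, y) = 1 - C(1-x, 1-y),$$

where $\vartheta^{[-1]}$ is the pseudo-inverse (clamped to 0 past
$\vartheta(0)$). $C$ plays the t-norm on the non-membership side, $C^*$
the t-conorm on the membership side, for grades and reference parameters
alike. Five classical families are provided (Gumbel, Clayton, Frank,
Ali–Mikhail–Haq, Joe), each with its standard parameter domain.

Two deliberate numerical choices:

* **Everything is computed from the generator composition**, never from
  per-family closed forms. The closed forms circulating in the literature
  for these families are inconsistently printed often enough that we treat
  them only as independent test oracles (evaluated directly in the test
  suite and compared against the composition path at $10^{-9}$).
* The printed Clayton generator $x^{-\lambda} - 1$ is *increasing* for
  $\lambda < 0$ and hence not a generator there; we use the standard
  scaled form $(x^{-\lambda}-1)/\lambda$ for $\lambda \in [-1, 0)$. For
  $\lambda > 0$ scaling a generator by a positive constant leaves the
  copula unchanged, so the unscaled form is kept. Similarly the Frank
  generator carries its conventional leading minus sign, and below
  $|\lambda| < 10^{-5}$ Frank is evaluated as its independence limit
  $-\ln x$ to avoid $0/0$.

Crisp components make the generator sum infinite; the pseudo-inverse clamp
then returns exactly 0, so a crisp 0 or 1 with positive weight is
*absorbing* in any aggregate — documented and tested rather than smoothed
away.

The extended operational laws follow: $L_1 \oplus L_2$ applies $C^*$ to
memberships and reference-memberships and $C$ to the other two components;
$\otimes$ is the dual; and for $\alpha > 0$,
$\alpha L = (1 - \vartheta^{-1}(\alpha\,\vartheta(1-\varphi)),\
\vartheta^{-1}(\alpha\,\vartheta(\psi)), \ldots)$, which agrees with the
$n$-fold $\oplus$-chain at integer $\alpha$ (property-tested to
$10^{-8}$). The weighted operator

$$\mathrm{LDFWCA}(L_1,\dots,L_n) = \bigoplus_i \omega_i L_i$$

telescopes to weighted generator sums, is idempotent, and reduces to the
classical LDFWA closed form under the product copula. The ordered variant
(LDFWOCA) sorts by the total order before applying position weights; the
hybrid (LDFWHCA) first rescales each value by $n\omega_i$. Both are named
but not specified in the source literature; we follow the standard
OWA/hybrid construction, under which the hybrid with uniform importance
weights collapses exactly to the ordered operator.

## Distance and entropy

The generalized distance of order $\Upsilon$ averages the four component
differences (prefactor $1/(4n)$), giving Hamming, Euclidean and Chebyshev
at $\Upsilon = 1, 2, \infty$. The weighted form is ambiguous in the
source: taken literally it keeps $1/(4n)$ *and* weights summing to one,
which double-normalizes. Both conventions are implemented; the literal
form is the default (`strict = TRUE`) and the conventional $1/4$-only
form — under which uniform weights reproduce the plain distance exactly —
is a flag. The same flag propagates to the ideal-solution distances of
phase 3.

Entropy needs a hesitancy degree $\pi$, which the source never defines.
We take $\pi = 1 - (\varphi\varrho^q + \psi\sigma^q)$, the slack of the
mixed constraint: it is the only natural candidate guaranteed to lie in
$[0,1]$ for *every* valid LDFN, and it is complement-invariant, which in
turn makes the entropy complement-invariant. The entropy of a collection
is the mean of per-element terms $\{1 - d(L, L^c)\}(1+\pi)/2$ with $d$ the
single-element Hamming distance; it vanishes exactly on crisp elements
and equals $0.75$ at the centre of the cube.

## The three-phase decision algorithm

Given a panel of $e$ expert matrices ($n$ alternatives $\times$ $m$
criteria), cost columns are complemented, then:

1. **Expert weights.** The group decision ideal solution (GDIS) is the
   cellwise LDFWCA aggregate across experts (uniform panel weights by
   default — the within-panel weighting is genuinely open, and uniform is
   the neutral choice); the right/left ideal solutions (GRIS/GLIS) pick
   the score-best/worst expert cell. Each expert's closeness index is
   $CI^k = (\Sigma DGRIS + \Sigma DGLIS) / (\Sigma DGDIS + \Sigma DGRIS +
   \Sigma DGLIS)$ over rowwise distances, and $w_k = CI^k / \Sigma CI$.
   An expert numerically indistinguishable from all three ideals (the
   single-expert and all-identical degeneracies) receives the neutral
   index $0.5$, so fully symmetric panels yield uniform weights instead
   of $0/0$.
2. **Criterion weights.** The panel is re-aggregated with the expert
   weights (RGDIS); each criterion's entropy is the *mean* per-cell
   entropy down its column, and the entropy weight method gives
   $\gamma_j = (1 - E_j)/(m - \Sigma E)$.
3. **Closeness and ranking.** Phase 3 runs *per expert*: each expert's
   matrix is column-rescaled by $\gamma_j L$ (copula scalar), the
   positive/negative ideal cells are the score extremes of each column,
   and $DIS^\pm$ are the $\gamma$-weighted distances of each alternative
   row to them. The relative closeness is $RCI = DIS^-/(DIS^+ + DIS^-)$
   — the *sum* denominator; the product variant printed in places is
   dimensionally wrong and does not reproduce the worked example's own
   tables — and the final closeness fuses experts,
   $FC(A_i) = \Sigma_k w_k RCI_k(A_i)$, ranked descending with label-order
   tie-breaks. A `collective_phase3` flag instead aggregates experts into
   one collective matrix before phase 3, the variant some descriptions of
   the algorithm state; the per-expert route is the default because it is
   the one whose worked-example arithmetic is internally consistent.
   An alternative at zero distance from both ideals gets $RCI = 0.5$ with
   a warning.

Defaults: Clayton copula ($\lambda = 1$, the family in which the
algorithm's aggregation steps are usually written), Hamming distance
($\Upsilon = 1$), reference pair $(0.5, 0.5)$ for pair-only inputs, $q =
1$ shared across a panel (mixed-$q$ arithmetic is rejected). The
$\lambda$ and $\Upsilon$ behind the published worked-example tables were
never stated, and several of those tables are internally inconsistent
(constant unexplained reference components in the aggregate table; a
right-ideal entry that is not among its candidate cells; one closeness
entry inconsistent with its own distances). We therefore do *not* attempt
to reproduce the intermediate tables; the package verifies instead the
subset of published values that follow by pure arithmetic from other
published values (`worked_example_checks()`), which reproduce exactly at
their printed rounding.

## The random panel generator

`random_panel()` draws, per cell, a reference pair uniformly from
$\{\varrho^q + \sigma^q \le 1\}$ by rejection from the unit square and
grades uniformly from $[0,1]$ (validity is then automatic), with random
benefit/cost senses, reproducibly for a fixed seed and without disturbing
the caller's RNG stream. It emulates a panel of independent, uninformative
experts: cells are exchangeable and carry no row/column structure, no
inter-expert correlation, and no agreement signal. Passing property tests
on such panels therefore establishes the algebraic invariants
(normalization, boundedness, equivariance) — not that the method ranks
*real* structured panels well, which is an empirical question outside the
scope of synthetic data.

## Problem sizes and test design

The suite checks the copula axioms on a $20 \times 20$ argument grid over
a parameter grid spanning all five families ($10^{-9}$ tolerance); the
scalar-multiplication theorem on 1000 random LDFNs per family for
$n = 2,\dots,5$ ($10^{-8}$); the product-copula reduction on 1000 random
weighted collections ($10^{-6}$, with Clayton at $\lambda = 10^{-6}$ as
the limit approximant); and pipeline integrity on the embedded panel plus
100 random panels with 2–5 alternatives, 2–5 criteria and 1–4 experts,
including relabeling equivariance. These sizes keep the whole suite
comfortably within interactive runtimes while exercising every family and
every degenerate branch (crisp absorption, zero-weight elements,
indistinguishable alternatives, single-expert panels).

## Known limitations

* Closure of the copula operations is guaranteed for $q = 1$ (the
  reference constraint is preserved by the co-copula/copula pair); for
  $q > 1$ an aggregate can in principle leave the valid region, in which
  case construction fails loudly rather than silently clamping.
* The worked example's free parameters are unrecoverable, so its final
  ranking under this package's defaults is reported, not asserted; the
  published final ranking places the probabilistic neural network first,
  while the defaults here need not.
* Only bivariate Archimedean copulas are supported; multi-argument
  aggregation always goes through the additive generator form.
* No copula parameter estimation: $\lambda$ is an input, chosen by the
  analyst.
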