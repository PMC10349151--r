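# ldftopsis

Multi-criteria **group decision analysis under linear Diophantine fuzzy
(LDF) information**: copula-parameterized aggregation operators, distance
and entropy measures, and a three-phase extended TOPSIS algorithm that
derives unknown expert and criterion weights before ranking alternatives.

The motivating application is clinical decision support — a panel of
experts scoring candidate EEG classifiers for depression screening
(k-NN, GMM, decision tree, naive Bayes, probabilistic neural network)
against entropy-feature criteria — but the machinery is generic: any
panel of fuzzy evaluations with benefit/cost criteria.

## The model

An LDF number couples grades with reference parameters,
`L = <(φ, ψ), (ϱ, σ)>`, valid when

    ϱ^q + σ^q ≤ 1   and   φ·ϱ^q + ψ·σ^q ≤ 1,

which frees the grades from the intuitionistic budget `φ + ψ ≤ 1`.
Aggregation runs through an Archimedean copula generator `ϑ`:
`C(x,y) = ϑ⁻¹(ϑ(x) + ϑ(y))` is the t-norm, its co-copula
`C*(x,y) = 1 − C(1−x, 1−y)` the t-conorm, and the weighted operator

    LDFWCA(L₁,…,Lₙ) = ( 1 − ϑ⁻¹(Σᵢ ωᵢ ϑ(1−φᵢ)),  ϑ⁻¹(Σᵢ ωᵢ ϑ(ψᵢ)), … )

aggregates a collection (references treated the same way). Five generator
families are built in — Gumbel, Clayton, Frank, Ali–Mikhail–Haq, Joe —
and the product-copula case recovers the classical LDFWA operator.

The decision algorithm (`ldf_topsis()`) then runs in three phases:
expert weights from each expert's closeness to the group
decision/right/left ideal solutions; criterion weights from column
entropies (entropy weight method); and per-expert relative closeness
`RCI = DIS⁻/(DIS⁺ + DIS⁻)` to the positive/negative ideal cells, fused
into final closeness `FC(Aᵢ) = Σₖ wₖ·RCIₖ(Aᵢ)` and a ranking.
See the methods vignette (`vignettes/ldf-topsis-methods.Rmd`) for the
design decisions and numerical choices.

## Worked example

```r
library(ldftopsis)

# an LDF value: high membership AND high non-membership is representable
x <- ldfn(0.8, 0.9, 0.3, 0.6)
x
#> LDFN vector of length 1 (q = 1)
#> [1] <(0.8, 0.9), (0.3, 0.6)>
ldf_score(x)
#> [1] -0.2

# Clayton-copula aggregation of two memberships 0.2 / 0.8, equal weights
ldfwca(from_pair(c(0.2, 0.8), c(0.5, 0.5)), c(0.5, 0.5), ldf_copula(2, 1))
#> LDFN vector of length 1 (q = 1)
#> [1] <(0.68, 0.5), (0.5, 0.5)>

# the embedded EEG classifier panel: 3 experts x 5 classifiers x 5 criteria
fit <- ldf_topsis(eeg_classifier_panel())
fit
#> Extended LDF-TOPSIS group decision
#>   3 experts, 5 alternatives, 5 criteria; copula family 2 (Clayton), lambda = 1
#> Final closeness:
#>    P1    P2    P3    P4    P5
#> 0.599 0.353 0.312 0.492 0.533
#> Ranking: P1 > P5 > P4 > P2 > P3
```

`summary(fit)` additionally prints the expert closeness indices and
weights, the criterion entropies and weights, and the per-expert relative
closeness matrix; `coef(fit)` returns the criterion weights
(`which = "experts"` or `"closeness"` for the others) and `plot(fit)`
draws the ranked closeness bar chart. The final closeness values are the
expert-weighted proximities to the ideal classifier: here the k-NN (P1)
and PNN (P5) classifiers clearly separate from the decision tree (P3).
Note the published study's ranking for this panel placed P5 first; its
copula parameter and distance order were not published, so the default
configuration need not reproduce it (the arithmetically derivable subset
of its numbers is verified instead, see below).

Panels interchange as JSON (`read_panel()` / `write_panel()`) or CSV
(`read_panel_csv()`), full traces as JSON (`write_trace()`), and
`inst/cli/ldftopsis` is a thin command-line wrapper
(`validate | topsis | aggregate | simulate | eeg-example`).

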