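---
title: "Inferring probiotic-metabolite synergies with MARS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring probiotic-metabolite synergies with MARS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synermars)
```

## The problem

Candidate probiotic strains are screened by adding combinations of them,
together with a polyphenol-rich prebiotic substrate, to a fermentation
system seeded with a complex gut microbiota, and measuring a panel of
polyphenol-derived metabolite concentrations in the supernatant. Because
strains cross-feed — one strain's fermentation products are another's
substrate — metabolite output is not a linear function of which strains
were added: combinations can produce far more (or less) of a metabolite
than the sum of their members' individual contributions. The analysis goal
is to identify, per metabolite, which strains and which combinations
predict its production, and to express each retained effect as a signed
percentage of the metabolite's level under the prebiotic alone.

## The model

For a design with $M$ probiotics, the dose vector $X \in \mathbb{R}^M$ has
$X_i$ equal to the dose of strain $i$ ($X_i = 0$: not added). Each
metabolite $Y_j$ is modeled separately as a linear combination of hinge
basis functions,

$$ f_j(X) = \sum_{k=1}^{K} C_k B_k(X), $$

where each $B_k$ is a product of at most `max_degree` hinge factors
$h(\pm(x_v - t))$, $h(x) = \max(0, x)$, with knots $t$ drawn from observed
dose values, and $B_1 \equiv 1$ is the intercept. This is multivariate
adaptive regression splines (MARS): products of hinges capture
interactions — a degree-2 basis on strains $u, v$ is nonzero only when both
are dosed (at the knots that arise on dose designs), so its coefficient is
exactly the extra production attributable to the pair beyond the main
effects, i.e. a synergy.

Fitting proceeds in two passes:

* **Forward pass.** Starting from the intercept, every admissible
  candidate — a parent basis already in the model, a variable the parent
  does not already use, and a knot from the parent-active dose values — is
  scored as a mirrored hinge pair by the residual sum of squares of the
  enlarged least-squares fit. The best pair is added (a member whose
  column is identically zero or adds no numerical rank is dropped — on
  single-dose designs this is the common case). Growth stops at
  `max_terms`, when no candidate remains, or when the relative RSS
  improvement falls below `forward_improvement_tol`.
* **Backward pass.** Terms that do not predict the metabolite are removed:
  bases are deleted one at a time — always the deletion that increases RSS
  least — down to the intercept, and the model with the lowest generalized
  cross-validation score along this sequence is returned (ties go to the
  smaller model). GCV is
  $\mathrm{GCV} = (\mathrm{RSS}/n)\,/\,(1 - C/n)^2$ with complexity charge
  $C = n_\text{terms} + d \cdot n_\text{knots}$, where $n_\text{knots}$
  counts all hinge factors across non-intercept bases and $d$ is
  `gcv_penalty`. When $C \ge n$ the score is $+\infty$, so
  over-parameterized models are never selected.

Ranking deletions by RSS rather than by GCV is a deliberate choice. The
unpruned model is often over-parameterized ($C \ge n$), where GCV is
infinite for every one-deletion neighbour except the one that removes the
highest-degree basis — the basis that sheds the most knots. A GCV-ranked
step would therefore always delete the most complex term first, which on
these designs is typically the genuine high-order synergy; RSS-ranked
deletion sheds the uninformative terms instead, and GCV still chooses the
final model along the sequence. This is also the classical formulation of
the MARS deletion step.

## Percentage normalization and the synergy report

The intercept $C_0$ equals the model's prediction at the all-zero dose
vector — the prebiotic-alone reference level (all retained hinge factors on
doses vanish there). Each retained term is evaluated at its *active* dose
vector $x_\text{active}$ (the term's strains at the maximum dose observed
for each, all others zero) and expressed as

$$ \mathrm{pct}_k = 100 \cdot C_k B_k(x_\text{active}) / C_0 . $$

Positive percentages mean the term increased production relative to the
reference; negative, decreased. Terms on the same strain subset that
differ only in knots are merged by summing their contributions, since the
report's columns are strain subsets. Metabolites whose pruned model is
intercept-only are *masked* (grey rows in a heatmap view): no tested
strain or combination predicted their production. A reference level that
is zero or negative (within `1e-8` of the coefficient scale) makes
percentages meaningless; such metabolites are reported masked with a
warning rather than failing the whole panel.

Two notes of interpretation. A masked metabolite does not prove absence of
effect — it may also mean every combination produced similar amounts. And
a negative percentage is not necessarily adverse: many panel metabolites
are precursors of further microbial products.

An alternative reference (the observed mean of the prebiotic-alone rows)
can be computed directly from the design when such rows are present
(`include_reference = TRUE` in `generate_design()`); the intercept is the
package default because it is internally consistent with the fitted model
and needs no dedicated reference rows.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_terms` | 21 | forward-pass basis budget (intercept included) |
| `max_degree` | 3 | highest interaction order (tertiary synergies) |
| `gcv_penalty` | 3 (2 if additive) | per-knot complexity charge $d$ |
| `forward_improvement_tol` | 1e-4 | relative RSS gain required to keep growing |
| `ridge_eps` | 1e-8 | ridge stabilization of the normal equations |
| `forward_criterion` | `"rss"` | candidate score; `"gcv"` available |

`ridge_eps` matters because indicator-like basis columns are routinely
duplicated or collinear on a 12-combination design; the augmented-QR ridge
solve keeps coefficients finite without changing well-posed fits.
Replicates enter as independent rows — the model has no replicate term.
Doses are in abstract units (1.0 = the inoculation dose, e.g. $10^{10}$
CFU/meal); the MARS machinery accepts arbitrary non-negative doses, but
single-dose designs are the intended regime, which is why knot candidates
are simply the observed dose values with no span refinements.

## The synthetic generator

Raw per-combination metabolite concentrations from screens of this kind
are rarely deposited at machine-readable resolution, so validation is
against a generator with known ground truth. `generate_design()` defaults to 6 strains, 12 combinations
(6 singletons, 5 pairs, 1 triple), 3 replicates — 36 rows.
`generate_panel()` draws

$$ y_{ij} = r_j \Big(1 + \sum_{T \text{ active in } i} e_T\Big)
   \cdot \varepsilon_{ij}, \qquad
   \varepsilon_{ij} = \exp\!\big(N(-\sigma^2/2,\ \sigma^2)\big), $$

where a planted subset $T$ is active iff all its strains are dosed, so
$E[\varepsilon] = 1$ and the planted percentage of effect $e_T$ is exactly
$100\,e_T$. Effects add on the fraction scale, matching the percentage
semantics of the report (a fully multiplicative variant is available).
Noise is multiplicative lognormal because concentrations are positive and
span orders of magnitude; the default $\sigma = 0.1$ is a placeholder for
the replicate-level variance of LC–MS quantification, which is rarely
reported, and is exposed in the effect specification. Baselines default to
10 µg/mL.

Two generator-level design choices deserve explanation:

* **Identifiability of the default layout.** A planted subset is
  recoverable only if its activity pattern across combinations is not
  reproduced by any subset of the same or smaller size. In particular,
  every sub-pair of a planted triple must co-occur in some combination
  *outside* the triple, otherwise a degree-2 term fits the triple's
  signature exactly and model selection rightly prefers it. The default
  pairs are chosen so the triple BL15707 × Lp126A7 × Ls126D10 satisfies
  this; `check_identifiability()` verifies the condition for any design and
  should gate exact-recovery expectations on custom layouts.
* **What the generator does not emulate.** Real panels have correlated
  metabolites (shared pathways), heteroscedastic measurement error,
  matrix effects, censoring at the quantification limit, and
  community-level dynamics (pH cycles, growth phases). Passing recovery
  tests on this generator demonstrates that the estimator correctly
  inverts its own forward model at realistic size and noise — not that
  every effect in real data would be found.

The demonstration spec (`demo_effect_spec()`) plants a +50% main effect
(BL15707 on 3-HPPA), a +200% pairwise synergy (BL15707 × Ls126D10 on
DHVL), and a +500% tertiary synergy (BL15707 × Lp126A7 × Ls126D10 on
3-HPVA) against 41 null metabolites.

```{r demo}
design <- generate_design()
spec <- demo_effect_spec(noise_sigma = 0.05)
panel <- generate_panel(design, spec, seed = 1)
report <- build_synergy_report(fit_panel(design, panel), design)
report$terms
```

## Numerical choices and degenerate inputs

* Least squares is solved by QR on the ridge-augmented system
  $[B;\ \sqrt{\varepsilon} I]$; reported RSS excludes the penalty term.
* Candidate ties in the forward pass are broken by (score, lower variable
  index, smaller knot, earlier parent), with a relative tolerance of
  1e-10, so fits are deterministic and equivariant under relabeling of the
  strain columns.
* On non-negative single-dose data the mirrored half $h(t - x)$ at
  $t = \min(x)$ is identically zero and is dropped; the two knots of a
  binary column give span-identical candidates, and the tie-break selects
  the positive-direction basis at knot 0, which keeps intercepts
  interpretable as the zero-dose prediction.
* A constant response yields an intercept-only model; an empty design or
  misaligned panel is an error; a non-positive reference level is reported
  per metabolite, not fatal to a panel run.
* The forward stop at relative improvement `1e-4` protects small-$n$ fits
  from chasing noise with near-collinear columns.

## Problem sizes used in the test suite

Unit and recovery tests run at the scale the package targets: 36-row
designs, 44-metabolite panels, and 50-seed recovery simulations at
$\sigma = 0.05$ (about five minutes in total). Oracle-equivalence tests
compare the forward pass with exhaustive candidate enumeration on designs
of up to 12 rows and 3 variables, and the backward pass with exhaustive
subset search for models with up to 6 non-intercept terms — sizes where
enumeration is exact and fast. Noiseless recovery checks use replicated
full-factorial binary designs, since the GCV charge requires $n > C$ for
any non-trivial model to be selectable.

## Known limitations

* Percentages are relative to the model intercept; if no combination
  leaves the reference regime (e.g. every row contains the same strain),
  the intercept extrapolates and percentages inherit that extrapolation.
* No uncertainty is attached to recovered percentages — the method is a
  model-selection screen, not an inferential procedure; no multiplicity
  correction is applied across metabolites.
* Greedy forward/backward search is not globally optimal; the oracle
  tests bound its behaviour only at small sizes.
* With one dose level per strain, hinge knots are degenerate (indicator
  regime); multi-dose designs exercise genuinely piecewise-linear fits but
  have not been a validation focus.
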