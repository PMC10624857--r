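---
title: "Multi-trait selection indices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait selection indices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selindex)
```

## The problem

A breeder rarely improves one trait at a time. Yield, its components and
quality traits are genetically correlated, differ in heritability, and
differ in economic importance, so selecting on any single trait wastes
information and can drag correlated traits the wrong way. The classical
answer is a *selection index*: a linear score

$$I = \sum_i b_i X_i = b'x$$

computed from each genotype's phenotypic trait values $x$, chosen so that
ranking genotypes by $I$ improves the *aggregate genotype*
$H = \sum_i a_i g_i = a'g$, the economically weighted sum of true genotypic
values. `selindex` implements the three index families in common use and
the machinery around them: estimating the covariance structure the indices
need, building economic weights, ranking and selecting genotypes, and
comparing indices by the standard evaluation criteria.

## Covariance structure from replicated trials

All indices consume the phenotypic and genotypic covariance matrices
$P$ and $G$ of the $m$ traits. `estimate_components()` obtains them from a
balanced randomized complete block design (RCBD: $n$ genotypes, each once
in each of $r$ blocks) by the method-of-moments solution of the expected
mean squares. Per trait, the two-way ANOVA (genotype, replicate, residual)
gives

$$\hat\sigma^2_g = \frac{MS_g - MS_e}{r}, \qquad \hat\sigma^2_e = MS_e,$$

and the multivariate analogue replaces mean squares by mean cross-products
of genotype means and residuals, giving every off-diagonal entry of $G$
and of the error covariance $E$. Setting $j = k$ in the cross-product path
reproduces the univariate path exactly, a property the tests assert.
Broad-sense heritability per trait is $h^2_b = \sigma^2_g / \sigma^2_p$,
and `correlation_matrices()` standardizes $G$ and $P$ into genetic and
phenotypic correlation matrices.

Two conventions exist for the phenotypic variance and we expose both as
`basis`:

* `"plot"` (default): $\sigma^2_p = \sigma^2_g + \sigma^2_e$, the variance
  of a single-plot observation;
* `"mean"`: $\sigma^2_p = \sigma^2_g + \sigma^2_e / r$, the variance of a
  genotype mean over $r$ replicates (never larger than the plot basis).

When genotype means are the values being scored, the mean basis is the
more coherent choice; the plot basis is the more widely printed one, which
is why it is the default. Since the choice only rescales $P$, index
rankings are often insensitive to it, but the evaluation criteria are not,
so the basis used is recorded in the pipeline log.

Negative estimates of $\sigma^2_g$ (possible whenever $MS_g < MS_e$) are
reported as estimated, with a warning; `clamp = TRUE` truncates them at
zero but breaks the sum-of-squares identity, so it is off by default.
Unbalanced or incomplete trials are rejected outright (naming the
offending genotype and replicate) rather than repaired: the expected-mean-
square solution assumes balance, and REML-style imputation is out of scope.

## The three indices

* **Optimum (Smith–Hazel)**: $b = P^{-1} G a$. Maximizes the correlation
  between $I$ and $H$ among all linear indices; needs $P$, $G$ and
  economic weights $a$.
* **Base (Brim)**: $b = a$. Uses the economic weights directly; needs no
  genetic parameters at all, which is its point — it is the fallback when
  $P$ and $G$ are unavailable or untrusted.
* **Pešek–Baker (desired gains)**: $b = G^{-1} d$, where $d$ states the
  desired genetic gain per trait. By default $d = \sqrt{\mathrm{diag}(G)}$
  — one genetic standard deviation of progress per trait — and
  `desired_gains()` accepts a breeder-specified override. This index
  avoids economic weights entirely.

`optimum_coefficients()` and `pesek_baker_coefficients()` solve the linear
systems $Pb = Ga$ and $Gb = d$ directly rather than forming explicit
inverses; the inverse notation is mathematical, not algorithmic. A
condition-number guard (default $10^{12}$, roughly the point where double
precision has lost all trustworthy digits) turns a near-singular $P$ or
$G$ into a clear error suggesting trait removal; for $G$ an explicit
`pseudo_inverse = TRUE` flag switches to a Moore–Penrose least-squares
solution instead of failing.

Scoring is $I = Xb$ over the genotype-mean panel; ranking is always
descending (larger $I$ is better, so traits to be *decreased* must carry
negative weights), ties keep input order for cross-platform determinism,
and truncation selection keeps the top $\lceil n \cdot p \rceil$ genotypes.

## Economic-weight schemes

Three built-in schemes produce the vector $a$; all are relative weights,
so only ratios matter:

1. **Unit** — $a_i = 1$ for every trait: all traits equally important.
2. **Correlation** — $a_i$ is the correlation of trait $i$ with a target
   trait (typically yield), and the target itself gets 1. The default
   source is the "total" Pearson correlation over the rows of the trait
   panel $X$; genetic or phenotypic correlation matrices can be used
   instead.
3. **Stepwise β** — standardized regression coefficients of the traits
   that enter a forward-stepwise regression of the target on the other
   traits, 0 for traits that never enter, 1 for the target. Entry and
   removal use partial-F tests with thresholds `sle` and `sls`, both
   defaulting to 0.15 — the long-standing convention of stepwise
   selection in the major statistical packages; both are exposed because
   the defaults are conventions, not laws. Ties in entry significance
   break toward the lower column index, and a variable that enters and is
   immediately removed terminates the search, so the procedure is
   deterministic. Standardized βs are invariant to affine rescaling of
   any predictor, which the tests verify.

## Evaluation criteria

For an index $b$ evaluated against aggregate-genotype weights $w$ ($a$ for
the optimum and base indices, $d$ for Pešek–Baker):

* **Accuracy** $R_{HI} = \dfrac{b'Gw}{\sqrt{(b'Pb)(w'Gw)}}$, the
  correlation between index scores and breeding values. The general
  covariance form is used *always*: the popular shortcut
  $\sqrt{b'Ga / a'Ga}$ is valid only when $b$ solves $Pb = Ga$ and would
  silently overstate the base and Pešek–Baker indices. For the optimum
  index the two coincide ($b'Pb = b'Ga$), which the property tests assert.
* **Aggregate gain** $\Delta H = k\, R_{HI}\, \sigma_H$ with
  $\sigma_H = \sqrt{w'Gw}$.
* **Per-trait gains** $\Delta = k\,Gb / \sqrt{b'Pb}$, the correlated
  response of each trait in its own units.
* **Relative efficiency** $RE = r_{G(A)I} / h_A$ for a target trait $A$,
  where $r_{G(A)I} = b'g / \sqrt{\sigma^2_{G(A)}\, b'Pb}$ with $g$ the
  target's column of $G$, and $h_A = \sqrt{G_{AA}/P_{AA}}$. $RE > 1$ means
  the index beats direct selection on the target trait.
* **Index CV** $CV_I = 100\,\sigma_I / \bar X$. We compute it from the
  *realized* scores — sample SD over mean of $I$ across genotypes —
  because the mean in the denominator is only defined over per-individual
  values; a `from = "model"` switch substitutes $\sqrt{b'Pb}$ for the SD.
  The CV is undefined (flagged `NA`) when the mean score is at zero,
  which can legitimately happen with mixed-sign coefficients.

The selection differential for truncating the best proportion $p$ of a
normal distribution is $k = \phi(z_p)/p$, the mean of the upper tail;
$k(0.10) \approx 1.75498$, conventionally rounded to 1.76.
`selection_differential()` returns full precision and rounding is left to
the report layer; a literal $k$ can be supplied anywhere one is accepted.

## The simulator, and what passing tests do and do not show

`simulate_rcbd_trial()` generates balanced multi-trait RCBD trials with
known ground truth: genotype effects $g_i \sim MVN(0, G_{true})$,
optional per-trait replicate effects $r_j \sim N(0, sd^2)$, and plot
errors $e_{ij} \sim MVN(0, E_{true})$, combined as
$y_{ij} = \mu + g_i + r_j + e_{ij}$. Draws occur in that fixed order
under the spec's seed, so trials are bit-reproducible. Replicate effects
default to zero because none of the index criteria involve the block
stratum; a nonzero SD exercises the replicate line of the ANOVA.

The recovery experiments use a 4-trait ground truth with trait SDs
between 0.8 and 6, genetic correlations between −0.4 and 0.5, and
broad-sense heritabilities between about 0.2 and 0.5 on the plot basis —
the range typical of agronomic traits in replicated yield trials. The
standard problem size is 200 genotypes × 3 replicates with 50 simulation
replicates (smaller sizes appear where only determinism or degeneracy is
being checked); at that size the estimated $G$, heritabilities and the
downstream optimum coefficients are unbiased within three Monte-Carlo
standard errors.

What the simulator deliberately does *not* emulate: genotype × environment
interaction, spatial field trend, unbalanced or missing plots, non-normal
traits, and pedigree or marker structure. Passing recovery tests therefore
show the estimators are correct *for the model the trial design assumes*,
not that real multi-environment data will behave as well; with real data
the quality of $\hat P$ and $\hat G$ is the binding constraint, and a
near-singular $\hat P$ (many correlated traits, few genotypes) is the most
common failure mode — hence the condition guard and its advice to drop
redundant traits.

## The worked fixture

`worked_fixture()` returns the 2-trait reference problem used across the
documentation and tests:
$P = \begin{pmatrix}4&1\\1&2\end{pmatrix}$,
$G = \begin{pmatrix}2&0.5\\0.5&1\end{pmatrix}$, $a = (1,1)$, plus a
6-genotype panel whose sample covariance equals $P$ exactly (a
deterministic base matrix is whitened and recolored with the Cholesky
factor of $P$). Every downstream value is short hand algebra: optimum
$b = (0.5, 0.5)$, $R_{HI} = \sqrt{1/2}$, $\Delta H(k{=}1.76) = 2.4890$,
$\Delta = (1.5556, 0.9334)$, $RE$ for trait 1 $= 0.8839$, Pešek–Baker
$b = (0.5224, 0.7388)$. Because the panel's covariance is exactly $P$,
the realized-score CV and the model-based CV coincide on this fixture.

```{r fixture}
fx <- worked_fixture()
opt <- optimum_coefficients(fx$P, fx$G, fx$a)
evaluate_index(opt, fx$P, fx$G, panel = fx$panel, target = 1, k = 1.76)
```

## Reproducing a published maize analysis

The pipeline's file layout follows a deposited maize data set
(BioStudies accession S-BSST853: 28 inbred lines, 7 traits, 3 replicates)
whose X, P, G and weight files can be dropped under
`inst/extdata/S-BSST853/` as `X.csv`, `P.csv`, `G.csv`, `a1.csv`. The
package does not redistribute those files; the reproduction test in the
suite runs only where a user has fetched them, and documents the expected
published values (index coefficient vectors, criteria rows, a 0.99979
base–optimum score correlation). Two ambiguities in the published account
are handled as follows: the phenotypic-variance basis behind the
deposited P is not stated, so the pipeline accepts either and the
reproduction should be attempted under the default plot basis first; and
the published stepwise fit's record level is not stated, so the stepwise
weights here use the genotype-level panel, which is what the deposited X
contains.

## Known limitations

* Balanced RCBD only; no lattice, split-plot, REML or missing-data paths.
* Broad-sense heritability only — no mating-design decomposition of
  additive vs non-additive variance, so "breeding value" here means total
  genotypic value.
* Single-stage, unrestricted indices; restricted (Kempthorne–Nordskog)
  and BLUP-based indices are out of scope.
* Expected, single-cycle gains; realized multi-generation response and
  economic discounting are not modeled.
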