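---
title: "Designing solubility screens: the yield model behind domainyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing solubility screens: the yield model behind domainyield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainyield)
```

## The problem

Dissecting large proteins into domains for structural or biochemical work
fails in two distinct ways: the predicted domain may not exist as an
independently soluble unit, or it may exist but the chosen N-/C-terminal
boundaries may be wrong. Screens therefore express several fragments
(boundary variants) per predicted domain and keep any domain with at
least one soluble fragment. `domainyield` models this process so that the
number of fragments tested per domain, `N`, can be chosen rationally
under a fixed budget.

## Model and assumptions

For a fragment of a correctly predicted (soluble) domain, solubility has
probability `p(S|D)`; a fragment cannot be soluble if its domain is not,
so the marginal fragment probability factorizes as
`p(S) = p(D) p(S|D)`, with `p(D)` the probability that a predicted domain
is soluble. All three are treated as homogeneous across domains — the
averaged-parameter assumption. A soluble domain is pictured as having `f`
soluble fragments among its `F` testable boundary combinations (a
30 x 30 termini window gives `F = 900`), and `P_N` is the probability
that testing `N` fragments hits at least one of the `f`:

* **multiple-copy** (designs may repeat; binomial):
  `P_N = 1 - (1 - f/F)^N`, depending only on the ratio `q = f/F`;
* **single-copy** (`N` distinct designs; hypergeometric):
  `P_N = 1 - C(F-f, N) / C(F, N)`, requiring integer `f`, `F` and
  `N <= F`.

The two differ by less than a couple of percent whenever `N` is a small
fraction of `F` (the regime of every practical screen); the test suite
asserts `|difference| <= 0.02` for `N <= 0.02 F` and that the single-copy
probability always dominates (sampling without replacement cannot
re-waste a draw).

Expected yield: `E_domain = M p(D) P_N` for `M` domains. With a set-up
cost `r` per new domain (in units of one fragment test) the budget is
`M (N + r)`; fixing it makes maximizing `E_domain` equivalent to
maximizing the normalized yield `e_domain = P_N / (N + r)`, which is
independent of `p(D)` and `M`.

## Parameters, units, defaults

| parameter | meaning | default / typical |
|---|---|---|
| `p(S|D)` (`q`) | boundary-prediction success | estimated; 0.63 in the pilot structure |
| `p(D)` | domain-prediction success | estimated; 0.81 |
| `f`, `F` | soluble / testable fragments per domain | `F_window = 900`, `f = round(q F)` |
| `N` | fragments tested per domain | the quantity being optimized |
| `r` | set-up cost ratio (dimensionless) | 0–10 typical; up to 1000 for screening-type work |
| `copy_mode` | `multiple` or `single` | `multiple` |

`f` and `F` enter the multiple-copy model only through `q`, so averaged,
non-integer values are accepted there; the single-copy model rejects them
because a hypergeometric draw from a non-integer population is undefined.

## Estimation

`classify_domains()` labels each domain soluble (one or more soluble
fragments), non-soluble (assessed, none soluble), or not assessable (all
fragments not applicable). `build_counts()` decomposes assessed fragments
into the three non-empty cells of the S/S^c x D/D^c table — the fourth
cell, soluble fragments of non-soluble domains, is empty by definition —
and `estimate_parameters()` turns counts into probabilities. On the
pilot-structured table (215 assessed fragments), `p(S) = 111/215 = 0.52`,
`p(S|D) = 111/175 = 0.63`, `p(D) = 175/215 = 0.81`; the product identity
holds exactly because `p(D)` is itself a count ratio. Note the joint cell
`S^c ∩ D` is reported from raw counts (64/215 = 0.30); summaries that
difference already-rounded marginals can disagree with it by one unit in
the last digit.

Standard errors use the binomial formula `sqrt(p (1-p) / n)` with `n` the
estimate's own denominator. This is the natural choice for proportions
from a single screen and reproduces the conventional ±0.03 scale at
`n ≈ 200`; correlation between the marginals is ignored, which is
adequate for planning purposes.

Fragments scored not-applicable (failed PCR, no expression, ambiguous
gels) carry no solubility signal. Point estimates exclude them;
`bounds_with_na()` brackets the truth by recoding every N/A fragment as
insoluble (lower limit) or soluble (upper limit) and recomputing domain
labels — on the pilot structure the domain-level success drops from
18/24 = 0.75 to a lower limit of 18/36 = 0.50, and `p(S)` from 0.52 to
111/436 = 0.25.

## Optimization

`find_N_optimum()` scans `N = 1..N_max` exhaustively — the domain is tiny
and the scan is exact — breaking ties toward the smaller, cheaper `N`.
Three numerical guards matter:

* **Boundary maxima are never silent.** The default
  `N_max = ceiling(10 (r+1) + 100)` exceeds the continuous optimum for
  any practical `(q, r)`; if the maximum still lands on `N_max` in
  multiple-copy mode the function errors rather than truncating. In
  single-copy mode the domain genuinely ends at `N = F`, so a maximum
  there is returned flagged `boundary = TRUE`.
* **Flat curves are flagged, not arbitrated.** For `f = 1`, `r = 0` in
  single-copy mode, `e_domain = (N/F)/N = 1/F` for every `N`; the scan
  detects flatness (relative spread below 1e-12), reports
  `N_optimum = 1` and sets `flat = TRUE`. The iterated-ratio evaluation
  of the hypergeometric keeps this case flat to machine precision, which
  a log-gamma formulation does not.
* **A continuous cross-check.** Treating `N` as continuous, the maximizer
  of `e_domain` solves `-(N+r)(1-q)^N ln(1-q) = 1 - (1-q)^N`.
  `solve_continuous_optimum()` finds this root by bracketing and
  bisection to 1e-9; uniqueness is verified numerically (monotone sign
  change) rather than analytically, and the integer optimum always falls
  in the root's floor/ceiling. At `r = 0` the derivative is negative for
  all `N > 0`, so the optimum pins to `N = 1`.

The resulting planning rules: with no set-up cost, test one fragment per
predicted domain; for `r = 1`, `N_optimum` stays between 1 and 4 over a
broad range of `p(S|D) > 0.1`; for `r = 10` and `p(S|D) > 0.5`, between
1 and 3; and even at `r = 1000` with `p(S|D) = 0.63` it is only 7.

## The simulator and what passing tests show

`generate_fragment_table()` draws whole synthetic screens under the
model's own generative assumptions: domains independently soluble with
probability `p_D_true`, fragments of soluble domains independently
soluble with probability `f/F` (or as a without-replacement draw), and an
independent per-fragment N/A dropout. Defaults mirror the pilot-screen
conditions (`F = 900`, `f = 567` so `q = 0.63`, `p_D_true = 0.81`,
`N = 9`). One root seed drives all streams through fixed per-operation
offsets (`derive_seed()`), with a fixed draw order — domain outcomes,
fragment outcomes, N/A mask, site labels — so two configs differing only
in `na_rate` share identical solubility outcomes and byte-identical
repeat runs.

What the generator does **not** emulate: between-domain heterogeneity in
`(f, F)` (real screens show all-soluble, mixed, and all-insoluble
domains; `expected_domains_heterogeneous()` handles the calculation but
the generator draws homogeneous domains), correlation between nearby
boundary choices, informative dropout (N/A more likely for insoluble
constructs), and any sequence-level realism. Cleavage-site labels are
cosmetic — drawn independently of solubility, sites 0–3 uniform and
site 4 at 5% (few domains sit at a protein terminus) — so site-balance
tests validate bookkeeping, not biology. Parameter-recovery tests
therefore show internal consistency of estimator and model, not that
real screens satisfy the averaged-parameter assumption; the
uniform-allocation bookkeeping (`uniform_allocation_example()`) shows
that assumption is at least self-consistent with domain-level outcomes
at pilot scale.

`simulate_P_N()` is an independent Monte-Carlo oracle for the closed
forms: it uses elementary uniform draws and random subsets, never the
formulas under test, and agrees within three Monte-Carlo standard errors
across both modes in the suite.

## Problem sizes and numerical choices

Test-suite simulations use screens of 400–2000 domains and Monte-Carlo
runs of 2e4–1e5 replicates: large enough that three-standard-error checks
are sharp (recovery of `q` to ±0.01), small enough to keep the whole
suite under half a minute. Exhaustive enumeration validates the
hypergeometric for every `F <= 12`. Probabilities are computed and
compared at full double precision and clipped to `[0, 1]` only to absorb
terminal rounding; presentation rounding (two decimals in reports)
happens exclusively at the output layer. The `model_parameters()`
consistency tolerance (0.015) accepts triples that were themselves
rounded to two decimals before being fed back in.

## Known limitations

* Averaged parameters: domains share one `(f, F)`; per-domain spreads are
  summed by `expected_domains_heterogeneous()` only when supplied
  explicitly.
* The N/A bounds are worst-case, not probabilistic; with high dropout
  they are wide.
* `e_domain` optimizes expected yield per cost only — no variance, time,
  or multi-objective terms, and no per-domain allocation of unequal `N`.
* The standard errors ignore the multinomial correlation between cells of
  the contingency table.
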