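# domainyield

Probabilistic planning for large-scale production of soluble protein
domains.

Structural-genomics and biochemistry labs rarely succeed by expressing a
predicted domain once: both the domain call and the exact N-/C-terminal
boundaries can be wrong, so several fragments (boundary variants) are
expressed and screened for solubility. `domainyield` answers the planning
question this raises: **given a fixed budget, how many fragments should be
tested per predicted domain to maximize the number of soluble domains
obtained?**

## The model

A pilot screen classifies each expressed fragment as soluble, insoluble,
or not applicable, and each predicted domain as *soluble* (at least one
soluble fragment), *non-soluble* (all assessed fragments insoluble — a
failed prediction), or *not assessable*. Three probabilities link the
fragment and domain levels:

- `p(S)` — a tested fragment is soluble (marginal);
- `p(S|D)` — a fragment of a soluble domain is soluble
  (boundary-prediction success);
- `p(D) = p(S) / p(S|D)` — a predicted domain is soluble
  (domain-prediction success).

If a soluble domain has `f` soluble fragments among its `F` testable
boundary combinations, the probability that at least one of `N` tested
fragments is soluble is

- multiple-copy (with replacement): `P_N = 1 − (1 − f/F)^N`;
- single-copy (without replacement, hypergeometric):
  `P_N = 1 − C(F−f, N) / C(F, N)`.

Testing `N` fragments in each of `M` domains yields
`E_domain = M · p(D) · P_N` soluble domains in expectation. With a set-up
cost ratio `r` (cost of starting a new domain relative to one more
fragment), the total cost is `M(N + r)`; holding it fixed, the quantity to
maximize is the normalized yield `e_domain = P_N / (N + r)`, whose integer
maximizer is `N_optimum`.

## Worked example

```r
library(domainyield)

# A synthetic table with the structure of a real pilot dissection screen:
# 36 predicted domains, 436 fragments, 24 domains (215 fragments) assessed.
tab <- pilot_structure_table()
est <- estimate_parameters(build_counts(tab), F_window = 900)
est
#> Solubility-screen model parameters
#>   p(S)   fragment soluble:             0.516 +/- 0.034
#>   p(S|D) boundary prediction success:  0.634 +/- 0.036
#>   p(D)   domain prediction success:    0.814 +/- 0.027
#>   f / F  soluble / testable fragments: 571 / 900
```

About half the fragments are soluble; the split shows that domain calls
are right ~81% of the time while boundary choices succeed ~63% of the
time. With nine fragments per domain a soluble domain is almost never
missed, so the per-domain yield equals `p(D)`:

```r
expected_domains(est, design_point(M = 1, N = 9))
#> Screen yield (multiple-copy model): M = 1, N = 9, r = 0
#>   P_N       = 0.9999   (P_N^C = 0.0001)
#>   E_domain  = 0.8139   (E_domain/M = 0.8139)
#>   e_domain  = 0.1111   (per unit cost)
```

But nine is far from cost-optimal. At a fixed total budget:

```r
find_N_optimum(q = 0.63, r = 0)$N_optimum     # 1  - no set-up cost: spread wide
find_N_optimum(q = 0.63, r = 10)$N_optimum    # 3  - typical set-up cost
find_N_optimum(q = 0.63, r = 1000)$N_optimum  # 7  - even a huge set-up cost
```

With no set-up cost, one fragment per predicted domain maximizes the
soluble-domain count; realistic set-up costs move the optimum only to a
handful of fragments — far fewer than the dozen-or-so a screen might use
by default.

Fragments that fail expression carry no solubility signal; treating them
all as insoluble or all as soluble bounds the estimates:

```r
b <- bounds_with_na(tab)
round(c(lower = b$lower$domain_fraction, upper = b$upper$domain_fraction), 2)
#> lower upper
#>  0.50  0.83
```

A seeded simulator generates whole synthetic screens
(`generate_fragment_table()`) and Monte-Carlo checks of `P_N`
(`simulate_P_N()`). The same operations are scriptable through the CLI at
`inst/cli/domainyield` (`estimate`, `expected`, `optimize`, `simulate`,
`generate`).

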