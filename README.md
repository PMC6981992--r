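# unsafebn

Bayesian-network analysis of how coded unsafe behaviors transmit probability
to building-construction accidents.

Fatal construction accidents rarely have a single cause: investigation
reports record a time-ordered *chain* of coded unsafe behaviors (e.g.
B18 → B14 → B12: equipment installed against procedure, then a specialized
operation without a permit, then missing PPE) ending in one of four accident
types — fall (F), collapse (C), struck-by (S) or lifting (L). `unsafebn` is
for safety researchers and site-safety analysts who want to quantify, from a
corpus of such coded cases, *which* behaviors drive *which* accident types
and *which groups* of co-occurring behaviors deserve joint control.

## The model

The package learns a tree-augmented naive Bayes (TAN) network: the accident
type `Y ∈ {S, C, F, L}` is the class node and a parent of every binary
behavior indicator `B_i`; on top of that, the behaviors are joined by a
maximum spanning tree under the class-conditional mutual information
`I(B_i; B_j | Y)` (the Chow–Liu construction), so each behavior has at most
one behavior parent:

    P(Y, B_1, …, B_m) = P(Y) · Π_i P(B_i | Y, B_parent(i))

Conditional probability tables use an additive small-cell adjustment
(pseudocount α = 0.5 per cell) so rare behavior–accident combinations keep
nonzero probability. On this model the package provides:

* **forward reasoning** — exact accident-type posteriors `P(Y | evidence)`
  under accumulating behavior evidence (`class_posterior()`,
  `sequential_prediction()`), and each behavior's *accident attribute
  strength*, the posterior increment it contributes (`attribute_strength()`);
* **backward diagnosis** — `P(B = Yes | Y = k, …)` and an iterative
  clamping loop that identifies the *critical group* of behaviors for each
  accident type: repeatedly select the highest-posterior behavior with
  within-type frequency ≥ 8%, clamp it to Yes, stop when no candidate
  reaches 15% (`behavior_posterior()`, `critical_group()`);
* **data handling** — behavior catalogs, accident-case files, chain
  extraction and Yes/No case matrices (`load_cases()`, `filter_cases()`,
  `extract_chains()`, `chains_to_matrix()`);
* **a synthetic generator** with known ground truth for validating the whole
  pipeline (`generator_config()`, `build_ground_truth()`, `sample_cases()`).

## Worked example

Simulate a corpus shaped like the motivating data (287 fatal cases,
F = 191, C = 39, S = 33, L = 24, 37 behavior indicators), fit the network,
and reason over it:

```r
library(unsafebn)

truth <- build_ground_truth(generator_config(seed = 17))
cases <- sample_cases(truth, n = 287, seed = 18,
                      class_counts = c(S = 33, C = 39, F = 191, L = 24))
model <- fit_tan(cases, alpha = 0.5)
class_posterior(model)
#> # A tibble: 4 × 2
#>   accident_type posterior
#>   <chr>             <dbl>
#> 1 S                0.116
#> 2 C                0.137
#> 3 F                0.663
#> 4 L                0.0848
```

With no evidence the posterior is the smoothed class prior — 66.3% fall,
13.7% collapse, 11.6% struck-by, 8.5% lifting. Now feed in the behavior chain
of a fall accident one observation at a time:

```r
sequential_prediction(model, c("B14", "B11", "B24", "B12"))
#>   step behavior state       S       C     F       L
#> 1    0     <NA>  <NA> 0.11592 0.13668 0.663 0.08478
#> 2    1      B14   Yes 0.11914 0.18654 0.590 0.10425
#> 3    2      B11   Yes 0.02164 0.02893 0.924 0.02561
#> 4    3      B24   Yes 0.00800 0.01206 0.964 0.01585
#> 5    4      B12   Yes 0.00888 0.00268 0.984 0.00469
```

The fall posterior climbs from 66.3% to 98.4% as the evidence accumulates;
the permit violation B14 barely moves it (weak accident attribute, it occurs
in every accident type) while the hole-protection and PPE failures B11 and
B12 produce the large jumps (strong fall attributes). The final row is
order-invariant: permuting the evidence changes the path, never the endpoint.

Backward diagnosis of the fall type identifies its critical group:

```r
critical_group(model, cases, "F")
#> Backward diagnosis for accident type F
#>   thresholds: frequency >= 8%, stop when max posterior < 15%
#>   critical group: {B12, B11, B24, B14, B37}
#>    step 1: B12 selected at P = 49.7%
#>    step 2: B11 selected at P = 49.2%
#>    step 3: B24 selected at P = 40.1%
#>    step 4: B14 selected at P = 22.1%
#>    step 5: B37 selected at P = 20.1%
```

The four behaviors planted as fall-critical in the generator are recovered in
order; B37 is a borderline background behavior pulled over the 15% threshold
by sampling noise at n = 287 — the trace (`tidy()`, `autoplot()`) makes such
selections inspectable. At n = 5,000 the recovery is exact for all four
accident types (see the vignette).

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "unsafebn.R", package = "unsafebn")` with subcommands
`simulate`, `extract-chains`, `fit`, `predict`, `diagnose` and `report`.

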