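---
title: "Modelling how unsafe behaviors transmit probability to construction accidents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling how unsafe behaviors transmit probability to construction accidents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(unsafebn)
```

## The problem

Fatal building-construction accidents are usually preceded by several coded
unsafe behaviors — a worker operating without a permit, inadequate hole
protection, missing personal protective equipment — occurring in a time
sequence. Investigators record these as a *chain* per accident, together with
the accident type: fall (F), collapse (C), struck-by (S) or lifting (L).
`unsafebn` models the relationship between the binary behavior indicators and
the accident type, so that one can ask two questions:

* **Forward**: given that certain behaviors have been observed on site, how do
  the probabilities of the four accident types shift?
* **Backward**: given that an accident of a certain type occurred, which group
  of behaviors most plausibly co-occurred — the *critical group* to control?

## The model

The network is a tree-augmented naive Bayes (TAN) classifier. The accident
type $Y \in \{S, C, F, L\}$ is the class node and a parent of every behavior
indicator $B_i \in \{\mathrm{Yes}, \mathrm{No}\}$. On top of the naive-Bayes
skeleton, the behaviors are connected by a spanning tree, so each behavior has
at most one behavior parent:

$$P(Y, B_1, \dots, B_m) \;=\; P(Y)\, \prod_{i=1}^{m} P\!\left(B_i \mid Y,\,
B_{\pi(i)}\right),$$

where $\pi(i)$ is the (possibly absent) tree parent of $B_i$. The tree is the
maximum-weight spanning tree under the conditional mutual information

$$I(B_i; B_j \mid Y) = \sum_{y, b_i, b_j} p(b_i, b_j, y)\,
\log \frac{p(b_i, b_j \mid y)}{p(b_i \mid y)\, p(b_j \mid y)},$$

computed in nats from smoothed counts (the Chow–Liu construction applied
conditionally on the class). This keeps exact inference closed-form and cheap
— the strongest pairwise dependency of each behavior is retained, all weaker
ones are dropped.

Conditional probability tables are estimated with an additive small-cell
adjustment: every cell is $(\text{count} + \alpha) / (\text{total} + \alpha
\cdot \#\text{states})$ with $\alpha = 0.5$ per cell by default. With 37 sparse
indicators and as few as 24 cases in the rarest class, many raw cells are
zero; the adjustment keeps every configuration possible without drowning the
signal. $\alpha$ is exposed everywhere (`alpha` argument) for sensitivity
checks; $\alpha = 0$ gives raw maximum-likelihood tables, and a parent
configuration never seen in training then falls back to a uniform column so
tables stay normalized.

### Forward reasoning

`class_posterior()` computes $P(Y = k \mid B_c)$ exactly for an evidence set
$B_c$ of observed behaviors, by collecting messages along the feature tree;
unobserved behaviors marginalize out. `sequential_prediction()` inserts
evidence one behavior at a time and records the posterior after each
insertion. Because the joint is fixed, the *final* posterior is invariant to
the insertion order; only the path of the trajectory changes. The size of the
jump a behavior produces is its *accident attribute strength*
(`attribute_strength()`): the increment in a type's posterior when the
behavior is added to the current evidence.

### Backward reasoning and critical groups

`behavior_posterior()` computes $P(B_i = \mathrm{Yes} \mid Y = k, \cdot)$ —
the probability a behavior occurred given the accident type (and any
behaviors already clamped). `critical_group()` iterates this: clamp the
accident type, select the behavior with the largest posterior among those
whose within-type frequency is at least 8%, clamp it to Yes, and repeat until
no eligible behavior reaches a 15% posterior. Both thresholds are arguments
(`frequency_floor`, `stop_posterior`); the 8%/15% defaults are the working
values of the procedure the package implements. Two deliberate choices:

* the frequency filter is applied from the **first** iteration — uniform
  application is simpler to reason about than starting it at the second
  round, and it never changes which behaviors are *selectable* when all
  high-posterior behaviors are also frequent;
* frequencies use the **per-type** denominator (share of cases of that
  accident type), which matches the worked eligibility arithmetic of the
  source procedure; `per_type = FALSE` switches to the all-cases base.

Clamping can *raise* a later candidate's posterior (dependent behaviors pull
each other up), so selection-time posteriors need not decrease monotonically;
the trace records every round for inspection (`tidy()`, `autoplot()`).

### Choosing a reporting root

Any behavior can serve as the drawn root of the feature tree without changing
the joint — `reroot()` re-derives the conditional tables along the reversed
edges exactly, and this invariance is asserted in the test suite. For
*reporting*, a good root is a behavior that occurs in all four accident types,
occurs often, and is type-neutral (weak accident attribute), so conditioning
on it does not privilege one accident type. `select_root()` ranks behaviors:
all-types coverage first, then attribute-strength spread ascending, then total
occurrences descending. Spread dominates raw frequency among all-types
behaviors deliberately: a very frequent behavior that is strongly tied to one
type (e.g. a PPE failure that almost always means a fall) makes a poor
neutral root even though it is common.

## The synthetic generator

No case-level accident matrix is publicly available, so the package ships a
generator (`generator_config()`, `build_ground_truth()`, `sample_cases()`,
`sample_chains()`) whose defaults emulate the published shape of the data:

* 287 cases with class probabilities 33 : 39 : 191 : 24 over S, C, F, L;
* 37 binary indicators; background conditional rates drawn per behavior,
  class and parent state from $[0.02, 0.10]$ — the range spanned by the minor
  published per-type occurrence rates (a behavior seen in 2–10% of cases of a
  type), and safely below the 15% diagnosis threshold;
* one frequent type-neutral behavior, B14 at rate 0.25 in every class,
  mirroring its published 25% overall rate;
* planted high-lift behaviors per type (falls: B12, B11, B24; lifting: B18,
  B27, B6; collapse: B17, B22; struck-by: B9, B1) with lifts 0.30–0.45 over a
  0.05 baseline, reproducing the strong-attribute structure of the published
  analyses. Planted and type-neutral behaviors are parent-independent by
  construction, so their true within-type rates are exactly their table
  entries.

The ground truth records, per accident type, the behaviors whose true rate
$P(B = \mathrm{Yes} \mid Y = k)$ is at least 0.15 — by construction exactly
the set an ideal diagnosis should return. The end-to-end regression
(generate at $n = 5{,}000$ → learn with $\alpha = 0.5$ → diagnose) recovers
each of the four sets exactly.

```{r closure}
truth <- build_ground_truth(generator_config(seed = 17))
truth$planted_sets$F
cases <- sample_cases(truth, n = 5000, seed = 101)
model <- fit_tan(cases)
critical_group(model, cases, "F")$group
```

What the generator does **not** emulate: narrative accident reports (chains
are uniform random orderings of each case's behaviors, because time order
carries no probability in this model), realistic background co-occurrence
beyond a single tree dependency, duplicate behaviors within a case, and any
non-fatal or non-modelled accident types. Passing the closure test therefore
shows the *pipeline* is sound — not that real accident data satisfy the TAN
assumptions.

## Numerical choices

* CMI is computed in nats; floating-point negatives are clamped to zero.
* Spanning-tree ties break by lexicographic (numeric) behavior-code order,
  then insertion order; diagnosis ties break toward the lower code number —
  builds and traces are deterministic and column-order invariant.
* The default orientation root is the lowest-numbered behavior; orientation
  never affects the joint (tested).
* `brute_force_posterior()` — the enumeration oracle used throughout the test
  suite as an independent check on message passing — refuses models with more
  than 14 behaviors ($4 \cdot 2^{14}$ joint cells).
* Every sampling function requires an explicit seed and is bit-exact
  reproducible; model JSON round-trips at full double precision.
* Test problem sizes: structure/parameter recovery at $n = 20{,}000$ (and
  $2{,}000$ for the error-shrinkage check), pipeline closure at $n =
  5{,}000$, oracle agreement on 200 random models of 3–12 behaviors.

## Limitations

* The TAN tree allows one behavior parent per behavior; richer co-occurrence
  (e.g. three-way synergies) is projected onto the strongest pairwise links.
* Time order is recorded in chains but deliberately not modelled; the package
  cannot distinguish early from late behaviors probabilistically.
* With realistic sample sizes (a few hundred cases), sampling noise can pull
  a background behavior above the 15% diagnosis threshold; the trace makes
  such borderline selections visible rather than hiding them.
* Diagnosis output is associational — a critical group is a set of behaviors
  that co-occur with an accident type, not a causal prescription.
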