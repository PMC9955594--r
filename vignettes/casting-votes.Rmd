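---
title: "Casting voters in sequential decision-making: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Casting voters in sequential decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castvote)
library(dplyr)
library(ggplot2)
```

## The model

`N` respondents answer a binary question in a fixed order. Respondent `n`
privately draws a *primary choice* that is correct with probability equal to
their ability $p_n \in (0.5, 1)$, observes all earlier public answers, and
answers to maximise their own probability of being correct. Every respondent
knows the full ability vector and assumes all antecedents behaved optimally.
Options are labelled relative to the first answer: $s$ = same option as
respondent 1, $t$ = the other option.

Three assumptions matter:

* **Open interval abilities.** $p_n = 0.5$ would be a coin flip (no
  information) and $p_n = 1$ an infallible respondent; both degenerate the
  likelihood algebra, so strict mode rejects them.
* **Generic distinctness.** With heterogeneous abilities the theory assumes
  subset odds products never tie exactly. Checking all $2^N$ subsets is
  exponential, so `ability_profile()` only records whether abilities are
  pairwise distinct; exact ties that nevertheless occur at run time are
  caught by the tie tolerance (below).
* **Individual, not group, optimality.** Each respondent maximises their own
  conditional accuracy. Rules that would maximise the *group's* accuracy are
  a different problem and are out of scope.

The central structural result is that the optimum is all-or-nothing: the
answer either equals the primary choice regardless of the antecedents
(*casting voter*) or is fully determined by the antecedents (*non-casting
voter*), with no partial weighting of one's own primary. Consequently an
answer reveals the primary choice exactly when its author is casting, and
the likelihood of the observed history under either hypothesis is a product
over casting voters only:
$L_s = \prod_{m \in S} p_m \prod_{m \in T} (1 - p_m)$, mirrored for $L_t$,
with $S$/$T$ the casting voters answering $s$/$t$. With
$r^*_m = \log\frac{p_m}{1 - p_m}$ and
$\Delta = \sum_{S} r^*_m - \sum_{T} r^*_m$, respondent $n$ is casting iff
$|\Delta| < r^*_n$, and otherwise answers the side of $\mathrm{sign}(\Delta)$.
`run_sequence()` iterates this rule; `conditional_performance()` returns the
posterior probability of being correct,
$\pi_n = \max(a, b) / (a + b)$ with $a, b$ the two hypothesis joint
probabilities including the focal primary factor, so $\pi_n \in [0.5, 1]$ by
construction.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `tol` | tie tolerance on the log-odds scale | `1e-9` | far below any ability-induced gap of interest, far above double rounding noise |
| `n_runs` | Monte-Carlo replicates | `10000` | binomial SE $\le 0.005$ per order, small enough to resolve the closed-form steps |
| `seed` | RNG seed | none (user-set) | all reported randomness flows from it |
| `min_gap` | pairwise gap of random profiles | `0.01` | keeps subset odds products generically distinct at small `N` |
| `n_max` in `effective_voters()` | search cap | `999` | the answer is 3–7 everywhere; the cap only guards pathological inputs |

**Tie rule.** The theory only needs a tie convention when log-odds sums tie
exactly. For equal abilities the convention is fixed: a respondent facing a
dead heat adopts their own primary choice (and is therefore casting). We
apply the same rule universally — any $|\,|\Delta| - r^*_n| \le$ `tol`
resolves to the primary — because it reduces to the equal-ability convention
when abilities coincide, keeps the classification total for every input, and
for pairwise-distinct profiles fires only on measure-zero coincidences,
which additionally emit a warning. All comparisons are done in the log
domain so long chains cannot underflow.

## Closed forms

For equal abilities the casting-vote count difference
$d_n = |S_{n-1}| - |T_{n-1}|$ performs a random walk absorbed at $\pm 2$:
while $|d| \le 1$ the next respondent is casting and moves the walk; at
$|d| = 2$ the gap $2r^*$ exceeds every individual weight $r^*$, so all
later respondents copy the leading side and the walk freezes. Mean
performance is
$$E[\pi_n] = \frac{p^2 + p(1-p)(1-2p)\,(2p(1-p))^{k-1}}{p^2 + (1-p)^2},
\qquad k = \tfrac{n+1}{2}\ (n\ \text{odd}),\ \ k = \tfrac{n}{2}\ (n\ \text{even}),$$
which equals $p$ at $n = 1, 2$ and rises to the ceiling
$\pi_{\max}(p) = p^2 / (p^2 + (1-p)^2)$. The package treats this expression
as a *reconstruction*: it is validated in the test suite against exact
enumeration to $10^{-12}$ for $n \le 12$, it reproduces the stated limit,
and it coincides with the unaware-expert form at $q = p$ — three
independent consistency checks.

The expert forms follow the same pattern. An aware expert with
$q \ge \pi_{\max}(p)$ ignores everyone ($E = q$ at every order, because even
a frozen walk carries less evidence than their own primary); otherwise, and
for every unaware expert, $E[\pi_{n,q}] = \pi_{\max} - (\pi_{\max} - q)(2p(1-p))^{k-1}$.

Comparing the ceiling with a simultaneous unweighted majority of $n$
independent voters (the binomial tail of `majority_accuracy()`) defines the
*effective number of voters*. The defining equality generically has no
integer solution, so `effective_voters()` returns the smallest odd $n$ whose
majority accuracy is at least $\pi_{\max}(p)$, and `crossing_ability()`
exposes the real-valued boundary: for $n = 5$ the root is
$(3 + \sqrt{3})/6 \approx 0.79$, found by bisection to $10^{-10}$ (the
bracket endpoints $0.5 + 10^{-6}$, $1 - 10^{-6}$ avoid the degenerate
boundary zeros). Computed over $p \in \{0.55, \dots, 0.95\}$ the effective
number is 7 below the root and 5 above it — the chain is worth at most a
handful of independent opinions however long it is.

```{r effn}
effective_voters_curve(seq(0.55, 0.95, by = 0.05))
```

## Exact enumeration and its pruning

`exact_curve()` computes $E[\pi_n]$ without sampling by enumerating
primary-choice outcomes in the *truth frame* (each primary correct or not,
rather than $s$/$t$): the recursion state is the signed log-odds evidence
$D$, a casting voter branches the recursion in two, and a non-casting voter
contributes a deterministic answer, so the cost is $2^{\#\text{casting}}$
rather than $2^N$. For equal-ability chains absorption keeps the branch
count near-linear. Two equivalences are themselves tested rather than
assumed: the pruned truth-frame recursion equals a full $2^N$ enumeration
driven through `run_sequence()` in the relative frame, and `run_sequence()`
itself equals a brute-force Bayes oracle that marginalises over all hidden
antecedent primaries without ever forming casting-voter sets.

## The simulator and what it emulates

`simulate_chain()` draws primary-choice correctness per respondent and runs
the decision rule vectorised across replicates; `d_walk_statistics()`
reports the absorption behaviour of the equal-ability walk through the same
engine, so the $|d| \le 2$ bound is an observed consequence of the log-odds
rule, not an assumption. Randomness uses R's global RNG seeded once per
call: execution is single-threaded and vectorised, so per-run substreams
would add machinery without changing reproducibility — identical
`(profile, n_runs, seed)` always yields a bit-identical report. Default
`n_runs = 10000` matches the regime in which per-order standard errors
($\approx 0.005$) separate the closed-form steps.

The generator families (`generate_profile()`) mirror the three study
conditions: equal abilities, a single expert among equals, and random
pairwise-distinct abilities. What the synthetic chains do *not* emulate:
mis-estimated or deceptive abilities, confidence-based weighting,
self-chosen decision order, or any dependence between primary choices
beyond what the answer-copying itself induces. Passing tests therefore
validate the algorithmic and analytic claims under the model's own
assumptions, not the behaviour of human groups.

```{r walk, fig.width = 6, fig.height = 3.5}
dw <- d_walk_statistics(generate_profile("equal", n = 20, p = 0.7),
                        n_runs = 2000, seed = 7)
autoplot(dw)
```

## Three respondents

`three_person_analysis()` enumerates the complete case structure. With
$p_2 > p_1$ both early respondents are casting voters and the third faces
three independent votes: they answer independently if
$r^*_3 > r^*_1 + r^*_2$, follow the second if $r^*_2 > r^*_1 + r^*_3$, and
otherwise follow the simple majority, earning
$M = p_1p_2p_3 + (1-p_1)p_2p_3 + p_1(1-p_2)p_3 + p_1p_2(1-p_3)$, which
exceeds every non-expert individual ability. With $p_1 > p_2$ the second
respondent follows blindly, the majority option disappears, and the third
earns only $\max(p_1, p_3)$ — hence the discontinuous drop in $E[\pi_3]$
across the $p_1 = p_2$ diagonal that `three_person_grid()` renders as data.
The region corner points (e.g. where the interior region meets the
diagonal at $p_1 = p_2 = \sqrt{p_3}/(\sqrt{p_3} + \sqrt{1 - p_3})$) emerge
from the inequalities; they are not hard-coded.

```{r phase, fig.width = 5, fig.height = 4.5}
plot_three_person_phase(three_person_grid(0.7, step = 0.02))
```

## Numerical choices and degenerate inputs

* All likelihood-ratio comparisons run in log space; `conditional_performance()`
  evaluates $\max(a,b)/(a+b)$ as $1/(1 + e^{-|\log a - \log b|})$, stable
  for arbitrarily long chains.
* The first primary must be `"s"`: the relative frame is *defined* by the
  first answer, so any other input is a usage error, not a choice.
* `is_optimal_weighting()` brute-forces all bipartitions and is capped at
  $N \le 20$; `exact_curve()` is capped at $N \le 25$ (worst-case
  heterogeneous profiles branch at every respondent).
* Even `n` in `majority_accuracy()` is rejected rather than tie-broken:
  the simultaneous baseline is defined for odd panels.
* `effective_voters()` uses "smallest odd $n$ with accuracy $\ge \pi_{\max}$";
  at the crossing ability itself the result steps from 7 to 5, and the
  boundary is exposed separately rather than folded into the integer answer.

## Problem sizes used in validation

The shipped tests exercise: oracle equivalence for all primary vectors on
ability grids up to $N = 6$; closed-form agreement to $10^{-12}$ up to order
12; simulation-versus-closed-form agreement within 3 standard errors at
10,000 runs for $p \in \{0.6, 0.7, 0.8, 0.9\}$, orders 1–13; and 10,000-run
absorption statistics at $p = 0.7$, $N = 20$. These sizes fully resolve the
phenomena of interest (absorption happens within the first few orders;
performance curves flatten by order 13) while keeping the whole suite in
the tens of seconds.

## Known limitations

* Exact enumeration of large heterogeneous chains is exponential; beyond
  $N \approx 25$ only the simulator applies.
* The tie rule is a modelling convention on a measure-zero set; alternative
  conventions (e.g. randomising) would change nothing off the boundaries
  but are not implemented.
* The unaware-expert closed form describes a *suboptimal* agent (they act on
  a wrong self-assessment); the package's chain runner always plays the
  optimal rule for the stated abilities, so unaware-expert behaviour is
  validated against a dedicated enumeration rather than `run_sequence()`.
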