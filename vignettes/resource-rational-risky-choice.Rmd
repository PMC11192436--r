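---
title: "Modeling risky choice as resource-rational strategy selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risky choice as resource-rational strategy selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrchoice)
```

## The model

A *gamble* is a finite distribution over monetary outcomes; a *choice
problem* is a pair of gambles (options A and B), classified as gain, loss,
or mixed by the signs of its payoffs. The model assumes the decision maker
owns a toolbox `S` of cognitive strategies and, facing problem `p`, selects

$$ s^* = \arg\max_{s \in S}\; r_{s,p} - \delta\, c_{s,p}, $$

where `r` is the strategy's expected payoff on the problem (the expected
value of the gamble it would choose), `c` its cognitive cost, and the cost
weight $\delta \ge 0$ (in units of money per elementary operation) captures
how expensive mental effort is for this individual. The selected strategy's
choice is then executed with a trembling-hand error $\epsilon \in [0, 0.5]$:

$$ P(A) = P(A \mid \delta, S)(1 - \epsilon) + P(B \mid \delta, S)\,\epsilon. $$

Two simplifying assumptions are inherited from this modeling tradition and
kept deliberately: the decision maker's internal estimates of `r` and `c`
are identified with the strategy's *actual* simulated payoff and cost (no
learning model for those estimates), and the parameters
$(S, \delta, \epsilon)$ are constant across problems and domains.

## The strategy set

The eleven heuristics (`strategy_ids()`) span the classic space from
outcome-only rules to full expectation: minimax and maximax (best worst /
best best outcome), least-likely and most-likely (probability of the worst
outcome / payoff of the likeliest outcome), better-than-average (count of
outcomes at or above the grand mean), equal-weight (unweighted outcome sum),
tallying (four attribute-wise marks), probable (mean of outcomes with
$p \ge 0.5$), lexicographic (likeliest payoff, then the second likeliest),
the priority heuristic (minimum, probability of minimum, maximum, with
aspiration-based stopping), and weighted-additive (expected value itself).

Conventions the verbal rules leave open, fixed here and mirrored in the
test oracle:

* **Signed payoffs everywhere.** All rules compare signed money amounts, so
  in the loss domain "best" means least bad. For tallying, the stated
  loss-domain substitution (swap "gain"/"loss" and "higher"/"lower") maps
  onto exactly the same four signed criteria as the gain version — higher
  minimum, higher maximum, lower probability of the minimum, higher
  probability of the maximum — so one signed rule serves all domains.
* **Priority heuristic mirroring.** For losses the aspiration level is one
  tenth of the largest *absolute* loss; for gain and mixed problems it is
  one tenth of the maximum gain (the problem-wide maximum, following the
  heuristic's original formulation). The probability aspiration is fixed at
  0.1 of the probability scale.
* **Within-gamble ties.** When two outcomes are equally likely, the
  "most likely outcome" is taken to be the one with the higher payoff;
  duplicated payoff values pool their probabilities. A safe option's single
  outcome serves as its minimum, maximum, and most likely outcome; in the
  lexicographic second stage it simply keeps that payoff.
* **Probable with nothing probable.** A gamble whose outcomes are all below
  the 0.5 threshold valuates to $-\infty$; two such gambles tie.
* **Between-option ties.** Scores equal within `1e-9` make the rule
  indifferent; the choice is then uniform random (seeded), and the decision
  carries a `tie` flag. Indifference, not error.

## Cost accounting

Strategy cost is the length of the execution trace in elementary
information processes (EIPs): READ, COMPARE, DIFFERENCE, ADD, PRODUCT,
ELIMINATE, CHOOSE. The per-strategy formulas (option sizes $n_A, n_B$,
$N = n_A + n_B$) are:

| strategy | trace | two two-outcome options |
|---|---|---|
| MINI / MAXI | $N$ READ, $(n_A{-}1)+(n_B{-}1)$ + 1 COMPARE, CHOOSE | 8 |
| LL / ML | as MINI plus 2 READ (the located outcome's other attribute) | 10 |
| BTA | $N$ READ, $N{-}1$ ADD, 1 PRODUCT, $N{+}1$ COMPARE, CHOOSE | 14 |
| EQW | $N$ READ, $(n_A{-}1)+(n_B{-}1)$ ADD, 1 COMPARE, CHOOSE | 8 |
| TALLY | $N$ + up to 4 READ, $2[(n_A{-}1)+(n_B{-}1)]$ + 5 COMPARE, CHOOSE | 18 |
| PROB | $N$ READ + $N$ COMPARE (threshold), ELIMINATE per improbable outcome, reads/means of the survivors, 1 COMPARE, CHOOSE | 14–18 |
| LEX | as ML, plus 2 READ + 1 COMPARE if a second stage is needed | 10–13 |
| PH | stage-wise; early stopping gives path-dependent 13–20 | 13–20 |
| WADD | $2N$ READ, $N$ PRODUCT, $(n_A{-}1)+(n_B{-}1)$ ADD, 1 COMPARE, CHOOSE | 16 |

The counts are a documented operationalization, not a claim about the one
true cost of a mental step: what the selection rule consumes is chiefly the
*ordering* of costs (weighted-additive is always costlier than minimax, and
the priority heuristic's early stopping makes its cost path dependent).
For auditing that dependence, `compute_strategy_stats()` accepts a YAML
cost-scheme file mapping strategies to fixed counts, which overrides the
trace-based default.

`compute_strategy_stats()` simulates each strategy `reps = 100` times per
problem (the tie-breaking is the only randomness) and averages `r` and `c`
across runs; it also records each strategy's structural choice probability
$P(A) \in \{0, 0.5, 1\}$, which the likelihood machinery reuses.

## Likelihood and fitting

One simulation run fixes, per problem, a selected strategy (selection ties
uniform random) and hence a run-level $P(A\mid\delta,S) \in \{0, 0.5, 1\}$;
the trembling-hand mixture turns that into a trial probability; the per-run
log-likelihood sums over trials; and the reported value averages the
per-run log-likelihoods across runs — averaging on the log scale, which is
not the same as averaging the probabilities and is therefore stated
explicitly. Because the per-run log-likelihood is linear in the counts of
matched/mismatched/indifferent predictions, the run average reduces to the
run-averaged counts; the implementation exploits this, and an exhaustive
enumeration through the public `log_likelihood()` reproduces `fit_participant()`
exactly (same seed), which the test suite verifies on fifty random
micro-grids.

Fitting is an exhaustive grid search over all toolboxes of the candidate
strategies at the allowed sizes, $\delta$, and $\epsilon$. Two presets:

* `"full"`: toolbox sizes 1–7, $\delta \in \{0, 0.1, \dots, 20\}$,
  $\epsilon \in \{0.01, \dots, 0.5\}$ in steps of 0.01, 100 runs — the
  complete estimation protocol (about 18 million cells);
* `"desk"` (default): sizes 1–4, $\delta$ step 0.5, $\epsilon$ step 0.05,
  20 runs (230,010 cells, a few seconds per participant), sized for
  interactive work, testing, and recovery studies.

Every grid cell replays the same seeded stream, making cells comparable and
the whole search reproducible. Among equal maxima the smaller toolbox is
preferred (a complexity tie-break, since nested toolboxes can be
likelihood-equivalent), remaining ties are resolved at random, and
`n_ties_at_max` is reported so that instability is visible rather than
hidden. $\epsilon = 0$ is allowed in simulation but excluded from the
fitting grids; a zero $\epsilon$ meeting a contradicted deterministic
prediction raises an explicit error instead of returning $-\infty$.

Degenerate inputs are rejected at construction: gambles whose probabilities
do not sum to one (tolerance `1e-9`), problems with identical options or
all-zero payoffs. The coefficient of variation is undefined (NA) at zero
expected value, and EV/CV ties make the corresponding indicator undefined
rather than worth half credit; undefined trials are excluded from averages.

## The CPT baseline

The comparison model is six-parameter cumulative prospect theory: power
value function $v(x) = x^{\alpha^+}$ for gains and
$v(x) = -\lambda(-x)^{\alpha^-}$ for losses, one-parameter inverse-S
weighting $w(p) = p^\gamma / (p^\gamma + (1-p)^\gamma)^{1/\gamma}$ applied
rank-dependently and separately per sign ($\gamma^+, \gamma^-$), and a
logistic choice rule with sensitivity $\theta$ on the value difference. The
split of outcome sensitivity into $\alpha^+/\alpha^-$ and these functional
forms are the dominant convention, adopted here as an explicit assumption;
the forms are isolated in `cpt_value()`/`cpt_decision_weights()` and easy to
swap. All six parameters are bounded to $[0, 2]$ for estimation: a grid of
15 steps per parameter, then L-BFGS-B refinement from the 30 best grid
points (both resolutions configurable; the test suite uses a 5-step grid
with 10 starts). $\gamma$ is floored at $10^{-4}$ inside the weighting
function so the boundary of the grid stays finite. With all transformation
parameters at 1 the subjective value provably equals the expected value,
which doubles as the correctness oracle.

## What the synthetic data emulate — and what they do not

`generate_problem_set()` reproduces the *design* of the target study: 105
problems (41 gain, 31 loss, 33 mixed), two-outcome risky gambles, and 9
problems pairing a risky gamble with a safe option whose payoff lies
strictly between the risky outcomes (the standard non-dominated
construction). The original problems' payoffs and probabilities are not
published, so magnitudes are integers up to 100 money units and
probabilities sit on a 0.05 grid — stated in `problem_set_config()` and
trivially changeable. Problems are rejection-sampled so that expected
values and coefficients of variation differ between options (both
behavioral indicators defined everywhere) unless ties are explicitly
requested; first-order dominated pairs can optionally be excluded.

`generate_population()` draws agents with toolboxes of 2–4 strategies
(mean about 3), $\delta$ from a normal distribution truncated at zero with
mean 2 and SD 3 (mass at zero included deliberately — many decision makers
are fitted as cost-insensitive), and $\epsilon$ normal around 0.26 (SD
0.06) clipped to $[0.01, 0.5]$; these centers correspond to the group-level
summaries typical of this paradigm. The default group contrast is
compositional only: the younger group's toolbox sampling favors
probability-sensitive strategies (MINI, LL, PH), the older group's favors
outcome-only ones (EQW, MAXI).

Passing tests on these data show that the estimation machinery is correct
and that parameters are recoverable *under the model's own assumptions*.
They do not show that real participants obey the model: the generator
contains no domain-specific strategy shifts, no learning or fatigue across
trials, no response-time information, and its problem magnitudes are a
guess at the unpublished originals.

## Problem sizes used by the test suite

The suite freezes the twelve hand-worked decisions; checks all eleven
strategies against an independently written rule-book oracle on 1,000
random problems; verifies $\delta$-monotonicity of the selected cost over
100 random toolboxes on the full $\delta$ grid; equates fitting with brute
force on 50 random micro-grids; runs an S7-style recovery with 20 agents
(toolbox sizes 1–3, $\delta \in [0,5]$, $\epsilon \in [0.05, 0.3]$) on a
105-problem set with the desk grid; recovers known CPT parameters
($\theta = 2$) from 105 simulated choices at the reduced grid; and reruns
the full pipeline twice to confirm bitwise reproducibility. These sizes
were chosen so the whole suite runs in minutes on one core while each check
still exercises the full code path.

## Known limitations

* The strategy set is the canonical eleven; it is not exhaustive, and no
  process-level predictions (information search order, response times) are
  made.
* The EIP scheme is one defensible operationalization; absolute cost levels
  (and hence the absolute scale of $\delta$) should not be
  over-interpreted.
* Toolbox composition is weakly identified from a single 105-trial
  participant — likelihood-equivalent toolboxes are common, which is why
  the fitter reports `n_ties_at_max` and the recovery tooling scores
  overlap against a random-subset baseline instead of expecting identity.
* Inferential statistics (Bayes factors, mixed-effects regressions,
  mediation) are out of scope; the report layer emits the descriptive
  quantities those analyses would consume, plus Cohen's d and Cramer's V as
  closed-form effect sizes.
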