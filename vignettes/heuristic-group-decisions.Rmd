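---
title: "Heuristic agents, majority rule, and the diversity–ability trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic agents, majority rule, and the diversity–ability trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heurigroup)
```

## The task and the model

heurigroup simulates a paired-comparison decision task: which of two
options has the larger value on a continuous criterion (say, which of two
flower patches offers more food), judged from a handful of binary cues.
Options are generated from a linear-Gaussian model

$$Y = \sum_{i=1}^{5} \beta_i X_i + \beta_e X_e,$$

where the cues $X_i$ and the error term $X_e$ are independent standard
normal variables. Binary cues are obtained by dichotomizing each $X_i$ at
its distributional median, 0. Because the perturbed cues used in the
noisy-perception setting are $N(0, 1+\sigma^2)$, their median is also 0;
using the distributional rather than the per-sample median keeps cue coding
identical across learning samples, testing samples and agents. A value
exactly at the cutoff codes as 0 — a probability-zero event for continuous
cues, so this is convention only.

Four bundled environments share almost the same total cue signal
($\sum_i \beta_i^2 / (\sum_i \beta_i^2 + \beta_e^2) \approx 0.865$) but
differ in how it is spread across cues, from highly concentrated to
completely flat:

```{r environments}
sapply(builtin_environments(), function(e)
  c(e$betas, beta_e = e$beta_e, var_expl = round(variance_explained(e), 3)))
```

The quality of a binary cue is its *validity* $V = R/(R+W)$: among option
pairs on which the cue's values differ, the proportion where the option
with cue value 1 has the larger criterion. `compute_validity()` estimates
it from a sample (all pairs, or a random pair subsample);
`objective_validity()` approximates the population value by Monte Carlo —
one million independent option pairs under a dedicated, documented seed
(default 424242), since the population quantity has no convenient closed
form. With $10^6$ pairs the standard error of each validity is about
0.0007. The session RNG stream is left untouched, so simulation runs are
reproducible regardless of when population values are (re)computed or
cached.

## The two heuristics

Both heuristics are one-reason decision makers: inspect cues one at a
time, stop at the first cue on which the two options differ, and choose
the option whose (direction-adjusted) value is 1; if no cue discriminates,
guess by a fair coin flip.

* **Take-the-best** inspects cues in descending order of validity.
* **Minimalist** inspects cues in a uniformly random order.

The classic minimalist redraws its search order for *every* pair decision,
and that is the default here. The alternative reading — one random order
per agent, fixed across decisions — is available as
`run_condition(minimalist_order = "per_agent")` for sensitivity checks; it
mainly lowers a group's search diversity.

A cue whose estimated validity is below 0.5 carries information in the
wrong direction; the learning procedure therefore uses it *reversed*
(treating value 1 as evidence for the smaller criterion) with effective
validity $1 - V$. A cue that never discriminates in a learning sample has
no defined validity and is treated as neutral (effective validity 0.5,
normal direction). Both choices are explicit package decisions: reversal
follows directly from the meaning of $V < 0.5$, and neutrality is the
least-informative default. Ties in effective validity are broken uniformly
at random per agent — in the flatter environments this sampling-driven
tie-breaking is itself a source of between-agent diversity. Objective-order
agents (`objective_agent()`) instead break ties by ascending cue index, so
that agents built from the same validities are exactly identical.

Batch decisions (`decide_pairs()`) are vectorized: the lexicographic
take-the-best decision is the sign of a base-2-weighted sum of per-cue
differences, and the minimalist random order is realized by per-(pair, cue)
uniform priorities, with search stopping at the discriminating cue of
minimal priority. The sequential reference implementation
(`decide_pair()`) is kept as the readable single-pair form, and the test
suite checks that the two routes agree decision-for-decision.

## Groups, scoring and diversity

Members decide independently; the group takes the option with more votes.
Exact ties (possible at even group sizes such as 100) are broken uniformly
at random and flagged, so tie frequency is reportable. Accuracy is the
percentage of decisions whose chosen option truly has the larger criterion
(PC); pairs with exactly equal criteria — probability zero here — are
excluded from scoring and counted.

One deliberate modelling choice concerns guesses in homogeneous groups.
When every member is the same deterministic take-the-best agent perceiving
the same error-free cues, the group has zero diversity: all members search
the same cues and make the same decisions. The simulation honours this by
sharing a single decision stream (including a single guess flip per pair)
across members of such a group, which makes group accuracy *exactly* equal
to individual accuracy and exactly invariant in group size — the defining
feature of the group-size study's take-the-best condition. In every
heterogeneous condition guesses are resolved by independent fair coin
flips per member, so aggregation over guessing members is simulated
faithfully rather than scored as 0.5. (For variance reduction at the
individual level only, `score_guess_half = TRUE` scores a member's guessed
decisions as 0.5; group aggregation always uses the realized votes.)

Group diversity is summarized two ways, both defined by this package:

* *decision diversity* — the mean fraction of member pairs disagreeing on
  a pair decision, computed from the vote split as
  $v_1(m - v_1)/\binom{m}{2}$;
* *search diversity* — the mean number of distinct cues the group
  inspects per pair decision (union of members' searched cue sets).

These are qualitative summaries of the two facets of diversity (what is
decided, what is looked at); no agreement with any external diversity
tabulation is claimed.

## The three study designs

`study_config()` encodes the three designs; `run_study()` sweeps a grid
and returns a tidy table (one row per condition) that `write_results()`
serializes as CSV.

1. **Group size.** Error-free cues, objective cue orders. Take-the-best
   groups are homogeneous (accuracy invariant in $m$); minimalist groups
   gain from size. Testing samples of $n = 15$ options, i.e. 105 pairs;
   group sizes 1, 5, 15, 100.
2. **Individual learning.** Each take-the-best member learns its cue order
   from its own independent learning sample (sizes 10, 15, 25, 50, or the
   population = the objective order), redrawn every replicate, then the
   group of 5 decides a common testing sample. Learning samples are
   redrawn per replicate rather than fixed per agent: each replicate is
   then an independent draw of the whole learning-plus-testing process,
   matching the replicate-averaged design.
3. **Information errors.** Each member perceives each continuous cue with
   independent $N(0, \sigma)$ noise added before dichotomization
   ($i \times m$ independent error sets per sample), $\sigma \in \{0, 0.2,
   0.4, 0.6, 0.8\}$, group size 5. Errors are drawn once per (agent, cue,
   option) and held fixed across all pair comparisons in the sample.
   $\sigma = 0$ takes the noise-free code path exactly, so the zero-noise
   condition is bit-identical to the corresponding error-free run at the
   same seed.

Each condition is fully reproducible from one seed; `run_study()` derives
an independent substream seed per condition from the root seed, so results
are independent of sweep order and any subset of conditions can be
reproduced alone. Replicates run sequentially within a condition.

The full designs use $N = 10{,}000$ replicate samples per condition
(`full = TRUE`). The package's default, used throughout the test suite, is
$N = 2{,}000$: all the qualitative contrasts of interest are stochastic
orderings with margins of one to several percentage points, while the
Monte-Carlo standard error of a condition's PC at $N = 2{,}000$ is on the
order of 0.1–0.2 points, leaving those orderings statistically
unambiguous at a fraction of the cost. Smoke tests and bit-exactness
checks use a few dozen replicates.

## What the generator does and does not emulate

The synthetic environment reproduces exactly the stated generative
structure: independent Gaussian cues, a linear criterion, median
dichotomization, and the four published coefficient profiles. It does not
emulate correlated cues, non-Gaussian cue distributions, cue sets other
than five, option sets with realistic ecological structure, or any
communication between agents (public information). Passing tests
therefore establish the behaviour of the heuristics and of majority
aggregation *within this generative family*, not on real foraging or
judgment data.

## Numerical and degenerate-input choices

* Dichotomization cutoff: distributional median 0; boundary codes as 0.
* Never-discriminating cue: `defined = FALSE`, validity reported 0.5.
* Pair enumeration: $(i, j)$, $i < j$ in option-index order; validity is a
  symmetric count, so order cannot matter.
* Criterion ties within a pair: excluded from validity counts and from
  scoring, and counted (`n_tied_pairs`, `n_excluded`).
* Degenerate learning samples (nothing discriminates) yield agents with a
  random cue order and neutral directions.
* Group-vote ties: uniform random break, logged via `tie_rate`.

## Known limitations

* The homogeneous-group shortcut is exact for its intended case
  (identical deterministic take-the-best members, shared error-free
  cues) and is applied only there; its flip side is that the "all members
  guess independently" reading of that degenerate case is not simulated.
* In the small-difference environment the learned take-the-best group and
  the minimalist group are very close at small learning samples; which
  one is ahead there depends on details of how sub-0.5 validity estimates
  are handled (reversal versus last-place search), and the package's
  reversal rule is one defensible choice among several. The robust
  contrasts — the large-difference ordering, the population-condition
  drop, the learning curve — do not depend on it.
* Population validities are Monte-Carlo approximations; at $10^6$ pairs
  their uncertainty (~0.0007) is negligible for ordering cues whose
  validities differ by 0.01 or more, but exact ties between near-equal
  cues (e.g. in the no-difference environment) are resolved by the
  realized sample, not analytically.
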