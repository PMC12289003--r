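---
title: "Simulating and fitting Bayesian mediation models on chatbot-collected PROs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and fitting Bayesian mediation models on chatbot-collected PROs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promediate)
```

## The scientific setting

Conversational agents are increasingly used to collect patient-reported
outcomes (PROs) in clinical trials: a chatbot asks a patient about fatigue,
stress, and treatment side effects, and the answers become analysis
variables. `promediate` studies a specific analytical question about such
data: how well does a Bayesian mediation model recover the causal pathway
from a randomized treatment to a patient-reported outcome when the data
arrive through a branching dialogue?

The causal structure is the classical single-mediator diagram. Treatment
assignment $X \in \{0, 1\}$ may affect the outcome $Y$ (fatigue severity)
directly, and indirectly through a mediator $M$ (adverse-event severity);
a covariate $Z$ (stress severity) also predicts the outcome:

$$M_i \sim \mathrm{Normal}(i_M + a X_i,\; \sigma_M), \qquad
  Y_i \sim \mathrm{Normal}(i_Y + c' X_i + d Z_i + b M_i,\; \sigma_Y).$$

Following the product-of-coefficients decomposition, the direct effect is
$c'$, the indirect (mediated) effect is $a \cdot b$, and the total effect
is $c = c' + a \cdot b$. All three are computed per posterior draw, so
their credible intervals propagate the joint parameter uncertainty —
including the non-Gaussian shape of the product $a \cdot b$.

## Assumptions of the model

- **Randomization.** $X$ is assigned 1:1 by the trial system, so $X$ is
  independent of all confounders; the causal reading of $a$ and $c'$ rests
  on this.
- **Sequential ignorability.** The mediator equation has no unmodelled
  confounding with the outcome equation; in the simulation this holds by
  construction because the data-generating process (DGP) *is* the model.
- **Linearity and Gaussian noise.** Severities are continuous and
  unclipped. A nominal 0–10 scale motivates the default parameter values,
  but nothing truncates the draws — clipping would bend the linear model
  and bias the simulation study, which is exactly the artifact the study
  is meant to be free of.
- **Conditional independence of the two equations.** Given the data, the
  mediator block $(i_M, a, \sigma_M^2)$ and the outcome block
  $(i_Y, c', d, b, \sigma_Y^2)$ share no parameters, so the Gibbs sampler
  updates them independently. This is an exactness property of the
  likelihood factorization, not an approximation.

## The synthetic-dialogue generator

No real patient data exist for this design, so cohorts are synthetic and
the truth is known. For each subject the generator draws
$Z \sim \mathrm{Normal}(5, 2)$, then $M$ and $Y$ from the equations above,
and renders the triple as a multi-turn transcript following the chatbot's
router: greeting, a fatigue yes/no question, a fatigue severity probe, a
branch-appropriate stress probe, and a side-effect probe. The patient
answers "Yes" to the fatigue question exactly when $Y \ge$
`fatigue_threshold` (default 3.0 on the severity scale); both branches
still elicit all three numeric severities, so every subject contributes a
complete $(Y, Z, M)$ record. Severities are embedded in the text rounded
to `render_precision` decimals (default 2) — the only place rounding ever
happens.

Surface wording is drawn from a fixed bank of at least three variants per
router node, selected by a deterministic hash of the node, the cohort
seed, and the subject index. This stands in for an LLM role-playing the
patient: the statistical content of the dialogue, not its linguistic
variety, is what the downstream stages consume. Consequently the generator
emulates the *information structure* of chatbot-collected PROs (branching
elicitation, numeric severities embedded in free text, trial-side
treatment metadata) but **not** free-text variability, evasive or
inconsistent answers, missing turns, or extraction ambiguity. Passing
tests therefore demonstrate correctness of the statistical machinery under
a well-specified DGP, not robustness to messy real-world dialogue.

Seeding is stream-based: each subject's draws come from a seed derived as
a hash of the cohort seed and the subject index, so enlarging a cohort
never perturbs earlier subjects; replication $r$ of a study uses
`master_seed + r`, so studies can be extended without re-running earlier
replications.

## Extraction

The parser mirrors what a structured-extraction step would do with real
transcripts, under the guarantees the template grammar provides: it takes
the first (and, enforced, only) numeric token of the user turn following
each severity node, reads the fatigue branch off the yes/no answer, and
copies the treatment arm from trial-side metadata — assignment is known to
the trial system, never self-reported. Extraction is fail-fast: a
malformed transcript aborts the cohort with the offending subject named,
because a simulation pipeline that silently drops subjects would corrupt
its own metrics. Round-trip losslessness (render then extract recovers
every value to rendering precision) is a tested invariant.

## Priors, sampler, and numerical choices

All six coefficients and intercepts receive independent
$\mathrm{Normal}(0, 10^2)$ priors and both residual variances receive
$\mathrm{InverseGamma}(0.001, 0.001)$ — weakly informative on a severity
scale where effects are order 0.1–1, and conjugate, which buys an exact
blocked Gibbs sampler: the coefficient vector of each equation is drawn
jointly from its multivariate-normal full conditional, then the residual
variance from its inverse-gamma full conditional. There is no tuning, no
acceptance step, and the draws with fixed variances are iid from the
exact posterior — which is also how the sampler is tested, against the
closed-form conjugate posterior.

Defaults and the reasoning behind them:

| Setting | Default | Why |
|---|---|---|
| chains | 4 | enough for split-chain R-hat to detect non-mixing |
| retained draws/chain | 2000 | pooled 8000 draws; quantile MC error well below reporting precision |
| burn-in/chain | 1000 | generous for a conjugate sampler that mixes in a few iterations |
| initialization | OLS estimate + Normal(0, 0.5·SE) jitter per chain | overdispersed starts make R-hat informative |
| convergence rule | all split-chain R-hat < 1.01 | replications failing it are flagged and excluded, with the count reported |
| interval type | equal-tailed quantile | order-statistic exact and the conventional reading of a "95% credible interval" |
| ESS | chain-averaged autocovariances, Geyer initial-positive-sequence truncation, lag cap 100 | the sampler is near-iid; long lags add only noise |

Residual spread is parameterized internally as the variance
$\sigma^2$ (the conjugate scale) and reported as $\sigma = \sqrt{\sigma^2}$,
the scale on which the metrics tabulate `sigma_m` and `sigma_y`.
Degenerate inputs fail loudly: a single-arm cohort, a constant covariate
(rank-deficient outcome design), fewer than 5 subjects, or non-finite
values are all typed errors, not warnings.

An identifiability note on the noiseless limit: $b$ and $c'$ are separated
only by within-arm variation of $M$, so the posterior SD of $b$ scales
like $(\sigma_Y/\sigma_M)/\sqrt{n}$. Shrinking both noises at the same
rate does *not* concentrate $b$; the package's noiseless-limit test
therefore shrinks $\sigma_Y$ faster than $\sigma_M$, which does pin every
coefficient.

## The simulation study and its metrics

A study runs $R$ replications of simulate → render → extract → fit →
summarize (the rendering/extraction legs can be bypassed with
`use_transcript_path = FALSE`; at high rendering precision both paths give
metrics identical to within rounding, a tested equivalence). Per quantity
$g$ with per-replication posterior mean $\hat g_r$ and 95% interval
$[l_r, u_r]$:

$$\mathrm{Bias} = \overline{\hat g_r - g}, \quad
  \mathrm{RMSE} = \sqrt{\overline{(\hat g_r - g)^2}}, \quad
  \mathrm{Coverage} = \overline{\mathbf{1}\{l_r \le g \le u_r\}}, \quad
  \mathrm{Width} = \overline{u_r - l_r},$$

computed over converged replications only. The table has ten rows: the
eight parameters plus the indirect and total effects (the direct effect
equals $c'$ and would duplicate that row).

The reference study uses $R = 100$ replications of $n = 75$ subjects with
truth $a = 0.4$, $b = 0.5$, $c' = 0.3$, $d = 0.2$, $i_M = 1$, $i_Y = 2$,
$\sigma_M = \sigma_Y = 0.5$ — moderate, detectable effects at trial scale,
and the regime in which the headline claims are checked: maximum absolute
bias of the direct effect, indirect effect, $a$ and $d$ below 0.05, and
coverage of each above 85%. Under this well-specified DGP the study also
satisfies $\mathrm{RMSE}^2 = \mathrm{Bias}^2 + \mathrm{Var}(\hat g_r)$
identically (an algebraic property the metrics code is tested to respect
at $10^{-10}$), and a null study with $a = 0$ checks that the
indirect-effect interval covers zero in at least 90 of 100 replications.

```{r study, eval = FALSE}
study <- run_study(study_config(master_seed = 20240101))
study$metrics
```

Problem sizes in the shipped test suite: unit tests run 2-chain, 600-draw
samplers on cohorts of 16–200 subjects; the reference-scale checks run the
full 100-replication study twice (default and null DGP), a 20-dataset
fixed-variance oracle sweep, 1000 round-trip cohorts, and a 4-replication
path-equivalence study at rendering precision 4 — sizes chosen so the whole
suite completes in a couple of minutes while keeping the headline checks at
the scale at which they are claimed.

## Known limitations

- The dialogue generator is a template renderer; nothing here validates
  LLM-based extraction, free-text parsing, or any natural-language
  robustness property.
- Exact per-cell reproduction of an external results table is not a goal:
  published tables of this design depend on unreported true parameter
  values. The reproduction targets are the structural ones — the table
  layout, the metric definitions, and the headline bias/coverage bounds
  under a declared DGP.
- Single mediator, single covariate, Gaussian likelihoods, complete data.
  Moderated mediation, hierarchical prompt-variability models, binary
  mediators, and missingness are out of scope.
- Coverage estimates over 100 replications carry binomial noise of a few
  percentage points; bounds are set with that in mind.
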