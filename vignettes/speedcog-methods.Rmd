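---
title: "Scoring and analysis methods for web-administered speeded cognitive tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analysis methods for web-administered speeded cognitive tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcog)
```

# The measurement problem

Speeded cognitive tests administered in web panels trade the controlled
testing room for scale: respondents take the tests on their own devices,
in their own environments, with latencies captured in the browser in
milliseconds. Two instruments are covered here:

* a **stop-and-go switching task** (executive functioning): 10 *normal*
  trials (respond "stop" to *red*), 10 *reverse* trials (respond "go" to
  *red*), then a mixed block of 23 *nonswitch* and 6 *switch* trials where
  the rule alternates. The four scores are the median response times per
  trial type, in seconds; slower medians indicate poorer executive
  functioning, and the switch-minus-nonswitch contrast indexes
  set-shifting cost.
* a **figure identification test** (perceptual speed): 60 items, each a
  target figure to be matched among five alternatives. The primary score
  counts figures solved correctly within a *posterior time limit*.

Both instruments inherit two web-specific problems this package is built
around: respondents answer on different device classes (keyboard/mouse vs
touch screen), and a minority answer carelessly, producing latencies that
do not measure the intended construct.

# Scoring rules

## Switching task

A session is exactly 49 scorable trials. Overall accuracy is the fraction
of correct trials out of 49; a session is scored only when accuracy is at
least 0.70 (the bound is inclusive: 35/49 = 0.714 passes, 34/49 = 0.694
does not). Unscored sessions carry no medians: low accuracy signals
careless or inattentive responding, after which the latencies are not
valid measures.

Medians are taken **over correct trials only** by default. The scoring
tradition for this task describes medians "across all trials within each
trial type" without specifying correctness handling; we default to
correct-only because an incorrect response does not reflect the process
being timed, and the 70% gate bounds the induced trial loss (at most 30%
of trials, in practice far fewer). The literal all-trials reading is
available via `include_incorrect_trials = TRUE` and is tested against the
same oracle. Even-count medians are the mean of the two central order
statistics — the ordinary sample median; no latency trimming is applied to
this test (the 30-second rule below is defined only for the figure test).

## Figure identification test

Scoring proceeds in three steps.

1. **Outlier removal.** Latencies strictly above 30 s (the comparison is
   done in milliseconds, `> 30000`, so exactly 30.000 s is retained) are
   removed from the data entirely: they contribute neither clock time nor
   credit, and they leave the accuracy denominator.
2. **Posterior time limit.** The 60 items form two sets by administered
   position (1–30 and 31–60, fixed *before* outlier removal — positions
   are the only stable definition once item blocks are randomized).
   Within each set, retained latencies accumulate in administration
   order; an item scores iff it is correct and the running clock through
   its own response is at most 90.000 s ("within 90 seconds" is read as
   inclusive). The primary score is the sum over both sets, 0–60.
3. **Validity gate and secondary measures.** Accuracy is correct
   non-outlier figures over non-outlier figures; sessions below 70%
   accuracy are not scored. The secondary measures deliberately ignore
   the time limit: `pct_incorrect` is `100 * (1 - accuracy)` and
   `median_rt_correct_s` is the median latency over *all* correct
   non-outlier figures, separating the accuracy and speed components the
   primary count conflates.

The 90-second-per-set limit replaces the legacy 120-second live limit of
the paper-and-pencil form, which produces ceiling effects in electronic
administration; 120 s remains available as a parameter
(`scoring_limits(set_limit_s = 120)`) but is not a supported score. The
score is provably monotone in the limit, which the suite asserts.

## Item-block balancing

To remove order effects, the 60 items are administered in 6 randomized
blocks of 10, and the blocks should be comparable in difficulty.
`design_item_blocks()` ranks items by pilot median response time, splits
the ranking into consecutive groups of 6, and assigns each group's items
one-per-block at random — a stratified randomization guaranteeing every
block spans the difficulty range. The draw is repeated (500 times by
default) and the best draw kept.

"Similar overall median and IQR across blocks" needs a concrete
objective; ours is the across-block variance of the per-block median of
item medians plus the across-block variance of the per-block IQR of item
medians, each standardized by the corresponding across-item variance so
the two scale-free terms are commensurable. Ties are broken by the lowest
iteration index, and a degenerate bank (identical item statistics) yields
objective 0 at iteration 1. On small instances the sampled optimum is
verified against exhaustive enumeration of all constrained assignments.

# Comparison statistics

**Cohen d.** Device effects are standardized mean differences
$d = (\bar{x}_{touch} - \bar{x}_{kb}) / s_p$ with the $(n-1)$-weighted
pooled SD, and a normal-approximation CI
$d \pm 1.96\,\sqrt{\tfrac{n_1+n_2}{n_1 n_2} + \tfrac{d^2}{2(n_1+n_2)}}$.
Feeding the published group summaries (rounded to 2 decimals) reproduces
the published $d$ for five of six reproducible rows to within ±0.015; the
nonswitch row is not recoverable from its rounded inputs (0.92/0.97 with
SDs 0.32/0.34 imply 0.15, not the printed 0.13), which we attribute to
input rounding and exclude rather than absorb with a wider tolerance.

**Cohen q.** Age-correlation differences across device groups use the
Fisher-z contrast $q = \operatorname{atanh}(r_{kb}) -
\operatorname{atanh}(r_{touch})$; the keyboard-minus-touch sign
convention matches every published contrast.

**Regression and partial correlation.** Distraction effects are estimated
by OLS of each score on age plus the eight binary environment indicators,
with conventional SEs and t-based p-values on complete cases; age is a
covariate because both cognitive performance and distraction exposure
vary with age. No multiplicity adjustment is applied (effects are read at
$\alpha = .05$, unadjusted). Partial correlations are correlations of OLS
residuals. Environment indicators that do not vary in the analysis sample
(the rarest distractors at small $n$) are dropped from the model by the
pipeline rather than failing the run; `ols_regression()` itself treats
rank deficiency as an error naming the offending column.

**Weighted norms.** Population norms are weighted means by age group
(18–34, 35–44, 45–54, 55–64, 65–74, ≥75) with
$SE^2 = \sum w_i^2 (x_i - \bar{x}_w)^2 / (\sum w_i)^2$, a
linearization-style estimator whose unit-weight special case is exactly
the large-sample (1/n-variance) CI — the identity the suite checks to
1e-12. The CI method behind the published norm tables is not stated;
this choice is a package convention. Groups of size 1 report a mean with
an unavailable CI.

# The synthetic cohort

No public microdata exist for the motivating panel study, so the
generator is the package's test bed and worked-example source. Per-trial
log-latency for respondent $i$ is

$$\log t_{ij} = \mu_{c(j)} + \beta_{age}(a_i - 50) + \delta_{dev}
\mathbb{1}[\text{touch}] + \delta_{int}\mathbb{1}[\text{interrupted}] +
u_i + \varepsilon_{ij},$$

with $u_i \sim N(0, \sigma_p^2)$, $\varepsilon_{ij} \sim N(0,
\sigma_t^2)$ — lognormal latencies with multiplicative covariate effects,
so medians transform cleanly and right skew is built in. Defaults:

| parameter | default | rationale |
|---|---|---|
| trial-type medians at age 50 | 1.00 / 1.10 / 0.95 / 1.50 s | magnitudes of the published mid-age score tables |
| item medians | 60 values log-spaced over 3–7 s | published figure-test latency range |
| `beta_age` | 0.006 / yr | ≈38% slowdown over 54 years, matching the published norm gradient |
| `delta_device` | 0.05 | small touch-screen slowdown, $d \approx 0.1$–0.2 |
| `delta_interrupt` | 0.08 | interruption effect comparable to ~10 years of age |
| `sigma_person`, `sigma_trial` | 0.25, 0.20 | between/within-person spread giving SD-to-mean ratios near the published tables |
| ages | discretized $N(50, 16)$ truncated to 18–101 | published sample mean 49.6–50.5, SD ~16 |
| `careless_fraction`, `p_correct_careless` | 0.05, 0.55 | a careless minority that the 70% gate catches ~97% of the time (binomial tail) |
| `p_outlier` | 0.002 | matches the ~99.8th-percentile origin of the 30-s cut |
| environment prevalences | interruption 12.5%, at home 89.6%, TV 15%, ... | published distraction frequency table |

Careless respondents draw latencies at 0.6× the attentive scale
(rushing) and correctness at 0.55. Interruption is drawn per session and
applied to all its trials; per-trial distraction is not modeled because
the self-reports are per session. Weights are inverse-inclusion weights
over age band × education: the population shares are fixed constants, the
sampling shares are the analytic shares implied by the generator's age
law and education sampling probabilities, and the ratio is normalized to
mean 1 — the simplest structure under which weighted and unweighted norms
genuinely differ.

Reproducibility uses a named-substream scheme: each respondent's draws
come from a seed derived from (master seed, respondent index), so
enlarging a cohort leaves earlier respondents' data bit-identical.

**What the generator does not emulate.** Three simplifications matter
when reading test results:

* Device ownership is independent of age, unlike the real panel where
  touch-only owners skew young. This makes the between-person device
  contrast an unbiased estimate of the generative device effect — which
  is what the parameter-recovery checks need — but it removes the
  ownership confounding a real analysis must worry about.
* There is no occasion (session-level) variance component beyond
  interruption, so simulated cross-device correlations of person scores
  (~0.9) exceed the 0.37–0.83 range seen in real repeated sessions.
  Test-retest structure is out of scope.
* Correctness is age-independent, so the percent-incorrect score has no
  age correlation by construction; tests assert it is near zero rather
  than signed.

Passing tests therefore demonstrate that the scoring and analysis
machinery recovers the parameters of *this* generative law, not that the
law captures every feature of panel data.

# Numerical conventions and problem sizes

Latencies are stored in integer-or-real milliseconds and converted to
seconds exactly once, inside scoring — boundary rules (30-s outlier cut,
90-s set limit) are evaluated in milliseconds to avoid float-second
ambiguity. The oracle-equivalence checks run 10,000 randomized sessions
per test and require exact equality; parameter recovery uses cohorts of
2,000 per device group against a brute-force generative-law oracle of
about $10^6$ trials, with agreement required within three standard errors
of the estimated effect; norm monotonicity uses a 5,000-respondent
cohort. These sizes give Monte-Carlo error comfortably below every
tolerance asserted.

# Limitations

The package scores and analyzes; it does not administer. Browser event
capture, device detection, recruitment and weight construction are
consumed as inputs. Norms produced from synthetic cohorts are
illustrations of the machinery, not population reference values, and no
clinical cutoffs are derived — the instruments' authors explicitly
disclaim diagnostic use.
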