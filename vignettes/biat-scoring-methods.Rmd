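---
title: "Scoring the Brief IAT: model, data treatment, and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the Brief IAT: model, data treatment, and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biatscore)
library(dplyr)
```

## The measurement problem

The Brief Implicit Association Test (BIAT) measures the strength of a
conceptual association by contrasting response latencies between two
speeded-categorization conditions. A respondent completes a 16-trial
practice block and four 20-trial response blocks; within a focal polarity,
blocks 2 and 4 present one category pairing (condition 1) and blocks 3 and
5 the other (condition 2). Each block opens with four category-only warm-up
trials. On an error, the task waits for the correct key, so a trial's
latency always runs from stimulus onset to the correct response.

The construct of interest is a per-respondent contrast between the two
conditions. The naive contrast — the difference of mean latencies — is
vulnerable to a well-documented artifact: people who respond slowly overall
also have larger trial-to-trial variance, so the same association produces
a larger millisecond difference in a slow respondent than in a fast one.
This package implements the recommended answer to that problem, the **D
transformation**, together with its conventional competitors and the
psychometric machinery needed to compare them.

## The D statistic

For one pair of blocks, with $n_1$ latencies in condition 1 and $n_2$ in
condition 2 ($N = n_1 + n_2$):

$$D = \frac{M_2 - M_1}{SD}$$

where $M_1, M_2$ are the condition means and $SD$ is the standard deviation
of all $N$ latencies pooled across both conditions — deliberately *not* the
pooled within-condition SD. Because the between-condition separation itself
contributes to the denominator, $D$ is bounded: for equal block sizes,
$|D| = 2\sqrt{(N-1)/N} < 2$ for two constant blocks, and no configuration
exceeds 2. $D$ is invariant to a positive rescaling and to a constant shift
of all latencies, which is exactly what removes the respondent-speed
artifact.

The session score computes $D$ separately for each pair of blocks that
spans both conditions (blocks 2+3 and 4+5 in the standard alternating
design) and averages the two pair scores. Pooling all four blocks into one
$D$ is measurably different and is not what this package does; the two
half-scores also feed the internal-consistency analysis directly.

The competitor transformations share the sign convention "slower in
condition 2 ⇒ positive": the raw latency difference (ms), the log-latency
difference, and the reciprocal difference computed as
$\overline{1000/x_1} - \overline{1000/x_2}$ (reversed subtraction, since a
reciprocal measures speed rather than slowness).

**Numerical choices.** The pooled SD uses the sample ($N-1$) denominator.
This is not dictated by the definition above, which says only "the standard
deviation of the N latencies"; we follow common D-score practice and expose
the choice as `sd_denominator` in `biat_config()` (the population-SD
variant rescales every score by $\sqrt{N/(N-1)}$ and reaches exactly 2 on
the degenerate construction). A pair whose pooled latencies are constant
has no defined $D$; the single-pair functions raise an error, while the
bulk scorer flags the session (`exclusion_reason = "degenerate_pair"`)
and continues.

## The data-treatment pipeline

`score_sessions()` applies the recommended treatment in a fixed order:

1. remove trials slower than 10,000 ms (inattention; never recoded);
2. remove the four warm-up trials of each response block;
3. apply the error-trial policy — **retain** by default, since the latency
   already includes the error-correction delay and that delay carries
   construct-relevant information;
4. recode latencies below 400 ms to 400 and above 2000 ms to 2000
   (deletion, other boundaries, or no treatment are configurable);
5. compute the per-pair scores and average;
6. exclude tasks with more than 10% of responses faster than 300 ms
   (optionally also tasks above a 30% or 40% error rate).

All comparisons are strict: a trial at exactly 10,000 ms, 400 ms, or
2000 ms is untouched, and a task at exactly the 10% fast fraction is kept.
The fast fraction and error rate are computed on scored-block trials
*after* the hard cutoff and warm-up removal but *before* the error policy
and tail recoding. The ordering matters and is the only self-consistent
one: recoding to a 400 ms floor would erase the sub-300 ms signal the
exclusion rule needs, and removing error trials first would make the error
rate trivially zero. Exclusion only masks scores — it never changes the
retained sessions' values — whereas moving the recode step after scoring
would change results; both properties are asserted in the test suite.

Every stage reports its trial counts in a manifest
(`run_manifest(scores)`), and the counts reconcile exactly: input =
practice block + removals at each stage + trials scored.

## The synthetic population

Because the evaluation battery needs populations, not single sessions, the
package ships a seeded generator. Subject $i$ has a true association
effect $a_i \sim N(\mu_a, \sigma_a)$ (ms of slowing in condition 2) and a
multiplicative speed factor $\lambda_i$, log-normal with log-SD
$\sigma_\lambda$. A trial latency is

$$x = \lambda_i\,(\text{base} + a_i\,[\text{cond 2}]) + \lambda_i\,\varepsilon,
\qquad \varepsilon \sim \text{exGaussian}(\mu, \sigma, \tau)$$

The ex-Gaussian noise (Gaussian plus exponential tail) is the standard
right-skewed response-time model; the slow tail is what the 2000 ms recode
clips. Scaling both the base and the noise by $\lambda_i$ produces the
mean–variance coupling that makes unstandardized difference scores
speed-confounded — the artifact $D$ exists to remove. Error trials occur
with a base probability and add an exponential correction delay; a small
fraction of subjects are fast-guessing contaminants (uniform latencies on
150–350 ms, 50% errors) that the fast-response exclusion rule should
catch. A standard normal group covariate correlated with $a_i$ supports
known-group analyses.

Defaults, chosen once as field-realistic values: base latency 700 ms,
effect mean 60 / SD 80 ms, speed log-SD 0.25, noise $\sigma$ 100 ms and
$\tau$ 150 ms, 8% error rate with ~300 ms mean correction delay, 5%
contaminants, group–effect correlation 0.5, 1000 subjects. Latencies are
floored at 100 ms so the log and reciprocal transforms stay defined in
extreme draws. Each subject draws from a deterministic RNG substream, so
enlarging a population never perturbs existing subjects.

**What the generator does and does not emulate.** It reproduces the block
structure, right-skewed latencies, error-correction delays, speed-coupled
variance, and fast-guessing contamination. It does *not* model block-order
effects, practice/fatigue drift within a session, stimulus-level
variation, or any good-focal/bad-focal validity difference (polarity is a
label, optionally with a noise multiplier — the mechanism behind the
empirical good-focal advantage is unknown and we do not invent one). One
consequence worth flagging: because subject speed is *purely*
multiplicative here, the log transformation cancels it exactly and the
log difference looks artificially speed-stable in simulation. In real
data, where speed effects are not exactly multiplicative, the log
difference does not enjoy that protection. Passing tests on this
population therefore demonstrate the pipeline's mechanics and the
D-versus-latency-difference contrast, not a full empirical ranking of all
four transformations.

## The evaluation battery

For a set of session scores the package computes:

- **Main effect**: Cohen's d of the mean score against zero.
- **Internal consistency**: the Pearson correlation between the two
  half-scores, plus two-half Cronbach's alpha and the Spearman–Brown
  projection $2r/(1+r)$ (the two coincide for equal-variance halves; both
  are reported because conventions differ).
- **Criterion correlations**: Pearson r per covariate with listwise
  deletion, averaged on Fisher's z scale
  ($\bar r = \tanh(\overline{\operatorname{atanh} r})$). Perfect
  correlations have no finite z and are excluded from the average.
- **Extraneous influence**: r between the score and the respondent's mean
  latency, mean log latency, and mean reciprocal — smaller magnitudes are
  better.
- **Latency operating characteristic (LOC)**: respondents ranked by mean
  latency, cut into 10 near-equal bins, each bin's mean score divided by
  the full-sample score SD. Bin sizes differ by at most one; the remainder
  is allocated one-per-bin from the fastest end, and latency ties break by
  session id, so the construction is deterministic. A flat profile
  indicates speed resistance.
- **Stability regression**: OLS of the score on the centered first four
  powers of mean latency; a small multiple R (overall F-test p reported)
  indicates stability. Centered raw powers and orthogonal polynomials give
  identical R; we use raw powers and do not report coefficients. The
  statistic is invariant to affine rescaling of the predictor.

`compare_configurations()` crosses treatment configurations with
transformations and focal polarities, evaluates every cell (per-cell
failures are flagged, never fatal), and `rank_configurations()` orders the
cells per criterion — larger is better for effect sizes and correlations
with criteria, smaller magnitude is better for speed-confound statistics.
No multiple-testing correction is applied anywhere: the battery reports
descriptive r and p values, as is conventional for this kind of
algorithm comparison.

```{r harness, eval = FALSE}
sim <- simulate_biat(biat_sim_params(n_subjects = 400), seed = 3)
cmp <- compare_configurations(
  sim$trials, biat_config(),
  transformations = c("D", "latency_diff", "log_diff", "reciprocal_diff"),
  covariates = dplyr::select(sim$truth, session_id, group)
)
rank_configurations(cmp)
```

On such a population the latency difference shows the largest correlation
with mean latency and the widest LOC range, and D is markedly more stable
— the qualitative pattern the transformation was designed for. (The log
difference also looks stable here for the generator-specific reason given
above.)

## Problem sizes and determinism

The test suite exercises populations of 300–1000 subjects (a 1000-subject
population is ~96,000 trials and scores in under a second; generation
takes a few seconds). The bound on $|D|$ is probed with $10^5$ randomized
equal-size block pairs plus the closed-form degenerate construction. All
stochastic tests fix seeds; identical seeds and parameters give
byte-identical populations.

## Known limitations

- Only the forced-error-correction procedure is supported; variants where
  errors are not corrected need a penalty-based scoring scheme that is out
  of scope here.
- The generator's contaminants are a single stylized type (uniform fast
  guessing); real non-compliance is more varied.
- Respondent exclusion is evaluated per task (session × focal polarity),
  so one polarity of a respondent can be excluded while the other is kept.
- Scores for sessions with missing or degenerate pairs are flagged `NA`
  rather than imputed.
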