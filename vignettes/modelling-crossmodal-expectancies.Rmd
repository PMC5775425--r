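---
title: "Modelling crossmodal cue-predictability learning from response speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crossmodal cue-predictability learning from response speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmcue)
```

## The scientific problem

In a multisensory location-cueing (Posner) paradigm an auditory cue
("left"/"right") predicts the side of an upcoming target that can be either
visual or tactile. The probability that the cue is valid — the *cue
predictability* — is fixed within a block but differs between the two target
modalities, creating two concurrent probabilistic contexts. The question the
package's models address: when a subject responds to, say, a visual target,
is their spatial expectation driven by the visual cue predictability alone
(separate, modality-specific attention), by the average of the visual and
tactile predictabilities (supramodal attention), or by something in between?

`xmcue` implements the full trial-wise analysis chain: an ideal-observer
learning model per modality, a weighted integration of the two
modality-specific estimates, a linear response-speed observation model, per
subject maximum-likelihood estimation of the integration weight, an
alternative no-learning model, and group-level random-effects Bayesian model
selection. Because raw data from such studies are typically not deposited,
the package also ships a first-class synthetic-cohort generator with known
ground truth, and parameter-/model-recovery studies built on it.

## The ideal observer

Within a block, validly and invalidly cued targets of one modality form a
Bernoulli sequence with unknown success probability $p$ (the cue
predictability). With a uniform Beta(1, 1) prior — both outcomes equally
likely at the beginning of each block — and observed counts $N_1$ valid and
$N_0$ invalid outcomes, the posterior is Beta$(1 + N_1, 1 + N_0)$ and the
observer's estimate is its mean,

$$\hat p = \frac{N_1 + 1}{N_1 + N_0 + 2}.$$

`run_observer()` tracks this quantity separately for visual and tactile
targets, recording for every trial the estimates *before* that trial's
outcome is seen: the expectation a subject can act on at trial $t$ comes
from trials $1 \dots t-1$. Three conventions matter and are fixed in the
code:

* beliefs reset to the uniform prior at every block boundary (predictability
  is constant within but not across blocks);
* each learner is updated only by its own modality's trials, but the
  prediction at trial $t$ reflects everything presented up to $t - 1$ in
  either modality;
* all *presented* trials update the beliefs, including trials later excluded
  from the behavioral likelihood — the cue–target contingency is observed
  whether or not the response was usable. The exclusion rules therefore only
  gate which trials enter the likelihood.

## Integration and the response model

The expectation entering a trial with a target of modality $m$ is a linear
mixture of the two modality-specific estimates,

$$p_{int} = w\,p_{m} + (1 - w)\,p_{m'},$$

with the weighting factor $w \in [0, 1]$: $w = 0.5$ is full averaging
(supramodal processing), $w = 1$ fully separate processing, and $w < 0.5$
weighs the other modality more. Although one source prints the range as a
set, the interior is clearly intended (weights below 0.5 are interpreted),
so the closed interval is used throughout.

Response speed ($RS = 1/RT$, in 1/s; speeds are used because they are closer
to normally distributed than RTs) is modelled linearly in the expectation,
separately per cue-validity condition:

$$RS^{(t)} =
\begin{cases}
\zeta_{1,valid} + \zeta_{2,valid}\; p_{int}^{(t-1)} & \text{valid trials}\\
\zeta_{1,invalid} + \zeta_{2,invalid}\,(1 - p_{int}^{(t-1)}) & \text{invalid trials,}
\end{cases}$$

with homoscedastic Gaussian noise of SD $\sigma$ per fitting unit. The
intercepts set the overall speed level; the slopes measure how strongly
speed follows the expected (in)validity. RTs are converted to seconds before
inversion so that $\zeta$ lives on an interpretable scale (about 2–2.5 1/s
for 400–500 ms responses). The $\zeta$ are not sign-constrained.

## Trial screening

`filter_trials()` applies the standard two-stage screening per subject:
incorrect responses, misses and anticipations (RT < 100 ms, strictly) are
dropped first; then trials deviating more than 2 SD from the subject's mean
RT — mean and SD computed over the stage-1 survivors of the whole session,
in a single pass without re-trimming — are dropped as outliers. The 2-SD
statistics could alternatively be computed per block or iterated to a fixed
point; the session-wide single pass is the simplest deterministic reading
and is what the package does. Each record carries exactly one label
(`kept`, `incorrect`, `miss`, `anticipation`, `outlier`), so the labels
always partition the input — a property the test suite asserts on random
tables.

## Estimation

`fit_weighting()` estimates $(w, \zeta, \sigma)$ for one subject and target
modality (per block, or with one shared parameter set across the
concatenated session) by profiled maximum likelihood. $w$ is the only
non-linear parameter: on a grid over $[0, 1]$ (step 0.01, then
golden-section refinement around the best grid point) the four $\zeta$ are
profiled in closed form by per-condition least squares and $\sigma^2$ is the
maximum-likelihood residual variance. The original analysis used variational
Bayes with unpublished priors; profiled ML over a 1-D grid is deterministic,
dependency-free and — because every nuisance parameter has a closed-form
profile — the grid itself is an almost exact oracle for the likelihood
surface, which the tests exploit by re-deriving it through `lm()`.

Numerical conventions:

* a validity condition with fewer than 3 kept trials, or with an effectively
  constant predictor, gets an intercept only (its slope is fixed at 0 and
  flagged); blocks with 10% predictability leave about 4 invalid trials, for
  which a free slope would be meaningless;
* a fitting unit with fewer than 6 kept trials returns a flagged failure
  record instead of raising, so cohort runs survive sparse subjects;
* if the likelihood is flat in $w$ (range below $10^{-8}$ nats across the
  grid, e.g. when both slopes are fixed at zero so $w$ enters nowhere), the
  fit is flagged `w_unidentified` and `w_hat` is `NA`;
* an exact fit ($SSE = 0$) floors the variance at the smallest positive
  double rather than producing an infinite likelihood.

Model evidence is BIC by default, $\log L - \tfrac{k}{2}\log n$, with $k$
counting $w$, the free slopes/intercepts and $\sigma$. A Laplace
approximation (numerical Hessian of the unprofiled likelihood) is available,
but BIC is the default deliberately: boundary optima of $w$ make the
Hessian indefinite and force method fallbacks that would compare the two
candidate models on different footings.

### Identifiability of w: a caveat worth knowing

In designs whose blocks pair *complementary* predictability levels
(90/10, 70/30), the two learners' trajectories are nearly mirror images,
$p_{m'} - 0.5 \approx -(p_m - 0.5)$, so

$$p_{int} - 0.5 \approx (2w - 1)(p_m - 0.5).$$

The likelihood then has a near-exact ridge: halving $(2w - 1)$ and doubling
$\zeta_2$ produces almost the same predictions. $w$ is identified only
through the stochastic asymmetries between the two trajectories, and
per-block estimates at realistic noise ($\sigma = 0.2$ 1/s against slopes of
0.5) are correspondingly unstable — simulation puts the per-block median
absolute error near 0.26 even though the noiseless limit recovers $w$ at
grid resolution, and an oracle given the true $\zeta$ and $\sigma$ still
shows substantial spread. Concatenating blocks (one $w$ per subject and
modality) pools the asymmetries and roughly halves the error. For this
reason every `weight_fit` also carries `w_mean`, the posterior mean of $w$
over the grid under a uniform prior (with profiled nuisances): unlike the
arg-max it stays interior when the profile is ridge-flat, which is closer in
spirit to the posterior-mean estimates a variational scheme reports.
`recovery_experiment()` tabulates both estimators at both levels so the
trade-off is visible rather than hidden.

## The alternative model and group-level selection

The no-learning alternative (`fit_constant_model()`) replaces the learner's
trajectory with one constant predictability per block (free, estimated),
keeping the $\zeta$ and $\sigma$ shared across blocks: predicted RS is then
constant within each block-by-validity cell. Estimation alternates two
closed forms — $\zeta$ by per-condition regression given the block
constants, each block constant by its analytic optimum (clipped to
$[0, 1]$) given $\zeta$ — which decreases the residual sum of squares
monotonically; iteration stops on a $10^{-12}$ relative change. Block
constants are initialized at each block's empirical valid fraction, kept
away from the boundary for identifiability. The parameter count is
$n_{blocks} + n_{free\ \zeta} + 1$.

`rfx_bms()` compares models across subjects treating the model identity as
a random effect (each subject may use a different model): a variational
scheme iterates per-subject posterior model assignments — a softmax of log
evidence plus digamma of the Dirichlet pseudo-counts — against the
Dirichlet update, from a uniform Dirichlet(1) prior. Exceedance
probabilities come from seeded Monte Carlo over the posterior Dirichlet
(10^6 draws by default; for two models the exact Beta integral is used as a
test oracle and agrees to well under $10^{-3}$). The Bayesian omnibus risk —
the posterior probability that all models are equally frequent — is
$1/(1 + e^{F_{rfx} - F_{null}})$ from the two variational free energies, and
protects the exceedance probabilities:
$pxp = xp\,(1 - bor) + bor/K$. In the strong-evidence limit the variational
$bor$ matches the closed-form Bayes factor of the two hypotheses to
machine precision (asserted in the tests), and with fully symmetric
evidence $pxp$ is exactly $1/K$ for any $bor$, as the formula requires.

## What the synthetic cohorts emulate — and what they do not

`simulate_subject()` composes the forward model: seeded balanced trial
sequences for the chosen design (exact valid/invalid quotas per block and
modality — predictability is a design property, not a sampling rate — with
cue sides and target elevations balanced and modalities interleaved by
shuffle), the observer's trajectories, the weighted integration with the
subject's true $w$, and Gaussian RS noise around the linear response model.
RT is $1000/RS$ ms. Defaults mirror the study conditions: 21 subjects per
cohort; 6 blocks × 80 trials (exp1/exp2 designs, 480 trials) or 4 × 80
(exp3, 320 trials); intercepts 2.2/2.0 1/s, slopes 0.5, $\sigma = 0.2$ 1/s,
which put mean RT in the low-400 ms range reported for such tasks. The
exact block-to-level pairing of the six exp1/exp2 blocks is not recoverable
from the published text; the shipped default — (90,50), (50,90), (70,30),
(30,70), (90,70), (30,50) — makes every level occur in each modality with
both divergence signs and is overridable via `standard_design(blocks =)`.

Two generator-only conventions: simulated RS is floored at 0.2 1/s (RT at
most 5 s) to keep Gaussian tails from producing non-positive speeds, and
behavioral errors are off by default (the response model concerns RS only);
an optional `error_rate` marks a seeded fraction of trials incorrect to
exercise the screening rules. When generating from the constant model,
each block's constant is drawn uniformly on $[0, 1]$ — the parameter's own
prior — so that model recovery probes the model's full generative range
rather than only the special case where its predictions coincide with the
learner's asymptote (under that special case the two models are nearly
indistinguishable by construction, and no evidence approximation can
separate them).

The generator deliberately omits several features of real data: sequential
RT autocorrelation, fatigue and practice drifts, miss/anticipation timing
processes, eye movements, and any volatility in the true predictabilities.
Passing recovery studies therefore demonstrate that the pipeline inverts
its own generative assumptions — a necessary condition — not that those
assumptions hold for any particular empirical dataset.

## Problem sizes and runtime

The shipped studies are sized to run comfortably on one CPU: recovery uses
21-subject cohorts (168 per-block fits plus 42 concatenated fits for exp3),
model recovery two 21-subject exp1 cohorts with both models fitted per
subject and modality, the observer oracle enumerates all 4096 binary
sequences of length 12, and Monte Carlo exceedance uses $10^6$ Dirichlet
draws. A full pass of everything takes well under a minute per study.

## Known limitations

* Per-block $w$ at realistic noise is weakly identified in complementary
  designs (see above); group-level conclusions should lean on concatenated
  fits or on many subjects.
* BIC is a large-$n$ approximation; with ~40 kept trials per block it is a
  coarse stand-in for the variational evidence of the original analysis,
  and model comparison outcomes near the decision boundary should be read
  with that in mind.
* The constant model's block constants trade off against its slopes (only
  $\zeta_1 + \zeta_2 p_b$ is determined per cell); this does not affect its
  predictions or evidence, but individual `p_const` values should not be
  over-interpreted.
* The group-level mixed-model analysis of $w$ against block factors is out
  of scope by design: `export_w_table()` emits the tidy table (estimates
  plus predictability distance and signed/absolute divergence recomputed
  from the design) for use with `lme4` or similar.
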