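---
title: "Models and methods in jointddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in jointddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointddm)
```

# The scientific problem

Two-choice motion discrimination in children produces, per trial, a choice
(left/right) and a response time. The diffusion model decomposes this joint
distribution into interpretable stages: evidence accumulates from a starting
point $z$ at drift-rate $v$ (with within-trial noise $s$) toward one of two
bounds separated by $a$; the observed RT adds a non-decision time $t_{er}$
covering encoding and motor output. Group comparisons (here: autistic versus
typically developing children) are then phrased as differences in these
parameters rather than in raw accuracy or speed, and a response-locked EEG
build-up signal over centro-parietal sites can be linked to the drift-rate
in a joint model.

This package implements the full analysis chain — exact Wiener
first-passage-time (WFPT) numerics, the hierarchical Bayesian
group-difference model, a differential-evolution MCMC (DE-MCMC) sampler
with chain migration, Savage–Dickey Bayes factors, joint bivariate models
linking drift to an EEG slope or to ADHD symptom scores, and the EEG
pipeline that produces that slope — together with a synthetic-data
generator whose ground truth makes every stage testable by parameter
recovery.

# Diffusion numerics

The WFPT density is evaluated with the standard small-time/large-time
series, switching automatically to whichever needs fewer terms, truncated
at an absolute error of $10^{-7}$ (configurable). Parameters are first
standardised by $s$ ($a' = a/s$, $v' = v/s$, $w = z/a$), which makes all
quantities invariant under a joint rescaling of $(a, z, v, s)$ — $s$ is
fixed at $0.1$ by convention purely to resolve this degeneracy. The
defective CDF of each bound uses the large-time exponential series with a
sin-free envelope as the truncation criterion (the terms themselves
oscillate through zero, so a term-magnitude stopping rule would truncate
prematurely). Timeout trials enter the likelihood through the survivor
function at the 2.5-s deadline: a no-response trial is a non-terminating
accumulation trajectory, not missing data.

Trial simulation inverts the defective CDFs by bisection, which is exact up
to series truncation; an independent Euler–Maruyama route with a
Brownian-bridge correction for within-step crossings (and interpolated
crossing times) is provided and used in the tests as a brute-force oracle
for the analytic code. Responded trials with RT at or below $t_{er}$ have
zero density; the log-likelihood returns $-\infty$ so that a sampler
rejects such proposals rather than aborting.

Two response codings are supported. Stimulus coding (the default) puts the
rightward response at the upper bound, flips the drift sign for leftward
stimuli, and reads $z/a$ as a left/right response bias — matching the
motivation of the starting point as a bias between the two response bounds.
Accuracy coding (upper = correct) is available behind a switch since fits
in this literature use both conventions.

# The hierarchical model

Each participant contributes $a_p$, $z_p/a_p$, $t_{er,p}$, and two drifts
parameterised as an across-level average $(v_{p1}+v_{p2})/2$ and difference
$v_{p1}-v_{p2}$ (level 1 = easy, so a positive difference means
easier-is-faster). Group-level laws are truncated normals on positive
(or unit-interval) support — with the truncation normalising constants
included — and plain normals for the drift moments:

* $a_p \sim N_+(\mu_a \pm \delta_a, \sigma_a)$, similarly for $t_{er}$;
* $z_p/a_p \sim TN_{(0,1)}(\mu_z \pm \delta_z, \sigma_z)$;
* drift average and difference $\sim N(\mu \pm \delta, \sigma)$.

The $\pm$ convention is $+\delta$ for the autistic-labelled group and
$-\delta$ for the comparison group, so the group difference is $2\delta$
and positive $\delta$ means a larger value in the autistic group.
Hyperpriors: $\mu_a \sim N_+(0.2, 0.2)$, $\mu_z \sim TN_{(0,1)}(0.5, 0.2)$,
$\mu_{ter} \sim N_+(0.3, 0.3)$, $\mu_{v.diff} \sim N(0, 0.1)$,
$\mu_{v.mean} \sim N(0.3, 0.3)$, every $\sigma \sim \Gamma(1, 1)$
(shape–rate), every $\delta \sim N(0, 0.01)$. Throughout, the second
argument of a normal is a standard deviation — the convention of the
hierarchical-diffusion literature these priors come from.

Covariate partialling (performance IQ, age, reading, spelling) is
implemented as a linear term on the group-level mean of *every* model
parameter, $\mu \pm \delta + \beta x_p$, with standardised covariates and
$\beta \sim N(0, 0.5)$. This analysis tradition reports covariates as
"partialled out" without committing to a mechanism; this design reproduces
the logic of "partial out, then compare $\delta$" and is deliberately
uniform across parameters. It is the one structural choice here with no external
specification, so it is worth flagging prominently.

# Sampling

The posterior is sampled with DE-MCMC: proposals are scaled differences of
two randomly chosen other chains plus a small uniform jitter
($\pm 0.001$), Metropolis-accepted. Defaults follow the study protocol
(15 interacting chains, 4000 iterations, 1500 burn-in, migration every 14
iterations between iterations 500 and 1100; joint models: 3000/1000, no
migration). Implementation choices, all standard DE-MCMC practice:

* **Blocking.** One block per participant (5 parameters,
  $\gamma = 2.38/\sqrt{2\cdot 5}$), and the hyper parameters in
  $(\mu, \sigma, \delta[, \beta])$ sub-blocks per model parameter. The
  hyper block as a single 15-dimensional proposal mixes poorly along the
  $(\mu_z, \sigma_z)$ ridge that appears when $\sigma_z$ is large enough
  to make the truncated-normal likelihood insensitive to $\mu_z$.
* **Step-size randomisation.** The DE step is scaled by a fresh
  $U(0.5, 1)$ factor per proposal.
* **Scale parameters on the log scale.** All $\sigma$ proposals are
  multiplicative (DE in log space with the Jacobian in the acceptance
  ratio), which mixes their skewed conditionals far better and never
  wastes proposals on negative values.
* **Migration.** Within the migration window, a random subset of chains
  (size uniform on $2..n/2$) exchanges states cyclically with Metropolis
  acceptance — blockwise: the hyper block and each participant block
  migrate along independent random cycles. Whole-state migration turned
  out to propagate a single participant's well-fitting mode far too
  slowly. Migration is confined to the burn-in phase.
* **Initialisation.** Chains start from hyperprior draws; participant
  blocks are redrawn from their group distributions (up to a bounded
  number of attempts) until prior and likelihood are finite. Because the
  likelihood update for the hyper block cancels, hyper proposals never
  re-evaluate the WFPT likelihood.

Convergence is summarised by the classic Gelman–Rubin PSRF
$\sqrt{((n-1)/n\,W + B/n)/W}$ per parameter; identical chains give exactly
$\sqrt{(n-1)/n}$.

# Inference

Savage–Dickey Bayes factors for the group-difference parameters divide the
prior density at zero by a posterior density estimate at zero — by default
a Gaussian kernel density estimate with Silverman bandwidth over the
pooled post-burn-in draws, with a normal approximation available for
sensitivity analysis. When almost no draws fall near zero the result is
flagged low-confidence rather than silently returned. Interpretation
bands use the conventional boundaries: below 1/3 moderate evidence for the
null, above 3 moderate evidence for a group difference, anecdotal in
between. Model fit is checked by posterior-predictive defective CDFs:
trial sets matching the data's size and composition are simulated from
posterior draws, so the predictive band reflects both posterior and
trial-sampling uncertainty.

# Joint models

The EEG joint model replaces the two univariate drift terms with bivariate
normals pairing $(v_{p1}-v_{p2})$ with the slope difference and
$(v_{p1}+v_{p2})/2$ with the slope average, with priors
$\mu_{EEG.diff} \sim N(0, 0.5)$, $\mu_{EEG.mean} \sim N(0, 1)$,
$\sigma \sim \Gamma(1,1)$, $\delta \sim N(0, 0.01)$ and
$\rho \sim U(-1, 1)$ — one correlation per pairing, either shared across
groups or estimated per group. Participants without EEG keep the
univariate drift marginals, so behavioural sample sizes stay comparable
(listwise exclusion amounts to dropping those rows from the input).
Proposals implying a non-positive-definite covariance are rejected with
$-\infty$, never an error. Age can be partialled out through the covariate
mechanism above.

The ADHD joint models link one behavioural parameter
($v.mean$, $a$ or $t_{er}$) with one subscale (inattentiveness or
hyperactivity/impulsivity) per model, correlation estimated per group,
priors $\mu \sim N(0.5, 0.2)$, $\sigma \sim \Gamma(1,1)$,
$\delta \sim N(0, 0.01)$, $\rho \sim U(-1,1)$. The bivariate term is the
untruncated normal exactly as specified even where the base model
truncates $a$ and $t_{er}$ to positive support; that inconsistency is
inherited deliberately, and a support-respecting variant (renormalising by
the marginal mass above zero) sits behind `truncate_support = TRUE`.

# EEG pipeline

Starting from cleaned continuous recordings (artifact removal, filtering
and interpolation are upstream concerns and out of scope), the pipeline
is: epoch $-600$ to $+200$ ms around each response made 200–2500 ms after
stimulus onset, baseline to the last 100 ms of the random-motion period,
and pool all participants' epochs into Reliable Components Analysis — the
generalized eigenproblem maximising across-trial covariance against
within-trial covariance. The within covariance is shrunk by diagonal
loading at 1% of its average eigenvalue before inversion; eigenvector sign
is fixed so the mean forward projection over centro-parietal channels is
positive; weights are scaled biorthogonally to the unit-norm forward
projection, so projecting data that contain the component recovers the
source time course up to the topography's norm.

Each participant's continuous data are projected through the most reliable
component's weights and deconvolved with a time-expanded design: one
predictor per (event type × difficulty × timepoint) over $-1$ to $+1$ s
around stimulus and response events — 500 timepoints per condition at
250 Hz — solved by least squares or ridge regression
(penalising the squared coefficient magnitude). Samples whose absolute
amplitude exceeds 250 µV are excluded from the design matrix. The ridge
penalty is chosen per participant by 5-fold cross-validation over
contiguous temporal segments on a logarithmic grid augmented with the
4–6 region, then constrained to the modal value across participants so
that regularisation differences cannot masquerade as group differences.
The slope measure entering the joint model is the ordinary least-squares
slope of the deconvolved response-locked waveform from 200 ms before the
response to the response itself (51 samples at 250 Hz, endpoints
inclusive).

# The synthetic-data generator

The generator defines the study conditions for every recovery test. Per
task it schedules 4 blocks × 38 trials (9 repetitions × 2 difficulty
levels × 2 directions + 2 catch trials), shuffled within block; behaviour
is drawn from each participant's diffusion process by exact inverse-CDF
sampling with the 2500-ms deadline; catch trials use a strong drift of
0.4 (unambiguous motion). An optional contaminant fraction replaces
responded trials with uniform RTs below 200 ms purely to exercise the
floor filter — the model itself has no contaminant component.

Population defaults: the group-level means $\mu$ and the group offsets
$\delta$ default to the hyperprior means (the analysis makes no other
population commitment). The spreads $\sigma$ default to
$(\sigma_a, \sigma_z, \sigma_{ter}, \sigma_{v.diff}, \sigma_{v.mean}) =
(0.05, 0.1, 0.1, 0.1, 0.15)$ — the population scale typical of
hierarchical diffusion studies of children, chosen once so that a
generated study reproduces the data conditions of real sessions in this
paradigm (roughly 1% of trials censored at the deadline and well under 2%
excluded below the RT floor). The $\Gamma(1,1)$ prior mean of 1 would be a
population in which many children cannot respond before the deadline at
all, which no empirical dataset in this paradigm resembles.

Synthetic EEG is built as a stimulus-locked Gaussian-bump kernel plus a
response-locked linear ramp rising over 600 ms to the response and
decaying over 200 ms, each projected through a fixed smooth topography
over an abstract channel array (32 channels by default, 128 by
configuration), plus 1/f noise band-limited to the cleaned-data passband
of 0.3–40 Hz. The true pre-response slope is
$\mathrm{sign}(\rho)\,|g|\,v_{pi} + \eta_p$ with the participant-level
disturbance scaled so that the correlation between the slope average and
$v.mean$ equals the target $\rho$ (default gain 40 µV/s per drift unit —
placing true slopes in the tens-of-µV/s range that deconvolved
centro-parietal build-up rates occupy — noise 10 µV, $\rho = 0.6$). Questionnaire subscales come from a Gaussian
copula with the linked parameter, squashed through a normal CDF calibrated
so each group attains its configured mean and SD (defaults from the
observed sample: inattentiveness 0.17/0.58, hyperactivity 0.08/0.55); the
latent correlation is inflated to undo the mild Pearson attenuation of the
squashing.

What the generator does **not** emulate: raw 500-Hz data with blinks, bad
channels or muscle artifacts; dot-motion stimuli; sequential effects,
fatigue or attention lapses in behaviour; genuine EEG source geometry.
Passing recovery tests therefore show that the estimation machinery is
correct under the model's own assumptions — not that those assumptions
hold in real data.

# Problem sizes and numerical choices

The test-suite and acceptance runs use reduced problem sizes chosen as the
smallest at which each property is informative: the reduced convergence
fit uses 8 participants per group with 60 trials per difficulty level and
1000 iterations (400 burn-in, migration in an early window); recovery
coverage uses 20 replicate fits at 6 participants per group; joint-model
correlation ordering uses 10 replicates across $\rho \in \{-0.5, 0, 0.5\}$
with the ground-truth slope measure entering directly; the full-pipeline
slope recovery uses 50 synthetic participants with complete 152-trial
sessions. Series truncation error is $10^{-7}$; WFPT scale invariance
holds to $10^{-8}$; integrals of the density conserve mass to $10^{-4}$.
Degenerate inputs are defined rather than left to chance: empty trial sets
have log-likelihood 0, all-censored participants are prior-dominated but
valid, a deadline at or below $t_{er}$ gives survivor probability 1, and
rank-deficient RCA covariances are handled by shrinkage with a warning.

# Known limitations

* The covariate-partialling mechanism is a uniform linear-shift model of
  unverifiable fidelity to the original analyses.
* The Savage–Dickey density at zero is estimator-dependent; KDE and
  normal-approximation routes are both provided, and very tight posteriors
  far from zero are flagged rather than trusted.
* Migration uses partial cyclic acceptance and is therefore confined to
  burn-in; post-burn-in mixing relies on the DE kernel alone.
* The RCA objective is the across-trial-covariance formulation; other
  published variants differ in normalisation, and reliability eigenvalues
  are comparable only within one formulation.
* The ADHD joint model's untruncated bivariate term can place mass on
  negative $a$ or $t_{er}$; the `truncate_support` flag exists precisely
  because this is a modelling inconsistency, not a numerical one.
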