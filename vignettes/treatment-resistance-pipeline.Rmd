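---
title: "Modelling reward learning, glutamate and treatment resistance with psytrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward learning, glutamate and treatment resistance with psytrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(psytrs)
```

## The problem

Roughly one third of people with early psychosis become resistant to
first-line antipsychotic treatment. `psytrs` packages the
behavioural-computational pathway of a longitudinal design that follows a
50-person early-psychosis cohort over a baseline visit (A) and a one-year
follow-up (C), with a six-month clinical visit (B) in between. At the scan
visits, participants perform an emotion-yoked probabilistic reward-learning
task; MR spectroscopy provides anterior-cingulate glutamate (Glu/tCr), and
task fMRI provides peak-voxel parameter estimates for three regions of
interest. At visit C each participant is labelled treatment-resistant,
treatment-responsive, or unclassified by explicit clinical rules. The
pipeline covers everything downstream of the extracted measurements;
image preprocessing, GLM estimation and spectral fitting are out of scope
and enter only through their outputs (ROI betas, metabolite ratios).

## The task and the generative agent model

Each of four blocks presents two faces for 30 trials; one option is rich
(reward probability 0.6) and the other lean (0.4). Two *emotional* blocks
contrast a happy and an angry expression of the same identity; two
*neutral* blocks use different neutral identities. Only the chosen option's
outcome is revealed.

Simulated agents (and the fitted model) use **double-update Q-learning**:
after a non-missing trial with reward $r \in \{0, 1\}$,

$$Q_c \leftarrow Q_c + \alpha\,(r - Q_c), \qquad
  Q_u \leftarrow Q_u + \alpha\,((1-r) - Q_u),$$

with a single learning rate $\alpha$ shared between the chosen and
unchosen update. The complementary target $1-r$ reflects the task's
anticorrelated two-option structure. Choices follow a softmax
$p_1 = \mathrm{logistic}(\beta\,(Q_1 - Q_2) + b)$, where $\beta \ge 0$ is
the inverse temperature and $b$ an additive bias toward the happy face
applied in emotional blocks only. Q resets to $(0.5, 0.5)$ at every block
start — each block is a fresh learning problem (neutral blocks use new
identities). Two useful consequences, both exploited and tested:

* with symmetric initialisation and binary rewards the update preserves
  $Q_1 + Q_2 = 1$ exactly, so the value difference follows a first-order
  linear recursion that the likelihood evaluates with `stats::filter`;
* both values stay in $[0, 1]$ for any trial sequence.

The published description of this model defers its equations and fitting
details to earlier work, so the precise update target for the unchosen
option, the shared learning rate, the absence of a fitted bias or lapse
term, and the fit granularity are implementation policy here, chosen as
the canonical double-update form for complementary two-option bandits and
documented as such. The fitted model is deliberately two-parameter
$(\alpha, \beta)$; `happy_bias` is a simulation-only knob (fitting it is
available behind the `bias` argument of the likelihood but is off by
default) so that the fitted model matches the two-parameter usage the
analysis assumes.

## Fitting and ideal choices

`fit_mle()` minimises the negative log-likelihood over one participant ×
visit × condition (pooling that condition's two blocks, Q reset between
blocks; missing trials contribute neither an update nor a likelihood
term). Numerical choices: bounds $\alpha \in [0.001, 1]$,
$\beta \in [0, 50]$; likelihood floored at $10^{-12}$ before logs;
L-BFGS-B from 10 Latin-hypercube start points with an NLL tolerance of
about $10^{-8}$ (`factr = 4.5e7`). Start points draw $\alpha$ uniformly
and $\beta$ log-uniformly: the likelihood surface can hold a narrow basin
at small $\beta$ next to a flat $\beta = 0$ ridge (where $\alpha$ is
unidentified), and log-spaced starts probe both regimes. Tests verify the
optimum against a 200 × 200 grid search and parameter recovery over 100
simulated agents.

A trial is **ideal** when the chosen option's Q at decision time is at
least the unchosen option's. Ties count as ideal — the stated first-trial
convention is exactly the tie case under symmetric initialisation, and
applying it uniformly avoids a special case. The *model-preferred face*
(`ideal_option`) is the strictly-higher-Q option and is undefined at ties;
the *emotional-bias score*

$$b = P(\text{choose happy} \mid \text{angry ideal}) -
      P(\text{choose angry} \mid \text{happy ideal})$$

conditions on it, so tied and missing trials never enter either
proportion, and the score is flagged undefined when a conditioning set is
empty. Proportions are computed within participant from trial counts
(rather than averaging per-block proportions), one score per participant ×
visit, with the pooled mean also reported.

## Statistics

* Eight one-sample t-tests (group × visit × condition) of per-participant
  ideal-choice proportions against 0.5, flagged at the Bonferroni-adjusted
  threshold $0.05 / 8 = 0.00625$. Zero-variance cells report $t = 0$ at
  the chance level itself (diverging otherwise) rather than failing.
* Mixed ANOVAs — 2 × 2 × 2 on ideal choices, group × visit on bias scores
  and on Glu/tCr — run through `car::Anova` with type-III sums of squares
  and sum-to-zero contrasts on the group factor (the SPSS-style
  computation). With a single between-subjects factor and complete
  within-subject cells this coincides with the sequential decomposition;
  participants with incomplete cells are dropped with a message. All
  within factors have two levels, so no sphericity correction arises.
  Partial $\eta^2$ is $SS_{\text{effect}} / (SS_{\text{effect}} +
  SS_{\text{error}})$ per effect's own error stratum. Tests verify the F
  statistics against a hand-rolled balanced split-plot decomposition.
* MRS records pass the strict QC triple (CRLB < 20 %, SNR > 10,
  FWHM < 0.1 ppm; the inequalities are strict as printed) before any
  statistic; every exclusion is logged with the failing criteria.
  Creatine stability uses a paired t-test across visits.
* Coupling: Spearman correlations (midranks, two-tailed t approximation)
  between visit-C mPFC betas and visit-C Glu/tCr within each group, then
  Fisher's r-to-z comparison
  $Z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
  \sqrt{1/(n_1-3) + 1/(n_2-3)}$. The transform is applied to rank
  correlations exactly as in the analysis being reproduced; note it is
  exact only for Pearson coefficients and mildly anticonservative for
  Spearman's $\rho$.
* Prediction: logistic regression of the visit-C resistance label on five
  visit-A features. Features are z-scored by default for comparability
  across heterogeneous units (set `scale = FALSE` for raw coefficients);
  classification is in-sample at threshold 0.5, as no cross-validation is
  part of the reproduced analysis. Nagelkerke $R^2$ rescales Cox–Snell by
  its maximum attainable value. Quasi-separation is detected and flagged
  rather than silently reported.

## The synthetic cohort: what it emulates and what it does not

No raw data are deposited, so the generator is a first-class module that
emulates the *study conditions*: 15 resistant / 35 responsive
participants; visits A and C with 2 + 2 blocks of 30 trials at 60/40;
TRRIP-consistent clinical fields sampled to satisfy the intended label
(so labels round-trip through the classifier); ROI betas with the reported
group × visit interaction directions; glutamate–mPFC coupling present only
in the responsive group at visit C (generating Pearson $\rho = -0.48$,
giving Spearman near $-0.46$); and QC fields drawn so roughly 95 % of
records pass the gate.

Agent parameters per group × visit cell (`default_agent_map()`): all
cells share $\alpha \sim N(0.35, 0.10)$, $\beta \sim N(3.5, 1.2)$
(truncated) and happy bias $N(0.20, 0.20)$, except resistant participants
at visit C, who get degraded learning ($\alpha \sim N(0.15, 0.06)$,
$\beta \sim N(1.1, 0.4)$) and a stronger pull toward the happy face
($b \sim N(1.0, 0.35)$). The bias offset of 0.20 was calibrated once so a
no-group-effect cohort shows a grand-mean emotional bias near 0.07; the
resistant visit-C cell was calibrated once so its emotional ideal-choice
proportion sits near chance (population mean ≈ 0.55–0.56, typically not
significantly above 0.5 at the adjusted threshold with n = 15) while its
neutral proportion stays above chance. The rich option is counterbalanced
across each condition's two blocks, which is also what keeps both
conditioning sets of the bias score populated.

Deliberate simplifications: no reaction times, stimulus identities or
trial timing; parameters are drawn independently per participant × visit
(no trait stability across visits); the emotional impairment is generated
through the bias-plus-degradation mechanism above, which inflates the
resistant visit-C bias scores relative to a cohort whose bias does not
differ by group; metabolites other than Glu and tCr are not generated;
ROI betas are single peak-voxel values with homogeneous variance.
Passing calibration tests therefore shows the statistics behave correctly
under the study's design and effect pattern — not that real data would
show these effects.

Determinism: every stage derives 31-bit child seeds from the run seed via
a fixed affine map modulo $2^{31}-1$ (`derive_seed`), so stages and
individual participant × visit streams are independently reproducible,
and identical configuration + seed yields byte-identical tables.

## Problem sizes used by the test suite

Oracle-equivalence tests run on fixtures of tens of trials; parameter
recovery uses 100 agents × 240 trials; Monte-Carlo calibration of the
null behavioural and glutamate interaction tests and of the Fisher
comparison uses 200 simulated cohorts each, with rejection rates compared
to the nominal $\alpha = 0.05$ within two Monte-Carlo standard errors;
coupling calibration averages 200 generator draws. These sizes were
chosen so each property is measured with useful precision while the whole
suite stays comfortably interactive.

## Interfaces

Functions consume and return tibbles with documented column schemas
(trial tables, metabolite and ROI tables, feature tables), so
user-supplied data can replace any simulated stage — `run_pipeline()`
accepts an external trial table directly, and every downstream function
only needs the schema, not the simulator. `write_bundle()` persists every
tabular output as CSV plus a plain-text report. The package's surface is
R functions plus this vignette; no shell entry point is provided because
the intended users work from R.

## Known limitations

* The fitted model is the two-parameter double-update learner; no
  hierarchical pooling, lapse terms, or model comparison against
  single-update or actor-critic variants.
* Type-III ANOVAs assume the multivariate normal working model of the
  repeated-measures route; with two-level factors and modest n this is
  standard practice, not a robustness guarantee.
* The Fisher r-to-z comparison of Spearman coefficients is approximate;
  with $n_1 = 35$, $n_2 = 15$ its standard error is mildly optimistic.
* In-sample classification metrics are optimistic by construction; the
  optional cross-validation mode deliberately does not exist because the
  reproduced analysis reports apparent performance.
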