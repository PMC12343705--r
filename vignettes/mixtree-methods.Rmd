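---
title: "Mixture IRTree models for response-strategy heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture IRTree models for response-strategy heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtree)
```

## The model

Responses to a four-point rating item ("strongly disagree" ... "strongly
agree") are decomposed into binary pseudo-decisions on a response tree.
The *direction* node $y^*_1$ separates the disagreement side (categories 1,
2) from the agreement side (3, 4); conditional on the direction, an
*extremity* node picks the extreme category on that side ($y^*_2$ on the
disagreement branch, $y^*_3$ on the agreement branch).  A node that is not
on the taken branch is missing by design.  The category probabilities are

$$P(1) = (1-p_1)(1-p_2), \quad P(2) = (1-p_1)\,p_2, \quad
  P(3) = p_1 (1-p_3), \quad P(4) = p_1\, p_3 .$$

Each node probability is an inverse-logit of a linear predictor in two
latent variables: the substantive trait $\theta$ and an extreme response
style (ERS) factor $\eta$.  With latent classes $c = 1, \dots, C$
representing response *strategies*,

$$p_1 = g^{-1}\!\left(\alpha^{(trait)}_j \theta + \beta_{1j}\right), \qquad
  p_2 = g^{-1}\!\left(\alpha^{(trait)}_j \omega_{jc}\, \theta
        - \alpha^{(ers)}_c \eta + \beta_{2jc}\right), \qquad
  p_3 = g^{-1}\!\left(\alpha^{(trait)}_j \omega_{jc}\, \theta
        + \alpha^{(ers)}_c \eta + \beta_{3jc}\right).$$

The direction node is class-invariant: every strategy engages enough to
decide agree-vs-disagree on the same measurement model, which also anchors
the trait metric across classes.  Heterogeneity is confined to *how*
specific categories are chosen: the proportionality constant $\omega_{jc}$
scales the trait's role at the extremity nodes relative to the direction
node, and the item-invariant ERS loading $\alpha^{(ers)}_c$ scales the
style factor's role.  A class with small $\omega$ and large
$\alpha^{(ers)}$ behaves like a satisficing-dominated strategy (category
extremity driven by style); the reverse pattern is optimizing-dominated.
ERS loadings are item-invariant because a response style is, by definition,
content-independent; $\omega$ is item-specific because item features can
modulate engagement.

Both latent variables have mean 0 and variance 1 in every class
(identification), with a class-invariant correlation.  The person-level
likelihood is the $\pi_c$-weighted mixture of class-conditional products of
Bernoulli node likelihoods; the node terms use
$p^{y^*}(1-p)^{1-y^*}$ for each observed pseudo-item, which is the standard
IRTree likelihood.

## Estimation: the three-step procedure

**Step 1.** Class proportions and all item parameters are estimated by
marginal maximum likelihood: the latent pair is integrated out over a
Gauss-Hermite product grid (default 15 nodes per dimension) rotated by the
Cholesky factor of the latent correlation matrix.  The maximiser is an EM
algorithm of the Bock-Aitkin type: the E-step computes the joint posterior
over (class, quadrature node) and condenses it into expected pseudo-item
counts per item, node and grid point; the M-step updates the class
proportions in closed form and improves the item parameters by a small
number of bounded quasi-Newton steps with analytic gradients on the
expected-count objective (a generalised EM; the M-step objective no longer
involves the sample size, so inner iterations are cheap).  The observed
log-likelihood is monotone non-decreasing across cycles and iteration stops
when its relative change falls below `tol` (default `1e-6`) or after
`max_iter` cycles (default 500, the convention of widely used IRT
software).

We deliberately do *not* run a high-precision quasi-Newton search directly
on the marginal likelihood.  Mixture likelihoods of this model possess
spurious maxima in which a small class drifts toward near-deterministic
node probabilities around a handful of extreme response vectors; a direct
second-order optimiser converges to them reliably, inflating the
log-likelihood gain of every additional class by roughly twice the added
parameter count and wrecking class enumeration.  The EM path combined with
moderate parameter boxes (intercepts in $[-5, 5]$, loadings in
$(0.05, 3]$, $|\omega| \le 3$ — far outside the plausible range of
four-point rating items) is the field's standard defence and keeps
reported solutions interior.  Multiple random starts (default 4 for one
class, 8 otherwise) perturb a single-class warm-start solution; the best
converged start by log-likelihood is kept.  Reported classes are relabelled
into descending-$\alpha^{(ers)}$ order (satisficing-like first), a
convention needed because mixture labels are arbitrary.

The trait-ERS correlation is estimated by default (it is part of the
model's free-parameter count) and can be fixed via `latent_corr`.  EAP
trait and ERS scores are posterior means over the same grid, marginalised
over classes, with posterior SDs as standard errors.

**Step 2.** Posterior class membership probabilities follow Bayes' rule
from the step-1 estimates; respondents are assigned to their modal class
(ties, which have measure zero in practice, break toward the lower index
and are logged in an attribute).  The classification-error matrix
$D[c,k] = P(w = k \mid X = c)$ averages posteriors over assignments and
feeds step 3.

**Step 3.** Covariate effects on class membership are estimated by a
latent-class model in which the modal assignment is the sole indicator of
the true class, $D$ is held fixed as its conditional response matrix, and
$P(X = c \mid Z)$ is a multinomial logistic regression (reference class 1).
Estimation is an EM whose M-step is a hand-written Newton weighted
multinomial logit; with $D = I$ the procedure reduces exactly to ordinary
multinomial regression of $w$ on $Z$.  Standard errors come from the
numerically differentiated observed information of the step-3 likelihood
and ignore step-1 sampling error, as is usual in three-step maximum
likelihood; this understates uncertainty somewhat and is a documented
limitation.

## Model selection and cross-validation

The free-parameter count splits into $n_{k_0} = 2J + 1 + (C-1)$
class-invariant parameters (direction node, latent correlation, mixing
proportions) and $C(3J+1)$ class-specific ones.  `information_criteria()`
computes AIC, BIC and HBIC, the latter penalising each class-specific
block by $\log(\pi_c N)$ — its class's effective sample size — so
HBIC $\le$ BIC, with equality at $C = 1$.  `r2_entropy()` reports the
relative entropy reduction $1 - \sum_{p,c} (-\hat\pi_{pc}
\ln \hat\pi_{pc}) / (N \ln C)$; the statistic is reported in the
literature without a printed formula, and this standard definition is the
package's choice, stated here once and used everywhere.

`kfold_cv()` splits respondents into folds by simple random assignment
(stratification is not part of the reference design), fits the model
independently on each training remainder and test fold, aligns the two
label sets with `align_labels()` (total squared distance over the
class-specific blocks, all $C!$ permutations), and reports item-parameter
correlation and *signed* mean difference, EAP-score correlations and mean
*absolute* differences on the test respondents (scored under train-fit vs.
test-fit parameters), class-posterior correlation, assignment overlap and
Cohen's $\kappa$.  The signed/absolute asymmetry mirrors the convention of
the diagnostic table this report reproduces.

## The synthetic-data generator

`sim_mixtree_data()` emulates a hypothetical population in which
respondents follow one of three strategies (satisficing-dominated,
balanced, optimizing-dominated):

* covariates: three independent standard normals;
* memberships: multinomial logit with slopes $(0, -1, 1)$, $(0, 0.5, -0.5)$
  and $(0, 0, 0)$ for the three covariates (strong, weak, null effect) and
  intercepts $(0, -0.37, -0.37)$ in the equal-three-class condition; for
  other class-size profiles the intercepts are calibrated numerically
  (deterministic Gauss-Hermite expectation) so the covariate-marginal class
  probabilities hit the nominal profile — the reference design states the
  profiles but not all intercepts, so calibration is the package's own
  resolution.  Two-class conditions drop the optimizing column;
* latent scores: bivariate normal, unit scales, correlation 0 or 0.30;
* item parameters: direction-node loadings $U(0.5, 1.25)$ and intercepts
  $N(0, 1)$; the balanced class draws $\omega \sim U(0.5, 0.7)$,
  $\alpha^{(ers)} \sim U(0.5, 0.7)$, intercepts $N(0, 1)$; the outer
  classes offset $\omega$ and $\alpha^{(ers)}$ in opposite directions by
  $U(0, 0.1)$ / $U(0.2, 0.3)$ / $U(0.4, 0.5)$ for low / medium / high
  separation and add $N(0, \sigma_s)$ intercept noise with
  $\sigma_s = 0.25 / 0.75 / 1.5$, truncated to $[-3, 3]$.  Separation
  increments are drawn independently per item, and independently for the
  two outer classes (the design table is silent on sharing draws);
* responses: one multinomial draw per person-item from the class-specific
  category probabilities.

Single-class populations reuse the machinery with unrelated covariates and
one named strategy column at medium separation.  The full factorial
(`design_grid()`) enumerates 378 mixture cells and 54 one-class cells; at
the reference 200 replications per cell that is 75,600 and 10,800
generated data sets.

What the generator does *not* emulate: content multidimensionality,
acquiescence or midpoint styles, missing responses, item-specific ERS
loadings, non-normal latent distributions, and covariate effects on item
parameters.  Passing recovery tests on these data therefore demonstrates
internal consistency of model, estimator and generator under the stated
design — not robustness to the many ways real questionnaire data violate
it.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suite and acceptance experiments are
the package's own scaled-down choices: quadrature at 7-9 nodes per
dimension, 1-2 random starts per class count and an EM cap of 150 cycles
for the large recovery experiments (quadrature error at these loading
magnitudes is orders of magnitude below sampling noise, and
correctly-specified fits converge well inside the cap), 20 replications of
the (C = 2, N = 2000, J = 20, high separation) cell for
selection/recovery/misfit properties, 5 replications and smaller samples
for smoke-level checks.  Class-proportion floors
(`1e-8`) guard the closed-form mixing update; log-sum-exp underflow guards
keep person likelihoods finite for all-extreme response vectors; ties in
modal assignment break to the lower index and are logged.  Degenerate
inputs (empty classes in the error matrix, singular covariate matrices,
out-of-range categories) raise informative errors naming the offending
class, column or cell.

## Known limitations

Only four-point scales are supported; acquiescence/midpoint nodes and
item-specific ERS loadings are out of scope.  Step-3 standard errors ignore
step-1 uncertainty.  Class enumeration near the selection boundary is
sensitive to the estimation path: because additional-class likelihood
gains on homogeneous data sit close to the AIC penalty, aggressive
optimisation settings (many starts, very tight tolerances, unbounded
parameters) shift information criteria toward over-selection — the
defaults encode the practical conventions described above, and users who
change them should re-validate enumeration behaviour on simulated data.
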