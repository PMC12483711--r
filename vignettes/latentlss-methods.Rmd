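---
title: "Latent location-scale-shape models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent location-scale-shape models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentlss)
```

## The model

`latentlss` fits latent variable models in which *every* distributional
parameter of an observed variable — not only its conditional mean — may
depend on continuous latent variables. For respondents $j = 1, \dots, n$
with responses $y_{1j}, \dots, y_{pj}$ and a latent vector
$z_j \in \mathbb{R}^q$, the model assumes local independence,

$$f(y_j) = \int \prod_{i=1}^{p} f_i\!\left(y_{ij} \mid \theta^{(i)}(z)\right)
\, \varphi_q(z; \Sigma) \, dz,$$

where $\theta^{(i)} = (\mu_i, \sigma_i, \nu_i)$ collects the location,
scale, and shape parameters of item $i$'s conditional distribution, and
each of them is a linked linear function of the latent variables:

$$v\!\left(\theta_{ik}(z)\right) = \alpha_{0,ik} + \alpha_{ik}^\top z,$$

with a parameter-specific monotone link $v$ (identity, log, logit, or a
scaled logit). The latent prior is multivariate normal with unit variances;
$\Sigma$ is either the identity or a correlation matrix whose
strictly-lower entries are free parameters. Classical item factor analysis,
the two-parameter logistic IRT model, and homoscedastic Beta or Normal
factor models are all special cases in which only the location equation
loads on $z$. The scientific payoff of the general form is that conditional
variance and skewness become functions of the latent trait, so
heteroscedasticity and asymmetry in the data are modelled rather than
absorbed into bias.

### Measurement families

Four families ship (`get_family()`):

* **bernoulli** — success probability $\mu \in (0,1)$, logit link;
* **normal** — mean $\mu$ (identity) and standard deviation $\sigma$ (log);
* **beta_ls** — the location-scale Beta for doubly-bounded responses:
  mean $\mu \in (0,1)$ and scale $\sigma \in (0,1)$, both logit-linked,
  with shapes $a = \mu(1-\sigma^2)/\sigma^2$,
  $b = (1-\mu)(1-\sigma^2)/\sigma^2$, variance $\sigma^2\mu(1-\mu)$, and
  precision $(1-\sigma^2)/\sigma^2$ (`beta_ls_shapes()`). Compared with the
  location-precision parametrization common in Beta regression, the scale
  form keeps the latent effect on the conditional variance directly
  interpretable;
* **skew_normal** — location $\xi$ (identity), scale $\omega$ (log), and a
  shape $\nu \in (0,1)$ (logit) with slant $\delta = 2\nu - 1$ and
  classical slant $\alpha = \delta/\sqrt{1-\delta^2}$. This box keeps all
  three linear predictors unconstrained on the real line. Moments follow
  the usual skew-normal formulas (`sn_moments()`); the skewness is bounded
  by $\approx 0.9953$ in absolute value, a structural limit of the family.
  Any other slant convention can be recovered through the $\delta$ mapping.

All log-densities are computed on the log scale throughout (log-gamma for
the Beta, a log-CDF for the skew-normal tail), and each family exposes
analytic derivatives of its log-density with respect to every
distributional parameter. These derivatives are certified in the test suite
against central finite differences at random parameter draws, since they
are the backbone of the score vector below.

### Boundary data

Doubly-bounded items observed exactly at 0 or 1 have no Beta density;
`read_lss_data()` (and `nudge_unit_interval()`) moves such values a
configurable `eps` (default $10^{-3}$) inside the interval and reports how
many values were moved. The count matters: silent nudging of many values
distorts scale-parameter estimates.

## Estimation

Parameters are estimated by full-information marginal maximum likelihood.
The latent integral is evaluated with a tensor-product Gauss–Hermite rule
rescaled to the standard normal (`gh_grid()`): with $m$ nodes per dimension
the grid integrates polynomials up to degree $2m-1$ exactly per coordinate.
Correlated factors are handled by transforming nodes, $z = Lt$ with
$\Sigma = LL^\top$ the Cholesky factor, so the weights never change. The
defaults are $m = 100$ for one factor and $m = 35$ per dimension for two.

A practical point the package makes measurable (see the saturation test):
a *fixed-point* rule is accurate while the per-case posteriors remain wide
relative to the node spacing. With 5 moderately informative items
(loadings ≲ 0.5) the one-factor likelihood changes by less than $10^{-6}$
per observation between $m = 21$ and $m = 45$; with strong loadings
(≳ 1) the posteriors sharpen and a 21-point rule visibly biases estimates
at large $n$, which is why the coverage experiments below use dense rules.
Adaptive quadrature is deliberately out of scope; the node budget guard in
`gh_grid()` refuses grids that would not fit in memory.

### Score vector

The score of the marginal log-likelihood has the classic posterior-expected
complete-data form: for any free intercept or loading of item $i$'s
parameter $\theta_k$, the per-case contribution is the posterior-weighted
family derivative chained through the link and the predictor design
$(1, z^\top)$. For the free correlation entries the chain runs through the
Cholesky factor, $\partial \eta / \partial L_{ab} = \alpha_a t_b$, and a
closed-form Jacobian $\partial L / \partial \rho$ obtained from the
Cholesky differential. For Bernoulli items the posterior-expected score
reduces to the residual form $E[y - \pi(z) \mid y]$, which the
implementation exploits. Everything is evaluated in a single pass over an
$n \times m^q$ grid; items whose loadings touch only the leading $r$
factors take just $m^r$ distinct parameter values on the tensor grid, and
the kernels evaluate those once.

### Optimization strategy

`lss_fit()` proceeds in three stages:

1. **Warm start** (`warm_start()`): principal-component scores of the
   mean-imputed, standardized data serve as observed proxies for $z$, and
   each item is fit by a complete-data distributional regression on those
   scores in its own family, respecting the free/fixed pattern. Intercepts
   start at link-transformed sample statistics. For the skew-normal the
   shape starts at a method-of-moments slant derived from the sample
   skewness — starting at the symmetric point is a stationary saddle of the
   skew-normal likelihood where every gradient vanishes, and a gradient
   method would never leave it. Free correlations start at 0.
2. **EM warm-up**: E-step posterior node weights, then per-item damped
   Newton blocks on the expected complete-data log-likelihood (block
   Hessians by finite differences of the analytic block gradient; blocks
   have at most $D(1+q)$ coordinates). Every accepted step is required not
   to decrease the *marginal* log-likelihood by more than $10^{-8}$
   (step-halving otherwise), so the EM trace is monotone by construction.
   An adaptive-learning-rate gradient rule is available as
   `em_method = "gradient"`. The correlation block is updated in the
   unconstrained coordinates described below. The default cap is 50
   iterations with early exit at a relative change of $10^{-6}$; the
   simulation presets use a short warm-up (5 iterations) because the PCA
   start is already close and the quasi-Newton stage converges quickly
   from there.
3. **BFGS**: direct maximization of the marginal log-likelihood with the
   analytic score. The search is preconditioned by inverse root curvatures
   taken from the empirical information at the warm-up solution
   (`precondition = TRUE`), which reduces the iteration count severalfold
   on mixed-family models. Free correlations are optimized through a
   tanh-spherical map — row $i$ of $L$ is built from $c = \tanh(\gamma)$
   via $l_{ij} = c_{ij} \prod_{k<j} \sqrt{1-c_{ik}^2}$ — so every iterate
   corresponds to a positive-definite correlation matrix and line searches
   cannot step outside the parameter space. The reported estimate and its
   standard error are on the $\rho$ scale.

Convergence is declared when the optimizer terminates normally and the
per-observation score sup-norm falls below `grad_tol` (default
$10^{-4}\sqrt{K}$). Because the likelihood is invariant to jointly flipping
the sign of one factor's loadings (and the matching correlation entries),
fits are only identified up to reflection; `align_signs()` resolves the
ambiguity against a reference, and all recovery metrics do so per
replication. Optional seeded multi-starts (`n_starts`) guard against local
maxima, which do occur in distributional models.

### Standard errors and empirical identification

The expected information is estimated by the empirical cross-product of
case-wise scores (the Fisher identity applied at $\hat\delta$); standard
errors are the square roots of the inverse's diagonal. The same matrix
doubles as the empirical local-identification check: the fit is flagged
non-identified when the condition number exceeds $10^{10}$ (or an
eigenvalue is non-positive), in which case no standard errors are reported
and downstream coverage calculations count the replication as SE-missing.
The test suite validates the cross-product estimator against a numerical
Hessian of the marginal log-likelihood on a small model (agreement of SEs
within sampling error) and confirms that a deliberately rank-deficient
spec — two factors with identical loading columns and no restrictions —
trips the flag while the standard designs do not.

Model comparison uses `aic_bic()`: $\mathrm{AIC} = -2\ell + 2K$,
$\mathrm{BIC} = -2\ell + K \log n$.

### Missing data

Missing entries are handled by the available-case conditional product
(MAR): a missing item simply contributes nothing to its row's conditional
likelihood or score. A fully missing row has posterior equal to the prior,
so its EAP score is 0 with variance 1.

## Factor scores

`eap_scores()` returns the posterior mean and variance of $z$ per
respondent, computed from the same fixed grid (expected a posteriori
scoring). Posterior variances are strictly below the prior variance
whenever at least one loading is non-zero and observed.

## Identification restrictions

Rotational indeterminacy requires at least $q(q-1)/2$ restrictions across
the loading matrices and latent covariance; `build_model()` warns below
that count (this is the orthogonal-case count; the package documents and
uses it for the warning rather than attempting a sharp model-specific
bound). `exploratory_model()` applies the standard echelon scheme — upper
triangle of the location loading matrix fixed to 0, $\Sigma = I$.
Confirmatory specs such as the IR/RT model impose zeros by structure.

## The simulation harness

`simulate_lss()` draws $z \sim N(0, \Sigma)$ and then each response from
its family at the linked predictors; everything is deterministic given the
seed. Two preset recovery designs mirror the package's two flagship model
classes, and `recovery_metrics()` reports, per parameter group, the
replication-averaged MSE, absolute bias
$\mathrm{AB}_k = \tfrac1R \sum_r |\hat\delta_k^{(r)} - \delta_k|$, and the
empirical coverage of nominal 95% Wald intervals
$\hat\delta \pm 1.96\,\mathrm{SE}$.

**One-factor heteroscedastic Beta design** (`study1_design()`,
`study1_true_params()`): $p$ Beta items whose location and scale equations
both load on one factor. True parameters are drawn uniformly — location
intercepts on $(-1, 1)$, location slopes with magnitude on $(0.5, 1.5)$,
scale intercepts on $(-1.5, -0.5)$, scale slopes with magnitude on
$(0.1, 0.5)$, slope signs $\pm$ with probability $\tfrac12$ — and each item
is redrawn until both implied Beta shapes exceed 1 for all $z \in [-3, 3]$,
keeping the conditional densities unimodal (bimodal Beta shapes are rare in
the bounded-rating applications this family targets). The canonical
factorial crosses $n \in \{200, 500, 1000, 5000\}$ with
$p \in \{5, 10, 20\}$.

**Two-factor IR/RT design** (`study2_design()`, `study2_true_params()`):
eight skew-normal log-response-time items whose location, scale, and shape
equations load on a speed factor, eight Bernoulli accuracy items loading on
an ability factor, and a free speed-ability correlation fixed at $-0.28$ in
the shipped truth. The remaining true values are a documented, replaceable
fixture: difficulties on $(-1.5, 1.5)$, discriminations on $(0.8, 2)$,
log-RT location intercepts on $(-0.7, 0.3)$ with speed loadings on
$(-0.5, -0.2)$, and small mixed-sign scale/shape equations (intercepts on
$(-1.2, -0.8)$ and $(-0.5, 0.5)$, slopes of magnitude $(0.1, 0.3)$),
drawn once from a fixed seed. Internally the speed factor is ordered first
so the expensive skew-normal kernels see only $m$ distinct node values; the
ordering is a computational convention with no statistical content.

Replication $r$ of a design uses seed $\texttt{seed} + r$ (the truth, when
drawn, uses the master seed itself), so every report is reproducible from
the design object alone. Replication failures are caught and counted, never
fatal.

### Problem sizes and expectations

The package's own calibration experiments (the acceptance test suite and
`scripts/acceptance.R`) run at desk scale on one core:

* coverage of nominal 95% intervals: $n = 5000$, $p = 5$, $R = 100$
  replications, dense rules ($m = 45$ in the tests, $m = 100$ in the
  acceptance script). Average empirical coverage lands near 0.95; at small
  $n$ the empirical-information SEs are mildly conservative, so coverage
  does not drop below the large-$n$ level;
* consistency: AvMSE and AvAB fall monotonically across
  $n \in \{200, 1000, 5000\}$ at $R = 50$;
* model selection: with heteroscedastic truth at $n = 1000$, AIC and BIC
  both prefer the heteroscedastic over the homoscedastic Beta model in at
  least 90% of replications;
* IR/RT recovery: $n = 1000$, $R = 20$, $m = 21$ per dimension recovers
  the $-0.28$ correlation to within 0.05 and keeps the reflection-aligned
  loading AvAB under 0.15.

These settings are the package's standard desk-scale defaults; larger
$R$ or denser rules change Monte-Carlo noise, not the qualitative
conclusions.

## What the generator does and does not emulate

The synthetic designs reproduce the *structure* of bounded-rating surveys
(latent-dependent location and scale of doubly-bounded responses) and of
joint accuracy/response-time testing data (correlated ability and speed,
latent-dependent RT variance and skewness). They do not emulate several
features of real survey and testing data: responses heaped at multiples of
5 or 10, boundary pile-ups of exact 0/100 ratings beyond what the nudging
rule absorbs, "don't know" mechanisms that are not missing-at-random,
within-person response dependence beyond the latent factors, or
item-by-covariate effects. Passing recovery tests therefore certifies the
estimator under the model's own assumptions, not robustness to these
violations.

## Numerical choices and degenerate inputs

* Linear predictors are clamped before the inverse link ($|\eta| \le 30$
  for logit-type links, $|\eta| \le 300$ for log links) so saturated
  probabilities or scales cannot produce non-finite densities during line
  searches; the clamp is far outside any plausibly estimable region.
* The tanh-spherical correlation coordinates are clamped at $|\gamma| \le 8$
  (correlations within $\pm(1 - 2\cdot10^{-7})$) to keep $L$ full rank.
* Beta draws that round onto the closed boundary in extreme tails are
  pulled one ulp inside the open interval by the simulator.
* A constant observed column gets zero starting loadings with a warning; a
  column whose values sit outside the family support fails fast with the
  row and item named.
* Log-sum-exp is used for all marginalization and posterior weights; an
  all-missing row degenerates cleanly to the prior.
* Ties in sign alignment (an exactly zero inner product between estimated
  and reference loadings) resolve to "no flip".

## Limitations

* Fixed-point quadrature limits the practical number of latent dimensions
  (the node budget grows as $m^q$); three factors are feasible with
  moderate $m$, more require methods out of scope here.
* Only the homoscedastic logit model is available for binary items; scale
  equations for categorical data would require an underlying-variable
  formulation the package does not implement.
* Shape parameters are weakly identified at small $n$; expect wide
  intervals for skew-normal shape loadings below $n \approx 1000$.
* The empirical cross-product information is consistent but noisier than
  the expected information at small $n$; its mild upward bias in SEs makes
  small-sample intervals conservative rather than anti-conservative.
* Exploratory fits are reported unrotated; apply your favourite rotation
  downstream if interpretability demands it.
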