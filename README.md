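# rrbridge

Bayesian bridging prediction of a clinical rate ratio (and vaccine
efficacy) from dichotomous biomarker counts, using only trial-level summary
data of historical randomized trials.

## The problem

Clinical endpoints such as disease occurrence can take years to observe,
while an early dichotomous biomarker (e.g. persistent virus infection in a
vaccine trial) is available quickly. When the biomarker is *associated*
with the endpoint — even if it is not a validated surrogate — the
association learned from completed historical trials can be *bridged* to a
new trial (for instance a new regional trial) to predict the treatment
effect on the clinical endpoint from the biomarker counts alone.

`rrbridge` is aimed at biostatisticians in drug development who have, per
historical trial *i*, only the per-arm responder counts: biomarker
responders `B_Ti / B_Ci` and endpoint responders `X_Ti / X_Ci`. No
patient-level data are required.

## The model

Let `phi_Bi` be the proportion of biomarker responders belonging to the
treatment arm (`phi_Bi = pi_BTi / (pi_BTi + pi_BCi)`, estimated under 1:1
allocation by `B_Ti / B_i` with `B_i = B_Ti + B_Ci`), and `phi_Xi` the same
share for the endpoint. Under 1:1 allocation `phi / (1 - phi)` equals the
between-arm rate ratio, so these shares carry the treatment effect without
reference to trial size. The association model is a trial-level GLM

    B_Ti ~ Binomial(B_i, phi_Bi)
    X_Ti ~ Binomial(X_i, phi_Xi)
    g(phi_Xi) = beta0 + beta * g(phi_Bi)

with `g` the logit (default), odds, or cloglog link, and priors
`beta ~ U(-100, 100)`, `phi_Bi ~ Beta(1, 1)`, and a weakly-informative
`beta0 ~ N(0, 1)` (the intercept is the endpoint log-RR of a trial whose
biomarker shows no effect, so unit-scale shrinkage softly encodes "no
biomarker effect implies no clinical effect"; see the methods vignette).
Posteriors come from a Metropolis-within-Gibbs sampler written in C++.

For a new trial *j* with observed biomarker counts, each posterior draw
maps `phi_Bj` through the fitted link to a predictive draw of `phi_Xj`,
hence of the rate ratio `RR_j = phi_Xj / (1 - phi_Xj)` and the vaccine
efficacy `VE_j = 1 - RR_j`. The point estimate is the predictive median;
the 95% credible interval the 2.5/97.5 percentiles.

A simulation engine generates historical trials at patient level from a
biomarker control-arm rate (0.3), a per-trial biomarker share
`phi_Bi ~ U(0, 0.76)`, and the biomarker's positive/negative predictive
values (PPV, NPV), which determine each patient's endpoint response by
concordance. It scores predictions by modified bias and modified RMSE
(mean and root-mean-square of `log10(RR_hat / RR_true)`) and by the average
ratio of the 95%-CI bounds (1 = perfectly precise). Applicability rules
distilled from those simulations — `PPV/NPV >= 0.5` when the two are equal,
`PPV + NPV >= 1` for high-NPV biomarkers, and at least 20 (equal) or 5
(high-NPV) historical trials — are reported with predictions.

## Worked example

Five historical placebo-controlled vaccine trials (1:1 allocation) with
infection (biomarker) and disease (endpoint) counts are packaged; a new
trial of 3,606 subjects observed 36 infections, 7 in the vaccine arm, and
no disease follow-up yet. The biomarker has NPV 99.99% and PPV 15%.

```r
library(rrbridge)
run_example(seed = 1)
```

```
Worked example: bridging vaccine efficacy from infection counts
  historical trials: 5; new trial infections: 7/29
PPV = 0.15, NPV = 0.9999: rule 'PPV + NPV >= 1 (high NPV, low PPV)' satisfied 
Predictive rate-ratio summary (new trial)
  link: logit; draws used: 20000 of 20000; phi_Bj uncertainty: plug-in
  RR: 0.1744  (95% CI 0.0511, 0.4861)
  VE: 82.56% (95% CI 51.39%, 94.89%)
```

Reading: given the observed infection split 7/29, the disease-endpoint
vaccine efficacy in the new population is predicted at about 82% with 95%
credible interval (52%, 95%) — significant efficacy, since the lower bound
is above zero, long before disease cases accrue. The applicability line
confirms the high-NPV rule `PPV + NPV >= 1` holds for this biomarker.

The same analysis from the command line:

```sh
Rscript -e 'rrbridge::rrbridge_cli()' predict --trials trials.csv \
    --new-bt 7 --new-bc 29 --link logit --seed 1
```

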