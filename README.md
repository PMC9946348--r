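# msomResurvey

Hierarchical Bayesian **dynamic multispecies occupancy modelling** (MSOM)
for paired historic/modern resurveys — the study design in which sites
surveyed for breeding birds early in the 20th century are revisited a
century later, and the question is how much occupancy and diversity really
changed once imperfect detection is accounted for, and how much of that
change each threat (climate change vs land-use change) is responsible for.

For species *i*, site *j*, visit *k*, era *t* (1 = historic, 2 = modern):

```
y_ijkt | z_ijt ~ Bernoulli(z_ijt * p_ijkt)                    (observation)
z_ij1          ~ Bernoulli(psi_ij1)                           (initial occupancy)
z_ij2 | z_ij1  ~ Bernoulli(phi_ij * z_ij1 + gamma_ij * (1 - z_ij1))
```

Detection *p*, initial occupancy *psi1*, persistence *phi* and
colonization *gamma* are logit-linear in survey and site covariates
(*p*: Julian day, day², survey era; *psi1*: temperature, precipitation,
water/urban/agriculture percent cover; *phi*, *gamma*: the
modern-minus-historic change in each), and all species coefficients are
partially pooled through normal community hyperdistributions
(hypermeans ~ N(0, 1.5²), hyper-SDs ~ half-Cauchy(1.5)).

What the package provides:

* a detection-history data model (CSV in/out) supporting the three historic
  collection modes (standardized counts, daily species lists,
  first-detection-only lists, the latter masked after first detection);
* a synthetic two-region resurvey generator with known truth — the test
  bed for everything downstream;
* the latent-incidence-**marginalized** likelihood (exact four-path
  enumeration, compiled), sampled by adaptive Metropolis-within-Gibbs with
  an interleaved non-centered move for the community hyperparameters;
* Gelman–Rubin diagnostics, WAIC (marginal, species×site pointwise),
  posterior summaries;
* posterior diversity change from imputed incidence: richness change,
  per-species occupancy change with significance classes, and the temporal
  beta-diversity partition (Sørensen = nestedness + Simpson turnover);
* occupancy-change **sensitivities** (the derivative of Δψ with respect to
  a covariate's change) and **counterfactual impact decomposition**
  (climate-only and land-use-only scenarios minus a no-change control),
  with windfall / double-whammy / opposing quadrant classification and
  posterior quadrant probabilities.

See `vignettes/msom-methods.Rmd` for the model, priors, numerical choices
and limitations.

## Worked example

Simulate a reduced two-region world (an urbanizing/drying region "LA" vs
an agriculture-expanding/wetting region "CV"), fit it, and decompose
impacts:

```r
library(msomResurvey)
tb  <- simulateResurvey(nSpecies = 15, seed = 42,
                        design = defaultRegionDesign(12, 16))
fit <- runMCMC(tb@dataset, tb@covariates, modelSpec(),
               mcmcConfig(2, 2000, 700, 3, seed = 1))
hd  <- hyperDraws(fit)
posteriorSummary(hd$mean[, c("mu.gamma.d_precipitation", "mu.phi.d_urban")])

z  <- drawIncidence(fit, seed = 2, thinTo = 400)
oc <- occupancyChange(z, region = regions(tb@dataset), which = "LA")
table(oc$class)
counterfactualImpacts(fit, "LA", zDraws = z)
```

Output from this exact run:

```
                          mean lower upper significant
mu.gamma.d_precipitation  1.52  0.47  3.19           1
mu.phi.d_urban           -0.60 -1.84  0.79           0

decrease increase     none
       7        1        7

ImpactSummary (LA): 15 species
double_whammy  opposing_LU+      windfall
            7             6             2
  impact correlation r = 0.057 (-0.387, 0.552)
```

Reading it: the community hypermean for the precipitation-change effect on
colonization is credibly positive (truth +0.8 in the generator; the short
demo chains give a wide interval), 7 of 15 species credibly declined in
the urbanizing region, and the counterfactual decomposition classifies
more species as double-whammy (both threats negative) than windfall in
that region — the direction the generator's community structure implies.
At this demo scale the `phi ~ d_urban` hypermean has the right sign but
its interval still spans zero; the shipped recovery study (25 species ×
40 sites, `mcmcPreset("desk")`) pins both structural hypermeans with
correct signs.

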