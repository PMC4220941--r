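# whitepox

Bayesian space-time modelling of white-pox disease on the elkhorn coral
*Acropora palmata*.

White-pox is a tissue-loss disease of a threatened Caribbean reef-building
coral. The central ecological question for a monitored population is whether
the disease is **contagious** — spread by proximity to infected neighbours —
or primarily a response of susceptible hosts to environmental stress. This
package implements an analysis designed for exactly that question: monthly
presence/absence surveys of mapped colonies are fitted with a
latent-Gaussian binomial model in which neighbourhood effects, host traits
and environmental forcing compete as explanations, while a spatio-temporal
random field absorbs structured variation that none of them explain.

It is intended for disease ecologists and biostatisticians working with
colony-level longitudinal survey panels (tens to a few hundred mapped
individuals, monthly-scale revisits).

## The model

Disease presence $y(s_i,t) \in \{0,1\}$ on colony $i$ at survey occasion
$t$ follows a Bernoulli-logit model

$$
\eta(s_i,t) \;=\; z(s_i,t)^\top \beta \;+\; \xi(s_i,t) \;+\; \varepsilon(s_i,t),
\qquad \Pr\{y = 1\} = \operatorname{logit}^{-1}(\eta),
$$

* $z(s_i,t)$: intercept plus eight standardized covariates — northing,
  easting, colony size (log10 cm³), the running count of previous disease
  incidences, distance to the nearest neighbouring colony (log10 m),
  distance from a colony infected at the previous occasion (log10 m),
  trailing 30-day mean water temperature (°C), and solar insolation
  (kW m⁻² day⁻¹);
* $\xi$: a separable latent field — Matérn in space (exact dense
  covariance at the colony sites), stationary AR(1) over occasions;
* $\varepsilon$: an iid observation-level effect, integrated out exactly
  by Gauss–Hermite quadrature inside the likelihood.

Inference is a nested Laplace scheme: a damped-Newton Gaussian
approximation over the latent vector at each point of a deterministic
hyperparameter grid, evidence-weighted mixing of the conditional coefficient
marginals, and a profile-Laplace marginal for the intercept. A covariate is
reported *significant* when its 2.5–97.5% posterior quantile range excludes
zero. The package also provides kernel-smoothed intensity maps of the
colony pattern and of disease reoccurrence, and a synthetic survey-panel
generator with known ground truth for simulation-based validation.

## Worked example

The `analysis/` scripts run the full workflow on a simulated
study-emulating panel (69 colonies in a 220 m × 560 m site, 83 monthly
surveys, published effect sizes as simulated truth):

```sh
Rscript analysis/01_simulate.R   # panel -> results/panel.csv
Rscript analysis/02_fit.R        # posterior summary -> results/summary.csv
Rscript analysis/03_intensity.R  # density maps -> results/intensity_*.csv
Rscript analysis/04_recovery.R   # calibration -> results/recovery_*.csv
```

Step 2 prints the coefficient table (here from the panel simulated in step
1, overall prevalence 8.7%):

```
                   term               label  mean   sd  q025  q500  q975  mode significant
              intercept           Intercept -3.28 0.23 -3.73 -3.27 -2.86 -3.25        TRUE
               northing            Northing  0.39 0.13  0.18  0.37  0.71  0.35        TRUE
                easting             Easting  0.35 0.09  0.17  0.35  0.54  0.35        TRUE
            colony_size         Colony size  0.17 0.07  0.04  0.17  0.30  0.17        TRUE
    previous_incidences Previous incidences  1.17 0.10  0.98  1.17  1.35  1.17        TRUE
       distance_nearest            Distance -0.16 0.07 -0.29 -0.16 -0.03 -0.16        TRUE
 distance_prev_infected   Previous distance -0.01 0.09 -0.17 -0.01  0.19 -0.03       FALSE
      water_temperature   Water temperature  0.51 0.08  0.35  0.51  0.68  0.51        TRUE
       solar_insolation    Solar insolation -0.01 0.08 -0.17 -0.01  0.14  0.00       FALSE
```

Each row is a posterior marginal of a
standardized coefficient: `mean` is the effect per standard deviation of
the covariate on the log-odds of disease, and `significant` applies the
credible-interval rule. In this realisation the strongest driver is the
colony's own disease history (`previous incidences`, 1.17 ± 0.10), with
water temperature (0.51 ± 0.08) positive as well — the maximum deviation of
any posterior mean from this panel's simulated truth is 0.12. The same
script reports the modal hyperparameters of the evidence grid, and step 3
prints mass checks of the intensity surfaces (68.8 integrated colonies for
69 mapped ones).

Equivalent calls from R:

```r
library(whitepox)
gen   <- generate_panel(scenario_config(seed = 2003))
fit   <- fit_stmodel(gen$panel, build_design(gen$panel))
summary(fit)
```

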