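# incitrend

Estimation of age-specific **incidence rates of chronic (irreversible)
diseases — and their secular trends — from a series of cross-sectional
prevalence surveys**, combined with general mortality and the mortality
rate ratio of ill versus healthy persons. The package is aimed at
epidemiologists doing NCD surveillance in settings where running a disease
register or a series of follow-up studies is impractical: a sequence of
prevalence studies plus vital statistics (and, e.g., a case-control
estimate of relative mortality) is enough.

## The model

In the illness-death model (Healthy → Ill → Dead, with incidence *i* and
mortality rates *m*₀ of the healthy, *m*₁ of the ill), the age-specific
prevalence *p*(*t*, *a*) satisfies a first-order PDE along the cohort
characteristics *t* − *a* = const:

    (∂t + ∂a) p = (1 − p) { i − p (m₁ − m₀) }
                = (1 − p) { i − m · PAR(p, R) }

where *m* = *p m*₁ + (1 − *p*) *m*₀ is the general mortality,
*R* = *m*₁/*m*₀ the mortality rate ratio, and
PAR(*p*, *R*) = *p*(*R*−1)/(*p*(*R*−1)+1) the population attributable
risk. Solving for *i* gives the **direct inversion** estimator

    î(t*, a) = (∂t + ∂a)p / (1 − p) + m · PAR(p, R)

with the derivative and the prevalence at *t*\* obtained from two surveys
along the cohort line (centered difference and convex midpoint
combination). The companion **weighted nonnegative least-squares**
estimator minimises the standardized squared deviation between the
observed survey prevalences and their first-order characteristic
predictions, weighting each survey cell by its sampling variance; it
decouples into closed-form scalar problems and equals the direct estimator
for noise-free, equally weighted data. Binomial survey noise and a
percentile bootstrap (B = 2000) provide 95 % confidence bands.

## Worked example

The built-in validation scenario emulates a national diabetes register
setting (Danish male population, ages 30+, 1995–2004): incidence rising
5.3 %/yr, mortality falling 2.5 %/yr (healthy) and 3.9 %/yr (ill), with
documented synthetic baseline age curves. `run_validation()` simulates
yearly prevalence cross-sections by Runge-Kutta integration along cohorts,
estimates the incidence at the nine midpoint times from consecutive survey
pairs, and compares against the generating ("true") incidence:

```r
library(incitrend)
val <- run_validation(method = "both")
val$errors[val$errors$method == "direct", ]
#>  t_star method median_per1e5 max_per1e5
#>  1995.5 direct          52.1      547.3
#>  1996.5 direct          49.5      363.8
#>  1997.5 direct          46.9      255.6
#>  1998.5 direct          44.4      189.2
#>  1999.5 direct          41.9      145.3
#>  2000.5 direct          39.7      114.9
#>  2001.5 direct          37.7       93.2
#>  2002.5 direct          35.9       81.6
#>  2003.5 direct          34.2       81.5
round(val$trend, 4)
#>        direct least_squares
#>        5.2998        5.2998
```

The error columns are absolute relative errors per 100,000 (so the worst
cell, 547 per 10⁵ at 1995.5, is a 0.55 % error); they decline over the
study period, the two methods agree cell for cell, and the log-linear
trend fitted to the estimated series at age 65.5 recovers the configured
5.3 %/yr increase to within 0.01 points. Individual estimates live on the
half-offset grid:

```r
df <- as.data.frame(val$estimates$direct[[1]])
df[df$age %in% c(45.5, 55.5, 65.5), c("time", "age", "incidence")]
#>    time  age incidence
#>  1995.5 45.5  0.002876
#>  1995.5 55.5  0.004918
#>  1995.5 65.5  0.006657   # rates per person-year
```

A thin command-line wrapper is installed as `exec/incitrend` with
subcommands `simulate`, `estimate`, `bootstrap` and `validate` over tidy
CSV files (`time,age,prevalence[,sigma][,n]` and `time,age,m,R`).

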