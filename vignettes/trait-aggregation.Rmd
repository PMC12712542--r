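---
title: "Transform first, then aggregate: methods behind traitagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transform first, then aggregate: methods behind traitagg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitagg)
```

## The model

Traits are measured on individuals; species-level analyses use
aggregates; and non-linear transformations (most often the natural log)
are applied somewhere in between. For one species with measurements
$x_1,\dots,x_n$, mean $\bar x$ and a transform $f$, the two possible
orders give different species values. Their difference is the *Jensen
gap*

$$\Delta \;=\; \frac{1}{n}\sum_j f(x_j) \;-\; f(\bar x),$$

which is $\le 0$ for concave $f$ (log, square root) and $\ge 0$ for
convex $f$, with equality exactly when $f$ is linear or the values have
no spread. Expanding $f$ to second order about $\bar x$,

$$\Delta \;\approx\; \tfrac12\, f''(\bar x)\, s^2,
\qquad s^2 = \frac{1}{n}\sum_j (x_j-\bar x)^2,$$

so for the log transform $\Delta \approx -s^2/(2\bar x^2)$: the gap
scales with the ratio of within-species variance to the squared species
mean. `jensen_gap_exact()` and `jensen_gap_quadratic()` compute the two
sides; `corrected_transformed_mean()` uses the approximation to recover
the mean of transformed values from a published summary (mean, SD, n)
when the individual records are gone.

### Why the order matters for relationships

Suppose a mechanism operating at the level of individuals links two
traits so that $f(y_j) = a + b\,g(x_j)$ exactly (a power law becomes
linear under logs). Averaging the transformed values preserves the
relationship exactly when both traits are measured on the same
individuals, and approximately otherwise. Transforming the averages
instead yields

$$f(\bar y) \;\approx\; a + b\,g(\bar x) + C,\qquad
C = \tfrac{b}{2}\,g''(\bar x)\,s_x^2-\tfrac12\,f''(\bar y)\,s_y^2,$$

and $C$ — evaluated by `species_offset_C()` — is species-specific
because it depends on the species' own means and variances. Unless $C$
happens to be constant, the species-level relationship is perturbed,
typically non-linearly.

### Exact decomposition of the distortion

Writing $x, y$ for the species values under the reference order and
$x^*, y^*$ under the other, define bias vectors
$\theta = x - x^*$ and $\omega = y - y^*$. Then, exactly,

$$\hat b_{x^*y^*}
 = \frac{\operatorname{cov}(x,y)-\operatorname{cov}(x,\omega)
        -\operatorname{cov}(\theta,y)+\operatorname{cov}(\theta,\omega)}
        {\operatorname{var}(x)+\operatorname{var}(\theta)
        -2\operatorname{cov}(x,\theta)},$$

with the analogous ratio for the Pearson correlation. This is algebra,
not approximation: `slope_decomposition()` verifies it by also fitting
the starred regression directly, and the two agree to $10^{-10}$
relative in the test suite, under either covariance divisor ($n$ or
$n-1$). A constant added to $\theta$ or $\omega$ changes nothing — only
the variance–covariance structure of the biases matters, not their
mean.

One sign convention had to be fixed: with $\theta$ *defined* as
$x - x^*$, the starred vector is $x^* = x - \theta$, so the cross terms
enter the decomposition with minus signs. The same identity is
sometimes written with plus signs throughout, which corresponds to
defining the bias as $x^* - x$; we kept the $x - x^*$ definition and
the minus signs, because making both choices simultaneously breaks the
identity. The labelling of which order is the reference is a parameter
(`reference` in `compare_aggregation_orders()`), not a hard-coded
assumption.

## The root-trait demonstration

Under cylindrical fine-root geometry, specific root length (root length
per unit dry mass, e.g. m g⁻¹) follows from root tissue density (RTD,
dry mass per root volume) and root diameter (D):

$$\mathrm{SRL} = \frac{4}{\pi\,\mathrm{RTD}\,D^2}
\quad\Longleftrightarrow\quad
\ln \mathrm{SRL} = \ln\tfrac{4}{\pi} - \ln \mathrm{RTD} - 2\ln D.$$

The identity holds for every individual root segment, so averaging the
log values per species preserves it *exactly*: the trivariate OLS fit
of mean-log SRL on mean-log RTD and mean-log D returns intercept
$\ln(4/\pi) = 0.2415645$, coefficients $-1$ (lnRTD) and $-2$ (lnD), and
$R^2 = 1$, for any non-degenerate data. `run_srl_demo()` performs this
fit and its aggregate-then-transform counterpart side by side, plus the
six pairwise regressions (SRL~RTD, SRL~D, RTD~D under each order). The
theoretical coefficients are bound to predictor *names*, never to
positions: $-1$ belongs to lnRTD and $-2$ to lnD, as the log-linear
identity dictates.

The constant $4/\pi$ is dimensionless only under mutually consistent
units; the package treats all values as unit-free and leaves unit
consistency to the caller. An inconsistent unit choice shifts the
intercept by a constant but leaves slopes and $R^2$ untouched, since a
unit change is linear.

## The synthetic-data generator

`simulate_trait_table()` emulates the structure of individual-level
records extracted from a large trait database:

- between-species variation: per trait, species log-means are drawn
  from $\mathcal N(\mu, \sigma_b^2)$;
- within-species variation: individual log values scatter around their
  species mean with SD $\sigma_w$ (lognormal on the raw scale, which
  keeps trait values strictly positive and the log transform always
  valid);
- per-species sample sizes: drawn uniformly from a configured integer
  range and rescaled by largest-remainder rounding so they sum exactly
  to the configured total;
- optionally disjoint individual sets per trait (each species' list is
  split in half, the odd individual going with the first trait) and
  independent multiplicative measurement noise.

The defaults are the study conditions the demonstration targets: 368
species and 1920 individuals, with two traits named RTD and D. The
distributional parameters are chosen once as realistic fine-root
values — RTD centred at 0.25 g cm⁻³ (log-mean $\ln 0.25$, log-SD 0.45),
D centred at 0.35 mm (log-SD 0.40), within-species log-SD 0.30,
per-species counts 1–10 — and are not tuned further. In the
*heterogeneous* mode, `within_log_sd = c(lo, hi)` assigns per-species
SDs spanning the range monotonically in the species log-mean, encoding
the empirical pattern that larger-mean species also vary more; this is
the configuration under which the aggregate-then-transform regression
visibly breaks down ($R^2$ well below 1, coefficients displaced), while
the transform-first fit still recovers the identity on the very same
table.

What the generator does **not** emulate: phylogenetic signal in species
means, correlated sampling effort, skew-free raw-scale noise,
measurement error correlated between traits, or the particular species
composition of any real database extract. Consequently, passing tests
show that the *machinery* is correct (the identities, the corrections,
the decompositions), not that any particular published number from real
data is reproduced — real-data coefficients depend on the actual
extract and are out of scope here.

## Numerical choices

- **Variance convention.** The stored within-species variance divides
  by $n$ (population form), matching the correction term's definition;
  a `sample` option converts an $n-1$ SD first. Species with $n = 1$
  are retained with zero variance — their gap is exactly zero and
  dropping them would silently change every regression.
- **Domain checks** are strict open-interval tests that raise errors
  naming the offending value; log of a zero trait value fails loudly
  rather than propagating $-\infty$ into covariances.
- **"Arcsine"** is implemented as $\arcsin\sqrt{x}$ on $(0,1)$, the
  variance-stabilising form used on proportions — not $\arcsin(x)$.
- **OLS** is solved by QR decomposition, never by inverting
  $X^\top X$, because the perfect-fit demonstration drives residuals to
  machine zero where normal equations lose digits. Saturated fits
  ($n = p$) return coefficients with `NaN` standard errors rather than
  erroring, since an exactly determined line is a legitimate limiting
  case. Perfect fits report their standard errors at floating-point
  noise (≲ 10⁻¹⁵) without clamping to zero.
- **Reproducibility.** The simulator seeds the base R generator once
  and consumes the stream in a fixed documented order (counts, species
  means per trait, then records trait by trait), so a config is
  reproducible across runs and platforms for a given RNG standard.
- **Problem sizes.** The test suite runs the full 368-species /
  1920-individual scale for the identity checks (fast: a 3-term OLS on
  368 rows), 200 random quadruples for the decomposition identity, 100
  random designs for the OLS unit, and 2000 species for the simulator's
  moment-recovery check; the whole suite completes in well under a
  minute.

## Known limitations

- The quadratic correction ignores third and higher moments; for
  strongly skewed within-species distributions the residual error is
  $O(\mu_3)$. No fourth-moment refinement is offered.
- No standard errors are attached to corrected transformed means
  (a delta-method variance would be a natural extension).
- The slope/correlation decomposition reports components; it does not
  attempt an errors-in-variables *correction* of the biased slope.
- Regression here is plain OLS; standardized major-axis fits, common in
  allometry, are deliberately excluded.
- With traits measured on disjoint individual sets the transform-first
  identity holds only approximately (means estimate expectations); the
  `disjoint` flag of `run_srl_demo()` exists precisely to show that
  degradation.

```{r demo}
tab <- simulate_trait_table(simulation_config(seed = 42))
rep <- run_srl_demo(tab)
rep$trivariate_transform_first
rep$trivariate_transform_last
```
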