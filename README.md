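# apcmort

Bayesian age-period-cohort (APC) analysis of cause-specific mortality on a
Lexis grid.

## The problem

Registries record deaths by calendar year, age and ICD cause code; census
offices supply mid-year population denominators. A recurring epidemiological
question is whether cause-specific risk is tied to *when people were born*
(a cohort effect — e.g. a generation that grew up under better early-life
conditions resisting bacterial infection in old age) rather than to *when
they die* (a period effect — diagnosis, treatment, coding). `apcmort` is for
analysts who want to decompose such registry tables into age, period and
birth-cohort effects, test whether the decomposition differs by sex, and
read the cohort curve through its inflection points — the only part of an
APC decomposition that is identified.

The package covers the whole workflow:

* **Lexis tabulation** — ICD-9/ICD-10 cause classification (septicaemia and
  non-bacterial pneumonia code sets built in), record-level tabulation onto
  an age x period x sex grid, directly age-standardized rates, delimited
  text I/O.
* **Bayesian Poisson APC models** — RW2 (second-order random-walk)
  smoothing priors, hard reference constraints (one corner age group, two
  reference periods, one reference cohort) that resolve the APC
  identifiability problem, adaptive Metropolis-within-Gibbs MCMC in C++,
  Gelman-Rubin R-hat diagnostics.
* **Model selection** — saturated-form Poisson deviance, DIC with the
  mean-parameterization plug-in pD, and a partial-model menu comparison.
* **Second-order curve analysis** — posterior second differences,
  downturn/upturn flags with posterior probabilities, female-vs-male
  divergence summaries.
* **A synthetic registry generator** — Poisson draws from known log-linear
  APC structure ("septicaemia-like" with a planted mid-century cohort
  downturn steeper for women, "pneumonia-like" with an upturn and no sex
  interaction, and a flat "null"), so every stage is testable without
  registry access.

## The model

Deaths in age group *a*, period *p*, sex *s* with exposure *E* follow

y ~ Poisson(E exp(η)),  η = μ + α_a + π_p + γ_c + 1[s=F](δ + α^F_a + π^F_p + γ^F_c),

with cohort index c = p − a + A along the Lexis diagonals. Because
c − p + a is constant, linear trends in (α, π, γ) are not identified; the
package pins α₁, two reference periods, one reference cohort (and the same
pattern on the female deviations) at zero and interprets only second-order
changes. Each curve carries a forward RW2 prior — level *i* is Gaussian
around 2x₍ᵢ₋₁₎ − x₍ᵢ₋₂₎ with a Gamma-hyperpriored precision — so curvature
is penalized adaptively. Models are compared with DIC = D̄ + p_D, and curves
are reported through d_i = x₍ᵢ₊₁₎ − 2x_i + x₍ᵢ₋₁₎ with posterior
probabilities P(d_i < 0). See `vignettes/apc-mortality-methods.Rmd` for the
full account.

## Worked example

```r
library(apcmort)

grid <- make_grid(20, 5, 14, 1976, 5, 6)   # ages 20-24..85+, 1976..2005
grid
#> Lexis grid: 14 age groups (20-24 .. 85+), 6 periods (1976-1980 ..
#> 2001-2005), 19 cohorts (labels 1896 .. 1986)

scenario <- make_scenario("septicaemia_like", grid = grid, seed = 1)
deaths <- simulate_table(scenario)
deaths
#> Lexis table [septicaemia_like]: 14 x 6 x 2 cells, 5706 deaths,
#> 16,800,000 person-years

round(age_standardized_rate(deaths, "M"), 1)
#> 1976-1980 1981-1985 1986-1990 1991-1995 1996-2000 2001-2005
#>      39.2      40.8      40.5      40.5      39.7      39.5

design <- build_design(grid, c("age", "period", "cohort"),
                       c("offset", "age", "period", "cohort"))
fit <- run_mcmc(deaths, design, prior_spec(),
                mcmc_config(n_chains = 4, n_burn = 1000, n_keep = 4000,
                            seed = 1))
fit
#> APC posterior samples: 4 chains x 4000 draws of 72 parameters
#> (+6 RW2 precisions); max R-hat 1.029

dic(fit, deaths)
#> APC+sex(o,a,p,c): DIC = 162.1 (Dbar 132.9, Dhat 103.7, pD 29.2)

cr <- curvature_report(fit, "cohort", "F")
subset(cr$table, label %in% c(1936, 1941, 1946))[,
       c("label", "mean", "lower", "upper", "p_negative")]
#>    label         mean      lower     upper p_negative
#> 8   1936  0.011620863 -0.1283490 0.1564160  0.4381250
#> 9   1941 -0.034269757 -0.1819468 0.1022377  0.6803125
#> 10  1946 -0.004795042 -0.1462848 0.1415214  0.5345000

sex_divergence(fit, "cohort", from_index = scenario$inflection_index)
#> Sex divergence (cohort): post-inflection slope difference -0.0275
#> [-0.1044, 0.0411] from index 10
```

Reading the output: the generator planted a slope change of −0.04 at the
cohort labelled 1941, and the posterior mean second difference there is
−0.034 with P(d < 0) = 0.68 — the evidence points the right way, but at
tens of deaths per cell a single 5-year second difference is inherently
noisy (the methods vignette quantifies this), which is why the curves are
read through their credible bands rather than point flags. The female
post-inflection slope difference (−0.028, truth −0.03) says women's cohort
curve declines faster after the inflection. All non-reference relative
risks, the DIC table and R-hat values come from `summarize_effects()`,
`fit_model_menu()` and `rhat_all()`.

## The analysis workflow

The `analysis/` directory holds the numbered drivers for a full synthetic
study; each is a thin narrative over the package and writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1    # registries + standardized rates
Rscript analysis/02_fit.R      --seed 1    # full APC+sex fits, R-hat, effects
Rscript analysis/03_compare.R  --seed 1    # DIC menu over 6 partial models
Rscript analysis/04_report.R   --seed 1    # curvature + sex-divergence report
```

`--scale paper` switches the fits from the desk-scale 4 chains x (1,000 +
4,000) to the full 5 chains x (10,000 + 40,000) configuration.

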