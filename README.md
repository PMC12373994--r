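# cb1pet

Quantification and inference chain for **CB1 receptor availability**
measured with [¹¹C]OMAR PET, and its association with PTSD diagnosis and
symptom clusters — implemented as a tested R package plus a set of
narrative analysis scripts.

The neuroimaging question: the endocannabinoid system is a candidate
substrate of stress pathology, and the CB1 receptor is its main central
receptor. CB1R availability is indexed by the tracer's regional **volume of
distribution**

V_T = equilibrium ratio of tissue to metabolite-corrected plasma tracer
concentration,

estimated here by **multilinear analysis-1 (MA1)** with t\* = 30 min from
regional time–activity curves and a metabolite-corrected arterial input
function, and then related to demographics, diagnostic group
(PTSD / trauma-exposed controls / healthy controls) and CAPS-5 symptom
clusters with **Bayesian robust regression**:

```
V_T ~ Student-t(mu, nu, eps),   mu = X beta
beta_j ~ Normal(0, 1),   nu ~ InverseGamma(3, 1),   eps ~ Exponential(1)
```

An association is called **robust** when the 89% highest-posterior-density
(HPD) interval of its slope excludes 0; fits are gated on split-R̂ < 1.01
and effective sample size > 1000 per coefficient.

Individual-level study data are not public, so the package ships a
synthetic-cohort generator (19 PTSD / 27 TC / 16 HC, published
demographics, two-tissue-compartment tracer kinetics, configurable planted
effects — by default an anhedonia/emotional-numbing slope of 0.014 V_T per
CAPS point) against which every stage is validated.

## Layout

- `R/` — the package: cohort and tracer-kinetics simulation
  (`generate_cohort`, `simulate_tac`, `simulate_blood`), input-function
  construction (`fit_parent_fraction`, `build_input_function`,
  `integrate_input`), kinetic estimators (`ma1_vt`, `logan_vt`,
  `composite_whole_brain`), Bayesian models (`build_design`, `fit_model`,
  `hpd_interval`, `run_model_suite`), summary-statistics checks
  (`welch_t`, `anova_f`, `pearson_chi2`, `cohort_table_checks`), and the
  orchestrator `run_pipeline`.
- `analysis/01...06_*.R` — numbered drivers that run each stage and write
  tables under `results/`.
- `vignettes/cb1pet-methods.Rmd` — the models, assumptions, numerical
  choices and limitations.
- `tests/testthat/` — unit, property and end-to-end tests.

## Worked example

```r
library(cb1pet)

# tracer kinetics: simulate a noiseless TAC and recover V_T by MA1
model <- input_function_model()          # Feng-type arterial model
inp   <- sample_input_function(model)    # corrected plasma input
kp    <- kinetic_params(K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0.05)
analytic_vt(kp)
#> [1] 4
tac <- simulate_tac(kp, inp, frame_schedule())
ma1_vt(tac, inp, t_star = 30)
#> region V_T estimate [MA1]: 3.9705 (b = -24.74 min, 18 frames, rms 0.254)

# symptom inference on a synthetic cohort with the planted 0.014 slope
cohort <- generate_cohort(cohort_config(), seed = 1)
fit <- fit_model(build_design(cohort, "symptom", cluster = "c8_anhedonia"),
                 seed = 1)
fit$coefficients[2, c("term", "mean", "hpd_low", "hpd_high", "robust")]
#>           term        mean      hpd_low   hpd_high robust
#> 2 c8_anhedonia 0.007779065 -0.002586907 0.01960505  FALSE
```

The MA1 estimate (3.97) sits within 1% of the analytic V_T = 4. The
symptom model recovers a positive anhedonia slope, but at the study's
sample size (46 trauma-exposed subjects) the posterior SD (~0.007) is
comparable to the planted effect, so the 89% HPD does not always exclude
zero — single-cohort detection of an effect this size is underpowered.
The test suite shows the slope is recovered to within 0.004 with its HPD
excluding zero on a 500-subject cohort.

Run the narrative analyses with, e.g.:

```sh
Rscript analysis/03_kinetics_vt.R
Rscript analysis/04_bayesian_models.R
```

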