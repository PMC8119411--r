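# elbmr

Non-invasive estimation of lean body mass from spot urine samples, for
field studies of wild primates (and other mammals) where weighing
animals is impossible.

## The science

Urinary **creatinine** (mg/ml) is a breakdown product of muscle creatine,
excreted roughly in proportion to skeletal muscle mass — but its
concentration in a spot sample also depends on how dilute the urine is.
**Specific gravity** (SG, water = 1.0) measures urine concentration
*only*. The variation in creatinine left over after removing the
variation explained by SG is therefore a proxy for muscle mass:
**estimated lean body mass (ELBM)**.

The calibration is a global least-squares fit forced through the origin
(water: SG = 1.0, creatinine = 0.0), with a quadratic term for the
curvilinear SG–creatinine relation:

```
creatinine = b1 (SG − 1) + b2 (SG − 1)²  +  ELBM
```

Samples with SG < 1.003 are too dilute to quantify and are removed
first. ELBM (the residual) is then modelled against a monthly **fruit
availability index** (FAI = percent of censused stems with dbh > 10 cm
bearing fruit) and age-sex class, with a GAMM:

```
ELBM ~ age_sex_class + s(FAI) + (1 | individual)
```

plus a companion linear mixed model with FAI binned high/low at its
median for visualization, and relevel-style pairwise class contrasts.

Because datasets of this kind are rarely deposited, the package includes
a first-class synthetic-data generator with explicit latent ground truth
(true lean mass, hydration factor per sample), so the entire pipeline is
testable by parameter recovery.

## Worked example

```r
library(elbmr)

ds  <- simulate_dataset(generator_config(seed = 1))  # 1,131 samples, 70 individuals
flt <- filter_dilute(ds$samples)                     # drop SG < 1.003
fit <- fit_calibration(flt$kept, excluded = flt$excluded)
print(fit)
#> Through-origin creatinine ~ SG calibration (two_coefficients)
#>   b1 (SG-1):        32.3185
#>   b2 (SG-1)^2:     272.3287
#>   r2 (uncentered): 0.9488   r2_adj: 0.9487
#>   n used: 1124   n excluded (dilute): 7

elbm <- compute_elbm(attach_fai(flt$kept, ds$fai), fit)
fit_gamm(elbm, ds$individuals)
#> ELBM GAMM (baseline class: adult_female)
#>                          term estimate      se t_stat   p_value
#> 1                 (Intercept) -0.05910 0.01678 -3.523 0.0004444
#> 2   age_sex_classflanged_male  0.09377 0.02435  3.850 0.0001251
#> 3 age_sex_classunflanged_male  0.14168 0.04099  3.457 0.0005683
#> 4     age_sex_classadolescent -0.08071 0.03361 -2.401 0.0165037
#> 5      age_sex_classdependent -0.17559 0.05344 -3.285 0.0010510
#> s(FAI): edf = 1.000, F = 103.22, p = 0
#> random intercept SD = 0.0698, residual SD = 0.1983, r2_adj = 0.246
#> n = 1124 observations, 70 individuals
```

Reading the output: both adult male classes carry more lean mass than
adult females (positive coefficients, here +0.094 and +0.142 mg/ml of
residual creatinine), immatures less (negative); the FAI smooth is
strongly significant — in this synthetic world lean mass genuinely
tracks fruit availability, and the model recovers it.

The full pipeline (calibration → ELBM → GAMM + contrasts + binary-FAI
model + predictions, with CSV artifacts, figures and a reproducibility
manifest) runs as:

```r
run_pipeline(pipeline_config(output_dir = "elbm_out", seed = 1))
```

or from the shell:

```sh
Rscript -e 'quit(status = elbmr::elbm_cli())' all --seed 1 --out elbm_out
```

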