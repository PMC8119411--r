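#' Accounting of the reference dataset emulated by the generator
#'
#' The published accounting of the wild-orangutan urine dataset whose
#' structure the synthetic generator reproduces: per-class sample counts
#' after the dilute-sample filter, the number of overly dilute samples
#' removed (SG < 1.003), and the number of sampled individuals. These are
#' inputs to the emulation, not outputs of this package.
#'
#' @return list with `per_class_samples` (named integer vector over
#'   [age_sex_classes()]), `n_used`, `n_excluded_dilute`,
#'   `n_individuals`.
#' @export
reference_study_counts <- function() {
  list(
    per_class_samples = c(
      adult_female = 511L, flanged_male = 431L, unflanged_male = 53L,
      adolescent = 113L, dependent = 22L
    ),
    n_used = 1130L,
    n_excluded_dilute = 14L,
    n_individuals = 70L
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the latent generative model. The defaults emulate
#' the sampling structure of a long-term wild-orangutan urine dataset:
#' about 1,130 first-morning-void samples from 70 individuals in five
#' age-sex classes, specific gravity mostly within 1.003--1.055 and
#' creatinine mostly within 0.022--3.10 mg/ml, with a curvilinear
#' SG--creatinine relation and a lean-mass signal coupled to monthly fruit
#' availability.
#'
#' The latent model for a sample from individual \eqn{i} in month \eqn{m}:
#' \deqn{C \sim LogNormal(0, \sigma_{hyd}^2)}
#' \deqn{LM = baseline_i (1 + \gamma z(FAI_m))}
#' \deqn{SG = 1 + a C}
#' \deqn{creatinine = \kappa \, LM (C + \lambda C^2) e^\epsilon,\quad
#'       \epsilon \sim N(0, \sigma_{assay}^2)}
#' where \eqn{C} is the latent urine-concentration factor and \eqn{z} is
#' the FAI series standardized to mean 0, SD 1.
#'
#' @param n_individuals_per_class Named integer vector (names from
#'   [age_sex_classes()]): individuals to generate per class. Default sums
#'   to 70 with class shares approximating the per-class sample counts of
#'   the emulated study.
#' @param samples_per_individual Samples per individual: a single count, a
#'   length-2 range (uniform integer draw), or a named per-class vector.
#'   The per-class default yields about 1,131 samples in total.
#' @param n_months Number of consecutive study months.
#' @param start_month First month, `"YYYY-MM"`.
#' @param fruiting_prob Monthly per-stem fruiting probabilities, recycled
#'   to `n_months`. Default is a mild seasonal sinusoid between about 0.03
#'   and 0.13, typical of a non-masting peat-swamp forest.
#' @param n_stems Number of censused stems (default 2400).
#' @param dbh_small_frac Fraction of stems generated with dbh <= 10 cm so
#'   the downstream size filter is exercised.
#' @param kappa Creatinine output per unit lean mass per unit
#'   concentration (mg/ml).
#' @param a SG units per unit concentration.
#' @param lambda_curv Quadratic concentration coefficient; positive values
#'   produce the curvilinear SG--creatinine relation.
#' @param gamma_fai Lean-mass sensitivity per SD of FAI.
#' @param class_mean_lean_mass Named per-class mean baseline lean mass
#'   (arbitrary units). Defaults preserve the ordering flanged male >=
#'   unflanged male > adult female > adolescent > dependent.
#' @param lean_mass_cv Coefficient of variation of individual baselines
#'   around their class mean (lognormal).
#' @param sigma_hydration Log-scale SD of the concentration factor C.
#' @param sigma_assay Log-scale SD of multiplicative assay noise.
#' @param seed Integer seed; all generator functions are deterministic
#'   given the config.
#' @return A list of class `elbm_generator_config`.
#' @export
generator_config <- function(n_individuals_per_class = c(
                               adult_female = 24, flanged_male = 22,
                               unflanged_male = 7, adolescent = 10,
                               dependent = 7
                             ),
                             samples_per_individual = c(
                               adult_female = 21, flanged_male = 20,
                               unflanged_male = 8, adolescent = 11,
                               dependent = 3
                             ),
                             n_months = 24,
                             start_month = "2015-01",
                             fruiting_prob = NULL,
                             n_stems = 2400,
                             dbh_small_frac = 0.15,
                             kappa = 0.35,
                             a = 0.015,
                             lambda_curv = 0.3,
                             gamma_fai = 0.1,
                             class_mean_lean_mass = c(
                               adult_female = 1.00, flanged_male = 1.15,
                               unflanged_male = 1.15, adolescent = 0.85,
                               dependent = 0.70
                             ),
                             lean_mass_cv = 0.1,
                             sigma_hydration = 0.6,
                             sigma_assay = 0.15,
                             seed = 1L) {
  classes <- age_sex_classes()
  bad <- setdiff(names(n_individuals_per_class), classes)
  if (length(bad) > 0) {
    elbm_error(paste0("unknown age-sex class key(s): ", paste(bad, collapse = ", ")),
               "elbm_config_error")
  }
  bad <- setdiff(names(class_mean_lean_mass), classes)
  if (length(bad) > 0) {
    elbm_error(paste0("unknown age-sex class key(s): ", paste(bad, collapse = ", ")),
               "elbm_config_error")
  }
  if (any(n_individuals_per_class < 0)) {
    elbm_error("individual counts must be >= 0", "elbm_config_error")
  }
  if (any(class_mean_lean_mass <= 0)) {
    elbm_error("class mean lean masses must be > 0", "elbm_config_error")
  }
  stopifnot(
    n_months >= 1, n_stems >= 1, kappa > 0, a > 0, lambda_curv >= 0,
    lean_mass_cv >= 0, sigma_hydration > 0, sigma_assay >= 0,
    dbh_small_frac >= 0, dbh_small_frac < 1
  )
  if (is.null(fruiting_prob)) {
    fruiting_prob <- 0.08 + 0.05 * sin(2 * pi * (seq_len(n_months) - 1) / 12)
  }
  fruiting_prob <- rep_len(fruiting_prob, n_months)
  if (any(fruiting_prob < 0 | fruiting_prob > 1)) {
    elbm_error("fruiting probabilities must lie in [0, 1]", "elbm_validation_error")
  }
  structure(list(
    n_individuals_per_class = n_individuals_per_class,
    samples_per_individual = samples_per_individual,
    n_months = as.integer(n_months),
    start_month = start_month,
    fruiting_prob = fruiting_prob,
    n_stems = as.integer(n_stems),
    dbh_small_frac = dbh_small_frac,
    kappa = kappa, a = a, lambda_curv = lambda_curv,
    gamma_fai = gamma_fai,
    class_mean_lean_mass = class_mean_lean_mass,
    lean_mass_cv = lean_mass_cv,
    sigma_hydration = sigma_hydration,
    sigma_assay = sigma_assay,
    seed = as.integer(seed)
  ), class = "elbm_generator_config")
}

class_prefix <- c(adult_female = "AF", flanged_male = "FM",
                  unflanged_male = "UM", adolescent = "AL", dependent = "DP")

# consecutive "YYYY-MM" keys starting at start_month
month_sequence <- function(start_month, n_months) {
  start <- as.Date(paste0(start_month, "-01"))
  format(seq(start, by = "month", length.out = n_months), "%Y-%m")
}

#' Generate a synthetic study population
#'
#' Draws one baseline lean mass per individual, lognormal around the class
#' mean with coefficient of variation `lean_mass_cv`. Deterministic given
#' the config (seed included).
#'
#' @param config An [generator_config()] object.
#' @return data.frame with columns `individual_id`, `age_sex_class`,
#'   `baseline_lean_mass`.
#' @export
make_population <- function(config) {
  stopifnot(inherits(config, "elbm_generator_config"))
  counts <- config$n_individuals_per_class
  classes <- names(counts)
  pop <- withr::with_seed(config$seed, {
    out <- lapply(classes, function(cl) {
      n <- counts[[cl]]
      if (n == 0) return(NULL)
      m <- config$class_mean_lean_mass[[cl]]
      cv <- config$lean_mass_cv
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        base <- rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        base <- rep(m, n)
      }
      data.frame(
        individual_id = sprintf("%s_%02d", class_prefix[[cl]], seq_len(n)),
        age_sex_class = cl,
        baseline_lean_mass = base,
        stringsAsFactors = FALSE
      )
    })
    out <- Filter(Negate(is.null), out)
    if (length(out) == 0) NULL
    else do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  if (is.null(pop)) {
    pop <- data.frame(individual_id = character(0), age_sex_class = character(0),
                      baseline_lean_mass = numeric(0))
  }
  pop
}

#' Simulate a monthly phenology census
#'
#' Each stem gets a fixed diameter at breast height (dbh); a fraction
#' `dbh_small_frac` is generated at or below the 10 cm threshold so the
#' FAI size filter is exercised. Each month every stem fruits
#' independently with that month's probability.
#'
#' @param n_stems Number of stems (>= 1).
#' @param n_months Number of months.
#' @param fruiting_prob Vector of per-month fruiting probabilities in
#'   \[0, 1\], recycled to `n_months`.
#' @param dbh_small_frac Fraction of stems with dbh <= 10 cm.
#' @param seed Integer seed.
#' @param start_month First month as `"YYYY-MM"`.
#' @return data.frame with columns `month`, `stem_id`, `dbh_cm`,
#'   `fruiting` (0/1), one row per stem-month.
#' @export
simulate_phenology <- function(n_stems, n_months, fruiting_prob,
                               dbh_small_frac = 0.15, seed = 1L,
                               start_month = "2015-01") {
  stopifnot(n_stems >= 1, n_months >= 1)
  fruiting_prob <- rep_len(fruiting_prob, n_months)
  if (any(fruiting_prob < 0 | fruiting_prob > 1)) {
    elbm_error("fruiting probabilities must lie in [0, 1]", "elbm_validation_error")
  }
  months <- month_sequence(start_month, n_months)
  withr::with_seed(seed, {
    n_small <- round(n_stems * dbh_small_frac)
    dbh <- c(
      if (n_small > 0) runif(n_small, 2, 10) else numeric(0),
      10 + stats::rexp(n_stems - n_small, rate = 1 / 15)
    )
    dbh <- sample(dbh)
    stem_id <- sprintf("T%04d", seq_len(n_stems))
    out <- lapply(seq_len(n_months), function(m) {
      data.frame(
        month = months[m],
        stem_id = stem_id,
        dbh_cm = dbh,
        fruiting = as.integer(runif(n_stems) < fruiting_prob[m]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# number of samples for one individual of class cl under the config
samples_for_class <- function(config, cl) {
  spi <- config$samples_per_individual
  if (!is.null(names(spi))) {
    if (!cl %in% names(spi)) {
      elbm_error(paste0("samples_per_individual has no entry for class ", cl),
                 "elbm_config_error")
    }
    return(as.integer(spi[[cl]]))
  }
  if (length(spi) == 2) {
    return(as.integer(round(runif(1, spi[1] - 0.5, spi[2] + 0.5))))
  }
  as.integer(spi[1])
}

#' Simulate urine samples with latent ground truth
#'
#' Applies the latent generative model (see [generator_config()]) to a
#' population and an FAI series. Collection dates are uniform over the
#' series months (one sample per individual-day at most is not enforced;
#' days are drawn uniformly in 1--28).
#'
#' @param individuals data.frame from [make_population()].
#' @param fai An `elbm_fai_series` from [fai_series()] or [binarize_fai()].
#' @param config An [generator_config()] object.
#' @return list with two data.frames: `samples` (sample_id, individual_id,
#'   date, specific_gravity, creatinine_mg_ml) and `truth` (sample_id,
#'   true_lean_mass, hydration_factor, assay_noise), matched one-to-one.
#' @export
simulate_samples <- function(individuals, fai, config) {
  stopifnot(inherits(config, "elbm_generator_config"))
  months <- fai$month
  z <- as.numeric(scale(fai$fai_percent))
  if (length(months) < 2 || any(!is.finite(z))) {
    elbm_error("FAI series must contain >= 2 months with varying FAI",
               "elbm_validation_error")
  }
  tlm_factor <- 1 + config$gamma_fai * z
  if (any(tlm_factor <= 0)) {
    elbm_error(paste0(
      "gamma_fai = ", config$gamma_fai,
      " drives true lean mass <= 0 in month(s): ",
      paste(months[tlm_factor <= 0], collapse = ", ")
    ), "elbm_generation_error")
  }
  withr::with_seed(config$seed + 1L, {
    rows <- lapply(seq_len(nrow(individuals)), function(i) {
      k <- samples_for_class(config, individuals$age_sex_class[i])
      if (k == 0) return(NULL)
      mi <- sample.int(length(months), k, replace = TRUE)
      day <- sample.int(28, k, replace = TRUE)
      C <- rlnorm(k, 0, config$sigma_hydration)
      eps <- if (config$sigma_assay > 0) rnorm(k, 0, config$sigma_assay) else numeric(k)
      tlm <- individuals$baseline_lean_mass[i] * tlm_factor[mi]
      data.frame(
        individual_id = individuals$individual_id[i],
        date = sprintf("%s-%02d", months[mi], day),
        specific_gravity = 1 + config$a * C,
        creatinine_mg_ml = config$kappa * tlm *
          (C + config$lambda_curv * C^2) * exp(eps),
        true_lean_mass = tlm,
        hydration_factor = C,
        assay_noise = eps,
        stringsAsFactors = FALSE
      )
    })
    all <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    all$sample_id <- sprintf("S%05d", seq_len(nrow(all)))
    list(
      samples = all[, c("sample_id", "individual_id", "date",
                        "specific_gravity", "creatinine_mg_ml")],
      truth = all[, c("sample_id", "true_lean_mass", "hydration_factor",
                      "assay_noise")]
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: population, phenology census, FAI series (with
#' high/low labels), and urine samples with ground truth, all from one
#' config.
#'
#' @param config An [generator_config()] object.
#' @return list with `individuals`, `phenology`, `fai`, `samples`,
#'   `truth`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "elbm_generator_config"))
  individuals <- make_population(config)
  phenology <- simulate_phenology(
    n_stems = config$n_stems, n_months = config$n_months,
    fruiting_prob = config$fruiting_prob,
    dbh_small_frac = config$dbh_small_frac,
    seed = config$seed + 2L, start_month = config$start_month
  )
  fai <- binarize_fai(fai_series(phenology))
  sim <- simulate_samples(individuals, fai, config)
  list(individuals = individuals, phenology = phenology, fai = fai,
       samples = sim$samples, truth = sim$truth)
}
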