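# Shared fixtures. Everything is generated in code; seeds are fixed so the
# suite is deterministic.

make_samples <- function(sg, creat = NULL, individual = "AF_01") {
  n <- length(sg)
  if (is.null(creat)) creat <- 50 * (sg - 1)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    individual_id = rep_len(individual, n),
    date = rep_len("2015-03-17", n),
    specific_gravity = sg,
    creatinine_mg_ml = creat,
    stringsAsFactors = FALSE
  )
}

# independent calibration oracle: 2x2 normal equations assembled by hand
oracle_through_origin <- function(sg, y) {
  x1 <- sg - 1
  x2 <- x1^2
  XtX <- matrix(c(sum(x1 * x1), sum(x1 * x2),
                  sum(x1 * x2), sum(x2 * x2)), 2, 2)
  Xty <- c(sum(x1 * y), sum(x2 * y))
  b <- solve(XtX, Xty)
  list(b1 = b[1], b2 = b[2], residuals = y - b[1] * x1 - b[2] * x2)
}

# small default simulation reused across model tests (computed once)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(
        n_individuals_per_class = c(
          adult_female = 8, flanged_male = 7, unflanged_male = 4,
          adolescent = 4, dependent = 3
        ),
        samples_per_individual = 12, seed = 42L
      )
      ds <- simulate_dataset(cfg)
      flt <- filter_dilute(ds$samples)
      fit <- fit_calibration(flt$kept, excluded = flt$excluded)
      elbm <- compute_elbm(attach_fai(flt$kept, ds$fai), fit)
      cache <<- list(config = cfg, data = ds, filter = flt,
                     calibration = fit, elbm = elbm)
    }
    cache
  }
})
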