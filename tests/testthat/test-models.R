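test_that("a zero-variance response collapses to the null model", {
  sim <- small_sim()
  e0 <- sim$elbm
  e0$elbm <- 0
  g <- fit_gamm(e0, sim$data$individuals, k = 5)
  expect_equal(max(abs(g$coefficients$estimate)), 0, tolerance = 1e-10)
  expect_equal(g$smooth_summary$edf, 1, tolerance = 0.1)
  expect_equal(g$random_intercept_sd, 0, tolerance = 1e-8)
  expect_equal(g$residual_sd, 0, tolerance = 1e-10)
})

test_that("with one sample per individual the fit reduces to OLS on class means", {
  # two balanced classes, no smooth, random intercept confounded with residual
  n <- 12
  ind <- data.frame(
    individual_id = sprintf("I%02d", 1:n),
    age_sex_class = rep(c("adult_female", "flanged_male"), each = n / 2)
  )
  set.seed(88)
  y <- c(rnorm(n / 2, 0.1, 0.05), rnorm(n / 2, 0.35, 0.05))
  tab <- data.frame(sample_id = sprintf("S%02d", 1:n),
                    individual_id = ind$individual_id,
                    date = "2015-06-01", elbm = y)
  g <- fit_gamm(tab, ind, smooth = FALSE)
  m1 <- mean(y[1:(n / 2)])
  m2 <- mean(y[(n / 2 + 1):n])
  est <- setNames(g$coefficients$estimate, g$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), m1, tolerance = 1e-6)
  expect_equal(unname(est["age_sex_classflanged_male"]), m2 - m1,
               tolerance = 1e-6)
})

test_that("GAMM errors on inestimable designs", {
  sim <- small_sim()
  one_class <- sim$elbm[sim$elbm$individual_id %in%
                          sim$data$individuals$individual_id[
                            sim$data$individuals$age_sex_class == "adult_female"], ]
  expect_error(fit_gamm(one_class, sim$data$individuals),
               class = "elbm_single_class_error")
  expect_error(fit_gamm(sim$elbm, sim$data$individuals,
                        baseline_class = "no_such_class"),
               class = "elbm_validation_error")
})

test_that("releveling changes coefficients but not the fit", {
  sim <- small_sim()
  g1 <- fit_gamm(sim$elbm, sim$data$individuals, k = 6)
  g2 <- fit_gamm(sim$elbm, sim$data$individuals,
                 baseline_class = "flanged_male", k = 6)
  expect_equal(fitted(g1$model), fitted(g2$model), tolerance = 1e-6)
  expect_equal(as.numeric(logLik(g1$model)), as.numeric(logLik(g2$model)),
               tolerance = 1e-6)
  # the two directions of one contrast are antisymmetric
  e12 <- g1$coefficients$estimate[g1$coefficients$term == "age_sex_classflanged_male"]
  e21 <- g2$coefficients$estimate[g2$coefficients$term == "age_sex_classadult_female"]
  expect_equal(e12, -e21, tolerance = 1e-6)
})

test_that("pairwise_contrasts reports every ordered pair", {
  sim <- small_sim()
  ct <- pairwise_contrasts(sim$elbm, sim$data$individuals, k = 6)
  expect_equal(nrow(ct), 5 * 4) # 10 unordered pairs, both directions
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_equal(length(unique(key(ct$baseline_class, ct$other_class))), 10)
  # antisymmetry across directions
  for (i in seq_len(nrow(ct))) {
    j <- which(ct$baseline_class == ct$other_class[i] &
                 ct$other_class == ct$baseline_class[i])
    expect_equal(ct$estimate[i], -ct$estimate[j], tolerance = 1e-6)
  }
})

test_that("identical data in two classes gives a null contrast", {
  y <- rep(c(-0.1, 0.05, 0.2, -0.15, 0.1, -0.05), 2)
  ind <- data.frame(
    individual_id = c("A1", "A2", "B1", "B2"),
    age_sex_class = rep(c("adult_female", "flanged_male"), each = 2)
  )
  tab <- data.frame(
    sample_id = sprintf("S%02d", 1:12),
    individual_id = rep(c("A1", "A2", "B1", "B2"), each = 3),
    date = "2015-06-01", elbm = y
  )
  g <- fit_gamm(tab, ind, smooth = FALSE)
  est <- g$coefficients
  b <- est$estimate[est$term == "age_sex_classflanged_male"]
  p <- est$p_value[est$term == "age_sex_classflanged_male"]
  expect_equal(b, 0, tolerance = 1e-8)
  expect_gt(p, 0.99)
})

test_that("binary-FAI model: exact high/low balance zeroes the FAI term", {
  ind <- data.frame(individual_id = c("A1", "A2", "B1", "B2"),
                    age_sex_class = rep(c("adult_female", "flanged_male"), each = 2))
  vals <- c(-0.1, 0.05, 0.2, -0.15)
  tab <- expand.grid(individual_id = ind$individual_id,
                     fai_label = c("high", "low"), rep = 1:2,
                     stringsAsFactors = FALSE)
  tab$elbm <- rep(vals, 4) # same values under both labels
  tab$sample_id <- sprintf("S%02d", seq_len(nrow(tab)))
  tab$date <- "2015-06-01"
  # the perfectly symmetric fixture is near-unidentifiable for lme4's
  # convergence checker; the point estimate is still exact
  m <- suppressWarnings(fit_glmm_binary(tab, ind))
  co <- m$coefficients
  expect_equal(co$estimate[co$term == "fai_labellow"], 0, tolerance = 1e-8)
})

test_that("binary-FAI model detects scarcity and predicts on the full grid", {
  sim <- small_sim()
  m <- fit_glmm_binary(sim$elbm, sim$data$individuals)
  co <- m$coefficients
  expect_lt(co$estimate[co$term == "fai_labellow"], 0) # lower ELBM in low fruit

  pr <- predict_elbm(m)
  expect_equal(nrow(pr), 10) # 5 classes x 2 FAI levels
  # baseline class at reference FAI level equals the intercept
  b0 <- co$estimate[co$term == "(Intercept)"]
  expect_equal(pr$estimate[pr$age_sex_class == "adult_female" &
                             pr$fai_label == "high"], b0, tolerance = 1e-10)
  # main-effects model: identical high-low gap in every class, equal to
  # the fai_labellow coefficient (design-matrix identity)
  gap <- with(pr, estimate[fai_label == "high"] - estimate[fai_label == "low"])
  expect_equal(gap, rep(-co$estimate[co$term == "fai_labellow"], 5),
               tolerance = 1e-10)

  # with an interaction the per-class gaps are free and assembled by hand
  mi <- fit_glmm_binary(sim$elbm, sim$data$individuals, interaction = TRUE)
  pri <- predict_elbm(mi)
  ci <- setNames(mi$coefficients$estimate, mi$coefficients$term)
  gapi <- with(pri, estimate[fai_label == "high"] - estimate[fai_label == "low"])
  classes <- pri$age_sex_class[pri$fai_label == "high"]
  manual <- -(ci["fai_labellow"] + ifelse(
    classes == "adult_female", 0,
    ci[paste0("fai_labellow:age_sex_class", classes)]
  ))
  expect_equal(gapi, unname(manual), tolerance = 1e-10)
  expect_gt(var(gapi), 0)

  expect_error(
    predict_elbm(m, data.frame(age_sex_class = "gorilla", fai_label = "high")),
    class = "elbm_unseen_level_error"
  )
})

test_that("binary-FAI model needs both FAI levels", {
  sim <- small_sim()
  hi <- sim$elbm[sim$elbm$fai_label == "high", ]
  expect_error(fit_glmm_binary(hi, sim$data$individuals),
               class = "elbm_single_level_error")
})

test_that("fitted FAI smooth is non-decreasing over the central FAI range", {
  sim <- small_sim()
  g <- fit_gamm(sim$elbm, sim$data$individuals)
  fr <- g$frame
  qs <- quantile(fr$fai_percent, c(0.1, 0.9), names = FALSE)
  grid <- data.frame(age_sex_class = "adult_female",
                     fai_percent = seq(qs[1], qs[2], length.out = 50))
  pr <- predict_elbm(g, grid)
  expect_true(all(diff(pr$estimate) >= -1e-8))
})
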