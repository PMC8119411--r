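# Mixed models for ELBM: a GAMM with a penalized spline of continuous FAI
# plus treatment-coded age-sex class and a Gaussian random intercept per
# individual, and a simpler linear mixed model using FAI binned high/low.

#' Assemble the modelling frame
#'
#' Joins age-sex class (and FAI, when a series is supplied and not already
#' attached) onto an ELBM table and sets up factors: `age_sex_class`
#' releveled to `baseline_class`, `individual_id` as a grouping factor,
#' `fai_label` with reference level `"high"` so the low-fruit coefficient
#' measures the ELBM deficit during fruit scarcity.
#'
#' @param elbm_table From [compute_elbm()].
#' @param individuals data.frame with `individual_id`, `age_sex_class`.
#' @param fai_series Optional FAI series for [attach_fai()].
#' @param baseline_class Reference age-sex class for treatment coding.
#' @return data.frame ready for [fit_gamm()] / [fit_glmm_binary()].
#' @export
assemble_model_frame <- function(elbm_table, individuals, fai_series = NULL,
                                 baseline_class = "adult_female") {
  df <- elbm_table
  if (!is.null(fai_series) && !"fai_percent" %in% names(df)) {
    df <- attach_fai(df, fai_series)
  }
  idx <- match(df$individual_id, individuals$individual_id)
  if (anyNA(idx)) {
    elbm_error(
      paste0("individual_id(s) not in metadata: ",
             paste(unique(df$individual_id[is.na(idx)]), collapse = ", ")),
      "elbm_consistency_error"
    )
  }
  df$age_sex_class <- individuals$age_sex_class[idx]
  present <- intersect(age_sex_classes(), unique(df$age_sex_class))
  if (!baseline_class %in% present) {
    elbm_error(paste0("baseline class ", baseline_class, " absent from data"),
               "elbm_validation_error")
  }
  df$age_sex_class <- stats::relevel(factor(df$age_sex_class, levels = present),
                                     ref = baseline_class)
  df$individual_id <- factor(df$individual_id)
  if ("fai_label" %in% names(df)) {
    df$fai_label <- factor(as.character(df$fai_label), levels = c("high", "low"))
  }
  df
}

gamm_vcomp_sd <- function(m, term = "s(individual_id)") {
  # for a random-effect smooth the smoothing parameter is sig2/sigma_b^2
  sps <- if (length(m$sp)) m$sp else m$full.sp
  sp <- sps[grep(term, names(sps), fixed = TRUE)]
  if (length(sp) == 0 && !is.null(m$full.sp)) {
    sp <- m$full.sp[grep(term, names(m$full.sp), fixed = TRUE)]
  }
  if (length(sp) != 1 || !is.finite(m$sig2)) return(NA_real_)
  if (!is.finite(sp) || sp <= 0) return(if (is.infinite(sp)) 0 else NA_real_)
  unname(sqrt(m$sig2 / sp))
}

#' Fit the ELBM generalized additive mixed model
#'
#' Model: `elbm ~ age_sex_class + s(fai_percent) + s(individual_id, bs =
#' "re")`, Gaussian, fitted by REML in \pkg{mgcv}. The FAI smooth is a
#' penalized cubic regression spline (basis dimension `k`, smoothing
#' parameter chosen by REML); the random intercept enters as a
#' random-effect smooth, which is the standard \pkg{mgcv} encoding of a
#' Gaussian random intercept.
#'
#' Fixed-effect p-values are Wald t-tests on residual degrees of freedom;
#' the smooth is summarized by its effective degrees of freedom (edf) and
#' an approximate F-test.
#'
#' @param elbm_table From [compute_elbm()], with FAI attached or
#'   accompanied by `fai_series`.
#' @param individuals Individual metadata.
#' @param fai_series Optional FAI series (needed if FAI is not yet
#'   attached).
#' @param baseline_class Reference class for treatment coding.
#' @param k Basis dimension of the FAI smooth (default 10).
#' @param smooth Set `FALSE` to drop the FAI smooth (class + random
#'   intercept only).
#' @return Object of class `elbm_gamm`: `coefficients` (term, estimate,
#'   se, t_stat, p_value), `smooth_summary` (edf, f_stat, p_value; `NULL`
#'   when `smooth = FALSE`), `random_intercept_sd`, `residual_sd`,
#'   `r2_adj`, `baseline_class`, `n_obs`, `n_groups`, and the fitted
#'   \pkg{mgcv} model as `model`.
#' @export
fit_gamm <- function(elbm_table, individuals, fai_series = NULL,
                     baseline_class = "adult_female", k = 10, smooth = TRUE) {
  df <- assemble_model_frame(elbm_table, individuals, fai_series, baseline_class)
  if (nlevels(df$age_sex_class) < 2) {
    elbm_error("only one age-sex class present: no contrasts estimable",
               "elbm_single_class_error")
  }
  if (nlevels(df$individual_id) < 2) {
    elbm_error("need >= 2 individuals for a random intercept",
               "elbm_validation_error")
  }
  if (smooth && !"fai_percent" %in% names(df)) {
    elbm_error("FAI not attached and no fai_series supplied", "elbm_validation_error")
  }
  fml <- if (smooth) {
    stats::as.formula(sprintf(
      "elbm ~ age_sex_class + s(fai_percent, bs = 'cr', k = %d) + s(individual_id, bs = 're')",
      as.integer(k)
    ))
  } else {
    elbm ~ age_sex_class + s(individual_id, bs = "re")
  }
  # REML breaks down on a zero-variance response; fall back to GCV with the
  # smoothing parameters pinned high (they are unidentified there, and the
  # null model is the honest answer: smooths at their minimal edf)
  if (var(df$elbm) > 0) {
    m <- mgcv::gam(fml, data = df, method = "REML")
  } else {
    n_sm <- if (smooth) 2L else 1L
    m <- mgcv::gam(fml, data = df, method = "GCV.Cp", sp = rep(1e10, n_sm))
  }
  if (!isTRUE(m$converged)) {
    elbm_error(paste0("REML smoothing-parameter selection did not converge; ",
                      "gradient/criterion diagnostics in attr(, 'diag')"),
               "elbm_convergence_error")
  }
  # summary.gam's random-effect test divides by the scale estimate, which
  # is 0 for a zero-variance response; fall back to direct extraction then
  sm <- tryCatch(summary(m), error = function(e) NULL)
  if (!is.null(sm)) {
    pt <- sm$p.table
    coef_rows <- data.frame(
      term = rownames(pt), estimate = pt[, 1], se = pt[, 2],
      t_stat = pt[, 3], p_value = pt[, 4],
      row.names = NULL, stringsAsFactors = FALSE
    )
    smooth_summary <- NULL
    if (smooth) {
      st <- sm$s.table
      i <- grep("fai_percent", rownames(st))
      smooth_summary <- list(edf = unname(st[i, "edf"]),
                             f_stat = unname(st[i, "F"]),
                             p_value = unname(st[i, "p-value"]))
    }
  } else {
    np <- m$nsdf
    est <- unname(coef(m)[seq_len(np)])
    se <- sqrt(diag(m$Vp)[seq_len(np)])
    coef_rows <- data.frame(
      term = names(coef(m))[seq_len(np)], estimate = est, se = unname(se),
      t_stat = est / unname(se), p_value = NaN, stringsAsFactors = FALSE
    )
    smooth_summary <- NULL
    if (smooth) {
      si <- which(vapply(m$smooth, function(s) grepl("fai_percent", s$label),
                         logical(1)))[1]
      idx <- m$smooth[[si]]$first.para:m$smooth[[si]]$last.para
      smooth_summary <- list(edf = sum(m$edf[idx]), f_stat = NaN,
                             p_value = NaN)
    }
  }
  structure(list(
    coefficients = coef_rows,
    smooth_summary = smooth_summary,
    random_intercept_sd = gamm_vcomp_sd(m),
    residual_sd = sqrt(m$sig2),
    r2_adj = sm$r.sq,
    baseline_class = baseline_class,
    n_obs = nrow(df),
    n_groups = nlevels(df$individual_id),
    model = m,
    frame = df
  ), class = "elbm_gamm")
}

#' @export
print.elbm_gamm <- function(x, ...) {
  cat("ELBM GAMM (baseline class: ", x$baseline_class, ")\n", sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$smooth_summary)) {
    cat(sprintf("s(FAI): edf = %.3f, F = %.2f, p = %.3g\n",
                x$smooth_summary$edf, x$smooth_summary$f_stat,
                x$smooth_summary$p_value))
  }
  cat(sprintf("random intercept SD = %.4f, residual SD = %.4f, r2_adj = %.3f\n",
              x$random_intercept_sd, x$residual_sd, x$r2_adj))
  cat(sprintf("n = %d observations, %d individuals\n", x$n_obs, x$n_groups))
  invisible(x)
}

#' All pairwise age-sex class contrasts by releveling
#'
#' Refits the GAMM once with each class as the treatment-coding baseline
#' and collects every non-baseline coefficient row. Each unordered pair
#' therefore appears in both directions; the two estimates are equal in
#' magnitude and opposite in sign (up to numerical tolerance), since
#' releveling only reparameterizes the same model.
#'
#' @inheritParams fit_gamm
#' @return data.frame with `baseline_class`, `other_class`, `estimate`,
#'   `se`, `t_stat`, `p_value`.
#' @export
pairwise_contrasts <- function(elbm_table, individuals, fai_series = NULL,
                               k = 10, smooth = TRUE) {
  df0 <- assemble_model_frame(elbm_table, individuals, fai_series)
  classes <- levels(df0$age_sex_class)
  rows <- lapply(classes, function(b) {
    fit <- fit_gamm(elbm_table, individuals, fai_series,
                    baseline_class = b, k = k, smooth = smooth)
    cr <- fit$coefficients
    cr <- cr[grepl("^age_sex_class", cr$term), , drop = FALSE]
    data.frame(
      baseline_class = b,
      other_class = sub("^age_sex_class", "", cr$term),
      estimate = cr$estimate, se = cr$se,
      t_stat = cr$t_stat, p_value = cr$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear mixed model with FAI binned high/low
#'
#' The companion model used for visualization: Gaussian response,
#' identity link, fixed effects = FAI category (+ optional class x FAI
#' interaction) + age-sex class, random intercept per individual, fitted
#' by REML in \pkg{lme4}. The FAI reference level is `"high"`, so the
#' `fai_labellow` coefficient is the expected ELBM change in low-fruit
#' months. p-values are Wald t with residual df `n - p` (an explicit
#' approximation; no Satterthwaite correction).
#'
#' @inheritParams fit_gamm
#' @param interaction Include `age_sex_class:fai_label`? Default `FALSE`
#'   (main effects only).
#' @return Object of class `elbm_glmm`: `coefficients`,
#'   `random_intercept_sd`, `residual_sd`, `baseline_class`, `n_obs`,
#'   `n_groups`, fitted \pkg{lme4} model as `model`.
#' @export
fit_glmm_binary <- function(elbm_table, individuals, fai_series = NULL,
                            baseline_class = "adult_female",
                            interaction = FALSE) {
  df <- assemble_model_frame(elbm_table, individuals, fai_series, baseline_class)
  if (!"fai_label" %in% names(df)) {
    elbm_error("no fai_label column: binarize the FAI series first",
               "elbm_validation_error")
  }
  if (length(unique(stats::na.omit(df$fai_label))) < 2) {
    elbm_error("only one FAI level present: high/low contrast not estimable",
               "elbm_single_level_error")
  }
  fml <- if (interaction) {
    elbm ~ fai_label * age_sex_class + (1 | individual_id)
  } else {
    elbm ~ fai_label + age_sex_class + (1 | individual_id)
  }
  m <- lme4::lmer(fml, data = df, REML = TRUE)
  ct <- coef(summary(m))
  df_resid <- nrow(df) - nrow(ct)
  coef_rows <- data.frame(
    term = rownames(ct), estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
    t_stat = ct[, "t value"],
    p_value = 2 * pt(-abs(ct[, "t value"]), df = df_resid),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(list(
    coefficients = coef_rows,
    random_intercept_sd = vc$sdcor[vc$grp == "individual_id"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    baseline_class = baseline_class,
    n_obs = nrow(df),
    n_groups = nlevels(df$individual_id),
    interaction = interaction,
    model = m,
    frame = df
  ), class = "elbm_glmm")
}

#' @export
print.elbm_glmm <- function(x, ...) {
  cat("ELBM linear mixed model, FAI binned high/low (baseline class: ",
      x$baseline_class, ")\n", sep = "")
  print(x$coefficients, digits = 4)
  cat(sprintf("random intercept SD = %.4f, residual SD = %.4f\n",
              x$random_intercept_sd, x$residual_sd))
  cat(sprintf("n = %d observations, %d individuals\n", x$n_obs, x$n_groups))
  invisible(x)
}

#' Population-level ELBM predictions
#'
#' Predictions with the random intercept set to zero (population level),
#' with standard errors from the fixed-effect covariance matrix. For the
#' binary-FAI mixed model the default grid is every class by both FAI
#' levels; for the GAMM supply `fai_percent` values in the grid.
#'
#' @param model An `elbm_glmm` or `elbm_gamm`.
#' @param grid Optional data.frame of prediction cells. For `elbm_glmm`:
#'   columns `age_sex_class`, `fai_label`; default all combinations seen
#'   in training. For `elbm_gamm`: columns `age_sex_class`,
#'   `fai_percent`.
#' @return data.frame: the grid plus `estimate` and `se`.
#' @export
predict_elbm <- function(model, grid = NULL) {
  UseMethod("predict_elbm")
}

check_grid_levels <- function(grid, col, seen) {
  bad <- setdiff(as.character(unique(grid[[col]])), seen)
  if (length(bad) > 0) {
    elbm_error(paste0("grid level(s) not present in training data for ", col,
                      ": ", paste(bad, collapse = ", ")),
               "elbm_unseen_level_error")
  }
}

#' @export
predict_elbm.elbm_glmm <- function(model, grid = NULL) {
  fr <- model$frame
  if (is.null(grid)) {
    grid <- expand.grid(
      age_sex_class = levels(fr$age_sex_class),
      fai_label = levels(fr$fai_label),
      stringsAsFactors = FALSE
    )
  }
  check_grid_levels(grid, "age_sex_class", levels(fr$age_sex_class))
  check_grid_levels(grid, "fai_label", levels(fr$fai_label))
  nd <- grid
  nd$age_sex_class <- factor(nd$age_sex_class, levels = levels(fr$age_sex_class))
  nd$fai_label <- factor(nd$fai_label, levels = levels(fr$fai_label))
  fml <- if (model$interaction) ~ fai_label * age_sex_class else ~ fai_label + age_sex_class
  X <- model.matrix(fml, nd)
  beta <- lme4::fixef(model$model)
  V <- as.matrix(vcov(model$model))
  grid$estimate <- as.numeric(X %*% beta)
  grid$se <- sqrt(rowSums((X %*% V) * X))
  grid
}

#' @export
predict_elbm.elbm_gamm <- function(model, grid = NULL) {
  fr <- model$frame
  if (is.null(grid)) {
    fp <- if (!is.null(model$smooth_summary)) {
      quantile(fr$fai_percent, c(0.1, 0.5, 0.9), names = FALSE)
    } else NA_real_
    grid <- expand.grid(
      age_sex_class = levels(fr$age_sex_class),
      fai_percent = fp, stringsAsFactors = FALSE
    )
  }
  check_grid_levels(grid, "age_sex_class", levels(fr$age_sex_class))
  nd <- grid
  nd$age_sex_class <- factor(nd$age_sex_class, levels = levels(fr$age_sex_class))
  nd$individual_id <- factor(levels(fr$individual_id)[1],
                             levels = levels(fr$individual_id))
  pr <- predict(model$model, newdata = nd, se.fit = TRUE,
                exclude = "s(individual_id)", newdata.guaranteed = TRUE)
  grid$estimate <- as.numeric(pr$fit)
  grid$se <- as.numeric(pr$se.fit)
  grid
}
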