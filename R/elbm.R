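# Calibration of urinary creatinine against specific gravity and the
# residual lean-body-mass estimate.
#
# Water has SG 1.0 and creatinine 0.0 mg/ml, so the calibration is forced
# through the origin: creatinine = b1*(SG-1) + b2*(SG-1)^2 with no
# intercept. Residuals from the global fit are the estimated lean body
# mass (ELBM), in mg/ml of creatinine unexplained by urine concentration.

validate_samples <- function(samples) {
  need <- c("sample_id", "individual_id", "specific_gravity", "creatinine_mg_ml")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    elbm_error(paste0("sample table missing column(s): ", paste(miss, collapse = ", ")),
               "elbm_schema_error")
  }
  bad <- which(samples$specific_gravity <= 1.0)
  if (length(bad) > 0) {
    elbm_error(
      paste0("specific gravity <= 1.0 is physically invalid (water is 1.0); rows: ",
             paste(samples$sample_id[bad], collapse = ", ")),
      "elbm_validation_error"
    )
  }
  if (any(samples$creatinine_mg_ml < 0)) {
    elbm_error("creatinine must be >= 0 mg/ml", "elbm_validation_error")
  }
  invisible(samples)
}

#' Remove overly dilute urine samples
#'
#' Samples with specific gravity strictly below the threshold are too
#' dilute for reliable creatinine quantification and are excluded before
#' calibration. A sample exactly at the threshold is kept.
#'
#' @param samples Urine-sample data.frame (see [read_samples()] schema).
#' @param threshold SG cutoff, default 1.003; exclusion is strict (`<`).
#' @return list with `kept` and `excluded` data.frames, input order
#'   preserved in both.
#' @export
filter_dilute <- function(samples, threshold = 1.003) {
  stopifnot(threshold > 1.0)
  if (nrow(samples) > 0) validate_samples(samples)
  dilute <- samples$specific_gravity < threshold
  list(
    kept = samples[!dilute, , drop = FALSE],
    excluded = samples[dilute, , drop = FALSE]
  )
}

#' Specific-gravity regression features
#'
#' Subtracts 1 (the SG of water) from each reading and returns the linear
#' and quadratic terms used by the through-origin calibration.
#'
#' @param specific_gravity Numeric vector, each value > 1.0.
#' @return Two-column matrix `cbind(linear = SG - 1, quadratic = (SG - 1)^2)`.
#' @export
#' @examples
#' sg_features(1.02) # 0.02 and 4e-04
sg_features <- function(specific_gravity) {
  if (any(specific_gravity <= 1.0)) {
    elbm_error("specific gravity must be > 1.0", "elbm_validation_error")
  }
  s <- specific_gravity - 1
  cbind(linear = s, quadratic = s^2)
}

#' Fit the through-origin creatinine ~ SG calibration
#'
#' Least-squares fit of creatinine on `(SG - 1)` and `(SG - 1)^2` with no
#' intercept, solved by QR (orthogonal) decomposition. The default
#' `"two_coefficients"` mode estimates both terms freely; the
#' `"single_regressor"` mode fits one coefficient on the combined
#' regressor `(SG - 1) + (SG - 1)^2` (an alternative reading of the same
#' recipe, kept for sensitivity analysis; the returned `b1` and `b2` are
#' then equal).
#'
#' R-squared uses the uncentered total sum of squares (the no-intercept
#' convention, as in `summary.lm`); the adjusted version uses residual
#' df `n - 2` in two-coefficient mode (`n - 1` in single-regressor mode).
#'
#' @param samples Kept (post-filter) urine-sample data.frame; needs >= 3
#'   rows and >= 2 distinct SG values.
#' @param mode `"two_coefficients"` (default) or `"single_regressor"`.
#' @param excluded Optional data.frame of excluded samples, recorded in
#'   the exclusion audit.
#' @return Object of class `elbm_calibration` with elements `b1`, `b2`,
#'   `mode`, `residuals` and `fitted` (named by sample_id),
#'   `r2_uncentered`, `r2_adj`, `n_used`, `n_excluded`, `excluded_ids`.
#' @export
fit_calibration <- function(samples,
                            mode = c("two_coefficients", "single_regressor"),
                            excluded = NULL) {
  mode <- match.arg(mode)
  validate_samples(samples)
  n <- nrow(samples)
  if (n < 3) {
    elbm_error("calibration needs at least 3 samples", "elbm_insufficient_data_error")
  }
  if (length(unique(samples$specific_gravity)) < 2) {
    elbm_error("all SG values identical: singular design", "elbm_singular_design_error")
  }
  X <- sg_features(samples$specific_gravity)
  y <- samples$creatinine_mg_ml
  if (mode == "two_coefficients") {
    fit <- lm(y ~ 0 + X)
    b <- unname(coef(fit))
    b1 <- b[1]; b2 <- b[2]
    p <- 2L
  } else {
    x <- X[, 1] + X[, 2]
    fit <- lm(y ~ 0 + x)
    b1 <- b2 <- unname(coef(fit))
    p <- 1L
  }
  r <- unname(resid(fit))
  f <- unname(fitted(fit))
  ssr <- sum(r^2)
  tss <- sum(y^2) # uncentered: regression through the origin
  r2 <- 1 - ssr / tss
  r2_adj <- 1 - (1 - r2) * n / (n - p)
  structure(list(
    b1 = b1, b2 = b2, mode = mode,
    residuals = setNames(r, samples$sample_id),
    fitted = setNames(f, samples$sample_id),
    r2_uncentered = r2, r2_adj = r2_adj,
    n_used = n,
    n_excluded = if (is.null(excluded)) 0L else nrow(excluded),
    excluded_ids = if (is.null(excluded)) character(0) else excluded$sample_id
  ), class = "elbm_calibration")
}

#' @export
print.elbm_calibration <- function(x, ...) {
  cat("Through-origin creatinine ~ SG calibration (", x$mode, ")\n", sep = "")
  cat(sprintf("  b1 (SG-1):    %10.4f\n", x$b1))
  cat(sprintf("  b2 (SG-1)^2:  %10.4f\n", x$b2))
  cat(sprintf("  r2 (uncentered): %.4f   r2_adj: %.4f\n", x$r2_uncentered, x$r2_adj))
  cat(sprintf("  n used: %d   n excluded (dilute): %d\n", x$n_used, x$n_excluded))
  invisible(x)
}

#' Estimated lean body mass per sample
#'
#' ELBM is the calibration residual: observed creatinine minus the amount
#' explained by urine concentration (SG). Positive values indicate more
#' creatinine than expected for the sample's concentration, i.e. more
#' muscle mass.
#'
#' @param samples The same kept sample table the fit was computed from.
#' @param fit An `elbm_calibration` from [fit_calibration()].
#' @return data.frame with `sample_id`, `individual_id`, `date`, `elbm`,
#'   one row per used sample. Any FAI annotation columns present on
#'   `samples` (`month`, `fai_percent`, `fai_label`) are carried through.
#' @export
compute_elbm <- function(samples, fit) {
  stopifnot(inherits(fit, "elbm_calibration"))
  missing_ids <- setdiff(samples$sample_id, names(fit$residuals))
  if (length(missing_ids) > 0) {
    elbm_error(
      paste0("sample_id(s) absent from calibration fit: ",
             paste(utils::head(missing_ids, 5), collapse = ", "),
             if (length(missing_ids) > 5) ", ..." else ""),
      "elbm_consistency_error"
    )
  }
  keep <- intersect(c("sample_id", "individual_id", "date", "month",
                      "fai_percent", "fai_label"), names(samples))
  out <- samples[, keep, drop = FALSE]
  out$elbm <- unname(fit$residuals[samples$sample_id])
  rownames(out) <- NULL
  out
}

#' Per-class ELBM summary statistics
#'
#' @param elbm_table From [compute_elbm()].
#' @param individuals data.frame with `individual_id`, `age_sex_class`.
#' @return data.frame, one row per age-sex class present: `age_sex_class`,
#'   `n`, `mean`, `sd` (n-1 denominator), `median`, `iqr` (Q3 - Q1,
#'   linear-interpolation quantiles).
#' @export
summarize_by_class <- function(elbm_table, individuals) {
  idx <- match(elbm_table$individual_id, individuals$individual_id)
  if (anyNA(idx)) {
    elbm_error(
      paste0("individual_id(s) not in metadata: ",
             paste(unique(elbm_table$individual_id[is.na(idx)]), collapse = ", ")),
      "elbm_consistency_error"
    )
  }
  cls <- individuals$age_sex_class[idx]
  classes <- intersect(age_sex_classes(), unique(cls))
  out <- do.call(rbind, lapply(classes, function(cl) {
    v <- elbm_table$elbm[cls == cl]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(
      age_sex_class = cl, n = length(v), mean = mean(v), sd = sd(v),
      median = median(v), iqr = q[2] - q[1], stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
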