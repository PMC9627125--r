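#' Split samples by tertiles
#'
#' Groups a numeric score at its 1/3 and 2/3 quantiles
#' (linear-interpolation estimator); values exactly on a boundary go to the
#' lower group, so with distinct values group sizes differ by at most one.
#'
#' @param values per-sample numeric vector (>= 3 distinct values).
#' @return factor with levels `low`, `mid`, `high`.
#' @export
tertile_split <- function(values) {
  ok <- !is.na(values)
  assert_that(sum(ok) >= 3L, "need >= 3 samples")
  assert_that(length(unique(values[ok])) >= 3L, "need >= 3 distinct values")
  q <- stats::quantile(values[ok], probs = c(1, 2) / 3, names = FALSE)
  cut(values, breaks = c(-Inf, q, Inf), labels = c("low", "mid", "high"),
      right = TRUE)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate per group; `S(0) = 1` and each curve is a
#' nonincreasing right-continuous step function.
#'
#' @param time follow-up times (months), nonnegative.
#' @param event event indicator (1 = death, 0 = censored).
#' @param groups optional group labels; a single curve when omitted.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_fit <- function(time, event, groups = NULL) {
  assert_that(all(time >= 0, na.rm = TRUE), "times must be nonnegative")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  df <- data.frame(time = time, event = event,
                   group = if (is.null(groups)) "all" else as.character(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; hazard ratios
#' with 95% Wald confidence intervals from the observed information and
#' two-sided Wald p-values.
#'
#' @param records data.frame with `time` and `event` columns plus the
#'   predictors.
#' @param predictors character vector of predictor column names.
#' @return data.frame with one row per coefficient: `term`, `coef`, `hr`,
#'   `lower`, `upper`, `p`; attribute `"fit"` holds the `coxph` object.
#' @export
cox_fit <- function(records, predictors) {
  assert_that(all(c("time", "event") %in% names(records)),
              "records need time and event columns")
  assert_that(all(predictors %in% names(records)),
              "missing predictor column(s)")
  for (p in predictors) {
    v <- records[[p]]
    if (is.numeric(v) && stats::sd(v, na.rm = TRUE) == 0) {
      stop_format("predictor '%s' is constant", p)
    }
  }
  assert_that(sum(records$event) >= length(predictors),
              "fewer events than predictors")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(predictors, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$fail)) stop_format("Cox fit failed to converge")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Per-event hazard ratio of the driver-event score
#'
#' Fits the event score (0-8) as a linear Cox term, unadjusted and
#' adjusted for ctDNA fraction plus the clinical covariate block.
#'
#' @param records survival data.frame (`time`, `event`, covariates).
#' @param event_score per-sample event counts, aligned with `records`.
#' @param covariates covariate column names for the adjusted model
#'   (default: every column of `records` other than `time`/`event`).
#' @return list with `unadjusted` and `adjusted` [cox_fit()] tables.
#' @export
adjusted_event_hr <- function(records, event_score, covariates = NULL) {
  assert_that(is.numeric(event_score) && all(event_score >= 0 & event_score <= 8,
                                             na.rm = TRUE),
              "event_score must be numeric in 0..8")
  df <- records
  df$event_score <- event_score
  covariates <- covariates %||%
    setdiff(names(records), c("time", "event", "true_hazard", "sample_id"))
  list(unadjusted = cox_fit(df, "event_score"),
       adjusted = cox_fit(df, c("event_score", covariates)))
}
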