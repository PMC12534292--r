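#' Survival records from a labeled cohort
#'
#' Builds the analysis table for the prognostic models: duration (years from
#' onset to death), event flag (all events observed by default — an autopsy
#' cohort has no right-censoring), onset age, sex, and subtype with PSP-PF as
#' the reference level.
#'
#' @param co A [psp_cohort()].
#' @param labels data.frame with `patient_id` and `subtype`; unlabeled
#'   patients are dropped.
#' @param reference Reference subtype level (default `"PSP-PF"`).
#' @return data.frame `patient_id`, `duration`, `event`, `age_at_onset`,
#'   `sex`, `subtype`.
#' @export
survival_records <- function(co, labels, reference = "PSP-PF") {
  stopifnot(inherits(co, "psp_cohort"))
  p <- co$patients
  sub <- labels$subtype[match(p$patient_id, labels$patient_id)]
  keep <- !is.na(sub)
  ev <- if (!is.null(p$event)) p$event else rep(TRUE, nrow(p))
  out <- data.frame(patient_id = p$patient_id[keep],
                    duration = p$disease_duration[keep],
                    event = ev[keep],
                    age_at_onset = p$age_at_onset[keep],
                    sex = factor(p$sex[keep], levels = c("male", "female")),
                    subtype = factor(as.character(sub[keep])),
                    stringsAsFactors = FALSE)
  if (reference %in% levels(out$subtype))
    out$subtype <- stats::relevel(out$subtype, ref = reference)
  rownames(out) <- NULL
  out
}

#' Multivariable Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization with Breslow handling
#' of tied event times, via [survival::coxph()]. Subtype enters as one-hot
#' indicators against the declared reference level (PSP-PF by default, set
#' when the records are built). Returns the coefficient table with hazard
#' ratios, the Breslow baseline cumulative hazard, and the in-sample
#' Harrell's concordance of the linear predictor.
#'
#' @param records data.frame from [survival_records()] (or any table with
#'   `duration`, `event`, and the covariate columns).
#' @param covariates Character vector of covariate column names, e.g.
#'   `c("age_at_onset", "sex", "subtype")`.
#' @return Object of class `psp_coxfit`: `model` (the `coxph` fit),
#'   `coefficients` (term, coef, hr, se, z, p), `baseline` (time, cumhaz),
#'   `c_index`, `covariates`.
#' @export
fit_cox <- function(records, covariates) {
  stopifnot(is.data.frame(records),
            all(c("duration", "event") %in% names(records)),
            length(covariates) >= 1)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(records$duration)) < 2)
    stop("need at least two distinct durations")
  fml <- stats::as.formula(paste("survival::Surv(duration, event) ~",
                                 paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = " + "))), data = records)[, -1,
                                                                     drop = FALSE]
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("singular design; linearly dependent term(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("separation: partial likelihood did not converge (monotone ",
             "likelihood in a covariate)")
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (any(is.na(cf)) || any(abs(cf) > 15))
    stop("singular or separated design; offending term(s): ",
         paste(names(cf)[is.na(cf) | abs(cf) > 15], collapse = ", "))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), coef = sm[, "coef"],
                      hr = exp(sm[, "coef"]), se = sm[, "se(coef)"],
                      z = sm[, "z"], p = sm[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(model = fit, coefficients = coefs,
                 baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 c_index = concordance_index(records$duration, records$event,
                                             unname(predict(fit, type = "lp"))),
                 covariates = covariates),
            class = "psp_coxfit")
}

#' @export
print.psp_coxfit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties) on",
      paste(x$covariates, collapse = " + "), "\n")
  print(transform(x$coefficients, hr = round(hr, 3), coef = round(coef, 3),
                  se = round(se, 3), z = round(z, 2), p = signif(p, 2)),
        row.names = FALSE)
  cat(sprintf("in-sample concordance: %.3f\n", x$c_index))
  invisible(x)
}

#' @export
coef.psp_coxfit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$term)
}

#' Model-based survival curve for a covariate profile
#'
#' Evaluates `S(t) = exp(-H0(t) exp(x'beta))` for a single covariate profile,
#' with the Breslow baseline cumulative hazard from the fit. The default use
#' is a representative profile (for instance mean onset age, male sex,
#' reference subtype) so curves are comparable across subtypes.
#'
#' @param fit A [fit_cox()] object.
#' @param profile One-row data.frame (or named list) giving every covariate.
#' @return data.frame `time`, `surv`, starting at `(0, 1)`, non-increasing.
#' @export
survival_curve <- function(fit, profile) {
  stopifnot(inherits(fit, "psp_coxfit"))
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  miss <- setdiff(fit$covariates, names(profile))
  if (length(miss)) stop("profile is missing covariate(s): ",
                         paste(miss, collapse = ", "))
  lp <- unname(predict(fit$model, newdata = profile, type = "lp",
                       reference = "zero"))
  s <- exp(-fit$baseline$cumhaz * exp(lp))
  out <- data.frame(time = c(0, fit$baseline$time), surv = c(1, s))
  out[order(out$time), ]
}

#' Harrell's concordance index
#'
#' The fraction of comparable patient pairs whose risk ordering matches
#' their survival ordering. A pair is comparable when the durations differ
#' and the shorter-lived patient's event was observed; concordant when that
#' patient carries the higher risk score; risk ties contribute one half.
#'
#' @param durations Numeric vector of survival times.
#' @param events Logical (or 0/1) event indicators; `TRUE` everywhere for a
#'   fully observed autopsy cohort.
#' @param risk_scores Numeric risk scores (higher = shorter expected
#'   survival), aligned with `durations`.
#' @return Concordance in `[0, 1]`.
#' @export
#' @examples
#' concordance_index(c(2, 4, 6), c(TRUE, TRUE, TRUE), c(3, 2, 1))  # 1
concordance_index <- function(durations, events, risk_scores) {
  n <- length(durations)
  stopifnot(length(events) == n, length(risk_scores) == n)
  events <- as.logical(events)
  ti <- matrix(durations, n, n)
  ei <- matrix(events, n, n)
  ri <- matrix(risk_scores, n, n)
  comp <- ti < t(ti) & ei  # row patient dies first, with event observed
  if (!any(comp)) stop("no comparable pairs")
  conc <- ri > t(ri)
  tie <- ri == t(ri)
  (sum(conc & comp) + 0.5 * sum(tie & comp)) / sum(comp)
}

#' Concordance gain from added covariates
#'
#' Fits the base and the extended Cox model and compares the in-sample
#' Harrell's C of their linear predictors: the statistic used to quantify
#' how much early subtyping adds to prognostic prediction over age and sex.
#'
#' @param records data.frame from [survival_records()].
#' @param base_covariates Covariates of the base model.
#' @param added_covariates Covariates added in the full model.
#' @return List `c_base`, `c_full`, `delta` (`c_full - c_base`).
#' @export
delta_c <- function(records, base_covariates, added_covariates) {
  fb <- fit_cox(records, base_covariates)
  ff <- fit_cox(records, c(base_covariates, added_covariates))
  list(c_base = fb$c_index, c_full = ff$c_index,
       delta = ff$c_index - fb$c_index)
}
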