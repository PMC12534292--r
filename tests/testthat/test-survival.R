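test_that("concordance matches brute-force pair enumeration on random instances", {
  expect_equal(concordance_index(c(2, 4, 6), rep(TRUE, 3), c(3, 2, 1)), 1)
  expect_equal(concordance_index(c(2, 4, 6), rep(TRUE, 3), c(5, 5, 5)), 0.5)
  set.seed(7)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    dur <- sample(1:12, n, replace = TRUE)  # ties in time on purpose
    ev <- runif(n) < 0.8
    if (!any(ev)) ev[1] <- TRUE
    sc <- sample(1:5, n, replace = TRUE)    # ties in risk on purpose
    expect_equal(concordance_index(dur, ev, sc),
                 concordance_oracle(dur, ev, sc), tolerance = 1e-12)
  }
  # 4-record toy table, hand-traceable
  expect_equal(concordance_index(c(1, 2, 3, 4), rep(TRUE, 4), c(4, 3, 1, 2)),
               concordance_oracle(c(1, 2, 3, 4), rep(TRUE, 4), c(4, 3, 1, 2)))
  expect_error(concordance_index(c(1, 1), c(FALSE, FALSE), c(1, 2)),
               "comparable")
})

test_that("concordance agrees with the survival package on continuous data", {
  set.seed(12)
  n <- 80
  dur <- rexp(n)
  ev <- runif(n) < 0.7
  sc <- rnorm(n)
  ours <- concordance_index(dur, ev, sc)
  ref <- survival::concordance(survival::Surv(dur, ev) ~ sc, reverse = TRUE)
  expect_equal(ours, unname(ref$concordance), tolerance = 1e-10)
})

test_that("Cox recovery: a known hazard ratio is inside its confidence interval", {
  set.seed(5)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  dur <- rexp(n, rate = 0.2 * exp(log(2) * x))
  rec <- data.frame(duration = dur, event = TRUE, x = x)
  fit <- fit_cox(rec, "x")
  beta <- fit$coefficients$coef
  se <- fit$coefficients$se
  expect_true(abs(beta - log(2)) < 1.96 * se)
  # null covariate: coefficient near zero
  rec$z <- rbinom(n, 1, 0.5)
  fit0 <- fit_cox(rec, "z")
  expect_lt(abs(fit0$coefficients$coef), 3 * fit0$coefficients$se)
})

test_that("Cox errors are informative for degenerate designs", {
  rec <- data.frame(duration = c(1, 2, 3, 4), event = TRUE,
                    a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  expect_error(fit_cox(rec, c("a", "b")), "singular|separated")
  expect_error(fit_cox(data.frame(duration = c(2, 2), event = TRUE,
                                  a = c(0, 1)), "a"), "distinct durations")
  expect_error(fit_cox(rec, "missing_col"), "missing covariate")
})

test_that("model survival curves start at 1, decrease, and order by risk", {
  co <- generate_cohort(300, seed = 6)
  lab <- classify_cohort(co)
  rec <- survival_records(co, lab)
  fit <- fit_cox(rec, c("age_at_onset", "sex", "subtype"))
  prof_pf <- data.frame(age_at_onset = 66, sex = "male", subtype = "PSP-PF")
  prof_p <- data.frame(age_at_onset = 66, sex = "male", subtype = "PSP-P")
  s_pf <- survival_curve(fit, prof_pf)
  s_p <- survival_curve(fit, prof_p)
  expect_equal(s_pf$surv[1], 1)
  expect_true(all(diff(s_pf$surv) <= 1e-12))
  # PSP-PF (shortest duration archetype) has the lower curve throughout
  expect_true(all(s_pf$surv <= s_p$surv + 1e-12))
  expect_error(survival_curve(fit, data.frame(age_at_onset = 66)),
               "missing covariate")
})

test_that("subtype hazard ratios against PSP-PF are all below 1 on default cohorts", {
  co <- generate_cohort(588, seed = 3)
  lab <- classify_cohort(co)
  rec <- survival_records(co, lab)
  expect_equal(levels(rec$subtype)[1], "PSP-PF")
  fit <- fit_cox(rec, c("age_at_onset", "sex", "subtype"))
  hr <- fit$coefficients$hr[grepl("^subtype", fit$coefficients$term)]
  expect_true(all(hr < 1))
})

test_that("delta-C is positive for informative subtypes and near zero for noise", {
  co <- generate_cohort(500, seed = 8)
  lab <- classify_cohort(co)
  rec <- survival_records(co, lab)
  dc <- delta_c(rec, c("age_at_onset", "sex"), "subtype")
  expect_gt(dc$delta, 0)
  expect_equal(dc$delta, dc$c_full - dc$c_base, tolerance = 1e-12)
  # pure-noise addition moves C very little
  set.seed(9)
  rec$noise <- rnorm(nrow(rec))
  dcn <- delta_c(rec, c("age_at_onset", "sex"), "noise")
  expect_lt(abs(dcn$delta), 0.05)
  # age and sex are survival-independent in the generator: base C near 1/2
  expect_lt(abs(dc$c_base - 0.5), 0.05)
})
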