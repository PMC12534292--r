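#' Simulate a longitudinal PSP cohort
#'
#' Draws patients from a mixture of archetypes. For each patient: (i) an
#' archetype is sampled by prevalence; (ii) disease duration is drawn from the
#' archetype's log-normal model and onset age from its normal model (all
#' patients die — the cohort emulates an autopsy series — unless
#' `censor_frac > 0`); (iii) each symptom develops with its lifetime
#' probability, at a log-normal latent onset time; onsets falling after death
#' never manifest; (iv) observations are emitted at Poisson-scheduled visits
#' (plus a baseline visit at onset and a terminal visit at death) with
#' per-visit assessment thinning: a symptom assessed at visit time `t` is
#' recorded present when `t` is at or after its latent onset, absent before.
#' With probability `p_onset_documented` a developed, ever-assessed symptom
#' additionally carries an observation exactly at its latent onset,
#' representing an explicitly documented onset date.
#'
#' The sampled archetype is stored in `latent_archetype` for provenance.
#'
#' @param n Number of patients (>= 1).
#' @param archetypes Named list of [psp_archetype()]; prevalences are
#'   normalized.
#' @param schedule A [psp_schedule()].
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @param censor_frac Fraction of patients whose death time is administratively
#'   censored (default 0; the event flag convention then matters only for the
#'   survival utilities).
#' @return A validated [psp_cohort()].
#' @export
#' @examples
#' co <- generate_cohort(50, seed = 1)
#' co
generate_cohort <- function(n, archetypes = default_archetypes(),
                            schedule = psp_schedule(), seed = NULL,
                            censor_frac = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  stopifnot(inherits(schedule, "psp_schedule"))
  n <- as.integer(n)
  prev <- vapply(archetypes, function(a) a$prevalence, 0)
  stopifnot(all(prev >= 0), sum(prev) > 0)
  prev <- prev / sum(prev)
  labs <- vapply(archetypes, function(a) a$label, "")

  with_seed(seed, {
    arch_idx <- sample.int(length(archetypes), n, replace = TRUE, prob = prev)
    pats <- vector("list", n)
    obs <- vector("list", n)
    for (i in seq_len(n)) {
      a <- archetypes[[arch_idx[i]]]
      dur <- stats::rlnorm(1, log(a$duration_median), a$duration_spread)
      dur <- max(dur, 0.5)
      age <- max(stats::rnorm(1, a$onset_age_median, a$onset_age_spread), 20)
      sex <- if (stats::runif(1) < a$p_male) "male" else "female"
      pid <- sprintf("pt%05d", i)
      pats[[i]] <- data.frame(patient_id = pid, sex = sex,
                              age_at_onset = age, disease_duration = dur,
                              latent_archetype = a$label,
                              stringsAsFactors = FALSE)

      s <- a$symptoms
      ever <- stats::runif(nrow(s)) < s$p_ever
      onset <- ifelse(ever,
                      stats::rlnorm(nrow(s), log(s$onset_median),
                                    s$onset_spread),
                      Inf)
      onset[onset > dur] <- Inf  # onsets after death never manifest

      nv <- stats::rpois(1, schedule$visit_rate * dur)
      visits <- sort(c(0, stats::runif(nv, 0, dur), dur))
      assessed <- matrix(stats::runif(length(visits) * nrow(s)) <
                           schedule$p_symptom_assessed,
                         nrow = length(visits))
      rows <- which(assessed, arr.ind = TRUE)
      if (nrow(rows)) {
        ot <- data.frame(patient_id = pid,
                         symptom = s$symptom[rows[, 2]],
                         t = visits[rows[, 1]],
                         present = visits[rows[, 1]] >= onset[rows[, 2]],
                         stringsAsFactors = FALSE)
      } else {
        ot <- NULL
      }
      # explicit onset documentation for developed, ever-assessed symptoms
      seen <- if (is.null(ot)) character() else unique(ot$symptom)
      dev <- which(is.finite(onset) & s$symptom %in% seen)
      if (length(dev)) {
        doc <- dev[stats::runif(length(dev)) < schedule$p_onset_documented]
        if (length(doc))
          ot <- rbind(ot, data.frame(patient_id = pid,
                                     symptom = s$symptom[doc],
                                     t = onset[doc], present = TRUE,
                                     stringsAsFactors = FALSE))
      }
      obs[[i]] <- ot
    }
    patients <- do.call(rbind, pats)
    observations <- do.call(rbind, obs)
    if (censor_frac > 0) {
      cens <- stats::runif(n) < censor_frac
      patients$event <- !cens
    }
    co <- suppressWarnings(psp_cohort(patients, observations))
    if (censor_frac > 0) co$patients$event <- patients$event
    co
  })
}

#' Simulate a binary early-feature table directly
#'
#' Shortcut generator producing the exact input shape the clustering stage
#' consumes: one binary row per patient over the 12 key symptoms, where a
#' symptom is 1 when it develops (with its lifetime probability) and its
#' latent onset falls within `window` years of disease onset. The
#' longitudinal observation layer is skipped. The latent archetype label is
#' retained.
#'
#' @inheritParams generate_cohort
#' @param window Early window in years (default 3).
#' @return data.frame with `patient_id`, one 0/1 column per symptom code, and
#'   `latent_archetype`.
#' @export
generate_feature_table <- function(n, archetypes = default_archetypes(),
                                   seed = NULL, window = 3) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, window > 0)
  n <- as.integer(n)
  prev <- vapply(archetypes, function(a) a$prevalence, 0)
  prev <- prev / sum(prev)
  with_seed(seed, {
    arch_idx <- sample.int(length(archetypes), n, replace = TRUE, prob = prev)
    m <- matrix(0L, n, length(psp_symptoms()),
                dimnames = list(NULL, psp_symptoms()))
    for (i in seq_len(n)) {
      a <- archetypes[[arch_idx[i]]]
      s <- a$symptoms
      ever <- stats::runif(nrow(s)) < s$p_ever
      onset <- stats::rlnorm(nrow(s), log(s$onset_median), s$onset_spread)
      m[i, ] <- as.integer(ever & onset <= window)
    }
    out <- data.frame(patient_id = sprintf("pt%05d", seq_len(n)), m,
                      stringsAsFactors = FALSE)
    out$latent_archetype <- vapply(archetypes[arch_idx],
                                   function(a) a$label, "")
    out
  })
}
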