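#' Construct and validate a longitudinal PSP cohort
#'
#' A `psp_cohort` holds per-patient demographics and death times together with
#' timed symptom observations. Time is measured in years from clinical
#' disease onset (onset-anchored, not calendar dates); all analyses in this
#' package operate on that scale. When a symptom's explicit onset is not
#' recorded, the first observation at which it is present serves as its onset.
#'
#' @param patients data.frame with columns `patient_id`, `sex` ("male" or
#'   "female"), `age_at_onset`, `disease_duration` (years, > 0), and
#'   optionally `latent_archetype` (simulator provenance). `age_at_death` is
#'   derived as onset age plus duration.
#' @param observations data.frame with columns `patient_id`, `symptom` (one of
#'   [psp_symptoms()]), `t` (years from onset, in `[0, disease_duration]`),
#'   and `present` (logical). Duplicate `(patient_id, symptom, t)` rows are
#'   collapsed by logical OR of `present`, with a warning.
#' @return An object of class `psp_cohort`: a list with validated `patients`
#'   and `observations` data.frames.
#' @export
#' @examples
#' co <- psp_cohort(
#'   data.frame(patient_id = "p1", sex = "male",
#'              age_at_onset = 65, disease_duration = 7),
#'   data.frame(patient_id = "p1",
#'              symptom = c("postural_instability", "ocular_motor"),
#'              t = c(0.5, 2), present = c(TRUE, FALSE)))
#' co
psp_cohort <- function(patients, observations = NULL) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "age_at_onset", "disease_duration")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patients table is missing column(s): ", paste(miss, collapse = ", "))
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table: ",
         patients$patient_id[duplicated(patients$patient_id)][1])
  bad_sex <- !patients$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("invalid sex at patients row ", which(bad_sex)[1],
         " (must be 'male' or 'female')")
  if (any(!is.finite(patients$disease_duration) | patients$disease_duration <= 0))
    stop("disease_duration must be > 0 (patients row ",
         which(!is.finite(patients$disease_duration) |
                 patients$disease_duration <= 0)[1], ")")
  if (any(!is.finite(patients$age_at_onset) | patients$age_at_onset < 0))
    stop("age_at_onset must be non-negative (patients row ",
         which(!is.finite(patients$age_at_onset) | patients$age_at_onset < 0)[1],
         ")")
  if (!is.null(patients$age_at_death)) {
    dev <- abs(patients$age_at_death -
                 (patients$age_at_onset + patients$disease_duration))
    if (any(dev > 0.51, na.rm = TRUE))
      stop("age_at_death inconsistent with onset age + duration at patients row ",
           which(dev > 0.51)[1])
  }
  patients$age_at_death <- patients$age_at_onset + patients$disease_duration
  if (is.null(patients$latent_archetype))
    patients$latent_archetype <- rep(NA_character_, nrow(patients))
  patients <- patients[, c(need, "age_at_death", "latent_archetype")]

  if (is.null(observations)) {
    observations <- data.frame(patient_id = character(), symptom = character(),
                               t = numeric(), present = logical())
  }
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  needo <- c("patient_id", "symptom", "t", "present")
  miss <- setdiff(needo, names(observations))
  if (length(miss))
    stop("observations table is missing column(s): ",
         paste(miss, collapse = ", "))
  observations <- observations[, needo]
  observations$patient_id <- as.character(observations$patient_id)
  observations$symptom <- as.character(observations$symptom)
  observations$present <- as.logical(observations$present)
  if (nrow(observations)) {
    bad <- !observations$symptom %in% psp_symptoms()
    if (any(bad))
      stop("unknown symptom code '", observations$symptom[bad][1],
           "' at observations row ", which(bad)[1])
    bad <- !is.finite(observations$t) | observations$t < 0
    if (any(bad))
      stop("negative or missing t at observations row ", which(bad)[1])
    if (any(is.na(observations$present)))
      stop("missing present flag at observations row ",
           which(is.na(observations$present))[1])
    bad <- !observations$patient_id %in% patients$patient_id
    if (any(bad))
      stop("observation for unknown patient_id '",
           observations$patient_id[bad][1], "' at observations row ",
           which(bad)[1])
    dur <- patients$disease_duration[match(observations$patient_id,
                                           patients$patient_id)]
    bad <- observations$t > dur + 1e-8
    if (any(bad))
      stop("observation time exceeds disease duration at observations row ",
           which(bad)[1])
    key <- paste(observations$patient_id, observations$symptom,
                 signif(observations$t, 12), sep = "\r")
    if (anyDuplicated(key)) {
      warning("collapsing ", sum(duplicated(key)),
              " duplicate (patient_id, symptom, t) observation(s) by OR of 'present'")
      agg <- tapply(observations$present, key, any)
      first <- !duplicated(key)
      observations <- observations[first, ]
      observations$present <- as.logical(agg[key[first]])
    }
    observations <- observations[order(observations$patient_id,
                                       observations$symptom, observations$t), ]
  }
  rownames(patients) <- NULL
  rownames(observations) <- NULL
  structure(list(patients = patients, observations = observations),
            class = "psp_cohort")
}

#' @export
print.psp_cohort <- function(x, ...) {
  cat("psp_cohort:", nrow(x$patients), "patients,",
      nrow(x$observations), "observations\n")
  if (nrow(x$patients)) {
    cat("  disease duration (years): median",
        round(stats::median(x$patients$disease_duration), 1),
        sprintf("[%s, %s]",
                round(stats::quantile(x$patients$disease_duration, .25), 1),
                round(stats::quantile(x$patients$disease_duration, .75), 1)),
        "\n")
    cat("  male:", sum(x$patients$sex == "male"), "/", nrow(x$patients), "\n")
    if (any(!is.na(x$patients$latent_archetype))) {
      tb <- table(x$patients$latent_archetype)
      cat("  latent archetypes:",
          paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
summary.psp_cohort <- function(object, ...) {
  p <- object$patients
  data.frame(
    n = nrow(p),
    n_observations = nrow(object$observations),
    male_frac = if (nrow(p)) mean(p$sex == "male") else NA_real_,
    duration_median = if (nrow(p)) stats::median(p$disease_duration) else NA_real_,
    onset_age_median = if (nrow(p)) stats::median(p$age_at_onset) else NA_real_
  )
}

#' Number of patients in a cohort
#' @param co A `psp_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(co) {
  stopifnot(inherits(co, "psp_cohort"))
  nrow(co$patients)
}
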