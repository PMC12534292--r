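#' Two-timepoint inclusion criterion
#'
#' A patient enters the analysis only when at least one key-symptom
#' observation (present or absent) falls within three years of disease onset
#' and at least one falls after three years, so that both the early window
#' and the subsequent course are documented.
#'
#' @param co A [psp_cohort()].
#' @param window Early-window bound in years (default 3; the bound is closed,
#'   so an observation at exactly `window` counts as early).
#' @return Named logical vector over patients, in `co$patients` order.
#' @export
meets_inclusion <- function(co, window = 3) {
  stopifnot(inherits(co, "psp_cohort"), window > 0)
  o <- co$observations
  early <- unique(o$patient_id[o$t <= window])
  late <- unique(o$patient_id[o$t > window])
  out <- co$patients$patient_id %in% early & co$patients$patient_id %in% late
  names(out) <- co$patients$patient_id
  out
}

# tri-state status of each symptom for one window:
#   P: some present observation at t <= window
#   A: in-window observations exist but none present (a present record after
#      the window does not retroactively mark the early status)
#   N: no in-window observation of the symptom
.tristate_status <- function(obs_sym, obs_t, obs_present, window) {
  inw <- obs_t <= window
  if (!length(obs_sym)) {
    out <- rep("N", length(psp_symptoms()))
    names(out) <- psp_symptoms()
    return(out)
  }
  pres <- tapply(obs_present & inw, obs_sym, any)
  eval_ <- tapply(inw, obs_sym, any)
  out <- rep("N", length(psp_symptoms()))
  names(out) <- psp_symptoms()
  seen <- names(eval_)[eval_]
  out[seen] <- "A"
  out[names(pres)[pres]] <- "P"
  out
}

# composite tri-state from constituent tri-states: present iff any
# constituent present; not evaluated iff all constituents not evaluated;
# otherwise absent
.composite_status <- function(states) {
  comp <- psp_composites()
  vapply(comp, function(parts) {
    s <- states[parts]
    if (any(s == "P")) "P" else if (all(s == "N")) "N" else "A"
  }, "")
}

.feature_frame <- function(co, window) {
  p <- co$patients
  o <- co$observations
  split_idx <- split(seq_len(nrow(o)), o$patient_id)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    idx <- split_idx[[p$patient_id[i]]]
    w <- if (is.finite(window)) window else p$disease_duration[i]
    st <- .tristate_status(o$symptom[idx], o$t[idx], o$present[idx], w)
    c(st, .composite_status(st))
  })
  m <- do.call(rbind, rows)
  out <- data.frame(patient_id = p$patient_id, m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Early tri-state feature vectors
#'
#' Reduces each patient's longitudinal observations to a tri-state status
#' (`"P"` present, `"A"` absent, `"N"` not evaluated) per key symptom within
#' the early window, plus the five composite manifestations (frontal,
#' postural instability, speech/language, ocular motor, parkinsonism). A
#' symptom is present when any present observation falls at or before
#' `window` years; absent when in-window observations exist but none are
#' present; not evaluated when the symptom has no in-window observation at
#' all — a present record after the window does not retroactively mark the
#' early status. The parkinsonism composite is present iff any of
#' bradykinesia, rigidity, or rest tremor is present, not evaluated iff all
#' three are, and absent otherwise.
#'
#' @param co A [psp_cohort()].
#' @param window Early window in years (default 3, closed bound).
#' @return data.frame of class `psp_features`: `patient_id`, one column per
#'   symptom code, and composite columns `frontal`, `pi`, `sl`, `om`,
#'   `parkinsonism`, each `"P"`/`"A"`/`"N"`; the window is stored as an
#'   attribute.
#' @export
early_features <- function(co, window = 3) {
  stopifnot(inherits(co, "psp_cohort"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("window must be a positive number of years")
  out <- .feature_frame(co, window)
  attr(out, "window") <- window
  class(out) <- c("psp_features", "data.frame")
  out
}

#' Lifelong tri-state feature vectors
#'
#' Same reduction as [early_features()] with the window equal to each
#' patient's disease duration, i.e. symptom status over the whole observed
#' life. A symptom present early is necessarily present lifelong.
#'
#' @param co A [psp_cohort()].
#' @return A `psp_features` data.frame (window attribute `Inf`).
#' @export
lifelong_features <- function(co) {
  stopifnot(inherits(co, "psp_cohort"))
  out <- .feature_frame(co, Inf)
  attr(out, "window") <- Inf
  class(out) <- c("psp_features", "data.frame")
  out
}

#' Binary matrix for clustering input
#'
#' Collapses tri-state features to the binary coding the clustering stage
#' uses: present is 1; absent and not-evaluated are both 0 (unavailable data
#' treated as absence).
#'
#' @param features A `psp_features` data.frame (or any data.frame with the 12
#'   symptom columns coded `"P"`/`"A"`/`"N"`).
#' @return Integer matrix, patients by the 12 symptom codes, with
#'   `patient_id` rownames.
#' @export
to_binary_matrix <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  miss <- setdiff(psp_symptoms(), names(features))
  if (length(miss))
    stop("features are missing symptom column(s): ",
         paste(miss, collapse = ", "))
  m <- vapply(psp_symptoms(), function(s) as.integer(features[[s]] == "P"),
              integer(nrow(features)))
  m <- matrix(m, nrow = nrow(features),
              dimnames = list(features$patient_id, psp_symptoms()))
  m
}
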