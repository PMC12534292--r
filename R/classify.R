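#' Classify early feature vectors into mutually exclusive subtypes
#'
#' Applies the published five-feature decision rule to the composite columns
#' of a feature table. Traversal (a not-evaluated composite is treated as
#' absent at every node):
#'
#' * postural instability present:
#'   * frontal present -> **PSP-PF**
#'   * frontal absent, ocular motor present -> **PSP-RS**
#'   * frontal absent, ocular motor absent -> **PSP-PI**
#' * postural instability absent:
#'   * frontal present -> **PSP-F**
#'   * speech/language present -> **PSP-SL**
#'   * ocular motor present -> **PSP-OM**
#'   * parkinsonism present -> **PSP-P**
#'   * otherwise -> **Misc**
#'
#' Every combination of composite states receives exactly one label
#' (totality and mutual exclusivity). On the postural-instability-absent side
#' frontal presentation is checked before speech/language; set
#' `sl_before_frontal = TRUE` to flip that priority.
#'
#' @param features A `psp_features` data.frame (see [early_features()]), or
#'   any data.frame with columns `frontal`, `pi`, `sl`, `om`, `parkinsonism`
#'   coded `"P"`/`"A"`/`"N"`.
#' @param sl_before_frontal Check speech/language before frontal on the
#'   postural-instability-absent branch (default `FALSE`).
#' @return Factor of subtype labels with levels [psp_labels()].
#' @export
#' @examples
#' f <- data.frame(frontal = "P", pi = "P", sl = "A", om = "N",
#'                 parkinsonism = "A")
#' classify_subtype(f)  # PSP-PF
classify_subtype <- function(features, sl_before_frontal = FALSE) {
  comp <- c("frontal", "pi", "sl", "om", "parkinsonism")
  miss <- setdiff(comp, names(features))
  if (length(miss))
    stop("feature table is missing composite column(s): ",
         paste(miss, collapse = ", "))
  for (cc in comp) {
    bad <- !features[[cc]] %in% .tristate
    if (any(bad))
      stop("malformed composite state '", features[[cc]][bad][1], "' in ", cc)
  }
  f  <- features$frontal == "P"
  pi <- features$pi == "P"
  sl <- features$sl == "P"
  om <- features$om == "P"
  pk <- features$parkinsonism == "P"
  lab <- rep("Misc", nrow(features))
  if (sl_before_frontal) {
    lab[!pi & pk] <- "PSP-P"
    lab[!pi & om] <- "PSP-OM"
    lab[!pi & f]  <- "PSP-F"
    lab[!pi & sl] <- "PSP-SL"
  } else {
    lab[!pi & pk] <- "PSP-P"
    lab[!pi & om] <- "PSP-OM"
    lab[!pi & sl] <- "PSP-SL"
    lab[!pi & f]  <- "PSP-F"
  }
  lab[pi] <- "PSP-PI"
  lab[pi & om] <- "PSP-RS"
  lab[pi & f]  <- "PSP-PF"
  factor(lab, levels = psp_labels())
}

#' Exhaustive rule table over the five composite features
#'
#' Enumerates all 32 present/absent combinations of the five composites and
#' the label each receives, with per-label combination counts. This is the
#' reference the learned, distilled tree is compared against.
#'
#' @inheritParams classify_subtype
#' @return data.frame with columns `frontal`, `pi`, `sl`, `om`,
#'   `parkinsonism` (0/1), and `label`; per-label counts in
#'   `attr(, "counts")`.
#' @export
enumerate_rule_table <- function(sl_before_frontal = FALSE) {
  g <- expand.grid(frontal = 0:1, pi = 0:1, sl = 0:1, om = 0:1,
                   parkinsonism = 0:1)
  st <- as.data.frame(lapply(g, function(x) ifelse(x == 1, "P", "A")),
                      stringsAsFactors = FALSE)
  g$label <- classify_subtype(st, sl_before_frontal = sl_before_frontal)
  attr(g, "counts") <- table(g$label)
  g
}

#' Classify a cohort
#'
#' Extracts early features at the given window and classifies every patient
#' passing the two-timepoint inclusion criterion; excluded patients are
#' flagged rather than labeled.
#'
#' @param co A [psp_cohort()].
#' @param window Early window in years (default 3).
#' @inheritParams classify_subtype
#' @return data.frame `patient_id`, `included` (logical), `subtype` (factor,
#'   `NA` for excluded patients).
#' @export
classify_cohort <- function(co, window = 3, sl_before_frontal = FALSE) {
  stopifnot(inherits(co, "psp_cohort"))
  if (nrow(co$patients) == 0)
    return(data.frame(patient_id = character(), included = logical(),
                      subtype = factor(character(), levels = psp_labels())))
  inc <- meets_inclusion(co, window)
  fx <- early_features(co, window)
  lab <- classify_subtype(fx, sl_before_frontal = sl_before_frontal)
  lab[!inc] <- NA
  data.frame(patient_id = co$patients$patient_id, included = unname(inc),
             subtype = lab, stringsAsFactors = FALSE)
}
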