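#' Read a cohort file
#'
#' Reads the on-disk cohort schema in either of two equivalent dialects:
#'
#' * **csv** — one row per observation with patient-level fields repeated:
#'   columns `patient_id`, `sex`, `age_at_onset`, `disease_duration`,
#'   `symptom`, `t_years`, `present` (booleans written as `true`/`false`,
#'   UTF-8, comma-separated, header row), plus an optional `latent_archetype`
#'   column. A patient without observations is encoded as a single row with
#'   empty `symptom`, `t_years`, and `present` fields.
#' * **json** — an array of patient objects, each with a nested
#'   `observations` array.
#'
#' Validation is total: the file either yields a validated [psp_cohort()] or
#' an error naming the offending row. Duplicate `(patient_id, symptom, t)`
#' rows collapse by OR of `present`, with a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A validated [psp_cohort()].
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    pats <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(pats) == 0 || NROW(pats) == 0)
      return(psp_cohort(data.frame(patient_id = character(), sex = character(),
                                   age_at_onset = numeric(),
                                   disease_duration = numeric())))
    pt <- data.frame(patient_id = pats$patient_id, sex = pats$sex,
                     age_at_onset = pats$age_at_onset,
                     disease_duration = pats$disease_duration,
                     latent_archetype = pats$latent_archetype %||% NA_character_,
                     stringsAsFactors = FALSE)
    obs_list <- pats$observations
    obs <- do.call(rbind, lapply(seq_along(obs_list), function(i) {
      o <- obs_list[[i]]
      if (is.null(o) || NROW(o) == 0) return(NULL)
      data.frame(patient_id = pt$patient_id[i], symptom = o$symptom,
                 t = o$t, present = o$present, stringsAsFactors = FALSE)
    }))
    return(psp_cohort(pt, obs))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient_id", "sex", "age_at_onset", "disease_duration",
            "symptom", "t_years", "present")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort csv is missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(x) & !(tab[[col]] %in% c("", "NA"))
    if (any(bad)) stop("non-numeric ", what, " at csv row ", which(bad)[1] + 1L)
    x
  }
  age <- num("age_at_onset", "age_at_onset")
  dur <- num("disease_duration", "disease_duration")
  tys <- num("t_years", "t_years")
  pres <- ifelse(tab$present %in% c("true", "TRUE", "True"), TRUE,
                 ifelse(tab$present %in% c("false", "FALSE", "False"), FALSE, NA))
  first <- !duplicated(tab$patient_id)
  pt <- data.frame(patient_id = tab$patient_id[first], sex = tab$sex[first],
                   age_at_onset = age[first], disease_duration = dur[first],
                   stringsAsFactors = FALSE)
  if ("latent_archetype" %in% names(tab)) {
    la <- tab$latent_archetype[first]
    pt$latent_archetype <- ifelse(la %in% c("", "NA"), NA_character_, la)
  }
  has_obs <- !(tab$symptom %in% c("", "NA"))
  bad <- has_obs & is.na(pres)
  if (any(bad))
    stop("present flag must be true/false at csv row ", which(bad)[1] + 1L)
  obs <- data.frame(patient_id = tab$patient_id[has_obs],
                    symptom = tab$symptom[has_obs],
                    t = tys[has_obs], present = pres[has_obs],
                    stringsAsFactors = FALSE)
  psp_cohort(pt, obs)
}

#' Write a cohort file
#'
#' Writes a validated cohort in the csv or json dialect documented in
#' [read_cohort()]. Reading the written file back reproduces the cohort
#' field-for-field.
#'
#' @param co A [psp_cohort()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(co, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(co, "psp_cohort"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    pats <- lapply(seq_len(nrow(co$patients)), function(i) {
      p <- co$patients[i, ]
      o <- co$observations[co$observations$patient_id == p$patient_id, ]
      out <- list(patient_id = p$patient_id, sex = p$sex,
                  age_at_onset = p$age_at_onset,
                  disease_duration = p$disease_duration)
      if (!is.na(p$latent_archetype)) out$latent_archetype <- p$latent_archetype
      out$observations <- if (nrow(o))
        data.frame(symptom = o$symptom, t = o$t, present = o$present)
      else list()
      out
    })
    jsonlite::write_json(pats, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    return(invisible(path))
  }
  p <- co$patients
  o <- co$observations
  idx <- match(o$patient_id, p$patient_id)
  rows <- data.frame(patient_id = o$patient_id, sex = p$sex[idx],
                     age_at_onset = p$age_at_onset[idx],
                     disease_duration = p$disease_duration[idx],
                     symptom = o$symptom,
                     t_years = o$t,
                     present = ifelse(o$present, "true", "false"),
                     latent_archetype = p$latent_archetype[idx],
                     stringsAsFactors = FALSE)
  lone <- !(p$patient_id %in% o$patient_id)
  if (any(lone)) {
    rows <- rbind(rows, data.frame(
      patient_id = p$patient_id[lone], sex = p$sex[lone],
      age_at_onset = p$age_at_onset[lone],
      disease_duration = p$disease_duration[lone],
      symptom = "", t_years = NA_real_, present = "",
      latent_archetype = p$latent_archetype[lone]))
  }
  rows <- rows[order(match(rows$patient_id, p$patient_id)), ]
  if (all(is.na(rows$latent_archetype))) rows$latent_archetype <- NULL
  else rows$latent_archetype[is.na(rows$latent_archetype)] <- ""
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
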