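# Resolve a symptom-or-composite argument to its constituent symptom codes.
.resolve_symptom <- function(symptom) {
  if (symptom %in% psp_symptoms()) return(symptom)
  comp <- psp_composites()
  if (symptom %in% names(comp)) return(comp[[symptom]])
  stop("unknown symptom or composite: ", symptom)
}

# per-patient evaluation flag and first-present onset time for a symptom set
.onset_by_patient <- function(co, parts) {
  o <- co$observations[co$observations$symptom %in% parts, ]
  ids <- co$patients$patient_id
  evaluated <- ids %in% o$patient_id
  op <- o[o$present, ]
  onset <- rep(Inf, length(ids))
  if (nrow(op)) {
    first <- tapply(op$t, op$patient_id, min)
    onset[match(names(first), ids)] <- as.numeric(first)
  }
  list(evaluated = evaluated, onset = onset)
}

#' Milestone-time quantiles per subtype
#'
#' For each subtype, the time by which 25%, 50%, and 75% of the patients
#' evaluated for a symptom have developed it: `t_q` is the smallest observed
#' onset time `t` such that the fraction of evaluated patients with onset at
#' or before `t` reaches `q`. A quantile is undefined (`NA`) when the
#' developed fraction never reaches `q` within observed life — non-developers
#' are treated as never developing, with no censoring correction. "Evaluated"
#' means having at least one observation of the symptom at any time.
#'
#' @param co A [psp_cohort()].
#' @param labels data.frame with `patient_id` and `subtype` (e.g. from
#'   [classify_cohort()]); unlabeled patients are dropped.
#' @param symptom A symptom code or composite name (`"frontal"`, `"pi"`,
#'   `"sl"`, `"om"`, `"parkinsonism"`); composites use the earliest
#'   constituent onset.
#' @param probs Quantile levels in (0, 1), default `c(0.25, 0.5, 0.75)`.
#' @return data.frame per subtype: `subtype`, `symptom`, `n_evaluated`,
#'   `n_developed`, and one `t<q>` column per level.
#' @export
milestone_quantiles <- function(co, labels, symptom,
                                probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(co, "psp_cohort"), all(probs > 0), all(probs < 1))
  parts <- .resolve_symptom(symptom)
  ob <- .onset_by_patient(co, parts)
  sub <- factor(labels$subtype[match(co$patients$patient_id,
                                     labels$patient_id)])
  keep <- !is.na(sub)
  res <- lapply(split(seq_len(nrow(co$patients))[keep], droplevels(sub[keep])),
                function(idx) {
    ev <- ob$evaluated[idx]
    on <- ob$onset[idx][ev]
    n_ev <- sum(ev)
    n_dev <- sum(is.finite(on))
    tq <- vapply(probs, function(q) {
      if (n_ev == 0 || n_dev / n_ev < q) return(NA_real_)
      sort(on)[ceiling(q * n_ev)]
    }, 0)
    c(n_evaluated = n_ev, n_developed = n_dev, tq)
  })
  out <- data.frame(subtype = names(res), symptom = symptom,
                    do.call(rbind, res), stringsAsFactors = FALSE)
  names(out)[-(1:4)] <- paste0("t", round(probs * 100))
  rownames(out) <- NULL
  out
}

#' Early and lifelong symptom frequencies per subtype
#'
#' For every subtype and symptom (the 12 codes plus the 5 composites): the
#' percentage of cases with the symptom present within `window` years of
#' onset, and the percentage present at death, both over the denominator of
#' cases evaluated for that symptom at any point of observed life. The early
#' percentage can never exceed the lifelong percentage.
#'
#' @inheritParams milestone_quantiles
#' @param window Early window in years (default 3).
#' @return data.frame `subtype`, `symptom`, `n_evaluated`, `early_pct`,
#'   `lifelong_pct`.
#' @export
frequency_table <- function(co, labels, window = 3) {
  stopifnot(inherits(co, "psp_cohort"), window > 0)
  syms <- c(psp_symptoms(), names(psp_composites()))
  sub <- factor(labels$subtype[match(co$patients$patient_id,
                                     labels$patient_id)])
  keep <- !is.na(sub)
  out <- list()
  for (symptom in syms) {
    parts <- .resolve_symptom(symptom)
    ob <- .onset_by_patient(co, parts)
    grp <- split(seq_len(nrow(co$patients))[keep],
                 droplevels(sub[keep]))
    for (g in names(grp)) {
      idx <- grp[[g]]
      ev <- ob$evaluated[idx]
      on <- ob$onset[idx][ev]
      n_ev <- sum(ev)
      out[[length(out) + 1L]] <- data.frame(
        subtype = g, symptom = symptom, n_evaluated = n_ev,
        early_pct = if (n_ev) 100 * sum(on <= window) / n_ev else NA_real_,
        lifelong_pct = if (n_ev) 100 * sum(is.finite(on)) / n_ev else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
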