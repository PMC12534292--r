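#' Run the end-to-end subtyping pipeline
#'
#' Orchestrates simulate -> classify -> distill -> progression -> stats as a
#' reproducible run. Every stochastic stage consumes a seed derived
#' deterministically from the single top-level seed (stage index folded in),
#' so stages can be re-run in isolation; identical configurations produce
#' byte-identical tables. Each stage logs row counts in and out, and every
#' output file is listed in the returned manifest with its MD5 hash.
#'
#' Stage outputs (CSV tables, JSON reports) in `output_dir`:
#' * `simulate`: `cohort.csv`
#' * `classify`: `features.csv`, `labels.csv` (requires `cohort.csv`)
#' * `distill`: `distill_report.json`, `rule_table.csv` (requires labels)
#' * `progression`: `milestones.csv`, `frequencies.csv`
#' * `stats`: `cox_summary.csv`, `duration_tests.csv`, `survival_curves.csv`,
#'   `delta_c.json`
#'
#' @param config List with `seed` (integer), `n_patients`, `window` (years,
#'   default 3), `archetypes` (`"default"`, a YAML path, or a list of
#'   [psp_archetype()]), `stages` (ordered subset of the five stage names),
#'   and `output_dir`.
#' @return data.frame manifest: `stage`, `file`, `md5`, `seed`, invisibly
#'   also written to `manifest.csv`.
#' @export
run_pipeline <- function(config) {
  stages_all <- c("simulate", "classify", "distill", "progression", "stats")
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$output_dir))
  stages <- config$stages %||% stages_all
  if (!length(stages) || !all(stages %in% stages_all))
    stop("stages must be a non-empty subset of: ",
         paste(stages_all, collapse = ", "))
  window <- config$window %||% 3
  stopifnot(window > 0)
  n <- config$n_patients %||% 588
  arch <- config$archetypes %||% "default"
  if (identical(arch, "default")) arch <- default_archetypes()
  else if (is.character(arch)) arch <- read_archetypes(arch)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  path <- function(f) file.path(out_dir, f)
  manifest <- list()
  note <- function(stage, files, sd) {
    for (f in files)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = stage, file = basename(f),
        md5 = unname(tools::md5sum(f)), seed = sd,
        stringsAsFactors = FALSE)
  }
  need <- function(stage, f, upstream) {
    if (!file.exists(path(f)))
      stop("stage '", stage, "' requires ", f,
           " produced by upstream stage '", upstream, "'")
  }

  if ("simulate" %in% stages) {
    sd <- derive_seed(seed, 1L)
    co <- generate_cohort(n, archetypes = arch, seed = sd)
    write_cohort(co, path("cohort.csv"))
    message("simulate: ", n_patients(co), " patients, ",
            nrow(co$observations), " observations -> cohort.csv")
    note("simulate", path("cohort.csv"), sd)
  }

  if ("classify" %in% stages) {
    need("classify", "cohort.csv", "simulate")
    co <- read_cohort(path("cohort.csv"))
    fx <- early_features(co, window)
    lab <- classify_cohort(co, window)
    utils::write.csv(cbind(fx, window = window), path("features.csv"),
                     row.names = FALSE)
    utils::write.csv(lab, path("labels.csv"), row.names = FALSE)
    message("classify: ", nrow(lab), " patients in, ",
            sum(lab$included), " pass the two-timepoint inclusion criterion")
    note("classify", c(path("features.csv"), path("labels.csv")),
         derive_seed(seed, 2L))
  }

  if ("distill" %in% stages) {
    need("distill", "features.csv", "classify")
    need("distill", "labels.csv", "classify")
    fx <- utils::read.csv(path("features.csv"), stringsAsFactors = FALSE)
    lab <- utils::read.csv(path("labels.csv"), stringsAsFactors = FALSE)
    keep <- lab$included
    m <- to_binary_matrix(fx[keep, ])
    sd <- derive_seed(seed, 3L)
    dd <- distill_subtypes(m, seed = sd)
    message("distill: ", sum(keep), " included patients, ",
            dd$clusters$n_clusters, " clusters, CV accuracy ",
            round(dd$cv$mean_accuracy, 3))
    jsonlite::write_json(list(
      n_clusters = dd$clusters$n_clusters,
      fold_accuracies = dd$cv$fold_accuracies,
      fold_aucs = dd$cv$fold_aucs,
      mean_accuracy = dd$cv$mean_accuracy, sd_accuracy = dd$cv$sd_accuracy,
      mean_auc = dd$cv$mean_auc, sd_auc = dd$cv$sd_auc,
      ablation = dd$ablation, selected_features = dd$selected_features),
      path("distill_report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(dd$simplified$rules, path("rule_table.csv"),
                     row.names = FALSE)
    note("distill", c(path("distill_report.json"), path("rule_table.csv")),
         sd)
  }

  if ("progression" %in% stages) {
    need("progression", "cohort.csv", "simulate")
    need("progression", "labels.csv", "classify")
    co <- read_cohort(path("cohort.csv"))
    lab <- utils::read.csv(path("labels.csv"), stringsAsFactors = FALSE)
    syms <- c(names(psp_composites()), "bradykinesia", "rigidity",
              "rest_tremor")
    ms <- do.call(rbind, lapply(syms, function(s)
      milestone_quantiles(co, lab, s)))
    fq <- frequency_table(co, lab, window)
    utils::write.csv(ms, path("milestones.csv"), row.names = FALSE)
    utils::write.csv(fq, path("frequencies.csv"), row.names = FALSE)
    message("progression: milestones for ", length(syms),
            " symptoms over ", length(unique(ms$subtype)), " subtypes")
    note("progression", c(path("milestones.csv"), path("frequencies.csv")),
         derive_seed(seed, 4L))
  }

  if ("stats" %in% stages) {
    need("stats", "cohort.csv", "simulate")
    need("stats", "labels.csv", "classify")
    co <- read_cohort(path("cohort.csv"))
    lab <- utils::read.csv(path("labels.csv"), stringsAsFactors = FALSE)
    rec <- survival_records(co, lab)
    fit <- fit_cox(rec, c("age_at_onset", "sex", "subtype"))
    utils::write.csv(fit$coefficients, path("cox_summary.csv"),
                     row.names = FALSE)
    groups <- split(rec$duration, rec$subtype)
    groups <- groups[lengths(groups) >= 2]
    kw <- kruskal_wallis(groups)
    sdw <- steel_dwass(groups, method = "asymptotic")
    sdw <- cbind(sdw, kw_h = kw$statistic, kw_p = kw$p_value)
    utils::write.csv(sdw, path("duration_tests.csv"), row.names = FALSE)
    prof <- data.frame(age_at_onset = mean(rec$age_at_onset), sex = "male",
                       subtype = levels(rec$subtype))
    curves <- do.call(rbind, lapply(seq_len(nrow(prof)), function(i) {
      cv <- survival_curve(fit, prof[i, ])
      cbind(subtype = prof$subtype[i], cv)
    }))
    utils::write.csv(curves, path("survival_curves.csv"), row.names = FALSE)
    dc <- delta_c(rec, c("age_at_onset", "sex"), "subtype")
    jsonlite::write_json(dc, path("delta_c.json"), auto_unbox = TRUE,
                         digits = NA)
    message("stats: Cox fit over ", nrow(rec), " records; delta-C = ",
            round(dc$delta, 3))
    note("stats", c(path("cox_summary.csv"), path("duration_tests.csv"),
                    path("survival_curves.csv"), path("delta_c.json")),
         derive_seed(seed, 5L))
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, path("manifest.csv"), row.names = FALSE)
  manifest
}
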