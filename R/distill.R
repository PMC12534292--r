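#' Fit a shallow classification tree to cluster labels
#'
#' Wraps [rpart::rpart()] with the distillation hyperparameters: Gini
#' impurity, best-split strategy, maximum depth 4, minimum 2 samples to split
#' an internal node, minimum 1 sample per leaf, no complexity pruning.
#' Single-class input yields a stump.
#'
#' @param x Binary matrix or data.frame of features (rows = patients).
#' @param labels Vector of class labels aligned with the rows of `x`.
#' @param maxdepth Maximum tree depth (default 4).
#' @return Object of class `psp_tree` wrapping the fitted `rpart` model.
#' @export
fit_subtype_tree <- function(x, labels, maxdepth = 4) {
  x <- as.data.frame(x)
  if (nrow(x) != length(labels)) stop("labels must align with rows of x")
  dat <- cbind(.class = factor(labels), x)
  if (nlevels(dat$.class) == 1L) {
    return(structure(list(rpart = NULL, features = colnames(x),
                          classes = levels(dat$.class),
                          single_class = levels(dat$.class)),
                     class = "psp_tree"))
  }
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = maxdepth, minsplit = 2, minbucket = 1,
                        cp = 0, xval = 0))
  structure(list(rpart = fit, features = colnames(x),
                 classes = levels(dat$.class)),
            class = "psp_tree")
}

#' @export
print.psp_tree <- function(x, ...) {
  cat("psp_tree over", length(x$features), "features,",
      length(x$classes), "classes\n")
  if (is.null(x$single_class)) print(x$rpart)
  else cat("degenerate stump: always predicts", x$single_class, "\n")
  invisible(x)
}

#' Predict from a fitted subtype tree
#' @param object A `psp_tree`.
#' @param newdata Feature matrix/data.frame with the training columns.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of classes, or a class-probability matrix.
#' @export
predict.psp_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (!is.null(object$single_class)) {
    # degenerate stump: one observed class
    if (type == "class")
      return(factor(rep(object$single_class, nrow(newdata)),
                    levels = object$classes))
    return(matrix(1, nrow(newdata), 1,
                  dimnames = list(NULL, object$single_class)))
  }
  predict(object$rpart, newdata = newdata, type = type)
}

.make_folds <- function(labels, k, seed) {
  n <- length(labels)
  with_seed(seed, {
    tab <- table(labels)
    if (min(tab) < k) {
      message("class with fewer than ", k,
              " members; falling back to non-stratified folds")
      folds <- sample(rep_len(seq_len(k), n))
    } else {
      folds <- integer(n)
      for (cl in names(tab)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    folds
  })
}

#' Cross-validated fidelity of a tree against cluster labels
#'
#' Stratified k-fold cross-validation of [fit_subtype_tree()]: per-fold
#' accuracy (label agreement) and macro one-vs-rest AUC computed from the
#' tree's leaf class-probability scores. Classes with fewer than `k` members
#' trigger a logged fallback to non-stratified folds.
#'
#' @inheritParams fit_subtype_tree
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List of class `psp_cv`: `fold_accuracies`, `fold_aucs`,
#'   `mean_accuracy`, `sd_accuracy`, `mean_auc`, `sd_auc`.
#' @export
cross_validate_tree <- function(x, labels, k = 10, seed = NULL) {
  x <- as.data.frame(x)
  labels <- factor(labels)
  n <- nrow(x)
  if (n < k) stop("need at least k = ", k, " rows")
  folds <- .make_folds(labels, k, seed)
  acc <- auc <- numeric(k)
  for (fold in seq_len(k)) {
    te <- folds == fold
    tree <- fit_subtype_tree(x[!te, , drop = FALSE], labels[!te])
    pred <- predict(tree, x[te, , drop = FALSE], type = "class")
    acc[fold] <- mean(as.character(pred) == as.character(labels[te]))
    pr <- predict(tree, x[te, , drop = FALSE], type = "prob")
    aucs <- vapply(colnames(pr), function(cl) {
      pos <- labels[te] == cl
      auc_rank(pr[, cl], pos)
    }, 0)
    auc[fold] <- mean(aucs, na.rm = TRUE)
  }
  structure(list(fold_accuracies = acc, fold_aucs = auc,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_auc = mean(auc), sd_auc = stats::sd(auc)),
            class = "psp_cv")
}

#' @export
print.psp_cv <- function(x, ...) {
  cat(sprintf("tree fidelity: accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f (%d folds)\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc,
              length(x$fold_accuracies)))
  invisible(x)
}

#' Leave-one-feature-out ablation
#'
#' Re-runs the cross-validated fit with each feature column dropped in turn;
#' the delta is the full-model metric minus the reduced-model metric, so a
#' large positive accuracy delta marks a feature the tree needs.
#'
#' @inheritParams cross_validate_tree
#' @return data.frame `feature`, `accuracy_delta`, `auc_delta`, sorted by
#'   accuracy delta; full-model CV stored in `attr(, "full")`.
#' @export
ablate_features <- function(x, labels, k = 10, seed = NULL) {
  x <- as.data.frame(x)
  full <- cross_validate_tree(x, labels, k = k, seed = seed)
  out <- do.call(rbind, lapply(colnames(x), function(feat) {
    red <- cross_validate_tree(x[, setdiff(colnames(x), feat), drop = FALSE],
                               labels, k = k, seed = seed)
    data.frame(feature = feat,
               accuracy_delta = full$mean_accuracy - red$mean_accuracy,
               auc_delta = full$mean_auc - red$mean_auc,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$accuracy_delta), ]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

# composite present/absent bits from a binary 12-symptom row block
.composites_from_binary <- function(x) {
  x <- as.data.frame(x)
  comp <- psp_composites()
  out <- lapply(comp, function(parts) {
    as.integer(rowSums(x[, parts, drop = FALSE]) > 0)
  })
  as.data.frame(out)
}

#' Name clusters by their modal symptom pattern
#'
#' Maps each cluster id to a subtype label by thresholding the cluster's mean
#' binary profile at 0.5 and passing the modal pattern through the published
#' decision rule.
#'
#' @param x Binary matrix, patients by the 12 symptom codes.
#' @param labels Integer cluster ids aligned with rows.
#' @return Named character vector, cluster id -> subtype label.
#' @export
cluster_to_subtype <- function(x, labels) {
  x <- as.data.frame(x)
  ids <- sort(unique(labels))
  out <- vapply(ids, function(cl) {
    modal <- as.data.frame(lapply(x[labels == cl, , drop = FALSE],
                                  function(v) as.integer(mean(v) >= 0.5)))
    cb <- .composites_from_binary(modal)
    st <- as.data.frame(lapply(cb, function(v) ifelse(v == 1, "P", "A")),
                        stringsAsFactors = FALSE)
    as.character(classify_subtype(st))
  }, "")
  names(out) <- as.character(ids)
  out
}

#' Simplify a distilled tree and append the parkinsonism leaf
#'
#' Refits the tree on the selected features only and exports an exhaustive
#' rule table over the five composite manifestations. The all-absent
#' combination (no frontal, postural-instability, speech/language, or ocular
#' motor involvement) is split by the parkinsonism composite into PSP-P
#' versus Misc — the appended leaf that the shallow tree cannot learn on its
#' own, since separating those two classes requires a fifth consecutive
#' split. Other combinations take the refit tree's cluster prediction, named
#' via [cluster_to_subtype()].
#'
#' @param x Binary matrix, patients by the 12 symptom codes.
#' @param labels Cluster ids aligned with rows.
#' @param selected_features Non-empty character vector of symptom codes to
#'   keep.
#' @return Object of class `psp_simplified_tree`: the refit `psp_tree`, the
#'   selected features, the cluster naming, and a 32-row rule table
#'   comparable to [enumerate_rule_table()].
#' @export
simplify_tree <- function(x, labels, selected_features) {
  if (!length(selected_features)) stop("selected_features must be non-empty")
  x <- as.data.frame(x)
  miss <- setdiff(selected_features, colnames(x))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  tree <- fit_subtype_tree(x[, selected_features, drop = FALSE], labels)
  naming <- cluster_to_subtype(x, labels)

  combos <- expand.grid(frontal = 0:1, pi = 0:1, sl = 0:1, om = 0:1,
                        parkinsonism = 0:1)
  # raw-feature probe rows for the tree: singles map directly, the three
  # parkinsonian symptoms carry the parkinsonism bit, others zero
  probe <- matrix(0L, nrow(combos), ncol(x),
                  dimnames = list(NULL, colnames(x)))
  probe[, "frontal_presentation"] <- combos$frontal
  probe[, "postural_instability"] <- combos$pi
  probe[, "speech_language"] <- combos$sl
  probe[, "ocular_motor"] <- combos$om
  for (s in psp_composites()$parkinsonism)
    probe[, s] <- combos$parkinsonism
  pred <- predict(tree, probe[, selected_features, drop = FALSE],
                  type = "class")
  combos$cluster <- as.character(pred)
  combos$label <- unname(naming[combos$cluster])
  resid <- combos$frontal == 0 & combos$pi == 0 & combos$sl == 0 &
    combos$om == 0
  combos$cluster[resid] <- NA
  combos$label[resid] <- ifelse(combos$parkinsonism[resid] == 1,
                                "PSP-P", "Misc")
  structure(list(tree = tree, selected_features = selected_features,
                 naming = naming, rules = combos),
            class = "psp_simplified_tree")
}

#' @export
print.psp_simplified_tree <- function(x, ...) {
  cat("psp_simplified_tree on {",
      paste(x$selected_features, collapse = ", "),
      "} + parkinsonism leaf\n")
  cat("rule table labels:\n")
  print(table(x$rules$label))
  invisible(x)
}

#' Predict subtypes from a simplified rule table
#'
#' Looks each patient's five composite bits (computed from the binary
#' 12-symptom profile) up in the exported rule table.
#'
#' @param object A `psp_simplified_tree`.
#' @param newdata Binary matrix/data.frame with the 12 symptom columns.
#' @param ... Unused.
#' @return Factor of subtype labels.
#' @export
predict.psp_simplified_tree <- function(object, newdata, ...) {
  cb <- .composites_from_binary(newdata)
  key <- do.call(paste, c(cb[c("frontal", "pi", "sl", "om", "parkinsonism")],
                          sep = "/"))
  r <- object$rules
  rkey <- paste(r$frontal, r$pi, r$sl, r$om, r$parkinsonism, sep = "/")
  factor(r$label[match(key, rkey)], levels = psp_labels())
}

#' End-to-end cluster-to-tree distillation
#'
#' Runs the discovery pipeline on a binary early-feature matrix: 2-D
#' embedding ([umap_embed()]), density-based cluster detection
#' ([detect_clusters()]), cross-validated tree fidelity
#' ([cross_validate_tree()]), per-feature ablation ([ablate_features()]),
#' selection of features whose accuracy delta exceeds
#' `ablation_threshold`, and simplification with the appended parkinsonism
#' leaf ([simplify_tree()]).
#'
#' @param x Binary matrix, patients by the 12 symptom codes.
#' @param seed Integer seed driving the embedding, folds, and ablation.
#' @param k Cross-validation folds (default 10).
#' @param min_cluster_size Density-core neighborhood count (default 15).
#' @param ablation_threshold Accuracy-delta cutoff for keeping a feature
#'   (default 0.02).
#' @return List of class `psp_distillation`: `embedding`, `clusters`, `cv`,
#'   `ablation`, `selected_features`, `simplified`.
#' @export
distill_subtypes <- function(x, seed = NULL, k = 10, min_cluster_size = 15,
                             ablation_threshold = 0.02) {
  x <- as.matrix(x)
  emb <- umap_embed(x, seed = seed)
  cl <- detect_clusters(emb, min_cluster_size = min_cluster_size)
  cv <- cross_validate_tree(x, cl$labels, k = k, seed = seed)
  abl <- ablate_features(x, cl$labels, k = k, seed = seed)
  sel <- abl$feature[abl$accuracy_delta > ablation_threshold]
  if (!length(sel)) sel <- abl$feature[1]
  simp <- simplify_tree(x, cl$labels, sel)
  structure(list(embedding = emb, clusters = cl, cv = cv, ablation = abl,
                 selected_features = sel, simplified = simp),
            class = "psp_distillation")
}

#' @export
print.psp_distillation <- function(x, ...) {
  cat("psp_distillation:", x$clusters$n_clusters, "clusters;")
  cat(sprintf(" CV accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f\n",
              x$cv$mean_accuracy, x$cv$sd_accuracy, x$cv$mean_auc,
              x$cv$sd_auc))
  cat("selected features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
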