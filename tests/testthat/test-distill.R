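test_that("a single decisive feature yields a depth-1 tree with perfect training accuracy", {
  set.seed(3)
  x <- as.data.frame(matrix(rbinom(200 * 12, 1, 0.5), 200, 12,
                            dimnames = list(NULL, psp_symptoms())))
  labels <- ifelse(x$ocular_motor == 1, "yes", "no")
  tree <- fit_subtype_tree(x, labels)
  pred <- predict(tree, x)
  expect_equal(mean(as.character(pred) == labels), 1)
  expect_lte(nrow(tree$rpart$frame[tree$rpart$frame$var != "<leaf>", ]), 1)
  # degenerate single-class input returns a stump
  stump <- fit_subtype_tree(x, rep("one", 200))
  expect_equal(as.character(predict(stump, x[1:5, ])), rep("one", 5))
  expect_equal(unname(predict(stump, x[1:5, ], type = "prob")[, 1]),
               rep(1, 5))
})

test_that("the 4-feature part of the published rule is depth-4 learnable with perfect CV", {
  g <- expand.grid(frontal = 0:1, pi = 0:1, sl = 0:1, om = 0:1)
  st <- as.data.frame(lapply(g, function(x) ifelse(x == 1, "P", "A")))
  st$parkinsonism <- "A"
  lab4 <- as.character(classify_subtype(st))
  lab4[lab4 %in% c("PSP-P", "Misc")] <- "residual"
  x <- g[rep(seq_len(16), 10), ]
  y <- rep(lab4, 10)
  cv <- cross_validate_tree(x, y, k = 10, seed = 1)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$sd_accuracy, 0)
  expect_equal(cv$mean_auc, 1)
})

test_that("cross-validation metrics live in [0,1], beat permuted labels, and reproduce", {
  ft <- generate_feature_table(300, separated_archetypes(), seed = 5)
  x <- ft[, psp_symptoms()]
  y <- ft$latent_archetype
  cv <- cross_validate_tree(x, y, k = 10, seed = 7)
  expect_identical(cv$fold_accuracies,
                   cross_validate_tree(x, y, k = 10, seed = 7)$fold_accuracies)
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  expect_true(all(cv$fold_aucs >= 0 & cv$fold_aucs <= 1))
  # training accuracy is at least the CV mean
  tr <- mean(as.character(predict(fit_subtype_tree(x, y), x)) == y)
  expect_gte(tr, cv$mean_accuracy - 1e-9)
  set.seed(42)
  yp <- sample(y)
  cvp <- cross_validate_tree(x, yp, k = 10, seed = 7)
  base <- max(table(y)) / length(y)
  expect_lt(cvp$mean_accuracy, base + 0.1)
  expect_gt(cv$mean_accuracy, cvp$mean_accuracy)
})

test_that("non-stratified fallback fires when a class is smaller than k", {
  x <- as.data.frame(matrix(rbinom(30 * 12, 1, 0.5), 30, 12,
                            dimnames = list(NULL, psp_symptoms())))
  y <- c(rep("big", 27), rep("tiny", 3))
  expect_message(cross_validate_tree(x, y, k = 10, seed = 1),
                 "non-stratified")
})

test_that("ablation pinpoints constructed dependence and ignores irrelevant features", {
  set.seed(11)
  x <- as.data.frame(matrix(rbinom(400 * 12, 1, 0.5), 400, 12,
                            dimnames = list(NULL, psp_symptoms())))
  y <- ifelse(x$speech_language == 1, "a", "b")  # labels copy one feature
  ab <- ablate_features(x, y, k = 5, seed = 3)
  expect_equal(ab$feature[which.max(ab$accuracy_delta)], "speech_language")
  others <- ab$accuracy_delta[ab$feature != "speech_language"]
  expect_true(all(abs(others) < 0.05))
})

test_that("ablation deltas for features absent from the generating process are near zero", {
  ft <- generate_feature_table(500, separated_archetypes(), seed = 9)
  ab <- ablate_features(ft[, psp_symptoms()], ft$latent_archetype,
                        k = 10, seed = 9)
  irrelevant <- c("ataxia", "motor_neuron_signs", "limb_rigidity_myoclonus",
                  "cortical_signs", "akinesia", "rest_tremor")
  expect_true(all(abs(ab$accuracy_delta[ab$feature %in% irrelevant]) <= 0.02))
})

test_that("simplify learns the exact published rules when training covers all combos", {
  # full-coverage training set: the 32 combinations replicated, labeled by
  # the published rule with the residual P/Misc classes merged (that split
  # is the appended leaf's job, not the tree's)
  g <- expand.grid(frontal = 0:1, pi = 0:1, sl = 0:1, om = 0:1,
                   parkinsonism = 0:1)
  st <- as.data.frame(lapply(g, function(v) ifelse(v == 1, "P", "A")))
  lab <- as.character(classify_subtype(st))
  lab[lab %in% c("PSP-P", "Misc")] <- "residual"
  x <- matrix(0L, 32, 12, dimnames = list(NULL, psp_symptoms()))
  x[, "frontal_presentation"] <- g$frontal
  x[, "postural_instability"] <- g$pi
  x[, "speech_language"] <- g$sl
  x[, "ocular_motor"] <- g$om
  for (s in psp_composites()$parkinsonism) x[, s] <- g$parkinsonism
  x <- as.data.frame(x[rep(1:32, 8), ])
  lab <- rep(lab, 8)
  simp <- simplify_tree(x, lab, c("frontal_presentation",
                                  "postural_instability", "speech_language",
                                  "ocular_motor"))
  er <- enumerate_rule_table()
  key <- function(d) paste(d$frontal, d$pi, d$sl, d$om, d$parkinsonism)
  got <- simp$rules$label[match(key(er), key(simp$rules))]
  expect_equal(got, as.character(er$label))
  # the all-absent residual is split by parkinsonism alone
  resid <- simp$rules[simp$rules$frontal == 0 & simp$rules$pi == 0 &
                        simp$rules$sl == 0 & simp$rules$om == 0, ]
  expect_equal(sort(resid$label), c("Misc", "PSP-P"))
  expect_error(simplify_tree(x, lab, character()), "non-empty")
})

test_that("on noiseless archetype data the rules match on every observed combination", {
  ft <- generate_feature_table(588, separated_archetypes(flip = 0), seed = 13)
  x <- ft[, psp_symptoms()]
  cl <- as.integer(factor(ft$latent_archetype))
  simp <- simplify_tree(x, cl, c("frontal_presentation",
                                 "postural_instability", "speech_language",
                                 "ocular_motor"))
  pred <- predict(simp, x)
  cb <- pspsubtype:::.composites_from_binary(x)
  st <- as.data.frame(lapply(cb, function(v) ifelse(v == 1, "P", "A")))
  expect_equal(as.character(pred), as.character(classify_subtype(st)))
  # selected_features = all 12 reduces to the plain fitted tree
  full <- simplify_tree(x, cl, psp_symptoms())
  expect_equal(as.character(predict(full$tree, x)), as.character(cl))
})

test_that("end-to-end distillation recovers the hard-coded rules on separated archetypes", {
  ft <- generate_feature_table(588, separated_archetypes(), seed = 3)
  m <- as.matrix(ft[, psp_symptoms()])
  dd <- distill_subtypes(m, seed = 3)
  expect_equal(dd$clusters$n_clusters, 6L)
  expect_setequal(dd$selected_features,
                  c("frontal_presentation", "postural_instability",
                    "speech_language", "ocular_motor"))
  pred <- predict(dd$simplified, m)
  cb <- pspsubtype:::.composites_from_binary(m)
  st <- as.data.frame(lapply(cb, function(v) ifelse(v == 1, "P", "A")))
  hard <- classify_subtype(st)
  expect_gte(mean(as.character(pred) == as.character(hard)), 0.95)
})
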