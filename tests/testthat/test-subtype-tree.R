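test_that("the decision rule reproduces the published subtype definitions", {
  # postural instability with frontal presentation, regardless of the rest
  expect_equal(as.character(classify_subtype(
    composite_row(frontal = "P", pi = "P", om = "P", sl = "P",
                  parkinsonism = "P"))), "PSP-PF")
  # PI + ocular motor without frontal: Richardson's syndrome
  expect_equal(as.character(classify_subtype(
    composite_row(pi = "P", om = "P"))), "PSP-RS")
  # PI without ocular motor or frontal
  expect_equal(as.character(classify_subtype(
    composite_row(pi = "P"))), "PSP-PI")
  # parkinsonian features without frontal, PI, or SL
  expect_equal(as.character(classify_subtype(
    composite_row(parkinsonism = "P"))), "PSP-P")
  # OM without frontal, PI, or SL
  expect_equal(as.character(classify_subtype(
    composite_row(om = "P"))), "PSP-OM")
  expect_equal(as.character(classify_subtype(composite_row(sl = "P"))),
               "PSP-SL")
  expect_equal(as.character(classify_subtype(composite_row(frontal = "P"))),
               "PSP-F")
  # everything not evaluated is treated as absent
  expect_equal(as.character(classify_subtype(
    composite_row("N", "N", "N", "N", "N"))), "Misc")
  expect_error(classify_subtype(data.frame(frontal = "P")), "missing composite")
  expect_error(classify_subtype(composite_row(pi = "yes")), "malformed")
})

test_that("classification is total and single-valued over all 3^5 tri-states", {
  g <- expand.grid(frontal = c("P", "A", "N"), pi = c("P", "A", "N"),
                   sl = c("P", "A", "N"), om = c("P", "A", "N"),
                   parkinsonism = c("P", "A", "N"),
                   stringsAsFactors = FALSE)
  lab <- classify_subtype(g)
  expect_equal(length(lab), 3^5)
  expect_false(any(is.na(lab)))
  # not_evaluated behaves exactly like absent at every node
  g2 <- as.data.frame(lapply(g, function(x) ifelse(x == "N", "A", x)),
                      stringsAsFactors = FALSE)
  expect_equal(classify_subtype(g2), lab)
})

test_that("rule-table enumeration yields 7 subtypes + Misc with the exact counts", {
  rt <- enumerate_rule_table()
  expect_equal(nrow(rt), 32)
  counts <- attr(rt, "counts")
  expect_equal(unname(counts[c("PSP-PF", "PSP-F", "PSP-RS", "PSP-PI",
                               "PSP-SL", "PSP-OM", "PSP-P", "Misc")]),
               as.array(c(8L, 8L, 4L, 4L, 4L, 2L, 1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(sum(counts), 32L)
  expect_equal(length(setdiff(unique(as.character(rt$label)), "Misc")), 7)
  # oracle equivalence: the enumerated table agrees with direct classification
  st <- as.data.frame(lapply(rt[1:5], function(x) ifelse(x == 1, "P", "A")),
                      stringsAsFactors = FALSE)
  expect_equal(classify_subtype(st), rt$label)
})

test_that("the frontal/SL priority switch flips only the contested combinations", {
  rt1 <- enumerate_rule_table()
  rt2 <- enumerate_rule_table(sl_before_frontal = TRUE)
  contested <- rt1$pi == 0 & rt1$frontal == 1 & rt1$sl == 1
  expect_equal(as.character(rt1$label[contested]),
               rep("PSP-F", sum(contested)))
  expect_equal(as.character(rt2$label[contested]),
               rep("PSP-SL", sum(contested)))
  expect_equal(rt1$label[!contested], rt2$label[!contested])
})

test_that("classify depends only on composite states, not symptom order", {
  co <- toy_cohort()
  perm <- co
  perm$observations <- perm$observations[rev(seq_len(nrow(perm$observations))), ]
  perm <- psp_cohort(perm$patients, perm$observations)
  expect_equal(classify_cohort(co)$subtype, classify_cohort(perm)$subtype)
})

test_that("classify_cohort labels included patients and flags the rest", {
  co <- generate_cohort(100, seed = 12)
  lab <- classify_cohort(co)
  expect_equal(nrow(lab), 100)
  expect_true(all(is.na(lab$subtype[!lab$included])))
  expect_false(any(is.na(lab$subtype[lab$included])))
  empty <- psp_cohort(data.frame(patient_id = character(),
                                 sex = character(), age_at_onset = numeric(),
                                 disease_duration = numeric()))
  expect_equal(nrow(classify_cohort(empty)), 0)
})

test_that("the 8 modal composite patterns map to 8 distinct labels", {
  pats <- rbind(
    composite_row(frontal = "P", pi = "P"),
    composite_row(pi = "P", om = "P"),
    composite_row(pi = "P"),
    composite_row(parkinsonism = "P"),
    composite_row(sl = "P"),
    composite_row(frontal = "P"),
    composite_row(om = "P"),
    composite_row())
  expect_equal(length(unique(classify_subtype(pats))), 8)
})
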