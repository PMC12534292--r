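test_that("cohort validation enforces the patient and observation invariants", {
  co <- toy_cohort()
  expect_s3_class(co, "psp_cohort")
  expect_equal(co$patients$age_at_death, c(73, 76))

  expect_error(psp_cohort(data.frame(patient_id = "x", sex = "male",
                                     age_at_onset = 60,
                                     disease_duration = -1)),
               "disease_duration")
  expect_error(psp_cohort(data.frame(patient_id = "x", sex = "other",
                                     age_at_onset = 60,
                                     disease_duration = 5)),
               "sex")
  expect_error(
    psp_cohort(data.frame(patient_id = "x", sex = "male",
                          age_at_onset = 60, disease_duration = 5),
               data.frame(patient_id = "x", symptom = "ocular_motor",
                          t = -1, present = TRUE)),
    "negative")
  expect_error(
    psp_cohort(data.frame(patient_id = "x", sex = "male",
                          age_at_onset = 60, disease_duration = 5),
               data.frame(patient_id = "x", symptom = "not_a_symptom",
                          t = 1, present = TRUE)),
    "unknown symptom")
  expect_error(
    psp_cohort(data.frame(patient_id = "x", sex = "male",
                          age_at_onset = 60, disease_duration = 5),
               data.frame(patient_id = "x", symptom = "ocular_motor",
                          t = 7, present = TRUE)),
    "exceeds disease duration")
})

test_that("duplicate observations collapse by OR of present, with a warning", {
  expect_warning(
    co <- psp_cohort(
      data.frame(patient_id = "x", sex = "male", age_at_onset = 60,
                 disease_duration = 5),
      data.frame(patient_id = c("x", "x"),
                 symptom = rep("ocular_motor", 2),
                 t = c(1, 1), present = c(FALSE, TRUE))),
    "collapsing")
  expect_equal(nrow(co$observations), 1)
  expect_true(co$observations$present)
})

test_that("write/read round-trips are the identity in both dialects", {
  co <- generate_cohort(10, seed = 5)
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(back$patients, co$patients)
    expect_equal(back$observations, co$observations, tolerance = 1e-10)
    unlink(path)
  }
})

test_that("csv and json dialects carry identical parsed content", {
  co <- generate_cohort(8, seed = 9)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".json")
  write_cohort(co, p1); write_cohort(co, p2)
  a <- read_cohort(p1); b <- read_cohort(p2)
  expect_equal(a$patients, b$patients, tolerance = 1e-10)
  expect_equal(a$observations, b$observations, tolerance = 1e-10)
  unlink(c(p1, p2))
})

test_that("an empty cohort writes a header-only csv and reads back empty", {
  co <- psp_cohort(data.frame(patient_id = character(), sex = character(),
                              age_at_onset = numeric(),
                              disease_duration = numeric()))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(n_patients(read_cohort(path)), 0L)
  unlink(path)
})

test_that("patients without observations survive the csv round-trip", {
  co <- psp_cohort(
    data.frame(patient_id = c("a", "b"), sex = c("male", "female"),
               age_at_onset = c(60, 62), disease_duration = c(5, 6)),
    data.frame(patient_id = "a", symptom = "ataxia", t = 2, present = TRUE))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$patients$patient_id, c("a", "b"))
  expect_equal(nrow(back$observations), 1)
  unlink(path)
})

test_that("malformed files are rejected with a located error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,sex,age_at_onset,disease_duration,symptom,t_years,present",
               "a,male,60,5,ocular_motor,-1,true"), path)
  expect_error(read_cohort(path), "row")
  writeLines(c("patient_id,sex,age_at_onset,disease_duration,symptom,t_years,present",
               "a,male,60,5,ocular_motor,1,maybe"), path)
  expect_error(read_cohort(path), "true/false")
  writeLines("patient_id,sex", path)
  expect_error(read_cohort(path), "missing column")
  unlink(path)
})
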