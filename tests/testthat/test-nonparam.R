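test_that("kruskal_wallis wraps the tie-corrected H test and handles degeneracy", {
  g <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(10, 12, 14, 16))
  ours <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), factor(rep(1:3, each = 4)))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  expect_message(deg <- kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "length")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(4)
  g <- list(rnorm(12), rnorm(12, 1), rnorm(12, 2))
  tr <- lapply(g, function(x) exp(x))  # strictly increasing map
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(tr)$statistic)
  s1 <- steel_dwass(g, method = "asymptotic")
  s2 <- steel_dwass(tr, method = "asymptotic")
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-12)
  expect_equal(s1$p_adjusted, s2$p_adjusted, tolerance = 1e-12)
})

test_that("Steel-Dwass flags separated groups and spares identical ones", {
  set.seed(10)
  g <- list(a = rnorm(30), b = rnorm(30, 3), c = rnorm(30, 6))
  sd_ <- steel_dwass(g, method = "asymptotic")
  expect_true(all(sd_$p_adjusted < 0.05))  # 3-sd shifts, n = 30: all pairs
  # two identical groups inside a 3-group design: that pair is null
  g2 <- list(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6),
             c = c(30, 40, 50, 60, 70, 80))
  sd2 <- steel_dwass(g2, method = "asymptotic")
  ab <- sd2[sd2$group_a == "a" & sd2$group_b == "b", ]
  expect_gt(ab$p_adjusted, 0.9)
  expect_true(all(sd_$p_adjusted >= sd_$p_raw - 1e-12))
})

test_that("Steel-Dwass permutation path matches the max-T oracle; asymptotics converge", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  perm <- steel_dwass_perm_oracle(g, n_perm = 4000, seed = 2)
  # on tiny groups the implementation's default is the seeded permutation path
  fb <- suppressMessages(steel_dwass(g, n_perm = 4000, seed = 2))
  expect_true(all(fb$method == "steel_dwass_permutation"))
  expect_true(all(abs(fb$p_adjusted - perm) < 0.04))
  # at moderate group sizes the studentized-range reference tracks the oracle
  set.seed(8)
  g2 <- list(a = rnorm(15), b = rnorm(15, 0.9), c = rnorm(15, 0.4))
  asym <- steel_dwass(g2, method = "asymptotic")
  perm2 <- steel_dwass_perm_oracle(g2, n_perm = 4000, seed = 3)
  expect_true(all(abs(asym$p_adjusted - perm2) < 0.05))
})

test_that("small groups trigger the logged permutation fallback", {
  g <- list(a = c(1, 2), b = c(5, 6), c = c(9, 10))
  expect_message(res <- steel_dwass(g, n_perm = 500, seed = 1), "permutation")
  expect_true(all(res$method == "steel_dwass_permutation"))
})

test_that("Holm adjustment matches the hand-computed step-down and is monotone", {
  # three pairs engineered to give raw p of about 0.01, 0.02, 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "holm"),
               c(0.03, 0.04, 0.04))
  counts <- rbind(g1 = c(35, 65), g2 = c(50, 50), g3 = c(52, 48),
                  g4 = c(65, 35))
  res <- pairwise_chisq_holm(counts)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, method = "holm"))
})

test_that("identical proportions yield no significant pairwise chi-square", {
  counts <- rbind(a = c(20, 80), b = c(21, 79), c = c(19, 81))
  res <- pairwise_chisq_holm(counts)
  expect_true(all(res$p_adjusted > 0.5))
})

test_that("zero-margin sub-tables are excluded with a notice", {
  counts <- rbind(a = c(0, 10), b = c(0, 15), c = c(5, 10))
  expect_message(res <- pairwise_chisq_holm(counts), "zero-margin")
  expect_equal(nrow(res), 2)  # the a-vs-b pair is dropped
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(2024)
  hits <- mean(replicate(600, {
    g <- split(rnorm(30), rep(1:3, each = 10))
    kruskal_wallis(g)$p_value < 0.05
  }))
  expect_lt(abs(hits - 0.05), 0.025)
})
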