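test_that("BH step-up adjustment matches hand calculation and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(40)
  expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "gdr_value_error")
})

test_that("normality screen passes Gaussian phase values and fails two-point masses", {
  set.seed(2)
  tab_norm <- synth_table(30, 8, "A",
                          phase_fun = function(i) 10 + rnorm(8),
                          pre_fun = function(i, ph) mean(ph))
  ns <- normality_screen(tab_norm)
  expect_true(ns$normality_pass)
  expect_identical(ns$n_evaluable, 30L)

  tab_bad <- synth_table(30, 8, "B",
                         phase_fun = function(i) sw_failing_values(8),
                         pre_fun = function(i, ph) mean(ph))
  nb <- normality_screen(tab_bad)
  expect_false(nb$normality_pass)
  expect_lte(nb$n_pass, 30 * 0.05)
})

test_that("the >70% rule is strict at the boundary", {
  mk <- function(n_pass) {
    rows <- lapply(seq_len(10), function(i) {
      v <- if (i <= n_pass) sw_passing_values(8) else sw_failing_values(8)
      data.frame(patient_id = sprintf("P%02d", i),
                 scan_role = sprintf("pre4d_phase_%d", 1:8),
                 segmentation = "manual", feature_name = "F",
                 value = v, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  expect_false(normality_screen(mk(7))$normality_pass)   # exactly 70%: fail
  expect_true(normality_screen(mk(8))$normality_pass)
})

test_that("constant-across-phases values count as flagged passes", {
  tab <- synth_table(10, 8, "C",
                     phase_fun = function(i) rep(5, 8),
                     pre_fun = function(i, ph) 5)
  ns <- normality_screen(tab)
  expect_true(ns$normality_pass)
  expect_identical(ns$n_constant, 10L)
})

test_that("comparability: identity passes, planted 20% shift is rejected", {
  set.seed(3)
  tab_id <- synth_table(30, 8, "A",
                        phase_fun = function(i) 10 + rnorm(8, 0, 0.5),
                        pre_fun = function(i, ph) mean(ph))
  cs <- comparability_screen(tab_id)
  expect_equal(cs$wsr_p, 1)
  expect_true(cs$comparable_pass)

  tab_shift <- synth_table(30, 8, "B",
                           phase_fun = function(i) {
                             mu <- runif(1, 5, 15); mu + rnorm(8, 0, 0.05 * mu)
                           },
                           pre_fun = function(i, ph) 1.20 * mean(ph))
  cb <- comparability_screen(tab_shift)
  expect_lt(cb$wsr_p_adj, 0.05)
  expect_gt(cb$ba_lo, 0)   # BA CI excludes 0: rejection confirmed
  expect_false(cb$comparable_pass)
})

test_that("Bland-Altman percentage difference uses the pair-mean denominator", {
  tab <- synth_table(8, 3, "F",
                     phase_fun = function(i) rep(110, 3),
                     pre_fun = function(i, ph) 100)
  cs <- comparability_screen(tab)
  expect_equal(cs$ba_mean_pct, 100 * (100 - 110) / 105, tolerance = 1e-12)
})

test_that("screen verdicts are invariant to row order and refuse tiny cohorts", {
  set.seed(4)
  tab <- rbind(
    synth_table(12, 8, "A", function(i) rnorm(8, 10), function(i, ph) mean(ph)),
    synth_table(12, 8, "B", function(i) sw_failing_values(8), function(i, ph) 2 * mean(ph)))
  sc1 <- screen_features(tab)
  sc2 <- screen_features(tab[sample(nrow(tab)), ])
  expect_identical(sc1$normality, sc2$normality)
  expect_identical(sc1$comparability, sc2$comparability)
  expect_identical(sc1$eligible, sc2$eligible)

  tiny <- synth_table(4, 8, "A", function(i) rnorm(8, 10), function(i, ph) mean(ph))
  expect_error(comparability_screen(tiny), class = "gdr_value_error")
})

test_that("select_eligible intersects deterministically", {
  norm <- data.frame(feature_name = c("A", "B"), normality_pass = c(TRUE, TRUE))
  comp <- data.frame(feature_name = c("B", "C"), comparable_pass = c(TRUE, TRUE))
  expect_identical(select_eligible(norm, comp), "B")
  comp2 <- data.frame(feature_name = "C", comparable_pass = TRUE)
  expect_warning(out <- select_eligible(norm, comp2))
  expect_identical(out, character(0))
})

test_that("planted screen separation: phase-Gaussian feature in, shifted feature out", {
  set.seed(5)
  tab <- rbind(
    synth_table(25, 8, "good",
                function(i) rnorm(8, 20, 1), function(i, ph) mean(ph) + rnorm(1, 0, 0.3)),
    synth_table(25, 8, "shifted",
                function(i) rnorm(8, 20, 1), function(i, ph) 1.3 * mean(ph)))
  sc <- screen_features(tab)
  expect_identical(sc$eligible, "good")
})
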