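test_that("contingency cells come from report-level presence", {
  cases <- toy_cases(
    is_target = c(TRUE, TRUE, FALSE, FALSE),
    pts = list("Sopor", "Nausea", "Sopor", "Nausea"))
  t1 <- build_contingency(cases, "Sopor", "PT")
  expect_equal(unlist(t1[c("a", "b", "c", "d")], use.names = FALSE), c(1, 1, 1, 1))
  # same PT twice in one report still contributes one pair
  cases2 <- toy_cases(TRUE, list(c("Sopor", "Sopor")))
  expect_equal(build_contingency(cases2, "Sopor", "PT")$a, 1)
  # event absent from the universe
  t0 <- build_contingency(cases, "Missing PT", "PT")
  expect_equal(t0$a + t0$c, 0)
  expect_error(build_contingency(cases[0, ], "Sopor", "PT"), "empty")
})

test_that("SOC-level tables count a report once if any PT maps to the SOC", {
  cases <- toy_cases(
    is_target = c(TRUE, TRUE, FALSE),
    pts = list(c("Sopor", "Somnolence"), "Nausea", c("Sopor", "Tachycardia")))
  t <- build_contingency(cases, "Psychiatric disorders", "SOC", map = test_map())
  expect_equal(unlist(t[c("a", "b", "c", "d")], use.names = FALSE), c(1, 1, 1, 0))
})

test_that("the four statistics reproduce hand-evaluated values", {
  s <- disprop(5, 95, 100, 9800)
  expect_equal(s$ror, 5.157894736842105, tolerance = 1e-12)
  expect_equal(s$ror_lo95, 2.054217669001474, tolerance = 1e-9)
  expect_equal(s$ror_hi95, 12.950856434447504, tolerance = 1e-9)

  s2 <- disprop(30, 70, 300, 9700)
  expect_equal(s2$prr, 10, tolerance = 1e-12)
  expect_equal(s2$chi2, 228.3707081045873, tolerance = 1e-9)
  expect_equal(s2$ic, log2(9.181818181818182), tolerance = 1e-12)
  expect_equal(s2$e_ic, 2.846947174708121, tolerance = 1e-9)
  expect_equal(s2$ic025, 2.235527057772979, tolerance = 1e-9)
  expect_equal(s2$ebgm, 9.181818181818182, tolerance = 1e-12)
  expect_true(s2$ic025 < s2$ic)

  id <- disprop(10, 10, 10, 10)
  expect_equal(id$ror, 1)
  expect_equal(id$prr, 1)
  expect_equal(id$chi2, 0)
  expect_equal(id$ic, 0)
  expect_equal(id$ebgm, 1)
  expect_true(id$ror_lo95 < 1 && id$ror_hi95 > 1)
  expect_false(id$positive)
})

test_that("statistics match the straight-line oracle on random tables", {
  set.seed(202406)
  n_tab <- 1000
  a <- sample(1:500, n_tab, TRUE); b <- sample(1:2000, n_tab, TRUE)
  cc <- sample(1:2000, n_tab, TRUE); d <- sample(1:50000, n_tab, TRUE)
  got <- disprop(a, b, cc, d)
  exp <- oracle_stats(a, b, cc, d)
  for (col in names(exp)) {
    expect_equal(got[[col]], exp[[col]], tolerance = 1e-12,
                 label = paste("column", col))
  }
  # algebraic identities
  expect_equal(got$ebgm, 2^got$ic, tolerance = 1e-12)
  gt1 <- exp$prr > 1
  expect_true(all(got$ror[gt1] > got$prr[gt1]))
})

test_that("each statistic is nondecreasing in a for fixed b, c, d", {
  a <- 1:60
  s <- disprop(a, 200, 150, 9000)
  for (col in c("ror", "prr", "ic", "ebgm")) {
    expect_true(all(diff(s[[col]]) > 0), label = col)
  }
})

test_that("criteria boundaries follow the inclusive/exclusive semantics", {
  # a = 3 passes the a >= 3 gate; a = 2 does not
  s3 <- disprop(3, 10, 30, 3000)
  expect_true(s3$a >= 3 && s3$ror_pos)
  s2 <- disprop(2, 10, 20, 3000)
  expect_false(s2$ror_pos)
  expect_false(s2$prr_pos)
  expect_false(s2$bcpnn_pos)

  # prr exactly 2 and chi2 exactly 4 both pass (>= inclusive)
  r <- disprop(100, 100, 100, 9700)
  r$prr <- 2; r$chi2 <- 4; r$a <- 100
  r <- apply_signal_criteria(r)
  expect_true(r$prr_pos)
  # just below either threshold fails
  r2 <- r; r2$prr <- 2 - 1e-9
  expect_false(apply_signal_criteria(r2)$prr_pos)
  r3 <- r; r3$chi2 <- 4 - 1e-9
  expect_false(apply_signal_criteria(r3)$prr_pos)

  # ic025 and ebgm05 are strict lower-bound comparisons
  r4 <- r; r4$ic025 <- 1e-12; expect_true(apply_signal_criteria(r4)$bcpnn_pos)
  r5 <- r; r5$ic025 <- 0;     expect_false(apply_signal_criteria(r5)$bcpnn_pos)
  r6 <- r; r6$ebgm05 <- 2 + 1e-12; expect_true(apply_signal_criteria(r6)$mgps_pos)
  r7 <- r; r7$ebgm05 <- 2;         expect_false(apply_signal_criteria(r7)$mgps_pos)
})

test_that("zero cells get the Haldane correction; a = 0 yields NA and no flags", {
  z <- disprop(3, 0, 1, 9996)
  expect_true(z$corrected)
  exp <- oracle_stats(3.5, 0.5, 1.5, 9996.5)
  expect_equal(z$ror, exp$ror, tolerance = 1e-12)
  expect_equal(z$prr, exp$prr, tolerance = 1e-12)
  expect_true(is.finite(z$ic025))

  a0 <- disprop(0, 100, 50, 5000)
  expect_true(is.na(a0$ror) && is.na(a0$ebgm))
  expect_false(a0$ror_pos || a0$prr_pos || a0$bcpnn_pos || a0$mgps_pos)
  expect_false(a0$positive)
})

test_that("positivity is the conjunction of all four algorithm flags", {
  # published-scale SOC example: a = 13177 over 14126 target reports in a
  # 52214-report universe with lower bounds 5.29 / 2.07 / 4.2 all passing
  r <- data.frame(a = 13177, ror_lo95 = 5.29, prr = 4.29, chi2 = 1e4,
                  ic025 = 2.07, ebgm05 = 4.2)
  expect_true(apply_signal_criteria(r)$positive)
  # one failing bound vetoes the verdict
  r$ic025 <- -0.2
  expect_false(apply_signal_criteria(r)$positive)
})

test_that("detect_signals ranks by frequency or ROR with name tie-breaks", {
  cases <- toy_cases(
    is_target = c(rep(TRUE, 6), rep(FALSE, 14)),
    pts = c(list(c("Sopor", "Nausea"), "Sopor", "Sopor", c("Beta", "Alpha"),
                 c("Alpha", "Beta"), "Nausea"),
            rep(list("Nausea"), 13), list("Sopor")))
  by_a <- detect_signals(cases, "PT", rank_by = "a")
  expect_equal(by_a$event[1], "Sopor")
  # Alpha and Beta tie at a = 2: name ascending
  ab <- by_a$event[by_a$a == 2]
  expect_equal(ab, sort(ab))
  by_ror <- detect_signals(cases, "PT", rank_by = "ror")
  expect_equal(by_ror$event[1:2], c("Alpha", "Beta"))  # b/c zero-corrected ties
  # no target reports -> empty result
  none <- detect_signals(cases, "PT", target = rep(FALSE, nrow(cases)))
  expect_equal(nrow(none), 0)
})

test_that("a planted pair dominates both ranking modes on synthetic data", {
  syn <- synth_faers(synth_config(
    n_cases = 4000, seed = 99,
    planted = data.frame(drug = "LORAZEPAM", pt = "Sopor", rr = 40)))
  cases <- build_case_reports(syn, lorazepam_synonyms())
  by_a <- detect_signals(cases, "PT")
  by_ror <- detect_signals(cases, "PT", rank_by = "ror")
  expect_equal(by_a$event[1], "Sopor")
  expect_equal(by_ror$event[1], "Sopor")
  expect_true(by_a$positive[by_a$event == "Sopor"])
})
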