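test_that("KM estimate matches hand-computed product limits", {
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$lower <= km$surv + 1e-12 & km$surv <= km$upper + 1e-12))

  allCens <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))

  expect_error(kmEstimate(numeric(), numeric()), "empty")
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("with no censoring KM equals 1 - ECDF at every event time", {
  set.seed(4)
  for (i in 1:10) {
    times <- rexp(50, 0.1)
    km <- kmEstimate(times, rep(1, 50))
    expect_equal(km$surv, ecdfSurvivor(times), tolerance = 1e-12)
  }
})

test_that("restricted mean survival time is the step-function area", {
  expect_equal(meanSurvival(kmEstimate(10, 1), horizon = 10), 10)
  expect_equal(meanSurvival(kmEstimate(c(2, 4), c(0, 0)), horizon = 50), 50)
  expect_equal(meanSurvival(kmEstimate(c(1, 2, 3), c(1, 0, 1)), horizon = 3),
               1 + (2 / 3) * 2, tolerance = 1e-12)
  expect_error(meanSurvival(kmEstimate(1, 1), horizon = -1), "> 0")
})

test_that("log-rank statistic matches the hand-tabulated hypergeometric form", {
  # A: event at 1; B: event at 2. At t=1: O_A=1, E_A=1/2, V=1/4; at t=2 V=0.
  lr <- logrankTest(1, 1, 2, 1)
  expect_equal(lr$statistic, 1, tolerance = 1e-12)
  expect_equal(lr$p.value, pchisq(1, 1, lower.tail = FALSE))
  expect_equal(sum(lr$expected), sum(lr$observed))

  set.seed(8)
  t1 <- rexp(30); e1 <- rbinom(30, 1, 0.8)
  e1[1] <- 1
  same <- logrankTest(t1, e1, t1, e1)   # identical groups
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p.value, 1, tolerance = 1e-10)
  # label swap invariance
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8)
  ab <- logrankTest(t1, e1, t2, e2)
  ba <- logrankTest(t2, e2, t1, e1)
  expect_equal(ab$statistic, ba$statistic)

  expect_error(logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               "at least one event")
  expect_error(logrankTest(numeric(), numeric(), 1, 1), "non-empty")
})

test_that("a subject censored before every event leaves the test intact", {
  set.seed(12)
  tA <- rexp(40); eA <- rbinom(40, 1, 0.7); eA[1] <- 1
  tB <- rexp(40); eB <- rbinom(40, 1, 0.7); eB[1] <- 1
  base <- logrankTest(tA, eA, tB, eB)
  # censored before the first event: out of the risk set at every event
  # time, so O, E and the statistic are untouched and stay finite
  aug <- logrankTest(c(min(c(tA, tB)) / 2, tA), c(0, eA), tB, eB)
  expect_true(is.finite(aug$statistic))
  expect_equal(aug$expected, base$expected)
  expect_equal(aug$statistic, base$statistic)
  swapped <- logrankTest(tB, eB, c(min(c(tA, tB)) / 2, tA), c(0, eA))
  expect_equal(aug$statistic, swapped$statistic)
})

test_that("dichotomization strategies split as defined", {
  cohort <- data.frame(id = paste0("p", 1:4), time_months = c(5, 6, 7, 8),
                       event = c(1, 1, 1, 1), G = c(1, 2, 3, 4))
  d <- dichotomize(cohort, "G", strategy = "median")
  expect_equal(d$n_high, 2)
  expect_equal(d$n_low, 2)
  expect_equal(unname(d$labels), c("low", "low", "high", "high"))

  constant <- transform(cohort, G = 1)
  expect_error(dichotomize(constant, "G", strategy = "median"), "constant")

  sim <- simulateCohort(nPatients = 120, beta = c(G = 0.8), seed = 5)
  d2 <- dichotomize(sim$cohort, "G", strategy = "optimal_logrank")
  # brute-force minimization over the same candidate grid
  x <- sim$cohort$G
  cand <- unique(quantile(x, probs = seq(0.10, 0.90, by = 0.05), names = FALSE))
  ps <- vapply(cand, function(cc) {
    hi <- x > cc
    survival::survdiff(survival::Surv(sim$cohort$time_months,
                                      sim$cohort$event) ~ hi)$chisq
  }, numeric(1))
  # max chisq == min p for 1 df
  expect_equal(d2$cut, cand[which.max(ps)])
  expect_true(d2$selection_inflated)
  expect_equal(nrow(d2$scan), length(cand))
})

test_that("the survival screen mirrors the per-gene building blocks", {
  sim <- simulateCohort(nPatients = 250,
                        beta = c(BAD = 0.8, NULL1 = 0, PROT = -0.8),
                        seed = 9)
  scr <- survivalScreen(sim$cohort, c("BAD", "NULL1", "PROT"),
                        strategy = "median", alpha = 0.05)
  expect_identical(scr$gene, c("BAD", "NULL1", "PROT"))
  expect_identical(scr$flag[scr$gene == "BAD"], "adverse-high")
  expect_identical(scr$flag[scr$gene == "PROT"], "adverse-low")
  expect_true(all(scr$q_value >= scr$p_value - 1e-15))
  horizon <- max(sim$cohort$time_months)
  # row content equals direct recomputation for one gene
  d <- dichotomize(sim$cohort, "BAD", strategy = "median")
  hi <- d$labels == "high"
  expect_equal(scr$p_value[1],
               logrankTest(sim$cohort$time_months[hi], sim$cohort$event[hi],
                           sim$cohort$time_months[!hi],
                           sim$cohort$event[!hi])$p.value)
  expect_equal(scr$high_mean[1],
               meanSurvival(kmEstimate(sim$cohort$time_months[hi],
                                       sim$cohort$event[hi]), horizon))

  empty <- survivalScreen(sim$cohort, character())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("gene", "p_value", "high_mean", "low_mean", "flag") %in%
                  colnames(empty)))

  # a failing gene is skipped with a warning, not fatal
  sim$cohort$CONST <- 1
  expect_warning(scr2 <- survivalScreen(sim$cohort, c("BAD", "CONST"),
                                        strategy = "median"),
                 "CONST.*skipped")
  expect_identical(scr2$gene, "BAD")
})

test_that("cohort CSV reading validates the clinical columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulateCohort(nPatients = 20, beta = c(G = 0), seed = 2)
  write.csv(sim$cohort, path, row.names = FALSE)
  back <- readSurvivalCohort(path)
  expect_equal(back$time_months, sim$cohort$time_months)

  bad <- transform(sim$cohort, event = 2)
  write.csv(bad, path, row.names = FALSE)
  expect_error(readSurvivalCohort(path), "event")
})
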