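make_cohort <- function(fracs_by_week, n_cells = 1000, tissue = "skin") {
  rows <- do.call(rbind, lapply(seq_along(fracs_by_week), function(w) {
    f <- fracs_by_week[[w]]
    data.frame(mouse_id = paste0("w", w, "_m", seq_along(f)),
               tissue = tissue, pulse_week = w, pulse_day = 7 * (w - 1) + 1,
               analysis_day = 56, n_cells = n_cells,
               n_tagged = round(f * n_cells))
  }))
  rows
}

test_that("group summaries use the median with the midpoint convention", {
  co <- make_cohort(list(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3, 0.4), 0.57))
  g <- summarize_groups(co, "skin")
  expect_equal(g$summary, c(0.4, 0.25, 0.57))
  expect_equal(g$n_mice, c(3, 4, 1))
  gm <- summarize_groups(co, "skin", statistic = "mean")
  expect_equal(gm$summary[1], 0.4)
  expect_equal(gm$summary[2], 0.25)
})

test_that("empty pulse groups are reported by week", {
  co <- make_cohort(list(c(0.2, 0.3), c(0.4, 0.5)))
  expect_error(summarize_groups(co, "skin", pulse_weeks = 1:3), "week 3")
  expect_error(summarize_groups(co, "VAT"), "no records")
})

test_that("efficiency correction divides and clamps", {
  expect_equal(correct_efficiency(0.57, 0.95), 0.6)
  expect_equal(correct_efficiency(0.99, 0.95), 1)
  expect_equal(correct_efficiency(0, 0.9), 0)
  expect_equal(correct_efficiency(c(0.45, 0.9), 0.9), c(0.5, 1))
  expect_error(correct_efficiency(0.5, 0), "efficiency")
  expect_error(correct_efficiency(0.5, -1), "efficiency")
})

test_that("isotonic regression reproduces hand-solved projections", {
  expect_equal(isotonic_nondecreasing(c(0.1, 0.2, 0.3)), c(0.1, 0.2, 0.3))
  expect_equal(isotonic_nondecreasing(c(0.3, 0.2)), c(0.25, 0.25))
  expect_equal(isotonic_nondecreasing(c(0.5, 0.4, 0.6)),
               c(0.45, 0.45, 0.6))
  # weighted pooling: weighted mean of the violating pair
  expect_equal(isotonic_nondecreasing(c(0.3, 0.2), weights = c(3, 1)),
               rep(0.275, 2))
})

test_that("isotonic regression matches brute force and isoreg", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    v <- round(runif(n), 3)
    w <- sample(1:4, n, replace = TRUE)
    expect_equal(isotonic_nondecreasing(v, w), isotonic_bruteforce(v, w),
                 tolerance = 1e-10)
  }
  for (i in 1:10) {
    v <- rnorm(12)
    expect_equal(isotonic_nondecreasing(v), stats::isoreg(v)$yf,
                 tolerance = 1e-10)
  }
})

test_that("decomposition differences the cumulative curve", {
  # printed skin-style cumulative values
  d <- decompose(c(0.60, 0.85))
  expect_equal(unname(d$increments), c(0.60, 0.25))
  expect_equal(d$tail, 0.15)
  d2 <- decompose(rep(1, 4))
  expect_equal(unname(d2$increments), c(1, 0, 0, 0))
  expect_equal(d2$tail, 0)
  # lymphoid-style week-2 values
  d3 <- decompose(c(0.25, 0.35))
  expect_equal(unname(d3$increments[2]), 0.10)
  expect_error(decompose(c(0.5, 0.4)), "nondecreasing")
  expect_error(decompose(c(0.5, 1.2)), "0, 1")
})

test_that("waffle allocation is largest-remainder with early-week ties", {
  expect_equal(unname(waffle_allocate(1)), 100L)
  expect_equal(unname(waffle_allocate(c(0.5, 0.5))), c(50L, 50L))
  # remainders 0.5, 0, 0.5: the tie goes to the earlier week
  expect_equal(unname(waffle_allocate(c(0.605, 0.25, 0.145))),
               c(61L, 25L, 14L))
  expect_error(waffle_allocate(c(-0.1, 1.1)), "nonnegative")
  expect_error(waffle_allocate(c(0.4, 0.4)), "sum")
  set.seed(31)
  for (i in 1:25) {
    f <- stats::rgamma(sample(2:8, 1), 1)
    f <- f / sum(f)
    a <- waffle_allocate(f)
    expect_equal(sum(a), 100L)
    expect_true(all(abs(a - 100 * f) < 1))
  }
})

test_that("the full reconstruction recovers a noiseless composition", {
  # E = 0.95 times cumulative; counts exact at n = 2000
  co <- make_cohort(list(0.57, 0.8075, 0.874), n_cells = 2000)
  est <- reconstruct_composition(co, "skin", efficiency = 0.95, B = 0)
  expect_s3_class(est, "treg_composition")
  expect_equal(unname(est$increments), c(0.60, 0.25, 0.07),
               tolerance = 1e-9)
  expect_equal(est$tail, 0.08, tolerance = 1e-9)
  expect_equal(sum(est$increments) + est$tail, 1, tolerance = 1e-9)
  expect_equal(sum(est$waffle), 100L)
  df <- as.data.frame(est)
  expect_equal(df$week, c("1", "2", "3", ">3"))
  expect_equal(sum(df$increment), 1, tolerance = 1e-9)
})

test_that("bootstrap intervals are seeded and degenerate on identical mice", {
  co <- make_cohort(list(rep(0.3, 6), rep(0.5, 6), rep(0.7, 6)))
  est <- reconstruct_composition(co, "skin", efficiency = 1, B = 200,
                                 seed = 9)
  expect_equal(unname(est$ci[, "lo"]), unname(est$ci[, "hi"]))
  set.seed(1234)
  noisy <- make_cohort(lapply(c(0.3, 0.5, 0.7),
                              function(m) pmin(1, m + rnorm(6, 0, 0.05))))
  e1 <- reconstruct_composition(noisy, "skin", efficiency = 1, B = 300,
                                seed = 4)
  e2 <- reconstruct_composition(noisy, "skin", efficiency = 1, B = 300,
                                seed = 4)
  expect_identical(e1$ci, e2$ci)
  expect_true(all(e1$ci[, "hi"] >= e1$ci[, "lo"]))
})

test_that("estimates converge to the simulator truth as sampling grows", {
  sch_small <- renewal_schedule(horizon = 60, loss = 0.02,
                                sampled_cells = 200, kappa = 30)
  truth <- true_composition(sch_small, 56)
  err_at <- function(mice, cells) {
    sch <- renewal_schedule(horizon = 60, loss = 0.02,
                            sampled_cells = cells, kappa = 30)
    sc <- as_scenario(sch, mice_per_group = mice)
    errs <- vapply(1:3, function(rep_i) {
      cohort <- simulate_cohort(sc, seed = 100 + rep_i,
                                pulse_days = aligned_pulse_days(1:6))
      est <- reconstruct_composition(cohort, "sim", efficiency = 1, B = 0)
      mean(abs(est$increments - truth$fractions))
    }, numeric(1))
    mean(errs)
  }
  e1 <- err_at(2, 200)
  e2 <- err_at(8, 2000)
  e3 <- err_at(32, 20000)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
})

test_that("correcting a reduced-efficiency cohort reproduces full-efficiency estimates", {
  sch <- renewal_schedule(horizon = 60, loss = 0.02)
  sc1 <- as_scenario(sch, efficiency = 1)
  sc9 <- as_scenario(sch, efficiency = 0.9)
  co1 <- simulate_cohort(sc1, seed = 55,
                         pulse_days = aligned_pulse_days(1:6))
  co9 <- simulate_cohort(sc9, seed = 56,
                         pulse_days = aligned_pulse_days(1:6))
  e1 <- reconstruct_composition(co1, "sim", efficiency = 1, B = 300,
                                seed = 2)
  e9 <- reconstruct_composition(co9, "sim", efficiency = 0.9, B = 300,
                                seed = 2)
  expect_true(all(e9$increments >= e1$ci[seq_along(e9$increments), "lo"] -
                    0.02 &
                  e9$increments <= e1$ci[seq_along(e9$increments), "hi"] +
                    0.02))
})

test_that("stratified reconstruction runs the same pipeline on subset counts", {
  base <- renewal_schedule("gut", horizon = 60)
  subA <- renewal_schedule("gut.A", horizon = 60, loss = 0.005)
  subB <- renewal_schedule("gut.B", horizon = 60, loss = 0.06)
  sc <- as_scenario(base, efficiency = 1,
                    subsets = list(A = list(weight = 0.5, schedule = subA),
                                   B = list(weight = 0.5, schedule = subB)))
  cohort <- simulate_cohort(sc, seed = 77,
                            pulse_days = aligned_pulse_days(1:6))
  eA <- stratified_reconstruct(cohort, "gut", "A", efficiency = 1, B = 0)
  eB <- stratified_reconstruct(cohort, "gut", "B", efficiency = 1, B = 0)
  # the slow-turnover subset is older: more of it generated by week 2
  expect_gt(sum(eA$increments[1:2]), sum(eB$increments[1:2]))
  qA <- true_composition(subA, 56)$fractions
  expect_lt(max(abs(eA$increments - qA)), 0.1)
  # absent subset: explicit skip
  expect_message(out <- stratified_reconstruct(cohort, "gut", "Z",
                                               efficiency = 1, B = 0),
                 "absent")
  expect_null(out)
})
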