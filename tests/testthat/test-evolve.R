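test_that("masses are conserved without division, loss or influx", {
  sch <- tissue_schedule("x", 40, influx = c(5, rep(0, 39)))
  st <- evolve_expectation(sch, NULL, 39)
  expect_equal(sum(st$N), 5)
  expect_true(all(st$N[-1] == 0))
})

test_that("balanced birth-death keeps cohort masses constant", {
  H <- 30
  sch <- tissue_schedule("x", H, influx = c(2, rep(0, H - 1)),
                         division_prob = 0.1, loss_resident = 0.1,
                         loss_flux = 0.1)
  st <- evolve_expectation(sch, NULL, H - 1)
  expect_equal(st$N[1], 2)
})

test_that("constant-pool replacement decays labels exponentially", {
  rho <- 0.01
  sch <- replacement_schedule(rho = rho, horizon = 220)
  pd <- pulse_design(49, c(sim = 1), kernel = delta_kernel())
  t_chase <- c(60, 100, 150, 210)
  f <- vapply(t_chase, function(t) tagged_fraction(sch, pd, t), numeric(1))
  # labels cover everything born through day 50; thereafter each day
  # replaces a fraction rho of a constant pool
  expect_equal(f, (1 - rho)^(t_chase - 50), tolerance = 1e-10)
  # within discretization error of the continuous-time limit exp(-rho t)
  expect_equal(f, exp(-rho * (t_chase - 50)), tolerance = rho)
})

test_that("labelled mass never exceeds cohort mass and fractions are proper", {
  sch <- renewal_schedule(horizon = 60, loss = 0.03, division = 0.05)
  pd <- pulse_design(15, c(sim = 0.9))
  st <- evolve_expectation(sch, pd, 55)
  expect_true(all(st$L >= 0))
  expect_true(all(st$L <= st$N + 1e-12))
  f <- tagged_fraction(sch, pd, 55)
  expect_gt(f, 0)
  expect_lt(f, 1)
})

test_that("full labelling makes the tagged fraction the cumulative composition", {
  # E = 1 and a pulse covering all cells present: the tagged fraction at any
  # later age equals the share of the pool descended from cells born before
  # the window closed (heritability).
  sch <- renewal_schedule(horizon = 80, loss = 0.02, division = 0.04)
  fd <- 19                                 # delta kernel: labels born <= 20
  pd <- pulse_design(fd, c(sim = 1), kernel = delta_kernel())
  for (t in c(30, 55, 79)) {
    st <- evolve_expectation(sch, NULL, t)
    truth <- sum(st$N[st$birth_day <= fd + 1]) / sum(st$N)
    expect_equal(tagged_fraction(sch, pd, t), truth, tolerance = 1e-12)
  }
})

test_that("expected tagged fraction is nondecreasing in pulse week", {
  sch <- renewal_schedule(horizon = 60, loss = 0.025, division = 0.03)
  f <- vapply(1:6, function(w) {
    pd <- pulse_design(7 * (w - 1) + 1, c(sim = 0.95))
    tagged_fraction(sch, pd, 56)
  }, numeric(1))
  expect_true(all(diff(f) >= -1e-12))
})

test_that("labels are time-invariant without turnover", {
  H <- 80
  sch <- tissue_schedule("x", H, influx = c(rep(1, 20), rep(0, H - 20)),
                         division_prob = 0.02)
  pd <- pulse_design(25, c(x = 0.95))
  f <- vapply(c(40, 60, 79), function(t) tagged_fraction(sch, pd, t),
              numeric(1))
  expect_equal(f[1], f[2], tolerance = 1e-12)
  expect_equal(f[1], f[3], tolerance = 1e-12)
})

test_that("negative growth factors are a parameter error", {
  sch <- tissue_schedule("x", 10, influx = c(1, rep(0, 9)),
                         division_prob = 0, loss_resident = 0.99,
                         loss_flux = 0.99)
  sch$division_prob <- rep(-0.5, 10)  # force 1 + pi - delta < 0
  expect_error(evolve_expectation(sch, NULL, 9), "growth factor")
})

test_that("true composition handles degenerate influx patterns", {
  H <- 60
  # all influx in week 1, no turnover
  s1 <- tissue_schedule("x", H, influx = c(rep(1, 7), rep(0, H - 7)))
  tc1 <- true_composition(s1, 56)
  expect_equal(unname(tc1$fractions[1]), 1)
  expect_equal(tc1$tail, 0)
  # equal influx weeks 1-8, no division or loss: 1/8 each
  s2 <- tissue_schedule("x", H, influx = rep(1, H))
  tc2 <- true_composition(s2, 55)
  expect_equal(unname(tc2$fractions), rep(1 / 8, 6), tolerance = 1e-12)
  expect_equal(tc2$tail, 2 / 8, tolerance = 1e-12)
  # composition is a proper distribution
  sch <- renewal_schedule(horizon = 60, loss = 0.02, division = 0.05)
  tc <- true_composition(sch, 56)
  expect_true(all(tc$fractions >= 0))
  expect_equal(sum(tc$fractions) + tc$tail, 1, tolerance = 1e-9)
})

test_that("recently-divided fraction matches the closed form", {
  H <- 40
  mk <- function(p) tissue_schedule("x", H, influx = c(1, rep(0, H - 1)),
                                    division_prob = p, loss_resident = 0,
                                    loss_flux = 0)
  expect_equal(divided_recent_fraction(mk(0), 20, 4), 0)
  expect_equal(divided_recent_fraction(mk(0.33), 20, 4), 1 - 0.67^4,
               tolerance = 1e-12)
  expect_equal(divided_recent_fraction(mk(0.05), 20, 4), 1 - 0.95^4,
               tolerance = 1e-12)
  # newborn cohorts only count divisions since birth
  sch <- tissue_schedule("x", H, influx = rep(1, H), division_prob = 0.2)
  dr <- divided_recent_fraction(sch, 2, 4)
  expect_lt(dr, 1 - 0.8^2 + 1e-12)
})
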