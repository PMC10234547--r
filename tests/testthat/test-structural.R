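test_that("no drug appears before the absorption lag", {
  p <- typical_params()
  d <- dose_schedule(0, 18000)
  expect_equal(predict_concentrations(p, d, c(0, 0.2, 0.5, 0.75)),
               rep(0, 4))
  # with a shifted dose time the lag shifts accordingly
  d2 <- dose_schedule(5, 18000)
  expect_equal(predict_concentrations(p, d2, c(0, 2, 5, 5.7)), rep(0, 4))
})

test_that("the system is linear in dose and superposes", {
  p <- typical_params()
  tt <- c(1, 3, 7, 24, 96, 168)
  c1 <- predict_concentrations(p, dose_schedule(0, 9000), tt)
  c2 <- predict_concentrations(p, dose_schedule(0, 18000), tt)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # two half doses at the same time equal one full dose
  c3 <- predict_concentrations(p, dose_schedule(c(0, 0), c(9000, 9000)), tt)
  expect_equal(c3, c2, tolerance = 1e-12)
})

test_that("AUC0-inf equals Dose/CL (adaptive-quadrature oracle)", {
  p <- typical_params()
  d <- dose_schedule(0, 18000)
  auc <- integrate(function(t) predict_concentrations(p, d, t), 0, Inf,
                   rel.tol = 1e-10, subdivisions = 2000)$value
  expect_equal(auc, 18000 / 7.02, tolerance = 1e-6)
  # and for random parameter draws
  for (pr in random_params(4, seed = 11)) {
    auc <- integrate(function(t) predict_concentrations(pr, d, t), 0, Inf,
                     rel.tol = 1e-10, subdivisions = 2000)$value
    expect_equal(auc, 18000 / pr[["CL"]], tolerance = 1e-6)
  }
})

test_that("vanishing input duration reproduces the textbook oral-bolus curve", {
  p <- structural_params(CL = 7.02, Q = 9.11, Vc = 138, Vp = 424.33,
                         Ka = 0.71, Tk0 = 1e-6, Tlag = 1e-9)
  # textbook first-order-absorption two-compartment closed form
  k10 <- 7.02 / 138; k12 <- 9.11 / 138; k21 <- 9.11 / 424.33; ka <- 0.71
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  D <- 18000
  textbook <- function(t) {
    ka * D / 138 * ((k21 - alpha) / ((ka - alpha) * (beta - alpha)) * exp(-alpha * t) +
                    (k21 - beta) / ((ka - beta) * (alpha - beta)) * exp(-beta * t) +
                    (k21 - ka) / ((alpha - ka) * (beta - ka)) * exp(-ka * t))
  }
  tt <- c(0.5, 1, 2, 4, 8, 24, 72, 168)
  got <- predict_concentrations(p, dose_schedule(0, D), tt)
  expect_equal(got, textbook(tt), tolerance = 1e-4)
})

test_that("closed form agrees with a stiff ODE integrator on random draws", {
  skip_if_not_installed("deSolve")
  d <- dose_schedule(0, 15000)
  tt <- c(0.5, 1, 2, 4, 6, 9, 12, 24, 48, 96, 168)
  for (p in random_params(5, seed = 3)) {
    rhs <- function(t, y, parms) {
      rate <- if (t > p[["Tlag"]] && t <= p[["Tlag"]] + p[["Tk0"]]) {
        15000 / p[["Tk0"]]
      } else 0
      k10 <- p[["CL"]] / p[["Vc"]]; k12 <- p[["Q"]] / p[["Vc"]]
      k21 <- p[["Q"]] / p[["Vp"]]; ka <- p[["Ka"]]
      list(c(rate - ka * y[1],
             ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
             k12 * y[2] - k21 * y[3]))
    }
    brk <- sort(unique(c(tt, p[["Tlag"]], p[["Tlag"]] + p[["Tk0"]])))
    out <- deSolve::ode(c(0, 0, 0), c(0, brk), rhs, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-12)
    ode_conc <- out[match(tt, out[, 1]), 3] / p[["Vc"]]
    got <- predict_concentrations(p, d, tt)
    expect_equal(got, unname(ode_conc), tolerance = 1e-6)
  }
})

test_that("mass balance holds at all times and states decay to elimination", {
  d <- dose_schedule(0, 10000)
  for (p in random_params(4, seed = 21)) {
    tt <- c(0.3, p[["Tlag"]] + p[["Tk0"]] / 2, 5, 24, 2000)
    ca <- compartment_amounts(p, d, tt)
    expect_equal(rowSums(ca[, c("depot", "central", "peripheral",
                                "eliminated", "not_yet_input")]),
                 rep(10000, length(tt)), tolerance = 1e-8)
    expect_true(all(ca[, 2:6] > -1e-8))
  }
  # asymptotics: everything eliminated
  p <- typical_params()
  ca <- compartment_amounts(p, d, 5000)
  expect_lt(ca$depot + ca$central + ca$peripheral, 1e-6)
  expect_equal(ca$eliminated, 10000, tolerance = 1e-8)
  # before input starts: nothing anywhere
  ca0 <- compartment_amounts(p, d, 0.5)
  expect_equal(unlist(ca0[, 2:5]), c(depot = 0, central = 0,
                                     peripheral = 0, eliminated = 0))
  expect_equal(ca0$not_yet_input, 10000)
})

test_that("expm and closed-form paths agree on the central amount", {
  d <- dose_schedule(0, 12000)
  tt <- c(1, 2.5, 6, 30, 150)
  for (p in random_params(3, seed = 8)) {
    ca <- compartment_amounts(p, d, tt)
    cf <- predict_concentrations(p, d, tt) * p[["Vc"]]
    expect_equal(ca$central, cf, tolerance = 1e-8)
  }
})

test_that("concentrations are continuous, non-negative, and reject bad input", {
  p <- typical_params()
  d <- dose_schedule(0, 18000)
  tt <- seq(0, 20, by = 0.01)
  cc <- predict_concentrations(p, d, tt)
  expect_true(all(cc >= 0))
  expect_lt(max(abs(diff(cc))), 0.5)  # no jumps on a 0.01 h grid
  expect_error(structural_params(-1, 9, 138, 424, 0.7, 3.7, 0.75),
               "positive")
  expect_error(predict_concentrations(p, d, c(-1, 2)), "non-negative")
  expect_error(dose_schedule(0, 0), "positive")
})
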