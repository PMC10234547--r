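# The linear Gaussian toy is the one model where FOCE-I is exact: a single
# observation y = eta + eps with omega^2 = 1, sigma_add = 1 has marginal
# y ~ N(0, 2), so the objective (2*pi constant omitted) is log 2 + y^2/2 and
# the conditional mode is y/2.
linear_toy <- function() {
  m <- population_model(theta = c(CL = 1, Q = 1, Vc = 1, Vp = 1, Ka = 1,
                                  Tk0 = 1, Tlag = 1),
                        omega = c(CL = 1, Q = 0, Vc = 0, Vp = 0, Ka = 0,
                                  Tk0 = 0, Tlag = 0),
                        sigma = c(add = 1, prop = 0), allometric = NULL)
  pl <- list(y = 1, times = 0, predict = function(eta) eta[1], id = "toy")
  list(m = m, pl = pl)
}

test_that("FOCE equals the exact marginal on the linear Gaussian toy", {
  toy <- linear_toy()
  eb <- ivmpoppk:::estimate_ebes_payload(toy$m, toy$pl)
  expect_equal(eb$eta[1], 0.5, tolerance = 1e-6)
  lin <- ivmpoppk:::payload_linearization(toy$m, toy$pl, eb$eta)
  expect_equal(lin$ofv, log(2) + 0.5, tolerance = 1e-6)
  # quadrature oracle agrees with the closed form to 1e-8
  q <- ivmpoppk:::payload_quadrature(toy$m, toy$pl, nodes = 64)
  expect_equal(q, log(2) + 0.5, tolerance = 1e-8)
})

test_that("a vanishing prior pins the conditional mode at zero", {
  m <- toy_model("CL", omega2 = 1e-12)
  s <- toy_subject()
  eb <- estimate_ebes(m, s)
  expect_equal(eb$eta, rep(0, 7), tolerance = 1e-3)
})

test_that("mirrored subjects get equal and opposite conditional modes", {
  m <- toy_model("CL", omega2 = 0.25, sigma = c(add = 0.5, prop = 0))
  p <- typical_params()
  d <- dose_schedule(0, 12000)
  tt <- c(4, 24, 72)
  f_up <- predict_concentrations(
    do.call(structural_params,
            as.list(published_theta * exp(c(0.3, 0, 0, 0, 0, 0, 0)))), d, tt)
  f_dn <- predict_concentrations(
    do.call(structural_params,
            as.list(published_theta * exp(c(-0.3, 0, 0, 0, 0, 0, 0)))), d, tt)
  s_up <- toy_subject("up", times = tt, dv = f_up)
  s_dn <- toy_subject("dn", times = tt, dv = f_dn)
  e_up <- estimate_ebes(m, s_up)$eta[1]
  e_dn <- estimate_ebes(m, s_dn)$eta[1]
  # additive-only error keeps the objective symmetric in the CL direction
  expect_equal(e_up, 0.3, tolerance = 0.05)
  expect_equal(e_dn, -0.3, tolerance = 0.05)
})

test_that("zero IIV reduces the objective to extended weighted least squares", {
  m <- toy_model("CL", omega2 = 0)  # all variances zero
  expect_length(ivmpoppk:::omega_support(m$omega), 0)
  s <- toy_subject()
  ds <- pk_dataset(list(s))
  ofv <- foce_objective(m, ds)
  pl <- ivmpoppk:::subject_payload(m, s)
  f <- ivmpoppk:::conc_from_base(pl, rep(0, 7))
  v <- residual_variance(m, f)
  expect_equal(ofv, sum(log(v) + (s$obs$dv - f)^2 / v), tolerance = 1e-10)
})

test_that("FOCE tracks the quadrature oracle on nonlinear 1- and 2-eta toys", {
  set.seed(14)
  for (rep in 1:4) {
    iiv <- if (rep %% 2 == 0) c("CL", "Vc") else "CL"
    m <- toy_model(iiv, omega2 = 0.3)
    eta_true <- rnorm(length(iiv), 0, sqrt(0.3))
    eta7 <- rep(0, 7); eta7[match(iiv, names(published_theta))] <- eta_true
    p <- individual_parameters(m, c(WT = 64, SEX = 0), eta7)
    tt <- c(2, 6, 24, 96)
    f <- predict_concentrations(p, dose_schedule(0, 12000), tt)
    dv <- pmax(f * (1 + rnorm(4, 0, 0.22)) + rnorm(4, 0, 0.46), 0.05)
    s <- toy_subject("q", times = tt, dv = dv)
    foce <- local({
      eb <- estimate_ebes(m, s)
      ivmpoppk:::subject_linearization(m, s, eb$eta)$ofv
    })
    agq <- marginal_likelihood_quadrature(m, s, nodes = 64)
    expect_lt(abs(foce - agq), 0.5)
    # node-doubling convergence
    agq32 <- marginal_likelihood_quadrature(m, s, nodes = 32)
    expect_lt(abs(agq - agq32), 1e-6)
  }
})

test_that("the objective is invariant to subject order and relabeling", {
  ds <- small_cohort(n = 8, seed = 31)
  m <- published_model()
  o1 <- foce_objective(m, ds)
  ds_rev <- ds
  ds_rev$subjects <- rev(ds$subjects)
  expect_equal(foce_objective(m, ds_rev), o1, tolerance = 1e-8)
  ds_rel <- ds
  for (i in seq_along(ds_rel$subjects)) {
    ds_rel$subjects[[i]]$id <- paste0("relabeled-", i)
  }
  expect_equal(foce_objective(m, ds_rel), o1, tolerance = 1e-8)
})

test_that("quadrature refuses more than two random-effect dimensions", {
  m <- published_model()
  expect_error(marginal_likelihood_quadrature(m, toy_subject()), "at most 2")
  expect_error(marginal_likelihood_quadrature(toy_model("CL"), toy_subject(),
                                              nodes = 8), "at least 16")
})

test_that("shrinkage formulas behave at their boundary cases", {
  ds <- small_cohort(n = 6, seed = 12)
  m <- published_model()
  fit <- fit_population(m, ds, estimate = list(theta = character(0),
                                               coef = integer(0),
                                               omega = FALSE, sigma = FALSE))
  # hand-built fit object: EBEs all zero -> 100% shrinkage
  fake <- fit
  fake$ebes[] <- 0
  expect_equal(unname(eta_shrinkage(fake)), rep(100, 7))
  # EBE spread equal to omega -> 0% shrinkage
  set.seed(2)
  fake$ebes <- MASS::mvrnorm(2000, rep(0, 7), m$omega)
  sh <- eta_shrinkage(fake)
  expect_true(all(abs(sh) < 10))
  # noiseless self-simulated data at eta = 0: IWRES all zero -> 100%
  truth0 <- published_model()
  diag(truth0$omega) <- 0
  truth0$sigma <- c(add = 1e-9, prop = 0)
  ds0 <- generate_dataset(cohort_spec(n_subjects = 3, n_missing_last = 0),
                          truth0, seed = 3)
  truth_eval <- truth0
  truth_eval$sigma <- c(add = 0.46, prop = 0.22)
  fit0 <- fit_population(truth_eval, ds0,
                         estimate = list(theta = character(0),
                                         coef = integer(0), omega = FALSE,
                                         sigma = FALSE))
  expect_equal(eps_shrinkage(fit0, ds0), 100, tolerance = 1e-4)
})
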