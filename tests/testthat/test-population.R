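test_that("allometric factor follows the fixed-exponent power law", {
  expect_equal(allometric_factor(64, 64, 0.75), 1)
  expect_equal(allometric_factor(128, 64, 1), 2)
  expect_equal(allometric_factor(128, 64, 0.75), 2^0.75)
  expect_equal(round(allometric_factor(128, 64, 0.75), 4), 1.6818)
  expect_error(allometric_factor(-5, 64, 1), "positive")
})

test_that("covariate multipliers evaluate the power and exponential forms", {
  e_cont <- covariate_effect("CL", "AGE", "continuous-power", 0.75,
                             reference = 40)
  expect_equal(continuous_covariate_multiplier(e_cont, 40), 1)
  expect_equal(continuous_covariate_multiplier(e_cont, 80), 2^0.75)
  e_zero <- covariate_effect("CL", "AGE", "continuous-power", 0,
                             reference = 40)
  expect_equal(continuous_covariate_multiplier(e_zero, 123), 1)
  e_cat <- covariate_effect("Vp", "SEX", "categorical-exponential", -0.74)
  expect_equal(categorical_covariate_multiplier(e_cat, 0), 1)
  expect_equal(round(categorical_covariate_multiplier(e_cat, 1), 4), 0.4771)
  # male typical peripheral volume under the fitted effect
  expect_equal(424.33 * exp(-0.74), 202.5, tolerance = 1e-3)
  expect_error(categorical_covariate_multiplier(e_cat, 2), "0 or 1")
  expect_error(continuous_covariate_multiplier(e_cat, 40), "not continuous")
})

test_that("typical subject at reference reproduces the final-model values", {
  m <- published_model(ref_weight = 64)
  p <- individual_parameters(m, c(WT = 64, SEX = 0))
  expect_equal(unclass(p)[names(published_theta)], published_theta)
  # log-normal IIV: eta on CL multiplies CL only
  eta <- c(CL = log(2), Q = 0, Vc = 0, Vp = 0, Ka = 0, Tk0 = 0, Tlag = 0)
  p2 <- individual_parameters(m, c(WT = 64, SEX = 0), eta)
  expect_equal(p2[["CL"]], 2 * 7.02)
  expect_equal(unclass(p2)[-1], unclass(p)[-1])
  # male sex scales Vp only
  p3 <- individual_parameters(m, c(WT = 64, SEX = 1))
  expect_equal(p3[["Vp"]], 424.33 * exp(-0.74))
  expect_equal(unclass(p3)[-4], unclass(p)[-4])
  # allometric weight scaling hits clearances at 0.75 and volumes at 1
  p4 <- individual_parameters(m, c(WT = 128, SEX = 0))
  expect_equal(p4[["CL"]], 7.02 * 2^0.75)
  expect_equal(p4[["Vc"]], 138 * 2)
  expect_equal(p4[["Ka"]], 0.71)  # absorption not weight-scaled
})

test_that("eta monotonicity: each component strictly increases its parameter", {
  m <- published_model()
  base <- individual_parameters(m, c(WT = 70, SEX = 1))
  for (k in 1:7) {
    eta <- rep(0, 7); eta[k] <- 0.3
    up <- individual_parameters(m, c(WT = 70, SEX = 1), eta)
    expect_gt(up[[k]], base[[k]])
    expect_equal(unclass(up)[-k], unclass(base)[-k])
  }
})

test_that("combined residual-error variance is additive plus proportional", {
  m <- published_model()
  expect_equal(residual_variance(m, 0), 0.46^2)
  expect_equal(residual_variance(m, 10), 0.46^2 + (0.22 * 10)^2)
  m2 <- toy_model(sigma = c(add = 0.5, prop = 0))
  expect_equal(residual_variance(m2, c(0, 5, 50)), rep(0.25, 3))
  expect_error(population_model(published_theta, published_omega2,
                                sigma = c(add = 0, prop = 0)),
               "not both zero")
})

test_that("log-normal CV% reproduces every printed IIV coefficient", {
  expect_equal(cv_percent_from_omega2(0), 0)
  expect_equal(round(cv_percent_from_omega2(0.19), 1), 45.7)
  expect_equal(round(cv_percent_from_omega2(0.55), 1), 85.6)
  for (nm in names(published_omega2)) {
    expect_equal(cv_percent_from_omega2(published_omega2[[nm]]),
                 published_cv[[nm]], tolerance = 0.1 / published_cv[[nm]])
  }
  expect_error(cv_percent_from_omega2(-0.1), "non-negative")
})

test_that("model configs round-trip through YAML", {
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  model_to_config(m, path)
  m2 <- model_from_config(path)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$omega, m$omega, tolerance = 1e-12)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$allometric$ref, m$allometric$ref)
  expect_equal(m2$covariate_effects[[1]]$coefficient, -0.74)
})
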