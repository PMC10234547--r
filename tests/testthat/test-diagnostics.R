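eval_only <- list(theta = character(0), coef = integer(0),
                  omega = FALSE, sigma = FALSE)

test_that("noiseless typical-subject data give PRED = IPRED = DV, CWRES = 0", {
  # additive-only evaluation model: with data exactly on the typical curves
  # the conditional mode is zero (a proportional term would let the
  # interaction trade log-variance against fit and shift the mode)
  truth <- published_model()
  truth$sigma <- c(add = 0.46, prop = 0)
  gen <- truth
  diag(gen$omega) <- 0
  gen$sigma <- c(add = 1e-12, prop = 0)
  ds <- generate_dataset(cohort_spec(n_subjects = 4, n_missing_last = 0),
                         gen, seed = 8)
  fit <- fit_population(truth, ds, estimate = eval_only)
  g <- gof_table(fit, ds)
  expect_equal(nrow(g), n_observations(ds))
  expect_equal(g$PRED, g$DV, tolerance = 1e-6)
  expect_equal(g$IPRED, g$DV, tolerance = 1e-4)
  expect_lt(max(abs(g$CWRES)), 0.01)
})

test_that("CWRES is approximately standard normal when the model is true", {
  truth <- published_model()
  ds <- generate_dataset(study_cohort_spec(), truth, seed = 23)
  fit <- fit_population(truth, ds, estimate = eval_only)
  g <- gof_table(fit, ds)
  expect_gt(mean(g$CWRES), -0.2)
  expect_lt(mean(g$CWRES), 0.2)
  expect_gt(sd(g$CWRES), 0.8)
  expect_lt(sd(g$CWRES), 1.2)
})

test_that("structural misspecification leaves a time trend in CWRES", {
  truth <- published_model()
  ds <- generate_dataset(cohort_spec(n_subjects = 20, n_missing_last = 0),
                         truth, seed = 31)
  wrong <- truth
  wrong$theta[["Q"]] <- 0.01  # peripheral exchange suppressed: 1-compartment
  fit_ok <- fit_population(truth, ds, estimate = eval_only)
  fit_bad <- fit_population(wrong, ds, estimate = eval_only)
  runs_z <- function(x) {
    s <- sign(x)
    r <- sum(diff(s) != 0) + 1
    n1 <- sum(s > 0); n2 <- sum(s < 0)
    mu <- 2 * n1 * n2 / (n1 + n2) + 1
    v <- (mu - 1) * (mu - 2) / (n1 + n2 - 1)
    (r - mu) / sqrt(v)
  }
  z_by_time <- function(fit) {
    g <- gof_table(fit, ds)
    g <- g[order(g$time, g$subject_id), ]
    runs_z(g$CWRES)
  }
  expect_lt(abs(z_by_time(fit_ok)), 3)
  expect_gt(abs(z_by_time(fit_bad)), 4)  # long same-sign runs across time
})

test_that("VPC bands collapse onto the typical curve without variability", {
  m <- published_model()
  diag(m$omega) <- 0
  m$sigma <- c(add = 1e-9, prop = 0)
  # identical subjects: without IIV, noise, or covariate spread every curve
  # is the typical curve
  spec <- cohort_spec(n_subjects = 6, n_missing_last = 0, sex_ratio = 0,
                      weight = list(mean = 64, sd = 1e-9,
                                    bounds = c(63.9, 64.1)))
  ds <- generate_dataset(spec, m, seed = 3)
  v <- vpc(m, ds, n_rep = 100, seed = 10)
  expect_equal(v$p50_lo, v$p50_hi, tolerance = 1e-6)
  expect_equal(v$obs_p50, v$p50_lo, tolerance = 1e-6)
  expect_equal(v$p5_lo, v$p95_hi, tolerance = 1e-6)  # all bands coincide
  # exact inside/outside comparisons can split nanoscale ties
  expect_gte(vpc_coverage(v), 0.9)
})

test_that("VPC is reproducible under a seed and keeps percentiles ordered", {
  m <- published_model()
  ds <- generate_dataset(cohort_spec(n_subjects = 15, n_missing_last = 0),
                         m, seed = 12)
  v1 <- vpc(m, ds, n_rep = 120, seed = 5)
  v2 <- vpc(m, ds, n_rep = 120, seed = 5)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_true(all(v1$obs_p5 <= v1$obs_p50 & v1$obs_p50 <= v1$obs_p95))
  expect_true(all(v1$p5_lo <= v1$p5_hi & v1$p50_lo <= v1$p50_hi &
                    v1$p95_lo <= v1$p95_hi))
  expect_equal(nrow(v1), length(unique(ds$subjects[[1]]$obs$time[
    ds$subjects[[1]]$obs$mdv == 0])))
})

test_that("the external-schedule design runs a VPC without refitting", {
  m <- published_model()
  ds <- generate_dataset(external_cohort_spec(), m, seed = 19)
  v <- vpc(m, ds, n_rep = 100, seed = 2)
  expect_equal(max(v$time), 72)
  expect_gte(vpc_coverage(v), 0.8)
})

test_that("bootstrap of identical subjects returns the point estimate", {
  s0 <- toy_subject()
  subjects <- lapply(1:5, function(i) {
    s <- s0; s$id <- as.character(i); s
  })
  ds <- pk_dataset(subjects)
  m <- published_model()
  fit <- fit_population(m, ds, estimate = list(theta = "CL",
                                               coef = integer(0),
                                               omega = FALSE, sigma = FALSE))
  b <- bootstrap(fit$model, ds, n_boot = 50, seed = 17,
                 estimate = list(theta = "CL", coef = integer(0),
                                 omega = FALSE, sigma = FALSE),
                 control = list(maxit = 25))
  cl <- b[b$parameter == "theta.CL", ]
  expect_equal(cl$median, fit$model$theta[["CL"]], tolerance = 0.02)
  expect_true(all(b$lo <= b$median & b$median <= b$hi))
  expect_false(attr(b, "unstable"))
})
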