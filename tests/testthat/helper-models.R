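# Shared fixtures, all built in code.

published_theta <- c(CL = 7.02, Q = 9.11, Vc = 138, Vp = 424.33,
                  Ka = 0.71, Tk0 = 3.73, Tlag = 0.75)
published_omega2 <- c(CL = 0.25, Q = 0.19, Vc = 0.23, Vp = 0.17,
                   Ka = 0.55, Tk0 = 0.11, Tlag = 0.35)
published_cv <- c(CL = 53.3, Q = 45.7, Vc = 50.8, Vp = 43.0,
               Ka = 85.6, Tk0 = 34.0, Tlag = 64.7)

typical_params <- function() do.call(structural_params, as.list(published_theta))

# a model with IIV restricted to `iiv_on` (quadrature-oracle scale)
toy_model <- function(iiv_on = "CL", omega2 = 0.25,
                      sigma = c(add = 0.46, prop = 0.22)) {
  om <- setNames(rep(0, 7), names(published_theta))
  om[iiv_on] <- omega2
  population_model(theta = published_theta, omega = om, sigma = sigma,
                   allometric = NULL)
}

toy_subject <- function(id = "1", times = c(4, 24, 72),
                        dv = c(50, 25, 8), amt = 12000,
                        covariates = c(WT = 64, SEX = 0, AGE = 30, ALT = 25,
                                       AST = 29, SCR = 1.1, INF = 0)) {
  subject_record(id, doses = data.frame(time = 0, amt = amt),
                 obs = data.frame(time = times, dv = dv, mdv = 0L),
                 covariates = covariates)
}

# random valid structural parameter draws around the typical values
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- published_theta * exp(rnorm(7, 0, 0.4))
    do.call(structural_params, as.list(p))
  })
}

small_cohort <- function(n = 12, seed = 1, truth = published_model(),
                         schedule = c(1, 2, 4, 8, 24, 72, 168)) {
  spec <- cohort_spec(n_subjects = n, schedule = schedule)
  generate_dataset(spec, truth, seed = seed)
}
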