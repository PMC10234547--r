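#' Cohort specification for synthetic study data
#'
#' Describes a virtual single-dose cohort: demographic distributions, the
#' plasma sampling schedule and the weight-based dose rule. The defaults of
#' [study_cohort_spec] emulate the modelled trial; [external_cohort_spec]
#' emulates the shorter 0-72 h external-validation design.
#'
#' @param n_subjects number of subjects
#' @param sex_ratio fraction male
#' @param weight list(mean, sd, bounds) of the truncated-normal body-weight
#'   distribution (kg)
#' @param age_range c(min, max) years, sampled uniformly
#' @param infection_prevalence fraction LF-infected
#' @param alt_range,ast_range,scr_range uniform sampling ranges of the
#'   nuisance laboratory covariates (U/L, U/L, mg/dL)
#' @param schedule post-dose observation times (h), strictly increasing
#' @param dose_per_kg dose rule (micrograms per kg)
#' @param lloq lower limit of quantification (ng/mL)
#' @param n_missing_last number of subjects whose last scheduled sample is
#'   dropped (the trial lost the 168 h sample for 4 subjects)
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_subjects, sex_ratio = 0.57,
                        weight = list(mean = 64, sd = 11, bounds = c(51, 135)),
                        age_range = c(18, 66), infection_prevalence = 0.57,
                        alt_range = c(14, 67), ast_range = c(15, 53),
                        scr_range = c(0.6, 1.6),
                        schedule = c(1, 2, 3, 4, 6, 8, 12, 24, 36, 48, 72, 168),
                        dose_per_kg = 200, lloq = 0.1, n_missing_last = 0) {
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop("schedule must be strictly increasing", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1 ||
      infection_prevalence < 0 || infection_prevalence > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (weight$bounds[1] >= weight$bounds[2] || weight$bounds[1] <= 0) {
    stop("weight bounds must be positive and ordered", call. = FALSE)
  }
  if (weight$mean + 6 * weight$sd < weight$bounds[1] ||
      weight$mean - 6 * weight$sd > weight$bounds[2]) {
    stop("weight truncation excludes mean +/- 6 SD", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
study_cohort_spec <- function() {
  cohort_spec(n_subjects = 56, n_missing_last = 4)
}

#' @rdname cohort_spec
#' @export
external_cohort_spec <- function() {
  cohort_spec(n_subjects = 25,
              schedule = c(1, 2, 3, 4, 6, 8, 12, 24, 48, 72))
}

# truncated-normal draws by rejection (bounds are a few SD from the mean in
# all built-in specs, so rejection is cheap)
rtruncnorm <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

#' Generate cohort demographics
#'
#' Draws one covariate record per subject: sex ~ Bernoulli(sex_ratio),
#' weight ~ truncated normal, age ~ uniform, infection ~
#' Bernoulli(prevalence), ALT/AST/SCR ~ uniform over their ranges.
#'
#' @param spec a [cohort_spec]
#' @param seed integer seed (draws are reproducible given the seed)
#' @return data.frame(ID, WT, SEX, AGE, ALT, AST, SCR, INF)
#' @export
generate_demographics <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  data.frame(
    ID = as.character(seq_len(n)),
    WT = round(rtruncnorm(n, spec$weight$mean, spec$weight$sd,
                          spec$weight$bounds), 1),
    SEX = stats::rbinom(n, 1, spec$sex_ratio),
    AGE = round(stats::runif(n, spec$age_range[1], spec$age_range[2])),
    ALT = round(stats::runif(n, spec$alt_range[1], spec$alt_range[2])),
    AST = round(stats::runif(n, spec$ast_range[1], spec$ast_range[2])),
    SCR = round(stats::runif(n, spec$scr_range[1], spec$scr_range[2]), 2),
    INF = stats::rbinom(n, 1, spec$infection_prevalence),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic study dataset from a population model
#'
#' Simulates the full observation process: individual parameters from
#' log-normal IIV, exact structural predictions at the schedule times, and
#' combined additive-proportional residual error
#' `DV = f * (1 + eps_prop) + eps_add`. Draws yielding a negative DV are
#' re-drawn (preserving the error-model scale; the re-draw count is recorded
#' as an attribute). A DV below the LLOQ is kept but flagged `mdv = 1`, as is
#' the pre-dose (time 0) record, whose concentration in treatment-naive
#' subjects is zero.
#'
#' @param spec a [cohort_spec]
#' @param truth the generating [population_model]
#' @param seed integer seed
#' @return a [pk_dataset]; attribute `n_redraws` counts re-drawn negative DVs
#' @examples
#' ds <- generate_dataset(study_cohort_spec(), published_model(), seed = 1)
#' ds
#' @export
generate_dataset <- function(spec, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  demo <- generate_demographics(spec, seed = NULL)
  n <- spec$n_subjects
  eta <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = truth$omega)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
  miss <- if (spec$n_missing_last > 0) {
    sample(seq_len(n), spec$n_missing_last)
  } else integer(0)
  n_redraws <- 0L
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- c(WT = demo$WT[i], SEX = demo$SEX[i], AGE = demo$AGE[i],
            ALT = demo$ALT[i], AST = demo$AST[i], SCR = demo$SCR[i],
            INF = demo$INF[i])
    amt <- spec$dose_per_kg * demo$WT[i]
    p <- individual_parameters(truth, cv, eta[i, ])
    tt <- spec$schedule
    if (i %in% miss) tt <- tt[-length(tt)]
    f <- predict_concentrations(p, dose_schedule(0, amt), tt)
    dv <- numeric(length(f))
    for (j in seq_along(f)) {
      repeat {
        cand <- f[j] * (1 + stats::rnorm(1, 0, truth$sigma[["prop"]])) +
          stats::rnorm(1, 0, truth$sigma[["add"]])
        if (cand >= 0) break
        n_redraws <- n_redraws + 1L
      }
      dv[j] <- cand
    }
    mdv <- as.integer(dv < spec$lloq)
    obs <- data.frame(time = c(0, tt), dv = c(0, dv), mdv = c(1L, mdv))
    subjects[[i]] <- subject_record(demo$ID[i],
                                    doses = data.frame(time = 0, amt = amt),
                                    obs = obs, covariates = cv)
  }
  ds <- pk_dataset(subjects, lloq = spec$lloq,
                   name = sprintf("synthetic cohort (n=%d)", n))
  attr(ds, "n_redraws") <- n_redraws
  ds
}

#' Total number of observation records (including MDV=1 rows)
#'
#' Counts every plasma-sample record, fit-eligible or not; the pre-dose
#' records and any below-LLOQ flags are included. For the emulated study
#' design this is 13 records per subject (pre-dose plus 12 post-dose) minus
#' the dropped last samples.
#'
#' @param ds a [pk_dataset]
#' @return integer count
#' @export
total_samples <- function(ds) {
  sum(vapply(ds$subjects, function(s) nrow(s$obs), 0L))
}
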