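#' Simulation configuration for dose-exposure Monte Carlo
#'
#' @param n_per_arm virtual subjects per dosing arm
#' @param arms list of dose rules; each is `list(per_kg = <micrograms/kg>)`
#'   or `list(fixed = <mg>)`, optionally named
#' @param weight list(mean, sd, bounds) of the truncated-normal body-weight
#'   distribution (kg)
#' @param sex_ratio fraction male
#' @param grid output time grid (h); the default is hourly over 0-168 h with
#'   quarter-hour refinement through the absorption phase
#' @param lloq ng/mL, used by the AUC0-t rule
#' @param with_iiv draw individual random effects (log-normal IIV)
#' @param with_residual add residual error to the simulated profiles
#'   (default off: exposure metrics are computed on model-predicted
#'   profiles)
#' @return a `simulation_config` object
#' @export
simulation_config <- function(n_per_arm = 1000,
                              arms = list(perkg200 = list(per_kg = 200),
                                          fixed18 = list(fixed = 18),
                                          fixed36 = list(fixed = 36)),
                              weight = list(mean = 64, sd = 11,
                                            bounds = c(51, 135)),
                              sex_ratio = 0.57,
                              grid = c(seq(0, 12, by = 0.25),
                                       seq(13, 168, by = 1)),
                              lloq = 0.1, with_iiv = TRUE,
                              with_residual = FALSE) {
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]",
                                           call. = FALSE)
  if (weight$bounds[1] <= 0 || weight$bounds[1] >= weight$bounds[2]) {
    stop("weight bounds must be positive and ordered", call. = FALSE)
  }
  for (arm in arms) {
    if (is.null(arm$per_kg) == is.null(arm$fixed)) {
      stop("each arm needs exactly one of per_kg or fixed", call. = FALSE)
    }
  }
  if (is.null(names(arms))) names(arms) <- paste0("arm", seq_along(arms))
  structure(
    list(n_per_arm = n_per_arm, arms = arms, weight = weight,
         sex_ratio = sex_ratio, grid = grid, lloq = lloq,
         with_iiv = with_iiv, with_residual = with_residual),
    class = "simulation_config")
}

arm_dose_ug <- function(arm, wt) {
  if (!is.null(arm$per_kg)) arm$per_kg * wt
  else rep(arm$fixed * 1000, length(wt))
}

#' Monte Carlo cohort simulation across dosing arms
#'
#' Draws one virtual population (sex ~ Bernoulli(sex_ratio), weight ~
#' truncated normal, random effects ~ MVN(0, Omega) when `with_iiv`) and
#' doses the *same* subjects under every arm rule, so arms are paired: a
#' fixed-dose doubling doubles each subject's profile exactly.
#'
#' @param m the generating [population_model]
#' @param cfg a [simulation_config]
#' @param seed integer seed; output is reproducible given the seed
#' @return list with `demographics` (data.frame ID, WT, SEX) and `arms`, a
#'   named list holding per arm the dose vector (micrograms) and the
#'   `n_per_arm` x length(grid) concentration matrix
#' @export
simulate_cohort <- function(m, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_per_arm
  wt <- rtruncnorm(n, cfg$weight$mean, cfg$weight$sd, cfg$weight$bounds)
  sex <- stats::rbinom(n, 1, cfg$sex_ratio)
  eta <- if (cfg$with_iiv) {
    MASS::mvrnorm(n, mu = rep(0, 7), Sigma = m$omega)
  } else {
    matrix(0, nrow = n, ncol = 7)
  }
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
  params <- lapply(seq_len(n), function(i) {
    individual_parameters(m, c(WT = wt[i], SEX = sex[i]), eta[i, ])
  })
  arms <- lapply(cfg$arms, function(arm) {
    dose <- arm_dose_ug(arm, wt)
    conc <- t(vapply(seq_len(n), function(i) {
      f <- predict_concentrations(params[[i]], dose_schedule(0, dose[i]),
                                  cfg$grid)
      if (cfg$with_residual) {
        f <- f * (1 + stats::rnorm(length(f), 0, m$sigma[["prop"]])) +
          stats::rnorm(length(f), 0, m$sigma[["add"]])
      }
      f
    }, numeric(length(cfg$grid))))
    list(dose_ug = dose, conc = conc)
  })
  list(demographics = data.frame(ID = seq_len(n), WT = wt, SEX = sex),
       grid = cfg$grid, arms = arms)
}

#' Noncompartmental exposure metrics of one profile
#'
#' Cmax/Tmax from the grid maximum; AUC0-t by the linear-up/log-down
#' trapezoidal rule from time zero to the last time with concentration at or
#' above the LLOQ; AUC0-inf adds Clast/lambda_z, with the terminal slope
#' lambda_z from the log-linear regression (over at least 3 post-Tmax
#' points) that maximises adjusted R-squared.
#'
#' @param times profile times (h), increasing
#' @param conc concentrations (ng/mL)
#' @param lloq ng/mL
#' @return list(Cmax, Tmax, AUC0t, AUC0inf, lambda_z); `AUC0inf` and
#'   `lambda_z` are `NA` when no acceptable terminal slope exists
#' @examples
#' nca_metrics(c(0, 1, 2), c(0, 10, 5), lloq = 0.1)
#' @export
nca_metrics <- function(times, conc, lloq = 0.1) {
  if (length(times) < 3) stop("need at least 3 profile points", call. = FALSE)
  keep <- conc >= lloq
  if (!any(keep)) stop("all concentrations below the LLOQ: metrics undefined",
                       call. = FALSE)
  i_last <- max(which(keep))
  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- times[imax]
  auc <- 0
  for (j in seq_len(i_last - 1)) {
    c1 <- conc[j]; c2 <- conc[j + 1]; dt <- times[j + 1] - times[j]
    auc <- auc + if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
      (c1 + c2) / 2 * dt           # linear up (and degenerate/equal cases)
    } else {
      (c1 - c2) / log(c1 / c2) * dt  # log down
    }
  }
  # terminal slope: candidate tails ending at the last measurable point,
  # considering at most the last 10 post-Tmax points (standard NCA practice)
  lz <- NA_real_
  best_r2 <- -Inf
  tail_ok <- which(keep & conc > 0 & seq_along(conc) > imax)
  tail_ok <- tail_ok[tail_ok <= i_last]
  if (length(tail_ok) > 10) tail_ok <- tail_ok[(length(tail_ok) - 9):length(tail_ok)]
  if (length(tail_ok) >= 3) {
    for (start in tail_ok[seq_len(length(tail_ok) - 2)]) {
      idx <- tail_ok[tail_ok >= start]
      x <- times[idx]; yy <- log(conc[idx])
      n_t <- length(idx)
      sxx <- sum((x - mean(x))^2)
      slope <- sum((x - mean(x)) * (yy - mean(yy))) / sxx
      res <- yy - mean(yy) - slope * (x - mean(x))
      syy <- sum((yy - mean(yy))^2)
      r2 <- if (syy > 0) 1 - (sum(res^2) / (n_t - 2)) / (syy / (n_t - 1)) else -Inf
      if (slope < 0 && r2 > best_r2) {
        best_r2 <- r2
        lz <- -slope
      }
    }
  }
  auc_inf <- if (is.na(lz)) NA_real_ else auc + conc[i_last] / lz
  list(Cmax = cmax, Tmax = tmax, AUC0t = auc, AUC0inf = auc_inf,
       lambda_z = lz)
}

#' Per-arm exposure metrics of a simulated cohort
#'
#' @param sim output of [simulate_cohort]
#' @param lloq ng/mL passed to [nca_metrics]
#' @return data.frame(arm, ID, WT, SEX, dose_ug, Cmax, Tmax, AUC0t, AUC0inf)
#' @export
cohort_exposure <- function(sim, lloq = 0.1) {
  rows <- lapply(names(sim$arms), function(an) {
    arm <- sim$arms[[an]]
    mets <- lapply(seq_len(nrow(arm$conc)), function(i) {
      nca_metrics(sim$grid, arm$conc[i, ], lloq = lloq)
    })
    data.frame(arm = an, ID = sim$demographics$ID,
               WT = sim$demographics$WT, SEX = sim$demographics$SEX,
               dose_ug = arm$dose_ug,
               Cmax = vapply(mets, `[[`, 0, "Cmax"),
               Tmax = vapply(mets, `[[`, 0, "Tmax"),
               AUC0t = vapply(mets, `[[`, 0, "AUC0t"),
               AUC0inf = vapply(mets, `[[`, 0, "AUC0inf"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise exposure by arm and by sex
#'
#' Medians and ranges of AUC0-t and Cmax per arm and per arm-by-sex stratum
#' (the strata reuse the same draws; no re-simulation), plus the fixed-dose
#' ratio diagnostics where two fixed arms exist.
#'
#' @param metrics data.frame from [cohort_exposure]
#' @return list(`by_arm`, `by_arm_sex` summary data.frames, and
#'   `fixed_dose_ratio`: named vector of median AUC0t and Cmax ratios
#'   between the largest and smallest fixed-dose arms, `NULL` when fewer
#'   than two fixed arms are present)
#' @export
exposure_summary <- function(metrics) {
  if (!nrow(metrics)) stop("no metrics to summarise", call. = FALSE)
  summarise <- function(d) {
    data.frame(
      n = nrow(d),
      AUC0t_median = stats::median(d$AUC0t),
      AUC0t_min = min(d$AUC0t), AUC0t_max = max(d$AUC0t),
      Cmax_median = stats::median(d$Cmax),
      Cmax_min = min(d$Cmax), Cmax_max = max(d$Cmax)
    )
  }
  by_arm <- do.call(rbind, lapply(split(metrics, metrics$arm), summarise))
  by_arm <- cbind(arm = rownames(by_arm), by_arm, row.names = NULL)
  key <- interaction(metrics$arm, ifelse(metrics$SEX == 1, "male", "female"),
                     sep = ":")
  by_sex <- do.call(rbind, lapply(split(metrics, key), summarise))
  by_sex <- cbind(stratum = rownames(by_sex), by_sex, row.names = NULL)
  ratio <- NULL
  fixed_arms <- unique(metrics$arm[!duplicated(metrics$arm)])
  per_arm_dose <- tapply(metrics$dose_ug, metrics$arm, function(x)
    if (length(unique(x)) == 1) unique(x) else NA_real_)
  fixed <- names(per_arm_dose)[!is.na(per_arm_dose)]
  if (length(fixed) >= 2) {
    lo <- fixed[which.min(per_arm_dose[fixed])]
    hi <- fixed[which.max(per_arm_dose[fixed])]
    mlo <- metrics[metrics$arm == lo, ]
    mhi <- metrics[metrics$arm == hi, ]
    ratio <- c(AUC0t = stats::median(mhi$AUC0t / mlo$AUC0t),
               Cmax = stats::median(mhi$Cmax / mlo$Cmax))
  }
  list(by_arm = by_arm, by_arm_sex = by_sex, fixed_dose_ratio = ratio)
}
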