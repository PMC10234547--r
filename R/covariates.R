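#' Likelihood-ratio OFV threshold
#'
#' Upper-tail chi-square quantile used to judge a change in OFV between
#' nested models: 6.635 for p = 0.01 and 1 degree of freedom (forward
#' addition), 10.828 for p = 0.001 (backward elimination).
#'
#' @param p significance level in (0, 1)
#' @param df degrees of freedom (>= 1); one per added coefficient
#' @return the OFV-change threshold
#' @examples
#' lrt_threshold(0.01, 1)  # 6.635
#' @export
lrt_threshold <- function(p, df = 1) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qchisq(1 - p, df)
}

#' Stepwise covariate selection by likelihood ratio
#'
#' Forward addition followed by backward elimination. Each forward round
#' fits the current model extended by one candidate at a time and adds the
#' candidate with the largest OFV drop, provided the drop exceeds
#' `lrt_threshold(p_fwd, 1)`; rounds repeat until no candidate qualifies.
#' Backward elimination then removes any included effect whose removal
#' raises the OFV by less than `lrt_threshold(p_bwd, 1)`, worst first, until
#' all surviving effects are significant at the stricter level. Ties are
#' broken by the larger drop, then candidate declaration order. A failed fit
#' skips the candidate and is recorded in the trace.
#'
#' @param base base [population_model]; its allometric scaling is fixed
#'   throughout, while any covariate effects it already carries are
#'   re-estimated alongside the candidates
#' @param ds a [pk_dataset]
#' @param candidates list of [covariate_effect] objects to consider
#' @param p_fwd forward significance level (default 0.01, threshold 6.635)
#' @param p_bwd backward significance level (default 0.001, threshold 10.828)
#' @param estimate,control passed to [fit_population] for every step's fit;
#'   restricting `estimate` (e.g. fixing omega/sigma) gives the usual
#'   fast scan
#' @return list(model = final refitted model, trace = data.frame of all
#'   attempted steps, included = list of retained candidate effects)
#' @export
stepwise_select <- function(base, ds, candidates, p_fwd = 0.01, p_bwd = 0.001,
                            estimate = NULL, control = list()) {
  thr_f <- lrt_threshold(p_fwd, 1)
  thr_b <- lrt_threshold(p_bwd, 1)
  n_base_eff <- length(base$covariate_effects)
  trace <- list()
  log_step <- function(direction, e, delta, accepted, note = "") {
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1, direction = direction,
      parameter = e$parameter, covariate = e$covariate,
      delta_ofv = delta, accepted = accepted, note = note,
      stringsAsFactors = FALSE)
  }
  fit_with <- function(effects) {
    m <- base
    m$covariate_effects <- c(base$covariate_effects, effects)
    est <- estimate
    est$coef <- seq_along(m$covariate_effects)
    tryCatch(fit_population(m, ds, estimate = est, control = control),
             error = function(e) e)
  }
  included <- list()
  cur_fit <- fit_with(included)
  if (inherits(cur_fit, "error")) {
    stop("base model fit failed: ", conditionMessage(cur_fit), call. = FALSE)
  }
  remaining <- candidates
  repeat {
    drops <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      f <- fit_with(c(included, remaining[k]))
      if (inherits(f, "error")) {
        log_step("forward", remaining[[k]], NA, FALSE,
                 paste("fit failed:", conditionMessage(f)))
        next
      }
      fits[[k]] <- f
      drops[k] <- cur_fit$ofv - f$ofv
    }
    ok <- which(!is.na(drops) & drops > thr_f)
    if (!length(ok)) {
      for (k in seq_along(remaining)) {
        if (!is.na(drops[k])) log_step("forward", remaining[[k]], drops[k], FALSE)
      }
      break
    }
    best <- ok[order(-drops[ok])][1]
    for (k in seq_along(remaining)) {
      if (!is.na(drops[k])) log_step("forward", remaining[[k]], drops[k], k == best)
    }
    included <- c(included, remaining[best])
    cur_fit <- fits[[best]]
    remaining <- remaining[-best]
    if (!length(remaining)) break
  }
  # backward elimination on the included set
  repeat {
    if (!length(included)) break
    rises <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    for (k in seq_along(included)) {
      f <- fit_with(included[-k])
      if (inherits(f, "error")) {
        log_step("backward", included[[k]], NA, TRUE,
                 paste("removal fit failed, effect kept:", conditionMessage(f)))
        rises[k] <- Inf
        next
      }
      fits[[k]] <- f
      rises[k] <- f$ofv - cur_fit$ofv
    }
    weakest <- which.min(rises)
    if (is.finite(rises[weakest]) && rises[weakest] < thr_b) {
      log_step("backward", included[[weakest]], rises[weakest], FALSE,
               "removed")
      cur_fit <- fits[[weakest]]
      included <- included[-weakest]
    } else {
      for (k in seq_along(included)) {
        if (is.finite(rises[k])) log_step("backward", included[[k]], rises[k], TRUE)
      }
      break
    }
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), direction = character(),
               parameter = character(), covariate = character(),
               delta_ofv = numeric(), accepted = logical(), note = character())
  list(model = cur_fit$model, fit = cur_fit, trace = trace_df,
       included = included)
}

#' Default candidate covariate effects
#'
#' The candidate set the study screened: sex and infection status
#' (categorical) and age, ALT, AST and serum creatinine (continuous,
#' normalised to the cohort average) on clearance and the volumes.
#' Creatinine clearance is deliberately absent: the drug is eliminated in
#' faeces with negligible renal excretion. Weight is handled by fixed
#' allometric scaling, not as an estimated candidate.
#'
#' @param ds a [pk_dataset], used for the continuous-covariate reference
#'   averages
#' @param parameters parameters to pair each covariate with
#' @return list of [covariate_effect] objects
#' @export
default_candidates <- function(ds, parameters = c("CL", "Vc", "Vp")) {
  cov_of <- function(cn) {
    vapply(ds$subjects, function(s) s$covariates[[cn]], 0)
  }
  out <- list()
  for (par in parameters) {
    out <- c(out, list(
      covariate_effect(par, "SEX", "categorical-exponential", 0),
      covariate_effect(par, "INF", "categorical-exponential", 0),
      covariate_effect(par, "AGE", "continuous-power", 0,
                       reference = mean(cov_of("AGE"))),
      covariate_effect(par, "ALT", "continuous-power", 0,
                       reference = mean(cov_of("ALT"))),
      covariate_effect(par, "AST", "continuous-power", 0,
                       reference = mean(cov_of("AST"))),
      covariate_effect(par, "SCR", "continuous-power", 0,
                       reference = mean(cov_of("SCR")))
    ))
  }
  out
}
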