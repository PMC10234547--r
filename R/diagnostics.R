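#' Goodness-of-fit table
#'
#' One row per fitted observation with the population prediction (PRED, all
#' random effects at zero), the individual prediction (IPRED, at the
#' subject's empirical Bayes estimates), the individual weighted residual
#' IWRES = (DV - IPRED)/sqrt(v(IPRED)) and the conditional weighted residual
#' CWRES. CWRES decorrelates the residuals with the same FOCE-I linearised
#' covariance C_i used by the objective function (one shared code path), so
#' it is approximately standard normal when the model is correct.
#'
#' @param fit a `foce_fit` from [fit_population]
#' @param ds the fitted [pk_dataset]
#' @return data.frame(subject_id, time, DV, PRED, IPRED, IWRES, CWRES)
#' @export
gof_table <- function(fit, ds) {
  if (is.null(fit$ebes)) stop("fit carries no EBEs", call. = FALSE)
  m <- fit$model
  rows <- lapply(seq_along(ds$subjects), function(i) {
    s <- ds$subjects[[i]]
    pl <- subject_payload(m, s)
    if (!length(pl$y)) return(NULL)
    eta_hat <- fit$ebes[i, ]
    lin <- payload_linearization(m, pl, eta_hat)
    pred <- payload_predict(pl, numeric(7))
    ipred <- lin$f
    iwres <- (pl$y - ipred) / sqrt(lin$v)
    # CWRES: whiten y - (f(eta-hat) - G eta-hat) by the Cholesky factor of
    # C_i; lin$z is exactly that solve, reused from the OFV computation.
    data.frame(subject_id = s$id, time = pl$times, DV = pl$y,
               PRED = pred, IPRED = ipred, IWRES = iwres, CWRES = lin$z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets at the observed design (same
#' subjects, covariates, dose events and sampling times), computes the 5th,
#' 50th and 95th concentration percentiles per time bin in each replicate,
#' and returns the observed percentiles together with the 2.5-97.5%
#' prediction band of each simulated percentile. Bins are the nominal
#' observation times (the design uses a fixed schedule); a bin with fewer
#' than `min_bin` observations is merged into its nearest neighbour and the
#' merge is recorded.
#'
#' @param m the [population_model] to check
#' @param ds a [pk_dataset] supplying the design and the observed values
#' @param n_rep number of replicate simulations (>= 100)
#' @param seed integer seed
#' @param lloq_censor if `TRUE`, simulated concentrations below `ds$lloq`
#'   are set to `NA` before percentile computation; the default keeps them,
#'   matching a dataset with no below-LLOQ observations
#' @param min_bin minimum observations per bin before merging
#' @return a `vpc_result`: data.frame with one row per bin (`time`, `n_obs`,
#'   observed `obs_p5/p50/p95`, and simulated band columns
#'   `p5_lo, p5_hi, p50_lo, p50_hi, p95_lo, p95_hi`), plus attributes
#'   `n_rep` and `merged_bins`
#' @export
vpc <- function(m, ds, n_rep = 1000, seed = NULL, lloq_censor = FALSE,
                min_bin = 3) {
  if (n_rep < 100) stop("use at least 100 replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  design <- lapply(ds$subjects, function(s) {
    fo <- fit_obs(s)
    list(times = fo$time, dv = fo$dv, doses = s$doses, cov = s$covariates)
  })
  design <- design[vapply(design, function(d) length(d$times) > 0, TRUE)]
  all_times <- unlist(lapply(design, `[[`, "times"))
  all_dv <- unlist(lapply(design, `[[`, "dv"))
  bins <- sort(unique(all_times))
  # merge sparse bins into their nearest neighbour
  merged <- character(0)
  counts <- vapply(bins, function(b) sum(all_times == b), 0L)
  bin_of <- function(tt, bins) bins[vapply(tt, function(t)
    which.min(abs(bins - t)), 0L)]
  while (any(counts < min_bin) && length(bins) > 1) {
    k <- which(counts < min_bin)[1]
    merged <- c(merged, sprintf("bin %g merged", bins[k]))
    bins <- bins[-k]
    counts <- vapply(bins, function(b) sum(bin_of(all_times, bins) == b), 0L)
  }
  obs_bin <- bin_of(all_times, bins)
  pct <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE,
                                     na.rm = TRUE)
  obs_p <- t(vapply(bins, function(b) pct(all_dv[obs_bin == b]), numeric(3)))
  sims <- array(NA_real_, dim = c(n_rep, length(bins), 3))
  supp_all <- seq_len(7)
  for (r in seq_len(n_rep)) {
    sim_dv <- unlist(lapply(design, function(d) {
      eta <- drop(MASS::mvrnorm(1, mu = rep(0, 7), Sigma = m$omega))
      p <- individual_parameters(m, d$cov, eta)
      f <- predict_concentrations(p, d$doses, d$times)
      dv <- f * (1 + stats::rnorm(length(f), 0, m$sigma[["prop"]])) +
        stats::rnorm(length(f), 0, m$sigma[["add"]])
      if (lloq_censor) dv[dv < ds$lloq] <- NA_real_
      dv
    }))
    for (k in seq_along(bins)) {
      sims[r, k, ] <- pct(sim_dv[obs_bin == bins[k]])
    }
  }
  band <- function(k, q) stats::quantile(sims[, k, q], c(0.025, 0.975),
                                         names = FALSE, na.rm = TRUE)
  out <- data.frame(
    time = bins,
    n_obs = vapply(bins, function(b) sum(obs_bin == b), 0L),
    obs_p5 = obs_p[, 1], obs_p50 = obs_p[, 2], obs_p95 = obs_p[, 3]
  )
  for (q in 1:3) {
    bb <- t(vapply(seq_along(bins), function(k) band(k, q), numeric(2)))
    out[[paste0("p", c(5, 50, 95)[q], "_lo")]] <- bb[, 1]
    out[[paste0("p", c(5, 50, 95)[q], "_hi")]] <- bb[, 2]
  }
  attr(out, "n_rep") <- n_rep
  attr(out, "merged_bins") <- merged
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Fraction of observed percentile points inside their simulated bands
#'
#' Calibration summary of a [vpc] result: with a correct model roughly 95%
#' of the observed 5th/50th/95th percentile points should fall inside their
#' 95% prediction bands.
#'
#' @param v a `vpc_result`
#' @return fraction in `[0, 1]`
#' @export
vpc_coverage <- function(v) {
  inside <- c(v$obs_p5 >= v$p5_lo & v$obs_p5 <= v$p5_hi,
              v$obs_p50 >= v$p50_lo & v$obs_p50 <= v$p50_hi,
              v$obs_p95 >= v$p95_lo & v$obs_p95 <= v$p95_hi)
  mean(inside)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement (to the original cohort size), refits
#' the model on each replicate and summarises every estimated quantity by
#' its median and 2.5th/97.5th percentiles. Refits warm-start from the
#' supplied estimates; a failed or non-converged replicate is re-attempted
#' once from `init` (when given) and otherwise excluded and counted.
#'
#' @param m0 the fitted [population_model] whose stability is assessed
#'   (replicate fits start here)
#' @param ds the original [pk_dataset]
#' @param n_boot number of bootstrap datasets (>= 50)
#' @param seed integer seed
#' @param init optional fall-back starting [population_model]
#' @param estimate,control passed to [fit_population]
#' @return a `bootstrap_result`: data.frame(parameter, median, lo, hi) over
#'   converged replicates; attributes `n_boot`, `n_failed`, `unstable`
#'   (more than 20\% failures)
#' @export
bootstrap <- function(m0, ds, n_boot = 1000, seed = NULL, init = NULL,
                      estimate = NULL, control = list()) {
  if (n_boot < 50) stop("use at least 50 bootstrap replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(ds$subjects)
  pk <- make_packing(m0, estimate)
  par_names <- names(pack_params(pk))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(par_names),
                  dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    subjects <- lapply(seq_along(idx), function(j) {
      s <- ds$subjects[[idx[j]]]
      s$id <- sprintf("%s.b%d", s$id, j)  # resampled copies are distinct units
      s
    })
    bds <- pk_dataset(subjects, lloq = ds$lloq, name = sprintf("boot %d", b))
    f <- tryCatch(fit_population(m0, bds, estimate = estimate,
                                 control = control),
                  error = function(e) NULL)
    if ((is.null(f) || !f$converged) && !is.null(init)) {
      f <- tryCatch(fit_population(init, bds, estimate = estimate,
                                   control = control),
                    error = function(e) NULL)
    }
    if (is.null(f) || !f$converged) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- f$par
  }
  ok <- stats::complete.cases(draws)
  natural <- natural_scale_draws(draws[ok, , drop = FALSE], pk)
  out <- data.frame(
    parameter = colnames(natural),
    median = apply(natural, 2, stats::median),
    lo = apply(natural, 2, stats::quantile, 0.025),
    hi = apply(natural, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  attr(out, "unstable") <- n_failed > 0.2 * n_boot
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

# transform packed (log / log-Cholesky) draws back to the natural scale
natural_scale_draws <- function(draws, pk) {
  out <- draws
  for (j in seq_len(ncol(draws))) {
    nm <- colnames(draws)[j]
    if (grepl("^theta\\.|^sigma\\.", nm)) {
      out[, j] <- exp(draws[, j])
    } else if (grepl("^omega\\.L", nm)) {
      # leave factor elements; variances are summarised via refit models
      out[, j] <- draws[, j]
    } else if (grepl("^omega\\.", nm)) {
      out[, j] <- exp(draws[, j])^2  # variance omega^2
    }
  }
  out
}
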