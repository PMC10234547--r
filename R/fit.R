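# Outer FOCE-I optimisation: packing of the estimated quantities onto an
# unconstrained scale (log for typical values and error SDs, log-Cholesky for
# the IIV covariance, raw for covariate coefficients), L-BFGS-B with
# central-difference step 1e-4 on that scale.

make_packing <- function(m0, estimate = NULL) {
  est <- list(theta = pk_param_names(),
              coef = seq_along(m0$covariate_effects),
              omega = TRUE, sigma = TRUE)
  est[names(estimate)] <- estimate
  supp <- omega_support(m0$omega)
  sig_est <- if (isTRUE(est$sigma)) which(m0$sigma > 0) else integer(0)
  list(m0 = m0, theta = intersect(pk_param_names(), est$theta),
       coef = est$coef, omega = isTRUE(est$omega), supp = supp,
       full = m0$omega_structure == "full", sigma = sig_est)
}

pack_params <- function(pk) {
  m0 <- pk$m0
  par <- numeric(0)
  if (length(pk$theta)) {
    par <- log(m0$theta[pk$theta])
    names(par) <- paste0("theta.", pk$theta)
  }
  for (i in pk$coef) {
    e <- m0$covariate_effects[[i]]
    v <- e$coefficient
    names(v) <- paste0("coef.", e$covariate, "_on_", e$parameter)
    par <- c(par, v)
  }
  if (pk$omega && length(pk$supp)) {
    os <- m0$omega[pk$supp, pk$supp, drop = FALSE]
    if (pk$full) {
      L <- t(chol(os + diag(1e-12, nrow(os))))
      v <- numeric(0)
      for (a in seq_len(nrow(L))) {
        for (b in seq_len(a)) {
          val <- if (a == b) log(L[a, a]) else L[a, b]
          names(val) <- paste0("omega.L", a, b)
          v <- c(v, val)
        }
      }
    } else {
      v <- log(sqrt(diag(os)))
      names(v) <- paste0("omega.", pk_param_names()[pk$supp])
    }
    par <- c(par, v)
  }
  if (length(pk$sigma)) {
    v <- log(m0$sigma[pk$sigma])
    names(v) <- paste0("sigma.", names(m0$sigma)[pk$sigma])
    par <- c(par, v)
  }
  par
}

unpack_params <- function(par, pk) {
  m <- pk$m0
  i <- 0
  take <- function(n) {
    out <- par[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  if (length(pk$theta)) m$theta[pk$theta] <- exp(take(length(pk$theta)))
  for (k in pk$coef) {
    m$covariate_effects[[k]]$coefficient <- unname(take(1))
  }
  if (pk$omega && length(pk$supp)) {
    d <- length(pk$supp)
    if (pk$full) {
      L <- matrix(0, d, d)
      for (a in seq_len(d)) {
        for (b in seq_len(a)) {
          val <- take(1)
          L[a, b] <- if (a == b) exp(val) else val
        }
      }
      os <- L %*% t(L)
    } else {
      os <- diag(exp(take(d))^2, nrow = d)
    }
    m$omega[pk$supp, pk$supp] <- os
  }
  if (length(pk$sigma)) m$sigma[pk$sigma] <- exp(take(length(pk$sigma)))
  m
}

#' Fit a population model by FOCE-I
#'
#' Outer quasi-Newton optimisation of [foce_objective] over the transformed
#' population parameters, with warm-started inner EBE updates. Any subset of
#' the population quantities can be held fixed through `estimate`, the usual
#' device for reduced refits (bootstrap warm starts, single-coefficient
#' likelihood-ratio scans, sensitivity runs).
#'
#' @param m0 initial [population_model]
#' @param ds a [pk_dataset]
#' @param estimate list overriding which quantities are estimated:
#'   `theta` (character vector of parameter names), `coef` (indices into
#'   `m0$covariate_effects`), `omega` (logical), `sigma` (logical)
#' @param compute_se compute CV\% of the estimates from the inverse
#'   finite-difference Hessian of OFV/2 (delta method on the transformed
#'   scale); costs O(p^2) objective evaluations
#' @param control list: `maxit` (outer iterations, default 100), `fd_step`
#'   (Hessian step, default 1e-4), `factr`, `pgtol` (L-BFGS-B tolerances)
#' @return a `foce_fit` object: final model, `ofv`, `ofv_initial`, `ebes`
#'   (subjects x 7 matrix), `se_cv` (CV\% per estimated quantity, NA when the
#'   Hessian is unavailable or not PD), `eta_shrinkage`, `eps_shrinkage`,
#'   `converged`, `n_iter`
#' @export
fit_population <- function(m0, ds, estimate = NULL, compute_se = FALSE,
                           control = list()) {
  ctl <- list(maxit = 100, fd_step = 1e-4, factr = 1e8, pgtol = 1e-3)
  ctl[names(control)] <- control
  pk <- make_packing(m0, estimate)
  par0 <- pack_params(pk)
  cache <- new.env(parent = emptyenv())
  nfail <- 0L
  obj <- function(par) {
    m <- tryCatch(unpack_params(par, pk), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    val <- tryCatch(foce_objective(m, ds, ebe_cache = cache),
                    error = function(e) {
                      nfail <<- nfail + 1L
                      NA_real_
                    })
    if (!is.finite(val)) return(1e10)
    val
  }
  ofv0 <- obj(par0)
  opt <- if (length(par0) == 0) {
    # evaluation-only: nothing to estimate, report the model as given
    list(par = par0, convergence = 0L, counts = c(`function` = 1L))
  } else {
    # forward-difference gradient: p+1 objective calls per gradient, enough
    # for the quasi-Newton outer step at fd_step on the transformed scale
    grd <- function(par) {
      f0 <- obj(par)
      vapply(seq_along(par), function(j) {
        pj <- par
        pj[j] <- pj[j] + ctl$fd_step
        (obj(pj) - f0) / ctl$fd_step
      }, 0)
    }
    stats::optim(par0, obj, gr = grd, method = "L-BFGS-B",
                 control = list(maxit = ctl$maxit, factr = ctl$factr,
                                pgtol = ctl$pgtol))
  }
  final <- unpack_params(opt$par, pk)
  # final EBEs and shrinkage at the optimum
  ebes <- matrix(0, nrow = length(ds$subjects), ncol = 7,
                 dimnames = list(vapply(ds$subjects, function(s) s$id, ""),
                                 pk_param_names()))
  ofv <- 0
  for (i in seq_along(ds$subjects)) {
    s <- ds$subjects[[i]]
    eb <- estimate_ebes(final, s, eta_start = cache[[paste0("s", s$id)]])
    ebes[i, ] <- eb$eta
    ofv <- ofv + subject_linearization(final, s, eb$eta)$ofv
  }
  se_cv <- rep(NA_real_, length(par0))
  names(se_cv) <- names(par0)
  if (compute_se) {
    se_cv <- tryCatch(estimate_cv(obj, opt$par, pk, ctl$fd_step),
                      error = function(e) se_cv)
  }
  fit <- structure(
    list(model = final, ofv = ofv, ofv_initial = ofv0, ebes = ebes,
         se_cv = se_cv, converged = opt$convergence == 0,
         n_iter = opt$counts[["function"]], n_obs = n_observations(ds),
         packing = pk, par = opt$par, dataset_name = ds$name,
         n_obj_failures = nfail),
    class = "foce_fit"
  )
  fit$eta_shrinkage <- eta_shrinkage(fit)
  fit$eps_shrinkage <- tryCatch(eps_shrinkage(fit, ds),
                                error = function(e) NA_real_)
  fit
}

# CV% of the estimates from the curvature of the objective.  On the log
# scale the SE of the log is itself (approximately) the CV of the natural
# parameter; raw coefficients are converted by the delta method.
estimate_cv <- function(obj, par, pk, h) {
  p <- length(par)
  H <- matrix(0, p, p)
  f0 <- obj(par)
  for (a in seq_len(p)) {
    for (b in a:p) {
      ea <- replace(numeric(p), a, h)
      eb <- replace(numeric(p), b, h)
      H[a, b] <- H[b, a] <-
        (obj(par + ea + eb) - obj(par + ea - eb) -
           obj(par - ea + eb) + obj(par - ea - eb)) / (4 * h * h)
    }
  }
  if (min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("OFV Hessian not positive definite")
  }
  se <- sqrt(diag(2 * solve(H)))
  cv <- 100 * se
  raw <- grepl("^coef\\.", names(par))
  cv[raw] <- 100 * se[raw] / abs(par[raw])
  names(cv) <- names(par)
  cv
}

#' @export
print.foce_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit of '%s': OFV %.3f (initial %.3f), %s after %d objective evaluations\n",
              x$dataset_name, x$ofv, x$ofv_initial,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  est <- cbind(estimate = c(x$model$theta,
                            vapply(x$model$covariate_effects,
                                   function(e) e$coefficient, 0),
                            x$model$sigma))
  print(round(est, 4))
  cat("IIV variances (omega^2):\n")
  print(round(diag(x$model$omega), 4))
  cat("eta shrinkage (%):\n")
  print(round(x$eta_shrinkage, 1))
  cat(sprintf("epsilon shrinkage: %.1f%%\n", x$eps_shrinkage))
  invisible(x)
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(eta-hat_p) / omega_p)` per parameter with estimated IIV;
#' near 0 when the data inform the individual estimates, near 100 when the
#' EBEs collapse to the population mean.
#'
#' @param fit a `foce_fit`
#' @return named vector of percentages (NA where IIV variance is zero)
#' @export
eta_shrinkage <- function(fit) {
  om <- sqrt(diag(fit$model$omega))
  out <- rep(NA_real_, 7)
  names(out) <- pk_param_names()
  for (p in seq_len(7)) {
    if (om[p] > 1e-8 && nrow(fit$ebes) > 1) {
      out[p] <- 100 * (1 - stats::sd(fit$ebes[, p]) / om[p])
    }
  }
  out
}

#' Epsilon shrinkage
#'
#' `100 * (1 - SD(IWRES))` with
#' `IWRES = (y - f(eta-hat)) / sqrt(v(eta-hat))`; near 0 when residual
#' variability is well characterised.
#'
#' @param fit a `foce_fit`
#' @param ds the fitted [pk_dataset]
#' @return percentage (NA with a warning when fewer than 2 observations)
#' @export
eps_shrinkage <- function(fit, ds) {
  iwres <- unlist(lapply(seq_along(ds$subjects), function(i) {
    s <- ds$subjects[[i]]
    pl <- subject_payload(fit$model, s)
    if (!length(pl$y)) return(numeric(0))
    f <- conc_from_base(pl, fit$ebes[i, ])
    v <- residual_variance(fit$model, pmax(f, 0))
    (pl$y - f) / sqrt(v)
  }))
  if (length(iwres) < 2) {
    warning("fewer than 2 observations: epsilon shrinkage undefined")
    return(NA_real_)
  }
  100 * (1 - stats::sd(iwres))
}
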