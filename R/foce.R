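# First-order conditional estimation with interaction (FOCE-I).
#
# Per-subject inner problem: the empirical Bayes estimate (EBE) eta-hat
# minimises
#   g(eta) = sum_j [ (y_j - f_j(eta))^2 / v_j(eta) + log v_j(eta) ]
#            + eta' Omega^-1 eta
# with f_j the structural prediction at the subject's covariates and
# v_j = residual_variance(f_j).  The population objective linearises f about
# eta-hat:  G_i = df/deta |eta-hat,  C_i = G Omega G' + diag(v(eta-hat))
# (the "interaction": v evaluated at the conditional estimate, not at 0),
# r_i = y - f(eta-hat) + G eta-hat, and
#   OFV = sum_i [ log|C_i| + r_i' C_i^-1 r_i ]
# omitting the n*log(2*pi) constant, the usual pharmacometric convention.

# Per-subject fitting payload: observation vector, times, doses and the
# eta-independent part of the individual parameters.
subject_payload <- function(m, s) {
  fo <- fit_obs(s)
  base <- individual_parameters(m, s$covariates, eta = rep(0, 7))
  list(y = fo$dv, times = fo$time, doses = s$doses,
       base = unclass(base), id = s$id)
}

conc_from_base <- function(pl, eta_full) {
  p <- pl$base * exp(eta_full)
  total <- numeric(length(pl$times))
  for (k in seq_len(nrow(pl$doses))) {
    total <- total + central_amount_one_dose(p, pl$doses$time[k],
                                             pl$doses$amt[k], pl$times)
  }
  total / p[["Vc"]]
}

# A payload may carry its own prediction function (used by the test toys);
# the default is the closed-form structural prediction.
payload_predict <- function(pl, eta_full) {
  if (!is.null(pl$predict)) pl$predict(eta_full) else conc_from_base(pl, eta_full)
}

# Support of the random effects: components with non-negligible IIV variance.
omega_support <- function(omega) which(diag(omega) > 1e-10)

omega_inverse_support <- function(omega, supp) {
  os <- omega[supp, supp, drop = FALSE]
  tryCatch(solve(os), error = function(e) MASS::ginv(os))
}

# Conditional (inner) objective for one subject, eta restricted to the
# support dimensions.
inner_objective <- function(pl, m, supp, oinv) {
  s2a <- m$sigma[["add"]]^2
  sp <- m$sigma[["prop"]]
  function(eta_s) {
    eta <- numeric(7)
    eta[supp] <- eta_s
    f <- payload_predict(pl, eta)
    v <- pmax(s2a + (sp * f)^2, 1e-290)
    sum((pl$y - f)^2 / v + log(v)) + drop(eta_s %*% oinv %*% eta_s)
  }
}

#' Empirical Bayes estimate for one subject
#'
#' Minimises the conditional FOCE-I objective over the subject's random
#' effects (components with zero IIV variance are pinned at 0). Starts at
#' eta = 0 (or `eta_start`) with deterministic perturbed restarts if the
#' optimiser fails.
#'
#' @param m a [population_model]
#' @param s a [subject_record] with at least one fit-eligible observation
#' @param eta_start optional warm start (7-vector)
#' @return list(eta = 7-vector eta-hat, objective = conditional objective
#'   value, converged = flag)
#' @export
estimate_ebes <- function(m, s, eta_start = NULL) {
  pl <- subject_payload(m, s)
  if (length(pl$y) == 0) stop("subject ", s$id, " has no fit-eligible observations",
                              call. = FALSE)
  estimate_ebes_payload(m, pl, eta_start)
}

estimate_ebes_payload <- function(m, pl, eta_start = NULL) {
  supp <- omega_support(m$omega)
  eta <- numeric(7)
  if (length(supp) == 0) {
    return(list(eta = eta, objective = inner_objective(pl, m, integer(0),
                matrix(0, 0, 0))(numeric(0)), converged = TRUE))
  }
  oinv <- omega_inverse_support(m$omega, supp)
  g <- inner_objective(pl, m, supp, oinv)
  starts <- list(numeric(length(supp)))
  if (!is.null(eta_start)) starts <- c(list(eta_start[supp]), starts)
  # deterministic perturbed restarts, used only on failure
  starts <- c(starts, list(rep(0.3, length(supp)), rep(-0.3, length(supp)),
                           seq_len(length(supp)) * 0.1))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, g, control = list(rel.tol = 1e-10, iter.max = 300)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
      best <- res
    }
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("EBE optimisation failed for subject ", pl$id,
                          call. = FALSE)
  eta[supp] <- best$par
  list(eta = eta, objective = best$objective, converged = best$convergence == 0)
}

# FOCE-I linearisation of one subject about eta-hat.  This single code path
# feeds both the population objective and the CWRES diagnostics.
subject_linearization <- function(m, s, eta_hat, fd_step = 1e-4) {
  payload_linearization(m, subject_payload(m, s), eta_hat, fd_step)
}

payload_linearization <- function(m, pl, eta_hat, fd_step = 1e-4) {
  supp <- omega_support(m$omega)
  f0 <- payload_predict(pl, eta_hat)
  v <- pmax(residual_variance(m, pmax(f0, 0)), 1e-290)
  G <- matrix(0, nrow = length(pl$y), ncol = length(supp))
  for (j in seq_along(supp)) {
    ep <- eta_hat; em <- eta_hat
    ep[supp[j]] <- ep[supp[j]] + fd_step
    em[supp[j]] <- em[supp[j]] - fd_step
    G[, j] <- (payload_predict(pl, ep) - payload_predict(pl, em)) / (2 * fd_step)
  }
  Om <- m$omega[supp, supp, drop = FALSE]
  C <- G %*% Om %*% t(G)
  diag(C) <- diag(C) + v
  r <- pl$y - f0 + drop(G %*% eta_hat[supp])
  # Cholesky with escalating jitter; hard error naming the subject if the
  # matrix stays indefinite.
  U <- NULL
  jitter <- 0
  for (k in 0:3) {
    U <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (!is.null(U)) break
    jitter <- if (jitter == 0) 1e-8 * mean(diag(C)) else jitter * 100
  }
  if (is.null(U)) stop("FOCE covariance not positive definite for subject ",
                       pl$id, call. = FALSE)
  z <- backsolve(U, r, transpose = TRUE)
  list(f = f0, v = v, G = G, C = C, U = U, r = r, z = z, y = pl$y,
       times = pl$times, supp = supp,
       ofv = 2 * sum(log(diag(U))) + sum(z^2))
}

#' FOCE-I population objective function value
#'
#' The -2 log approximate marginal likelihood (2*pi constant omitted) of a
#' population model on a dataset, by per-subject linearisation at the
#' conditional modes with residual variance evaluated at the mode
#' (interaction).
#'
#' @param m a [population_model]
#' @param ds a [pk_dataset]; every subject needs at least one fit-eligible
#'   observation
#' @param ebe_cache optional environment used to warm-start the inner
#'   optimisations across repeated calls (as during outer optimisation)
#' @return the objective function value (scalar)
#' @export
foce_objective <- function(m, ds, ebe_cache = NULL) {
  total <- 0
  for (i in seq_along(ds$subjects)) {
    s <- ds$subjects[[i]]
    key <- paste0("s", s$id)
    start <- if (!is.null(ebe_cache)) ebe_cache[[key]] else NULL
    eb <- estimate_ebes(m, s, eta_start = start)
    if (!is.null(ebe_cache)) ebe_cache[[key]] <- eb$eta
    lin <- subject_linearization(m, s, eb$eta)
    total <- total + lin$ofv
  }
  total
}

gauss_hermite_rule <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * (e$vectors[1, ord])^2)
}

#' Subject -2 log marginal likelihood by adaptive Gauss-Hermite quadrature
#'
#' Independent oracle for the FOCE-I approximation: integrates the subject
#' likelihood over the random effects by Gauss-Hermite quadrature centred and
#' scaled at the conditional mode. Restricted to at most 2 random-effect
#' dimensions (test scale). Reported on the same scale as [foce_objective]
#' (the n*log(2*pi) observation constant is omitted).
#'
#' @param m a [population_model] with IIV on at most 2 parameters
#' @param s a [subject_record]
#' @param nodes quadrature nodes per dimension (>= 16)
#' @return -2 log marginal likelihood (2*pi observation constant omitted)
#' @export
marginal_likelihood_quadrature <- function(m, s, nodes = 64) {
  payload_quadrature(m, subject_payload(m, s), nodes)
}

payload_quadrature <- function(m, pl, nodes = 64) {
  supp <- omega_support(m$omega)
  d <- length(supp)
  if (d > 2) stop("quadrature oracle supports at most 2 random-effect dimensions",
                  call. = FALSE)
  if (nodes < 16) stop("use at least 16 nodes", call. = FALSE)
  n <- length(pl$y)
  if (d == 0) {
    f <- payload_predict(pl, numeric(7))
    v <- residual_variance(m, pmax(f, 0))
    return(sum(log(v) + (pl$y - f)^2 / v))
  }
  Om <- m$omega[supp, supp, drop = FALSE]
  oinv <- solve(Om)
  ldet_om <- as.numeric(determinant(Om, logarithm = TRUE)$modulus)
  log_joint <- function(eta_s) {
    eta <- numeric(7)
    eta[supp] <- eta_s
    f <- payload_predict(pl, eta)
    v <- pmax(residual_variance(m, pmax(f, 0)), 1e-290)
    -0.5 * (sum(log(2 * pi * v) + (pl$y - f)^2 / v) +
              d * log(2 * pi) + ldet_om + drop(eta_s %*% oinv %*% eta_s))
  }
  eb <- estimate_ebes_payload(m, pl)
  mode <- eb$eta[supp]
  # FD Hessian of -log joint at the mode
  h <- 1e-3
  H <- matrix(0, d, d)
  f0 <- log_joint(mode)
  for (a in seq_len(d)) {
    for (b in a:d) {
      ea <- numeric(d); ea[a] <- h
      eb2 <- numeric(d); eb2[b] <- h
      H[a, b] <- H[b, a] <- -(log_joint(mode + ea + eb2) -
                                log_joint(mode + ea - eb2) -
                                log_joint(mode - ea + eb2) +
                                log_joint(mode - ea - eb2)) / (4 * h * h)
    }
  }
  S <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  Ru <- chol((S + t(S)) / 2)
  rule <- gauss_hermite_rule(nodes)
  grid <- do.call(expand.grid, rep(list(seq_len(nodes)), d))
  lw <- log(rule$w)
  acc <- vapply(seq_len(nrow(grid)), function(k) {
    idx <- as.integer(grid[k, ])
    x <- rule$x[idx]
    eta_k <- mode + sqrt(2) * drop(t(Ru) %*% x)
    log_joint(eta_k) - f0 + sum(x^2) + sum(lw[idx])
  }, 0)
  log_jac <- (d / 2) * log(2) + sum(log(diag(Ru)))
  log_int <- f0 + log(sum(exp(acc - max(acc)))) + max(acc) + log_jac
  -2 * log_int - n * log(2 * pi)
}
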