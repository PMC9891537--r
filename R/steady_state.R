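#' Effective degradation rates under trans exposure
#'
#' `beta1 = beta + k_t * N_ext` is the effective clearance of ligand monomer
#' (degradation plus loss into trans complexes with neighbouring receptors);
#' `beta2 = beta + k_t * L_ext` is the analogous effective clearance of the
#' receptor.
#'
#' @inheritParams rhs_general
#' @return named numeric vector `(beta1, beta2)` in 1/hour.
#' @export
effective_rates <- function(p, ext = external_signal()) {
  c(beta1 = p$beta + p$k_t * ext[[3]],
    beta2 = p$beta + p$k_t * ext[[1]])
}

# stable "+" root of x^2 - 2 B x - C = 0 (C >= 0): x = B + sqrt(B^2 + C)
.plus_root <- function(B, C) {
  if (B > 0) B + sqrt(B^2 + C) else C / (sqrt(B^2 + C) - B)
}

#' Closed-form steady state of the mutual-inactivation model
#'
#' Solves the monomer-only model analytically. The ligand steady state is the
#' positive root of a quadratic balance,
#' `L = B + sqrt(B^2 + beta2 b_L / (beta1 k_ci))` with
#' `B = (b_L - b_N)/(2 beta1) - beta2/(2 k_ci)`, the receptor follows from the
#' production balance `N = b_N / (beta2 + k_ci L)` (algebraically equal to
#' `(beta1 L - (b_L - b_N))/beta2` but immune to cancellation when `N` is
#' small), and `S = k_t N L_ext / beta_S`.
#'
#' @inheritParams rhs_general
#' @return named numeric vector `(L, N, S)` satisfying [rhs_mi()] = 0.
#' @export
mi_steady_state <- function(p = notch_params(), ext = external_signal()) {
  validate_params(p); check_nonneg(ext, "external signal")
  if (p$k_ci <= 0)
    stop("mi_steady_state() requires k_ci > 0; with no cis-inhibition the ",
         "model is linear with L = b_L/beta1, N = b_N/beta2", call. = FALSE)
  er <- effective_rates(p, ext)
  b1 <- er[[1]]; b2 <- er[[2]]
  B <- (p$b_L - p$b_N) / (2 * b1) - b2 / (2 * p$k_ci)
  L <- .plus_root(B, b2 * p$b_L / (b1 * p$k_ci))
  N <- p$b_N / (b2 + p$k_ci * L)
  c(L = L, N = N, S = p$k_t * N * ext[[1]] / p$beta_S)
}

#' Asymptotic sender/receiver branches of the mutual-inactivation model
#'
#' In the strong cis-inhibition limit the MI steady state collapses onto one
#' of two mutually exclusive branches: a "sender" with
#' `L ~ (b_L - b_N)/beta1`, `N ~ 0` when ligand production dominates, or a
#' "receiver" with `L ~ 0`, `N ~ (b_N - b_L)/beta2` when receptor production
#' dominates.
#'
#' @inheritParams rhs_general
#' @return a list with elements `branch` (`"sender"`, `"receiver"` or
#'   `"degenerate"`) and, for the non-degenerate branches, `L` and `N`.
#' @export
mi_asymptotic <- function(p = notch_params(), ext = external_signal()) {
  validate_params(p); check_nonneg(ext, "external signal")
  er <- effective_rates(p, ext)
  if (p$b_L > p$b_N) {
    list(branch = "sender", L = (p$b_L - p$b_N) / er[[1]], N = 0)
  } else if (p$b_L < p$b_N) {
    list(branch = "receiver", L = 0, N = (p$b_N - p$b_L) / er[[2]])
  } else {
    list(branch = "degenerate")
  }
}

#' Closed-form steady state of the ligand-dimerization model T1
#'
#' The monomer equation decouples (monomers are not cis-inhibited), giving
#' `L = sqrt((beta1/(4 k_d))^2 + b_L/(2 k_d)) - beta1/(4 k_d)`; note `L` is
#' independent of the receptor production rate `b_N`. The dimer level is the
#' positive root `Lstar = A + sqrt(A^2 + beta2 k_d L^2 / (beta k_ci))` with
#' `A = (k_d L^2 - b_N)/(2 beta) - beta2/(2 k_ci)`, the receptor follows from
#' `N = b_N / (beta2 + k_ci Lstar)` (equal to
#' `(beta Lstar - (k_d L^2 - b_N))/beta2` in exact arithmetic), and
#' `S = k_t L_ext N / beta_S`.
#'
#' @inheritParams rhs_general
#' @return named numeric vector `(L, Lstar, N, S)` satisfying [rhs_t1()] = 0.
#' @export
t1_steady_state <- function(p = notch_params(), ext = external_signal()) {
  validate_params(p); check_nonneg(ext, "external signal")
  if (p$k_d <= 0)
    stop("t1_steady_state() requires k_d > 0; with no dimerization use ",
         "mi_steady_state()", call. = FALSE)
  if (p$k_ci <= 0)
    stop("t1_steady_state() requires k_ci > 0", call. = FALSE)
  er <- effective_rates(p, ext)
  b1 <- er[[1]]; b2 <- er[[2]]
  a <- b1 / (4 * p$k_d)
  L <- (p$b_L / (2 * p$k_d)) / (sqrt(a^2 + p$b_L / (2 * p$k_d)) + a)
  dim_prod <- p$k_d * L^2
  A <- (dim_prod - p$b_N) / (2 * p$beta) - b2 / (2 * p$k_ci)
  Ls <- if (dim_prod > 0) {
    .plus_root(A, b2 * dim_prod / (p$beta * p$k_ci))
  } else 0
  N <- p$b_N / (b2 + p$k_ci * Ls)
  c(L = L, Lstar = Ls, N = N, S = p$k_t * ext[[1]] * N / p$beta_S)
}

#' High-affinity receptor limit of model T1
#'
#' When the affinity of Notch for ligand dimers is high, the steady-state
#' receptor level approaches 0 if dimer production exceeds receptor production
#' (`b_N < k_d L^2`), and `(b_N - k_d L^2)/beta2` otherwise, with `L` the
#' closed-form monomer steady state. Unlike the mutual-inactivation model this
#' limit allows high receptor and high ligand monomer to coexist.
#'
#' @inheritParams rhs_general
#' @return approximate steady-state receptor level (molecules).
#' @export
t1_receptor_limit <- function(p = notch_params(), ext = external_signal()) {
  validate_params(p); check_nonneg(ext, "external signal")
  ss <- t1_steady_state(p, ext)
  excess <- p$b_N - p$k_d * ss[["L"]]^2
  if (excess < 0) 0 else excess / effective_rates(p, ext)[[2]]
}

#' Numeric fixed point of any model right-hand side
#'
#' Validation oracle for the closed-form steady states and general-purpose
#' steady-state solver for the configurations without a closed form. The
#' system is integrated until the maximum relative state change over a
#' trailing window falls below `tol`, then polished by damped Newton iteration
#' on the algebraic system `rhs = 0` with a finite-difference Jacobian. The
#' returned state has residual below `1e-8 * max(b_L, b_N, 1)`.
#'
#' @param rhs a model right-hand side: `function(state, ext, p)`, e.g.
#'   [rhs_t1()] or any of the other `rhs_*` functions (their internal cores
#'   are also accepted).
#' @param p model parameters.
#' @param ext external signal (ignored by RHS functions that take none).
#' @param init initial state (named vector matching the RHS).
#' @param tol relative-change convergence tolerance of the integration phase.
#' @param window trailing window (hours) over which the change is measured.
#' @param t_max integration horizon after which non-convergence is an error.
#' @return steady state as a named numeric vector, with attributes `residual`
#'   (max absolute RHS component) and `t` (integration time used).
#' @export
steady_state_numeric <- function(rhs, p = notch_params(),
                                 ext = external_signal(), init,
                                 tol = 1e-8, window = 10, t_max = 1e5) {
  validate_params(p)
  f <- function(y) rhs(y, ext, p)
  y <- as.numeric(init)
  nm <- names(init)
  scale <- max(p$b_L, p$b_N, 1)
  # integration phase: chunks sized to the slowest clearance time scale
  chunk <- max(5 * window, 10 / p$beta)
  t <- 0
  converged <- FALSE
  dfun <- function(t, y, parms) list(f(pmax(y, 0)))
  while (t < t_max) {
    t_end <- min(t + chunk, t_max)
    times <- c(t, t_end - window, t_end)
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = times, func = dfun, parms = NULL,
                   method = "lsoda", rtol = 1e-10, atol = 1e-10 * scale,
                   maxsteps = 50000))
    got_all <- nrow(sol) == length(times)
    y_mid <- pmax(sol[max(nrow(sol) - 1, 1), -1], 0)
    y <- pmax(sol[nrow(sol), -1], 0)
    t <- sol[nrow(sol), 1]
    if (got_all) {
      delta <- max(abs(y - y_mid) / pmax(abs(y), tol * scale))
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  y <- .newton_polish(f, y, scale)
  res <- max(abs(f(y)))
  if (!converged && res > 1e-8 * scale) {
    cond <- simpleError(sprintf(
      "steady_state_numeric() did not converge within t_max = %g h (residual %.3g)",
      t_max, res))
    cond$state <- y; cond$residual <- res
    stop(cond)
  }
  names(y) <- nm
  structure(y, residual = res, t = t)
}

# damped Newton with forward-difference Jacobian; state kept non-negative
.newton_polish <- function(f, y, scale, max_iter = 60, tol_res = NULL) {
  if (is.null(tol_res)) tol_res <- 1e-11 * scale
  n <- length(y)
  res <- f(y)
  for (it in seq_len(max_iter)) {
    if (max(abs(res)) < tol_res) break
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(abs(y[j]), 1e-3 * scale)
      yj <- y; yj[j] <- yj[j] + h
      J[, j] <- (f(yj) - res) / h
    }
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      y_new <- pmax(y + lambda * step, 0)
      res_new <- f(y_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(res_new)) >= max(abs(res))) break
    y <- y_new; res <- res_new
  }
  y
}
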