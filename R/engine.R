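#' Integrate a model over time
#'
#' Adaptive explicit Runge-Kutta integration (Dormand-Prince 4(5) via
#' \pkg{deSolve}) of any of the package's model right-hand sides, with dense
#' output sampled on `times`. Tolerances default to a relative tolerance of
#' 1e-8 and an absolute tolerance of 1e-10; tiny negative solver excursions
#' (within 100 times the absolute tolerance) are clamped to zero, anything
#' more negative is an error.
#'
#' @param rhs a model right-hand side, `function(state, ext, p)`.
#' @param init initial state (named non-negative vector).
#' @param times output time grid (hours, non-decreasing).
#' @param ext external signal held constant over the run.
#' @param p model parameters.
#' @param rtol,atol solver tolerances.
#' @param method \pkg{deSolve} method; `"ode45"` by default, `"lsoda"` is a
#'   faster choice for stiff or large systems.
#' @return a `notch_trajectory`: a data frame with column `time` followed by
#'   the state components, with the model parameters attached as attribute
#'   `params`.
#' @examples
#' tr <- simulate_cell(rhs_t1, cell_state(), seq(0, 100, by = 1))
#' tail(tr, 1)
#' @export
simulate_cell <- function(rhs, init, times, ext = external_signal(),
                          p = notch_params(), rtol = 1e-8, atol = 1e-10,
                          method = "ode45") {
  check_nonneg(init, "initial state")
  validate_params(p)
  if (any(diff(times) < 0)) stop("'times' must be non-decreasing")
  if (length(times) == 1L) {
    out <- data.frame(time = times, as.list(init))
  } else {
    dfun <- function(t, y, parms) list(rhs(pmax(y, 0), ext, p))
    sol <- deSolve::ode(y = init, times = times, func = dfun, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    states <- unclass(sol)[, -1, drop = FALSE]
    if (min(states) < -100 * atol)
      stop("integration produced a negative excursion beyond tolerance (min ",
           signif(min(states), 4), ")", call. = FALSE)
    states[states < 0] <- 0
    out <- data.frame(time = sol[, 1], states)
  }
  names(out) <- c("time", names(init))
  structure(out, params = p, class = c("notch_trajectory", "data.frame"))
}

#' Normalize activity values against their maximum
#'
#' @param values numeric vector with at least one positive entry.
#' @return `values / max(values)`, so the maximum is 1.
#' @export
normalize_activity <- function(values) {
  check_nonneg(values, "activity values")
  m <- max(values)
  if (m <= 0) stop("cannot normalize: all activity values are zero",
                   call. = FALSE)
  values / m
}

# assemble a sweep_result data frame
.sweep_result <- function(param, values, S, states = NULL,
                          normalized = FALSE) {
  out <- data.frame(values, S = S)
  names(out)[1] <- param
  if (normalized) out$S_normalized <- normalize_activity(S)
  structure(out, states = states, swept = param,
            class = c("sweep_result", "data.frame"))
}

# steady state of a single receiving cell under a general-model configuration
.receiving_steady <- function(p, ext) {
  init <- cell_state(N = p$b_N / p$beta)
  steady_state_numeric(.rhs_general, p, ext, init)
}

#' Steady-state Notch activity versus ligand production rate
#'
#' Dose-response of steady-state Notch activity (free intracellular domain
#' `S`) to ligand production. In `mode = "cis"` the receiving cell's own
#' ligand production `b_L` is swept while the cell is exposed to a fixed
#' trans-ligand level (1500 molecules by default); the cis-inhibition
#' configuration is chosen by `cis` (dimer-mediated `"C1"`, monomer-mediated
#' `"C2"`, or both `"C3"`). In `mode = "trans"` the sending cell's `b_L` is
#' swept: sender and receiver are solved as a coupled two-cell system so the
#' trans-ligand seen by the receiver is the sender's own steady-state ligand
#' level; the trans-activation configuration is chosen by `trans`
#' (monomer-mediated `"T1"`, dimer-mediated `"T2"`, or both `"T3"`).
#'
#' @param p model parameters (receiving cell; in trans mode also the template
#'   for the sending cell).
#' @param b_L_grid swept ligand production rates (molecules/hour).
#' @param mode `"cis"` or `"trans"`.
#' @param cis,trans cis-inhibition / trans-activation configuration, see
#'   [set_interactions()].
#' @param L_ext,N_ext fixed trans levels seen by the receiving cell in cis
#'   mode.
#' @param receiver_b_L fixed ligand production of the receiving cell in trans
#'   mode.
#' @param normalize add an `S_normalized` column.
#' @return a `sweep_result` data frame with columns `b_L`, `S` (and
#'   optionally `S_normalized`).
#' @export
production_sweep <- function(p = notch_params(), b_L_grid,
                             mode = c("cis", "trans"),
                             cis = "C1", trans = "T1",
                             L_ext = 1500, N_ext = 0,
                             receiver_b_L = p$b_L, normalize = FALSE) {
  mode <- match.arg(mode)
  check_nonneg(b_L_grid, "b_L grid")
  if (length(b_L_grid) == 0) stop("'b_L_grid' must be non-empty")
  if (mode == "cis") {
    pc <- set_interactions(p, cis = cis, trans = trans)
    ext <- external_signal(L_ext = L_ext, N_ext = N_ext)
    S <- vapply(b_L_grid, function(b) {
      pc$b_L <- b
      .receiving_steady(pc, ext)[["S"]]
    }, numeric(1))
  } else {
    pc <- set_interactions(p, cis = cis, trans = trans)
    S <- vapply(b_L_grid, function(b) {
      sender <- pc; sender$b_L <- b
      receiver <- pc; receiver$b_L <- receiver_b_L
      two_cell_steady_state(sender, receiver)$cell2[["S"]]
    }, numeric(1))
  }
  .sweep_result("b_L", b_L_grid, S, normalized = normalize)
}

#' Steady-state Notch activity versus ligand dimerization rate
#'
#' Companion sweep to [production_sweep()] at a high, fixed ligand production
#' rate (the maximum of the companion production grid): the dimerization rate
#' of the cis ligand (`mode = "cis"`) or of the sending cell's ligand
#' (`mode = "trans"`) is varied. Under dimer-mediated cis-inhibition ("C1"),
#' Notch activity recovers as `k_d` drops to zero (dimer-deficient ligand
#' cannot cis-inhibit); under monomer-mediated cis-inhibition ("C2") it stays
#' suppressed.
#'
#' @inheritParams production_sweep
#' @param k_d_grid swept dimerization rates.
#' @param b_L fixed ligand production rate (cis mode: receiving cell; trans
#'   mode: sending cell).
#' @return a `sweep_result` data frame with columns `k_d`, `S`.
#' @export
dimerization_sweep <- function(p = notch_params(), k_d_grid, b_L,
                               mode = c("cis", "trans"),
                               cis = "C1", trans = "T1",
                               L_ext = 1500, N_ext = 0,
                               receiver_b_L = p$b_L, normalize = FALSE) {
  mode <- match.arg(mode)
  check_nonneg(k_d_grid, "k_d grid")
  pc <- set_interactions(p, cis = cis, trans = trans)
  if (mode == "cis") {
    ext <- external_signal(L_ext = L_ext, N_ext = N_ext)
    pc$b_L <- b_L
    S <- vapply(k_d_grid, function(kd) {
      pc$k_d <- kd
      .receiving_steady(pc, ext)[["S"]]
    }, numeric(1))
  } else {
    S <- vapply(k_d_grid, function(kd) {
      sender <- pc; sender$b_L <- b_L; sender$k_d <- kd
      receiver <- pc; receiver$b_L <- receiver_b_L
      two_cell_steady_state(sender, receiver)$cell2[["S"]]
    }, numeric(1))
  }
  .sweep_result("k_d", k_d_grid, S, normalized = normalize)
}

#' Steady state of two coupled cells
#'
#' Integrates the coupled eight-dimensional system of two adjacent cells under
#' the general model, where each cell's trans input is the other cell's
#' current ligand (and, when dimer trans-activation is active, dimer) and
#' receptor level, then polishes to a fixed point. Cell 1 is conventionally
#' the "sender" and cell 2 the "receiver", but the system is symmetric: with
#' identical parameters and initial conditions both cells remain identical.
#'
#' @param p1,p2 `notch_params` for cell 1 and cell 2 (interaction rates
#'   `k1..k6` as wired, e.g. via [set_interactions()]).
#' @param init1,init2 optional initial states.
#' @return list with named state vectors `cell1` and `cell2` and the
#'   attribute-carried residual.
#' @export
two_cell_steady_state <- function(p1, p2 = p1,
                                  init1 = NULL, init2 = NULL) {
  validate_params(p1); validate_params(p2)
  if (is.null(init1)) init1 <- cell_state(
                                          N = p1$b_N / p1$beta)
  if (is.null(init2)) init2 <- cell_state(
                                          N = p2$b_N / p2$beta)
  rhs <- function(y, ext, p) {
    y1 <- y[1:4]; y2 <- y[5:8]
    e1 <- c(y2[1], y2[2], y2[3])
    e2 <- c(y1[1], y1[2], y1[3])
    c(.rhs_general(y1, e1, p1), .rhs_general(y2, e2, p2))
  }
  init <- c(init1, init2)
  scale <- max(p1$b_L, p1$b_N, p2$b_L, p2$b_N, 1)
  ss <- steady_state_numeric(rhs, p1, external_signal(), init)
  list(cell1 = stats::setNames(ss[1:4], names(init1)),
       cell2 = stats::setNames(ss[5:8], names(init2)),
       residual = attr(ss, "residual"))
}

#' Notch activity of two identical coupled cells versus ligand production
#'
#' Sweeps the common ligand production rate of two identical, mutually
#' signalling cells and reports the (normalized) steady-state Notch activity.
#' Under model T1 (monomer trans-activation) higher ligand expression
#' eventually elicits stronger dimer cis-inhibition, so the normalized curve
#' rises to an interior peak and falls; under T3 (monomer and dimer
#' trans-activation) activity does not collapse at high production.
#'
#' @inheritParams production_sweep
#' @param trans trans-activation configuration, `"T1"` or `"T3"`.
#' @return a `sweep_result` with columns `b_L`, `S`, `S_normalized`.
#' @export
two_cell_sweep <- function(p = notch_params(), b_L_grid, trans = "T1",
                           cis = "C1") {
  check_nonneg(b_L_grid, "b_L grid")
  pc <- set_interactions(p, cis = cis, trans = trans)
  S <- vapply(b_L_grid, function(b) {
    pc$b_L <- b
    two_cell_steady_state(pc, pc)$cell1[["S"]]
  }, numeric(1))
  .sweep_result("b_L", b_L_grid, S, normalized = TRUE)
}

#' Cis-activation dose-response in an isolated cell
#'
#' Steady-state Notch activity versus ligand production in a cell without
#' cell-cell contact (all external levels zero), under one of the three
#' cis-activation scenarios: monomer-mediated (1), dimer-mediated (2), or both
#' (3). Ligand dimers cis-inhibit in every scenario. Scenario 1 produces the
#' characteristic non-monotonic (rise-then-fall) response.
#'
#' @param scenario cis-activation scenario, 1, 2 or 3.
#' @inheritParams production_sweep
#' @param k_ca,k_d,k_ci optional overrides of the cis-activation,
#'   dimerization and cis-inhibition rates.
#' @return a `sweep_result` with columns `b_L`, `S`.
#' @export
cis_activation_sweep <- function(scenario = 1, p = notch_params(), b_L_grid,
                                 k_ca = p$k_ca, k_d = p$k_d, k_ci = p$k_ci,
                                 normalize = FALSE) {
  if (!scenario %in% 1:3)
    stop("cis-activation 'scenario' must be 1, 2 or 3", call. = FALSE)
  check_nonneg(b_L_grid, "b_L grid")
  p$k_ca <- k_ca; p$k_d <- k_d; p$k_ci <- k_ci
  validate_params(p)
  k5 <- if (scenario %in% c(1, 3)) k_ca else 0
  k6 <- if (scenario %in% c(2, 3)) k_ca else 0
  rhs <- function(y, ext, pp) .rhs_cis_activation(y, pp, k5, k6)
  S <- vapply(b_L_grid, function(b) {
    p$b_L <- b
    init <- cell_state(N = p$b_N / p$beta)
    steady_state_numeric(rhs, p, external_signal(), init)[["S"]]
  }, numeric(1))
  .sweep_result("b_L", b_L_grid, S, normalized = normalize)
}

#' Cis-inhibition relief dynamics from a dimer-loaded initial state
#'
#' Time course of model T1 for a cell pre-loaded with ligand (mostly dimers)
#' whose ligand production is switched off, under constant trans-ligand
#' exposure: Notch activity shows a delayed onset while the decaying dimer
#' pool titrates newly made receptor, then rises to the ligand-free steady
#' state.
#'
#' @param p model parameters; `b_L` is forced to 0.
#' @param times output grid (hours).
#' @param init initial state, by default `(L, Lstar, N, S) = (500, 9500, 0,
#'   0)` molecules.
#' @param L_ext constant trans-ligand exposure (molecules).
#' @return a `notch_trajectory`.
#' @export
cis_inhibition_dynamics <- function(p = notch_params(),
                                    times = seq(0, 100, by = 0.5),
                                    init = cell_state(L = 500, Lstar = 9500),
                                    L_ext = 1500) {
  p$b_L <- 0
  simulate_cell(rhs_t1, init, times, external_signal(L_ext = L_ext), p)
}

#' Notch response across ligand oligomer sizes
#'
#' Normalized steady-state Notch activity versus ligand production for a
#' homogeneous oligomer population of size `n`, in one of three settings:
#' `"fixed_trans"` (single cell exposed to a fixed trans-ligand level),
#' `"two_cell"` (two identical coupled cells) or `"single_cell"` (isolated
#' cell, cis-activation active). Cis-activation is ignored whenever trans
#' ligand is present, so `k_ca` only acts in the `"single_cell"` setting.
#'
#' @param setting one of `"fixed_trans"`, `"two_cell"`, `"single_cell"`.
#' @param n oligomer size (>= 2).
#' @inheritParams production_sweep
#' @return a `sweep_result` with columns `b_L`, `S`, `S_normalized`.
#' @export
oligomer_sweep <- function(setting = c("fixed_trans", "two_cell",
                                       "single_cell"),
                           n = 2, p = notch_params(), b_L_grid,
                           L_ext = 1500) {
  setting <- match.arg(setting)
  check_nonneg(b_L_grid, "b_L grid")
  p$n <- as.integer(n)
  validate_params(p)
  p_off <- p
  S <- switch(setting,
    fixed_trans = {
      p_off$k_ca <- 0  # trans present: cis-activation ignored
      ext <- external_signal(L_ext = L_ext)
      vapply(b_L_grid, function(b) {
        p_off$b_L <- b
        init <- cell_state(N = p$b_N / p$beta)
        steady_state_numeric(.rhs_oligomer, p_off, ext, init)[["S"]]
      }, numeric(1))
    },
    two_cell = {
      p_off$k_ca <- 0
      vapply(b_L_grid, function(b) {
        p_off$b_L <- b
        init <- cell_state(N = p$b_N / p$beta)
        rhs <- function(y, ext, pp) {
          y1 <- y[1:4]; y2 <- y[5:8]
          c(.rhs_oligomer(y1, c(y2[1], y2[2], y2[3]), p_off),
            .rhs_oligomer(y2, c(y1[1], y1[2], y1[3]), p_off))
        }
        ss <- steady_state_numeric(rhs, p_off, external_signal(),
                                   c(init, init))
        ss[[4]]
      }, numeric(1))
    },
    single_cell = {
      ext <- external_signal()
      vapply(b_L_grid, function(b) {
        p$b_L <- b
        init <- cell_state(N = p$b_N / p$beta)
        steady_state_numeric(.rhs_oligomer, p, ext, init)[["S"]]
      }, numeric(1))
    })
  .sweep_result("b_L", b_L_grid, S, normalized = TRUE)
}

#' Notch response under cytoplasmic versus homogeneous cis-inhibition
#'
#' Compares the subcellular-compartment model (dimerization and dimer
#' cis-inhibition confined to the cytoplasm, trans- and cis-activation at the
#' membrane, transport at `k_r`) with the spatially homogeneous
#' oligomerization model at matched parameters, as steady-state Notch
#' activity versus ligand production.
#'
#' @param localization `"cytoplasmic"` (compartment model) or
#'   `"homogeneous"`.
#' @inheritParams oligomer_sweep
#' @return a `sweep_result` with columns `b_L`, `S`, `S_normalized`.
#' @export
compartment_sweep <- function(setting = c("fixed_trans", "two_cell",
                                          "single_cell"),
                              localization = c("cytoplasmic", "homogeneous"),
                              p = notch_params(), b_L_grid, L_ext = 1500) {
  setting <- match.arg(setting)
  localization <- match.arg(localization)
  if (localization == "homogeneous")
    return(oligomer_sweep(setting, n = 2, p = p, b_L_grid = b_L_grid,
                          L_ext = L_ext))
  check_nonneg(b_L_grid, "b_L grid")
  validate_params(p)
  p_off <- p
  single <- function(pp, ext) {
    init <- compartment_state(N_c = pp$b_N / pp$beta)
    steady_state_numeric(.rhs_compartment, pp, ext, init)[["S"]]
  }
  S <- switch(setting,
    fixed_trans = {
      p_off$k_ca <- 0
      ext <- external_signal(L_ext = L_ext)
      vapply(b_L_grid, function(b) { p_off$b_L <- b; single(p_off, ext) },
             numeric(1))
    },
    two_cell = {
      p_off$k_ca <- 0
      vapply(b_L_grid, function(b) {
        p_off$b_L <- b
        init <- compartment_state(N_c = p$b_N / p$beta)
        rhs <- function(y, ext, pp) {
          y1 <- y[1:6]; y2 <- y[7:12]
          # trans exposure is the neighbour's membrane ligand/receptor
          c(.rhs_compartment(y1, c(y2[4], 0, y2[5]), p_off),
            .rhs_compartment(y2, c(y1[4], 0, y1[5]), p_off))
        }
        ss <- steady_state_numeric(rhs, p_off, external_signal(),
                                   c(init, init))
        ss[[6]]
      }, numeric(1))
    },
    single_cell = {
      ext <- external_signal()
      vapply(b_L_grid, function(b) { p$b_L <- b; single(p, ext) },
             numeric(1))
    })
  .sweep_result("b_L", b_L_grid, S, normalized = TRUE)
}
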