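#' Steady-state Notch activity in one of the three reference settings
#'
#' The three experimental settings used throughout the single-cell analyses:
#' a cell with dimer-mediated cis-inhibition exposed to a fixed trans-ligand
#' level (`"fixed_trans"`, model T1, `L_ext = 1500`), two identical coupled
#' cells (`"two_cell"`, model T1), and an isolated cell with monomer
#' cis-activation (`"single_cell"`, cis-activation scenario 1, no contact).
#'
#' @param setting one of `"fixed_trans"`, `"two_cell"`, `"single_cell"`.
#' @param p model parameters.
#' @param L_ext fixed trans-ligand level for `"fixed_trans"`.
#' @return steady-state Notch activity (molecules of free intracellular
#'   domain).
#' @export
setting_activity <- function(setting = c("fixed_trans", "two_cell",
                                         "single_cell"),
                             p = notch_params(), L_ext = 1500) {
  setting <- match.arg(setting)
  switch(setting,
    fixed_trans = {
      pc <- set_interactions(p, cis = "C1", trans = "T1")
      .receiving_steady(pc, external_signal(L_ext = L_ext))[["S"]]
    },
    two_cell = {
      pc <- set_interactions(p, cis = "C1", trans = "T1")
      two_cell_steady_state(pc, pc)$cell1[["S"]]
    },
    single_cell = {
      rhs <- function(y, ext, pp) .rhs_cis_activation(y, pp, pp$k_ca, 0)
      init <- cell_state(N = p$b_N / p$beta)
      steady_state_numeric(rhs, p, external_signal(), init)[["S"]]
    })
}

#' Local parameter-sensitivity scan of steady-state Notch activity
#'
#' One-at-a-time perturbation of each parameter over a log-symmetric
#' fold-change grid, in each of the three reference settings (see
#' [setting_activity()]). For each parameter a summary sensitivity index
#' `|d log S / d log theta|` is estimated by a central difference at fold 1
#' (evaluations at 0.95x and 1.05x the baseline). Parameters a setting does
#' not use (e.g. the trans-activation rate in the contact-free single-cell
#' setting) get an index of 0; a baseline activity of 0 makes the index
#' undefined (`NA`) for that setting.
#'
#' @param settings settings to scan.
#' @param parameters parameter names to perturb.
#' @param fold_grid multiplicative fold changes; must include 1.
#' @param p baseline parameters.
#' @return a `sensitivity_report`: a long data frame with columns `setting`,
#'   `parameter`, `fold`, `S`, and an `index` attribute (data frame with
#'   columns `setting`, `parameter`, `index`).
#' @export
sensitivity_scan <- function(settings = c("fixed_trans", "two_cell",
                                          "single_cell"),
                             parameters = c("b_L", "b_N", "k_d", "k_t",
                                            "k_ci", "k_ca", "beta",
                                            "beta_S"),
                             fold_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                             p = notch_params()) {
  stopifnot(all(fold_grid > 0), 1 %in% fold_grid)
  eval_S <- function(setting, param, fold) {
    pp <- p
    pp[[param]] <- pp[[param]] * fold
    setting_activity(setting, pp)
  }
  rows <- list(); idx <- list()
  for (setting in settings) {
    base_S <- setting_activity(setting, p)
    for (param in parameters) {
      S <- vapply(fold_grid, function(f) {
        if (f == 1) base_S else eval_S(setting, param, f)
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(setting = setting, parameter = param,
                   fold = fold_grid, S = S)
      index <- if (base_S <= 0) {
        NA_real_
      } else {
        S_lo <- eval_S(setting, param, 0.95)
        S_hi <- eval_S(setting, param, 1.05)
        if (S_lo <= 0 || S_hi <= 0) NA_real_
        else abs((log(S_hi) - log(S_lo)) / (log(1.05) - log(0.95)))
      }
      idx[[length(idx) + 1L]] <-
        data.frame(setting = setting, parameter = param, index = index)
    }
  }
  structure(do.call(rbind, rows),
            index = do.call(rbind, idx),
            class = c("sensitivity_report", "data.frame"))
}
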