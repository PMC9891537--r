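#' Time derivatives of the general ligand-dimerization model
#'
#' The general model tracks, in one cell, ligand monomers `L`, ligand dimers
#' `Lstar`, Notch receptors `N` and free Notch intracellular domain `S`.
#' Monomers are produced at `b_L`, degraded at `beta`, consumed pairwise by
#' dimerization (`2 k_d L^2`), and lost to trans complexes with neighbouring
#' receptors (`k1 N_ext L`) and to cis complexes (`k3 N L`, `k5 N L`). Dimers
#' gain `k_d L^2` and are lost analogously through `k2`, `k4`, `k6`. The
#' receptor is consumed by every complex it enters, and `S` is produced by the
#' activating interactions only (trans `k1`, `k2`; cis-activation `k5`, `k6`)
#' and degraded at `beta_S`.
#'
#' @param state cell state, see [cell_state()].
#' @param ext external (trans-presented) levels, see [external_signal()].
#' @param p model parameters, see [notch_params()]; the interaction rates used
#'   are `k1..k6`.
#' @return named derivative vector `(L, Lstar, N, S)` in molecules/hour.
#' @export
rhs_general <- function(state, ext = external_signal(), p = notch_params()) {
  check_nonneg(state, "state"); check_nonneg(ext, "external signal")
  validate_params(p)
  .rhs_general(state, ext, p)
}

.rhs_general <- function(y, e, p) {
  L <- y[[1]]; Ls <- y[[2]]; N <- y[[3]]; S <- y[[4]]
  act <- p$k1 * e[[1]] + p$k2 * e[[2]] + p$k5 * L + p$k6 * Ls
  c(L = p$b_L - p$beta * L - 2 * p$k_d * L^2 -
        (p$k1 * e[[3]] + p$k3 * N + p$k5 * N) * L,
    Lstar = p$k_d * L^2 - p$beta * Ls -
        (p$k2 * e[[3]] + p$k4 * N + p$k6 * N) * Ls,
    N = p$b_N - p$beta * N - (act + p$k3 * L + p$k4 * Ls) * N,
    S = act * N - p$beta_S * S)
}

#' Time derivatives of the mutual-inactivation model
#'
#' The monomer-only reduction of the general model (no dimerization,
#' `k_d = 0`): same-cell ligand and receptor titrate each other at `k_ci`
#' while trans ligand activates the receptor at `k_t`. The state has three
#' components `(L, N, S)`.
#'
#' @param state named numeric vector `(L, N, S)`.
#' @inheritParams rhs_general
#' @return named derivative vector `(L, N, S)`.
#' @export
rhs_mi <- function(state, ext = external_signal(), p = notch_params()) {
  check_nonneg(state, "state"); check_nonneg(ext, "external signal")
  validate_params(p)
  .rhs_mi(state, ext, p)
}

.rhs_mi <- function(y, e, p) {
  L <- y[[1]]; N <- y[[2]]; S <- y[[3]]
  c(L = p$b_L - p$beta * L - p$k_t * e[[3]] * L - p$k_ci * N * L,
    N = p$b_N - p$beta * N - p$k_t * e[[1]] * N - p$k_ci * L * N,
    S = p$k_t * N * e[[1]] - p$beta_S * S)
}

#' Time derivatives of the ligand-dimerization model T1
#'
#' The favoured configuration of the general model: ligand monomers
#' trans-activate (`k_t`), ligand dimers cis-inhibit (`k_ci`), and nothing
#' else. Equivalent to [rhs_general()] with `k1 = k_t`, `k4 = k_ci` and
#' `k2 = k3 = k5 = k6 = 0`.
#'
#' @inheritParams rhs_general
#' @return named derivative vector `(L, Lstar, N, S)`.
#' @export
rhs_t1 <- function(state, ext = external_signal(), p = notch_params()) {
  check_nonneg(state, "state"); check_nonneg(ext, "external signal")
  validate_params(p)
  .rhs_t1(state, ext, p)
}

.rhs_t1 <- function(y, e, p) {
  L <- y[[1]]; Ls <- y[[2]]; N <- y[[3]]; S <- y[[4]]
  c(L = p$b_L - p$beta * L - 2 * p$k_d * L^2 - p$k_t * e[[3]] * L,
    Lstar = p$k_d * L^2 - p$beta * Ls - p$k_ci * N * Ls,
    N = p$b_N - p$beta * N - p$k_ci * Ls * N - p$k_t * e[[1]] * N,
    S = p$k_t * e[[1]] * N - p$beta_S * S)
}

#' Time derivatives of the cis-activation scenarios
#'
#' Isolated-cell model (no cell-cell contact, so all external levels are
#' zero) in which ligand dimers cis-inhibit at `k_ci` while cis-activation is
#' carried by monomers (`scenario = 1`), dimers (`scenario = 2`) or both
#' (`scenario = 3`), at rate `k_ca`.
#'
#' @param scenario 1, 2 or 3.
#' @inheritParams rhs_general
#' @return named derivative vector `(L, Lstar, N, S)`.
#' @export
rhs_cis_activation <- function(state, p = notch_params(), scenario = 1) {
  if (!scenario %in% 1:3)
    stop("cis-activation 'scenario' must be 1, 2 or 3", call. = FALSE)
  check_nonneg(state, "state"); validate_params(p)
  k5 <- if (scenario %in% c(1, 3)) p$k_ca else 0
  k6 <- if (scenario %in% c(2, 3)) p$k_ca else 0
  .rhs_cis_activation(state, p, k5, k6)
}

.rhs_cis_activation <- function(y, p, k5, k6) {
  L <- y[[1]]; Ls <- y[[2]]; N <- y[[3]]; S <- y[[4]]
  c(L = p$b_L - p$beta * L - 2 * p$k_d * L^2 - k5 * N * L,
    Lstar = p$k_d * L^2 - p$beta * Ls - p$k_ci * N * Ls - k6 * N * Ls,
    N = p$b_N - p$beta * N - p$k_ci * Ls * N - k5 * L * N - k6 * Ls * N,
    S = k5 * L * N + k6 * Ls * N - p$beta_S * S)
}

#' Time derivatives of the ligand-oligomerization model
#'
#' Extension of model T1 to oligomers of size `n` (a homogeneous population of
#' one defined size): monomers are drained into oligomers at `n k_d L^n`,
#' oligomers gain `k_d L^n`, and monomers additionally cis-activate at `k_ca`.
#' `n = 2` with `k_ca = 0` reproduces model T1 exactly.
#'
#' @inheritParams rhs_general
#' @return named derivative vector `(L, Lstar, N, S)`.
#' @export
rhs_oligomer <- function(state, ext = external_signal(), p = notch_params()) {
  check_nonneg(state, "state"); check_nonneg(ext, "external signal")
  validate_params(p)
  .rhs_oligomer(state, ext, p)
}

.rhs_oligomer <- function(y, e, p) {
  L <- y[[1]]; Ls <- y[[2]]; N <- y[[3]]; S <- y[[4]]
  oligo <- p$k_d * L^p$n
  c(L = p$b_L - p$beta * L - p$n * oligo - p$k_t * e[[3]] * L -
        p$k_ca * N * L,
    Lstar = oligo - p$beta * Ls - p$k_ci * N * Ls,
    N = p$b_N - p$beta * N - p$k_ci * Ls * N - p$k_t * e[[1]] * N -
        p$k_ca * L * N,
    S = p$k_t * e[[1]] * N + p$k_ca * L * N - p$beta_S * S)
}

#' Time derivatives of the cytoplasm/membrane compartment model
#'
#' Ligands and receptors are produced in the cytoplasm, where dimerization and
#' dimer-mediated cis-inhibition take place; non-inhibited monomeric ligand
#' and receptor are transported to the membrane at `k_r`, where
#' trans-activation (`k_t`) and cis-activation (`k_ca`) occur.
#'
#' @param state compartment state, see [compartment_state()].
#' @inheritParams rhs_general
#' @return named derivative vector `(L_c, Lstar, N_c, L_m, N_m, S)`.
#' @export
rhs_compartment <- function(state, ext = external_signal(),
                            p = notch_params()) {
  check_nonneg(state, "state"); check_nonneg(ext, "external signal")
  validate_params(p)
  .rhs_compartment(state, ext, p)
}

.rhs_compartment <- function(y, e, p) {
  Lc <- y[[1]]; Ls <- y[[2]]; Nc <- y[[3]]
  Lm <- y[[4]]; Nm <- y[[5]]; S <- y[[6]]
  c(L_c = p$b_L - p$beta * Lc - 2 * p$k_d * Lc^2 - p$k_r * Lc,
    Lstar = p$k_d * Lc^2 - p$beta * Ls - p$k_ci * Nc * Ls,
    N_c = p$b_N - p$beta * Nc - p$k_ci * Ls * Nc - p$k_r * Nc,
    L_m = p$k_r * Lc - p$beta * Lm - p$k_t * e[[3]] * Lm - p$k_ca * Nm * Lm,
    N_m = p$k_r * Nc - p$beta * Nm - p$k_t * e[[1]] * Nm - p$k_ca * Lm * Nm,
    S = p$k_t * e[[1]] * Nm + p$k_ca * Lm * Nm - p$beta_S * S)
}
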