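#' Model parameters for the Notch ligand-dimerization model family
#'
#' Constructs the full parameter set shared by every model variant. Units are
#' molecules per cell for amounts and hours for time; interaction rates are
#' per-molecule per-hour. The defaults are the baseline simulation values used
#' throughout the package.
#'
#' The general model carries six interaction rates `k1..k6`:
#' trans-activation by external ligand monomers (`k1`) and dimers (`k2`),
#' cis-inhibition by same-cell monomers (`k3`) and dimers (`k4`), and
#' cis-activation by same-cell monomers (`k5`) and dimers (`k6`). The named
#' rates `k_t`, `k_ci` and `k_ca` are convenience aliases: by default the
#' constructor wires them into the favoured "T1" configuration
#' (`k1 = k_t`, `k4 = k_ci`, all other `k` zero, no cis-activation). Use
#' [set_interactions()] to select any other cis/trans/cis-activation
#' configuration, or pass `k1..k6` explicitly to override the wiring.
#'
#' @param b_L ligand production rate (molecules/hour).
#' @param b_N receptor production rate (molecules/hour).
#' @param k_d ligand oligomerization rate (molecules^-(n-1)/hour).
#' @param k_t trans-activation rate (1/molecule/hour).
#' @param k_ci cis-inhibition rate (1/molecule/hour).
#' @param k_ca cis-activation rate (1/molecule/hour).
#' @param beta degradation rate of ligands and receptors (1/hour).
#' @param beta_S degradation rate of free Notch intracellular domain (1/hour).
#' @param k_r cytoplasm-to-membrane transport rate (1/hour), used only by the
#'   subcellular-compartment model.
#' @param n oligomer size (integer >= 2); 2 means dimers.
#' @param k1,k2,k3,k4,k5,k6 optional explicit interaction rates of the general
#'   model; any that are `NULL` are filled from the default T1 wiring.
#' @return An object of class `notch_params` (a named list).
#' @examples
#' p <- notch_params()
#' p$k1 # equals k_t under the default T1 wiring
#' @export
notch_params <- function(b_L = 200, b_N = 200, k_d = 1e-4, k_t = 5e-5,
                         k_ci = 6e-4, k_ca = 5e-6, beta = 0.1, beta_S = 0.5,
                         k_r = 0.1, n = 2L,
                         k1 = NULL, k2 = NULL, k3 = NULL,
                         k4 = NULL, k5 = NULL, k6 = NULL) {
  p <- list(
    b_L = b_L, b_N = b_N, k_d = k_d, k_t = k_t, k_ci = k_ci, k_ca = k_ca,
    beta = beta, beta_S = beta_S, k_r = k_r, n = as.integer(n),
    # default wiring: monomer trans-activation, dimer cis-inhibition (T1)
    k1 = if (is.null(k1)) k_t else k1,
    k2 = if (is.null(k2)) 0 else k2,
    k3 = if (is.null(k3)) 0 else k3,
    k4 = if (is.null(k4)) k_ci else k4,
    k5 = if (is.null(k5)) 0 else k5,
    k6 = if (is.null(k6)) 0 else k6
  )
  class(p) <- "notch_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, strict positivity of the degradation
#' rates and an oligomer size of at least 2. Called by every constructor and
#' right-hand-side function; negative inputs are an error, never clamped.
#'
#' @param p a `notch_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  rates <- c("b_L", "b_N", "k_d", "k_t", "k_ci", "k_ca", "beta", "beta_S",
             "k_r", "k1", "k2", "k3", "k4", "k5", "k6")
  for (r in rates) {
    v <- p[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", r, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", r, "' must be non-negative (got ", v, ")",
           call. = FALSE)
  }
  if (p$beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (p$beta_S <= 0) stop("'beta_S' must be > 0", call. = FALSE)
  if (p$n < 2) stop("oligomer size 'n' must be >= 2", call. = FALSE)
  invisible(p)
}

#' Select a cis/trans/cis-activation configuration of the general model
#'
#' Rewires the `k1..k6` interaction rates of a parameter set from the named
#' rates `k_t`, `k_ci`, `k_ca` according to the standard model configurations:
#'
#' * cis-inhibition: `"C1"` dimers only (`k3 = 0, k4 = k_ci`), `"C2"` monomers
#'   only (`k3 = k_ci, k4 = 0`), `"C3"` both, `"none"` neither.
#' * trans-activation: `"T1"` monomers only (`k1 = k_t, k2 = 0`), `"T2"` dimers
#'   only, `"T3"` both, `"none"` neither.
#' * cis-activation scenario: `"1"` monomers (`k5 = k_ca, k6 = 0`), `"2"`
#'   dimers, `"3"` both, `"none"` neither (the default; cis-activation is
#'   always ignored when trans-presented ligand is present).
#'
#' @param p a `notch_params` object.
#' @param cis cis-inhibition configuration.
#' @param trans trans-activation configuration.
#' @param cis_activation cis-activation scenario.
#' @return the rewired `notch_params` object.
#' @export
set_interactions <- function(p, cis = c("C1", "C2", "C3", "none"),
                             trans = c("T1", "T2", "T3", "none"),
                             cis_activation = c("none", "1", "2", "3")) {
  cis <- match.arg(cis)
  trans <- match.arg(trans)
  cis_activation <- match.arg(as.character(cis_activation),
                              c("none", "1", "2", "3"))
  p[c("k3", "k4")] <- switch(cis,
    C1 = list(0, p$k_ci), C2 = list(p$k_ci, 0),
    C3 = list(p$k_ci, p$k_ci), none = list(0, 0))
  p[c("k1", "k2")] <- switch(trans,
    T1 = list(p$k_t, 0), T2 = list(0, p$k_t),
    T3 = list(p$k_t, p$k_t), none = list(0, 0))
  p[c("k5", "k6")] <- switch(cis_activation,
    none = list(0, 0), `1` = list(p$k_ca, 0),
    `2` = list(0, p$k_ca), `3` = list(p$k_ca, p$k_ca))
  validate_params(p)
  p
}

#' @export
print.notch_params <- function(x, ...) {
  cat("Notch model parameters (molecules, hours):\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 7), " = ",
             format(flat, digits = 6)), sep = "\n")
  invisible(x)
}

#' @export
as.list.notch_params <- function(x, ...) unclass(x)

#' Cell state of the single-compartment models
#'
#' @param L ligand monomer count.
#' @param Lstar ligand dimer/oligomer count.
#' @param N receptor count.
#' @param S free Notch intracellular domain count.
#' @return named numeric vector `(L, Lstar, N, S)`.
#' @export
cell_state <- function(L = 0, Lstar = 0, N = 0, S = 0) {
  s <- c(L = L, Lstar = Lstar, N = N, S = S)
  check_nonneg(s, "state")
  s
}

#' Cell state of the cytoplasm/membrane compartment model
#'
#' @param L_c,Lstar,N_c cytoplasmic ligand monomer, ligand dimer and receptor.
#' @param L_m,N_m membrane ligand monomer and receptor.
#' @param S free Notch intracellular domain.
#' @return named numeric vector of length 6.
#' @export
compartment_state <- function(L_c = 0, Lstar = 0, N_c = 0,
                              L_m = 0, N_m = 0, S = 0) {
  s <- c(L_c = L_c, Lstar = Lstar, N_c = N_c, L_m = L_m, N_m = N_m, S = S)
  check_nonneg(s, "state")
  s
}

#' Trans-presented external signal seen by one cell
#'
#' @param L_ext trans ligand monomer level.
#' @param Lstar_ext trans ligand dimer level.
#' @param N_ext trans receptor level.
#' @return named numeric vector `(L_ext, Lstar_ext, N_ext)`.
#' @export
external_signal <- function(L_ext = 0, Lstar_ext = 0, N_ext = 0) {
  e <- c(L_ext = L_ext, Lstar_ext = Lstar_ext, N_ext = N_ext)
  check_nonneg(e, "external signal")
  e
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x))
    stop(what, " must be numeric and finite", call. = FALSE)
  if (any(x < 0))
    stop(what, " must be non-negative (got ",
         paste(signif(x[x < 0], 4), collapse = ", "), ")", call. = FALSE)
  invisible(x)
}
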