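#' Define a ligand species for tissue simulations
#'
#' A tissue carries one or more ligand species (e.g. Delta and Serrate), each
#' with its own per-cell production field, kinetic rates and a Fringe gating
#' rule saying which compartments' Notch it can trans-activate. Gating is
#' binary: in the wing disc, Fringe glycosylation of dorsal Notch means Notch
#' in dorsal cells can only be trans-activated by Delta, and Notch in ventral
#' cells only by Serrate.
#'
#' @param name species name (e.g. `"Delta"`).
#' @param b_L per-cell production field: a rows x cols matrix, or a scalar
#'   recycled over the grid (molecules/hour).
#' @param activates compartments whose Notch this species can trans-activate;
#'   a character vector drawn from the tissue's compartment labels, or
#'   `"all"`.
#' @param k_d,k_t,k_ci species kinetic rates (defaults: baseline values).
#' @return an object of class `ligand_species`.
#' @export
ligand_species <- function(name, b_L, activates = "all",
                           k_d = 1e-4, k_t = 5e-5, k_ci = 6e-4) {
  stopifnot(is.character(name), length(name) == 1L)
  check_nonneg(c(k_d = k_d, k_t = k_t, k_ci = k_ci), "species rates")
  structure(list(name = name, b_L = b_L, activates = activates,
                 k_d = k_d, k_t = k_t, k_ci = k_ci),
            class = "ligand_species")
}

# neighbour index lists for the supported grid topologies (1-based matrix
# indexing, column-major like R matrices; hex uses odd-row offset coordinates)
.neighbor_offsets <- function(topology, row) {
  switch(topology,
    von_neumann = list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
    moore = list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)),
    hex = if (row %% 2 == 1) {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(1, -1))
    } else {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, 1), c(1, 1))
    },
    stop("unknown topology '", topology, "'"))
}

# row-normalized neighbour-averaging matrix (cells indexed column-major)
.neighbor_matrix <- function(rows, cols, topology) {
  idx <- function(r, c) (c - 1L) * rows + r
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) {
    offs <- .neighbor_offsets(topology, r)
    for (c in seq_len(cols)) {
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols) {
          from <- c(from, idx(r, c)); to <- c(to, idx(rr, cc))
        }
      }
    }
  }
  W <- Matrix::sparseMatrix(i = from, j = to, x = 1,
                            dims = c(rows * cols, rows * cols))
  deg <- Matrix::rowSums(W)
  if (any(deg == 0)) stop("every cell must have at least one neighbor")
  W / deg
}

#' Construct a tissue (cell lattice)
#'
#' A rectangular grid of cells, each running the ligand-dimerization (T1) or
#' mutual-inactivation dynamics with one or more ligand species. The
#' trans-ligand seen by a cell is the arithmetic mean of that species' ligand
#' monomers over its neighbours (and symmetrically for the trans receptor
#' seen by a ligand), restricted by the Fringe gating of each species.
#'
#' @param rows,cols grid dimensions.
#' @param species a list of [ligand_species()] objects.
#' @param b_N receptor production field: matrix or scalar (molecules/hour).
#' @param compartment per-cell compartment labels (`"dorsal"`, `"ventral"` or
#'   `"none"`): matrix or scalar.
#' @param topology `"von_neumann"` (4 neighbours), `"moore"` (8) or `"hex"`
#'   (6).
#' @param p shared non-species parameters ([notch_params()]): `beta`,
#'   `beta_S`, `b_N` default, `k_ci` for receptor-side bookkeeping.
#' @return an object of class `notch_tissue`.
#' @export
make_tissue <- function(rows, cols, species, b_N = 200,
                        compartment = "none", topology = "von_neumann",
                        p = notch_params()) {
  stopifnot(rows >= 1, cols >= 1, length(species) >= 1)
  as_field <- function(x) {
    m <- matrix(x, nrow = rows, ncol = cols)
    m
  }
  b_N <- as_field(b_N)
  check_nonneg(b_N, "b_N field")
  compartment <- as_field(compartment)
  species <- lapply(species, function(s) {
    s$b_L <- as_field(s$b_L)
    check_nonneg(s$b_L, paste0("b_L field of species ", s$name))
    s
  })
  structure(list(rows = rows, cols = cols, species = species, b_N = b_N,
                 compartment = compartment, topology = topology, p = p,
                 W = .neighbor_matrix(rows, cols, topology)),
            class = "notch_tissue")
}

#' Trans-presented signal seen by one cell of a tissue
#'
#' Returns, for each ligand species, the arithmetic mean of that species'
#' monomer level over the cell's neighbours (boundary cells average over
#' existing neighbours only), given a per-cell monomer field.
#'
#' @param tissue a `notch_tissue`.
#' @param row,col the cell.
#' @param fields a named list of rows x cols matrices, one per species
#'   (monomer levels).
#' @return named numeric vector of per-species trans-ligand levels.
#' @export
neighbor_trans_input <- function(tissue, row, col, fields) {
  stopifnot(row >= 1, row <= tissue$rows, col >= 1, col <= tissue$cols)
  i <- (col - 1L) * tissue$rows + row
  w <- tissue$W[i, ]
  vapply(fields, function(f) sum(w * as.vector(f)), numeric(1))
}

#' Exponential ligand-production gradient
#'
#' Production profile `b_L(y) = L_max * exp(-|y - y0|)` decaying from the
#' centre `y0`, used for the wing-vein ligand gradient and for ectopic
#' expression stripes.
#'
#' @param L_max peak production rate (molecules/hour).
#' @param y0 gradient centre (grid row units).
#' @param y positions at which to evaluate.
#' @return production rates at `y`.
#' @export
gradient_profile <- function(L_max, y0, y) {
  if (L_max < 0) stop("'L_max' must be non-negative")
  L_max * exp(-abs(y - y0))
}

# right-hand side of the whole-lattice system, vectorized over cells.
# model "T1": per-species monomer/dimer dynamics, dimer cis-inhibition;
# model "MI": monomer-only dynamics, monomer cis-inhibition.
# state layout: per species (L[, Lstar]) blocks, then N, then S.
.tissue_system <- function(tissue, model) {
  n_cells <- tissue$rows * tissue$cols
  ns <- length(tissue$species)
  per_sp <- if (model == "T1") 2L else 1L
  comp <- as.vector(tissue$compartment)
  perm <- lapply(tissue$species, function(s) {
    if ("all" %in% s$activates) rep(1, n_cells)
    else as.numeric(comp %in% s$activates)
  })
  b_N <- as.vector(tissue$b_N)
  b_L <- lapply(tissue$species, function(s) as.vector(s$b_L))
  W <- tissue$W
  p <- tissue$p
  i_N <- ns * per_sp * n_cells + seq_len(n_cells)
  i_S <- (ns * per_sp + 1L) * n_cells + seq_len(n_cells)
  sp_idx <- lapply(seq_len(ns), function(s) {
    off <- (s - 1L) * per_sp * n_cells
    list(L = off + seq_len(n_cells),
         Lstar = if (per_sp == 2L) off + n_cells + seq_len(n_cells))
  })
  rhs <- function(y) {
    N <- y[i_N]; S <- y[i_S]
    dN <- b_N - p$beta * N
    act <- numeric(n_cells)
    d <- numeric(length(y))
    for (s in seq_len(ns)) {
      sp <- tissue$species[[s]]
      ix <- sp_idx[[s]]
      L <- y[ix$L]
      # trans fields: neighbour-averaged ligand seen by each cell (gated by
      # the receiving cell's compartment), and neighbour-averaged responsive
      # receptor seen by each cell's ligand
      L_ext_recv <- as.vector(W %*% L) * perm[[s]]
      N_ext <- as.vector(W %*% (N * perm[[s]]))
      if (model == "T1") {
        Ls <- y[ix$Lstar]
        dL <- b_L[[s]] - p$beta * L - 2 * sp$k_d * L^2 - sp$k_t * N_ext * L
        dLs <- sp$k_d * L^2 - p$beta * Ls - sp$k_ci * N * Ls
        dN <- dN - sp$k_ci * Ls * N - sp$k_t * L_ext_recv * N
        act <- act + sp$k_t * L_ext_recv * N
        d[ix$Lstar] <- dLs
      } else {
        dL <- b_L[[s]] - p$beta * L - sp$k_t * N_ext * L - sp$k_ci * N * L
        dN <- dN - sp$k_ci * L * N - sp$k_t * L_ext_recv * N
        act <- act + sp$k_t * L_ext_recv * N
      }
      d[ix$L] <- dL
    }
    d[i_N] <- dN
    d[i_S] <- act - p$beta_S * S
    d
  }
  init <- numeric((ns * per_sp + 2L) * n_cells)
  for (s in seq_len(ns)) init[sp_idx[[s]]$L] <- b_L[[s]] / p$beta
  init[i_N] <- b_N / p$beta
  list(rhs = rhs, init = init, i_N = i_N, i_S = i_S, sp_idx = sp_idx,
       n_cells = n_cells, per_sp = per_sp)
}

#' Integrate a tissue to steady state
#'
#' Integrates the whole-lattice coupled ODE system (all cells at once, so the
#' result is independent of any cell-update order) until the residual of
#' every cell's equations falls below `tol * max(b_N)`.
#'
#' @param tissue a [make_tissue()] object.
#' @param model `"T1"` (ligand-dimerization) or `"MI"`
#'   (mutual-inactivation).
#' @param t_max integration horizon (hours).
#' @param tol residual tolerance relative to the peak receptor production.
#' @return a list of per-cell steady-state fields: `S`, `N` (rows x cols
#'   matrices), `L` and (for T1) `Lstar` (named lists of matrices, one per
#'   species), plus `residual`.
#' @export
simulate_tissue <- function(tissue, model = c("T1", "MI"),
                            t_max = 5000, tol = 1e-6) {
  model <- match.arg(model)
  sys <- .tissue_system(tissue, model)
  scale <- max(tissue$b_N, 1)
  y <- sys$init
  dfun <- function(t, y, parms) list(sys$rhs(pmax(y, 0)))
  t <- 0; chunk <- 200
  repeat {
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = c(t, t + chunk), func = dfun,
                   parms = NULL, method = "lsoda",
                   rtol = 1e-8, atol = 1e-8 * scale, maxsteps = 50000))
    y <- pmax(sol[nrow(sol), -1], 0)
    t <- t + chunk
    res <- max(abs(sys$rhs(y)))
    if (res < tol * scale || t >= t_max) break
  }
  if (res >= tol * scale)
    stop("tissue simulation did not reach steady state within t_max = ",
         t_max, " h (residual ", signif(res, 3), ")", call. = FALSE)
  shape <- function(v) matrix(v, nrow = tissue$rows, ncol = tissue$cols)
  sp_names <- vapply(tissue$species, `[[`, "", "name")
  out <- list(
    S = shape(y[sys$i_S]),
    N = shape(y[sys$i_N]),
    L = stats::setNames(
      lapply(sys$sp_idx, function(ix) shape(y[ix$L])), sp_names),
    residual = res)
  if (model == "T1")
    out$Lstar <- stats::setNames(
      lapply(sys$sp_idx, function(ix) shape(y[ix$Lstar])), sp_names)
  out
}

#' Wing-vein patterning under a ligand-production gradient
#'
#' Simulates a field of cells under model T1 with a single ligand (Delta)
#' whose production decays exponentially from a central row `y0`
#' (`b_L(y) = L_max exp(-|y - y0|)`) and uniform receptor production. The
#' high-ligand central cells are cis-inhibited senders; Notch signalling
#' concentrates in two parallel bands flanking the centre, which delimit the
#' site of vein formation.
#'
#' @param rows,cols grid dimensions (rows indexed by the gradient coordinate
#'   `y`).
#' @param p model parameters.
#' @param L_max peak ligand production (molecules/hour).
#' @param y0 gradient centre row.
#' @param b_N uniform receptor production (molecules/hour).
#' @param topology grid topology, see [make_tissue()].
#' @return as [simulate_tissue()], plus the `tissue` used.
#' @export
wing_vein_simulation <- function(rows = 20, cols = 20, p = notch_params(),
                                 L_max = 15000, y0 = (rows + 1) / 2,
                                 b_N = 200, topology = "von_neumann") {
  b_L <- matrix(gradient_profile(L_max, y0, seq_len(rows)),
                nrow = rows, ncol = cols)
  delta <- ligand_species("Delta", b_L = b_L, activates = "all",
                          k_d = p$k_d, k_t = p$k_t, k_ci = p$k_ci)
  tissue <- make_tissue(rows, cols, list(delta), b_N = b_N,
                        topology = topology, p = p)
  out <- simulate_tissue(tissue, model = "T1")
  out$tissue <- tissue
  out
}

#' Dorsoventral-boundary patterning with Delta/Serrate compartments
#'
#' Simulates a wing-disc-like tissue split into a dorsal half producing
#' Serrate and a ventral half producing Delta, with Notch produced uniformly.
#' Fringe gating restricts trans-activation: Notch in dorsal cells responds
#' only to Delta, Notch in ventral cells only to Serrate. Under the
#' ligand-dimerization model T1 this yields stripes of Notch activity in the
#' cell rows flanking the compartment interface; under the
#' mutual-inactivation model the required ligand/receptor coexistence is
#' impossible and no boundary signal forms.
#'
#' Optional perturbations: receptor-production titration (`b_N`), and an
#' ectopic ligand expression stripe with an exponential production profile
#' centred on `ectopic$center` (an independently parameterized copy of the
#' named species, so its dimerization rate can differ, e.g.
#' `ectopic = list(species = "Delta", center = 3, L_max = 15000, k_d =
#' 1e-6)`).
#'
#' @param rows,cols grid dimensions; rows `1..rows/2` are dorsal.
#' @param p model parameters.
#' @param model `"T1"` or `"MI"`.
#' @param b_N uniform receptor production (molecules/hour).
#' @param b_L default ligand production in each compartment
#'   (molecules/hour).
#' @param ectopic optional list with elements `species` (`"Delta"` or
#'   `"Serrate"`), `center` (row), `L_max` (peak production) and optionally
#'   `k_d` (dimerization rate of the ectopic ligand).
#' @param topology grid topology.
#' @return as [simulate_tissue()], plus the `tissue` used and `dorsal_rows`.
#' @export
dv_boundary_simulation <- function(rows = 20, cols = 20, p = notch_params(),
                                   model = c("T1", "MI"), b_N = 1000,
                                   b_L = 200, ectopic = NULL,
                                   topology = "von_neumann") {
  model <- match.arg(model)
  if (rows < 4) stop("need at least 4 rows for a dorsoventral tissue")
  dorsal_rows <- seq_len(floor(rows / 2))
  comp <- matrix("ventral", nrow = rows, ncol = cols)
  comp[dorsal_rows, ] <- "dorsal"
  in_rows <- function(which) {
    m <- matrix(0, nrow = rows, ncol = cols)
    m[which, ] <- b_L
    m
  }
  serrate <- ligand_species("Serrate", b_L = in_rows(dorsal_rows),
                            activates = "ventral",
                            k_d = p$k_d, k_t = p$k_t, k_ci = p$k_ci)
  delta <- ligand_species("Delta", b_L = in_rows(setdiff(seq_len(rows),
                                                         dorsal_rows)),
                          activates = "dorsal",
                          k_d = p$k_d, k_t = p$k_t, k_ci = p$k_ci)
  species <- list(serrate, delta)
  if (!is.null(ectopic)) {
    if (is.null(ectopic$species) || is.null(ectopic$center) ||
        is.null(ectopic$L_max))
      stop("'ectopic' needs elements species, center and L_max")
    prof <- matrix(gradient_profile(ectopic$L_max, ectopic$center,
                                    seq_len(rows)),
                   nrow = rows, ncol = cols)
    gate <- if (ectopic$species == "Delta") "dorsal" else "ventral"
    species <- c(species, list(ligand_species(
      paste0(ectopic$species, "_ectopic"), b_L = prof, activates = gate,
      k_d = if (is.null(ectopic$k_d)) p$k_d else ectopic$k_d,
      k_t = p$k_t, k_ci = p$k_ci)))
  }
  tissue <- make_tissue(rows, cols, species, b_N = b_N, compartment = comp,
                        topology = topology, p = p)
  out <- simulate_tissue(tissue, model = model)
  out$tissue <- tissue
  out$dorsal_rows <- dorsal_rows
  out
}
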