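#' Load a scenario configuration file
#'
#' Scenario files are YAML with a small, validated schema. Top-level keys:
#' `scenario` (one of `"simulate"`, `"sweep"`, `"two_cell"`, `"lattice"`,
#' `"sensitivity"`), `parameters` (overrides of [notch_params()] fields,
#' including explicit `k1..k6`), `ext` (`L_ext`, `Lstar_ext`, `N_ext`), and
#' one section matching the scenario (`dynamics`, `sweep`, `lattice` or
#' `sensitivity`). Unknown keys are rejected; all omitted parameters take
#' their baseline defaults, and an empty file resolves to the full baseline
#' parameter set with model T1.
#'
#' @param path path to a YAML scenario file.
#' @return a `scenario_config` list with elements `scenario`, `params`
#'   (a `notch_params`), `ext` (an [external_signal()]) and the
#'   scenario-specific spec.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("scenario", "parameters", "ext", "dynamics", "sweep",
               "lattice", "sensitivity", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scenario <- if (is.null(cfg$scenario)) "simulate" else cfg$scenario
  if (!scenario %in% c("simulate", "sweep", "two_cell", "lattice",
                       "sensitivity"))
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  par_over <- cfg$parameters
  if (!is.null(par_over)) {
    bad <- setdiff(names(par_over), names(notch_params()))
    if (length(bad))
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  params <- do.call(notch_params, as.list(par_over %||% list()))
  ext_over <- cfg$ext %||% list()
  bad <- setdiff(names(ext_over), c("L_ext", "Lstar_ext", "N_ext"))
  if (length(bad))
    stop("unknown ext key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ext <- do.call(external_signal, as.list(ext_over))
  structure(list(scenario = scenario, params = params, ext = ext,
                 spec = cfg[[switch(scenario, simulate = "dynamics",
                                    two_cell = "sweep", scenario)]] %||%
                        list(),
                 seed = cfg$seed),
            class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a loaded scenario
#'
#' Dispatches a [load_scenario_config()] object to the matching simulation
#' routine and returns its result (a trajectory, sweep result, lattice field
#' list or sensitivity report).
#'
#' @param cfg a `scenario_config`.
#' @return the scenario's result object.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$params; spec <- cfg$spec
  switch(cfg$scenario,
    simulate = {
      type <- spec$type %||% "cell"
      times <- seq(spec$t0 %||% 0, spec$t_end %||% 200,
                   by = spec$dt %||% 0.5)
      if (type == "cis_inhibition") {
        init <- cell_state(L = 500, Lstar = 9500)
        if (!is.null(spec$init)) init <- do.call(cell_state,
                                                 as.list(spec$init))
        cis_inhibition_dynamics(p, times, init,
                                L_ext = spec$L_ext %||% cfg$ext[["L_ext"]])
      } else {
        model <- spec$model %||% "T1"
        rhs <- switch(model, T1 = rhs_t1, MI = rhs_mi,
                      general = rhs_general, oligomer = rhs_oligomer,
                      compartment = rhs_compartment,
                      stop("unknown model tag '", model, "'"))
        init <- if (!is.null(spec$init)) {
          if (model == "MI") do.call(function(L = 0, N = 0, S = 0)
            c(L = L, N = N, S = S), as.list(spec$init))
          else if (model == "compartment")
            do.call(compartment_state, as.list(spec$init))
          else do.call(cell_state, as.list(spec$init))
        } else if (model == "MI") c(L = 0, N = 0, S = 0)
          else if (model == "compartment") compartment_state()
          else cell_state()
        simulate_cell(rhs, init, times, cfg$ext, p)
      }
    },
    sweep = {
      quantity <- spec$quantity %||% "production"
      grid <- as.numeric(spec$grid %||%
        stop("sweep config needs a 'grid' of values"))
      switch(quantity,
        production = production_sweep(p, grid, mode = spec$mode %||% "cis",
          cis = spec$cis %||% "C1", trans = spec$trans %||% "T1",
          L_ext = spec$L_ext %||% cfg$ext[["L_ext"]],
          N_ext = spec$N_ext %||% cfg$ext[["N_ext"]],
          normalize = isTRUE(spec$normalize)),
        dimerization = dimerization_sweep(p, grid,
          b_L = spec$b_L %||% stop("dimerization sweep needs fixed 'b_L'"),
          mode = spec$mode %||% "cis", cis = spec$cis %||% "C1",
          trans = spec$trans %||% "T1",
          L_ext = spec$L_ext %||% cfg$ext[["L_ext"]],
          N_ext = spec$N_ext %||% cfg$ext[["N_ext"]],
          normalize = isTRUE(spec$normalize)),
        cis_activation = cis_activation_sweep(spec$scenario %||% 1, p, grid,
          k_ca = spec$k_ca %||% p$k_ca, k_d = spec$k_d %||% p$k_d,
          k_ci = spec$k_ci %||% p$k_ci,
          normalize = isTRUE(spec$normalize)),
        oligomer = oligomer_sweep(spec$setting %||% "fixed_trans",
          n = spec$n %||% 2, p = p, b_L_grid = grid,
          L_ext = spec$L_ext %||% cfg$ext[["L_ext"]]),
        compartment = compartment_sweep(spec$setting %||% "fixed_trans",
          localization = spec$localization %||% "cytoplasmic", p = p,
          b_L_grid = grid, L_ext = spec$L_ext %||% cfg$ext[["L_ext"]]),
        stop("unknown sweep quantity '", quantity, "'"))
    },
    two_cell = {
      grid <- as.numeric(spec$grid %||%
        stop("two_cell config needs a 'grid' of values"))
      two_cell_sweep(p, grid, trans = spec$trans %||% "T1",
                     cis = spec$cis %||% "C1")
    },
    lattice = {
      type <- spec$type %||% "wing_vein"
      rows <- spec$rows %||% 20; cols <- spec$cols %||% 20
      topology <- spec$topology %||% "von_neumann"
      if (type == "wing_vein") {
        wing_vein_simulation(rows, cols, p,
          L_max = spec$L_max %||% 15000,
          y0 = spec$y0 %||% ((rows + 1) / 2),
          b_N = spec$b_N %||% 200, topology = topology)
      } else if (type == "dv_boundary") {
        dv_boundary_simulation(rows, cols, p,
          model = spec$model %||% "T1", b_N = spec$b_N %||% 1000,
          b_L = spec$b_L %||% 200, ectopic = spec$ectopic,
          topology = topology)
      } else stop("unknown lattice type '", type, "'")
    },
    sensitivity = {
      defaults <- formals(sensitivity_scan)
      sensitivity_scan(
        settings = unlist(spec$settings %||% eval(defaults$settings)),
        parameters = unlist(spec$parameters %||% eval(defaults$parameters)),
        fold_grid = as.numeric(unlist(spec$fold_grid %||%
                                      eval(defaults$fold_grid))),
        p = p)
    })
}

#' Flatten a lattice result to a per-cell table
#'
#' @param result a [simulate_tissue()] / [wing_vein_simulation()] /
#'   [dv_boundary_simulation()] result.
#' @return a data frame keyed by `(row, col)` with species-wise ligand
#'   columns, `N` and `S`.
#' @export
lattice_as_table <- function(result) {
  stopifnot(is.list(result), !is.null(result$S))
  rows <- nrow(result$S); cols <- ncol(result$S)
  out <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  for (sp in names(result$L)) out[[paste0("L_", sp)]] <-
    as.vector(result$L[[sp]])
  for (sp in names(result$Lstar)) out[[paste0("Lstar_", sp)]] <-
    as.vector(result$Lstar[[sp]])
  out$N <- as.vector(result$N)
  out$S <- as.vector(result$S)
  out
}

#' Write a result table with a metadata header
#'
#' Writes any package result (trajectory, sweep result, sensitivity report,
#' or lattice field list, which is flattened via [lattice_as_table()]) as a
#' comma-delimited table preceded by `#`-prefixed metadata lines. Numeric
#' values are written with 17 significant digits so that a round-trip through
#' [read_results()] reproduces them exactly.
#'
#' @param result the result object.
#' @param path output file path.
#' @param meta named list of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, meta = list()) {
  if (is.list(result) && !is.data.frame(result) && !is.null(result$S))
    result <- lattice_as_table(result)
  if (!is.data.frame(result)) stop("unsupported result type")
  p <- attr(result, "params")
  header <- c(
    paste0("# notchdimer v",
           as.character(utils::packageVersion("notchdimer"))),
    if (!is.null(attr(result, "swept")))
      paste0("# swept: ", attr(result, "swept")),
    if (!is.null(p)) paste0("# params: ",
      paste(names(unclass(p)), vapply(unclass(p), format, "", digits = 15),
            sep = "=", collapse = " ")),
    vapply(names(meta), function(k) paste0("# ", k, ": ", meta[[k]]), ""))
  fmt <- as.data.frame(lapply(result, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(fmt, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file path.
#' @return a data frame (metadata lines are skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
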