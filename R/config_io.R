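#' Read a case configuration file and run it
#'
#' Cases are described by a YAML file with blocks `geometry`, `fluid`,
#' `rheology`, `interaction`, `bc`, `solver`, `grid` and `output`; every key
#' is optional and defaults to the package defaults. `run_case` builds the
#' geometry and grid, solves the steady problem and (if an output directory
#' is configured or given) writes the standard outputs.
#'
#' @param path Path to the YAML case file.
#' @return `read_case` returns a list with the constructed `geom`, `grid`,
#'   `bc`, `props`, `coeffs`, `params`, `config` and `output` settings.
#' @examples
#' \dontrun{
#' case <- read_case("stenosis.yaml")
#' state <- run_case("stenosis.yaml", out_dir = "results")
#' }
#' @export
read_case <- function(path) {
  cf <- yaml::read_yaml(path)
  geo <- cf$geometry %||% list()
  geom <- if (identical(geo$case, "expansion")) {
    do.call(expansion_geometry,
            geo[intersect(names(geo), names(formals(expansion_geometry)))])
  } else {
    do.call(stenosis_geometry,
            geo[intersect(names(geo), names(formals(stenosis_geometry)))])
  }
  gr <- cf$grid %||% list()
  grid <- if (inherits(geom, "expansion_geometry")) {
    build_expansion_grid(geom, nx_up = gr$nx_up %||% 40,
                         ny_up = gr$ny_up %||% 10,
                         nx_down = gr$nx_down %||% (2 * (gr$nx_up %||% 40)))
  } else {
    build_stenosis_grid(geom, nx = gr$nx %||% 120, ny = gr$ny %||% 20,
                        cluster_wall = gr$cluster_wall %||% -1.2,
                        cluster_throat = gr$cluster_throat %||% 2.5)
  }
  props <- do.call(fluid_properties, keep_args(cf$fluid, fluid_properties))
  coeffs <- do.call(rheology_coefficients,
                    keep_args(cf$rheology, rheology_coefficients))
  params <- do.call(interaction_params,
                    keep_args(cf$interaction, interaction_params))
  bcb <- cf$bc %||% list()
  bc <- boundary_conditions(
    inlet_velocity_Vt = bcb$Vt %||% 0.2,
    inlet_hematocrit_Ht = bcb$Ht %||% 0.2,
    outlet_pressure = bcb$outlet_pressure %||% 0)
  config <- do.call(solver_config, keep_args(cf$solver, solver_config))
  list(geom = geom, grid = grid, bc = bc, props = props, coeffs = coeffs,
       params = params, config = config, output = cf$output %||% list())
}

keep_args <- function(lst, fun) {
  if (is.null(lst)) return(list())
  lst[intersect(names(lst), names(formals(fun)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_case
#' @param out_dir Output directory, overriding the case file's `output: dir`.
#' @param overrides Named list overriding `bc` values (`Vt`, `Ht`) or grid
#'   resolution (`nx`, `ny`), as the command line does.
#' @export
run_case <- function(path, out_dir = NULL, overrides = list()) {
  case <- read_case(path)
  if (!is.null(overrides$Vt) || !is.null(overrides$Ht)) {
    case$bc <- boundary_conditions(
      overrides$Vt %||% case$bc$inlet_velocity_Vt,
      overrides$Ht %||% case$bc$inlet_hematocrit_Ht,
      case$bc$outlet_pressure)
  }
  if (!is.null(overrides$nx) || !is.null(overrides$ny)) {
    if (inherits(case$geom, "stenosis_geometry")) {
      case$grid <- build_stenosis_grid(case$geom,
                                       nx = overrides$nx %||% 120,
                                       ny = overrides$ny %||% 20)
    }
  }
  state <- steady_solve(case$grid, case$bc, case$props, case$coeffs,
                        case$params, case$config)
  dir <- out_dir %||% case$output$dir
  if (!is.null(dir)) {
    secs <- case$output$sections %||% numeric(0)
    write_outputs(state, case$grid, dir, sections = as.numeric(secs))
  }
  state
}
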