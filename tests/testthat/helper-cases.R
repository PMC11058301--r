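## Shared solved cases, computed once per test session. Resolutions are
## desk-scale: large enough for the qualitative physics and the stated
## analytic tolerances, small enough to keep the suite fast.

.case_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (is.null(.case_cache[[name]])) .case_cache[[name]] <- fun()
  .case_cache[[name]]
}

## single-phase Poiseuille reference solves (tube and plane channel)
poiseuille_fixture <- function(mode, nx = 200, ny = 24) {
  cached(paste("pois", mode, nx, ny, sep = "_"), function() {
    hemoflow:::poiseuille_case(mode, nx, ny)
  })
}

## two-phase stenosis reference case (Vt = 0.2 m/s, Ht = 20%), converged
## tightly for the conservation checks
stenosis_fixture <- function() {
  cached("stenosis_tight", function() {
    geom <- stenosis_geometry()
    grid <- build_stenosis_grid(geom, nx = 120, ny = 24,
                                cluster_wall = -1.2, cluster_throat = 2.5)
    bc <- boundary_conditions(0.2, 0.2)
    state <- suppressWarnings(steady_solve(
      grid, bc, config = solver_config(max_outer = 1200, tol = 1e-9)))
    list(state = state, grid = grid, geom = geom, bc = bc)
  })
}

## coarse qualitative stenosis runs for the sweep trends
stenosis_sweep_fixture <- function() {
  cached("stenosis_sweep", function() {
    lapply(c(0.1, 0.2, 0.4, 0.8), function(Vt) {
      hemoflow:::run_stenosis_case(Vt, 0.2, nx = 90, ny = 14)
    })
  })
}

## expansion validation run
expansion_fixture <- function() {
  cached("expansion", function() {
    run_expansion_validation(nx_up = 30, ny_up = 8)
  })
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                         utils::tail(y, -1)) / 2)
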