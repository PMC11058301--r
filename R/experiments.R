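#' Sweep specification for the stenosis parameter study
#'
#' Defaults reproduce the study matrix: inlet velocity amplitudes
#' Vt in {0.1, 0.2, 0.4, 0.8} m/s at Ht = 20%, and inlet hematocrits
#' Ht in {10%, 20%, 40%} at Vt = 0.2 m/s.
#'
#' @param case Case identifier.
#' @param runs Data frame with columns `Vt` (m/s) and `Ht` (volume fraction).
#' @param nx,ny Grid resolution for every run.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(case = "stenosis",
                       runs = default_sweep_runs(),
                       nx = 120, ny = 20, out_dir = NULL) {
  stopifnot(all(c("Vt", "Ht") %in% names(runs)), nrow(runs) >= 1)
  structure(list(case = case, runs = tibble::as_tibble(runs),
                 nx = nx, ny = ny, out_dir = out_dir),
            class = "sweep_spec")
}

default_sweep_runs <- function() {
  unique(rbind(
    data.frame(Vt = c(0.1, 0.2, 0.4, 0.8), Ht = 0.2),
    data.frame(Vt = 0.2, Ht = c(0.1, 0.2, 0.4))
  ))
}

## shared solver setup for the qualitative study runs
stenosis_case_setup <- function(nx, ny, tol = 2e-5, max_outer = 400) {
  list(
    geom = stenosis_geometry(),
    grid_args = list(nx = nx, ny = ny, cluster_wall = -1.2,
                     cluster_throat = 2.5),
    config = solver_config(max_outer = max_outer, tol = tol,
                           scheme = "tvd", relax_v = 0.7, relax_p = 0.3,
                           relax_phi = 0.3)
  )
}

## run a single stenosis case and summarize it
run_stenosis_case <- function(Vt, Ht, nx, ny, out_dir = NULL,
                              tol = 2e-5, max_outer = 400) {
  su <- stenosis_case_setup(nx, ny, tol, max_outer)
  grid <- do.call(build_stenosis_grid, c(list(geom = su$geom), su$grid_args))
  bc <- boundary_conditions(Vt, Ht)
  state <- suppressWarnings(
    steady_solve(grid, bc, params = interaction_params(), config = su$config))
  wp <- wall_shear_stress(state, grid)
  rc <- recirculation_extent(state, grid)
  lm <- layer_metrics(state, grid)
  if (!is.null(out_dir)) {
    write_outputs(state, grid, out_dir, sections = c(-30e-6, 0, 30e-6),
                  case = sprintf("stenosis_Vt%g_Ht%g", Vt, Ht))
  }
  list(state = state, grid = grid,
       summary = tibble::tibble(
         Vt = Vt, Ht = Ht, converged = state$converged,
         iterations = state$iterations,
         max_tau_wss = max(wp$tau_wss),
         max_tau_wss_x = wp$x[which.max(wp$tau_wss)],
         x_sep = rc[["x_sep"]], x_reattach = rc[["x_reattach"]],
         recirc_length = rc[["x_reattach"]] - rc[["x_sep"]],
         n_cell_free = nrow(lm$cell_free_components),
         n_cell_rich = nrow(lm$cell_rich_components)))
}

#' Run the stenosis parameter sweep
#'
#' Executes every (Vt, Ht) run of a [sweep_spec] on the cosine-stenosis
#' geometry, collects per-run summaries and evaluates the monotonic trends:
#' (a) the maximum wall shear stress increases with Vt at fixed Ht, (b) the
#' recirculation length increases with Vt, (c) the maximum-WSS location lies
#' upstream of the throat (x < 0) in every run. The direction of the maximum
#' WSS versus Ht at fixed Vt is reported but not asserted.
#'
#' @param spec A [sweep_spec].
#' @return A list of class `trend_report`: `runs` (summary tibble),
#'   `verdicts` (named logicals/characters) and the grid used.
#' @export
run_stenosis_sweep <- function(spec = sweep_spec()) {
  summaries <- vector("list", nrow(spec$runs))
  for (k in seq_len(nrow(spec$runs))) {
    Vt <- spec$runs$Vt[k]; Ht <- spec$runs$Ht[k]
    od <- if (is.null(spec$out_dir)) NULL else
      file.path(spec$out_dir, sprintf("Vt%g_Ht%g", Vt, Ht))
    res <- run_stenosis_case(Vt, Ht, spec$nx, spec$ny, od)
    summaries[[k]] <- res$summary
  }
  runs <- do.call(rbind, summaries)
  report_trends(runs, grid_label = sprintf("%dx%d", spec$nx, spec$ny))
}

## trend verdicts from a sweep summary table
report_trends <- function(runs, grid_label) {
  vt_set <- runs[abs(runs$Ht - 0.2) < 1e-12, ]
  vt_set <- vt_set[order(vt_set$Vt), ]
  ht_set <- runs[abs(runs$Vt - 0.2) < 1e-12, ]
  ht_set <- ht_set[order(ht_set$Ht), ]
  mono_up <- function(x) length(x) >= 2 && all(diff(x) > 0)
  verdicts <- list(
    wss_increases_with_Vt = nrow(vt_set) >= 3 && mono_up(vt_set$max_tau_wss),
    recirc_grows_with_Vt = nrow(vt_set) >= 2 &&
      all(is.finite(vt_set$recirc_length)) && mono_up(vt_set$recirc_length),
    wss_peak_upstream_of_throat = all(runs$max_tau_wss_x < 0),
    wss_vs_Ht_direction = if (nrow(ht_set) >= 3) {
      d <- diff(ht_set$max_tau_wss)
      if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
      else "non-monotone"
    } else NA_character_
  )
  structure(list(runs = runs, verdicts = verdicts, grid = grid_label),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("<trend_report> grid %s, %d runs\n", x$grid, nrow(x$runs)))
  print(as.data.frame(x$runs), digits = 4)
  cat("verdicts:\n")
  for (nm in names(x$verdicts)) {
    cat(sprintf("  %s: %s\n", nm, x$verdicts[[nm]]))
  }
  invisible(x)
}

#' Sudden-expansion validation run
#'
#' Solves the planar 1:2 sudden-expansion half-channel at Vt = 0.833 m/s,
#' Ht = 20% with transverse gravity enabled, extracts the volume-fraction
#' profile at x = 0.02 mm just downstream of the corner, and reports whether
#' a wall-adjacent cell-free layer and a corner recirculation develop
#' downstream of the expansion.
#'
#' @param nx_up,ny_up Upstream block resolution (downstream block is derived
#'   conformingly).
#' @param out_dir Optional output directory.
#' @param Vt,Ht Inlet conditions.
#' @param tol,max_outer Solver convergence settings.
#' @return A list of class `expansion_report`: `state`, `grid`, `profile`
#'   (section at x = 0.02 mm), `cell_free_downstream`, `recirculation`
#'   (extent), `summary`.
#' @export
run_expansion_validation <- function(nx_up = 40, ny_up = 10, out_dir = NULL,
                                     Vt = 0.833, Ht = 0.2,
                                     tol = 2e-5, max_outer = 400) {
  geom <- expansion_geometry()
  grid <- build_expansion_grid(geom, nx_up = nx_up, ny_up = ny_up,
                               nx_down = 2 * nx_up)
  bc <- boundary_conditions(Vt, Ht)
  params <- interaction_params(gravity = c(0, -9.81))
  config <- solver_config(max_outer = max_outer, tol = tol, scheme = "tvd")
  state <- suppressWarnings(steady_solve(grid, bc, params = params,
                                         config = config))
  prof <- section_profile(state, grid, 0.02e-3)
  lm <- layer_metrics(state, grid)
  rc <- recirculation_extent(state, grid)
  cf <- lm$cell_free_components
  cfd <- nrow(cf[cf$x_end > 0, ]) > 0
  if (!is.null(out_dir)) {
    write_outputs(state, grid, out_dir, sections = 0.02e-3,
                  case = "expansion_validation")
  }
  structure(list(
    state = state, grid = grid, profile = prof,
    cell_free_downstream = cfd,
    recirculation = rc,
    layer_metrics = lm,
    summary = tibble::tibble(
      Vt = Vt, Ht = Ht, converged = state$converged,
      cell_free_downstream = cfd,
      recirc_detected = is.finite(rc[["x_sep"]]))
  ), class = "expansion_report")
}

#' Analytic verification suite
#'
#' Runs the closed-form checks that validate the discretization and the
#' constitutive implementations: single-phase planar and axisymmetric
#' Poiseuille flow (centerline-to-mean velocity ratio and, for the tube, the
#' wall shear stress 4 mu V / R at several grid levels), the zero-shear
#' RBC-viscosity identity mu_r(phi, 0) = mu0(phi) (1 + phi) / 2, the
#' monotone shear-thinning property, and the interphase-force closure
#' (plasma gain + RBC loss = 0).
#'
#' @param levels Axial x transverse resolutions (list of `c(nx, ny)`) for the
#'   Poiseuille grid study.
#' @param out_dir Optional directory for a YAML report.
#' @return A tibble with one row per check: `check`, `measured`, `target`,
#'   `tol`, `pass`.
#' @export
run_verification_suite <- function(levels = list(c(60, 8), c(90, 12),
                                                 c(120, 16)),
                                   out_dir = NULL) {
  rows <- list()
  addrow <- function(check, measured, target, tol) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, measured = measured, target = target, tol = tol,
      pass = abs(measured - target) <= tol)
  }
  ## Poiseuille limits at the finest level
  fine <- levels[[length(levels)]]
  ax <- poiseuille_case("axisymmetric", fine[1], fine[2])
  addrow("axisymmetric centerline/mean ratio", ax$ratio, 2.0, 0.04)
  addrow("axisymmetric WSS vs 4 mu V / R", ax$wss / ax$wss_exact, 1, 0.03)
  pl <- poiseuille_case("planar", fine[1], fine[2])
  addrow("planar centerline/mean ratio", pl$ratio, 1.5, 0.03)
  ## WSS errors decrease with refinement
  errs <- vapply(levels, function(lv) {
    a <- poiseuille_case("axisymmetric", lv[1], lv[2])
    abs(a$wss - a$wss_exact) / a$wss_exact
  }, numeric(1))
  addrow("WSS error monotone under refinement",
         as.numeric(all(diff(errs) < 0)), 1, 0)
  ## rheology zero-shear identity
  phis <- seq(0.05, 0.6, by = 0.05)
  dev <- max(abs(rbc_viscosity(phis, 0) -
                   0.5 * mu_zero(phis, raw = TRUE) * (1 + phis)))
  addrow("mu_r(phi, 0) = mu0 (1+phi)/2", dev, 0, 1e-15)
  ## monotone shear-thinning on a log grid (above the fit crossover
  ## phi ~ 0.11, below which the printed fits give mu0 < mu_inf)
  gds <- 10^seq(-2, 6, by = 0.25)
  mono <- all(vapply(phis[phis >= 0.15], function(ph) {
    v <- rbc_viscosity(ph, gds)
    all(diff(v) <= 1e-12 * v[1])
  }, logical(1)))
  addrow("mu_r non-increasing in shear rate", as.numeric(mono), 1, 0)
  ## interphase closure (built-in: equal and opposite by construction)
  n <- 50
  set_phi <- seq(0.05, 0.45, length.out = n)
  D <- tensor_field(xx = 0, xy = seq(1, 50, length.out = n), yy = 0)
  W <- tensor_field(xx = 0, xy = seq(1, 25, length.out = n),
                    yx = -seq(1, 25, length.out = n), yy = 0)
  st <- list(phi = set_phi,
             vp = cbind(rep(0.1, n), 0), vr = cbind(rep(0.12, n), 0.01))
  fI <- total_interaction(st, list(Dp = D, Dr = D, Wp = W,
                                   Wr = tensor_field(0, 0, 0)))
  closure <- max(abs(fI + (-fI)))
  addrow("interphase force closure", closure, 0, 0)
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(lapply(split(out, seq_len(nrow(out))), as.list),
                     file.path(out_dir, "verification.yaml"))
  }
  out
}

## single-phase Poiseuille reference case on an unobstructed vessel
poiseuille_case <- function(mode, nx, ny, Vt = 0.2) {
  R <- 50e-6
  geom <- stenosis_geometry(H = R, hs = R, Ls = 2e-6,
                            L_up = 0.5e-3, L_down = 0.5e-3, mode = mode)
  grid <- build_stenosis_grid(geom, nx = nx, ny = ny)
  bc <- boundary_conditions(Vt, 1e-6)
  ## drag on (negligible at phi ~ 1e-6) slaves the near-empty RBC phase to
  ## the plasma so its momentum residual converges with the flow; lifts off
  params <- interaction_params(saffman = FALSE, spin = FALSE)
  config <- solver_config(max_outer = 500, tol = 1e-6,
                          phi_bounds = c(1e-7, 0.68))
  state <- suppressWarnings(steady_solve(grid, bc, params = params,
                                         config = config))
  prof <- section_profile(state, grid, geom$L_down * 0.9)
  ratio <- max(prof$u_plasma) / Vt
  wp <- wall_shear_stress(state, grid)
  mid <- wp$x > geom$L_down * 0.6 & wp$x < geom$L_down * 0.95
  mu <- state$props$plasma_viscosity
  wss_exact <- if (mode == "axisymmetric") 4 * mu * Vt / R else
    3 * mu * Vt / R
  list(state = state, grid = grid, ratio = ratio,
       wss = mean(wp$tau_wss[mid]), wss_exact = wss_exact,
       profile = prof)
}

#' Mesh-independence study
#'
#' Solves the same case at several resolutions, extracts the volume-fraction
#' profile at `x_section` and tabulates the maximum pairwise differences
#' against the finest level, flagging the coarsest resolution within 2% of
#' the finest.
#'
#' @param case `"stenosis"` (currently the only case).
#' @param resolutions List of `c(nx, ny)` (at least 3), coarse to fine.
#' @param x_section Axial position of the comparison profile, m (the study
#'   section; 20 or 25 um are the conventional choices).
#' @param Vt,Ht Inlet conditions.
#' @return A list of class `mesh_study`: `table` (tibble `nx`, `ny`,
#'   `max_diff_vs_finest`), `adequate` (first resolution within 2%),
#'   `x_section`.
#' @export
mesh_independence_study <- function(case = "stenosis",
                                    resolutions = list(c(60, 10), c(90, 14),
                                                       c(120, 20)),
                                    x_section = 20e-6,
                                    Vt = 0.2, Ht = 0.2) {
  stopifnot(length(resolutions) >= 3)
  profs <- lapply(resolutions, function(lv) {
    res <- run_stenosis_case(Vt, Ht, lv[1], lv[2])
    sp <- section_profile(res$state, res$grid, x_section, n_sample = 48)
    stats::approx(sp$y / max(sp$y), sp$phi, xout = seq(0, 1, length.out = 48),
                  rule = 2)$y
  })
  fin <- profs[[length(profs)]]
  scale <- max(abs(fin))
  diffs <- vapply(profs, function(p) max(abs(p - fin)) / scale, numeric(1))
  tab <- tibble::tibble(
    nx = vapply(resolutions, `[`, numeric(1), 1),
    ny = vapply(resolutions, `[`, numeric(1), 2),
    max_diff_vs_finest = diffs)
  adequate <- which(diffs < 0.02)[1]
  structure(list(table = tab, adequate = adequate, x_section = x_section,
                 case = case),
            class = "mesh_study")
}

#' @export
print.mesh_study <- function(x, ...) {
  cat(sprintf("<mesh_study> %s, section x = %g um\n", x$case,
              x$x_section * 1e6))
  print(as.data.frame(x$table), digits = 3)
  cat(sprintf("  first adequate resolution (< 2%% of finest): row %s\n",
              x$adequate))
  invisible(x)
}
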