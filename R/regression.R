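#' Configuration for the shape regression
#'
#' Bundles the model parameters. `gamma` trades the regularity (kinetic
#' energy) term against the currents data-fidelity term; the default 1e-4
#' scales the large-magnitude energy down relative to the fidelity.
#' `lambda_v` is the deformation kernel scale; when `NULL` it is set per fit
#' to `lambda_v_fraction` times the longest edge of the axis-aligned
#' bounding box of all observed lesion vertices. `lambda_w` is the currents
#' test-space scale (5 mm resolves fine shape detail; 35 mm is a coarse
#' alternative for irregular shapes). Time is discretized at `dt_hours`.
#'
#' @param gamma regularity/fidelity trade-off (> 0), default 1e-4.
#' @param lambda_v deformation kernel scale in mm, or `NULL` for the
#'   bounding-box rule.
#' @param lambda_v_fraction fraction of the bounding-box extent used when
#'   `lambda_v` is `NULL` (default 0.30).
#' @param lambda_w currents kernel scale, mm (default 5; 35 for coarse).
#' @param lambda_w_pairwise currents scale used by [fit_pairwise()] for the
#'   cross-modality correspondence deformation (default 35 mm). The
#'   DWI-to-MTT gap exceeds the fine 5 mm scale, at which the currents
#'   gradient cannot see the target and descent degenerates; the coarse
#'   member of the model's 5-or-35 mm two-scale choice is the appropriate
#'   one there.
#' @param dt_hours time discretization step, hours (default 3).
#' @param max_iter gradient-descent iteration cap (default 200).
#' @param tol relative energy-decrease stopping threshold (default 1e-6).
#' @param pairwise_steps number of flow steps used for the pairwise
#'   correspondence deformation on its unit time interval (default 10).
#' @param normals `"area"` or `"unit"` currents normals.
#' @param seed integer seed recorded with the fit (fitting itself is
#'   deterministic; the seed governs synthetic-data generation only).
#' @param verbose print one line per accepted optimizer iteration.
#' @return A `regression_config` list.
#' @export
regression_config <- function(gamma = 1e-4, lambda_v = NULL,
                              lambda_v_fraction = 0.30, lambda_w = 5,
                              lambda_w_pairwise = 35,
                              dt_hours = 3, max_iter = 200L, tol = 1e-6,
                              pairwise_steps = 10L,
                              normals = c("area", "unit"),
                              seed = 1L, verbose = FALSE) {
  if (gamma <= 0) stop("regression_config: gamma must be > 0")
  if (!is.null(lambda_v) && lambda_v <= 0) stop("regression_config: lambda_v must be > 0")
  if (lambda_w <= 0) stop("regression_config: lambda_w must be > 0")
  if (dt_hours <= 0) stop("regression_config: dt_hours must be > 0")
  structure(list(gamma = gamma, lambda_v = lambda_v,
                 lambda_v_fraction = lambda_v_fraction, lambda_w = lambda_w,
                 lambda_w_pairwise = lambda_w_pairwise,
                 dt_hours = dt_hours, max_iter = as.integer(max_iter),
                 tol = tol, pairwise_steps = as.integer(pairwise_steps),
                 normals = match.arg(normals), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "regression_config")
}

#' Deformation scale from the observed lesions' bounding box
#'
#' The longest edge of the axis-aligned box enclosing the vertices of all
#' supplied surfaces, multiplied by `fraction` (default 30%).
#'
#' @param surfaces list of `lesion_surface` objects.
#' @param fraction scale fraction, default 0.30.
#' @return lambda_V in mm.
#' @export
lambda_v_from_surfaces <- function(surfaces, fraction = 0.30) {
  v <- do.call(rbind, lapply(surfaces, function(s) s$vertices))
  extents <- apply(v, 2, function(x) diff(range(x)))
  fraction * max(extents)
}

resolve_lambda_v <- function(cfg, surfaces) {
  if (!is.null(cfg$lambda_v)) cfg$lambda_v
  else lambda_v_from_surfaces(surfaces, cfg$lambda_v_fraction)
}

# target descriptor for the compiled objective: current rep + its self
# inner product, attached to a state index on the step grid
make_target <- function(surface, step, lambda_w, normals) {
  cur <- surface_to_current(surface, lambda_w, normals)
  list(step = as.integer(step), centers = cur$centers, normals = cur$normals,
       self = cpp_currents_inner(cur$centers, cur$normals,
                                 cur$centers, cur$normals, lambda_w))
}

#' Regression functional J(v)
#'
#' `J = gamma * kinetic_energy(mom) + sum_i ||current(chi_{t_i}(S0)) -
#' target_i||^2_W`, the objective minimized by the fitting routines. Target
#' times are snapped to the step grid of `mom` by rounding.
#'
#' @param mom a `momenta_field` whose control points were built from
#'   `baseline`'s face centers.
#' @param baseline the baseline `lesion_surface` advected by the flow.
#' @param targets list of `lesion_surface` objects with `t_hours` set, or a
#'   list of `list(t_hours =, surface =)` pairs.
#' @param cfg a [regression_config()]; `lambda_w`, `gamma` and the normals
#'   convention are taken from it.
#' @return Scalar J, with attributes `energy` and `fidelity`.
#' @export
objective <- function(mom, baseline, targets, cfg = regression_config()) {
  tl <- lapply(targets, function(tg) {
    if (inherits(tg, "lesion_surface")) tg else tg$surface
  })
  th <- vapply(seq_along(targets), function(i) {
    tg <- targets[[i]]
    if (inherits(tg, "lesion_surface")) tg$t_hours else tg$t_hours
  }, numeric(1))
  steps <- as.integer(round((th - mom$t0_hours) / mom$dt_hours))
  if (any(steps < 1L) || any(steps > n_flow_steps(mom)))
    stop("objective: target time off the flow's step grid")
  tgts <- lapply(seq_along(tl), function(i)
    make_target(tl[[i]], steps[i], cfg$lambda_w, cfg$normals))
  ev <- cpp_objective_grad(baseline$vertices, baseline$faces - 1L,
                           array_slice(mom$ctrl_traj, 1L), mom$momenta,
                           mom$lambda_v, cfg$gamma, cfg$lambda_w, tgts, FALSE)
  structure(ev$value, energy = ev$energy, fidelity = ev$fidelity)
}

# Gradient descent with backtracking line search on one flow problem.
# Returns momenta, the deformed vertex trajectory and the iteration log.
fit_flow <- function(baseline, targets_steps, n_steps, lambda_v, cfg) {
  v0 <- baseline$vertices
  f0 <- baseline$faces - 1L
  c0 <- face_centers(baseline)
  n_ctrl <- nrow(c0)
  mom <- array(0, c(n_ctrl, 3L, n_steps))
  evaluate <- function(m, want_grad) {
    cpp_objective_grad(v0, f0, c0, m, lambda_v, cfg$gamma, cfg$lambda_w,
                       targets_steps, want_grad)
  }
  ev <- evaluate(mom, TRUE)
  J <- ev$value
  J0 <- max(abs(J), .Machine$double.xmin)
  if (!is.finite(J)) stop("fit: non-finite objective at initialization")
  log <- list(list(iter = 0L, J = J, energy = ev$energy,
                   fidelity = ev$fidelity, step_size = NA_real_))
  step_size <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    g <- ev$grad
    gmax <- max(abs(g))
    if (!is.finite(gmax)) stop("fit: non-finite gradient")
    if (gmax == 0) { converged <- TRUE; break }
    if (is.null(step_size)) step_size <- 0.05 * lambda_v / gmax
    accepted <- FALSE
    for (bt in seq_len(30L)) {
      m_try <- mom - step_size * g
      J_try <- evaluate(m_try, FALSE)$value
      if (is.finite(J_try) && J_try < J) { accepted <- TRUE; break }
      step_size <- step_size / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    rel <- (J - J_try) / J0   # progress relative to the initial objective
    mom <- m_try
    ev <- evaluate(mom, TRUE)
    J <- ev$value
    log[[length(log) + 1L]] <- list(iter = it, J = J, energy = ev$energy,
                                    fidelity = ev$fidelity,
                                    step_size = step_size)
    if (cfg$verbose)
      message(sprintf("  iter %3d  J = %.6g  energy = %.6g  fidelity = %.6g  step = %.3g",
                      it, J, ev$energy, ev$fidelity, step_size))
    step_size <- step_size * 1.5
    if (rel < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit: iteration cap reached before tolerance; returning best momenta")
  flow <- cpp_flow_forward(v0, c0, mom, lambda_v)
  list(momenta = mom, ctrl_traj = flow$ctrl, vertex_traj = flow$points,
       max_step_disp = flow$max_step_disp,
       log = do.call(rbind, lapply(log, as.data.frame)))
}

#' Pairwise correspondence deformation between two surfaces
#'
#' Estimates the geodesic deformation `phi` morphing `source` onto `target`
#' over a unit time interval by the same energy-minimization scheme as the
#' temporal regression (zero-momenta initialization, gradient descent with
#' backtracking). Used to identify corresponding areas on the DWI and MTT
#' baseline lesions.
#'
#' @param source,target `lesion_surface` objects in the same physical frame.
#' @param cfg a [regression_config()].
#' @return A `correspondence_map` with fields `momenta` (a single-interval
#'   `momenta_field`), `source`, `target`, `deformed` (phi(source)) and the
#'   optimizer `log`.
#' @export
fit_pairwise <- function(source, target, cfg = regression_config()) {
  validate_surface(source)
  validate_surface(target)
  lambda_v <- resolve_lambda_v(cfg, list(source, target))
  n_steps <- cfg$pairwise_steps
  lambda_w <- cfg$lambda_w_pairwise %||% cfg$lambda_w
  cfg_pair <- cfg
  cfg_pair$lambda_w <- lambda_w
  tgt <- list(make_target(target, n_steps, lambda_w, cfg$normals))
  fit <- fit_flow(source, tgt, n_steps, lambda_v, cfg_pair)
  mom <- new_momenta_field(fit$ctrl_traj, fit$momenta, lambda_v,
                           dt_hours = 1, t0_hours = 0)
  deformed <- lesion_surface(array_slice(fit$vertex_traj, n_steps + 1L),
                             source$faces, source$t_hours)
  structure(list(momenta = mom, source = source, target = target,
                 deformed = deformed, lambda_v = lambda_v, config = cfg,
                 log = fit$log),
            class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf("<correspondence_map> %d faces, lambda_V = %.2f mm, final J = %.4g\n",
              nrow(x$source$faces), x$lambda_v, x$log$J[nrow(x$log)]))
  invisible(x)
}

#' Apply a correspondence map to points
#' @param phi a `correspondence_map`.
#' @param points P x 3 matrix (defaults to the source vertices).
#' @param inverse map backward from target frame to source frame.
#' @return P x 3 matrix of mapped points.
#' @export
apply_correspondence <- function(phi, points = phi$source$vertices,
                                 inverse = FALSE) {
  if (inverse) flow_endpoint(flow_inverse(points, phi$momenta))
  else flow_endpoint(flow_forward(points, phi$momenta))
}

#' Piecewise-geodesic regression of a lesion time series
#'
#' Estimates the continuous evolution scenario `chi(t)` deforming the first
#' observed surface so that it passes near each later observation. Momenta
#' are estimated per inter-observation interval, sequentially: interval i
#' starts from the deformed state at `t_i` (continuity of position by
#' construction) and minimizes its own regression functional with the
#' surface observed at `t_{i+1}` as target. The full scenario is sampled at
#' every `dt_hours` step.
#'
#' @param surfaces list of >= 2 `lesion_surface` objects with strictly
#'   increasing `t_hours`.
#' @param cfg a [regression_config()].
#' @return An `evolution_scenario`: `baseline`, `momenta` (combined
#'   `momenta_field` over the whole grid), `surfaces_t` (one mesh per grid
#'   step, shared connectivity), `times_hours`, `obs_times_hours`,
#'   `obs_steps`, per-interval logs.
#' @export
fit_timeseries <- function(surfaces, cfg = regression_config()) {
  if (length(surfaces) < 2L) stop("fit_timeseries: need at least 2 surfaces")
  th <- vapply(surfaces, function(s) s$t_hours, numeric(1))
  if (any(!is.finite(th)) || any(diff(th) <= 0))
    stop("fit_timeseries: acquisition times must be finite and strictly increasing")
  for (s in surfaces) validate_surface(s)
  lambda_v <- resolve_lambda_v(cfg, surfaces)
  obs_steps <- as.integer(round((th - th[1]) / cfg$dt_hours))
  if (any(diff(obs_steps) < 1L))
    stop("fit_timeseries: observations closer than one time step")
  n_total <- obs_steps[length(obs_steps)]
  baseline <- surfaces[[1]]
  n_ctrl <- nrow(face_centers(baseline))

  momenta <- array(0, c(n_ctrl, 3L, n_total))
  ctrl_traj <- array(NA_real_, c(n_ctrl, 3L, n_total + 1L))
  vert_traj <- array(NA_real_, c(nrow(baseline$vertices), 3L, n_total + 1L))
  vert_traj[, , 1L] <- baseline$vertices
  logs <- vector("list", length(surfaces) - 1L)
  current_mesh <- baseline
  for (i in seq_len(length(surfaces) - 1L)) {
    n_i <- obs_steps[i + 1L] - obs_steps[i]
    tgt <- list(make_target(surfaces[[i + 1L]], n_i, cfg$lambda_w, cfg$normals))
    fit <- fit_flow(current_mesh, tgt, n_i, lambda_v, cfg)
    sl <- obs_steps[i] + seq_len(n_i)
    momenta[, , sl] <- fit$momenta
    ctrl_traj[, , c(obs_steps[i] + 1L, sl + 1L)] <- fit$ctrl_traj
    vert_traj[, , sl + 1L] <- fit$vertex_traj[, , -1L, drop = FALSE]
    logs[[i]] <- fit$log
    current_mesh <- lesion_surface(array_slice(fit$vertex_traj, n_i + 1L),
                                   baseline$faces,
                                   th[1] + obs_steps[i + 1L] * cfg$dt_hours)
  }
  mom <- new_momenta_field(ctrl_traj, momenta, lambda_v,
                           dt_hours = cfg$dt_hours, t0_hours = th[1])
  times <- th[1] + cfg$dt_hours * (0:n_total)
  surfaces_t <- lapply(seq_len(n_total + 1L), function(s)
    lesion_surface(array_slice(vert_traj, s), baseline$faces, times[s]))
  structure(list(baseline = baseline, momenta = mom, surfaces_t = surfaces_t,
                 times_hours = times, obs_times_hours = th,
                 obs_steps = obs_steps, lambda_v = lambda_v, config = cfg,
                 logs = logs),
            class = "evolution_scenario")
}

#' @export
print.evolution_scenario <- function(x, ...) {
  cat(sprintf("<evolution_scenario> %d faces, %d steps of %g h over [%g, %g] h, %d observations\n",
              nrow(x$baseline$faces), length(x$surfaces_t) - 1L,
              x$momenta$dt_hours, x$times_hours[1],
              x$times_hours[length(x$times_hours)],
              length(x$obs_times_hours)))
  invisible(x)
}

#' Build an evolution scenario from a known momenta field
#'
#' Advects a baseline surface along an existing `momenta_field` and wraps
#' the result as an `evolution_scenario` — the same container
#' [fit_timeseries()] returns, but driven by prescribed momenta. Used for
#' generator ground truth and for analysing hand-built flows.
#'
#' @param baseline a `lesion_surface` at the flow's start time.
#' @param mom a `momenta_field` (its `t0_hours`/`dt_hours` define the grid).
#' @param obs_times_hours optional observation times to record.
#' @return An `evolution_scenario`.
#' @export
scenario_from_momenta <- function(baseline, mom, obs_times_hours = NULL) {
  fl <- flow_forward(baseline$vertices, mom)
  times <- flow_times(mom)
  surfaces_t <- lapply(seq_along(times), function(s)
    lesion_surface(array_slice(fl$point_trajectories, s), baseline$faces,
                   times[s]))
  if (is.null(obs_times_hours))
    obs_times_hours <- c(times[1], times[length(times)])
  structure(list(baseline = baseline, momenta = mom, surfaces_t = surfaces_t,
                 times_hours = times, obs_times_hours = obs_times_hours,
                 obs_steps = as.integer(round((obs_times_hours - times[1]) /
                                                mom$dt_hours)),
                 lambda_v = mom$lambda_v, config = NULL, logs = NULL),
            class = "evolution_scenario")
}

#' Scenario truth/estimate surface nearest to a time
#'
#' Returns the mesh of the scenario's step grid nearest to `t_hours`
#' (no sub-step interpolation).
#'
#' @param scn an `evolution_scenario`.
#' @param t_hours query time, within the scenario's span.
#' @return A `lesion_surface`.
#' @export
sample_surface <- function(scn, t_hours) {
  tmin <- scn$times_hours[1]
  tmax <- scn$times_hours[length(scn$times_hours)]
  if (t_hours < tmin || t_hours > tmax)
    stop("sample_surface: time outside the scenario span")
  idx <- which.min(abs(scn$times_hours - t_hours))
  scn$surfaces_t[[idx]]
}

#' Serialize fitted momenta as plain tabular arrays with a JSON header
#'
#' Writes `<stem>.json` (lambda values, step, times, dimensions) and
#' `<stem>_momenta.csv` / `<stem>_control_points.csv` in long format.
#'
#' @param mom a `momenta_field`.
#' @param stem output path stem.
#' @return The JSON path, invisibly.
#' @export
write_momenta <- function(mom, stem) {
  d <- dim(mom$momenta)
  hdr <- list(n_control = d[1], n_steps = d[3], lambda_v = mom$lambda_v,
              dt_hours = mom$dt_hours, t0_hours = mom$t0_hours,
              times_hours = flow_times(mom))
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  long <- function(a, nm) {
    dd <- dim(a)
    data.frame(step = rep(seq_len(dd[3]), each = dd[1]),
               point = rep(seq_len(dd[1]), times = dd[3]),
               x = as.vector(a[, 1, ]), y = as.vector(a[, 2, ]),
               z = as.vector(a[, 3, ]))
  }
  write.csv(long(mom$momenta), paste0(stem, "_momenta.csv"), row.names = FALSE)
  write.csv(long(mom$ctrl_traj), paste0(stem, "_control_points.csv"),
            row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
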