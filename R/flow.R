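#' Time-indexed momenta parameterizing a diffeomorphic flow
#'
#' Momentum vectors `alpha_k(t)` attached to control points generate the
#' velocity field `v_t(x) = sum_k exp(-|x_k(t) - x|^2 / lambda_v^2) alpha_k(t)`
#' (mm per time step). The constructor integrates the self-advection of the
#' control points with explicit Euler on the step grid, so the full
#' control-point trajectories are stored alongside the momenta.
#'
#' @param control_points N x 3 matrix, initial control points (typically the
#'   face centers of the baseline surface), mm.
#' @param momenta N x 3 x T array of momentum vectors (mm per step), or
#'   N x 3 matrix recycled over `n_steps`.
#' @param lambda_v deformation kernel scale, mm.
#' @param dt_hours physical duration of one step (default 3 h).
#' @param t0_hours time of the first frame, hours from onset.
#' @param n_steps required when `momenta` is a matrix.
#' @return An object of class `momenta_field` with the control trajectories
#'   in `$ctrl_traj` (N x 3 x (T+1)).
#' @export
momenta_field <- function(control_points, momenta, lambda_v,
                          dt_hours = 3, t0_hours = 0, n_steps = NULL) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 3L) stop("momenta_field: control_points must be N x 3")
  if (length(dim(momenta)) == 2L) {
    if (is.null(n_steps)) stop("momenta_field: n_steps needed for constant momenta")
    momenta <- array(rep(as.matrix(momenta), n_steps),
                     c(nrow(control_points), 3L, n_steps))
  }
  if (length(dim(momenta)) != 3L || dim(momenta)[1] != nrow(control_points) ||
      dim(momenta)[2] != 3L)
    stop("momenta_field: momenta must be N x 3 x T")
  if (!is.numeric(lambda_v) || lambda_v <= 0) stop("momenta_field: lambda_v must be > 0")
  if (dt_hours <= 0) stop("momenta_field: dt_hours must be > 0")
  fl <- cpp_flow_forward(control_points[0, , drop = FALSE], control_points,
                         momenta, lambda_v)
  out <- new_momenta_field(fl$ctrl, momenta, lambda_v, dt_hours, t0_hours)
  if (fl$max_step_disp > lambda_v)
    stop("momenta_field: single-step displacement exceeds lambda_v; ",
         "momenta magnitude is unstable")
  out
}

# internal constructor when control trajectories are already integrated
new_momenta_field <- function(ctrl_traj, momenta, lambda_v, dt_hours, t0_hours) {
  structure(list(ctrl_traj = ctrl_traj, momenta = momenta,
                 lambda_v = as.numeric(lambda_v), dt_hours = as.numeric(dt_hours),
                 t0_hours = as.numeric(t0_hours)),
            class = "momenta_field")
}

#' @export
print.momenta_field <- function(x, ...) {
  cat(sprintf("<momenta_field> %d control points, %d steps of %g h, lambda_V = %g mm\n",
              dim(x$momenta)[1], dim(x$momenta)[3], x$dt_hours, x$lambda_v))
  invisible(x)
}

n_flow_steps <- function(mom) dim(mom$momenta)[3]

# slice s of an N x 3 x T array as an N x 3 matrix (robust to N == 1)
array_slice <- function(a, s) matrix(a[, , s], ncol = 3L)

flow_times <- function(mom) {
  mom$t0_hours + mom$dt_hours * (0:n_flow_steps(mom))
}

#' Evaluate the kernel velocity field
#'
#' `v_i = sum_k exp(-|x_k(t) - q_i|^2 / lambda_v^2) alpha_k(t)` using the
#' control-point positions at the given step.
#'
#' @param query P x 3 matrix of evaluation points, mm.
#' @param step step index in `1..T` (velocity acting over
#'   `[t_{step-1}, t_step]`).
#' @param mom a `momenta_field`.
#' @return P x 3 matrix of velocities, mm per step.
#' @export
velocity_at <- function(query, step, mom) {
  step <- as.integer(step)
  if (step < 1L || step > n_flow_steps(mom))
    stop("velocity_at: step out of range")
  cpp_velocity(as.matrix(query), array_slice(mom$ctrl_traj, step),
               array_slice(mom$momenta, step), mom$lambda_v)
}

#' Advect points forward along a momenta flow
#'
#' Explicit Euler integration of the flow ODE on the step grid; the queried
#' points ride the same velocity field that self-advects the control points.
#'
#' @param points P x 3 matrix of tracked points, mm.
#' @param mom a `momenta_field`.
#' @return A `flow_result`: `point_trajectories` (P x 3 x (T+1), first frame
#'   equals the input) and `times_hours`.
#' @export
flow_forward <- function(points, mom) {
  points <- as.matrix(points)
  fl <- cpp_flow_forward(points, array_slice(mom$ctrl_traj, 1L),
                         mom$momenta, mom$lambda_v)
  if (fl$max_step_disp > mom$lambda_v)
    stop("flow_forward: single-step displacement exceeds lambda_v; ",
         "momenta magnitude is unstable")
  structure(list(point_trajectories = fl$points, times_hours = flow_times(mom)),
            class = "flow_result")
}

#' Advect points backward (inverse flow)
#'
#' Integrates the negated velocity field backward along the stored
#' control-point trajectories, so that composing with [flow_forward()]
#' approximately returns the start points.
#'
#' @param points P x 3 matrix of points at the final time, mm.
#' @param mom a `momenta_field`.
#' @return A `flow_result`; frame `s + 1` holds the state after `s` backward
#'   steps and `times_hours` decreases accordingly.
#' @export
flow_inverse <- function(points, mom) {
  points <- as.matrix(points)
  tr <- cpp_flow_inverse(points, mom$ctrl_traj, mom$momenta, mom$lambda_v)
  structure(list(point_trajectories = tr, times_hours = rev(flow_times(mom))),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  d <- dim(x$point_trajectories)
  cat(sprintf("<flow_result> %d points over %d frames (%g..%g h)\n",
              d[1], d[3], x$times_hours[1], x$times_hours[length(x$times_hours)]))
  invisible(x)
}

#' Final frame of a flow as a point matrix
#' @param flow a `flow_result`.
#' @return P x 3 matrix.
#' @export
flow_endpoint <- function(flow) {
  d <- dim(flow$point_trajectories)
  array_slice(flow$point_trajectories, d[3])
}

#' Kinetic energy of a momenta field
#'
#' `sum_t sum_ij K_V(x_i(t), x_j(t)) (alpha_i(t) . alpha_j(t))`, the squared
#' RKHS norm of the velocity field accumulated over the step grid (one
#' internal time unit per step). This is the regularity term of the
#' regression functional and is physically the kinetic energy of the
#' deformation.
#'
#' @param mom a `momenta_field`.
#' @return Non-negative scalar.
#' @export
kinetic_energy <- function(mom) {
  cpp_kinetic_energy(mom$ctrl_traj, mom$momenta, mom$lambda_v)
}
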