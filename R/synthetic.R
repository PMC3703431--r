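#' Triangulated sphere by icosahedron subdivision
#'
#' Starts from a regular icosahedron, splits each face into four and
#' projects new vertices back to the sphere; faces are wound consistently
#' outward.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 1-to-4 refinement passes (0 = icosahedron;
#'   3 gives 1280 faces).
#' @param center sphere center, mm.
#' @param t_hours acquisition time stamped on the surface.
#' @return A closed `lesion_surface`.
#' @export
make_icosphere <- function(radius, subdivisions = 2L, center = c(0, 0, 0),
                           t_hours = NA_real_) {
  if (radius <= 0) stop("make_icosphere: radius must be > 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c_, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  # orient every face outward (valid on a convex sphere)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], ]
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * colMeans(tri)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  verts <- sweep(v * radius, 2, center, `+`)
  out <- lesion_surface(verts, f, t_hours)
  validate_surface(out)
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# outward unit vertex normals (area-weighted average of adjacent faces)
vertex_normals <- function(surface) {
  fn <- face_normals(surface)
  acc <- rowsum(rbind(fn, fn, fn),
                c(surface$faces[, 1], surface$faces[, 2], surface$faces[, 3]),
                reorder = TRUE)
  vn <- matrix(0, nrow(surface$vertices), 3L)
  vn[as.integer(rownames(acc)), ] <- acc
  vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
}

# lobe momenta on a sphere-like baseline: unit radial momenta inside the
# angular lobes, scaled so the apex point moves at the requested speed
lobe_momenta <- function(surface, center, axis, half_angle_deg,
                         expand_mm_step, contract_mm_step, lambda_v) {
  ctr <- face_centers(surface)
  u <- sweep(ctr, 2, center, `-`)
  r <- sqrt(rowSums(u^2))
  u <- u / r
  cos_thr <- cos(half_angle_deg * pi / 180)
  ca <- as.vector(u %*% axis)
  in_exp <- ca >= cos_thr
  in_con <- -ca >= cos_thr
  alpha <- matrix(0, nrow(ctr), 3L)
  scale_for <- function(members, sign_, apex, rate) {
    if (!any(members) || rate == 0) return(NULL)
    a <- matrix(0, nrow(ctr), 3L)
    a[members, ] <- sign_ * u[members, , drop = FALSE]
    v <- cpp_velocity(rbind(apex), ctr, a, lambda_v)
    sp <- sqrt(sum(v^2))
    if (sp < 1e-12) return(NULL)
    a * rate / sp
  }
  r_mean <- mean(r)
  ae <- scale_for(in_exp, 1, center + r_mean * axis, expand_mm_step)
  ac <- scale_for(in_con, -1, center - r_mean * axis, contract_mm_step)
  if (!is.null(ae)) alpha <- alpha + ae
  if (!is.null(ac)) alpha <- alpha + ac
  list(alpha = alpha, expansion = in_exp, contraction = in_con)
}

#' Generate one synthetic stroke patient with full ground truth
#'
#' Emulates the data structure the analysis expects: solitary DWI and MTT
#' lesions observed at three timepoints (~5 h, ~5 d, ~10.5 d), the MTT
#' lesion enclosing the DWI lesion at baseline with a mismatch above
#' 3 cm^3, anisotropic dynamics (an expansion lobe and a contraction lobe
#' per modality, by default MTT expanding faster and DWI contracting
#' faster), and a final T2 surface that the evolving DWI lesion crosses at
#' a known time. Dynamics live in the model's own family (kernel momenta
#' flows), so every downstream quantity has an exact truth; the `"radial"`
#' mode instead grows the lesions by direct radial reparameterization,
#' outside the model family.
#'
#' @param seed integer seed; identical seeds give bit-identical patients.
#' @param dwi_r0,mtt_r0 baseline sphere radii, mm (defaults 20 and 28).
#' @param center lesion center, mm.
#' @param lobe_axis unit direction of the expansion lobe (contraction lobe
#'   is antipodal).
#' @param lobe_half_angle half-opening angle of each lobe, degrees.
#' @param dwi_expand_speed,dwi_contract_speed,mtt_expand_speed,
#'   mtt_contract_speed apex speeds in cm/3h.
#' @param lambda_v_true deformation scale of the generating flow, mm.
#' @param subdivisions icosphere refinement (2 = 320 faces).
#' @param noise_sd SD of vertex jitter along vertex normals (mm), applied
#'   to the emitted t2/t3 observations only.
#' @param t1_hours first acquisition time (default 5 h).
#' @param t2_hours,t3_hours later acquisition times; when `NULL`, drawn as
#'   120 +/- 24 h and 252 +/- 60 h.
#' @param t2_cross_hours time at which the DWI front is defined to coincide
#'   with the T2 surface; when `NULL`, the midpoint of [t2, t3] (snapped to
#'   the step grid).
#' @param dt_hours step of the truth flow grid (default 3 h).
#' @param dynamics `"momenta"` (in-family, default) or `"radial"`
#'   (out-of-family uniform radial growth at the apex speeds).
#' @return A `synthetic_patient`: `dwi_surfaces`, `mtt_surfaces`
#'   (3 timed surfaces each), `t2_surface`, `times_hours`, `truth` (momenta,
#'   truth scenarios, lobe memberships, T2-crossing time) and `params`.
#' @export
generate_patient <- function(seed = 1L, dwi_r0 = 20, mtt_r0 = 28,
                             center = c(0, 0, 0), lobe_axis = c(0, 0, 1),
                             lobe_half_angle = 50,
                             dwi_expand_speed = 0.015,
                             dwi_contract_speed = 0.010,
                             mtt_expand_speed = 0.030,
                             mtt_contract_speed = 0.008,
                             lambda_v_true = 15, subdivisions = 2L,
                             noise_sd = 0, t1_hours = 5, t2_hours = NULL,
                             t3_hours = NULL, t2_cross_hours = NULL,
                             dt_hours = 3,
                             dynamics = c("momenta", "radial")) {
  dynamics <- match.arg(dynamics)
  set.seed(as.integer(seed))
  t2_draw <- 120 + runif(1, -24, 24)
  t3_draw <- 252 + runif(1, -60, 60)
  if (is.null(t2_hours)) t2_hours <- t2_draw
  if (is.null(t3_hours)) t3_hours <- t3_draw
  if (!(t1_hours < t2_hours && t2_hours < t3_hours))
    stop("generate_patient: need t1 < t2 < t3")
  if (dwi_r0 >= mtt_r0)
    stop("generate_patient: DWI baseline must nest strictly inside MTT")
  lobe_axis <- lobe_axis / sqrt(sum(lobe_axis^2))

  n_steps <- as.integer(round((t3_hours - t1_hours) / dt_hours))
  s2 <- as.integer(round((t2_hours - t1_hours) / dt_hours))
  if (s2 < 1L || s2 >= n_steps)
    stop("generate_patient: t2 collapses onto t1 or t3 on the step grid")
  t2_snap <- t1_hours + s2 * dt_hours
  t3_snap <- t1_hours + n_steps * dt_hours
  if (is.null(t2_cross_hours)) t2_cross_hours <- (t2_snap + t3_snap) / 2
  s_cross <- as.integer(round((t2_cross_hours - t1_hours) / dt_hours))
  s_cross <- max(1L, min(n_steps, s_cross))
  t_cross <- t1_hours + s_cross * dt_hours

  dwi0 <- make_icosphere(dwi_r0, subdivisions, center, t1_hours)
  mtt0 <- make_icosphere(mtt_r0, subdivisions, center, t1_hours)
  mismatch <- enclosed_volume(mtt0) - enclosed_volume(dwi0)
  if (mismatch <= 3000)
    stop("generate_patient: MTT/DWI mismatch must exceed 3 cm^3")

  to_mm_step <- function(cm3h) cm3h * 10 * dt_hours / 3

  if (dynamics == "momenta") {
    build <- function(base, es, cs) {
      lm <- lobe_momenta(base, center, lobe_axis, lobe_half_angle,
                         to_mm_step(es), to_mm_step(cs), lambda_v_true)
      mom <- momenta_field(face_centers(base), lm$alpha, lambda_v_true,
                           dt_hours, t1_hours, n_steps = n_steps)
      scn <- scenario_from_momenta(base, mom,
                                   c(t1_hours, t2_snap, t3_snap))
      list(mom = mom, scn = scn, lm = lm)
    }
    dwi <- build(dwi0, dwi_expand_speed, dwi_contract_speed)
    mtt <- build(mtt0, mtt_expand_speed, mtt_contract_speed)
    dwi_meshes <- dwi$scn$surfaces_t
    mtt_meshes <- mtt$scn$surfaces_t
  } else {
    radial_mesh <- function(base, rate_mm_step, step, t) {
      u <- sweep(base$vertices, 2, center, `-`)
      r <- sqrt(rowSums(u^2))
      lesion_surface(sweep(u * (1 + rate_mm_step * step / r), 2, center, `+`),
                     base$faces, t)
    }
    dwi_meshes <- lapply(0:n_steps, function(s)
      radial_mesh(dwi0, to_mm_step(dwi_expand_speed), s,
                  t1_hours + s * dt_hours))
    mtt_meshes <- lapply(0:n_steps, function(s)
      radial_mesh(mtt0, to_mm_step(mtt_expand_speed), s,
                  t1_hours + s * dt_hours))
    dwi <- mtt <- NULL
  }

  jitter <- function(mesh) {
    if (noise_sd <= 0) return(mesh)
    vn <- vertex_normals(mesh)
    lesion_surface(mesh$vertices + vn * rnorm(nrow(vn), 0, noise_sd),
                   mesh$faces, mesh$t_hours)
  }
  pick <- function(meshes, s, t) {
    m <- meshes[[s + 1L]]
    lesion_surface(m$vertices, m$faces, t)
  }
  dwi_surfaces <- list(pick(dwi_meshes, 0L, t1_hours),
                       jitter(pick(dwi_meshes, s2, t2_snap)),
                       jitter(pick(dwi_meshes, n_steps, t3_snap)))
  mtt_surfaces <- list(pick(mtt_meshes, 0L, t1_hours),
                       jitter(pick(mtt_meshes, s2, t2_snap)),
                       jitter(pick(mtt_meshes, n_steps, t3_snap)))
  t2_surface <- lesion_surface(dwi_meshes[[s_cross + 1L]]$vertices,
                               dwi_meshes[[s_cross + 1L]]$faces, NA_real_)

  truth <- list(
    dwi_scenario = if (!is.null(dwi)) dwi$scn,
    mtt_scenario = if (!is.null(mtt)) mtt$scn,
    dwi_momenta = if (!is.null(dwi)) dwi$mom,
    mtt_momenta = if (!is.null(mtt)) mtt$mom,
    dwi_expansion_faces = if (!is.null(dwi)) dwi$lm$expansion,
    dwi_contraction_faces = if (!is.null(dwi)) dwi$lm$contraction,
    mtt_expansion_faces = if (!is.null(mtt)) mtt$lm$expansion,
    mtt_contraction_faces = if (!is.null(mtt)) mtt$lm$contraction,
    t2_cross_hours = t_cross, t2_cross_step = s_cross)

  structure(list(dwi_surfaces = dwi_surfaces, mtt_surfaces = mtt_surfaces,
                 t2_surface = t2_surface,
                 times_hours = c(t1_hours, t2_snap, t3_snap),
                 truth = truth, seed = as.integer(seed),
                 params = list(dwi_r0 = dwi_r0, mtt_r0 = mtt_r0,
                               center = center, lobe_axis = lobe_axis,
                               lobe_half_angle = lobe_half_angle,
                               dwi_expand_speed = dwi_expand_speed,
                               dwi_contract_speed = dwi_contract_speed,
                               mtt_expand_speed = mtt_expand_speed,
                               mtt_contract_speed = mtt_contract_speed,
                               lambda_v_true = lambda_v_true,
                               subdivisions = subdivisions,
                               noise_sd = noise_sd, dt_hours = dt_hours,
                               dynamics = dynamics,
                               mismatch_mm3 = mismatch)),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> seed %d: DWI r0 %.1f mm, MTT r0 %.1f mm, mismatch %.1f cm^3\n  times %s h, T2 crossed at %g h (%s dynamics)\n",
              x$seed, x$params$dwi_r0, x$params$mtt_r0,
              x$params$mismatch_mm3 / 1000,
              paste(round(x$times_hours, 1), collapse = " / "),
              x$truth$t2_cross_hours, x$params$dynamics))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient geometry and kinetics from configured ranges (baseline
#' radii, lobe axis, speed multipliers, acquisition schedule) with seeds
#' derived deterministically from one master seed; the default size mirrors
#' an 8-patient study design.
#'
#' @param n number of patients (default 8).
#' @param seed master seed.
#' @param subdivisions,noise_sd,dynamics passed to [generate_patient()].
#' @param dwi_r0_range,mtt_gap_range uniform ranges for the DWI baseline
#'   radius and the MTT-minus-DWI radius gap, mm.
#' @param speed_scale_range uniform range of the per-patient multiplier
#'   applied to all four default apex speeds.
#' @return List of `synthetic_patient` objects.
#' @export
generate_cohort <- function(n = 8L, seed = 1L, subdivisions = 2L,
                            noise_sd = 0, dynamics = "momenta",
                            dwi_r0_range = c(16, 24),
                            mtt_gap_range = c(6, 10),
                            speed_scale_range = c(0.7, 1.3)) {
  n <- as.integer(n)
  if (n < 1L) stop("generate_cohort: n must be >= 1")
  set.seed(as.integer(seed))
  seeds <- sample.int(1000000L, n)
  lapply(seq_len(n), function(i) {
    dwi_r0 <- runif(1, dwi_r0_range[1], dwi_r0_range[2])
    mtt_r0 <- dwi_r0 + runif(1, mtt_gap_range[1], mtt_gap_range[2])
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    sc <- runif(1, speed_scale_range[1], speed_scale_range[2])
    generate_patient(seed = seeds[i], dwi_r0 = dwi_r0, mtt_r0 = mtt_r0,
                     lobe_axis = ax,
                     dwi_expand_speed = 0.015 * sc,
                     dwi_contract_speed = 0.010 * sc,
                     mtt_expand_speed = 0.030 * sc,
                     mtt_contract_speed = 0.008 * sc,
                     subdivisions = subdivisions, noise_sd = noise_sd,
                     dynamics = dynamics)
  })
}
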