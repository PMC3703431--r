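# Shared fixtures and independent oracles, all built in code.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# pentagonal bipyramid: the smallest closed mesh with exactly 10 faces
make_bipyramid <- function(r = 10, h = 12, center = c(0, 0, 0)) {
  th <- 2 * pi * (0:4) / 5
  v <- rbind(cbind(r * cos(th), r * sin(th), 0), c(0, 0, h), c(0, 0, -h))
  f <- NULL
  for (i in 1:5) {
    j <- i %% 5 + 1
    f <- rbind(f, c(i, j, 6), c(j, i, 7))
  }
  lesion_surface(sweep(v, 2, center, `+`), f)
}

# axis-aligned box as 12 outward-wound triangles
make_box <- function(lo, hi) {
  v <- rbind(c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
             c(hi[1], hi[2], lo[3]), c(lo[1], hi[2], lo[3]),
             c(lo[1], lo[2], hi[3]), c(hi[1], lo[2], hi[3]),
             c(hi[1], hi[2], hi[3]), c(lo[1], hi[2], hi[3]))
  f <- rbind(c(1, 4, 3), c(1, 3, 2), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
             c(4, 1, 5), c(4, 5, 8), c(2, 3, 7), c(2, 7, 6))
  lesion_surface(v, f)
}

translate_surface <- function(s, d) {
  lesion_surface(sweep(s$vertices, 2, d, `+`), s$faces, s$t_hours)
}

# pure 1-to-4 midpoint subdivision (no reprojection): represents the same
# piecewise-flat geometry with 4x the faces
subdivide_mesh <- function(s) {
  v <- s$vertices
  f <- s$faces
  env <- new.env(hash = TRUE)
  newv <- list()
  nv <- nrow(v)
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- env[[key]]
    if (!is.null(id)) return(id)
    newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
    id <- nv + length(newv)
    env[[key]] <- id
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
  lesion_surface(rbind(v, do.call(rbind, newv)), nf, s$t_hours)
}

# naive O(M^2) double-sum currents inner product in plain R
naive_currents_inner <- function(A, B) {
  s <- 0
  il2 <- 1 / A$lambda_w^2
  for (i in seq_len(nrow(A$centers)))
    for (j in seq_len(nrow(B$centers)))
      s <- s + exp(-sum((A$centers[i, ] - B$centers[j, ])^2) * il2) *
        sum(A$normals[i, ] * B$normals[j, ])
  s
}

# naive kernel velocity: direct triple sum
naive_velocity <- function(query, ctrl, alpha, lambda_v) {
  out <- matrix(0, nrow(query), 3)
  for (p in seq_len(nrow(query)))
    for (k in seq_len(nrow(ctrl)))
      out[p, ] <- out[p, ] +
        exp(-sum((ctrl[k, ] - query[p, ])^2) / lambda_v^2) * alpha[k, ]
  out
}

# naive kinetic energy along stored control trajectories
naive_kinetic_energy <- function(mom) {
  E <- 0
  n_steps <- dim(mom$momenta)[3]
  for (t in seq_len(n_steps)) {
    x <- matrix(mom$ctrl_traj[, , t], ncol = 3)
    a <- matrix(mom$momenta[, , t], ncol = 3)
    for (i in seq_len(nrow(x)))
      for (j in seq_len(nrow(x)))
        E <- E + exp(-sum((x[i, ] - x[j, ])^2) / mom$lambda_v^2) *
          sum(a[i, ] * a[j, ])
  }
  E
}

# point-to-triangle distance by plane projection + clamped edge segments
# (formulation independent of the region-based implementation)
naive_pt_tri <- function(p, a, b, c) {
  d_seg <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- cross3(b - a, c - a)
  nn <- sum(n * n)
  edge_min <- min(d_seg(p, a, b), d_seg(p, b, c), d_seg(p, c, a))
  if (nn < 1e-30) return(edge_min)
  q <- p - n * sum((p - a) * n) / nn
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((p - q)^2)))
  edge_min
}

naive_min_dist <- function(points, surface) {
  vapply(seq_len(nrow(points)), function(p) {
    best <- Inf
    for (f in seq_len(nrow(surface$faces))) {
      tri <- surface$vertices[surface$faces[f, ], ]
      best <- min(best, naive_pt_tri(points[p, ], tri[1, ], tri[2, ], tri[3, ]))
    }
    best
  }, numeric(1))
}

# smooth random momenta field on a surface's face centers (for flow tests)
random_momenta <- function(surface, lambda_v, sd_frac = 0.01, n_steps = 8L,
                           dt_hours = 3, t0_hours = 0) {
  ctr <- face_centers(surface)
  alpha <- matrix(rnorm(nrow(ctr) * 3, 0, sd_frac * lambda_v), ncol = 3)
  momenta_field(ctr, alpha, lambda_v, dt_hours, t0_hours, n_steps = n_steps)
}

# evolution-scenario shell around a prescribed list of meshes (for analytic
# kinetics fixtures that are not generated by a kernel flow)
fake_scenario <- function(meshes, dt_hours = 3, t0_hours = 0) {
  times <- t0_hours + dt_hours * (seq_along(meshes) - 1L)
  structure(list(baseline = meshes[[1]],
                 momenta = list(dt_hours = dt_hours),
                 surfaces_t = meshes, times_hours = times,
                 obs_times_hours = range(times),
                 obs_steps = c(0L, length(meshes) - 1L),
                 lambda_v = NA_real_, config = NULL, logs = NULL),
            class = "evolution_scenario")
}

expect_valid_surface <- function(s) {
  expect_silent(validate_surface(s))
}
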