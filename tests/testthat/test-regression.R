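test_that("the objective assembles gamma * energy + currents fidelity", {
  s <- make_icosphere(10, 1)
  s$t_hours <- 0
  cfg <- regression_config(lambda_v = 15, dt_hours = 3)
  ctr <- face_centers(s)

  # zero momenta, target = baseline -> J = 0
  mom0 <- momenta_field(ctr, array(0, c(nrow(ctr), 3, 4)), 15, dt_hours = 3,
                        t0_hours = 0)
  tgt_same <- s
  tgt_same$t_hours <- 12
  expect_equal(as.numeric(objective(mom0, s, list(tgt_same), cfg)), 0,
               tolerance = 1e-9)

  # zero momenta, displaced target -> J = currents_dist2(baseline, target)
  tgt <- translate_surface(s, c(4, 0, 0))
  tgt$t_hours <- 12
  d2 <- currents_dist2(surface_to_current(s, cfg$lambda_w),
                       surface_to_current(tgt, cfg$lambda_w))
  expect_equal(as.numeric(objective(mom0, s, list(tgt), cfg)), d2,
               tolerance = 1e-8)

  # random momenta: equals the hand-assembled sum of the two audited terms
  set.seed(21)
  mom <- random_momenta(s, 15, sd_frac = 0.01, n_steps = 4)
  J <- objective(mom, s, list(tgt), cfg)
  fw <- flow_forward(s$vertices, mom)
  deformed <- lesion_surface(flow_endpoint(fw), s$faces)
  fid <- currents_dist2(surface_to_current(deformed, cfg$lambda_w),
                        surface_to_current(tgt, cfg$lambda_w))
  expect_equal(as.numeric(J), cfg$gamma * kinetic_energy(mom) + fid,
               tolerance = 1e-8)
  expect_equal(attr(J, "energy"), kinetic_energy(mom), tolerance = 1e-10)
  expect_equal(attr(J, "fidelity"), fid, tolerance = 1e-8)
})

test_that("analytic gradients agree with central finite differences", {
  b <- make_bipyramid(10, 12)              # 10-face problem
  tgt <- lesion_surface(b$vertices * 1.15 +
                          matrix(rep(c(2, -1, 1), each = 7), 7),
                        b$faces)
  tg <- lesion4d:::make_target(tgt, 3L, 5, "area")
  c0 <- face_centers(b)
  set.seed(42)
  mom <- array(rnorm(10 * 3 * 3, 0, 0.3), c(10, 3, 3))
  obj <- function(m, grad) {
    lesion4d:::cpp_objective_grad(b$vertices, b$faces - 1L, c0, m, 12, 1e-4,
                                  5, list(tg), grad)
  }
  g <- obj(mom, TRUE)$grad
  fd <- array(0, dim(mom))
  eps <- 1e-5
  for (i in seq_along(mom)) {
    mp <- mom; mp[i] <- mp[i] + eps
    mm <- mom; mm[i] <- mm[i] - eps
    fd[i] <- (obj(mp, FALSE)$value - obj(mm, FALSE)$value) / (2 * eps)
  }
  expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 1e-4)
})

test_that("fitting a surface to itself stays near the identity", {
  s <- make_icosphere(10, 1, t_hours = 0)
  cfg <- regression_config(lambda_v = 20, max_iter = 60)
  self_fit <- fit_pairwise(s, s, cfg)
  moved <- fit_pairwise(s, translate_surface(s, c(5, 0, 0)), cfg)
  expect_lt(kinetic_energy(self_fit$momenta),
            1e-6 * kinetic_energy(moved$momenta))
  expect_lt(max(abs(self_fit$deformed$vertices - s$vertices)), 0.05)
})

test_that("a pure 5 mm translation is recovered to sub-millimetre accuracy", {
  s <- make_icosphere(10, 2, t_hours = 0)
  tgt <- translate_surface(s, c(5, 0, 0))
  cfg <- regression_config(lambda_v = 20, max_iter = 150)
  phi <- fit_pairwise(s, tgt, cfg)
  err <- sqrt(rowSums((phi$deformed$vertices - tgt$vertices)^2))
  expect_lt(mean(err), 1)
  expect_true(all(diff(phi$log$J) <= 0))      # monotone under backtracking
  # final objective never exceeds the initial one
  expect_lte(phi$log$J[nrow(phi$log)], phi$log$J[1])
})

test_that("sphere-to-ellipsoid matching reaches dice >= 0.9", {
  s <- make_icosphere(10, 2, t_hours = 0)
  ell <- lesion_surface(sweep(s$vertices, 2, c(1.4, 1.0, 0.8), `*`), s$faces)
  cfg <- regression_config(lambda_v = 20, max_iter = 150)
  phi <- suppressWarnings(fit_pairwise(s, ell, cfg))
  expect_gte(dice_surfaces(phi$deformed, ell), 0.9)
  expect_true(all(diff(phi$log$J) <= 0))
})

test_that("time-series regression snaps observations onto the step grid", {
  p <- generate_patient(seed = 2, subdivisions = 1L)
  cfg <- regression_config(max_iter = 40)
  scn <- suppressWarnings(fit_timeseries(p$dwi_surfaces, cfg))
  t1 <- p$times_hours[1]
  t3 <- p$times_hours[3]
  expect_equal(length(scn$surfaces_t) - 1L, round((t3 - t1) / 3))
  expect_equal(scn$times_hours, seq(t1, t3, by = 3))
  # sampling rules
  expect_identical(sample_surface(scn, t1), scn$surfaces_t[[1]])
  expect_identical(sample_surface(scn, t1 + 1.4), scn$surfaces_t[[1]])
  expect_identical(sample_surface(scn, t1 + 1.6), scn$surfaces_t[[2]])
  expect_identical(sample_surface(scn, t3), scn$surfaces_t[[length(scn$surfaces_t)]])
  expect_error(sample_surface(scn, t3 + 5), "span")
  # baseline is the first observation, connectivity shared throughout
  expect_identical(scn$surfaces_t[[1]]$vertices, p$dwi_surfaces[[1]]$vertices)
  expect_identical(scn$surfaces_t[[10]]$faces, scn$baseline$faces)
})

test_that("three identical observations produce a near-identity scenario", {
  s <- make_icosphere(12, 1)
  surfaces <- lapply(c(5, 120, 250), function(t) {
    out <- s
    out$t_hours <- t
    out
  })
  scn <- fit_timeseries(surfaces, regression_config(max_iter = 30))
  sp <- signed_speed(scn)
  expect_lt(max(abs(sp$speeds)), 1e-4)     # cm/3h
})

test_that("in-family synthetic dynamics are recovered with dice >= 0.85", {
  p <- generate_patient(seed = 14, subdivisions = 1L)
  scn <- fit_timeseries(p$dwi_surfaces, regression_config())
  d2 <- dice_surfaces(sample_surface(scn, p$times_hours[2]),
                      p$dwi_surfaces[[2]])
  d3 <- dice_surfaces(sample_surface(scn, p$times_hours[3]),
                      p$dwi_surfaces[[3]])
  expect_gte(d2, 0.85)
  expect_gte(d3, 0.85)
  # objective non-increasing on every interval
  for (lg in scn$logs) expect_true(all(diff(lg$J) <= 0))
  # diffeomorphism proxy: no face normal flips along the flow
  prev <- face_normals(scn$surfaces_t[[1]])
  for (t in seq(2, length(scn$surfaces_t))) {
    cur <- face_normals(scn$surfaces_t[[t]])
    expect_true(all(rowSums(cur * prev) > 0))
    prev <- cur
  }
})

test_that("degenerate regression inputs are rejected", {
  s <- make_icosphere(10, 1, t_hours = 5)
  expect_error(fit_timeseries(list(s)), "at least 2")
  s2 <- s
  s2$t_hours <- 5
  expect_error(fit_timeseries(list(s, s2)), "increasing")
  expect_error(regression_config(gamma = 0), "gamma")
  expect_error(regression_config(lambda_w = -5), "lambda_w")
})

test_that("the bounding-box rule sets lambda_v from the observed lesions", {
  s1 <- make_box(c(0, 0, 0), c(10, 10, 10))
  s2 <- make_box(c(30, 0, 0), c(40, 10, 10))
  expect_equal(lambda_v_from_surfaces(list(s1, s2)), 0.30 * 40)
  expect_equal(lambda_v_from_surfaces(list(s1, s2), fraction = 0.5), 20)
})
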