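test_that("voxelization recovers analytic volumes", {
  cube <- make_box(c(0, 0, 0), c(10, 10, 10))
  m <- voxelize(cube, spacing = 0.5)
  expect_equal(sum(m$voxels), 8000, tolerance = 2400 / 8000) # +/- one shell
  expect_lt(abs(mask_volume(m) - 1000) / 1000, 0.03)

  sph <- make_icosphere(10, 3)
  ms <- voxelize(sph, spacing = 1)
  expect_lt(abs(mask_volume(ms) - 4188.8) / 4188.8, 0.03)
})

test_that("open surfaces are rejected by voxelize", {
  sph <- make_icosphere(10, 1)
  holed <- lesion_surface(sph$vertices, sph$faces[-1, , drop = FALSE])
  expect_error(voxelize(holed), "closed|watertight")
})

test_that("dice index matches its closed forms", {
  cube <- make_box(c(0, 0, 0), c(10, 10, 10))
  self <- dice_surfaces(cube, cube, spacing = 0.5)
  expect_equal(self, 1)

  # equal cubes overlapping exactly half their volume -> dice = 0.5 exactly
  half <- make_box(c(5, 0, 0), c(15, 10, 10))
  expect_equal(dice_surfaces(cube, half, spacing = 0.5), 0.5)

  apart <- make_box(c(30, 0, 0), c(40, 10, 10))
  expect_equal(dice_surfaces(cube, apart, spacing = 0.5), 0)
})

test_that("dice index validates grids and flags the empty-empty case", {
  a <- lesion_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  b <- lesion_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(d <- dice_index(a, b), "empty")
  expect_equal(d, 0)
  c_ <- lesion_mask(array(FALSE, c(4, 4, 5)), c(1, 1, 1))
  expect_error(dice_index(a, c_), "grid")
  d_ <- lesion_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 2))
  expect_error(dice_index(a, d_), "grid")
})

test_that("symmetric distance matches analytic and brute-force oracles", {
  a <- make_icosphere(10, 3)
  expect_equal(symmetric_distance(a, a), 0)

  b <- make_icosphere(12, 3)
  d <- symmetric_distance(a, b)
  expect_lt(abs(d - 2) / 2, 0.05)          # concentric spheres r = 10, 12

  # symmetry and the naive R point-to-triangle scan
  a1 <- make_icosphere(8, 1, center = c(2, 1, 0))     # 80 faces
  b1 <- make_bipyramid(9, 11, center = c(-3, 2, 4))   # 10 faces
  expect_equal(symmetric_distance(a1, b1), symmetric_distance(b1, a1))
  naive <- (sum(naive_min_dist(a1$vertices, b1)) +
              sum(naive_min_dist(b1$vertices, a1))) /
    (nrow(a1$vertices) + nrow(b1$vertices))
  expect_equal(symmetric_distance(a1, b1), naive, tolerance = 1e-9)

  # linear under uniform scaling of both surfaces
  scale_s <- function(s, k) lesion_surface(s$vertices * k, s$faces)
  expect_equal(symmetric_distance(scale_s(a1, 2.5), scale_s(b1, 2.5)),
               2.5 * symmetric_distance(a1, b1), tolerance = 1e-9)
})

test_that("concordance curves locate the best-match time with early ties", {
  # identity scenario whose baseline is the T2 surface: dice = 1 throughout,
  # tie broken toward t1
  s <- make_icosphere(10, 1)
  idc <- fake_scenario(lapply(1:5, function(i) s), dt_hours = 3, t0_hours = 5)
  cc <- concordance_curves(idc, s)
  expect_true(all(cc$dice_t == 1))
  expect_equal(cc$t_dice, 5)
  expect_equal(cc$t_dsym, 5)
  expect_equal(cc$max_dice, 1)

  # monotonically receding surface: best match at the first timepoint
  rec <- fake_scenario(lapply(0:4, function(t) make_icosphere(10 - t, 1)),
                       dt_hours = 3, t0_hours = 5)
  ccr <- concordance_curves(rec, make_icosphere(10, 1))
  expect_equal(ccr$t_dice, 5)
  expect_equal(ccr$t_dsym, 5)
  expect_true(all(diff(ccr$dice_t) < 0))
})

test_that("a growing ball crossing a T2 ball is timed to within one step", {
  # truth: r(t) = 14 + 0.5 t, T2 ball of radius 16 -> crossing at step 4
  meshes <- lapply(0:10, function(t) make_icosphere(14 + 0.5 * t, 2))
  scn <- fake_scenario(meshes, dt_hours = 3, t0_hours = 5)
  t2 <- make_icosphere(16, 2)
  cc <- concordance_curves(scn, t2)
  t_star <- 5 + 4 * 3
  expect_lte(abs(cc$t_dice - t_star), 3)
  expect_lte(abs(cc$t_dsym - t_star), 3)
  # argmax/argmin definition holds on the whole grid
  expect_true(all(cc$dice_t <= cc$dice_t[which(cc$times_hours == cc$t_dice)]))
  expect_true(all(cc$dsym_t >= cc$dsym_t[which(cc$times_hours == cc$t_dsym)]))
})

test_that("an unreachable T2 yields max dice < 1 and is reported faithfully", {
  # the evolving surface passes beside the T2 lesion: the dice curve peaks
  # strictly below 1 and the symmetric distance never reaches 0
  meshes <- lapply(0:8, function(t) make_icosphere(12 + 0.5 * t, 2))
  scn <- fake_scenario(meshes, dt_hours = 3, t0_hours = 5)
  t2 <- make_icosphere(14, 2, center = c(6, 0, 0))
  cc <- concordance_curves(scn, t2)
  expect_lt(cc$max_dice, 1)
  expect_gt(cc$max_dice, 0)
  expect_gt(cc$min_dsym, 0)
})

test_that("T2-crossing time is recovered from generator truth across seeds", {
  for (seed in 1:5) {
    p <- generate_patient(seed = seed, subdivisions = 1L)
    cc <- concordance_curves(p$truth$dwi_scenario, p$t2_surface)
    expect_lte(abs(cc$t_dice - p$truth$t2_cross_hours), 3)
    expect_lte(abs(cc$t_dsym - p$truth$t2_cross_hours), 3)
  }
})
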