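test_that("signed speeds vanish on an identity scenario", {
  s <- make_icosphere(10, 1)
  meshes <- lapply(1:5, function(i) s)
  sp <- signed_speed(fake_scenario(meshes))
  expect_true(all(sp$speeds == 0))
})

test_that("a radially growing ball has uniform positive signed speed", {
  # r(t) = 10 + 1 * t mm per 3 h step -> 0.1 cm/3h everywhere
  meshes <- lapply(0:6, function(t) make_icosphere(10 + t, 2))
  sp <- signed_speed(fake_scenario(meshes, dt_hours = 3))
  expect_true(all(sp$speeds > 0))
  expect_true(all(abs(sp$speeds - 0.1) / 0.1 < 0.10))

  # flipping the mesh orientation flips the sign convention
  flip <- function(s) lesion_surface(s$vertices, s$faces[, c(1, 3, 2)])
  spf <- signed_speed(fake_scenario(lapply(meshes, flip), dt_hours = 3))
  expect_equal(spf$speeds, -sp$speeds, tolerance = 1e-12)
})

test_that("mean +/- SD thresholds match a hand-computed oracle", {
  sp <- structure(list(speeds = matrix(c(1, 1, 1, 1, 10), 1),
                       times_hours = 8, dt_hours = 3),
                  class = "speed_field")
  lb <- extract_regions(sp, 1)
  expect_identical(which(lb$high_expansion), 5L)   # mean 2.8 + sd 4.02 = 6.82
  expect_equal(lb$threshold_expansion, mean(c(1, 1, 1, 1, 10)) +
                 sd(c(1, 1, 1, 1, 10)))
  expect_false(any(lb$high_contraction))           # no contracting subset

  # uniform expansion (SD = 0): strict inequality flags nothing
  spu <- structure(list(speeds = matrix(rep(2, 6), 1), times_hours = 8,
                        dt_hours = 3), class = "speed_field")
  lbu <- extract_regions(spu, 1)
  expect_false(any(lbu$high_expansion))
  expect_false(any(lbu$high_contraction))

  # pure contraction field leaves the expansion flags empty
  spc <- structure(list(speeds = matrix(c(-1, -1, -2, -8), 1), times_hours = 8,
                        dt_hours = 3), class = "speed_field")
  lbc <- extract_regions(spc, 1)
  expect_false(any(lbc$high_expansion))
  expect_identical(which(lbc$high_contraction), 4L)
  expect_error(extract_regions(spc, 2), "range")
})

test_that("region extraction is scale-equivariant", {
  set.seed(13)
  v <- rnorm(40, 0, 2)
  mk <- function(x) structure(list(speeds = matrix(x, 1), times_hours = 8,
                                   dt_hours = 3), class = "speed_field")
  a <- extract_regions(mk(v), 1)
  b <- extract_regions(mk(3.7 * v), 1)
  expect_identical(a$high_expansion, b$high_expansion)
  expect_identical(a$high_contraction, b$high_contraction)
})

test_that("labels map back to the baseline by face identity", {
  p <- generate_patient(seed = 8, subdivisions = 1L)
  scn <- p$truth$dwi_scenario
  sp <- signed_speed(scn)
  # late-step extraction maps back inside the known lobe footprint
  late <- extract_regions(sp, at_step = nrow(sp$speeds))
  base <- map_regions_to_baseline(scn, late)
  expect_identical(base$high_expansion, late$high_expansion)
  expect_equal(base$source_step, nrow(sp$speeds))
  flagged <- which(base$high_expansion)
  expect_gte(mean(p$truth$dwi_expansion_faces[flagged]), 0.90)

  # step-1 labels are unchanged; empty labels stay empty
  first <- extract_regions(sp, at_step = 1L)
  expect_identical(map_regions_to_baseline(scn, first)$high_contraction,
                   first$high_contraction)
  empty <- first
  empty$high_expansion[] <- FALSE
  empty$high_contraction[] <- FALSE
  expect_false(any(map_regions_to_baseline(scn, empty)$high_expansion))
})

test_that("labels transfer from DWI to MTT through the correspondence map", {
  # nested concentric spheres: an equatorial DWI band must land on an
  # equatorial MTT band
  dwi <- make_icosphere(20, 1, t_hours = 0)
  mtt <- make_icosphere(28, 1, t_hours = 0)
  phi <- fit_pairwise(dwi, mtt, regression_config(max_iter = 80))

  ctr <- face_centers(dwi)
  lat_dwi <- abs(ctr[, 3]) / sqrt(rowSums(ctr^2))
  band <- lat_dwi < 0.25
  labels <- structure(list(high_expansion = band,
                           high_contraction = rep(FALSE, length(band)),
                           at_step = 0L), class = "region_labels")
  out <- transfer_dwi_to_mtt(phi, labels)
  expect_identical(out$high_expansion, band)     # face identity transport
  # geometric check: the deformed band sits near the MTT equator
  dctr <- face_centers(phi$deformed)
  lat_mtt <- abs(dctr[, 3]) / sqrt(rowSums(dctr^2))
  expect_gte(mean(lat_mtt[band] < 0.35), 0.80)

  # identity correspondence leaves labels unchanged trivially
  phi_id <- fit_pairwise(dwi, dwi, regression_config(max_iter = 10))
  expect_identical(transfer_dwi_to_mtt(phi_id, labels)$high_expansion, band)
  bad <- labels
  bad$high_expansion <- bad$high_expansion[-1]
  bad$high_contraction <- bad$high_contraction[-1]
  expect_error(transfer_dwi_to_mtt(phi, bad), "match")
})

test_that("mean-speed curves follow the flagged regions", {
  # identity scenario: all-zero curves
  s <- make_icosphere(10, 1)
  idc <- fake_scenario(lapply(1:4, function(i) s))
  lab_all <- structure(list(high_expansion = rep(TRUE, nrow(s$faces)),
                            high_contraction = rep(TRUE, nrow(s$faces)),
                            at_step = 0L), class = "region_labels")
  cv <- mean_speed_curves(idc, lab_all)
  expect_true(all(cv$mean_speed_expanding == 0))
  expect_true(all(cv$mean_speed_contracting == 0))

  # radial ball, all faces flagged expanding: flat curve at the known rate
  meshes <- lapply(0:5, function(t) make_icosphere(10 + t, 2))
  scn <- fake_scenario(meshes, dt_hours = 3)
  lab <- structure(list(high_expansion = rep(TRUE, nrow(meshes[[1]]$faces)),
                        high_contraction = rep(FALSE, nrow(meshes[[1]]$faces)),
                        at_step = 0L), class = "region_labels")
  expect_warning(cv2 <- mean_speed_curves(scn, lab), "empty")
  expect_true(all(abs(cv2$mean_speed_expanding - 0.1) / 0.1 < 0.10))
  expect_true(all(is.nan(cv2$mean_speed_contracting)))

  # two-lobe truth: expanding curve >= 0, contracting curve <= 0 throughout
  p <- generate_patient(seed = 4, subdivisions = 1L)
  tscn <- p$truth$dwi_scenario
  tsp <- signed_speed(tscn)
  tl <- map_regions_to_baseline(tscn, extract_regions(tsp, 1))
  tc <- mean_speed_curves(tscn, tl, tsp)
  expect_true(all(tc$mean_speed_expanding >= 0))
  expect_true(all(tc$mean_speed_contracting <= 0))
})

test_that("the sign convention is volume-consistent", {
  # area-weighted mean signed speed > 0 exactly when the lesion grows
  grow <- fake_scenario(lapply(0:3, function(t) make_icosphere(10 + t, 1)))
  shrink <- fake_scenario(lapply(0:3, function(t) make_icosphere(10 - t, 1)))
  for (scn in list(grow, shrink)) {
    sp <- signed_speed(scn)
    for (t in seq_len(nrow(sp$speeds))) {
      areas <- face_areas(scn$surfaces_t[[t]])
      mean_sp <- sum(sp$speeds[t, ] * areas) / sum(areas)
      dvol <- enclosed_volume(scn$surfaces_t[[t + 1]]) -
        enclosed_volume(scn$surfaces_t[[t]])
      expect_identical(mean_sp > 0, dvol > 0)
    }
  }
})

test_that("fast-MTT / slow-DWI generator ordering survives the analysis", {
  # generator truth: MTT expansion faster, DWI contraction faster
  p <- generate_patient(seed = 6, subdivisions = 1L)
  dsp <- signed_speed(p$truth$dwi_scenario)
  msp <- signed_speed(p$truth$mtt_scenario)
  dl <- map_regions_to_baseline(p$truth$dwi_scenario,
                                extract_regions(dsp, 1))
  ml <- map_regions_to_baseline(p$truth$mtt_scenario,
                                extract_regions(msp, 1))
  dcv <- mean_speed_curves(p$truth$dwi_scenario, dl, dsp)
  mcv <- mean_speed_curves(p$truth$mtt_scenario, ml, msp)
  expect_gt(mean(mcv$mean_speed_expanding), mean(dcv$mean_speed_expanding))
  expect_lt(mean(dcv$mean_speed_contracting), mean(mcv$mean_speed_contracting))
})
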