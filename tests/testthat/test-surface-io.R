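test_that("NIfTI masks round-trip with header spacing and binarize at > 0", {
  vox <- array(0, c(10, 10, 5))
  vox[4:6, 4:7, 2:3] <- 1
  vox[5, 5, 2] <- 2.5          # any positive value counts as foreground
  m <- lesion_mask(vox > 0, spacing = c(1.875, 1.875, 6.97))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_equal(m2$spacing, c(1.875, 1.875, 6.97), tolerance = 1e-6)
  expect_identical(m2$voxels, m$voxels)

  # all-zero volume reads as a valid, empty mask; surfacing rejects it
  write_mask(lesion_mask(array(0, c(4, 4, 4)), c(1, 1, 1)), path)
  empty <- read_mask(path)
  expect_equal(sum(empty$voxels), 0)
  expect_error(mask_to_surface(empty), "empty")
})

test_that("read_mask rejects non-3D input", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(1, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, path)
  expect_error(read_mask(path), "3D")
})

test_that("z-subsampling replicates slices and conserves physical volume", {
  set.seed(7)
  vox <- array(runif(8 * 8 * 15) > 0.6, c(8, 8, 15))
  m <- lesion_mask(vox, spacing = c(1.875, 1.875, 6.97))
  s6 <- z_subsample(m, 6)
  expect_equal(dim(s6$voxels)[3], 90)                   # 15 slices -> 90
  expect_equal(sum(s6$voxels), 6 * sum(m$voxels))       # count exactly x6
  expect_equal(s6$spacing[3], 6.97 / 6)
  expect_equal(mask_volume(s6), mask_volume(m))          # exact conservation

  expect_identical(z_subsample(m, 1), m)                 # identity
  expect_error(z_subsample(m, 0), "factor")

  # replication oracle on a known count
  vox2 <- array(FALSE, c(10, 10, 4))
  vox2[seq_len(100) + 0] <- TRUE                          # 100 voxels
  m2 <- lesion_mask(vox2, c(1, 1, 6))
  expect_equal(sum(z_subsample(m2, 6)$voxels), 600)
})

test_that("mask_to_surface reconstructs a ball within 10% of its voxel volume", {
  r <- 10
  g <- seq(-14, 14, by = 1)
  vox <- array(outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2,
               c(length(g), length(g), length(g)))
  m <- lesion_mask(vox, c(1, 1, 1))
  s <- mask_to_surface(m)
  expect_valid_surface(s)
  vol_vox <- mask_volume(m)
  expect_lt(abs(enclosed_volume(s) - vol_vox) / vol_vox, 0.10)
  expect_lt(abs(enclosed_volume(s) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.10)
})

test_that("a single isolated voxel yields a tiny closed surface", {
  vox <- array(FALSE, c(3, 3, 3))
  vox[2, 2, 2] <- TRUE
  s <- mask_to_surface(lesion_mask(vox, c(1, 1, 1)), smooth_iterations = 0)
  expect_valid_surface(s)
  expect_equal(enclosed_volume(s), 1, tolerance = 1e-9)
})

test_that("multi-component masks are rejected (solitary-lesion criterion)", {
  vox <- array(FALSE, c(8, 8, 8))
  vox[2:3, 2:3, 2:3] <- TRUE
  vox[6:7, 6:7, 6:7] <- TRUE
  m <- lesion_mask(vox, c(1, 1, 1))
  expect_equal(n_components(m), 2L)
  expect_error(mask_to_surface(m), "solitary|components")
})

test_that("PLY and VTK surface files round-trip with per-face scalars", {
  s <- make_icosphere(8, 1, t_hours = 5)
  speeds <- seq_len(nrow(s$faces)) / 10
  for (ext in c(".ply", ".vtk")) {
    path <- withr::local_tempfile(fileext = ext)
    write_surface(s, path, face_scalars = list(speed = speeds))
    s2 <- read_surface(path, t_hours = 5)
    expect_equal(s2$vertices, s$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(s2$faces, s$faces)
    expect_equal(attr(s2, "face_scalars")$speed, speeds, tolerance = 1e-12)
    expect_valid_surface(s2)
  }
})

test_that("non-triangular mesh files are rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), path)
  expect_error(read_surface(path), "triangular|triangle")
})

test_that("the validator catches holes, inconsistent winding and inversion", {
  s <- make_icosphere(10, 1)
  expect_valid_surface(s)

  holed <- lesion_surface(s$vertices, s$faces[-1, , drop = FALSE])
  expect_error(validate_surface(holed), "closed")

  miswound <- s$faces
  miswound[1, ] <- miswound[1, c(1, 3, 2)]
  expect_error(validate_surface(lesion_surface(s$vertices, miswound)),
               "orientation|closed")

  inverted <- lesion_surface(s$vertices, s$faces[, c(1, 3, 2)])
  expect_error(validate_surface(inverted), "inward")

  degen <- lesion_surface(rbind(s$vertices, s$vertices[1, ]),
                          rbind(s$faces, c(1, 1, nrow(s$vertices) + 1L)))
  expect_error(validate_surface(degen), "degenerate")
})

test_that("laplacian smoothing keeps meshes closed and shrinks gently", {
  s <- make_icosphere(10, 2)
  sm <- laplacian_smooth(s, 2, 0.2)
  expect_valid_surface(sm)
  expect_lt(abs(enclosed_volume(sm) - enclosed_volume(s)) / enclosed_volume(s),
            0.10)
})
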