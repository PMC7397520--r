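test_that("plane means on constant and gradient fields are exact", {
  vol <- voxel_volume(array(7.5, c(11, 11, 11)), 2)
  roi <- spherical_roi(c(10, 10, 10), 12, exclusion = "none")
  for (p in c("coronal", "axial", "sagittal"))
    expect_identical(as.numeric(plane_mean_uptake(vol, roi, p)), 7.5)
  m <- roi_mean_uptake(vol, roi)
  expect_identical(m$combined_mean, 7.5)
  expect_identical(m$combined_mean, mean(m$plane_means))

  # counts = x world coordinate: the sagittal central plane at x = c has mean c
  shape <- c(11, 11, 11)
  xs <- (seq_len(shape[1]) - 1) * 2
  grad <- voxel_volume(array(rep(xs, times = prod(shape[2:3])), shape), 2)
  expect_identical(as.numeric(plane_mean_uptake(grad, roi, "sagittal")), 10)
})

test_that("plane means match brute-force voxel enumeration on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    spacing <- sample(c(1, 2, 2.95), 3, replace = TRUE)
    vol <- random_volume_fixture(shape = c(9L, 9L, 9L), spacing = spacing)
    center <- runif(3, 2, 6) * spacing          # inside the 8-voxel extent
    roi <- spherical_roi(center, diameter = 6 * min(spacing),
                         exclusion = "none")
    for (p in c("coronal", "axial", "sagittal")) {
      got <- plane_mean_uptake(vol, roi, p)
      want <- brute_plane_mean(vol$counts, vol$spacing, center,
                               roi$diameter, p)
      expect_identical(as.numeric(got), want$mean)
      expect_identical(attr(got, "n_voxels"), want$n)
    }
  }
})

test_that("disc voxel counts at study geometry match brute-force enumeration", {
  # 30 mm and 10 mm ROIs on a 2.95 mm isotropic grid
  vol <- voxel_volume(array(1, c(32, 32, 32)), 2.95)
  center <- (c(15, 15, 15)) * 2.95      # on-lattice center
  for (d in c(30, 10)) {
    roi <- spherical_roi(center, d, exclusion = "none")
    got <- plane_mean_uptake(vol, roi, "axial")
    want <- brute_plane_mean(vol$counts, vol$spacing, center, d, "axial")
    expect_identical(attr(got, "n_voxels"), want$n)
  }
  # sanity: the known analytic count for an on-lattice disc of radius
  # 15 mm at 2.95 mm spacing (voxel-center-in-closed-disc rule)
  r_vox <- 15 / 2.95
  lat <- expand.grid(i = -6:6, j = -6:6)
  expect_identical(
    attr(plane_mean_uptake(vol, spherical_roi(center, 30, "none"), "axial"),
         "n_voxels"),
    sum(lat$i^2 + lat$j^2 <= r_vox^2))
})

test_that("head ROI on the phantom samples only cancellous bone", {
  ph <- build_hip_phantom(small_anatomy(), uptake_params(noise_model = "none"),
                          affected_side = "right")
  roi <- make_head_roi(ph$counts, ph$labels, c(190, 130, 100))
  expect_identical(roi$diameter, 30)
  expect_identical(roi$exclusion, "exclude_cortical")
  m <- roi_mean_uptake(ph$counts, roi, ph$labels)
  expect_identical(m$combined_mean, 66.3)   # affected cancellous rate, exactly
  # full-sphere mode agrees on this phantom and is flagged as such
  ms <- roi_mean_uptake(ph$counts, roi, ph$labels, mode = "sphere")
  expect_identical(ms$mode, "sphere")
  expect_identical(ms$combined_mean, 66.3)

  dome <- make_acetabular_roi(ph$counts, ph$labels, c(170, 130, 128))
  expect_identical(dome$diameter, 10)
  expect_identical(roi_mean_uptake(ph$counts, dome, ph$labels)$combined_mean,
                   319.1)
})

test_that("oversized acetabular ROI warns and still excludes cortex", {
  ph <- build_hip_phantom(small_anatomy(),
                          uptake_params(noise_model = "none",
                                        acetabular_rate = 319.1),
                          affected_side = "right")
  # a 40 mm dome ROI spills past the 10 mm dome into head cortex territory
  expect_warning(
    dome <- make_acetabular_roi(ph$counts, ph$labels, c(170, 130, 128),
                                diameter = 44),
    "cancellous space")
  m <- roi_mean_uptake(ph$counts, dome, ph$labels)
  cortical_rate <- 400
  expect_true(all(m$plane_means != cortical_rate))
})

test_that("off-volume ROI parts are clipped and counted", {
  vol <- voxel_volume(array(3, c(9, 9, 9)), 1)
  corner <- spherical_roi(c(0, 0, 0), 6, exclusion = "none")
  m <- roi_mean_uptake(vol, corner)
  expect_identical(m$combined_mean, 3)
  full <- roi_mean_uptake(vol, spherical_roi(c(4, 4, 4), 6, "none"))
  expect_true(all(m$n_voxels < full$n_voxels))  # clipped discs are smaller
  # entirely outside -> geometry error
  expect_error(
    plane_mean_uptake(vol, spherical_roi(c(50, 50, 50), 6, "none"), "axial"),
    "outside the volume")
})

test_that("means are translation-equivariant and scale linearly", {
  set.seed(77)
  vol <- random_volume_fixture(shape = c(12L, 12L, 12L), spacing = 2)
  center <- c(10, 10, 10)
  roi <- spherical_roi(center, 8, exclusion = "none")
  base <- roi_mean_uptake(vol, roi)

  # whole-voxel translation of both volume and center
  shift <- c(1L, 2L, 1L)
  shifted_counts <- array(0, dim = dim(vol$counts) + shift)
  shifted_counts[shift[1] + seq_len(12), shift[2] + seq_len(12),
                 shift[3] + seq_len(12)] <- vol$counts
  vol2 <- voxel_volume(shifted_counts, 2)
  roi2 <- spherical_roi(center + shift * vol$spacing, 8, "none")
  expect_identical(roi_mean_uptake(vol2, roi2)$plane_means, base$plane_means)

  # count scaling scales every mean
  vol_k <- voxel_volume(vol$counts * 3.5, 2)
  expect_equal(roi_mean_uptake(vol_k, roi)$plane_means,
               3.5 * base$plane_means, tolerance = 1e-12)
})

test_that("cortical exclusion can only lower the mean of a hot-shell head", {
  ph <- build_hip_phantom(small_anatomy(),
                          uptake_params(cortical_rate = 400,
                                        noise_model = "none"),
                          affected_side = "right")
  # ROI large enough to touch the shell
  roi_ex <- spherical_roi(c(190, 130, 100), 42, "exclude_cortical")
  roi_in <- spherical_roi(c(190, 130, 100), 42, "none")
  m_ex <- roi_mean_uptake(ph$counts, roi_ex, ph$labels)
  m_in <- roi_mean_uptake(ph$counts, roi_in)
  expect_true(all(m_ex$plane_means <= m_in$plane_means))
  expect_lt(m_ex$combined_mean, m_in$combined_mean)
})
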