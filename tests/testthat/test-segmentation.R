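box_region <- function(grd, lo, hi) rbind(lo = lo, hi = hi)

test_that("COA closed form on the undegraded phantom: threshold 4.5, exact mask", {
  grd <- small_grid()
  ph <- make_static_phantom(flat_lesion(), quiet_motion(), grd, seed = 1)
  res <- coa_segment(ph$volume, box_region(grd, c(4, 4, 4), c(29, 29, 29)))
  expect_equal(res$msuv70, 8)
  expect_equal(res$background_suv, 1)
  expect_equal(res$threshold_suv, 4.5)
  expect_identical(res$mask$values, ph$mask$values)
})

test_that("COA exactness holds for any a,b placing the threshold inside the contrast", {
  grd <- small_grid()
  ph <- make_static_phantom(flat_lesion(), quiet_motion(), grd, seed = 1)
  for (ab in list(c(0.3, 0.7), c(0.8, 0.2), c(0.25, 0.25))) {
    res <- coa_segment(ph$volume, box_region(grd, c(4, 4, 4), c(29, 29, 29)),
                       coa_config(a = ab[1], b = ab[2]))
    thr <- ab[1] * 8 + ab[2] * 1
    expect_equal(res$threshold_suv, thr)
    if (thr > 1 && thr <= 8)
      expect_identical(res$mask$values, ph$mask$values)
  }
})

test_that("threshold is linear in global intensity scaling and mask is unchanged", {
  grd <- small_grid()
  ph <- make_static_phantom(lesion_spec(), motion_spec(noise_cv = 0.05), grd, seed = 2)
  reg <- box_region(grd, c(3, 3, 3), c(30, 30, 30))
  r1 <- coa_segment(ph$volume, reg)
  v2 <- image_volume(ph$volume$values * 3, ph$volume$spacing, ph$volume$origin)
  r2 <- coa_segment(v2, reg)
  expect_equal(r2$threshold_suv, 3 * r1$threshold_suv, tolerance = 1e-12)
  expect_identical(r2$mask$values, r1$mask$values)
})

test_that("increasing the mSUV70 weight never grows the mask", {
  grd <- small_grid()
  ph <- make_static_phantom(lesion_spec(), motion_spec(noise_cv = 0.05), grd, seed = 3)
  reg <- box_region(grd, c(3, 3, 3), c(30, 30, 30))
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(a)
    coa_segment(ph$volume, reg, coa_config(a = a, b = 0.5))$n_voxels, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("blurred sphere >= 3x PSF FWHM is recovered within 15% of truth volume", {
  grd <- grid_spec(dim = c(40, 40, 40), spacing = c(2, 2, 2))
  les <- flat_lesion(radii_mm = c(15, 15, 15))   # 30 mm diameter vs 4.8 mm PSF
  mot <- motion_spec(amplitude_mm = c(0, 0, 0), psf_fwhm_mm = 4.8, noise_cv = 0)
  ph <- make_static_phantom(les, mot, grd, seed = 1)
  res <- coa_segment(ph$volume, box_region(grd, c(5, 5, 5), c(36, 36, 36)))
  truth <- sum(ph$mask$values)
  expect_lt(abs(res$n_voxels - truth) / truth, 0.15)
})

test_that("declared COA errors are raised", {
  grd <- small_grid()
  flat <- image_volume(array(1, grd$dim), grd$spacing, grd$origin)
  expect_error(coa_segment(flat, box_region(grd, c(4, 4, 4), c(20, 20, 20))),
               class = "gdr_segmentation_error")
  ph <- make_static_phantom(flat_lesion(), quiet_motion(), grd, seed = 1)
  expect_error(
    coa_segment(ph$volume, box_region(grd, c(4, 4, 4), c(29, 29, 29)),
                coa_config(min_lesion_voxels = 1e6)),
    class = "gdr_segmentation_error")
})

test_that("manual masks pass through; empty and disconnected cases behave as declared", {
  ph <- make_static_phantom(flat_lesion(), quiet_motion(), small_grid(), seed = 1)
  mf <- tempfile(fileext = ".nii.gz")
  write_nifti(ph$mask, mf)
  m <- load_manual_mask(mf, ph$volume)
  expect_identical(m$values, ph$mask$values)

  empty <- roi_mask(array(FALSE, dim(ph$mask$values)), ph$mask$spacing, ph$mask$origin)
  ef <- tempfile(fileext = ".nii.gz"); write_nifti(empty, ef)
  expect_error(load_manual_mask(ef, ph$volume), class = "gdr_empty_mask_error")

  two <- array(FALSE, dim(ph$mask$values))
  two[3, 3, 3] <- TRUE; two[20, 20, 20] <- TRUE
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti(roi_mask(two, ph$mask$spacing, ph$mask$origin), tf)
  expect_identical(sum(load_manual_mask(tf, ph$volume)$values), 2L)
})

test_that("phase-series segmentation tracks motion and reports failing phases", {
  grd <- small_grid()
  ps0 <- make_phase_series(flat_lesion(), quiet_motion(), grd, seed = 2)
  reg <- box_region(grd, c(4, 4, 4), c(29, 29, 29))
  seg0 <- segment_phase_series(ps0, reg)
  for (k in 2:seg0$K)
    expect_identical(seg0$phases[[k]]$mask$values, seg0$phases[[1]]$mask$values)

  # volume-recovery accuracy is assessed on a homogeneous moving lesion at
  # fine spacing (on a lumpy lesion mSUV70 reflects the hot spots and the
  # COA contour is legitimately tighter than the ground-truth ellipsoid)
  grd2 <- grid_spec(dim = c(36, 36, 36), spacing = c(2, 2, 2))
  mot <- motion_spec(amplitude_mm = c(0, 0, 10), psf_fwhm_mm = 4.8, noise_cv = 0.05)
  ps <- make_phase_series(flat_lesion(radii_mm = c(16, 14, 12)), mot, grd2, seed = 2)
  reg2 <- box_region(grd2, c(4, 4, 4), c(33, 33, 33))
  seg <- segment_phase_series(ps, reg2)
  for (k in seq_len(seg$K)) {
    truth <- sum(ps$phases[[k]]$mask$values)
    expect_lt(abs(sum(seg$phases[[k]]$mask$values) - truth) / truth, 0.15)
  }

  # one all-background phase: series-level error naming the phase
  flatvol <- image_volume(array(1, grd$dim), grd$spacing, grd$origin)
  bad <- ps0$phases
  bad[[2]]$volume <- flatvol
  expect_error(segment_phase_series(phase_series(bad), reg),
               "phase 2", class = "gdr_segmentation_error")
})
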