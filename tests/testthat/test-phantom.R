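test_that("undegraded homogeneous phantom has exact lesion and background values", {
  ph <- make_static_phantom(flat_lesion(), quiet_motion(), small_grid(), seed = 1)
  inside <- ph$mask$values
  expect_true(all(ph$volume$values[inside] == 8))
  expect_true(all(ph$volume$values[!inside] == 1))
  expect_gt(sum(inside), 0)
})

test_that("generators are deterministic per seed and vary across seeds", {
  les <- lesion_spec()
  a <- make_static_phantom(les, seed = 42)
  b <- make_static_phantom(les, seed = 42)
  c <- make_static_phantom(les, seed = 43)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("blurred sphere matches a direct Gaussian-convolution oracle", {
  grd <- small_grid(n = 36, sp = 2)
  les <- flat_lesion(radii_mm = c(15, 15, 15))
  mot <- motion_spec(amplitude_mm = c(0, 0, 0), psf_fwhm_mm = 4.8, noise_cv = 0)
  ph <- make_static_phantom(les, mot, grd, seed = 1)
  expect_lt(max(ph$volume$values), 8)
  expect_gt(max(ph$volume$values), 1)

  # oracle: voxelize the analytic phantom, convolve with a full (non-
  # separable) 3D Gaussian kernel by direct summation
  co <- lapply(1:3, function(a) grd$origin[a] + (seq_len(grd$dim[a]) - 1) * grd$spacing[a])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  truth <- array(1, grd$dim); truth[r2 <= 15^2] <- 8
  sig <- 4.8 / 2.3548 / 2   # sigma in voxels at 2 mm spacing
  r <- ceiling(3 * sig)
  off <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  w <- exp(-(off$x^2 + off$y^2 + off$z^2) / (2 * sig^2)); w <- w / sum(w)
  conv <- array(0, grd$dim)
  n <- grd$dim
  for (i in seq_len(nrow(off))) {
    ix <- pmin(pmax(seq_len(n[1]) + off$x[i], 1), n[1])
    iy <- pmin(pmax(seq_len(n[2]) + off$y[i], 1), n[2])
    iz <- pmin(pmax(seq_len(n[3]) + off$z[i], 1), n[3])
    conv <- conv + w[i] * truth[ix, iy, iz]
  }
  m <- ph$mask$values
  expect_equal(mean(ph$volume$values[m]), mean(conv[m]), tolerance = 1e-3)
})

test_that("phase series honours K, motion amplitude and the no-motion identity", {
  grd <- small_grid()
  ps <- make_phase_series(flat_lesion(), quiet_motion(K = 8), grd, seed = 2)
  expect_s3_class(ps, "phase_series")
  expect_identical(ps$K, 8L)
  for (k in 2:8)
    expect_identical(ps$phases[[k]]$volume$values, ps$phases[[1]]$volume$values)

  # 10 mm peak-to-peak displacement recovered from noiseless mask centroids
  grd2 <- grid_spec(dim = c(20, 20, 30), spacing = c(2, 2, 2))
  mot <- motion_spec(amplitude_mm = c(0, 0, 10), psf_fwhm_mm = 0, noise_cv = 0)
  ps2 <- make_phase_series(flat_lesion(radii_mm = c(10, 10, 10)), mot, grd2, seed = 3)
  cz <- vapply(ps2$phases, function(p) {
    idx <- which(p$mask$values, arr.ind = TRUE)
    mean(grd2$origin[3] + (idx[, 3] - 1) * grd2$spacing[3])
  }, 0)
  expect_equal(max(cz) - min(cz), 10, tolerance = grd2$spacing[3] / 2)
})

test_that("mean of noiseless phases equals the motion-blurred static scan", {
  grd <- small_grid()
  les <- lesion_spec()
  mot <- motion_spec(noise_cv = 0)
  ps <- make_phase_series(les, mot, grd, seed = 5)
  st <- make_static_phantom(les, mot, grd, seed = 5)
  avg <- Reduce(`+`, lapply(ps$phases, function(p) p$volume$values)) / ps$K
  expect_gt(cor(c(avg), c(st$volume$values)), 0.99)
})

test_that("noise CV converges to the requested coefficient of variation", {
  grd <- grid_spec(dim = c(30, 30, 30), spacing = c(4, 4, 4))
  mot <- motion_spec(amplitude_mm = c(0, 0, 0), psf_fwhm_mm = 0, noise_cv = 0.10)
  ph <- make_static_phantom(flat_lesion(radii_mm = c(8, 8, 8)), mot, grd, seed = 9)
  bg <- ph$volume$values[!ph$mask$values]   # > 10^4 homogeneous voxels
  expect_gt(length(bg), 1e4)
  expect_equal(sd(bg) / mean(bg), 0.10, tolerance = 0.10 * 0.10)
})

test_that("follow-up homogenization shrinks deviations as specified", {
  grd <- small_grid()
  les <- lesion_spec(texture_seed = 77L)
  qm <- quiet_motion()
  base <- make_static_phantom(les, qm, grd, seed = 4)
  # identity: no-op effect, same seed
  f0 <- simulate_followup(les, list(homogenization = 0), qm, grd, seed = 4)
  expect_identical(f0$volume$values, base$volume$values)
  # full shrinkage: lesion voxels all at the lesion mean
  f1 <- simulate_followup(les, list(homogenization = 1), qm, grd, seed = 4)
  expect_true(all(abs(f1$volume$values[f1$mask$values] - 8) < 1e-12))
  # half shrinkage: pre-blur pre-noise lesion variance scales by 0.25
  f5 <- simulate_followup(les, list(homogenization = 0.5), qm, grd, seed = 4)
  v_base <- var(base$volume$values[base$mask$values])
  v_half <- var(f5$volume$values[f5$mask$values])
  expect_equal(v_half / v_base, 0.25, tolerance = 1e-10)
})

test_that("cohort generator enforces counts, determinism and label balance", {
  expect_error(simulate_cohort(n = 1), class = "gdr_value_error")
  grd <- small_grid(n = 20)
  les <- flat_lesion(radii_mm = c(12, 12, 12))
  mot <- quiet_motion(K = 3)
  co <- simulate_cohort(n = 6, lr_fraction = 0.5, lesion = les, motion = mot,
                        grid = grd, seed = 8)
  expect_length(co, 6)
  expect_identical(sum(vapply(co, function(cs) cs$outcome$LR, 0L)), 3L)
  co2 <- simulate_cohort(n = 6, lr_fraction = 0.5, lesion = les, motion = mot,
                         grid = grd, seed = 8)
  expect_identical(co[[2]]$pre3d$volume$values, co2[[2]]$pre3d$volume$values)
  # n=20, lr_fraction 0.4 -> exactly 8 LR cases (labels only; reuse specs)
  co3 <- simulate_cohort(n = 20, lr_fraction = 0.4, lesion = les, motion = mot,
                         grid = grd, seed = 9)
  expect_identical(sum(vapply(co3, function(cs) cs$outcome$LR, 0L)), 8L)
})

test_that("lesions that do not fit the grid raise a geometry error", {
  expect_error(
    make_static_phantom(lesion_spec(radii_mm = c(60, 60, 60)),
                        motion_spec(), grid_spec(dim = c(16, 16, 16))),
    class = "gdr_geometry_error")
})
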