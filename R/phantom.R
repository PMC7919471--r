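# Synthetic gated-PET phantom generator.
#
# Emulates what the downstream method consumes: reconstructed SUV images of a
# heterogeneous lung lesion, degraded by scanner resolution (Gaussian PSF),
# reconstruction noise (multiplicative Gaussian, CV-parameterized) and
# periodic respiratory displacement. The static 3D scan is modelled as the
# time average over the breathing cycle (motion blur), the gated 4D series as
# K quasi-static snapshots. No sinogram-level physics: the analysis operates
# on reconstructed SUV images only.

#' Lesion specification for the phantom generator
#'
#' The lesion is an ellipsoid of elevated uptake on a uniform background,
#' with intra-lesion heterogeneity modelled as a sum of seeded Gaussian
#' blobs ("lumpy" texture) — simple, with controllable variance and a
#' differentiable effect on cumulative-histogram heterogeneity indices.
#'
#' @param center_mm lesion centre in world mm (length 3).
#' @param radii_mm ellipsoid semi-axes in mm (> 0). The default gives a
#'   ~25 mL lesion, between the study-like cohort medians (86 mL central
#'   primaries, 12 mL peripheral SBRT lesions).
#' @param uptake_mean mean lesion SUV (default 8, a typical FDG-avid NSCLC
#'   primary); must exceed `background`.
#' @param background background SUV (default 1, soft tissue / lung blend).
#' @param n_blobs,blob_amplitude,blob_scale_mm heterogeneity texture: number
#'   of Gaussian lumps, SD of their (zero-mean) amplitudes in SUV, and their
#'   spatial scale in mm.
#' @param texture_seed optional integer pinning the texture realization so
#'   the same lesion can be re-imaged across scans; `NA` derives it from the
#'   generator seed.
#' @export
lesion_spec <- function(center_mm = c(0, 0, 0), radii_mm = c(22, 18, 15),
                        uptake_mean = 8, background = 1,
                        n_blobs = 30, blob_amplitude = 2, blob_scale_mm = 6,
                        texture_seed = NA_integer_) {
  if (any(radii_mm <= 0)) stop_gdr("gdr_value_error", "radii_mm must be > 0")
  if (!(uptake_mean > background && background > 0))
    stop_gdr("gdr_value_error", "need uptake_mean > background > 0")
  structure(list(center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 uptake_mean = uptake_mean, background = background,
                 n_blobs = as.integer(n_blobs),
                 blob_amplitude = blob_amplitude,
                 blob_scale_mm = blob_scale_mm,
                 texture_seed = texture_seed),
            class = "lesion_spec")
}

#' Motion / acquisition specification for the phantom generator
#'
#' @param amplitude_mm peak-to-peak lesion displacement per axis (mm).
#'   Default 10 mm superior-inferior, a typical lower-lobe excursion.
#' @param pattern `"cos2"` (regular breathing, cos^2 phase weighting) or
#'   `"irregular"` (per-phase amplitude jitter; robustness loss under
#'   irregular respiration is a known failure mode of gated protocols).
#' @param K number of gated respiratory bins (>= 3, default 8).
#' @param psf_fwhm_mm scanner point-spread FWHM, default 4.8 mm (transverse
#'   resolution of the emulated PET/CT systems).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   reconstruction noise (default 0.10).
#' @param jitter_cv relative SD of per-phase amplitude jitter in
#'   `"irregular"` mode.
#' @export
motion_spec <- function(amplitude_mm = c(0, 0, 10), pattern = c("cos2", "irregular"),
                        K = 8L, psf_fwhm_mm = 4.8, noise_cv = 0.10,
                        jitter_cv = 0.2) {
  pattern <- match.arg(pattern)
  if (any(amplitude_mm < 0)) stop_gdr("gdr_value_error", "amplitude_mm must be >= 0")
  if (K < 3L) stop_gdr("gdr_value_error", "K must be >= 3")
  if (psf_fwhm_mm < 0 || noise_cv < 0)
    stop_gdr("gdr_value_error", "psf_fwhm_mm and noise_cv must be >= 0")
  structure(list(amplitude_mm = as.numeric(amplitude_mm), pattern = pattern,
                 K = as.integer(K), psf_fwhm_mm = psf_fwhm_mm,
                 noise_cv = noise_cv, jitter_cv = jitter_cv),
            class = "motion_spec")
}

#' Grid specification (shape + spacing + origin)
#'
#' @param dim voxels per axis. @param spacing mm per voxel (default the
#'   study-like 4 mm isotropic). @param origin world mm of the first voxel
#'   centre; `NULL` centres the grid on (0,0,0).
#' @export
grid_spec <- function(dim = c(32, 32, 32), spacing = c(4, 4, 4), origin = NULL) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- -(dim - 1) * spacing / 2
  list(dim = dim, spacing = spacing, origin = as.numeric(origin))
}

# Centred phase displacement weights; peak-to-peak span is exactly 1 so the
# lesion excursion equals amplitude_mm.
.phase_weights <- function(K, pattern) {
  k <- seq_len(K) - 1
  w <- cos(pi * k / K)^2
  w - mean(w)
}

# Pre-blur, pre-noise lesion-plus-background field at displacement disp_mm.
# shrink scales the texture deviations (follow-up homogenization), gain the
# whole lesion signal (uptake response).
.lesion_field <- function(lesion, grid, disp_mm = c(0, 0, 0),
                          texture_seed, shrink = 1, gain = 1) {
  co <- axis_coords(grid$dim, grid$spacing, grid$origin)
  cx <- lesion$center_mm + disp_mm
  ux <- (co[[1]] - cx[1]) / lesion$radii_mm[1]
  uy <- (co[[2]] - cx[2]) / lesion$radii_mm[2]
  uz <- (co[[3]] - cx[3]) / lesion$radii_mm[3]
  r2 <- outer(outer(ux^2, uy^2, `+`), uz^2, `+`)
  inside <- r2 <= 1
  vals <- array(lesion$background, dim = grid$dim)
  if (!any(inside)) return(list(values = vals, mask = inside))
  lesion_val <- rep(lesion$uptake_mean, sum(inside))
  if (lesion$n_blobs > 0 && lesion$blob_amplitude > 0) {
    set.seed(texture_seed)
    # blob centres uniform in the unit ball, scaled to 85% of the semi-axes
    # so lumps stay interior; amplitudes zero-mean Gaussian
    m <- lesion$n_blobs
    pts <- matrix(numeric(0), ncol = 3)
    while (nrow(pts) < m) {
      cand <- matrix(stats::runif(3 * m * 4, -1, 1), ncol = 3)
      pts <- rbind(pts, cand[rowSums(cand^2) <= 1, , drop = FALSE])
    }
    pts <- pts[seq_len(m), , drop = FALSE]
    amps <- stats::rnorm(m, 0, lesion$blob_amplitude)
    centers <- sweep(pts, 2, 0.85 * lesion$radii_mm, `*`)
    centers <- sweep(centers, 2, cx, `+`)
    idx <- which(inside, arr.ind = TRUE)
    wx <- co[[1]][idx[, 1]]; wy <- co[[2]][idx[, 2]]; wz <- co[[3]][idx[, 3]]
    tex <- numeric(nrow(idx))
    s2 <- 2 * lesion$blob_scale_mm^2
    for (j in seq_len(m)) {
      d2 <- (wx - centers[j, 1])^2 + (wy - centers[j, 2])^2 + (wz - centers[j, 3])^2
      tex <- tex + amps[j] * exp(-d2 / s2)
    }
    lesion_val <- lesion$uptake_mean + shrink * tex
  }
  vals[inside] <- pmax(gain * lesion_val, 0.05 * lesion$background)
  list(values = vals, mask = inside)
}

# Separable Gaussian blur with edge replication; sigma in voxels per axis.
.gauss_blur <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    r <- ceiling(3 * s)
    w <- stats::dnorm(-r:r, sd = s); w <- w / sum(w)
    n <- dim(arr)[ax]
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- matrix(a, nrow = d[1])
    out <- matrix(0, nrow = d[1], ncol = ncol(a))
    for (j in seq_along(w)) {
      off <- j - r - 1
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + w[j] * a[idx, , drop = FALSE]
    }
    arr <- aperm(array(out, d), order(perm))
  }
  arr
}

.apply_noise <- function(vals, noise_cv, noise_seed) {
  if (noise_cv <= 0) return(vals)
  set.seed(noise_seed)
  pmax(vals * (1 + noise_cv * stats::rnorm(length(vals))), 0)
}

.check_fit <- function(lesion, motion, grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1) * grid$spacing
  margin <- lesion$radii_mm + motion$amplitude_mm / 2 + 2 * motion$psf_fwhm_mm
  if (any(lesion$center_mm - margin < lo) || any(lesion$center_mm + margin > hi))
    stop_gdr("gdr_geometry_error",
             "lesion plus motion and 2x PSF margin does not fit the grid")
}

.static_phantom <- function(lesion, motion, grid, seed, shrink = 1, gain = 1) {
  .check_fit(lesion, motion, grid)
  ts <- if (is.na(lesion$texture_seed)) derive_seed(seed, "texture")
        else as.integer(lesion$texture_seed)
  w <- .phase_weights(motion$K, "cos2")
  moving <- any(motion$amplitude_mm > 0)
  if (moving) {
    acc <- NULL
    for (wk in w) {
      f <- .lesion_field(lesion, grid, wk * motion$amplitude_mm, ts, shrink, gain)
      acc <- if (is.null(acc)) f$values else acc + f$values
    }
    vals <- acc / length(w)
  } else {
    vals <- .lesion_field(lesion, grid, c(0, 0, 0), ts, shrink, gain)$values
  }
  vals <- .gauss_blur(vals, (motion$psf_fwhm_mm / 2.3548) / grid$spacing)
  vals <- .apply_noise(vals, motion$noise_cv, derive_seed(seed, "noise", "static"))
  mask <- .lesion_field(lesion, grid, c(0, 0, 0), ts, shrink, gain)$mask
  list(volume = image_volume(vals, grid$spacing, grid$origin),
       mask = roi_mask(mask, grid$spacing, grid$origin))
}

#' Generate a static (3D) phantom scan
#'
#' Returns the blurred, noisy SUV volume together with the ground-truth
#' (pre-blur) lesion mask. With nonzero motion amplitude the static scan is
#' the average over the breathing cycle, emulating the ungated time-averaged
#' acquisition; the truth mask is the lesion at its mean position.
#' Deterministic for fixed seed.
#'
#' @param lesion a [lesion_spec()]. @param motion a [motion_spec()].
#' @param grid a [grid_spec()]. @param seed integer seed.
#' @return `list(volume = image_volume, mask = roi_mask)`.
#' @export
make_static_phantom <- function(lesion, motion = motion_spec(),
                                grid = grid_spec(), seed = 1L) {
  .static_phantom(lesion, motion, grid, seed)
}

#' Generate a gated (4D) phase series
#'
#' Phase k displaces the lesion by `pattern(k) * amplitude` before blur and
#' noise; each phase carries its own ground-truth mask and an independent
#' noise realization from the seeded stream.
#'
#' @inheritParams make_static_phantom
#' @return a [phase_series()].
#' @export
make_phase_series <- function(lesion, motion = motion_spec(),
                              grid = grid_spec(), seed = 1L) {
  .check_fit(lesion, motion, grid)
  ts <- if (is.na(lesion$texture_seed)) derive_seed(seed, "texture")
        else as.integer(lesion$texture_seed)
  w <- .phase_weights(motion$K, motion$pattern)
  if (motion$pattern == "irregular") {
    set.seed(derive_seed(seed, "jitter"))
    w <- w * (1 + motion$jitter_cv * stats::rnorm(motion$K))
  }
  phases <- vector("list", motion$K)
  for (k in seq_len(motion$K)) {
    d <- w[k] * motion$amplitude_mm
    f <- .lesion_field(lesion, grid, d, ts)
    vals <- .gauss_blur(f$values, (motion$psf_fwhm_mm / 2.3548) / grid$spacing)
    vals <- .apply_noise(vals, motion$noise_cv,
                         derive_seed(seed, "noise", "phase", k))
    phases[[k]] <- list(volume = image_volume(vals, grid$spacing, grid$origin),
                        mask = roi_mask(f$mask, grid$spacing, grid$origin))
  }
  phase_series(phases)
}

#' Simulate the during/after-treatment follow-up scan
#'
#' Applies a planted treatment effect to the baseline lesion: lesion-internal
#' intensity deviations from the lesion mean are shrunk by
#' `(1 - homogenization)` (increasing homogeneity, hence cumulative-histogram
#' AUC), the volume is rescaled by `volume_scale` and the uptake by
#' `uptake_scale`. With a no-op effect and the same seed the baseline phantom
#' is reproduced exactly.
#'
#' @param lesion baseline [lesion_spec()] (its `texture_seed` must pin the
#'   texture if the follow-up is to image the *same* lesion; [simulate_cohort()]
#'   does this automatically).
#' @param effect `list(volume_scale = 1, homogenization = 0, uptake_scale = 1)`
#'   with `homogenization` in \[0, 1\].
#' @inheritParams make_static_phantom
#' @return `list(volume = image_volume, mask = roi_mask)`.
#' @export
simulate_followup <- function(lesion, effect = list(), motion = motion_spec(),
                              grid = grid_spec(), seed = 1L) {
  eff <- utils::modifyList(list(volume_scale = 1, homogenization = 0,
                                uptake_scale = 1), effect)
  if (eff$homogenization < 0 || eff$homogenization > 1)
    stop_gdr("gdr_value_error", "homogenization must be in [0, 1]")
  les <- lesion
  les$radii_mm <- lesion$radii_mm * eff$volume_scale^(1 / 3)
  .static_phantom(les, motion, grid, seed,
                  shrink = 1 - eff$homogenization, gain = eff$uptake_scale)
}

#' Simulate a synthetic patient cohort
#'
#' Generates `n` complete patient cases (pre-treatment gated series, static
#' pre-treatment scan, follow-up scan). `round(n * lr_fraction)` cases are
#' labelled `LR = 1` and receive `effect_lr` in their follow-up; the rest
#' receive `effect_nolr`. Per-patient lesions vary around the base spec by
#' lognormal jitter on radii and uptake. Fully reproducible per seed.
#'
#' @param n number of patients (>= 2).
#' @param lr_fraction fraction with local recurrence (0..1).
#' @param effect_lr,effect_nolr follow-up effects, see [simulate_followup()].
#' @param lesion,motion,grid base specifications.
#' @param radii_cv,uptake_cv lognormal coefficients of variation of the
#'   per-patient lesion jitter.
#' @param seed integer master seed.
#' @return list of [patient_case()] objects.
#' @export
simulate_cohort <- function(n, lr_fraction = 0.4,
                            effect_lr = list(homogenization = 0.7),
                            effect_nolr = list(),
                            lesion = lesion_spec(), motion = motion_spec(),
                            grid = grid_spec(), radii_cv = 0.12,
                            uptake_cv = 0.15, seed = 1L) {
  if (n < 2) stop_gdr("gdr_value_error", "a cohort needs n >= 2 patients")
  if (lr_fraction < 0 || lr_fraction > 1)
    stop_gdr("gdr_value_error", "lr_fraction must be in [0, 1]")
  n_lr <- round(n * lr_fraction)
  set.seed(derive_seed(seed, "labels"))
  lr <- sample(rep(c(1L, 0L), c(n_lr, n - n_lr)))
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, "patient", i, "spec"))
    les <- lesion
    les$radii_mm <- lesion$radii_mm * exp(stats::rnorm(3, 0, radii_cv))
    les$uptake_mean <- lesion$background +
      (lesion$uptake_mean - lesion$background) * exp(stats::rnorm(1, 0, uptake_cv))
    les$texture_seed <- derive_seed(seed, "patient", i, "texture")
    interval <- max(7, round(stats::rnorm(1, 19, 10)))
    os <- round(stats::runif(1, 6, 96))
    eff <- if (lr[i] == 1L) effect_lr else effect_nolr
    patient_case(
      patient_id = sprintf("P%03d", i),
      pre4d = make_phase_series(les, motion, grid,
                                derive_seed(seed, "patient", i, "pre4d")),
      pre3d = make_static_phantom(les, motion, grid,
                                  derive_seed(seed, "patient", i, "pre3d")),
      post3d = simulate_followup(les, eff, motion, grid,
                                 derive_seed(seed, "patient", i, "post3d")),
      outcome = list(LR = lr[i], DM = as.integer(stats::runif(1) < 0.4),
                     OS_months = os, OS_event = as.integer(stats::runif(1) < 0.5)),
      interval_days = interval)
  })
}
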