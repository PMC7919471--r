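# Contrast-oriented algorithm (COA) segmentation.
#
# Semi-automatic PET delineation: the threshold is a weighted combination of
# the mean SUV inside the 70%-of-maximum isocontour (mSUV70) and a local
# background estimate, threshold = a * mSUV70 + b * background. The
# calibration constants of the clinically used COA are not published with
# the motivating study; defaults a = b = 0.5 reproduce the published
# threshold structure and are exposed in the configuration, and every
# result reports the constants used.

#' COA configuration
#'
#' @param a weight on mSUV70 (>= 0).
#' @param b weight on the background estimate (>= 0); `a + b > 0`.
#' @param background_shell_vox thickness (voxels) of the background shell,
#'   offset `background_gap_vox` voxels outside the bounding box of the 40%
#'   isocontour.
#' @param background_gap_vox gap between the 40%-isocontour bounding box and
#'   the background shell.
#' @param min_lesion_voxels smallest acceptable segmented component.
#' @export
coa_config <- function(a = 0.5, b = 0.5, background_shell_vox = 2L,
                       background_gap_vox = 2L, min_lesion_voxels = 1L) {
  if (a < 0 || b < 0 || a + b <= 0)
    stop_gdr("gdr_value_error", "need a, b >= 0 and a + b > 0")
  if (min_lesion_voxels < 1L)
    stop_gdr("gdr_value_error", "min_lesion_voxels must be >= 1")
  structure(list(a = a, b = b,
                 background_shell_vox = as.integer(background_shell_vox),
                 background_gap_vox = as.integer(background_gap_vox),
                 min_lesion_voxels = as.integer(min_lesion_voxels)),
            class = "coa_config")
}

.as_region_mask <- function(search_region, volume) {
  if (inherits(search_region, "roi_mask")) {
    check_alignment(volume, search_region)
    return(search_region$values)
  }
  # bounding box given as rbind(lo =, hi =) index ranges
  d <- dim(volume$values)
  reg <- array(FALSE, d)
  lo <- pmax(as.integer(search_region["lo", ]), 1L)
  hi <- pmin(as.integer(search_region["hi", ]), d)
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  reg
}

# Mean SUV in a shell outside the bounding box of the 40% isocontour.
.coa_background <- function(vals, region, suvmax, cfg) {
  iso40 <- region & (vals >= 0.4 * suvmax)
  bb <- mask_bbox(iso40)
  d <- dim(vals)
  inner_lo <- pmax(bb["lo", ] - cfg$background_gap_vox, 1L)
  inner_hi <- pmin(bb["hi", ] + cfg$background_gap_vox, d)
  outer_lo <- pmax(inner_lo - cfg$background_shell_vox, 1L)
  outer_hi <- pmin(inner_hi + cfg$background_shell_vox, d)
  shell <- array(FALSE, d)
  shell[outer_lo[1]:outer_hi[1], outer_lo[2]:outer_hi[2],
        outer_lo[3]:outer_hi[3]] <- TRUE
  shell[inner_lo[1]:inner_hi[1], inner_lo[2]:inner_hi[2],
        inner_lo[3]:inner_hi[3]] <- FALSE
  if (!any(shell))
    stop_gdr("gdr_segmentation_error",
             "no voxels available for background estimation")
  mean(vals[shell])
}

#' Segment a lesion with the contrast-oriented algorithm
#'
#' Within the search region: `mSUV70` is the mean of voxels at or above 70%
#' of the region SUVmax; the background is estimated in a shell outside the
#' 40%-isocontour bounding box; the threshold is `a * mSUV70 +
#' b * background`; the mask is the largest 26-connected component of the
#' supra-threshold voxels (single pass, no hole filling).
#'
#' @param volume an [image_volume()].
#' @param search_region an [roi_mask()] or an index bounding box
#'   `rbind(lo = c(x,y,z), hi = c(x,y,z))`.
#' @param cfg a [coa_config()].
#' @return object of class `coa_result`: `mask` ([roi_mask()]),
#'   `threshold_suv`, `msuv70`, `background_suv`, `n_voxels`, `cfg`.
#' @export
coa_segment <- function(volume, search_region, cfg = coa_config()) {
  region <- .as_region_mask(search_region, volume)
  if (!any(region))
    stop_gdr("gdr_segmentation_error", "empty search region")
  vals <- volume$values
  suvmax <- max(vals[region])
  msuv70 <- mean(vals[region & (vals >= 0.7 * suvmax)])
  background <- .coa_background(vals, region, suvmax, cfg)
  if (suvmax <= background)
    stop_gdr("gdr_segmentation_error",
             "search region has no uptake above background")
  threshold <- cfg$a * msuv70 + cfg$b * background
  seg <- region & (vals >= threshold)
  if (!any(seg))
    stop_gdr("gdr_segmentation_error",
             "no voxel exceeds COA threshold %.3g", threshold)
  lab <- cpp_label_mask(as.logical(seg), dim(seg))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask_arr <- array(lab == keep, dim(seg))
  if (sum(mask_arr) < cfg$min_lesion_voxels)
    stop_gdr("gdr_segmentation_error",
             "segmented component (%d voxels) below min_lesion_voxels (%d)",
             sum(mask_arr), cfg$min_lesion_voxels)
  structure(list(mask = roi_mask(mask_arr, volume$spacing, volume$origin),
                 threshold_suv = threshold, msuv70 = msuv70,
                 background_suv = background, n_voxels = sum(mask_arr),
                 cfg = cfg),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat(sprintf(paste0("<coa_result: threshold %.3f = %.2g*mSUV70(%.3f) + ",
                     "%.2g*bg(%.3f); %d voxels>\n"),
              x$threshold_suv, x$cfg$a, x$msuv70, x$cfg$b, x$background_suv,
              x$n_voxels))
  invisible(x)
}

#' Load an externally supplied (manual) mask for a volume
#'
#' Manual contours are consumed as-is (they may be disconnected); only
#' geometry and non-emptiness are enforced.
#'
#' @param path NIfTI mask file.
#' @param volume the [image_volume()] the mask belongs to.
#' @return an [roi_mask()].
#' @export
load_manual_mask <- function(path, volume) {
  mask <- read_nifti(path, as = "mask")
  check_alignment(volume, mask, require_nonempty = FALSE)
  if (!any(mask$values))
    stop_gdr("gdr_empty_mask_error", "manual mask %s is empty", path)
  mask
}

#' Segment every phase of a gated series with COA
#'
#' The search region is re-centred per phase on the centroid of the voxels
#' at or above 40% of the phase maximum (tracking the breathing excursion),
#' then [coa_segment()] runs independently per phase. If any phase fails,
#' the whole series is rejected with an error listing the failing phases.
#'
#' @param series a [phase_series()].
#' @param search_region initial region ([roi_mask()] or bounding box).
#' @param cfg a [coa_config()].
#' @return a [phase_series()] whose masks are the COA masks; the per-phase
#'   `coa_result`s are attached as attribute `coa`.
#' @export
segment_phase_series <- function(series, search_region, cfg = coa_config()) {
  region0 <- .as_region_mask(search_region, series$phases[[1]]$volume)
  bb0 <- mask_bbox(region0)
  half <- (bb0["hi", ] - bb0["lo", ]) / 2
  results <- vector("list", series$K)
  failures <- character()
  phases <- vector("list", series$K)
  for (k in seq_len(series$K)) {
    vol <- series$phases[[k]]$volume
    res <- tryCatch({
      vals <- vol$values
      reg <- .as_region_mask(rbind(lo = bb0["lo", ], hi = bb0["hi", ]), vol)
      mx <- max(vals[reg])
      idx <- which(reg & vals >= 0.4 * mx, arr.ind = TRUE)
      cen <- round(colMeans(idx))
      d <- dim(vals)
      lo <- pmax(round(cen - half), 1)
      hi <- pmin(round(cen + half), d)
      coa_segment(vol, rbind(lo = lo, hi = hi), cfg)
    }, gdr_error = function(e) e)
    if (inherits(res, "gdr_error")) {
      failures <- c(failures, sprintf("phase %d: %s", k, conditionMessage(res)))
    } else {
      results[[k]] <- res
      phases[[k]] <- list(volume = vol, mask = res$mask)
    }
  }
  if (length(failures))
    stop_gdr("gdr_segmentation_error", "phase segmentation failed:\n%s",
             paste(failures, collapse = "\n"))
  out <- phase_series(phases)
  attr(out, "coa") <- results
  out
}
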