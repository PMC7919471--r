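#' Image volume: a 3D SUV grid with physical geometry
#'
#' The core container for a reconstructed PET volume. Values are standardized
#' uptake values (SUV, g/mL), stored as a 3D array in (x, y, z) axis order.
#' World coordinates follow `world = origin + (index - 1) * spacing` with
#' 1-based array indices (i.e. the first voxel centre sits at `origin`).
#'
#' @param values 3D numeric array, finite and >= 0.
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, world position (mm) of the first voxel.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_gdr("gdr_geometry_error", "image_volume requires a 3D array")
  if (any(dim(values) < 1L))
    stop_gdr("gdr_geometry_error", "each axis needs >= 1 voxel")
  if (!all(is.finite(values)) || any(values < 0))
    stop_gdr("gdr_value_error", "SUV values must be finite and >= 0")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_gdr("gdr_geometry_error", "spacing must be 3 positive numbers")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop_gdr("gdr_geometry_error", "origin must be 3 finite numbers")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary region-of-interest mask paired with an image volume
#'
#' @param values 3D array coercible to logical; same shape contract as the
#'   paired [image_volume()].
#' @param spacing,origin geometry, must match the paired volume exactly.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_gdr("gdr_geometry_error", "roi_mask requires a 3D array")
  mode(values) <- "logical"
  if (anyNA(values))
    stop_gdr("gdr_value_error", "mask values must be 0/1 without NA")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, SUV [%.3g, %.3g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d foreground voxels>\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Check that a mask and a volume share grid geometry exactly
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param require_nonempty error if the mask has no foreground voxel.
#' @export
check_alignment <- function(volume, mask, require_nonempty = TRUE) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop_gdr("gdr_alignment_error",
             "mask shape (%s) does not match volume shape (%s)",
             paste(dim(mask$values), collapse = "x"),
             paste(dim(volume$values), collapse = "x"))
  if (!isTRUE(all.equal(volume$spacing, mask$spacing)) ||
      !isTRUE(all.equal(volume$origin, mask$origin)))
    stop_gdr("gdr_alignment_error", "mask and volume geometry differ")
  if (require_nonempty && !any(mask$values))
    stop_gdr("gdr_empty_mask_error", "mask has no foreground voxel")
  invisible(TRUE)
}

#' Ordered set of gated-phase (volume, mask) pairs for one breathing cycle
#'
#' @param phases list of `list(volume =, mask =)` pairs, one per gated
#'   respiratory bin, in phase order. K >= 3 and shared grid geometry are
#'   enforced.
#' @return an object of class `phase_series` with element `phases` and `K`.
#' @export
phase_series <- function(phases) {
  if (length(phases) < 3L)
    stop_gdr("gdr_value_error", "a phase series needs K >= 3 phases")
  ref <- phases[[1L]]$volume
  for (p in phases) {
    check_alignment(p$volume, p$mask)
    if (!identical(dim(p$volume$values), dim(ref$values)) ||
        !isTRUE(all.equal(p$volume$spacing, ref$spacing)))
      stop_gdr("gdr_geometry_error", "all phases must share grid geometry")
  }
  structure(list(phases = phases, K = length(phases)), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series K=%d, grid %s>\n", x$K,
              paste(dim(x$phases[[1]]$volume$values), collapse = "x")))
  invisible(x)
}

#' One patient's scans and outcome labels
#'
#' A complete case carries the pre-treatment gated series, the pre-treatment
#' static 3D scan, the during/after-treatment 3D scan, and outcome labels.
#'
#' @param patient_id character scalar.
#' @param pre4d a [phase_series()].
#' @param pre3d,post3d `list(volume =, mask =)` pairs.
#' @param outcome list with `LR`, `DM` in {0,1}, `OS_months` >= 0,
#'   `OS_event` in {0,1}.
#' @param interval_days days between the two static scans.
#' @export
patient_case <- function(patient_id, pre4d, pre3d, post3d,
                         outcome = list(LR = 0L, DM = 0L,
                                        OS_months = NA_real_, OS_event = 0L),
                         interval_days = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!inherits(pre4d, "phase_series"))
    stop_gdr("gdr_value_error", "pre4d must be a phase_series")
  check_alignment(pre3d$volume, pre3d$mask)
  check_alignment(post3d$volume, post3d$mask)
  for (lab in c("LR", "DM", "OS_event")) {
    v <- outcome[[lab]]
    if (!is.null(v) && !is.na(v) && !v %in% c(0, 1))
      stop_gdr("gdr_value_error", "outcome label %s must be 0/1", lab)
  }
  structure(list(patient_id = patient_id, pre4d = pre4d, pre3d = pre3d,
                 post3d = post3d, outcome = outcome,
                 interval_days = interval_days),
            class = "patient_case")
}

#' Bounding box of the foreground of a mask (1-based index ranges)
#' @noRd
mask_bbox <- function(mask_values) {
  idx <- which(mask_values, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

#' World coordinates of voxel centres along each axis
#' @noRd
axis_coords <- function(dim3, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim3[a]) - 1) * spacing[a])
}
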