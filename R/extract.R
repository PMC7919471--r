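# Feature bank orchestration: raw / wavelet-filtered (WF-) /
# equal-probability-quantized (Q-) preprocessing variants over the four
# texture families plus first-order statistics.

.fo_names <- c("SUVmax", "SUVmean", "variance", "skewness", "kurtosis",
               "CoV", "volume_ml", "AUC_CSH")
.tex_names <- list(
  glcm = c("Variance_CM", "energy", "entropy", "contrast", "homogeneity",
           "correlation"),
  glrlm = c("SRE", "LRE", "RLN", "RP", "GLN"),
  glszm = c("SZE", "LZE", "ZSN", "ZP"),
  ngtdm = c("Coarseness", "Contrast_NG", "Busyness"))

#' Names of the default feature set
#'
#' First-order features from raw SUV plus all four texture families under
#' the three preprocessing variants (raw, `WF-`, `Q-`). This superset covers
#' the 17 features that survive the eligibility screen in the motivating
#' study: AUC_CSH, Variance_CM, WF-Variance_CM, WF-SRE, WF-LRE, WF-RLN,
#' WF-RP, Q-SZE, Q-LZE, Q-ZSN, Q-ZP, Q-SRE, Q-LRE, Q-RLN, Q-RP,
#' Q-Contrast_NG, Q-Busyness.
#'
#' @return character vector of feature names.
#' @export
default_feature_set <- function() {
  tex <- unlist(.tex_names, use.names = FALSE)
  c(.fo_names, tex, paste0("WF-", tex), paste0("Q-", tex))
}

#' Extract the feature bank from one (volume, mask) pair
#'
#' First-order features are computed from raw SUV only. Texture features are
#' computed on: raw SUV discretized with fixed bin width `W`; wavelet
#' band-pass filtered values (then fixed-bin discretized), prefix `WF-`;
#' equal-probability quantized values, prefix `Q-`. Family-level failures
#' (e.g. a single-voxel mask) propagate as NA sentinels.
#'
#' @param volume an [image_volume()]. @param mask an aligned [roi_mask()].
#' @param W fixed bin width in SUV (default 0.01).
#' @param n_levels equal-probability quantization levels (default 64).
#' @param wavelet wavelet basis for the WF- variant.
#' @param anchor fixed-bin anchor, see [discretize_fixed_bin()].
#' @param features optional character vector restricting the output (subset
#'   of [default_feature_set()]); unneeded variants are then skipped.
#' @return named numeric vector with metadata attributes `W`, `n_levels`,
#'   `n_voxels`.
#' @export
extract_features <- function(volume, mask, W = 0.01, n_levels = 64L,
                             wavelet = "coif1", anchor = "min",
                             features = NULL) {
  check_alignment(volume, mask)
  all_names <- default_feature_set()
  if (is.null(features)) features <- all_names
  unknown <- setdiff(features, all_names)
  if (length(unknown))
    stop_gdr("gdr_value_error", "unknown features: %s",
             paste(unknown, collapse = ", "))
  vals <- volume$values[mask$values]
  out <- stats::setNames(rep(NA_real_, length(features)), features)

  fo_wanted <- intersect(features, .fo_names)
  if (length(fo_wanted)) {
    fo <- .first_order_features(vals, volume$spacing)
    out[fo_wanted] <- fo[fo_wanted]
  }

  tex_all <- unlist(.tex_names, use.names = FALSE)
  variant_values <- function(prefix) {
    wanted <- intersect(features, paste0(prefix, tex_all))
    if (!length(wanted)) return(NULL)
    base_vals <- if (prefix == "WF-") {
      tryCatch(wavelet_bandpass(volume, mask, wavelet = wavelet),
               gdr_error = function(e) NULL)
    } else vals
    if (is.null(base_vals)) return(stats::setNames(rep(NA_real_, length(wanted)), wanted))
    levels <- if (prefix == "Q-") equalize_quantize(base_vals, n_levels)
              else discretize_fixed_bin(base_vals, W, anchor)
    grid <- .level_grid(levels, mask$values)
    fam_vals <- c()
    for (fam in names(.tex_names)) {
      fam_names <- paste0(prefix, .tex_names[[fam]])
      if (!length(intersect(wanted, fam_names))) next
      fv <- switch(fam,
        glcm = glcm_features(grid), glrlm = glrlm_features(grid),
        glszm = glszm_features(grid), ngtdm = ngtdm_features(grid))
      names(fv) <- paste0(prefix, names(fv))
      fam_vals <- c(fam_vals, fv)
    }
    fam_vals[wanted]
  }
  for (prefix in c("", "WF-", "Q-")) {
    v <- variant_values(prefix)
    if (!is.null(v)) out[names(v)] <- v
  }
  structure(out, W = W, n_levels = as.integer(n_levels),
            n_voxels = length(vals))
}

#' Extract the feature bank for a whole cohort into a long feature table
#'
#' Produces the long-format table consumed by the screening and delta
#' stages: one row per (patient, scan_role, segmentation, feature).
#' `scan_role` is `pre3d`, `post3d`, or `pre4d_phase_k`.
#'
#' @param cases list of [patient_case()] objects.
#' @param segmentation `"manual"` (use the masks carried by the cases) or
#'   `"coa"` (re-segment every scan with [coa_segment()]).
#' @param coa_cfg a [coa_config()] for `segmentation = "coa"`.
#' @param ... passed to [extract_features()] (`W`, `n_levels`, `features`, ...).
#' @return data.frame: patient_id, scan_role, segmentation, feature_name, value.
#' @export
extract_cohort <- function(cases, segmentation = c("manual", "coa"),
                           coa_cfg = coa_config(), ...) {
  segmentation <- match.arg(segmentation)
  rows <- list()
  for (case in cases) {
    scans <- c(list(pre3d = case$pre3d, post3d = case$post3d),
               stats::setNames(case$pre4d$phases,
                               sprintf("pre4d_phase_%d", seq_len(case$pre4d$K))))
    if (segmentation == "coa") {
      scans <- lapply(scans, function(s) {
        res <- coa_segment(s$volume, search_region = .coa_search_region(s),
                           cfg = coa_cfg)
        list(volume = s$volume, mask = res$mask)
      })
    }
    for (role in names(scans)) {
      fv <- extract_features(scans[[role]]$volume, scans[[role]]$mask, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = case$patient_id, scan_role = role,
        segmentation = segmentation, feature_name = names(fv),
        value = as.numeric(fv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Generous search region for COA on simulated scans: the carried mask's
# bounding box dilated by 6 voxels (covers breathing excursion + PSF tails).
.coa_search_region <- function(scan, dilate = 6L) {
  bb <- mask_bbox(scan$mask$values)
  d <- dim(scan$mask$values)
  lo <- pmax(bb["lo", ] - dilate, 1L)
  hi <- pmin(bb["hi", ] + dilate, d)
  reg <- array(FALSE, d)
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  roi_mask(reg, scan$mask$spacing, scan$mask$origin)
}
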