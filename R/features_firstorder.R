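# First-order (histogram) features, computed from raw SUV values only.

#' Area under the cumulative SUV-volume histogram
#'
#' The cumulative SUV-volume histogram plots `f(t)`, the fraction of lesion
#' voxels with SUV >= `t * SUVmax`, against the relative threshold
#' `t in [0, 1]` (the analogue of a dose-volume histogram). Its area has the
#' exact closed form `AUC_CSH = mean(v) / max(v)` for non-negative values,
#' since each voxel contributes measure `v / max(v)` to the integral — no
#' threshold grid is involved. AUC_CSH is 1 for a perfectly homogeneous
#' lesion and decreases with heterogeneity; it is invariant under positive
#' rescaling of SUV.
#'
#' @param values non-empty numeric SUV values with `max(values) > 0`.
#' @return a fraction in (0, 1].
#' @export
auc_csh <- function(values) {
  if (length(values) == 0L || !all(is.finite(values)))
    stop_gdr("gdr_value_error", "values must be non-empty and finite")
  mx <- max(values)
  if (mx <= 0) stop_gdr("gdr_value_error", "AUC_CSH needs max(values) > 0")
  mean(pmax(values, 0)) / mx
}

#' First-order feature family
#' @param values in-mask SUV values.
#' @param spacing voxel spacing in mm (for volume_ml).
#' @return named numeric vector.
#' @noRd
.first_order_features <- function(values, spacing) {
  m <- mean(values)
  c(SUVmax = max(values),
    SUVmean = m,
    variance = stats::var(values),
    skewness = .skewness(values),
    kurtosis = .kurtosis(values),
    CoV = if (m > 0) stats::sd(values) / m else NA_real_,
    volume_ml = length(values) * prod(spacing) / 1000,
    AUC_CSH = auc_csh(values))
}
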