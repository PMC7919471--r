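# Gray-level discretization for texture computation.

#' Fixed-bin-width discretization of SUV values
#'
#' `level(v) = floor((v - anchor) / W) + 1` with the anchor at the mask
#' minimum (default) so level 1 starts at the lowest in-mask SUV. The bin
#' width default W = 0.01 SUV follows the study protocol; an anchor at zero
#' is exposed as the IBSI-style alternative.
#'
#' @param values numeric SUV values (non-empty, finite).
#' @param W bin width in SUV (> 0), default 0.01.
#' @param anchor `"min"` (default) or `"zero"`.
#' @return integer gray levels >= 1.
#' @export
discretize_fixed_bin <- function(values, W = 0.01, anchor = c("min", "zero")) {
  anchor <- match.arg(anchor)
  if (length(values) == 0L || !all(is.finite(values)))
    stop_gdr("gdr_value_error", "values must be non-empty and finite")
  if (W <= 0) stop_gdr("gdr_value_error", "bin width W must be > 0")
  a <- if (anchor == "min") min(values) else 0
  lev <- floor((values - a) / W) + 1L
  as.integer(pmax(lev, 1L))
}

#' Equal-probability quantization
#'
#' Assigns gray levels so that level occupancy is as equal as achievable
#' given ties (the histogram-equalization analogue): values are ranked with
#' ties sharing the maximal rank and mapped onto `n_levels` equal quantile
#' slots. Monotone in the input value by construction.
#'
#' @param values numeric values (non-empty, finite).
#' @param n_levels number of levels (>= 2), default 64.
#' @return integer gray levels in `[1, n_levels]`.
#' @export
equalize_quantize <- function(values, n_levels = 64L) {
  if (length(values) == 0L || !all(is.finite(values)))
    stop_gdr("gdr_value_error", "values must be non-empty and finite")
  if (n_levels < 2L) stop_gdr("gdr_value_error", "n_levels must be >= 2")
  r <- rank(values, ties.method = "max")
  as.integer(ceiling(n_levels * r / length(values)))
}
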