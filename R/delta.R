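# The normalized delta statistic: treatment-induced relative feature change
# weighted by the feature's intrinsic variability across the pre-treatment
# breathing phases,
#
#     delta = delta_r / sigma_4d,
#     delta_r  = 100 * (post - pre) / |pre|       (relative change, %)
#     sigma_4d = 100 * SD(phases) / |mean(phases)| (relative phase SD, %)
#
# Both terms are percentages of their reference values, so delta is
# dimensionless and invariant under rescaling of the feature.

#' Compute per-patient normalized delta values
#'
#' @param table long feature table with `pre3d`, `post3d` and
#'   `pre4d_phase_k` rows (see [extract_cohort()]).
#' @param features which features to evaluate (default: all in the table) —
#'   normally the eligible list from [screen_features()].
#' @param epsilon absolute floor on |pre| and |mean(phases)| below which the
#'   record is excluded (`zero_reference`).
#' @param sigma_floor relative-SD floor in percent (default 0.1): records
#'   with `sigma_4d` below it are excluded (`sigma_floor`) rather than
#'   reported as near-infinite deltas.
#' @return data.frame of class `delta_table`: patient_id, feature_name,
#'   delta_r, sigma_4d, delta, excluded, reason.
#' @export
compute_delta <- function(table, features = NULL, epsilon = 1e-8,
                          sigma_floor = 0.1) {
  if (is.null(features)) features <- sort(unique(table$feature_name))
  ids <- unique(table$patient_id)
  pre <- table[table$scan_role == "pre3d", , drop = FALSE]
  post <- table[table$scan_role == "post3d", , drop = FALSE]
  ph <- table[.phase_rows(table), , drop = FALSE]
  rows <- list()
  for (f in features) {
    pre_f <- pre[pre$feature_name == f, , drop = FALSE]
    post_f <- post[post$feature_name == f, , drop = FALSE]
    ph_f <- ph[ph$feature_name == f & !is.na(ph$value), , drop = FALSE]
    ph_split <- split(ph_f$value, ph_f$patient_id)
    for (id in ids) {
      p0 <- pre_f$value[pre_f$patient_id == id]
      p1 <- post_f$value[post_f$patient_id == id]
      pv <- ph_split[[id]]
      rec <- data.frame(patient_id = id, feature_name = f,
                        delta_r = NA_real_, sigma_4d = NA_real_,
                        delta = NA_real_, excluded = TRUE,
                        reason = NA_character_, stringsAsFactors = FALSE)
      if (length(p0) != 1L || length(p1) != 1L || is.na(p0) || is.na(p1)) {
        rec$reason <- "missing_scan"
      } else if (is.null(pv) || length(pv) < 3L) {
        rec$reason <- "few_phases"
      } else if (abs(p0) < epsilon || abs(mean(pv)) < epsilon) {
        rec$reason <- "zero_reference"
      } else {
        delta_r <- 100 * (p1 - p0) / abs(p0)
        sigma <- 100 * stats::sd(pv) / abs(mean(pv))
        rec$delta_r <- delta_r
        rec$sigma_4d <- sigma
        if (sigma < sigma_floor) {
          rec$reason <- "sigma_floor"
        } else {
          rec$delta <- delta_r / sigma
          rec$excluded <- FALSE
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("delta_table", class(out))
  out
}

#' Per-feature Mann-Whitney U group comparison of delta values
#'
#' Two-sided test of delta between outcome groups: exact when the total
#' sample is <= 20 and tie-free, normal approximation with tie correction
#' otherwise; BH adjustment across the tested features.
#'
#' @param deltas a [compute_delta()] table (excluded records are dropped).
#' @param outcome named 0/1 vector indexed by patient_id, or data.frame
#'   with columns `patient_id` and the label.
#' @param label column name when `outcome` is a data.frame (default "LR").
#' @return data.frame: feature_name, n1, n0, U, p, p_adj, median1, median0.
#' @export
group_test <- function(deltas, outcome, label = "LR") {
  if (is.data.frame(outcome))
    outcome <- stats::setNames(outcome[[label]], outcome$patient_id)
  d <- deltas[!deltas$excluded, , drop = FALSE]
  feats <- sort(unique(d$feature_name))
  rows <- lapply(feats, function(f) {
    di <- d[d$feature_name == f, , drop = FALSE]
    y <- as.numeric(outcome[di$patient_id])
    g1 <- di$delta[y == 1]; g0 <- di$delta[y == 0]
    if (!length(g1) || !length(g0))
      stop_gdr("gdr_value_error", "feature %s: an outcome group is empty", f)
    n <- length(g1) + length(g0)
    exact <- n <= 20 && !anyDuplicated(c(g1, g0))
    wt <- suppressWarnings(stats::wilcox.test(g1, g0, exact = exact,
                                              correct = TRUE))
    data.frame(feature_name = f, n1 = length(g1), n0 = length(g0),
               U = unname(wt$statistic), p = wt$p.value,
               median1 = stats::median(g1), median0 = stats::median(g0))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("feature_name", "n1", "n0", "U", "p", "p_adj", "median1", "median0")]
}
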