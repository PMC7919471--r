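# Feature eligibility screening: (1) normality across the gated breathing
# phases in more than 70% of patients (Shapiro-Wilk), (2) comparability
# between the static 3D value and the 4D summary (Wilcoxon signed rank with
# FDR control, significant shifts vetoed only if the Bland-Altman 95% CI of
# the mean percentage difference excludes zero).

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Own implementation of the step-up rule with monotonicity enforcement
#' (equivalent to `p.adjust(method = "BH")`, kept independent so the screen
#' is testable against it).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_gdr("gdr_value_error", "p-values must lie in [0, 1]")
  m <- sum(!is.na(p))
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  o <- order(p[idx])
  ranked <- p[idx][o]
  adj <- ranked * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out[idx[o]] <- adj
  out
}

.phase_rows <- function(table) grepl("^pre4d_phase_", table$scan_role)

#' Normality screen across gated breathing phases
#'
#' Per (patient, feature): Shapiro-Wilk on the K phase values, pass iff
#' p >= alpha. Values constant across phases (test undefined) count as PASS
#' — zero intrinsic variability is maximal stability — but are flagged,
#' since a zero sigma makes the delta statistic undefined downstream.
#' A feature passes iff *strictly more than* `patient_fraction` of its
#' evaluable patients pass.
#'
#' @param table long feature table (see [extract_cohort()]).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @param patient_fraction strict lower bound on the passing-patient
#'   fraction (default 0.70).
#' @return data.frame: feature_name, n_evaluable, n_pass, n_constant,
#'   normal_fraction, normality_pass.
#' @export
normality_screen <- function(table, alpha = 0.05, patient_fraction = 0.70) {
  ph <- table[.phase_rows(table) & !is.na(table$value), , drop = FALSE]
  feats <- sort(unique(table$feature_name))
  rows <- lapply(feats, function(f) {
    d <- ph[ph$feature_name == f, , drop = FALSE]
    per_pat <- split(d$value, d$patient_id)
    per_pat <- per_pat[vapply(per_pat, length, 1L) >= 3L]
    n_eval <- length(per_pat)
    if (n_eval == 0L)
      return(data.frame(feature_name = f, n_evaluable = 0L, n_pass = 0L,
                        n_constant = 0L, normal_fraction = NA_real_,
                        normality_pass = FALSE))
    verdicts <- vapply(per_pat, function(v) {
      if (max(v) - min(v) < .Machine$double.eps^0.5 * max(1, abs(mean(v))))
        return(2L)  # constant: pass, flagged
      p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
      if (is.na(p)) 2L else if (p >= alpha) 1L else 0L
    }, integer(1))
    n_pass <- sum(verdicts > 0L)
    frac <- n_pass / n_eval
    data.frame(feature_name = f, n_evaluable = n_eval, n_pass = n_pass,
               n_constant = sum(verdicts == 2L), normal_fraction = frac,
               normality_pass = frac > patient_fraction)
  })
  do.call(rbind, rows)
}

#' Comparability screen between static 3D and gated 4D values
#'
#' Pairs each patient's `pre3d` value with the mean across that patient's
#' gated phases (the mean mirrors the time-averaged static acquisition).
#' Per feature, a two-sided Wilcoxon signed-rank test is run over patients
#' and BH-adjusted across features. A feature is comparable iff the adjusted
#' p >= alpha, or the adjusted p < alpha but the Bland-Altman 95% CI of the
#' mean percentage difference (per-pair difference as percent of the pair
#' mean) contains 0, i.e. significance is not confirmed.
#'
#' @param table long feature table.
#' @param alpha significance level (default 0.05).
#' @param min_patients refuse features with fewer complete pairs (default 6,
#'   the power floor). If no feature reaches the floor the screen errors.
#' @return data.frame: feature_name, n_pairs, wsr_p, wsr_p_adj, ba_mean_pct,
#'   ba_lo, ba_hi, comparable_pass.
#' @export
comparability_screen <- function(table, alpha = 0.05, min_patients = 6L) {
  feats <- sort(unique(table$feature_name))
  pre <- table[table$scan_role == "pre3d" & !is.na(table$value), , drop = FALSE]
  ph <- table[.phase_rows(table) & !is.na(table$value), , drop = FALSE]
  per_feat <- lapply(feats, function(f) {
    x3 <- pre[pre$feature_name == f, , drop = FALSE]
    d4 <- ph[ph$feature_name == f, , drop = FALSE]
    y4 <- vapply(split(d4$value, d4$patient_id),
                 function(v) if (length(v) >= 3L) mean(v) else NA_real_, 0)
    ids <- intersect(x3$patient_id, names(y4)[!is.na(y4)])
    x <- x3$value[match(ids, x3$patient_id)]
    y <- as.numeric(y4[ids])
    list(f = f, x = x, y = y, n = length(ids))
  })
  if (!any(vapply(per_feat, `[[`, 0L, "n") >= min_patients))
    stop_gdr("gdr_value_error",
             "comparability screen refused: fewer than %d complete pairs",
             min_patients)
  wsr_p <- vapply(per_feat, function(pf) {
    if (pf$n < min_patients) return(NA_real_)
    d <- pf$x - pf$y
    if (all(abs(d) < .Machine$double.eps^0.5 * max(1, max(abs(pf$x)))))
      return(1)
    p <- suppressWarnings(
      stats::wilcox.test(pf$x, pf$y, paired = TRUE, exact = FALSE)$p.value)
    if (is.na(p)) 1 else p
  }, 0)
  p_adj <- bh_adjust(wsr_p)
  rows <- Map(function(pf, p, pa) {
    if (pf$n < min_patients)
      return(data.frame(feature_name = pf$f, n_pairs = pf$n, wsr_p = NA_real_,
                        wsr_p_adj = NA_real_, ba_mean_pct = NA_real_,
                        ba_lo = NA_real_, ba_hi = NA_real_,
                        comparable_pass = NA))
    mid <- (pf$x + pf$y) / 2
    ok <- abs(mid) > .Machine$double.eps
    pct <- 100 * (pf$x[ok] - pf$y[ok]) / mid[ok]
    n <- length(pct)
    mu <- mean(pct)
    half <- 1.96 * stats::sd(pct) / sqrt(n)
    contains0 <- (mu - half) <= 0 && 0 <= (mu + half)
    data.frame(feature_name = pf$f, n_pairs = pf$n, wsr_p = p,
               wsr_p_adj = pa, ba_mean_pct = mu, ba_lo = mu - half,
               ba_hi = mu + half,
               comparable_pass = pa >= alpha || contains0)
  }, per_feat, wsr_p, p_adj)
  do.call(rbind, rows)
}

#' Intersect the two screen verdicts into the eligible feature list
#'
#' @param normality output of [normality_screen()].
#' @param comparability output of [comparability_screen()].
#' @return character vector of eligible feature names, sorted; empty (with a
#'   warning) when the intersection is empty.
#' @export
select_eligible <- function(normality, comparability) {
  a <- normality$feature_name[normality$normality_pass %in% TRUE]
  b <- comparability$feature_name[comparability$comparable_pass %in% TRUE]
  out <- sort(intersect(a, b))
  if (!length(out)) warning("no feature passed both screens")
  out
}

#' Run both screens and assemble a screen report
#'
#' @inheritParams normality_screen
#' @inheritParams comparability_screen
#' @param patient_fraction see [normality_screen()].
#' @return list of class `screen_report`: `normality`, `comparability`,
#'   `eligible`, `config`.
#' @export
screen_features <- function(table, alpha = 0.05, patient_fraction = 0.70,
                            min_patients = 6L) {
  norm <- normality_screen(table, alpha, patient_fraction)
  comp <- comparability_screen(table, alpha, min_patients)
  structure(list(normality = norm, comparability = comp,
                 eligible = suppressWarnings(select_eligible(norm, comp)),
                 config = list(alpha = alpha,
                               patient_fraction = patient_fraction,
                               min_patients = min_patients)),
            class = "screen_report")
}
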