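# End-to-end pipeline: simulate -> segment -> extract -> screen -> delta ->
# model, as a configured, seeded, logged run. Configuration is a nested
# key-value structure (JSON on disk); every stage output carries the digest
# of the resolved configuration so runs are auditable.

.default_config <- function() {
  list(
    seed = 1L,
    output_dir = "gdr_out",
    manifest = NULL,                    # read cases instead of simulating
    cohort = list(n = 12L, lr_fraction = 0.4, radii_cv = 0.12, uptake_cv = 0.15),
    lesion = list(center_mm = c(0, 0, 0), radii_mm = c(22, 18, 15),
                  uptake_mean = 8, background = 1, n_blobs = 30L,
                  blob_amplitude = 2, blob_scale_mm = 6),
    motion = list(amplitude_mm = c(0, 0, 10), pattern = "cos2", K = 8L,
                  psf_fwhm_mm = 4.8, noise_cv = 0.10, jitter_cv = 0.2),
    grid = list(dim = c(32L, 32L, 32L), spacing = c(4, 4, 4)),
    effect_lr = list(homogenization = 0.7, volume_scale = 1, uptake_scale = 1),
    effect_nolr = list(homogenization = 0, volume_scale = 1, uptake_scale = 1),
    segmentation = list(mode = "manual", a = 0.5, b = 0.5,
                        min_lesion_voxels = 1L),
    extraction = list(W = 0.01, n_levels = 64L, wavelet = "coif1",
                      features = NULL),
    screen = list(alpha = 0.05, patient_fraction = 0.70, min_patients = 6L),
    model = list(endpoint = "LR", B = 1000L, max_features = 2L)
  )
}

.merge_config <- function(base, user, path = "") {
  errs <- character()
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) {
      errs <- c(errs, sprintf("unknown key: %s", full))
    } else if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]])) {
        errs <- c(errs, sprintf("key %s must be a section", full))
      } else {
        sub <- .merge_config(base[[k]], user[[k]], full)
        base[[k]] <- sub$config
        errs <- c(errs, sub$errors)
      }
    } else {
      base[[k]] <- user[[k]]
    }
  }
  list(config = base, errors = errs)
}

#' Validate and resolve a pipeline run configuration
#'
#' Fills defaults, reports every unknown key, and range-checks the values
#' that gate the statistics. Accepts a JSON file path or a nested list.
#'
#' @param config path to a JSON config file, or a (possibly partial) list.
#' @return the fully resolved config list (class `run_config`) with a
#'   `digest` attribute, or an error listing all problems.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_gdr("gdr_manifest_error", "config file %s not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merged <- .merge_config(.default_config(), config)
  cfg <- merged$config
  errs <- merged$errors
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$cohort$n >= 2, "cohort.n must be >= 2")
  chk(cfg$cohort$lr_fraction >= 0 && cfg$cohort$lr_fraction <= 1,
      "cohort.lr_fraction must be in [0, 1]")
  for (e in c("effect_lr", "effect_nolr"))
    chk(cfg[[e]]$homogenization >= 0 && cfg[[e]]$homogenization <= 1,
        sprintf("%s.homogenization must be in [0, 1]", e))
  chk(cfg$screen$alpha > 0 && cfg$screen$alpha < 1,
      "screen.alpha must be in (0, 1)")
  chk(cfg$screen$patient_fraction >= 0 && cfg$screen$patient_fraction <= 1,
      "screen.patient_fraction must be in [0, 1]")
  chk(cfg$segmentation$mode %in% c("manual", "coa"),
      "segmentation.mode must be 'manual' or 'coa'")
  chk(cfg$model$endpoint %in% c("LR", "DM"),
      "model.endpoint must be 'LR' or 'DM'")
  chk(cfg$motion$K >= 3, "motion.K must be >= 3")
  chk(cfg$extraction$W > 0, "extraction.W must be > 0")
  if (length(errs))
    stop_gdr("gdr_config_error", "invalid configuration:\n  %s",
             paste(errs, collapse = "\n  "))
  attr(cfg, "digest") <- digest::digest(cfg, algo = "md5")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.write_with_meta <- function(obj, path, cfg_digest) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(obj, path, row.names = FALSE)
    jsonlite::write_json(list(config_digest = cfg_digest),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  } else {
    obj$config_digest <- cfg_digest
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  path
}

#' Run the full pipeline
#'
#' Executes simulate (or manifest load), segmentation, feature extraction,
#' eligibility screening, delta computation, group testing and outcome
#' modelling. Any stage failure marks that stage failed and skips the
#' downstream stages; the report is still returned. Deterministic per seed:
#' re-running an identical configuration reproduces identical output
#' digests.
#'
#' @param config a [validate_config()] result, a partial list, or a JSON
#'   config path.
#' @return list of class `pipeline_report`: per-stage `stages` (status +
#'   output digests), `eligible`, `group_tests`, `model`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dg <- attr(cfg, "digest")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  report <- list(stages = list(), eligible = character(0),
                 group_tests = NULL, model = NULL, config = cfg,
                 config_digest = dg)
  note <- function(name, status, outputs = character(0), error = NULL) {
    report$stages[[name]] <<- list(
      status = status, outputs = outputs,
      digests = if (length(outputs)) unname(tools::md5sum(outputs)) else character(0),
      error = error)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(name, "failed", error = conditionMessage(res))
      NULL
    } else res
  }

  cases <- run_stage("simulate", function() {
    out <- if (!is.null(cfg$manifest)) {
      cases <- read_cohort(cfg$manifest)
      if (anyDuplicated(names(cases)))
        stop_gdr("gdr_manifest_error", "duplicate patient_id: %s",
                 paste(unique(names(cases)[duplicated(names(cases))]),
                       collapse = ", "))
      cases
    } else {
      simulate_cohort(
        n = cfg$cohort$n, lr_fraction = cfg$cohort$lr_fraction,
        effect_lr = cfg$effect_lr, effect_nolr = cfg$effect_nolr,
        lesion = do.call(lesion_spec, cfg$lesion),
        motion = do.call(motion_spec, cfg$motion),
        grid = grid_spec(cfg$grid$dim, cfg$grid$spacing),
        radii_cv = cfg$cohort$radii_cv, uptake_cv = cfg$cohort$uptake_cv,
        seed = cfg$seed)
    }
    note("simulate", "ok")
    out
  })
  if (is.null(cases)) return(structure(report, class = "pipeline_report"))

  table <- run_stage("extract", function() {
    tab <- extract_cohort(
      cases, segmentation = cfg$segmentation$mode,
      coa_cfg = coa_config(a = cfg$segmentation$a, b = cfg$segmentation$b,
                           min_lesion_voxels = cfg$segmentation$min_lesion_voxels),
      W = cfg$extraction$W, n_levels = cfg$extraction$n_levels,
      wavelet = cfg$extraction$wavelet, features = cfg$extraction$features)
    path <- .write_with_meta(tab, file.path(cfg$output_dir, "features.csv"), dg)
    note("extract", "ok", path)
    tab
  })
  if (is.null(table)) return(structure(report, class = "pipeline_report"))

  screen <- run_stage("screen", function() {
    sc <- screen_features(table, alpha = cfg$screen$alpha,
                          patient_fraction = cfg$screen$patient_fraction,
                          min_patients = cfg$screen$min_patients)
    path <- .write_with_meta(unclass(sc),
                             file.path(cfg$output_dir, "screen_report.json"), dg)
    note("screen", "ok", path)
    sc
  })
  if (is.null(screen)) return(structure(report, class = "pipeline_report"))
  report$eligible <- screen$eligible

  deltas <- run_stage("delta", function() {
    if (!length(screen$eligible))
      stop_gdr("gdr_value_error", "no eligible features for the delta stage")
    dt <- compute_delta(table, features = screen$eligible)
    path <- .write_with_meta(dt, file.path(cfg$output_dir, "deltas.csv"), dg)
    note("delta", "ok", path)
    dt
  })
  if (is.null(deltas)) return(structure(report, class = "pipeline_report"))

  model <- run_stage("model", function() {
    lab <- vapply(cases, function(cs) as.numeric(cs$outcome[[cfg$model$endpoint]]), 0)
    names(lab) <- vapply(cases, `[[`, "", "patient_id")
    gt <- group_test(deltas, lab)
    # rank candidates by adjusted p, breaking the small-n exact-test ties by
    # group-median separation; cap the model size to avoid rank deficiency
    ord <- order(gt$p_adj, -abs(gt$median1 - gt$median0), gt$feature_name)
    sig <- gt$feature_name[ord][gt$p_adj[ord] < cfg$screen$alpha]
    exploratory <- FALSE
    if (!length(sig)) {
      sig <- gt$feature_name[ord][1L]
      exploratory <- TRUE
    }
    sig <- utils::head(sig, cfg$model$max_features)
    keep <- deltas[!deltas$excluded & deltas$feature_name %in% sig, , drop = FALSE]
    wide <- stats::reshape(keep[, c("patient_id", "feature_name", "delta")],
                           idvar = "patient_id", timevar = "feature_name",
                           direction = "wide")
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    names(wide) <- sub("^delta\\.", "", names(wide))
    x <- wide[, sig, drop = FALSE]
    names(x) <- make.names(sig)
    fit <- fit_logistic_bootstrap(x, lab[wide$patient_id],
                                  B = cfg$model$B, seed = cfg$seed)
    res <- list(group_tests = gt, model = fit, selected = sig,
                exploratory = exploratory)
    path <- .write_with_meta(
      list(selected = sig, exploratory = exploratory,
           auc = fit$auc, sensitivity = fit$sensitivity,
           specificity = fit$specificity, B_effective = fit$B_effective,
           coefficients = fit$coefficients),
      file.path(cfg$output_dir, "model.json"), dg)
    note("model", "ok", path)
    res
  })
  if (!is.null(model)) {
    report$group_tests <- model$group_tests
    report$model <- model$model
    report$model_exploratory <- model$exploratory
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %s\n", nm, x$stages[[nm]]$status))
  if (length(x$eligible))
    cat("  eligible:", paste(utils::head(x$eligible, 8), collapse = ", "),
        if (length(x$eligible) > 8) "..." else "", "\n")
  if (!is.null(x$model))
    cat(sprintf("  model AUC %.3f (spec %.3f)\n", x$model$auc,
                x$model$specificity))
  invisible(x)
}
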