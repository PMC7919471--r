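# Cohort manifest I/O: one CSV row per scan, NIfTI volume + mask per row.

.manifest_cols <- c("patient_id", "role", "volume_path", "mask_path",
                    "LR", "DM", "OS_months", "OS_event", "interval_days")

#' Write one patient case to NIfTI files plus manifest rows
#'
#' @param case a [patient_case()].
#' @param dir output directory (created if needed).
#' @return data.frame of manifest rows (paths relative to `dir`).
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- case$patient_id
  rows <- list()
  emit <- function(role, pair) {
    vp <- sprintf("%s_%s_vol.nii.gz", id, role)
    mp <- sprintf("%s_%s_mask.nii.gz", id, role)
    write_nifti(pair$volume, file.path(dir, vp))
    write_nifti(pair$mask, file.path(dir, mp))
    data.frame(patient_id = id, role = role, volume_path = vp, mask_path = mp,
               LR = case$outcome$LR, DM = case$outcome$DM,
               OS_months = case$outcome$OS_months,
               OS_event = case$outcome$OS_event,
               interval_days = case$interval_days, stringsAsFactors = FALSE)
  }
  rows <- c(rows, list(emit("pre3d", case$pre3d), emit("post3d", case$post3d)))
  for (k in seq_len(case$pre4d$K))
    rows <- c(rows, list(emit(sprintf("pre4d_phase_%d", k), case$pre4d$phases[[k]])))
  do.call(rbind, rows)
}

#' Write a cohort of cases and its manifest
#' @param cases list of [patient_case()].
#' @param dir output directory.
#' @return path of the written `manifest.csv`, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  man <- do.call(rbind, lapply(cases, write_case, dir = dir))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

.read_pair <- function(dir, vp, mp, role) {
  for (p in c(vp, mp))
    if (!file.exists(file.path(dir, p)))
      stop_gdr("gdr_manifest_error", "missing file for %s: %s", role, p)
  vol <- read_nifti(file.path(dir, vp), as = "volume")
  mask <- read_nifti(file.path(dir, mp), as = "mask")
  check_alignment(vol, mask, require_nonempty = FALSE)
  list(volume = vol, mask = mask)
}

#' Read one patient case back from a manifest
#'
#' @param manifest a manifest data.frame or path to `manifest.csv`; paths in
#'   it are taken relative to the manifest's directory (or `dir`).
#' @param patient_id which patient to load.
#' @param dir base directory for relative paths (derived from the manifest
#'   path when that is given).
#' @return a [patient_case()].
#' @export
read_case <- function(manifest, patient_id, dir = ".") {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop_gdr("gdr_manifest_error", "manifest %s not found", manifest)
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  miss <- setdiff(.manifest_cols, names(manifest))
  if (length(miss))
    stop_gdr("gdr_manifest_error", "manifest lacks columns: %s",
             paste(miss, collapse = ", "))
  man <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (nrow(man) == 0L)
    stop_gdr("gdr_manifest_error", "patient %s not in manifest", patient_id)
  need <- function(role) {
    r <- man[man$role == role, , drop = FALSE]
    if (nrow(r) != 1L)
      stop_gdr("gdr_manifest_error", "patient %s: expected one %s row, found %d",
               patient_id, role, nrow(r))
    .read_pair(dir, r$volume_path, r$mask_path, role)
  }
  phase_roles <- grep("^pre4d_phase_", man$role, value = TRUE)
  ks <- sort(as.integer(sub("^pre4d_phase_", "", phase_roles)))
  if (length(ks) < 3L)
    stop_gdr("gdr_manifest_error", "patient %s: found %d phase rows, need >= 3",
             patient_id, length(ks))
  if (!identical(ks, seq_along(ks)))
    stop_gdr("gdr_manifest_error", "patient %s: phase indices not contiguous",
             patient_id)
  phases <- lapply(ks, function(k) need(sprintf("pre4d_phase_%d", k)))
  r1 <- man[1L, ]
  patient_case(patient_id,
               pre4d = phase_series(phases),
               pre3d = need("pre3d"), post3d = need("post3d"),
               outcome = list(LR = r1$LR, DM = r1$DM,
                              OS_months = r1$OS_months, OS_event = r1$OS_event),
               interval_days = r1$interval_days)
}

#' Read all patients of a manifest
#' @inheritParams read_case
#' @return named list of [patient_case()].
#' @export
read_cohort <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop_gdr("gdr_manifest_error", "manifest %s not found", manifest)
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  ids <- unique(manifest$patient_id)
  pre_ids <- manifest$patient_id[manifest$role == "pre3d"]
  if (anyDuplicated(pre_ids))
    stop_gdr("gdr_manifest_error", "duplicate patient_id in manifest: %s",
             paste(unique(pre_ids[duplicated(pre_ids)]), collapse = ", "))
  stats::setNames(lapply(ids, function(id) read_case(manifest, id, dir)), ids)
}
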