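# Cohort serialization: NIfTI-1 volumes/masks (one file per scan, affine
# recording the voxel spacing) plus the clinical long table as CSV.

.write_nifti <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr * 1)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' One `.nii.gz` per scan per patient (`<id>_baseline.nii.gz`,
#' `<id>_baseline_mask.nii.gz`, `<id>_followup<k>_mask.nii.gz`) with the
#' voxel spacing recorded in the NIfTI header, plus `clinical.csv` in the
#' package's clinical-table layout and `config.csv` echoing seed and
#' geometry for provenance.
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- cohort@config@voxel_spacing
  for (p in cohort@patients) {
    base <- file.path(dir, p@patient_id)
    .write_nifti(p@baseline_volume, paste0(base, "_baseline.nii.gz"), sp)
    .write_nifti(p@baseline_mask, paste0(base, "_baseline_mask.nii.gz"), sp)
    for (k in seq_along(p@followup_masks))
      .write_nifti(p@followup_masks[[k]],
                   sprintf("%s_followup%02d_mask.nii.gz", base, k), sp)
  }
  write.csv(cohort@clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  cfg <- cohort@config
  write.csv(data.frame(key = c("seed", "n_patients", "grid_x", "grid_y",
                               "grid_z", "spacing_x", "spacing_y",
                               "spacing_z"),
                       value = c(cfg@seed, cfg@n_patients, cfg@grid_shape,
                                 cfg@voxel_spacing)),
            file.path(dir, "config.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory back
#'
#' Rebuilds a [PhantomCohort-class] from [writeCohort()] output: baseline
#' volumes and masks, follow-up masks, measurements and outcomes from
#' `clinical.csv`. Morphology scores and trajectory classes are not stored
#' on disk and come back as NA/"unknown"; everything the prognostic
#' pipeline consumes is restored.
#'
#' @param dir directory written by [writeCohort()].
#' @return a [PhantomCohort-class].
#' @export
readCohort <- function(dir) {
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  cfgtab <- read.csv(file.path(dir, "config.csv"), stringsAsFactors = FALSE)
  val <- setNames(cfgtab$value, cfgtab$key)
  ids <- unique(clin$patient_id)
  config <- PhantomConfig(n_patients = length(ids),
                          grid_shape = val[c("grid_x", "grid_y", "grid_z")],
                          voxel_spacing = val[c("spacing_x", "spacing_y",
                                                "spacing_z")],
                          seed = val[["seed"]])
  patients <- lapply(ids, function(id) {
    rows <- clin[clin$patient_id == id, ]
    base <- file.path(dir, id)
    vol <- array(as.numeric(RNifti::readNifti(paste0(base, "_baseline.nii.gz"))),
                 config@grid_shape)
    msk <- array(as.numeric(RNifti::readNifti(paste0(base, "_baseline_mask.nii.gz"))) != 0,
                 config@grid_shape)
    fu_files <- sort(Sys.glob(paste0(base, "_followup*_mask.nii.gz")))
    fmasks <- lapply(fu_files, function(f)
      array(as.numeric(RNifti::readNifti(f)) != 0, config@grid_shape))
    new("PhantomPatient", patient_id = id,
        baseline_volume = vol, baseline_mask = msk,
        followup_masks = fmasks,
        scan_times_months = rows$scan_time_months,
        true_diameters = rows$diameter_mm,
        true_volumes = rows$volume_mm3,
        morphology_score = NA_real_, trajectory_class = "unknown",
        os_time = rows$os_time_yr[1], os_event = as.integer(rows$os_event[1]),
        dss_time = rows$dss_time_yr[1], dss_event = as.integer(rows$dss_event[1]),
        lpfs_time = rows$lpfs_time_yr[1],
        lpfs_event = as.integer(rows$lpfs_event[1]),
        two_year_os = as.integer(rows$two_year_os[1]),
        two_year_dss = as.integer(rows$two_year_dss[1]),
        two_year_lpfs = as.integer(rows$two_year_lpfs[1]))
  })
  new("PhantomCohort", patients = patients, config = config, clinical = clin)
}
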