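#' @import methods
#' @importFrom stats rnorm runif rbinom sd quantile setNames pchisq qnorm
#'   pnorm coef predict cor dist
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib desep, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# Phantom cohort classes
# ---------------------------------------------------------------------------

#' Configuration of a synthetic tumor-phantom cohort
#'
#' Describes the study conditions a synthetic SBRT lung cohort is generated
#' under: crop geometry, lesion morphology, surveillance schedule, and the
#' survival model that links planted morphology to hazard. Defaults mirror a
#' tumor-centered 96 x 96 x 48 crop with 1 mm isotropic voxels, follow-up
#' imaging at 2 months after treatment and every 3 months thereafter, and
#' event rates calibrated to the reference SBRT cohort composition shipped
#' with the package (see [referenceCohortComposition()]).
#'
#' @slot n_patients number of subjects.
#' @slot grid_shape integer 3-vector, crop size in voxels.
#' @slot voxel_spacing numeric 3-vector, mm per voxel along each axis.
#' @slot radius_range numeric 2-vector, min/max lesion semi-axis in mm.
#' @slot spiculation_strength dimensionless in [0, 1]; 0 gives exact
#'   ellipsoids.
#' @slot lesion_contrast lesion-over-background mean intensity difference.
#' @slot texture_noise_sd base intensity SD of intralesional texture.
#' @slot background_noise_sd intensity SD of background noise.
#' @slot baseline_hazard events/year for a subject with morphology score 0.
#' @slot log_hr_morphology log hazard ratio per SD of morphology score.
#' @slot censoring_rate events/year of the independent censoring process.
#' @slot cancer_death_fraction fraction of deaths flagged cancer-related
#'   (drives the disease-specific survival endpoint).
#' @slot admin_censor_years administrative end-of-study censoring time.
#' @slot followup_first_months time of the first surveillance scan.
#' @slot followup_interval_months interval between subsequent scans.
#' @slot followup_horizon_months last scheduled surveillance scan.
#' @slot trajectory_mix named proportions of responder/stable/progressor
#'   trajectory classes; must sum to 1.
#' @slot progressor_link tilt of the progressor-class probability by
#'   exp(progressor_link * z), linking morphology to local progression.
#' @slot seed integer root seed; per-patient substreams are derived by
#'   counter so patients are independent of cohort size.
#' @export
setClass("PhantomConfig", representation(
  n_patients = "integer",
  grid_shape = "integer",
  voxel_spacing = "numeric",
  radius_range = "numeric",
  spiculation_strength = "numeric",
  lesion_contrast = "numeric",
  texture_noise_sd = "numeric",
  background_noise_sd = "numeric",
  baseline_hazard = "numeric",
  log_hr_morphology = "numeric",
  censoring_rate = "numeric",
  cancer_death_fraction = "numeric",
  admin_censor_years = "numeric",
  followup_first_months = "numeric",
  followup_interval_months = "numeric",
  followup_horizon_months = "numeric",
  trajectory_mix = "numeric",
  progressor_link = "numeric",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@n_patients < 1L) msg <- c(msg, "n_patients must be >= 1")
  if (length(object@grid_shape) != 3L || any(object@grid_shape < 4L))
    msg <- c(msg, "grid_shape must be three voxel counts >= 4")
  if (length(object@voxel_spacing) != 3L || any(object@voxel_spacing <= 0))
    msg <- c(msg, "voxel_spacing must be three positive lengths (mm)")
  if (length(object@radius_range) != 2L ||
      any(object@radius_range <= 0) || diff(object@radius_range) < 0)
    msg <- c(msg, "radius_range must be increasing positive semi-axes (mm)")
  # lesion must fit inside the grid with a margin of >= 2 voxels
  half_extent <- object@grid_shape * object@voxel_spacing / 2
  margin <- 2 * object@voxel_spacing
  if (any(max(object@radius_range) > half_extent - margin))
    msg <- c(msg, "radius_range does not fit inside grid with 2-voxel margin")
  if (object@spiculation_strength < 0 || object@spiculation_strength > 1)
    msg <- c(msg, "spiculation_strength must lie in [0, 1]")
  if (abs(sum(object@trajectory_mix) - 1) > 1e-8)
    msg <- c(msg, "trajectory_mix must sum to 1")
  if (length(object@trajectory_mix) != 3L ||
      !identical(names(object@trajectory_mix),
                 c("responder", "stable", "progressor")))
    msg <- c(msg, "trajectory_mix needs proportions named responder, stable, progressor")
  for (nm in c("baseline_hazard", "censoring_rate", "admin_censor_years",
               "followup_first_months", "followup_interval_months",
               "followup_horizon_months"))
    if (slot(object, nm) <= 0) msg <- c(msg, paste(nm, "must be > 0"))
  if (object@cancer_death_fraction < 0 || object@cancer_death_fraction > 1)
    msg <- c(msg, "cancer_death_fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a phantom-cohort configuration
#'
#' @param n_patients cohort size.
#' @param grid_shape crop size in voxels (default 96 x 96 x 48).
#' @param voxel_spacing mm per voxel (default 1 x 1 x 1).
#' @param radius_range lesion semi-axis range in mm.
#' @param spiculation_strength boundary spike intensity in [0, 1].
#' @param lesion_contrast mean lesion-minus-background intensity.
#' @param texture_noise_sd base intralesional texture SD.
#' @param background_noise_sd background noise SD.
#' @param baseline_hazard,log_hr_morphology,censoring_rate survival model:
#'   event hazard is baseline_hazard * exp(log_hr_morphology * z) with
#'   independent exponential censoring.
#' @param cancer_death_fraction fraction of deaths that are cancer-related.
#' @param admin_censor_years administrative censoring horizon.
#' @param followup_first_months,followup_interval_months,followup_horizon_months
#'   surveillance schedule (first scan, interval, last scan), months.
#' @param trajectory_mix named responder/stable/progressor proportions.
#' @param progressor_link morphology tilt of the progressor probability.
#' @param seed integer root seed (mandatory for reproducibility).
#' @return a validated [PhantomConfig-class] object.
#' @examples
#' cfg <- PhantomConfig(n_patients = 4, seed = 1)
#' @export
PhantomConfig <- function(n_patients,
                          grid_shape = c(96L, 96L, 48L),
                          voxel_spacing = c(1, 1, 1),
                          radius_range = c(6, 9),
                          spiculation_strength = 0.5,
                          lesion_contrast = 1.0,
                          texture_noise_sd = 0.2,
                          background_noise_sd = 0.1,
                          baseline_hazard = 0.35,
                          log_hr_morphology = 1.5,
                          censoring_rate = 0.15,
                          cancer_death_fraction = 0.69,
                          admin_censor_years = 5,
                          followup_first_months = 2,
                          followup_interval_months = 3,
                          followup_horizon_months = 24,
                          trajectory_mix = c(responder = 0.30,
                                             stable = 0.30,
                                             progressor = 0.40),
                          progressor_link = 0.8,
                          seed) {
  if (missing(seed)) stop("seed required for reproducibility")
  new("PhantomConfig",
      n_patients = as.integer(n_patients),
      grid_shape = as.integer(grid_shape),
      voxel_spacing = as.numeric(voxel_spacing),
      radius_range = as.numeric(radius_range),
      spiculation_strength = spiculation_strength,
      lesion_contrast = lesion_contrast,
      texture_noise_sd = texture_noise_sd,
      background_noise_sd = background_noise_sd,
      baseline_hazard = baseline_hazard,
      log_hr_morphology = log_hr_morphology,
      censoring_rate = censoring_rate,
      cancer_death_fraction = cancer_death_fraction,
      admin_censor_years = admin_censor_years,
      followup_first_months = followup_first_months,
      followup_interval_months = followup_interval_months,
      followup_horizon_months = followup_horizon_months,
      trajectory_mix = trajectory_mix,
      progressor_link = progressor_link,
      seed = as.integer(seed))
}

#' A single synthetic subject
#'
#' Holds the baseline crop and ground-truth mask, serial follow-up masks,
#' exact diameter/volume measurements per scan, the planted morphology score,
#' and censored event times for the three endpoints (OS, DSS, LPFS) together
#' with two-year labels (NA when follow-up is insufficient).
#'
#' @slot patient_id character id.
#' @slot baseline_volume 3D intensity array.
#' @slot baseline_mask 3D logical array (ground truth).
#' @slot followup_masks list of 3D logical arrays, one per surveillance scan.
#' @slot scan_times_months numeric, baseline (0) plus follow-up scan times.
#' @slot true_diameters mm per scan (baseline first).
#' @slot true_volumes mm^3 per scan, voxel count x voxel volume of the mask.
#' @slot morphology_score standardized planted score z.
#' @slot trajectory_class responder/stable/progressor.
#' @slot os_time,dss_time,lpfs_time years from SBRT start.
#' @slot os_event,dss_event,lpfs_event 0/1 event indicators.
#' @slot two_year_os,two_year_dss,two_year_lpfs binary two-year event labels,
#'   NA for patients censored before 2 years without an event.
#' @export
setClass("PhantomPatient", representation(
  patient_id = "character",
  baseline_volume = "array",
  baseline_mask = "array",
  followup_masks = "list",
  scan_times_months = "numeric",
  true_diameters = "numeric",
  true_volumes = "numeric",
  morphology_score = "numeric",
  trajectory_class = "character",
  os_time = "numeric", os_event = "integer",
  dss_time = "numeric", dss_event = "integer",
  lpfs_time = "numeric", lpfs_event = "integer",
  two_year_os = "integer", two_year_dss = "integer",
  two_year_lpfs = "integer"
))

setValidity("PhantomPatient", function(object) {
  msg <- character()
  n_scan <- length(object@scan_times_months)
  if (length(object@true_diameters) != n_scan ||
      length(object@true_volumes) != n_scan)
    msg <- c(msg, "diameters/volumes must align with scan times")
  if (any(diff(object@scan_times_months) <= 0))
    msg <- c(msg, "scan times must be strictly increasing")
  if (any(c(object@os_time, object@dss_time, object@lpfs_time) <= 0))
    msg <- c(msg, "event times must be > 0")
  if (object@dss_event == 1L &&
      (object@os_event != 1L || object@dss_time != object@os_time))
    msg <- c(msg, "DSS events must be a subset of OS events at the same time")
  if (length(msg)) msg else TRUE
})

#' A synthetic cohort
#'
#' List of [PhantomPatient-class] subjects plus the generating configuration
#' and a clinical long table (one row per scan). Created by
#' [generateCohort()].
#'
#' @slot patients list of PhantomPatient objects.
#' @slot config the generating PhantomConfig.
#' @slot clinical data.frame in the package's clinical-table layout.
#' @export
setClass("PhantomCohort", representation(
  patients = "list",
  config = "PhantomConfig",
  clinical = "data.frame"
))

setMethod("show", "PhantomCohort", function(object) {
  cat("PhantomCohort with", length(object@patients), "patients\n")
  cat("  grid:", paste(object@config@grid_shape, collapse = "x"),
      " spacing:", paste(object@config@voxel_spacing, collapse = "x"), "mm\n")
  cls <- vapply(object@patients, function(p) p@trajectory_class, "")
  print(table(trajectory = cls))
  invisible(object)
})

# ---------------------------------------------------------------------------
# Segmentation network classes
# ---------------------------------------------------------------------------

#' 3D segmentation U-Net configuration
#'
#' Architecture and training hyper-parameters of the segmentation network.
#' The "full" preset is the full-scale network: 96 x 96 x 48 input, four
#' encoder blocks (3x3x3 conv + ReLU + 2x2x2 max-pool, stride 2) producing
#' 64/128/256/512 feature maps, a symmetric decoder whose deconvolutions
#' produce 512/256/128/64 and convolutions 256/128/64/32 maps, and a final
#' 1x1x1 convolution with a two-channel softmax. Its bottleneck is
#' 6 x 6 x 3 x 512 = 55296 latent features. The "desk" preset is the same
#' topology at 32 x 32 x 16 with 8/16/32/64 channels so that training runs in
#' minutes on one CPU core; its bottleneck is 2 x 2 x 1 x 64 = 256.
#'
#' @slot input_shape integer 3-vector; each axis divisible by 16.
#' @slot encoder_channels 4 conv output channel counts.
#' @slot decoder_deconv_channels 4 deconvolution output channel counts.
#' @slot decoder_conv_channels 4 decoder conv output channel counts.
#' @slot learning_rate Adam learning rate.
#' @slot batch_size minibatch size.
#' @slot epochs training epochs (no early stopping).
#' @slot normalize if TRUE, volumes are z-scored per volume before use.
#' @slot seed integer seed for weight init and batch shuffling.
#' @slot scale_preset "full" or "desk".
#' @export
setClass("UNetConfig", representation(
  input_shape = "integer",
  encoder_channels = "integer",
  decoder_deconv_channels = "integer",
  decoder_conv_channels = "integer",
  learning_rate = "numeric",
  batch_size = "integer",
  epochs = "integer",
  normalize = "logical",
  seed = "integer",
  scale_preset = "character"
))

setValidity("UNetConfig", function(object) {
  msg <- character()
  if (length(object@input_shape) != 3L || any(object@input_shape %% 16L != 0L))
    msg <- c(msg, "input_shape must be divisible by 16 on every axis (4 pooling halvings)")
  if (length(object@encoder_channels) != 4L)
    msg <- c(msg, "encoder must have 4 blocks")
  if (length(object@decoder_deconv_channels) != 4L ||
      length(object@decoder_conv_channels) != 4L)
    msg <- c(msg, "decoder must have 4 blocks")
  if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a U-Net configuration
#'
#' @param preset "desk" (default; trains in minutes on a CPU) or "full"
#'   (full-scale architecture).
#' @param input_shape,encoder_channels,decoder_deconv_channels,decoder_conv_channels
#'   overrides of the preset architecture.
#' @param learning_rate Adam learning rate. Default 1e-4 for the full-scale
#'   preset; 3e-3 for the desk preset, whose training budget is two orders
#'   of magnitude fewer optimizer steps.
#' @param batch_size minibatch size (default 4).
#' @param epochs training epochs.
#' @param normalize z-score each volume before use (default TRUE).
#' @param seed integer seed.
#' @return a validated [UNetConfig-class].
#' @examples
#' cfg <- UNetConfig("desk", seed = 1)
#' @export
UNetConfig <- function(preset = c("desk", "full"),
                       input_shape = NULL,
                       encoder_channels = NULL,
                       decoder_deconv_channels = NULL,
                       decoder_conv_channels = NULL,
                       learning_rate = NULL,
                       batch_size = 4L,
                       epochs = 30L,
                       normalize = TRUE,
                       seed) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed required for reproducibility")
  def <- if (preset == "full") {
    list(shape = c(96L, 96L, 48L), enc = c(64L, 128L, 256L, 512L),
         dec_up = c(512L, 256L, 128L, 64L), dec_conv = c(256L, 128L, 64L, 32L),
         lr = 1e-4)
  } else {
    list(shape = c(32L, 32L, 16L), enc = c(8L, 16L, 32L, 64L),
         dec_up = c(64L, 32L, 16L, 8L), dec_conv = c(32L, 16L, 8L, 4L),
         lr = 3e-3)
  }
  new("UNetConfig",
      input_shape = as.integer(input_shape %||% def$shape),
      encoder_channels = as.integer(encoder_channels %||% def$enc),
      decoder_deconv_channels = as.integer(decoder_deconv_channels %||% def$dec_up),
      decoder_conv_channels = as.integer(decoder_conv_channels %||% def$dec_conv),
      learning_rate = as.numeric(learning_rate %||% def$lr),
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      normalize = normalize,
      seed = as.integer(seed),
      scale_preset = preset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A 3D segmentation U-Net model
#'
#' Weights plus configuration and per-epoch training loss. Created by
#' [buildModel()]; trained in place by [trainModel()].
#'
#' @slot weights nested list of conv/deconv weight arrays and biases.
#' @slot config the [UNetConfig-class] used to build the model.
#' @slot training_history numeric per-epoch mean training loss.
#' @export
setClass("SegNetModel", representation(
  weights = "list",
  config = "UNetConfig",
  training_history = "numeric"
))

setMethod("show", "SegNetModel", function(object) {
  bs <- bottleneckShape(object)
  cat("SegNetModel (", object@config@scale_preset, " preset)\n", sep = "")
  cat("  input:", paste(object@config@input_shape, collapse = "x"),
      " bottleneck:", paste(bs, collapse = "x"),
      " latent length:", prod(bs), "\n")
  if (length(object@training_history))
    cat("  trained", length(object@training_history), "epochs; final loss",
        signif(tail_loss(object), 4), "\n")
  invisible(object)
})

tail_loss <- function(model)
  model@training_history[length(model@training_history)]

# ---------------------------------------------------------------------------
# Feature-reduction classes
# ---------------------------------------------------------------------------

#' Cohort x latent-feature panel
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with latent features
#' as rows and patients as columns; assay "latent" holds the bottleneck
#' activations. rowData flags zero-variance features (excluded from
#' clustering); metadata stores per-feature standardization constants once
#' [standardizePanel()] has been applied.
#'
#' @export
setClass("FeaturePanel", contains = "SummarizedExperiment")

#' Result of k-medoids clustering of latent features
#'
#' @slot k number of clusters.
#' @slot medoid_feature_ids indices (into the flattened bottleneck) of the
#'   representative features.
#' @slot assignments integer cluster of every clustered feature, named by
#'   feature id.
#' @slot mean_silhouette mean silhouette width in [-1, 1] (0 when k equals
#'   the number of features, by the singleton convention).
#' @export
setClass("MedoidSet", representation(
  k = "integer",
  medoid_feature_ids = "integer",
  assignments = "integer",
  mean_silhouette = "numeric"
))

setValidity("MedoidSet", function(object) {
  msg <- character()
  if (length(object@medoid_feature_ids) != object@k)
    msg <- c(msg, "number of medoids must equal k")
  if (!all(object@medoid_feature_ids %in% as.integer(names(object@assignments))))
    msg <- c(msg, "medoids must be members of the clustered feature set")
  if (object@mean_silhouette < -1 || object@mean_silhouette > 1)
    msg <- c(msg, "mean silhouette must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' LASSO feature-retention result
#'
#' @slot lambda selected penalty (minimum mean CV binomial deviance).
#' @slot retained_feature_ids features with nonzero coefficients at lambda.
#' @slot coefficients named coefficients of the retained features.
#' @export
setClass("LassoSelection", representation(
  lambda = "numeric",
  retained_feature_ids = "integer",
  coefficients = "numeric"
))

# ---------------------------------------------------------------------------
# Prognostication classes
# ---------------------------------------------------------------------------

#' Cross-validation plan
#'
#' Seeded, outcome-stratified split into a held-out test set and folds that
#' partition the remaining patients.
#'
#' @slot n_total total patients.
#' @slot test_ids held-out test patient ids.
#' @slot folds list of lists with train_ids and val_ids per fold.
#' @slot n_folds number of folds.
#' @slot seed integer seed.
#' @export
setClass("CVPlan", representation(
  n_total = "integer",
  test_ids = "character",
  folds = "list",
  n_folds = "integer",
  seed = "integer"
))

setValidity("CVPlan", function(object) {
  msg <- character()
  non_test <- sort(unique(unlist(lapply(object@folds,
                                        function(f) c(f$train_ids, f$val_ids)))))
  if (length(intersect(object@test_ids, non_test)))
    msg <- c(msg, "test set must be disjoint from train/validation folds")
  vals <- sort(unlist(lapply(object@folds, `[[`, "val_ids")))
  if (anyDuplicated(vals) || !identical(vals, non_test))
    msg <- c(msg, "validation folds must partition the non-test set")
  if (length(msg)) msg else TRUE
})

#' Per-patient risk prediction for one endpoint
#'
#' Plain data.frame rows (patient_id, endpoint, probability, risk_group,
#' cutoff) are used throughout; this constructor documents the dichotomy
#' rule: risk_group is "high" iff probability >= cutoff (a probability of
#' exactly 0.5 at the default cutoff is high risk).
#'
#' @param patient_id,endpoint,probability vectors of equal length.
#' @param cutoff dichotomization cutoff, default 0.5 (a 50% predicted
#'   probability of an event within 2 years).
#' @return data.frame with a risk_group factor (low/high).
#' @export
riskPrediction <- function(patient_id, endpoint, probability, cutoff = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1))
  data.frame(patient_id = as.character(patient_id),
             endpoint = endpoint,
             probability = probability,
             risk_group = factor(ifelse(probability >= cutoff, "high", "low"),
                                 levels = c("low", "high")),
             cutoff = cutoff,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Serial-measurement classes
# ---------------------------------------------------------------------------

#' Time-ordered lesion measurements for one patient
#'
#' @slot patient_id character id.
#' @slot scan_times months from SBRT start; first entry is the
#'   pre-treatment baseline.
#' @slot diameters longest lesion diameters in mm (>= 0).
#' @slot volumes lesion volumes in mm^3 (>= 0); may be empty for manual
#'   unidimensional series.
#' @slot source "manual" or "auto_segmentation".
#' @export
setClass("MeasurementSeries", representation(
  patient_id = "character",
  scan_times = "numeric",
  diameters = "numeric",
  volumes = "numeric",
  source = "character"
))

setValidity("MeasurementSeries", function(object) {
  msg <- character()
  if (any(diff(object@scan_times) <= 0))
    msg <- c(msg, "scan times must be strictly increasing")
  if (length(object@scan_times) != length(object@diameters))
    msg <- c(msg, "one diameter per scan required")
  if (any(object@diameters < 0)) msg <- c(msg, "diameters must be >= 0")
  if (length(object@volumes)) {
    if (length(object@volumes) != length(object@scan_times))
      msg <- c(msg, "one volume per scan required when volumes are present")
    if (any(object@volumes < 0)) msg <- c(msg, "volumes must be >= 0")
    if (object@source == "auto_segmentation" &&
        any((object@diameters == 0) != (object@volumes == 0)))
      msg <- c(msg, "auto-segmentation series must have diameter 0 iff volume 0")
  }
  if (!object@source %in% c("manual", "auto_segmentation"))
    msg <- c(msg, "source must be manual or auto_segmentation")
  if (length(msg)) msg else TRUE
})

#' Create a measurement series
#' @param patient_id id string.
#' @param scan_times months from SBRT start, strictly increasing, baseline
#'   first.
#' @param diameters mm, one per scan.
#' @param volumes mm^3, one per scan (optional for manual series).
#' @param source "manual" or "auto_segmentation".
#' @return a [MeasurementSeries-class].
#' @export
MeasurementSeries <- function(patient_id, scan_times, diameters,
                              volumes = numeric(), source = "manual") {
  new("MeasurementSeries", patient_id = as.character(patient_id),
      scan_times = as.numeric(scan_times), diameters = as.numeric(diameters),
      volumes = as.numeric(volumes), source = source)
}

#' RECIST v1.1 categorization parameters
#'
#' Standard unidimensional thresholds: progressive disease at a 20% or
#' greater diameter increase over the nadir with an absolute increase of at
#' least 5 mm; partial response at a 30% or greater decrease from baseline;
#' complete response on lesion disappearance. Volumetric presets carry
#' (decrease, increase) fractions: ellipsoid (-30%, +20%) and spherical
#' (-65%, +73%); no absolute floor applies to volumes.
#'
#' @param pd_rel_increase PD relative-increase threshold (default 0.20).
#' @param pd_abs_min PD absolute floor in mm (default 5).
#' @param pr_rel_decrease PR relative-decrease threshold (default 0.30).
#' @return list of parameters with a volumetric preset table.
#' @export
RecistParams <- function(pd_rel_increase = 0.20, pd_abs_min = 5,
                         pr_rel_decrease = 0.30) {
  stopifnot(pd_rel_increase > 0, pd_rel_increase < 1,
            pr_rel_decrease > 0, pr_rel_decrease < 1, pd_abs_min >= 0)
  list(pd_rel_increase = pd_rel_increase,
       pd_abs_min = pd_abs_min,
       pr_rel_decrease = pr_rel_decrease,
       volumetric_presets = list(
         ellipsoid = c(down = 0.30, up = 0.20),
         spherical = c(down = 0.65, up = 0.73)))
}

#' Response category levels, ordered worst-last
#'
#' CR < PR < SD < PD; "worst" aggregation takes the maximum under this
#' order.
#' @export
responseLevels <- c("CR", "PR", "SD", "PD")
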