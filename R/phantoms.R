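# Synthetic tumor-phantom cohorts: ellipsoidal/spiculated lesions in a
# tumor-centered crop, serial follow-up trajectories, and censored survival
# outcomes whose hazard depends on the planted morphology score.

# -- seeded substreams -------------------------------------------------------

# Per-patient L'Ecuyer-CMRG substreams derived from the root seed by
# counter, so patient i is identical regardless of cohort size.
.cohort_streams <- function(seed, n) {
  old_kind <- RNGkind("L'Ecuyer-CMRG")[1L]
  on.exit(RNGkind(old_kind), add = TRUE)
  set.seed(seed)
  s <- .Random.seed
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# Evaluate expr with the RNG positioned at `stream`; restores global state.
.with_stream <- function(stream, expr) {
  if (is.null(stream)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  assign(".Random.seed", stream, envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

# -- lesion geometry ---------------------------------------------------------

.voxel_coords_mm <- function(grid, spacing) {
  lapply(1:3, function(a)
    (seq_len(grid[a]) - (grid[a] + 1) / 2) * spacing[a])
}

# Largest radial boost the capped spike field can produce (the per-voxel
# spike sum is clipped so spiculated lesions have a guaranteed reach bound).
.SPIKE_CAP <- 1.5

.spike_bound <- function(shape, s) 1 + s * 0.35 * min(sum(shape$w), .SPIKE_CAP)

# Voxelize a (possibly spiculated) ellipsoid. `shape` carries semi-axes and
# the frozen spike field; `factor_xy`/`factor_z` rescale the in-plane and
# cranio-caudal semi-axes (trajectory scans cap z growth to stay inside the
# crop). Returns a logical array on the full grid.
.voxelize_lesion <- function(shape, config, factor_xy = 1,
                             factor_z = factor_xy) {
  grid <- config@grid_shape
  sp <- config@voxel_spacing
  semi <- shape$semi * c(factor_xy, factor_xy, factor_z)
  s <- config@spiculation_strength
  co <- .voxel_coords_mm(grid, sp)
  reach <- max(semi) * .spike_bound(shape, s) + max(sp)
  ix <- which(abs(co[[1]]) <= reach)
  iy <- which(abs(co[[2]]) <= reach)
  iz <- which(abs(co[[3]]) <= reach)
  mask <- array(FALSE, grid)
  if (!length(ix) || !length(iy) || !length(iz)) return(mask)
  ux <- co[[1]][ix] / semi[1]
  uy <- co[[2]][iy] / semi[2]
  uz <- co[[3]][iz] / semi[3]
  nb <- c(length(ix), length(iy), length(iz))
  U <- cbind(rep(ux, times = nb[2] * nb[3]),
             rep(rep(uy, each = nb[1]), times = nb[3]),
             rep(uz, each = nb[1] * nb[2]))
  rho <- sqrt(rowSums(U * U))
  thr <- rep(1, length(rho))
  if (s > 0) {
    ok <- rho > 0
    D <- (U[ok, , drop = FALSE] / rho[ok]) %*% t(shape$V)  # cosines to spikes
    D[D < 0] <- 0
    thr[ok] <- 1 + s * 0.35 * pmin(as.vector(D^8 %*% shape$w), .SPIKE_CAP)
  }
  inside <- array(rho <= thr, nb)
  mask[ix, iy, iz] <- inside
  mask
}

.check_in_bounds <- function(mask) {
  d <- dim(mask)
  shell <- mask
  shell[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- FALSE
  if (any(shell)) stop("lesion out of bounds")
  invisible(TRUE)
}

#' Generate one synthetic lesion
#'
#' Draws an ellipsoid with semi-axes from `radius_range`, centered in the
#' grid, with boundary spikes scaled by `spiculation_strength` and
#' intralesional texture whose amplitude grows with the same spiculation
#' draw. The raw morphology score is a deterministic function of the spike
#' RMS amplitude and the texture-contrast draw (zero when
#' spiculation_strength is 0); [generateCohort()] standardizes it to
#' approximately N(0, 1) across the cohort.
#'
#' @param config a [PhantomConfig-class].
#' @param stream optional RNG substream (a `.Random.seed` vector) for
#'   reproducible per-patient generation; NULL uses the current RNG state.
#' @return list with `volume` (3D intensity array), `mask` (3D logical
#'   array), `score_raw` (unstandardized morphology score), and `shape`
#'   (frozen lesion geometry reused for follow-up scans).
#' @examples
#' cfg <- PhantomConfig(n_patients = 1, grid_shape = c(32, 32, 32),
#'                      voxel_spacing = c(2, 2, 2), seed = 1)
#' set.seed(1)
#' les <- generateLesion(cfg)
#' sum(les$mask) > 0
#' @export
generateLesion <- function(config, stream = NULL) {
  .with_stream(stream, {
    validObject(config)
    semi <- runif(3, config@radius_range[1], config@radius_range[2])
    M <- 6L
    V <- matrix(rnorm(3 * M), M, 3)
    V <- V / sqrt(rowSums(V * V))
    w <- runif(M, 0.3, 1)
    eta <- runif(1)
    s <- config@spiculation_strength
    shape <- list(semi = semi, V = V, w = w, eta = eta)
    mask <- .voxelize_lesion(shape, config)
    .check_in_bounds(mask)
    score_raw <- s * (sqrt(mean(w^2)) + eta)
    tau <- config@texture_noise_sd * (1 + 2 * s * eta)
    vol <- .render_volume(mask, config, tau)
    list(volume = vol, mask = mask, score_raw = score_raw,
         shape = c(shape, list(tau = tau)))
  })
}

# Intensity model: background Gaussian noise; lesion adds a constant
# contrast plus blocky low-frequency texture and fine-grain noise, both
# scaled by the per-patient texture amplitude tau.
.render_volume <- function(mask, config, tau) {
  grid <- config@grid_shape
  vol <- array(rnorm(prod(grid), 0, config@background_noise_sd), grid)
  n_in <- sum(mask)
  if (n_in > 0) {
    cg <- pmax(1L, grid %/% 4L)
    coarse <- array(rnorm(prod(cg)), cg)
    up <- coarse[ceiling(seq_len(grid[1]) / grid[1] * cg[1]),
                 ceiling(seq_len(grid[2]) / grid[2] * cg[2]),
                 ceiling(seq_len(grid[3]) / grid[3] * cg[3]), drop = FALSE]
    vol[mask] <- config@lesion_contrast +
      tau * (0.7 * up[mask] + 0.7 * rnorm(n_in))
  }
  vol
}

# -- trajectories ------------------------------------------------------------

# Scale factor below which a responder lesion is recorded as disappeared
# (sub-resolution remnants are not representable on the voxel grid).
.VANISH_FACTOR <- 0.25

.followup_times <- function(config) {
  seq(config@followup_first_months, config@followup_horizon_months,
      by = config@followup_interval_months)
}

# Draw trajectory parameters for all three classes (fixed stream length).
.draw_trajectory_params <- function(config) {
  n_scan <- length(.followup_times(config))
  list(responder_shrink = runif(1, 0.4, 0.8),
       stable_wiggle = runif(n_scan, 0.92, 1.08),
       progressor_end = runif(1, 1.8, 2.0),
       u_class = runif(1))
}

.trajectory_factors <- function(class, params, times_months, horizon) {
  ty <- times_months / 12
  switch(class,
         responder = {
           f <- (1 - params$responder_shrink)^ty
           ifelse(f < .VANISH_FACTOR, 0, f)
         },
         stable = params$stable_wiggle,
         progressor = params$progressor_end^(times_months / horizon),
         stop("unknown trajectory class: ", class))
}

#' Simulate serial follow-up scans for one lesion
#'
#' Rescales the frozen lesion shape by a trajectory-class-specific factor at
#' each surveillance scan (responders shrink monotonically and may disappear
#' entirely; stable lesions stay within +/-8% of baseline; progressors grow
#' monotonically far past the 20%/5 mm progression threshold) and records
#' the exact diameter and mask-derived volume at every scan.
#'
#' @param lesion result of [generateLesion()].
#' @param config the generating [PhantomConfig-class].
#' @param class trajectory class: "responder", "stable" or "progressor".
#' @param params trajectory parameter draws (internal; defaults drawn from
#'   the current RNG when NULL).
#' @return list with `masks` (per-scan logical arrays), `times_months`,
#'   `diameters` (mm, analytic caliper measurement of the lesion body; 0
#'   when the mask is empty), `volumes` (mm^3, voxel count x voxel volume),
#'   and `factors`.
#' @export
simulateTrajectory <- function(lesion, config, class, params = NULL) {
  if (is.null(params)) params <- .draw_trajectory_params(config)
  times <- .followup_times(config)
  factors <- .trajectory_factors(class, params, times,
                                 config@followup_horizon_months)
  voxvol <- prod(config@voxel_spacing)
  d0 <- 2 * max(lesion$shape$semi[1:2])
  # cranio-caudal growth is capped so the grown lesion (including its
  # bounded spike reach) stays inside the crop with a 2.5-voxel margin;
  # RECIST diameters are in-plane and unaffected
  half_z <- config@grid_shape[3] * config@voxel_spacing[3] / 2
  z_cap <- (half_z - 2.5 * config@voxel_spacing[3]) /
    (lesion$shape$semi[3] *
       .spike_bound(lesion$shape, config@spiculation_strength))
  masks <- vector("list", length(times))
  diam <- vol <- numeric(length(times))
  for (k in seq_along(times)) {
    if (factors[k] <= 0) {
      masks[[k]] <- array(FALSE, config@grid_shape)
    } else {
      masks[[k]] <- .voxelize_lesion(lesion$shape, config, factors[k],
                                     min(factors[k], z_cap))
      .check_in_bounds(masks[[k]])
    }
    vol[k] <- sum(masks[[k]]) * voxvol
    diam[k] <- if (vol[k] == 0) 0 else d0 * factors[k]
  }
  list(masks = masks, times_months = times, diameters = diam,
       volumes = vol, factors = factors)
}

# -- survival ----------------------------------------------------------------

#' Simulate censored survival outcomes from morphology scores
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr_morphology * z)`; censoring is an
#' independent exponential at `censoring_rate` plus administrative
#' censoring at `admin_censor_years`. A fraction
#' `cancer_death_fraction` of deaths is flagged cancer-related and drives
#' the disease-specific endpoint (non-cancer deaths are censored for DSS).
#' Local progression-free survival takes the earlier of a supplied
#' progression time and death.
#'
#' @param morphology_scores standardized scores z.
#' @param config a [PhantomConfig-class].
#' @param progression_times optional per-patient progression times in years
#'   (Inf for none); default none.
#' @param uniforms optional list of pre-drawn uniforms (u_death, u_censor,
#'   u_cancer), used by [generateCohort()] to keep per-patient streams
#'   intact; drawn from the current RNG when NULL.
#' @return data.frame with os/dss/lpfs times (years), event indicators, and
#'   two-year labels (NA when censored before 2 years without an event).
#' @examples
#' cfg <- PhantomConfig(n_patients = 3, seed = 1)
#' set.seed(1)
#' simulateSurvival(c(-1, 0, 1), cfg)
#' @export
simulateSurvival <- function(morphology_scores, config,
                             progression_times = NULL, uniforms = NULL) {
  n <- length(morphology_scores)
  if (is.null(progression_times)) progression_times <- rep(Inf, n)
  if (is.null(uniforms))
    uniforms <- list(u_death = runif(n), u_censor = runif(n),
                     u_cancer = runif(n))
  h <- config@baseline_hazard * exp(config@log_hr_morphology * morphology_scores)
  T_death <- -log(uniforms$u_death) / h
  C <- pmin(-log(uniforms$u_censor) / config@censoring_rate,
            config@admin_censor_years)
  os_time <- pmin(T_death, C)
  os_event <- as.integer(T_death <= C)
  cancer <- uniforms$u_cancer < config@cancer_death_fraction
  dss_event <- as.integer(os_event == 1L & cancer)
  dss_time <- os_time
  P <- progression_times
  lpfs_time <- pmin(P, T_death, C)
  lpfs_event <- as.integer(pmin(P, T_death) <= C)
  data.frame(os_time = os_time, os_event = os_event,
             dss_time = dss_time, dss_event = dss_event,
             lpfs_time = lpfs_time, lpfs_event = lpfs_event,
             two_year_os = .two_year_label(os_time, os_event),
             two_year_dss = .two_year_label(dss_time, dss_event),
             two_year_lpfs = .two_year_label(lpfs_time, lpfs_event))
}

# Event within 2 years -> 1; observed event-free past 2 years -> 0;
# censored before 2 years without an event -> NA (insufficient follow-up).
.two_year_label <- function(time, event) {
  ifelse(event == 1L & time <= 2, 1L, ifelse(time > 2, 0L, NA_integer_))
}

# -- cohort ------------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Two-pass generation: per-patient substreams first produce lesions,
#' trajectory parameter draws and survival uniforms; the raw morphology
#' scores are then standardized across the cohort, the trajectory class is
#' drawn from `trajectory_mix` tilted toward progression by
#' `exp(progressor_link * z)`, follow-up masks and measurements are
#' rendered, and survival outcomes are transformed from the pre-drawn
#' uniforms. Identical configuration (including seed) yields a bit-identical
#' cohort.
#'
#' @param config a [PhantomConfig-class].
#' @return a [PhantomCohort-class].
#' @examples
#' cohort <- generateCohort(PhantomConfig(
#'   n_patients = 3, grid_shape = c(32, 32, 16),
#'   voxel_spacing = c(2, 2, 3), seed = 7))
#' clinicalTable(cohort)[1:3, 1:4]
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@n_patients
  streams <- .cohort_streams(config@seed, n)
  base <- vector("list", n)
  for (i in seq_len(n)) {
    base[[i]] <- .with_stream(streams[[i]], {
      lesion <- generateLesion(config)
      params <- .draw_trajectory_params(config)
      unis <- list(u_death = runif(1), u_censor = runif(1),
                   u_cancer = runif(1))
      list(lesion = lesion, params = params, unis = unis)
    })
  }
  raw <- vapply(base, function(b) b$lesion$score_raw, 0)
  z <- if (n > 1 && sd(raw) > 0) as.numeric(scale(raw)) else rep(0, n)

  mix <- config@trajectory_mix
  classes <- vapply(seq_len(n), function(i) {
    p <- mix
    p["progressor"] <- p["progressor"] * exp(config@progressor_link * z[i])
    p <- p / sum(p)
    names(mix)[findInterval(base[[i]]$params$u_class, cumsum(p),
                            rightmost.closed = TRUE) + 1L]
  }, "")

  trajs <- lapply(seq_len(n), function(i)
    simulateTrajectory(base[[i]]$lesion, config, classes[i],
                       base[[i]]$params))
  prog_times <- vapply(seq_len(n), function(i) {
    if (classes[i] != "progressor") return(Inf)
    .first_pd_time(c(0, trajs[[i]]$times_months) / 12,
                   c(2 * max(base[[i]]$lesion$shape$semi[1:2]),
                     trajs[[i]]$diameters))
  }, 0)
  surv <- simulateSurvival(z, config, prog_times,
                           uniforms = list(
                             u_death = vapply(base, function(b) b$unis$u_death, 0),
                             u_censor = vapply(base, function(b) b$unis$u_censor, 0),
                             u_cancer = vapply(base, function(b) b$unis$u_cancer, 0)))

  voxvol <- prod(config@voxel_spacing)
  patients <- vector("list", n)
  clin <- vector("list", n)
  for (i in seq_len(n)) {
    les <- base[[i]]$lesion
    tr <- trajs[[i]]
    id <- sprintf("P%03d", i)
    d0 <- 2 * max(les$shape$semi[1:2])
    diam <- c(d0, tr$diameters)
    vols <- c(sum(les$mask) * voxvol, tr$volumes)
    patients[[i]] <- new("PhantomPatient",
      patient_id = id,
      baseline_volume = les$volume,
      baseline_mask = les$mask,
      followup_masks = tr$masks,
      scan_times_months = c(0, tr$times_months),
      true_diameters = diam,
      true_volumes = vols,
      morphology_score = z[i],
      trajectory_class = classes[i],
      os_time = surv$os_time[i], os_event = surv$os_event[i],
      dss_time = surv$dss_time[i], dss_event = surv$dss_event[i],
      lpfs_time = surv$lpfs_time[i], lpfs_event = surv$lpfs_event[i],
      two_year_os = surv$two_year_os[i],
      two_year_dss = surv$two_year_dss[i],
      two_year_lpfs = surv$two_year_lpfs[i])
    clin[[i]] <- data.frame(
      patient_id = id,
      scan_time_months = c(0, tr$times_months),
      diameter_mm = diam,
      volume_mm3 = vols,
      os_time_yr = surv$os_time[i], os_event = surv$os_event[i],
      dss_time_yr = surv$dss_time[i], dss_event = surv$dss_event[i],
      lpfs_time_yr = surv$lpfs_time[i], lpfs_event = surv$lpfs_event[i],
      two_year_os = surv$two_year_os[i],
      two_year_dss = surv$two_year_dss[i],
      two_year_lpfs = surv$two_year_lpfs[i])
  }
  new("PhantomCohort", patients = patients, config = config,
      clinical = do.call(rbind, clin))
}

# First time (years) at which the standard unidimensional PD rule fires on
# an exact diameter series (baseline first); Inf if never.
.first_pd_time <- function(times_yr, diameters) {
  for (k in 2:length(diameters)) {
    nadir <- min(diameters[1:(k - 1)])
    if (diameters[k] >= 1.2 * nadir - 1e-9 &&
        diameters[k] - nadir >= 5 - 1e-9)
      return(times_yr[k])
  }
  Inf
}

#' Manual measurement series of a phantom patient
#'
#' The generator's exact per-scan diameters and volumes, i.e. what a
#' perfectly reliable reader would record.
#'
#' @param patient a [PhantomPatient-class].
#' @return a [MeasurementSeries-class] with source "manual".
#' @export
measurementSeries <- function(patient) {
  MeasurementSeries(patient@patient_id, patient@scan_times_months,
                    patient@true_diameters, patient@true_volumes,
                    source = "manual")
}

#' Auto-segmentation measurement series of a phantom patient
#'
#' Diameters are re-measured from the (here: ground-truth) masks with
#' [longestAxialDiameter()]; volumes are voxel count x voxel volume.
#' Substitute predicted masks to emulate computer-based serial measurement.
#'
#' @param patient a [PhantomPatient-class].
#' @param masks optional list of per-scan masks (baseline first); defaults
#'   to the patient's ground-truth masks.
#' @param spacing voxel spacing in mm; defaults to cube root of volume per
#'   voxel implied by the patient's stored volumes.
#' @return a [MeasurementSeries-class] with source "auto_segmentation".
#' @export
autoMeasurementSeries <- function(patient, masks = NULL, spacing) {
  if (is.null(masks))
    masks <- c(list(patient@baseline_mask), patient@followup_masks)
  voxvol <- prod(spacing)
  diam <- vapply(masks, longestAxialDiameter, 0, spacing = spacing)
  vols <- vapply(masks, function(m) sum(m) * voxvol, 0)
  MeasurementSeries(patient@patient_id, patient@scan_times_months,
                    diam, vols, source = "auto_segmentation")
}

#' Reference cohort composition table
#'
#' Counts (over n = 108) of the institutional SBRT NSCLC cohort composition
#' that the phantom generator's default rates are calibrated against:
#' survival status, cause of death, local progression, two-year endpoint
#' labels (including insufficient follow-up), prior treatment, stage,
#' performance score and histology. The recorded percentages are recomputed
#' from the counts.
#'
#' @return data.frame with section, category, count, total, percent
#'   (recorded) and percent_recomputed (count / total, half-up rounded to
#'   one decimal).
#' @examples
#' head(referenceCohortComposition())
#' @export
referenceCohortComposition <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "desep", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$percent_recomputed <- floor(1000 * tab$count / tab$total + 0.5) / 10
  tab
}
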