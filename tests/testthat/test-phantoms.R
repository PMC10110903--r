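# Phantom generator: geometry oracles, determinism, trajectory classes,
# survival model calibration, and cohort invariants.

test_that("unspiculated sphere voxelizes to the analytic volume", {
  cfg <- PhantomConfig(n_patients = 1, radius_range = c(10, 10),
                       spiculation_strength = 0, seed = 1)
  set.seed(1)
  les <- generateLesion(cfg)
  expect_lt(abs(sum(les$mask) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3),
            0.05)
  # morphology raw score is zero (cohort minimum) without spiculation
  expect_equal(les$score_raw, 0)
  # exact discrete ellipsoid: mask = {rho <= 1}
  co <- desep:::.voxel_coords_mm(cfg@grid_shape, cfg@voxel_spacing)
  rho2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+") / 100
  expect_identical(les$mask, rho2 <= 1)
})

test_that("lesion generation is bit-identical under a fixed stream", {
  cfg <- desk_phantom_config(n = 1, seed = 5)
  set.seed(99); l1 <- generateLesion(cfg)
  set.seed(99); l2 <- generateLesion(cfg)
  expect_identical(l1, l2)
})

test_that("oversized lesions are rejected", {
  expect_error(PhantomConfig(n_patients = 1, grid_shape = c(16, 16, 16),
                             radius_range = c(10, 14), seed = 1),
               "does not fit")
  # runtime shell check for masks touching the boundary
  m <- array(TRUE, c(8, 8, 8))
  expect_error(desep:::.check_in_bounds(m), "out of bounds")
})

test_that("cohorts are deterministic and patients independent of size", {
  cfg <- desk_phantom_config(n = 4, seed = 21)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(c1@clinical, c2@clinical)
  expect_identical(c1@patients[[3]]@baseline_volume,
                   c2@patients[[3]]@baseline_volume)
  # growing the cohort leaves earlier patients' raw draws untouched
  # (standardized scores and class draws are cohort-level by definition)
  c3 <- generateCohort(desk_phantom_config(n = 6, seed = 21))
  expect_identical(c1@patients[[2]]@baseline_volume,
                   c3@patients[[2]]@baseline_volume)
  expect_identical(c1@patients[[4]]@baseline_mask,
                   c3@patients[[4]]@baseline_mask)
})

test_that("cohort generation stays in bounds across seeds", {
  # progressor growth (including spike reach) must fit the crop for any
  # draw; z-axis growth is capped, in-plane growth is bounded by design
  for (s in 1:6)
    expect_no_error(generateCohort(desk_phantom_config(n = 6, seed = s)))
  expect_no_error(generateCohort(PhantomConfig(n_patients = 4, seed = 3)))
})

test_that("volume conservation holds for every scan of every patient", {
  cohort <- generateCohort(desk_phantom_config(n = 5, seed = 13))
  voxvol <- prod(cohort@config@voxel_spacing)
  for (p in cohort@patients) {
    expect_equal(p@true_volumes[1], sum(p@baseline_mask) * voxvol)
    for (k in seq_along(p@followup_masks))
      expect_equal(p@true_volumes[k + 1],
                   sum(p@followup_masks[[k]]) * voxvol)
  }
})

test_that("trajectory classes behave as constructed", {
  cohort <- generateCohort(desk_phantom_config(n = 30, seed = 17))
  params <- RecistParams()
  for (p in cohort@patients) {
    d0 <- p@true_diameters[1]
    fu <- p@true_diameters[-1]
    if (p@trajectory_class == "stable") {
      expect_true(all(abs(fu / d0 - 1) <= 0.10))
    } else if (p@trajectory_class == "responder") {
      nz <- fu[fu > 0]
      expect_true(all(diff(c(d0, nz)) < 0))  # monotone shrink while visible
      if (any(fu == 0))  # disappearance is permanent and zero-volume
        expect_true(all(p@true_volumes[-1][fu == 0] == 0))
    } else {
      # progressor meets the PD rule: >= +20% over nadir and >= +5 mm
      nadir <- cummin(c(d0, fu))[-1]
      expect_true(any(fu >= 1.2 * nadir & fu - nadir >= 5))
      expect_true(all(diff(fu) > 0))
    }
  }
})

test_that("responder reaching zero voxels records 0 mm and 0 mm^3", {
  cohort <- generateCohort(desk_phantom_config(n = 40, seed = 29))
  vanished <- FALSE
  for (p in cohort@patients) {
    zero <- p@true_volumes == 0
    expect_equal(p@true_diameters[zero], rep(0, sum(zero)))
    if (p@trajectory_class == "responder" && any(zero)) vanished <- TRUE
  }
  expect_true(vanished)  # the mix produces at least one complete response
})

test_that("exponential survival model matches its analytic mean", {
  cfg <- PhantomConfig(n_patients = 1, baseline_hazard = 0.35,
                       log_hr_morphology = 0, censoring_rate = 1e-9,
                       admin_censor_years = 1e9, seed = 1)
  set.seed(2)
  s <- simulateSurvival(rnorm(2000), cfg)
  expect_equal(mean(s$os_time[s$os_event == 1]), 1 / 0.35,
               tolerance = 0.05)
  expect_gt(mean(s$os_event), 0.999)
})

test_that("planted morphology signal reaches the survival outcomes", {
  cfg_sig <- PhantomConfig(n_patients = 1, log_hr_morphology = 1.5, seed = 1)
  cfg_null <- PhantomConfig(n_patients = 1, log_hr_morphology = 0, seed = 1)
  set.seed(31)
  z <- rnorm(400)
  s_sig <- simulateSurvival(z, cfg_sig)
  s_null <- simulateSurvival(z, cfg_null)
  unc <- s_sig$os_event == 1
  expect_lt(cor(z[unc], s_sig$os_time[unc], method = "spearman"), -0.3)
  unc0 <- s_null$os_event == 1
  expect_lt(abs(cor(z[unc0], s_null$os_time[unc0], method = "spearman")),
            0.15)
  # Cox recovers a positive log-HR for top-vs-bottom halves in >= 95% of
  # seeded replicates at beta = 1.5
  hits <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    zz <- rnorm(200)
    ss <- simulateSurvival(zz, cfg_sig)
    grp <- as.integer(zz > median(zz))
    fit <- tryCatch(suppressWarnings(
      coxHRBinary(ss$os_time, ss$os_event, grp)), error = function(e) NULL)
    if (!is.null(fit) && fit$hr > 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("DSS events are a subset of OS events and labels are consistent", {
  cohort <- generateCohort(desk_phantom_config(n = 25, seed = 37))
  cl <- cohortOutcomes(cohort)
  expect_true(all(cl$os_event[cl$dss_event == 1] == 1))
  expect_true(all(cl$dss_time[cl$dss_event == 1] ==
                    cl$os_time[cl$dss_event == 1]))
  # censored before 2 years without event -> missing two-year label
  short <- cl$os_time <= 2 & cl$os_event == 0
  expect_true(all(is.na(cl$two_year_os[short])))
  expect_true(all(!is.na(cl$two_year_os[!short])))
  expect_true(all(cl$two_year_os[cl$os_event == 1 & cl$os_time <= 2] == 1,
                  na.rm = TRUE))
  # LPFS events are at least as frequent as OS events (progression or death)
  expect_gte(sum(cl$lpfs_event), sum(cl$os_event))
  expect_true(all(cl$lpfs_time <= cl$os_time + 1e-12))
})

test_that("morphology scores are standardized across the cohort", {
  cohort <- generateCohort(desk_phantom_config(n = 50, seed = 41))
  z <- vapply(cohort@patients, function(p) p@morphology_score, 0)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("auto and manual measurement series agree on the PD dichotomy", {
  cohort <- generateCohort(PhantomConfig(n_patients = 12, seed = 43))
  sp <- cohort@config@voxel_spacing
  for (p in cohort@patients) {
    man <- dichotomizeResponse(worstCategory(
      categorizeUnidimensional(measurementSeries(p))))
    auto <- dichotomizeResponse(worstCategory(
      categorizeUnidimensional(autoMeasurementSeries(p, spacing = sp))))
    expect_equal(as.character(man), as.character(auto),
                 info = p@patient_id)
  }
})

test_that("reference cohort percentages recompute from their counts", {
  tab <- referenceCohortComposition()
  expect_equal(tab$percent_recomputed, tab$percent)
  expect_true(all(tab$total == 108))
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  cohort <- generateCohort(desk_phantom_config(n = 3, seed = 47))
  dir <- tempfile("cohort")
  writeCohort(cohort, dir)
  back <- readCohort(dir)
  expect_equal(length(back@patients), 3)
  p0 <- cohort@patients[[2]]; p1 <- back@patients[[2]]
  expect_equal(p1@baseline_volume, p0@baseline_volume, tolerance = 1e-6)
  expect_identical(p1@baseline_mask, p0@baseline_mask)
  expect_identical(p1@followup_masks, p0@followup_masks)
  expect_equal(p1@true_volumes, p0@true_volumes)
  expect_equal(back@clinical$os_time_yr, cohort@clinical$os_time_yr)
  # header spacing survives the round trip
  img <- RNifti::readNifti(file.path(dir, "P002_baseline.nii.gz"))
  expect_equal(RNifti::pixdim(img), c(2, 2, 3))
  unlink(dir, recursive = TRUE)
})
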