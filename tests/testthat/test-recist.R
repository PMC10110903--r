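# RECIST v1.1 engines: boundary cases of the written rules, an exhaustive
# decision-table sweep, monotonicity, aggregation and mask measurement.

test_that("unidimensional boundary cases follow the written rules", {
  cat1 <- function(d) as.character(
    categorizeUnidimensional(MeasurementSeries("P", c(0, 2), c(d[1], d[2]))))
  expect_equal(cat1(c(30, 21)), "PR")     # exactly -30% from baseline
  expect_equal(cat1(c(10, 12.5)), "SD")   # +25% but only +2.5 mm < 5 mm floor
  expect_equal(cat1(c(20, 25)), "PD")     # +25% and +5 mm
  expect_equal(cat1(c(20, 0)), "CR")      # disappearance
  expect_equal(cat1(c(20, 24)), "SD")     # +20% but +4 mm
  expect_equal(cat1(c(30, 36)), "PD")     # exactly +20% and +6 mm
  expect_equal(cat1(c(30, 21.1)), "SD")   # just above -30%
})

test_that("PD is judged against the nadir including prior minima", {
  # shrink to nadir 10 then regrow: PD referenced to 10, not baseline 30
  s <- MeasurementSeries("P", c(0, 2, 5, 8), c(30, 10, 15, 16))
  cats <- as.character(categorizeUnidimensional(s))
  expect_equal(cats, c("PR", "PD", "PD"))
  # without the regrowth the lesion stays below -30% of baseline: still PR
  s2 <- MeasurementSeries("P", c(0, 2, 5), c(30, 10, 11))
  expect_equal(as.character(categorizeUnidimensional(s2))[2], "PR")
})

test_that("exhaustive decision grid reproduces the rule table", {
  params <- RecistParams()
  baseline <- 40
  # follow-up 1 establishes a nadir below baseline; follow-up 2 sweeps a
  # grid of relative changes vs that nadir
  for (nadir in c(40, 25, 12)) {
    for (rel in seq(-1, 1.2, by = 0.05)) {
      d2 <- nadir * (1 + rel)
      if (d2 < 0) next
      series <- if (nadir == baseline)
        MeasurementSeries("P", c(0, 2), c(baseline, d2))
      else MeasurementSeries("P", c(0, 2, 5), c(baseline, nadir, d2))
      got <- as.character(tail(categorizeUnidimensional(series, params), 1))
      expected <-
        if (d2 <= 0) "CR"
        else if (rel >= 0.20 - 1e-12 && d2 - nadir >= 5 - 1e-9) "PD"
        else if (d2 <= baseline * 0.7 + 1e-9) "PR"
        else "SD"
      expect_equal(got, expected,
                   info = sprintf("nadir %g rel %g", nadir, rel))
    }
  }
  # every category is reachable
  expect_setequal(
    unique(c(
      as.character(categorizeUnidimensional(
        MeasurementSeries("P", c(0, 2, 5, 8, 11), c(30, 40, 20, 0, 0))))),
      c("PD", "PR", "CR")),
    c("PD", "PR", "CR"))
})

test_that("category never improves as a follow-up diameter grows", {
  rank_of <- function(d) {
    s <- MeasurementSeries("P", c(0, 2, 5), c(30, 20, d))
    match(as.character(tail(categorizeUnidimensional(s), 1)), responseLevels)
  }
  ranks <- vapply(seq(0.1, 40, by = 0.1), rank_of, 0)
  expect_true(all(diff(ranks) >= 0))
})

test_that("volumetric presets apply their thresholds with no absolute floor", {
  vs <- function(vols, preset)
    as.character(categorizeVolumetric(
      MeasurementSeries("P", seq(0, by = 3, length.out = length(vols)),
                        rep(10, length(vols)), vols), preset = preset))
  expect_equal(vs(c(1000, 700), "ellipsoid"), "PR")     # exactly -30%
  expect_equal(vs(c(1000, 1200), "ellipsoid"), "PD")    # exactly +20%
  expect_equal(vs(c(1000, 1200), "spherical"), "SD")    # below +73%
  expect_equal(vs(c(1000, 1731), "spherical"), "PD")    # above +73%
  expect_equal(vs(c(1000, 349), "spherical"), "PR")     # below -65%
  expect_equal(vs(c(1000, 500), "spherical"), "SD")
  # tiny absolute volume increases still trigger PD (no 5 mm analogue)
  expect_equal(vs(c(10, 12.1), "ellipsoid"), "PD")
})

test_that("worst-category aggregation and dichotomization", {
  expect_equal(as.character(worstCategory(c("PR", "SD", "PD", "PR"))), "PD")
  expect_equal(as.character(worstCategory(c("CR", "CR"))), "CR")
  expect_equal(as.character(worstCategory(c("PR", "SD"))), "SD")
  expect_error(worstCategory(character()), "no follow-up")
  expect_equal(as.character(dichotomizeResponse("PD")), "PD")
  expect_equal(as.character(dichotomizeResponse("CR")), "non-PD")
  expect_equal(as.character(dichotomizeResponse("SD")), "non-PD")
})

test_that("series validity and degenerate baselines are rejected", {
  expect_error(MeasurementSeries("P", c(0, 2, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(categorizeUnidimensional(
    MeasurementSeries("P", c(0, 2), c(0, 5))), "no measurable baseline")
  expect_error(categorizeVolumetric(
    MeasurementSeries("P", c(0, 2), c(10, 10))), "no volumes")
})

test_that("longest axial diameter matches endpoints and brute force", {
  m <- array(0, c(40, 8, 4)); m[5:35, 4, 2] <- 1  # 31 voxels in a row
  expect_equal(longestAxialDiameter(m, c(1, 1, 1)), 30)
  expect_equal(longestAxialDiameter(array(0, c(4, 4, 4))), 0)
  m1 <- array(0, c(4, 4, 4)); m1[2, 2, 2] <- 1
  expect_equal(longestAxialDiameter(m1), 0)
  # spacing scales in-plane distances only
  expect_equal(longestAxialDiameter(m, c(2, 1, 1)), 60)

  # random blobs vs O(n^2) slice-wise oracle
  set.seed(8)
  for (r in 1:3) {
    blob <- array(runif(16 * 16 * 4) < 0.1, c(16, 16, 4))
    sp <- c(1.5, 0.8, 2)
    oracle <- 0
    for (z in 1:4) {
      ix <- which(blob[, , z], arr.ind = TRUE)
      if (nrow(ix) < 2) next
      for (i in 1:(nrow(ix) - 1)) for (j in (i + 1):nrow(ix)) {
        d <- sqrt(sum(((ix[i, ] - ix[j, ]) * sp[1:2])^2))
        oracle <- max(oracle, d)
      }
    }
    expect_equal(longestAxialDiameter(blob, sp), oracle)
  }
})

test_that("ellipsoid-model volume estimate is the pi/6 formula", {
  expect_equal(ellipsoidVolumeEstimate(10), pi / 6 * 1000)
  expect_equal(ellipsoidVolumeEstimate(10, 20, 30), pi / 6 * 6000)
})
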