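# RECIST v1.1 response categorization of serial lesion measurements.
#
# Rules (single treated target lesion):
#   CR  lesion disappearance (measurement 0), checked first;
#   PD  >= 20% increase over the nadir (smallest of all previous
#       measurements, baseline included) AND an absolute increase of at
#       least 5 mm (unidimensional only);
#   PR  >= 30% decrease from the pre-treatment baseline;
#   SD  anything that meets none of the above.
# Precedence CR > PD > PR > SD; the final per-patient category is the worst
# category over all follow-up scans (CR < PR < SD < PD).

.EPS <- 1e-9

.categorize_series <- function(values, up_rel, down_rel, abs_min) {
  baseline <- values[1]
  if (baseline <= 0) stop("no measurable baseline lesion")
  n <- length(values)
  if (n < 2) stop("at least one follow-up measurement required")
  out <- character(n - 1)
  for (k in 2:n) {
    v <- values[k]
    nadir <- min(values[1:(k - 1)])
    out[k - 1] <-
      if (v <= 0) "CR"
      else if (v >= nadir * (1 + up_rel) - .EPS &&
               v - nadir >= abs_min - .EPS) "PD"
      else if (v <= baseline * (1 - down_rel) + .EPS) "PR"
      else "SD"
  }
  factor(out, levels = responseLevels, ordered = TRUE)
}

#' Unidimensional RECIST v1.1 categorization
#'
#' Categorizes every follow-up scan of a diameter series against the
#' standard thresholds: complete response on disappearance, progressive
#' disease at a 20% or greater increase over the nadir with a minimum
#' absolute increase of 5 mm, partial response at a 30% or greater decrease
#' from baseline, stable disease otherwise.
#'
#' @param series a [MeasurementSeries-class]; the first entry is the
#'   pre-treatment baseline.
#' @param params a [RecistParams()] list.
#' @return ordered factor of per-follow-up categories (CR < PR < SD < PD).
#' @examples
#' s <- MeasurementSeries("P1", c(0, 2, 5), c(30, 21, 36))
#' categorizeUnidimensional(s)  # PR then PD
#' @export
categorizeUnidimensional <- function(series, params = RecistParams()) {
  validObject(series)
  .categorize_series(series@diameters, params$pd_rel_increase,
                     params$pr_rel_decrease, params$pd_abs_min)
}

#' Volumetric RECIST categorization
#'
#' Same precedence structure applied to lesion volumes with
#' preset-specific thresholds and no absolute floor: the ellipsoid preset
#' uses -30% / +20%, the spherical preset -65% / +73%.
#'
#' @param series a [MeasurementSeries-class] carrying volumes.
#' @param params a [RecistParams()] list.
#' @param preset "ellipsoid" or "spherical".
#' @return ordered factor of per-follow-up categories.
#' @export
categorizeVolumetric <- function(series, params = RecistParams(),
                                 preset = c("ellipsoid", "spherical")) {
  validObject(series)
  preset <- match.arg(preset)
  if (!length(series@volumes)) stop("series carries no volumes")
  thr <- params$volumetric_presets[[preset]]
  .categorize_series(series@volumes, thr[["up"]], thr[["down"]], 0)
}

#' Worst response category
#'
#' The final per-patient categorization: the maximum category over all
#' follow-up scans under the order CR < PR < SD < PD.
#'
#' @param categories ordered factor (or character) of per-scan categories.
#' @return single ordered factor level.
#' @examples
#' worstCategory(c("PR", "SD", "PD", "PR"))  # PD
#' @export
worstCategory <- function(categories) {
  if (!length(categories)) stop("no follow-up categories")
  f <- factor(as.character(categories), levels = responseLevels,
              ordered = TRUE)
  if (anyNA(f)) stop("unknown response category")
  max(f)
}

#' Dichotomize a final response category
#'
#' Progression of disease versus any other category indicating
#' non-progressive disease.
#'
#' @param final a response category.
#' @return factor with levels "non-PD", "PD".
#' @export
dichotomizeResponse <- function(final) {
  f <- factor(as.character(final), levels = responseLevels)
  if (anyNA(f)) stop("unknown response category")
  factor(ifelse(f == "PD", "PD", "non-PD"), levels = c("non-PD", "PD"))
}

#' Ellipsoid-model volume estimate
#'
#' Optional input transform for volumetric categorization when only caliper
#' diameters are available: the lesion is modelled as an ellipsoid,
#' V = (pi / 6) d1 d2 d3; with a single diameter the model degenerates to a
#' sphere, V = (pi / 6) d^3.
#'
#' @param d1 largest diameter in mm.
#' @param d2,d3 optional orthogonal diameters; default `d1`.
#' @return volume in mm^3.
#' @export
ellipsoidVolumeEstimate <- function(d1, d2 = d1, d3 = d1) {
  stopifnot(all(d1 >= 0), all(d2 >= 0), all(d3 >= 0))
  pi / 6 * d1 * d2 * d3
}
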