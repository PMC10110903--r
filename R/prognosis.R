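# Final prognostication stage: cross-validation planning, unpenalized
# logistic prognosticators on the LASSO-retained medoid features,
# dichotomization of predicted two-year event probabilities at 50%, and the
# end-to-end pipeline runner.

#' Build a cross-validation plan
#'
#' Reserves a seeded, outcome-stratified test set (touched once, at final
#' evaluation) and partitions the remaining patients into `n_folds`
#' validation folds; each fold's training set is the non-test complement of
#' its validation set. With 96 patients, 16 test cases and 5 folds this
#' reproduces the 64 train / 16 validation / 16 test arithmetic.
#' Stratification degrades to unstratified with a warning when a class is
#' smaller than the fold count. Missing labels (insufficient follow-up)
#' form their own stratum.
#'
#' @param patient_ids character ids.
#' @param labels binary outcome labels used for stratification (NA
#'   allowed).
#' @param n_folds number of validation folds (>= 2; `n_folds` equal to the
#'   number of non-test patients gives leave-one-out).
#' @param test_fraction fraction of patients reserved as the test set.
#' @param seed integer seed.
#' @return a [CVPlan-class].
#' @examples
#' plan <- makeCVPlan(sprintf("P%02d", 1:96), rep(c(0, 1), 48),
#'                    n_folds = 5, test_fraction = 1/6, seed = 1)
#' lengths(lapply(plan@folds, `[[`, "train_ids"))  # all 64
#' @export
makeCVPlan <- function(patient_ids, labels, n_folds = 6L,
                       test_fraction = 1/6, seed) {
  if (missing(seed)) stop("seed required for reproducibility")
  n <- length(patient_ids)
  stopifnot(n >= 3, length(labels) == n, n_folds >= 2)
  n_test <- round(n * test_fraction)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  strata <- split(seq_len(n), addNA(factor(labels), ifany = TRUE))
  test_ix <- integer()
  for (ix in strata)
    test_ix <- c(test_ix, sample(ix, round(length(ix) * n_test / n)))
  # top up / trim rounding drift
  pool <- setdiff(seq_len(n), test_ix)
  if (length(test_ix) < n_test)
    test_ix <- c(test_ix, sample(pool, n_test - length(test_ix)))
  if (length(test_ix) > n_test)
    test_ix <- sort(sample(test_ix, n_test))
  non_test <- setdiff(seq_len(n), test_ix)
  if (length(non_test) < n_folds)
    stop("not enough patients for ", n_folds, " folds")
  foldid <- .stratified_folds(labels[non_test], n_folds, seed + 1L)
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- non_test[foldid == f]
    list(train_ids = patient_ids[setdiff(non_test, val)],
         val_ids = patient_ids[val])
  })
  new("CVPlan", n_total = as.integer(n),
      test_ids = patient_ids[sort(test_ix)],
      folds = folds, n_folds = as.integer(n_folds),
      seed = as.integer(seed))
}

#' Fit an unpenalized logistic prognosticator
#'
#' Newton-Raphson maximum likelihood with convergence at an infinity-norm
#' gradient below 1e-8. Perfectly separable data are flagged and refit with
#' a small L2 penalty on the non-intercept coefficients (with a warning) so
#' predictions stay finite.
#'
#' @param X patients x features matrix (may have zero columns: the null
#'   model's intercept is then the logit of the event rate).
#' @param y binary outcome with both classes present.
#' @return list with intercept, coefficients (named), converged, separable,
#'   feature_names.
#' @export
fitPrognosticator <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y) || ncol(X) == 0L)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  n <- length(y)
  fn <- colnames(X) %||% if (ncol(X)) paste0("M", seq_len(ncol(X))) else character()
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- .newton_logistic(X1, y, ridge = 0)
  separable <- !fit$converged || any(abs(fit$beta) > 15)
  if (separable) {
    warning("perfect separation detected; coefficients capped by L2 fallback")
    fit <- .newton_logistic(X1, y, ridge = 1e-2)
  }
  list(intercept = unname(fit$beta[1]),
       coefficients = setNames(unname(fit$beta[-1]), fn),
       converged = fit$converged, separable = separable,
       feature_names = fn)
}

.newton_logistic <- function(X1, y, ridge = 0, max_iter = 100L) {
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X1, y - mu)) - drop(pen %*% beta)
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * W, X1) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (any(abs(beta) > 30)) break
  }
  list(beta = beta, converged = converged)
}

#' Predict event probabilities and dichotomize into risk groups
#'
#' Per-patient two-year event probability from a fitted prognosticator,
#' dichotomized into low/high risk at the probability cutoff (default 50%;
#' exactly 0.5 is high risk). Increasing a positive-coefficient feature
#' never decreases the probability.
#'
#' @param model result of [fitPrognosticator()].
#' @param X patients x features matrix with the training feature columns.
#' @param patient_ids character ids (default rownames of X).
#' @param endpoint endpoint label stored in the output.
#' @param cutoff probability cutoff (default 0.5).
#' @return data.frame from [riskPrediction()].
#' @export
predictAndDichotomize <- function(model, X, patient_ids = rownames(X),
                                  endpoint = "OS", cutoff = 0.5) {
  X <- as.matrix(X)
  if (!identical(colnames(X) %||% character(), model$feature_names))
    stop("feature columns do not match the trained prognosticator")
  eta <- model$intercept +
    (if (length(model$coefficients)) drop(X %*% model$coefficients) else 0)
  riskPrediction(patient_ids, endpoint, 1 / (1 + exp(-eta)), cutoff)
}

#' Build an outcome table from simulated survival draws
#'
#' Convenience for outcome-redraw experiments (e.g. null calibration):
#' attaches patient ids to a [simulateSurvival()] result in the
#' [cohortOutcomes()] column layout expected by [runPrognosis()].
#'
#' @param ids character patient ids.
#' @param surv data.frame from [simulateSurvival()].
#' @return data.frame with rownames = patient ids.
#' @export
survivalOutcomesTable <- function(ids, surv) {
  stopifnot(length(ids) == nrow(surv))
  out <- data.frame(patient_id = as.character(ids),
                    surv, row.names = as.character(ids),
                    stringsAsFactors = FALSE)
  colnames(out) <- c("patient_id", "os_time_yr", "os_event", "dss_time_yr",
                     "dss_event", "lpfs_time_yr", "lpfs_event",
                     "two_year_os", "two_year_dss", "two_year_lpfs")
  out
}

#' Per-patient outcome table of a cohort
#' @param cohort a [PhantomCohort-class].
#' @return data.frame, one row per patient, with event times (years),
#'   indicators and two-year labels for OS, DSS and LPFS.
#' @export
cohortOutcomes <- function(cohort) {
  cl <- cohort@clinical
  out <- cl[!duplicated(cl$patient_id),
            c("patient_id", "os_time_yr", "os_event", "dss_time_yr",
              "dss_event", "lpfs_time_yr", "lpfs_event", "two_year_os",
              "two_year_dss", "two_year_lpfs")]
  rownames(out) <- out$patient_id
  out
}

.ENDPOINT_COLS <- list(
  OS = c(time = "os_time_yr", event = "os_event", label = "two_year_os"),
  DSS = c(time = "dss_time_yr", event = "dss_event", label = "two_year_dss"),
  LPFS = c(time = "lpfs_time_yr", event = "lpfs_event", label = "two_year_lpfs"))

#' Run the prognostic stage on a precomputed feature panel
#'
#' Phase 2 and 3 of the pipeline: per-feature standardization constants,
#' k-medoids medoid selection and the Silhouette k choice are computed on
#' the non-test patients only; per endpoint, LASSO (with the plan's
#' validation folds driving the penalty choice) retains medoid features and
#' an unpenalized logistic prognosticator is fit on the non-test patients
#' with observed two-year labels. The held-out test set is then scored,
#' dichotomized at the cutoff, and compared against survival with the
#' package's statistics. Patients with missing two-year labels are excluded
#' from training.
#'
#' @param panel a [FeaturePanel-class] for the whole cohort.
#' @param outcomes per-patient outcome table ([cohortOutcomes()] layout).
#' @param plan a [CVPlan-class] over the panel's patients.
#' @param endpoints subset of c("OS", "DSS", "LPFS").
#' @param k_grid Silhouette candidate cluster counts.
#' @param max_features PAM subsample cap.
#' @param cutoff risk-group probability cutoff.
#' @param recist_final optional named factor (per patient) of final RECIST
#'   dichotomies ("PD"/"non-PD") for the agreement statistic.
#' @param seed integer seed.
#' @return list with per-endpoint results (model, retained features,
#'   predictions, survival statistics) plus the medoid set and plan.
#' @export
runPrognosis <- function(panel, outcomes, plan,
                         endpoints = c("OS", "DSS", "LPFS"),
                         k_grid = c(2, 4, 8, 16, 32),
                         max_features = 4096L, cutoff = 0.5,
                         recist_final = NULL, seed = 1L) {
  stopifnot(all(endpoints %in% names(.ENDPOINT_COLS)))
  if (!length(endpoints)) stop("empty endpoint list")
  ids <- colnames(panel)
  train_ids <- setdiff(ids, plan@test_ids)
  test_ids <- intersect(ids, plan@test_ids)

  stand <- panelStandardization(panel, train_ids)
  Z <- applyStandardization(featureMatrix(panel), stand)
  ksel <- selectKSilhouette(panel, k_grid, ids = train_ids,
                            max_features = max_features, seed = seed)
  med <- ksel$medoids
  Xmed <- Z[, med@medoid_feature_ids, drop = FALSE]
  colnames(Xmed) <- paste0("F", med@medoid_feature_ids)

  # map plan folds to foldid over the training rows of each endpoint
  fold_of <- integer(0)
  for (f in seq_along(plan@folds))
    fold_of[plan@folds[[f]]$val_ids] <- f

  res <- list()
  for (ep in endpoints) {
    cols <- .ENDPOINT_COLS[[ep]]
    y_all <- setNames(outcomes[[cols["label"]]], outcomes$patient_id)
    tr <- train_ids[!is.na(y_all[train_ids])]
    y <- y_all[tr]
    if (length(unique(y)) < 2L) {
      warning("endpoint ", ep, " has a single class in training; skipped")
      res[[ep]] <- NULL
      next
    }
    sel <- lassoSelect(Xmed[tr, , drop = FALSE], y,
                       cv_folds = plan@n_folds, seed = seed,
                       foldid = unname(fold_of[tr]))
    keep <- sel@retained_feature_ids
    Xfit <- Xmed[tr, keep, drop = FALSE]
    model <- fitPrognosticator(Xfit, y)
    preds <- predictAndDichotomize(model, Xmed[test_ids, keep, drop = FALSE],
                                   test_ids, endpoint = ep, cutoff = cutoff)
    stats <- .endpoint_stats(preds, outcomes[test_ids, ], cols)
    res[[ep]] <- list(lasso = sel, model = model, predictions = preds,
                      stats = stats, n_retained = length(keep))
  }
  phi <- NULL
  if (!is.null(recist_final) && "LPFS" %in% names(res) &&
      !is.null(res$LPFS)) {
    tab <- table(risk = factor(res$LPFS$predictions$risk_group,
                               levels = c("low", "high")),
                 recist = factor(recist_final[test_ids],
                                 levels = c("non-PD", "PD")))
    phi <- tryCatch(cramersPhi(unclass(matrix(tab, 2))),
                    error = function(e) list(phi = NA_real_, p = NA_real_,
                                             error = conditionMessage(e)))
  }
  list(endpoints = res, medoids = med, k_selection = ksel$silhouettes,
       standardization = stand, plan = plan, phi_lpfs_recist = phi,
       cutoff = cutoff, seed = seed)
}

.endpoint_stats <- function(preds, test_outcomes, cols) {
  time <- test_outcomes[[cols["time"]]]
  event <- test_outcomes[[cols["event"]]]
  grp <- preds$risk_group
  out <- list(n_test = nrow(preds),
              n_high = sum(grp == "high"))
  out$c_index <- tryCatch(harrellsC(time, event, preds$probability),
                          error = function(e) NA_real_)
  if (all(c("low", "high") %in% grp) && sum(event) > 0) {
    lo <- grp == "low"
    out$logrank <- logrankTest(time[lo], event[lo], time[!lo], event[!lo])
    out$cox <- tryCatch(
      suppressWarnings(coxHRBinary(time, event, as.integer(grp == "high"))),
      error = function(e) NULL)
    out$km <- list(low = kmCurve(time[lo], event[lo]),
                   high = kmCurve(time[!lo], event[!lo]))
  }
  out
}

#' Run the full pipeline on a phantom cohort
#'
#' Phase 1 trains the segmentation U-Net on baseline volumes and
#' ground-truth masks of (a subset of) non-test patients; Phase 2 extracts
#' the central latent vectors, selects medoid features by k-medoids +
#' Silhouette and retains outcome-associated ones by LASSO; Phase 3 fits
#' logistic prognosticators per endpoint, scores the held-out test set,
#' dichotomizes at 50% and runs the survival comparison (Kaplan-Meier,
#' log-rank, Cox hazard ratio, Harrell's c, and agreement of the
#' LPFS risk group with the manual RECIST dichotomy). A single seeded run
#' is reproducible end to end.
#'
#' @param cohort a [PhantomCohort-class] (or a directory written by
#'   [writeCohort()]).
#' @param endpoints subset of c("OS", "DSS", "LPFS").
#' @param net_config a [UNetConfig-class]; default desk preset with the
#'   run seed. Its input shape must match the cohort grid.
#' @param seg_train_n number of training patients used for Phase 1.
#' @param n_folds,test_fraction cross-validation layout.
#' @param k_grid,max_features,cutoff see [runPrognosis()].
#' @param seed integer seed for the whole run.
#' @return list with the trained segmentation model, the feature panel, the
#'   prognosis report of [runPrognosis()], the per-patient RECIST finals,
#'   and the configuration echo.
#' @export
runDesep <- function(cohort, endpoints = c("OS", "DSS", "LPFS"),
                     net_config = NULL, seg_train_n = 20L,
                     n_folds = 6L, test_fraction = 0.2,
                     k_grid = c(2, 4, 8, 16, 32), max_features = 4096L,
                     cutoff = 0.5, seed) {
  if (missing(seed)) stop("seed required for reproducibility")
  if (is.character(cohort)) cohort <- readCohort(cohort)
  net_config <- net_config %||% UNetConfig("desk", seed = seed)
  if (!identical(net_config@input_shape, cohort@config@grid_shape))
    stop("network input shape must match the cohort grid")
  outcomes <- cohortOutcomes(cohort)
  ids <- outcomes$patient_id
  plan <- makeCVPlan(ids, outcomes$two_year_os, n_folds = n_folds,
                     test_fraction = test_fraction, seed = seed)
  train_ids <- setdiff(ids, plan@test_ids)

  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed + 2L)
  seg_ids <- sample(train_ids, min(seg_train_n, length(train_ids)))
  by_id <- setNames(cohort@patients,
                    vapply(cohort@patients, function(p) p@patient_id, ""))
  model <- buildModel(net_config)
  model <- trainModel(model,
                      lapply(by_id[seg_ids], function(p) p@baseline_volume),
                      lapply(by_id[seg_ids], function(p) p@baseline_mask * 1))
  panel <- buildFeaturePanel(model,
                             lapply(by_id[ids], function(p) p@baseline_volume),
                             ids)
  recist_final <- vapply(by_id[ids], function(p) {
    as.character(dichotomizeResponse(worstCategory(
      categorizeUnidimensional(measurementSeries(p)))))
  }, "")
  prognosis <- runPrognosis(panel, outcomes, plan, endpoints = endpoints,
                            k_grid = k_grid, max_features = max_features,
                            cutoff = cutoff, recist_final = recist_final,
                            seed = seed)
  list(model = model, panel = panel, prognosis = prognosis,
       recist_final = recist_final, outcomes = outcomes,
       config = list(seed = seed, n_folds = n_folds,
                     test_fraction = test_fraction, k_grid = k_grid,
                     seg_train_n = seg_train_n, cutoff = cutoff,
                     net_preset = net_config@scale_preset))
}
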