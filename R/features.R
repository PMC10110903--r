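# Unsupervised reduction of the latent vectors: k-medoids (PAM) clustering
# of feature profiles across patients, Silhouette-based selection of the
# cluster count, and LASSO retention of outcome-associated medoid features.

#' Build a cohort x latent-feature panel
#'
#' Extracts the central latent vector of every volume and assembles a
#' [FeaturePanel-class] (features as rows, patients as columns, assay
#' "latent"). Zero-variance features are flagged in rowData and excluded
#' from clustering.
#'
#' @param model a trained [SegNetModel-class].
#' @param volumes list of 3D volumes matching the model input shape.
#' @param patient_ids character ids, one per volume.
#' @return a [FeaturePanel-class].
#' @export
buildFeaturePanel <- function(model, volumes, patient_ids) {
  stopifnot(length(volumes) == length(patient_ids))
  lat <- vapply(volumes, function(v) extractLatent(model, v),
                numeric(latentLength(model)))
  colnames(lat) <- patient_ids
  featurePanelFromMatrix(lat)
}

#' Create a feature panel from a features x patients matrix
#' @param lat numeric matrix, latent features in rows, patients in columns
#'   (column names are patient ids).
#' @return a [FeaturePanel-class].
#' @export
featurePanelFromMatrix <- function(lat) {
  stopifnot(is.matrix(lat), !anyNA(lat), !is.null(colnames(lat)))
  rd <- S4Vectors::DataFrame(
    feature_id = seq_len(nrow(lat)),
    constant = apply(lat, 1, function(r) sd(r) == 0))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(latent = lat), rowData = rd)
  rownames(se) <- paste0("F", seq_len(nrow(lat)))
  new("FeaturePanel", se)
}

setMethod("featureMatrix", "FeaturePanel", function(object)
  t(SummarizedExperiment::assay(object, "latent")))

setMethod("show", "FeaturePanel", function(object) {
  cat("FeaturePanel:", nrow(object), "latent features x",
      ncol(object), "patients (",
      sum(SummarizedExperiment::rowData(object)$constant),
      "zero-variance )\n")
  invisible(object)
})

#' Per-feature standardization constants
#'
#' Means and SDs computed over a reference patient set (normally the
#' training patients, so that test data never influence them). Zero SDs
#' are replaced by 1 so constant features map to 0.
#'
#' @param panel a [FeaturePanel-class].
#' @param ids patient ids to compute the constants over; default all.
#' @return list with mean and sd vectors (one entry per feature).
#' @export
panelStandardization <- function(panel, ids = colnames(panel)) {
  lat <- SummarizedExperiment::assay(panel, "latent")[, ids, drop = FALSE]
  m <- rowMeans(lat)
  s <- apply(lat, 1, sd)
  s[s == 0] <- 1
  list(mean = m, sd = s)
}

#' Apply standardization constants to a patients x features matrix
#' @param X patients x features matrix (all features of the panel).
#' @param stand result of [panelStandardization()].
#' @return z-scored matrix.
#' @export
applyStandardization <- function(X, stand) {
  sweep(sweep(X, 2, stand$mean, "-"), 2, stand$sd, "/")
}

# z-scored feature profiles (rows = features) over a patient subset,
# excluding zero-variance features; optionally a seeded subsample when the
# feature count exceeds `max_features` (exact PAM over all 55296 full-scale
# features is infeasible; the cap is configuration).
.feature_profiles <- function(panel, ids, max_features, seed) {
  lat <- SummarizedExperiment::assay(panel, "latent")[, ids, drop = FALSE]
  sds <- apply(lat, 1, sd)
  keep <- unname(which(sds > 0))
  if (!length(keep)) stop("all features are constant; nothing to cluster")
  if (length(keep) > max_features) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    keep <- sort(sample(keep, max_features))
  }
  prof <- (lat[keep, , drop = FALSE] - rowMeans(lat[keep, , drop = FALSE])) /
    sds[keep]
  list(profiles = prof, feature_ids = keep)
}

#' k-medoids clustering of latent features
#'
#' Clusters feature profiles across patients (each feature is represented
#' by its z-scored vector of per-patient activations; Euclidean distance)
#' with PAM build + swap until no improving swap, so the total
#' within-cluster dissimilarity is locally minimal. Deterministic given the
#' seed (randomness enters only through the optional feature subsample).
#'
#' @param panel a [FeaturePanel-class].
#' @param k number of clusters (2 <= k <= number of non-constant features;
#'   k equal to the feature count yields the trivial every-feature-its-own-
#'   medoid solution with zero dissimilarity).
#' @param ids patient ids whose profiles drive the clustering (default
#'   all); pass the training patients to keep test data out of medoid
#'   selection.
#' @param max_features seeded subsample cap before exact PAM (default
#'   4096).
#' @param seed integer seed.
#' @return a [MedoidSet-class].
#' @export
clusterFeatures <- function(panel, k, ids = colnames(panel),
                            max_features = 4096L, seed = 1L) {
  fp <- .feature_profiles(panel, ids, max_features, seed)
  nf <- nrow(fp$profiles)
  k <- as.integer(k)
  if (k < 1L || k > nf)
    stop("k must lie between 1 and the number of non-constant features (",
         nf, ")")
  if (k == nf) {
    asg <- seq_len(nf)
    names(asg) <- fp$feature_ids
    return(new("MedoidSet", k = k, medoid_feature_ids = fp$feature_ids,
               assignments = asg, mean_silhouette = 0))
  }
  pm <- cluster::pam(fp$profiles, k = k, metric = "euclidean",
                     keep.diss = FALSE, keep.data = FALSE)
  asg <- as.integer(pm$clustering)
  names(asg) <- fp$feature_ids
  new("MedoidSet", k = k,
      medoid_feature_ids = as.integer(fp$feature_ids[pm$id.med]),
      assignments = asg,
      mean_silhouette = if (k >= 2L) pm$silinfo$avg.width else 0)
}

#' Silhouette-based selection of the cluster count
#'
#' Runs [clusterFeatures()] over a grid of k and returns the k maximizing
#' the mean silhouette width s(i) = (b - a) / max(a, b) (singleton clusters
#' contribute s = 0); ties break to the smallest k.
#'
#' @param panel a [FeaturePanel-class].
#' @param k_grid candidate cluster counts.
#' @param ids,max_features,seed as in [clusterFeatures()].
#' @return list with k (the selection), silhouettes (named by k), and the
#'   winning [MedoidSet-class] as `medoids`.
#' @export
selectKSilhouette <- function(panel, k_grid, ids = colnames(panel),
                              max_features = 4096L, seed = 1L) {
  if (!length(k_grid)) stop("empty k grid")
  k_grid <- sort(unique(as.integer(k_grid)))
  sets <- lapply(k_grid, function(k)
    clusterFeatures(panel, k, ids = ids, max_features = max_features,
                    seed = seed))
  sil <- vapply(sets, function(s) s@mean_silhouette, 0)
  names(sil) <- k_grid
  best <- which.max(sil)  # first maximum = smallest k on ties
  list(k = k_grid[best], silhouettes = sil, medoids = sets[[best]])
}

.stratified_folds <- function(y, k, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  foldid <- integer(length(y))
  strata <- split(seq_along(y), addNA(factor(y), ifany = TRUE))
  small <- any(vapply(strata, length, 0L) < k)
  if (small) {
    warning("a class is smaller than the fold count; folds are unstratified")
    strata <- list(seq_along(y))
  }
  for (ix in strata) {
    ix <- sample(ix)
    foldid[ix] <- rep_len(seq_len(k), length(ix))
  }
  foldid
}

#' LASSO retention of outcome-associated features
#'
#' L1-penalized logistic regression over a lambda path with seeded,
#' outcome-stratified cross-validation; the penalty minimizing the mean CV
#' binomial deviance is selected and features with nonzero coefficients at
#' that penalty are retained.
#'
#' @param X patients x features matrix (z-scored medoid features).
#' @param y binary outcome with both classes present.
#' @param lambda_grid optional decreasing penalty path; default glmnet's.
#'   A single value skips cross-validation and retains the nonzero
#'   coefficients at exactly that penalty.
#' @param cv_folds number of CV folds (default 6).
#' @param seed integer seed.
#' @param foldid optional explicit fold assignment overriding `cv_folds`.
#' @return a [LassoSelection-class].
#' @export
lassoSelect <- function(X, y, lambda_grid = NULL, cv_folds = 6L, seed = 1L,
                        foldid = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L) stop("empty feature matrix")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  ids <- colnames(X) %||% paste0("M", seq_len(ncol(X)))
  pad <- ncol(X) == 1L  # glmnet requires >= 2 columns
  Xf <- if (pad) cbind(X, .zero = 0) else X
  if (!is.null(lambda_grid) && length(lambda_grid) == 1L) {
    lam <- lambda_grid
    path <- sort(unique(c(lam + 1, lam * 2 + 0.1, lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xf, y, family = "binomial", lambda = path,
                          standardize = FALSE, thresh = 1e-12,
                          maxit = 1e6)
    cf <- as.numeric(coef(fit, s = lam))  # lam is on the fitted path
  } else {
    if (is.null(foldid)) foldid <- .stratified_folds(y, cv_folds, seed)
    cv <- glmnet::cv.glmnet(Xf, y, family = "binomial",
                            lambda = lambda_grid, foldid = foldid,
                            standardize = FALSE, thresh = 1e-10,
                            type.measure = "deviance")
    lam <- cv$lambda.min
    cf <- as.numeric(coef(cv, s = "lambda.min"))
  }
  beta <- cf[-1][seq_len(ncol(X))]
  nz <- which(beta != 0)
  new("LassoSelection", lambda = as.numeric(lam),
      retained_feature_ids = as.integer(nz),
      coefficients = setNames(beta[nz], ids[nz]))
}
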