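# Segmentation quality metrics: dice similarity coefficient and average
# symmetric surface distance, plus the RECIST-style longest axial diameter
# measured from a mask.

.as_mask <- function(m) {
  if (!all(m %in% c(0, 1, TRUE, FALSE))) stop("mask must be binary")
  m != 0
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, 2|A n B| / (|A| + |B|), in [0, 1].
#' Two empty masks are identical and score 1 by convention.
#'
#' @param maskA,maskB binary arrays of identical shape.
#' @return dice coefficient.
#' @examples
#' a <- array(0, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1
#' diceCoefficient(a, a)  # 1
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("mask shapes differ")
  a <- .as_mask(maskA); b <- .as_mask(maskB)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# Boundary voxels: foreground with at least one face-adjacent background
# neighbor (voxels on the grid edge count as boundary).
.boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1, -1))
    interior <- interior & shift_and(mask, ax, by)
  which(mask & !interior, arr.ind = TRUE)
}

.min_cross_dist <- function(A, B) {
  # per row of A, min Euclidean distance to rows of B; differences are
  # formed explicitly (the expanded quadratic loses precision)
  tB <- t(B)
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min(colSums((tB - A[i, ])^2))), 0)
}

#' Average symmetric surface distance
#'
#' Mean of the two directed mean boundary distances: for each boundary
#' voxel center of one mask, the distance to the nearest boundary voxel
#' center of the other, averaged within each direction and then across the
#' two directions. Distances are in mm using `spacing`. Boundaries are
#' foreground voxels with at least one face-adjacent background neighbor.
#'
#' @param maskA,maskB nonempty binary arrays of identical shape.
#' @param spacing mm per voxel along each axis.
#' @return ASSD in mm (0 iff the boundaries coincide).
#' @export
assd <- function(maskA, maskB, spacing = c(1, 1, 1)) {
  if (!identical(dim(maskA), dim(maskB))) stop("mask shapes differ")
  a <- .as_mask(maskA); b <- .as_mask(maskB)
  if (sum(a) == 0 || sum(b) == 0) stop("ASSD undefined for empty mask")
  stopifnot(all(spacing > 0))
  BA <- .boundary_voxels(a) %*% diag(spacing)
  BB <- .boundary_voxels(b) %*% diag(spacing)
  (mean(.min_cross_dist(BA, BB)) + mean(.min_cross_dist(BB, BA))) / 2
}

#' Longest axial lesion diameter from a mask
#'
#' RECIST measures the largest in-plane tumor diameter: the maximum over
#' axial (z) slices of the largest pairwise distance between foreground
#' voxel centers within the slice, in mm. An empty mask (and a single
#' voxel) measures 0.
#'
#' @param mask binary 3D array.
#' @param spacing mm per voxel along each axis.
#' @return diameter in mm.
#' @examples
#' m <- array(0, c(40, 8, 4)); m[5:35, 4, 2] <- 1
#' longestAxialDiameter(m, c(1, 1, 1))  # 30 mm
#' @export
longestAxialDiameter <- function(mask, spacing = c(1, 1, 1)) {
  m <- .as_mask(mask)
  stopifnot(all(spacing > 0))
  best <- 0
  for (z in seq_len(dim(m)[3])) {
    sl <- which(m[, , z], arr.ind = TRUE)
    if (nrow(sl) < 2) next
    pts <- cbind(sl[, 1] * spacing[1], sl[, 2] * spacing[2])
    best <- max(best, max(dist(pts)))
  }
  best
}
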