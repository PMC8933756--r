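#' @title Tensor field
#' @description A `tensor_field` holds, per voxel, the symmetric diffusion
#' tensor in lower-triangle order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), in units
#' of 1e-3 mm^2/s, together with its eigensystem (eigenvalues sorted
#' descending, orthonormal eigenvectors), a validity mask, the grid
#' geometry, and the number of negative eigenvalues clamped to zero.
#' @name tensor_field
NULL

# build the eigensystem for a lower-triangle array; clamps negative
# eigenvalues to 0 and counts the clamps
tensor_field_from_lower <- function(lower, geometry, mask = NULL) {
  dm <- geometry$dim
  nvox <- prod(dm)
  L <- matrix(lower, nrow = nvox, ncol = 6)
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  evals <- matrix(0, nvox, 3)
  evecs <- array(0, dim = c(nvox, 3, 3))
  idx <- which(as.vector(mask))
  n_clamped <- 0L
  neg_eval <- rep(FALSE, nvox)
  for (i in idx) {
    D <- matrix(c(L[i, 1], L[i, 2], L[i, 4],
                  L[i, 2], L[i, 3], L[i, 5],
                  L[i, 4], L[i, 5], L[i, 6]), 3, 3)
    e <- eigen(D, symmetric = TRUE)  # values descending
    neg <- e$values < 0
    if (any(neg)) {
      n_clamped <- n_clamped + sum(neg)
      neg_eval[i] <- TRUE
      e$values[neg] <- 0
    }
    evals[i, ] <- e$values
    evecs[i, , ] <- e$vectors
  }
  structure(list(
    lower = array(L, dim = c(dm, 6)),
    evals = array(evals, dim = c(dm, 3)),
    evecs = array(evecs, dim = c(dm, 3, 3)),  # [..., component, which]
    mask = mask,
    geometry = geometry,
    n_clamped = n_clamped,
    neg_eval = array(neg_eval, dim = dm)
  ), class = "tensor_field")
}

#' Construct a tensor field from a lower-triangle array
#'
#' @param lower 4-D array (nx, ny, nz, 6) of tensor elements in the order
#'   Dxx, Dxy, Dyy, Dxz, Dyz, Dzz, units 1e-3 mm^2/s.
#' @param geometry a [volume_geometry()].
#' @param mask optional logical validity mask.
#' @return a `tensor_field` with the eigensystem computed (eigenvalues
#'   descending, negatives clamped to zero and counted).
#' @export
tensor_field <- function(lower, geometry, mask = NULL) {
  if (length(dim(lower)) != 4 || dim(lower)[4] != 6 ||
      !all(dim(lower)[1:3] == geometry$dim)) {
    stop("`lower` must be (nx, ny, nz, 6) matching the geometry", call. = FALSE)
  }
  tensor_field_from_lower(lower, geometry, mask)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$geometry$dim, collapse = " x "),
      " voxels, ", sum(x$mask), " valid, ", x$n_clamped,
      " eigenvalue(s) clamped\n", sep = "")
  invisible(x)
}

# linear voxel index (1-based) from a 0-based (i,j,k) triple
voxel_linear <- function(vox, dim) {
  1L + vox[1] + dim[1] * (vox[2] + dim[2] * vox[3])
}

# tensor elements at one 0-based voxel, as a named length-6 vector
tensor_at <- function(tf, vox) {
  li <- voxel_linear(vox, tf$geometry$dim)
  L <- matrix(tf$lower, ncol = 6)
  stats::setNames(L[li, ], c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz"))
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, estimates the symmetric tensor D minimising the ordinary
#' least-squares residual of `log(S/S0) = -b * g' D g`, with S0 the mean of
#' all b=0 volumes. Signals at or below zero are floored to a small epsilon
#' before the log; all-zero voxels are marked invalid rather than fatal.
#' Negative eigenvalues are clamped to zero and the clamp count is
#' reported on the returned field.
#'
#' @param dwi a [dwi_volume()].
#' @param mask optional logical 3-D array restricting the fit.
#' @return a [tensor_field].
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- validate_scheme_for_fit(dwi$scheme)
  dm <- dwi$geometry$dim
  nvox <- prod(dm)
  nvol <- length(scheme$bvalues)
  S <- matrix(dwi$signal, nrow = nvox, ncol = nvol)
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  b0 <- scheme$bvalues == 0
  S0 <- rowMeans(S[, b0, drop = FALSE])
  valid <- as.vector(mask) & S0 > 0 & rowSums(S > 0) > 0
  eps <- 1e-12
  Y <- -log(pmax(S, eps) / pmax(S0, eps))  # nvox x nvol, = b g'Dg
  X <- tensor_design_matrix(scheme)
  # OLS for all voxels at once: coefficients in mm^2/s
  XtXinv <- solve(crossprod(X))
  coefs <- Y %*% X %*% XtXinv          # nvox x 6
  coefs[!valid, ] <- 0
  lower <- array(coefs * 1e3, dim = c(dm, 6))  # to 1e-3 mm^2/s
  tensor_field_from_lower(lower, dwi$geometry, mask = array(valid, dim = dm))
}

#' Scalar diffusion maps (FA, MD, AD, RD)
#'
#' From the per-voxel eigenvalues (descending):
#' `MD = (l1 + l2 + l3) / 3`, `AD = l1`, `RD = (l2 + l3) / 2`, and
#' `FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#'  sqrt(l1^2 + l2^2 + l3^2)`, with FA of the zero tensor defined as 0.
#'
#' @param tf a [tensor_field].
#' @return object of class `scalar_maps`: 3-D arrays `fa` (unitless),
#'   `md`, `ad`, `rd` (1e-3 mm^2/s) plus the geometry.
#' @export
scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dm <- tf$geometry$dim
  ev <- matrix(tf$evals, ncol = 3)
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  md <- (l1 + l2 + l3) / 3
  ad <- l1
  rd <- (l2 + l3) / 2
  den <- sqrt(l1^2 + l2^2 + l3^2)
  num <- sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2)
  fa <- ifelse(den > 0, num / den, 0)
  structure(list(fa = array(fa, dm), md = array(md, dm),
                 ad = array(ad, dm), rd = array(rd, dm),
                 geometry = tf$geometry),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat("<scalar_maps> FA/MD/AD/RD over ",
      paste(x$geometry$dim, collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' Global DTI parameter summary
#'
#' Unweighted voxel means of FA, MD, AD and RD over a summary mask. The
#' intended masks are either the set of voxels visited by at least one
#' accepted streamline (see [visited_mask()]), mirroring whole-brain-seeded
#' region statistics, or a plain FA threshold mask; the provenance label
#' records which was used.
#'
#' @param maps a [scalar_maps()] result.
#' @param mask logical 3-D array; must select at least one voxel.
#' @param provenance label recording how the mask was built.
#' @return a one-row tibble with columns fa, md, ad, rd, n_voxels, mask.
#' @export
global_summary <- function(maps, mask, provenance = "user") {
  stopifnot(inherits(maps, "scalar_maps"))
  if (!any(mask)) stop("summary mask is empty", call. = FALSE)
  m <- as.vector(mask)
  tibble::tibble(
    fa = mean(maps$fa[m]), md = mean(maps$md[m]),
    ad = mean(maps$ad[m]), rd = mean(maps$rd[m]),
    n_voxels = sum(m), mask = provenance
  )
}

#' FA-threshold summary mask
#' @param maps a [scalar_maps()] result.
#' @param threshold FA cut-off.
#' @export
fa_mask <- function(maps, threshold = 0.2) {
  maps$fa > threshold
}
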