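#' Voxel box (0-based, half-open)
#'
#' A rectangular voxel region given per axis as `c(lo, hi)` with 0-based
#' inclusive-exclusive bounds, so `vox_box(c(0, 4), c(0, 4), c(0, 2))`
#' covers 4 x 4 x 2 voxels.
#'
#' @param x,y,z integer vectors `c(lo, hi)`.
#' @export
vox_box <- function(x, y, z) {
  b <- list(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  for (ax in names(b)) {
    if (length(b[[ax]]) != 2 || b[[ax]][1] < 0 || b[[ax]][2] <= b[[ax]][1]) {
      stop("box ", ax, "-range must be c(lo, hi) with 0 <= lo < hi",
           call. = FALSE)
    }
  }
  structure(b, class = "vox_box")
}

box_in_grid <- function(box, dim) {
  all(c(box$x[2] <= dim[1], box$y[2] <= dim[2], box$z[2] <= dim[3]))
}

# 1-based index ranges for R array subsetting
box_ranges <- function(box) {
  list(x = (box$x[1] + 1):box$x[2],
       y = (box$y[1] + 1):box$y[2],
       z = (box$z[1] + 1):box$z[2])
}

box_n_voxels <- function(box) {
  prod(box$x[2] - box$x[1], box$y[2] - box$y[1], box$z[2] - box$z[1])
}

boxes_overlap <- function(a, b) {
  all(vapply(c("x", "y", "z"),
             function(ax) a[[ax]][1] < b[[ax]][2] && b[[ax]][1] < a[[ax]][2],
             logical(1)))
}

#' Fiber region specification
#'
#' One homogeneous fiber compartment of a diffusion phantom. Inside the box
#' every voxel carries a diagonal tensor: the parallel eigenvalue
#' `lambdas[1]` sits on the principal fiber axis and the two perpendicular
#' eigenvalues on the remaining axes (in x < y < z order). The perivascular
#' boost `g` is then added to the xx element, emulating the extra
#' x-direction diffusivity that perivascular flow contributes in the
#' periventricular geometry (projection fibers run head-foot, association
#' fibers anterior-posterior, subcortical fibers left-right, and the deep
#' medullary perivascular spaces run left-right across all of them).
#'
#' @param label one of `"projection"`, `"association"`, `"subcortical"`,
#'   `"background"`.
#' @param box a [vox_box()].
#' @param axis principal fiber axis, `"x"`, `"y"` or `"z"`.
#' @param lambdas eigenvalue triple (parallel, perp1, perp2) in
#'   1e-3 mm^2/s; must satisfy `lambdas[1] >= lambdas[2] >= lambdas[3] > 0`.
#' @param g perivascular boost added to Dxx, in 1e-3 mm^2/s, `>= 0`.
#' @export
fiber_region <- function(label, box, axis, lambdas = c(1.4, 0.4, 0.4), g = 0) {
  label <- match.arg(label,
                     c("projection", "association", "subcortical", "background"))
  axis <- match.arg(axis, c("x", "y", "z"))
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) != 3 ||
      !(lambdas[1] >= lambdas[2] && lambdas[2] >= lambdas[3] && lambdas[3] > 0)) {
    stop("need lambda_par >= lambda_perp1 >= lambda_perp2 > 0", call. = FALSE)
  }
  if (g < 0) stop("perivascular boost g must be >= 0", call. = FALSE)
  structure(list(label = label, box = box, axis = axis,
                 lambdas = lambdas, g = g),
            class = "fiber_region")
}

# diagonal tensor (Dxx, Dyy, Dzz) of a region, in 1e-3 mm^2/s
region_diag <- function(region) {
  ax <- match(region$axis, c("x", "y", "z"))
  d <- numeric(3)
  d[ax] <- region$lambdas[1]
  d[-ax] <- region$lambdas[2:3]
  d[1] <- d[1] + region$g
  d
}

#' Build a tensor-field phantom from fiber regions
#'
#' Lays disjoint fiber regions into a grid of diagonal tensors; voxels not
#' covered by any region are isotropic with diffusivity `background_adc`.
#'
#' @param regions list of [fiber_region()] objects; boxes must be pairwise
#'   disjoint and inside the grid.
#' @param geometry a [volume_geometry()].
#' @param background_adc isotropic background diffusivity, 1e-3 mm^2/s.
#' @return a `tensor_field` (see [fit_tensor()] for the class contract).
#' @export
make_phantom <- function(regions, geometry, background_adc = 0.8) {
  if (inherits(regions, "fiber_region")) regions <- list(regions)
  for (r in regions) {
    if (!inherits(r, "fiber_region")) stop("regions must be fiber_region objects",
                                           call. = FALSE)
    if (!box_in_grid(r$box, geometry$dim)) {
      stop("region '", r$label, "' box extends outside the grid", call. = FALSE)
    }
  }
  if (length(regions) > 1) {
    for (i in seq_along(regions)[-1]) for (j in seq_len(i - 1)) {
      if (boxes_overlap(regions[[i]]$box, regions[[j]]$box)) {
        stop("regions overlap: '", regions[[i]]$label, "' and '",
             regions[[j]]$label, "'", call. = FALSE)
      }
    }
  }
  dm <- geometry$dim
  lower <- array(0, dim = c(dm, 6))  # Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
  lower[, , , 1] <- background_adc
  lower[, , , 3] <- background_adc
  lower[, , , 6] <- background_adc
  for (r in regions) {
    d <- region_diag(r)
    rg <- box_ranges(r$box)
    lower[rg$x, rg$y, rg$z, 1] <- d[1]
    lower[rg$x, rg$y, rg$z, 3] <- d[2]
    lower[rg$x, rg$y, rg$z, 6] <- d[3]
  }
  tf <- tensor_field_from_lower(lower, geometry)
  tf$regions <- regions
  tf
}

#' Default periventricular phantom
#'
#' A 24 x 24 x 12 grid at 2 mm isotropic with left/right symmetric
#' projection (head-foot), association (anterior-posterior) and subcortical
#' (left-right) fiber boxes laid along a mediolateral line in one axial
#' band, mimicking the layout at the level of the lateral-ventricle body.
#' With the white-matter-like default eigenvalues (1.4, 0.4, 0.4) 1e-3
#' mm^2/s and perivascular boost `g`, the ground-truth perivascular-space
#' index is `(0.4 + g) / 0.4` in closed form (1.5 at the default g = 0.2).
#'
#' @param g perivascular boost in 1e-3 mm^2/s.
#' @param lambdas fiber eigenvalue triple in 1e-3 mm^2/s.
#' @param background_adc isotropic background diffusivity.
#' @return list with elements `tensor_field`, `regions`, `roi_spec`
#'   (bilateral [alps_roi_spec()]), `geometry`, and the closed-form
#'   `truth_alps`.
#' @export
default_phantom <- function(g = 0.2, lambdas = c(1.4, 0.4, 0.4),
                            background_adc = 0.8) {
  geom <- volume_geometry(c(24, 24, 12), 2)
  yb <- c(10, 14); zb <- c(5, 7)
  mk <- function(label, xr, axis) {
    fiber_region(label, vox_box(xr, yb, zb), axis, lambdas, g)
  }
  regions <- list(
    mk("subcortical", c(1, 4), "x"),
    mk("projection",  c(5, 8), "z"),
    mk("association", c(9, 12), "y"),
    mk("association", c(12, 15), "y"),
    mk("projection",  c(16, 19), "z"),
    mk("subcortical", c(20, 23), "x")
  )
  tf <- make_phantom(regions, geom, background_adc = background_adc)
  roi <- list(
    left = alps_roi_spec(
      projection  = vox_box(c(5, 8), yb, zb),
      association = vox_box(c(9, 12), yb, zb),
      subcortical = vox_box(c(1, 4), yb, zb),
      laterality = "left"),
    right = alps_roi_spec(
      projection  = vox_box(c(16, 19), yb, zb),
      association = vox_box(c(12, 15), yb, zb),
      subcortical = vox_box(c(20, 23), yb, zb),
      laterality = "right")
  )
  truth <- ground_truth_alps(regions)
  list(tensor_field = tf, regions = regions, roi_spec = roi,
       geometry = geom, truth_alps = truth)
}

#' Closed-form ground-truth perivascular-space index of a phantom
#'
#' Computes the index directly from the region specifications: Dxx of the
#' projection and association regions over Dyy of the projection and Dzz of
#' the association region. With several regions per fiber type the first of
#' each type is used (the default phantom is left/right symmetric so the
#' choice is immaterial).
#'
#' @param regions list of [fiber_region()] objects containing at least one
#'   projection and one association region.
#' @export
ground_truth_alps <- function(regions) {
  lab <- vapply(regions, function(r) r$label, character(1))
  ip <- which(lab == "projection")[1]
  ia <- which(lab == "association")[1]
  if (is.na(ip) || is.na(ia)) {
    stop("need at least one projection and one association region", call. = FALSE)
  }
  dp <- region_diag(regions[[ip]])
  da <- region_diag(regions[[ia]])
  compute_alps(dxx_proj = dp[1], dxx_assoc = da[1],
               dyy_proj = dp[2], dzz_assoc = da[3])
}

#' Uniform-fiber slab phantom for tractography checks
#'
#' A slab of fibers all parallel to one axis, with the stated physical
#' extent along that axis, surrounded by isotropic background. Streamlines
#' seeded inside must run parallel to the axis and have lengths close to
#' the slab extent.
#'
#' @param extent_mm slab extent along the fiber axis, mm.
#' @param axis fiber axis.
#' @param voxel_mm voxel size, mm.
#' @param width_vox slab width in voxels on the other two axes.
#' @export
slab_phantom <- function(extent_mm = 40, axis = "z", voxel_mm = 2,
                         width_vox = 8) {
  n_along <- ceiling(extent_mm / voxel_mm)
  pad <- 2L
  dims <- rep(width_vox + 2 * pad, 3)
  ax <- match(axis, c("x", "y", "z"))
  dims[ax] <- n_along + 2 * pad
  geom <- volume_geometry(dims, voxel_mm)
  rng <- list(c(pad, pad + width_vox), c(pad, pad + width_vox))
  along <- c(pad, pad + n_along)
  b <- switch(axis,
              x = vox_box(along, rng[[1]], rng[[2]]),
              y = vox_box(rng[[1]], along, rng[[2]]),
              z = vox_box(rng[[1]], rng[[2]], along))
  reg <- fiber_region("projection", b, axis, c(1.4, 0.4, 0.4), g = 0)
  # low-diffusion isotropic background keeps FA ~ 0 outside the slab
  make_phantom(list(reg), geom, background_adc = 0.8)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Mono-exponential tensor forward model: for each gradient volume the
#' noiseless signal is `S0 * exp(-b * g' D g)`. Finite `snr` adds Rician
#' noise, i.e. independent Gaussian perturbations of scale `S0/snr` on two
#' quadrature channels followed by the magnitude operation; `snr = Inf`
#' is exact.
#'
#' @param tf a `tensor_field`.
#' @param scheme a [gradient_scheme()].
#' @param S0 non-diffusion-weighted signal level, must be positive.
#' @param snr signal-to-noise ratio at b=0; `Inf` for noiseless.
#' @param seed integer seed consumed when `snr` is finite.
#' @return a [dwi_volume()].
#' @export
simulate_dwi <- function(tf, scheme, S0 = 100, snr = Inf, seed = NULL) {
  stopifnot(inherits(tf, "tensor_field"))
  if (S0 <= 0) stop("S0 must be positive", call. = FALSE)
  if (snr <= 0) stop("snr must be positive (or Inf)", call. = FALSE)
  bad <- which(tf$neg_eval, arr.ind = TRUE)
  if (length(bad) > 0) {
    bad <- matrix(bad, ncol = 3)
    stop("tensor not positive semidefinite at voxel (0-based) ",
         paste(bad[1, ] - 1L, collapse = ","), call. = FALSE)
  }
  dm <- tf$geometry$dim
  nvol <- length(scheme$bvalues)
  X <- tensor_design_matrix(scheme)  # nvol x 6, units: s/mm^2 * unitless
  L <- matrix(tf$lower, nrow = prod(dm), ncol = 6)  # 1e-3 mm^2/s
  expo <- tcrossprod(L, X) * 1e-3    # nvox x nvol, b * g'Dg
  sig <- S0 * exp(-expo)
  if (is.finite(snr)) {
    if (!is.null(seed)) set.seed(seed)
    sigma <- S0 / snr
    n1 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow = nrow(sig))
    n2 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow = nrow(sig))
    sig <- sqrt((sig + n1)^2 + n2^2)
  }
  dwi_volume(array(sig, dim = c(dm, nvol)), scheme, tf$geometry)
}

#' Random weighted connectome fixture
#'
#' Symmetric nonnegative matrix with zero diagonal and exactly
#' `floor(density * n * (n - 1) / 2)` undirected edges chosen uniformly,
#' with positive weights.
#'
#' @param n_nodes number of nodes, `>= 3`.
#' @param density fraction of possible edges, in (0, 1].
#' @param weights either `"uniform"` (weights ~ U(0.1, 1)) or a function
#'   `f(m)` returning `m` positive weights.
#' @param seed integer seed.
#' @export
make_random_connectome <- function(n_nodes, density = 0.5,
                                   weights = "uniform", seed = 1) {
  if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  m_all <- n_nodes * (n_nodes - 1) / 2
  m <- floor(density * m_all)
  if (m < 1) stop("density yields fewer than 1 edge", call. = FALSE)
  set.seed(seed)
  pick <- sort(sample.int(m_all, m))
  w <- if (identical(weights, "uniform")) stats::runif(m, 0.1, 1) else weights(m)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  W <- matrix(0, n_nodes, n_nodes)
  ut <- which(upper.tri(W))
  W[ut[pick]] <- w
  W <- W + t(W)
  dimnames(W) <- list(paste0("n", seq_len(n_nodes)), paste0("n", seq_len(n_nodes)))
  connectivity_matrix(W, thresholded = FALSE, normalized = FALSE)
}
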