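#' ROI specification for the perivascular-space index
#'
#' Rectangular voxel boxes for the projection, association and subcortical
#' fiber regions of one hemisphere. The three boxes must be pairwise
#' disjoint, and — matching the construction in which the three ROIs sit on
#' one mediolateral line in a single axial band — must share the same
#' z-range, so the selected voxels lie "on the same x-axis" row.
#'
#' @param projection,association,subcortical [vox_box()] objects.
#' @param laterality label, e.g. `"left"` or `"right"`.
#' @export
alps_roi_spec <- function(projection, association, subcortical = NULL,
                          laterality = "unspecified") {
  boxes <- list(projection = projection, association = association)
  if (!is.null(subcortical)) boxes$subcortical <- subcortical
  for (nm in names(boxes)) {
    if (!inherits(boxes[[nm]], "vox_box")) {
      stop(nm, " must be a vox_box", call. = FALSE)
    }
  }
  zr <- vapply(boxes, function(b) b$z, integer(2))
  if (any(zr[1, ] != zr[1, 1]) || any(zr[2, ] != zr[2, 1])) {
    stop("all ROI boxes must share the same z-range (same axial band)",
         call. = FALSE)
  }
  nb <- names(boxes)
  for (i in seq_along(boxes)[-1]) for (j in seq_len(i - 1)) {
    if (boxes_overlap(boxes[[i]], boxes[[j]])) {
      stop("ROI boxes overlap: ", nb[i], " and ", nb[j], call. = FALSE)
    }
  }
  structure(c(boxes, list(laterality = laterality)), class = "alps_roi_spec")
}

#' Dominant diffusion axis of a voxel
#'
#' The scanner axis (x, y or z) onto which the principal eigenvector has
#' the largest absolute projection; ties are broken in the fixed order
#' x < y < z.
#'
#' @param tf a [tensor_field].
#' @param vox 0-based voxel index triple.
#' @return `"x"`, `"y"` or `"z"`.
#' @export
dominant_axis <- function(tf, vox) {
  dm <- tf$geometry$dim
  if (any(vox < 0) || any(vox >= dm)) {
    stop("voxel out of grid: ", paste(vox, collapse = ","), call. = FALSE)
  }
  li <- voxel_linear(vox, dm)
  if (!as.vector(tf$mask)[li]) {
    stop("voxel is invalid (outside fit mask)", call. = FALSE)
  }
  E <- array(tf$evecs, dim = c(prod(dm), 3, 3))
  e1 <- abs(E[li, , 1])
  c("x", "y", "z")[which.max(e1)]  # which.max keeps first => x < y < z
}

# vectorised dominant axis + alignment for a set of linear indices
dominant_axis_bulk <- function(tf, lin_idx) {
  E <- array(tf$evecs, dim = c(prod(tf$geometry$dim), 3, 3))
  a <- abs(E[lin_idx, , 1, drop = FALSE])
  a <- matrix(a, ncol = 3)
  ax <- max.col(a, ties.method = "first")
  list(axis = ax, align = a[cbind(seq_along(ax), ax)])
}

#' Select the representative fiber voxel of an ROI
#'
#' Implements the "most frequent orientation" rule: (1) compute the modal
#' dominant axis over the ROI's voxels; (2) among the voxels attaining the
#' mode, return the one whose principal eigenvector is most aligned with
#' that axis (largest `|e1 . axis|`), breaking ties lexicographically by
#' 0-based voxel index (x, then y, then z).
#'
#' @param tf a [tensor_field].
#' @param box a [vox_box()] ROI.
#' @return list with `vox` (0-based triple), `axis` (modal axis label) and
#'   `align` (the winning alignment).
#' @export
select_fiber_voxel <- function(tf, box) {
  dm <- tf$geometry$dim
  if (!box_in_grid(box, dm)) stop("ROI box outside the grid", call. = FALSE)
  rg <- box_ranges(box)
  # voxels in lexicographic (x, y, z) order, 0-based
  grid <- expand.grid(x = rg$x - 1L, y = rg$y - 1L, z = rg$z - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$x, grid$y, grid$z), , drop = FALSE]
  if (nrow(grid) == 0) stop("empty ROI", call. = FALSE)
  lin <- 1L + grid$x + dm[1] * (grid$y + dm[2] * grid$z)
  keep <- as.vector(tf$mask)[lin]
  if (!any(keep)) stop("no valid voxel in ROI", call. = FALSE)
  grid <- grid[keep, , drop = FALSE]
  lin <- lin[keep]
  da <- dominant_axis_bulk(tf, lin)
  counts <- tabulate(da$axis, nbins = 3)
  modal <- which.max(counts)  # ties x < y < z
  cand <- which(da$axis == modal)
  stopifnot(length(cand) > 0)
  best <- cand[which.max(da$align[cand])]  # strict >, keeps lexicographic first
  list(vox = as.integer(grid[best, ]),
       axis = c("x", "y", "z")[modal],
       align = da$align[best])
}

#' Perivascular-space diffusivity index
#'
#' `index = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`:
#' the ratio of diffusivity along the perivascular (left-right) axis in the
#' projection and association fiber voxels to the diffusivity perpendicular
#' to both the fibers and the perivascular spaces.
#'
#' @param dxx_proj,dxx_assoc x-axis diffusivities in the projection and
#'   association voxels.
#' @param dyy_proj y-axis diffusivity in the projection voxel.
#' @param dzz_assoc z-axis diffusivity in the association voxel.
#' @return the unitless index.
#' @export
compute_alps <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  v <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all four diffusivities must be positive", call. = FALSE)
  }
  mean(c(dxx_proj, dxx_assoc)) / mean(c(dyy_proj, dzz_assoc))
}

# one hemisphere
alps_one <- function(tf, roi) {
  sp <- select_fiber_voxel(tf, roi$projection)
  sa <- select_fiber_voxel(tf, roi$association)
  ss <- if (!is.null(roi$subcortical)) select_fiber_voxel(tf, roi$subcortical)
  Dp <- tensor_at(tf, sp$vox)
  Da <- tensor_at(tf, sa$vox)
  idx <- compute_alps(Dp["Dxx"], Da["Dxx"], Dp["Dyy"], Da["Dzz"])
  structure(list(
    index = unname(idx),
    dxx_proj = unname(Dp["Dxx"]), dxx_assoc = unname(Da["Dxx"]),
    dyy_proj = unname(Dp["Dyy"]), dzz_assoc = unname(Da["Dzz"]),
    voxel_projection = sp$vox, voxel_association = sa$vox,
    voxel_subcortical = if (!is.null(ss)) ss$vox,
    axis_projection = sp$axis, axis_association = sa$axis,
    axis_subcortical = if (!is.null(ss)) ss$axis,
    laterality = roi$laterality
  ), class = "alps_measurement")
}

#' Run the perivascular-space index pipeline on a tensor field
#'
#' Selects one voxel per fiber ROI by modal dominant orientation, extracts
#' the scanner-frame tensor elements Dxx (projection and association), Dyy
#' (projection) and Dzz (association), and forms the index. The subcortical
#' ROI, when given, is selected and reported but does not enter the
#' formula. With a list of hemisphere specs (e.g. the bilateral default),
#' per-hemisphere measurements are computed and the reported index is
#' their mean.
#'
#' @param tf a [tensor_field].
#' @param roi_spec an [alps_roi_spec()] or a list of them (bilateral).
#' @return an `alps_measurement` (single spec) or `alps_bilateral` with
#'   per-hemisphere measurements and the averaged `index`.
#' @export
alps_pipeline <- function(tf, roi_spec) {
  stopifnot(inherits(tf, "tensor_field"))
  if (inherits(roi_spec, "alps_roi_spec")) return(alps_one(tf, roi_spec))
  stopifnot(is.list(roi_spec), length(roi_spec) >= 1)
  parts <- lapply(roi_spec, function(r) alps_one(tf, r))
  structure(list(
    index = mean(vapply(parts, function(p) p$index, numeric(1))),
    hemispheres = parts
  ), class = "alps_bilateral")
}

#' @export
print.alps_measurement <- function(x, ...) {
  cat(sprintf("<alps_measurement> index = %.4f (%s)\n", x$index, x$laterality))
  cat(sprintf("  Dxx proj %.4f | Dxx assoc %.4f | Dyy proj %.4f | Dzz assoc %.4f (1e-3 mm^2/s)\n",
              x$dxx_proj, x$dxx_assoc, x$dyy_proj, x$dzz_assoc))
  invisible(x)
}

#' @export
print.alps_bilateral <- function(x, ...) {
  cat(sprintf("<alps_bilateral> mean index = %.4f over %d hemisphere(s)\n",
              x$index, length(x$hemispheres)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn alps_pipeline tidy() returns the four diffusivities, the
#'   selected voxels and the index as a one-row tibble per hemisphere.
#' @param x an `alps_measurement` or `alps_bilateral`.
#' @param ... unused.
#' @export
tidy.alps_measurement <- function(x, ...) {
  tibble::tibble(
    laterality = x$laterality,
    dxx_proj = x$dxx_proj, dxx_assoc = x$dxx_assoc,
    dyy_proj = x$dyy_proj, dzz_assoc = x$dzz_assoc,
    vox_proj = paste(x$voxel_projection, collapse = ","),
    vox_assoc = paste(x$voxel_association, collapse = ","),
    axis_proj = x$axis_projection, axis_assoc = x$axis_association,
    index = x$index
  )
}

#' @export
tidy.alps_bilateral <- function(x, ...) {
  dplyr::bind_rows(lapply(x$hemispheres, tidy))
}

#' @export
glance.alps_bilateral <- function(x, ...) {
  tibble::tibble(index = x$index, n_hemispheres = length(x$hemispheres))
}

#' @export
glance.alps_measurement <- function(x, ...) {
  tibble::tibble(index = x$index, n_hemispheres = 1L)
}
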