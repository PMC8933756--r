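#' Volume geometry
#'
#' Grid shape and voxel size of an image volume. The axis convention is
#' fixed throughout the package and recorded as metadata:
#' x = left-right, y = anterior-posterior, z = head-foot (the orientation
#' the perivascular-space index construction assumes for an axial
#' acquisition aligned to scanner axes). Voxel indices are 0-based and
#' world coordinates are in mm from the grid origin corner.
#'
#' @param dim integer vector (nx, ny, nz).
#' @param voxel_mm numeric vector of voxel edge lengths in mm (length 1 or 3).
#' @param axes axis convention label.
#' @export
volume_geometry <- function(dim, voxel_mm = 2,
                            axes = "x=LR, y=AP, z=HF") {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) {
    stop("`dim` must be three integers >= 1", call. = FALSE)
  }
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be 1 or 3 positive numbers", call. = FALSE)
  }
  structure(list(dim = dim, voxel_mm = voxel_mm, axes = axes),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry> ", paste(x$dim, collapse = " x "), " voxels @ ",
      paste(signif(x$voxel_mm, 4), collapse = " x "), " mm (", x$axes, ")\n",
      sep = "")
  invisible(x)
}

#' Diffusion-weighted volume
#'
#' A 4-D signal grid plus its gradient scheme and geometry; the raw input
#' of the pipeline.
#'
#' @param signal 4-D numeric array (nx, ny, nz, n_volumes).
#' @param scheme a [gradient_scheme()].
#' @param geometry a [volume_geometry()].
#' @export
dwi_volume <- function(signal, scheme, geometry) {
  if (length(dim(signal)) != 4) {
    stop("`signal` must be a 4-D array", call. = FALSE)
  }
  if (dim(signal)[4] != length(scheme$bvalues)) {
    stop("volume count (", dim(signal)[4], ") does not match gradient count (",
         length(scheme$bvalues), ")", call. = FALSE)
  }
  if (!all(dim(signal)[1:3] == geometry$dim)) {
    stop("signal grid does not match geometry dimensions", call. = FALSE)
  }
  structure(list(signal = signal, scheme = scheme, geometry = geometry),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("<dwi_volume> ", paste(dim(x$signal), collapse = " x "), "\n", sep = "")
  print(x$scheme)
  print(x$geometry)
  invisible(x)
}

#' Read a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' Reads a 4-D NIfTI volume together with FSL-dialect gradient tables:
#' `bval` is one whitespace-separated line of b-values, `bvec` is three
#' whitespace-separated rows (x, y, z components) with one column per
#' volume.
#'
#' @param path_nifti path to a 4-D `.nii`/`.nii.gz` file.
#' @param path_bval,path_bvec paths to the gradient table files.
#' @return a [dwi_volume()].
#' @export
read_dwi <- function(path_nifti, path_bval, path_bvec) {
  for (p in c(path_nifti, path_bval, path_bvec)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  img <- RNifti::readNifti(path_nifti)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # strip NIfTI attributes
  if (length(dim(arr)) != 4) {
    stop("NIfTI is not 4-D: ", path_nifti, call. = FALSE)
  }
  bval <- scan(path_bval, quiet = TRUE)
  bvec_rows <- readLines(path_bvec)
  bvec_rows <- bvec_rows[nzchar(trimws(bvec_rows))]
  if (length(bvec_rows) != 3) {
    stop("bvec must have exactly 3 rows (FSL dialect), got ",
         length(bvec_rows), call. = FALSE)
  }
  bvec <- t(vapply(bvec_rows,
                   function(l) scan(text = l, quiet = TRUE),
                   numeric(length(bval))))
  if (ncol(bvec) != length(bval)) {
    stop("bval/bvec column counts differ", call. = FALSE)
  }
  if (length(bval) != dim(arr)[4]) {
    stop("gradient table has ", length(bval), " entries but NIfTI has ",
         dim(arr)[4], " volumes", call. = FALSE)
  }
  scheme <- gradient_scheme(bval, t(bvec))
  if (sum(scheme$bvalues == 0) < 1) {
    stop("dataset has no b=0 volume", call. = FALSE)
  }
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  geom <- volume_geometry(dim(arr)[1:3], voxel_mm = pd[1:3])
  dwi_volume(arr, scheme, geom)
}

#' Write a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' Inverse of [read_dwi()]: signal values round-trip within float32 storage
#' precision and the gradient scheme round-trips exactly at the written
#' precision. b-values go on a single space-separated line; bvec as 3 rows.
#'
#' @param dwi a [dwi_volume()].
#' @param path_nifti,path_bval,path_bvec output paths.
#' @export
write_dwi <- function(dwi, path_nifti, path_bval, path_bvec) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (dim(dwi$signal)[4] < 1) stop("empty volume list", call. = FALSE)
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$geometry$voxel_mm, 1)  # 4th dim is volume index
  RNifti::writeNifti(img, path_nifti)
  writeLines(paste(format_num(dwi$scheme$bvalues), collapse = " "), path_bval)
  bvec <- t(dwi$scheme$directions)  # 3 x N
  writeLines(apply(bvec, 1, function(r) paste(format_num(r), collapse = " ")),
             path_bvec)
  invisible(c(path_nifti, path_bval, path_bvec))
}

format_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write / read an integer label volume
#' @param labels 3-D integer array.
#' @param geometry a [volume_geometry()].
#' @param path output path (.nii/.nii.gz).
#' @export
write_labels <- function(labels, geometry, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim = geometry$dim))
  RNifti::pixdim(img) <- geometry$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("label volume must be 3-D", call. = FALSE)
  list(labels = array(as.integer(round(arr)), dim = dim(arr)),
       geometry = volume_geometry(dim(arr), RNifti::pixdim(img)[1:3]))
}
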