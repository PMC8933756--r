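#' Diffusion gradient scheme
#'
#' Bundles the b-values and unit gradient directions of a diffusion
#' acquisition. Directions of b=0 volumes may be the zero vector; all
#' diffusion-weighted directions must be unit vectors (tolerance 1e-6).
#' Tensor fitting requires at least six unique non-b0 directions.
#'
#' @param bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @param directions numeric matrix with one row per volume and three
#'   columns (x, y, z components).
#' @return an object of class `gradient_scheme`.
#' @examples
#' sch <- default_scheme(n_dir = 32)
#' length(sch$bvalues)
#' @export
gradient_scheme <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (!is.numeric(directions) || ncol(directions) != 3) {
    stop("`directions` must be a numeric matrix with 3 columns", call. = FALSE)
  }
  if (nrow(directions) != length(bvalues)) {
    stop("lengths of `bvalues` and `directions` must match (",
         length(bvalues), " vs ", nrow(directions), ")", call. = FALSE)
  }
  if (any(bvalues < 0)) stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  dw <- bvalues > 0
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    stop("non-b0 directions must have unit norm (tolerance 1e-6)", call. = FALSE)
  }
  structure(list(bvalues = bvalues, directions = directions),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> ", length(x$bvalues), " volumes (",
      sum(x$bvalues == 0), " b=0, b_max = ", max(x$bvalues), " s/mm^2)\n",
      sep = "")
  invisible(x)
}

n_unique_directions <- function(scheme) {
  d <- scheme$directions[scheme$bvalues > 0, , drop = FALSE]
  if (nrow(d) == 0) return(0L)
  # antipodal pairs sense the same tensor: canonicalise sign
  flip <- d[, 1] < 0 | (d[, 1] == 0 & d[, 2] < 0) |
    (d[, 1] == 0 & d[, 2] == 0 & d[, 3] < 0)
  d[flip, ] <- -d[flip, , drop = FALSE]
  nrow(unique(round(d, 6)))
}

validate_scheme_for_fit <- function(scheme) {
  if (sum(scheme$bvalues == 0) < 1) {
    stop("gradient scheme has no b=0 volume", call. = FALSE)
  }
  if (n_unique_directions(scheme) < 6) {
    stop("tensor fitting needs >= 6 unique non-b0 directions, got ",
         n_unique_directions(scheme), call. = FALSE)
  }
  invisible(scheme)
}

#' Default 32-direction b=1000 scheme
#'
#' Emulates a single-shell 32-direction acquisition at b = 1000 s/mm^2 with
#' one leading b=0 volume. Directions are placed on a deterministic Fibonacci
#' hemisphere, a standard quasi-uniform layout.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param bvalue shell b-value in s/mm^2.
#' @param n_b0 number of leading b=0 volumes.
#' @export
default_scheme <- function(n_dir = 32, bvalue = 1000, n_b0 = 1) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  # hemisphere: z from 0..1 (antipodal symmetry of diffusion encoding)
  z <- i / n_dir
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_scheme(
    bvalues = c(rep(0, n_b0), rep(bvalue, n_dir)),
    directions = rbind(matrix(0, n_b0, 3), dirs)
  )
}

# design matrix mapping the 6 lower-triangle tensor elements
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) to b * g' D g, one row per volume
tensor_design_matrix <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(
    b * g[, 1]^2,         # Dxx
    b * 2 * g[, 1] * g[, 2], # Dxy
    b * g[, 2]^2,         # Dyy
    b * 2 * g[, 1] * g[, 3], # Dxz
    b * 2 * g[, 2] * g[, 3], # Dyz
    b * g[, 3]^2          # Dzz
  )
}
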