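#' Deterministic streamline tractography (principal-eigenvector following)
#'
#' FACT-style fiber tracking on a fitted tensor field: seeds are drawn
#' uniformly inside the FA > `stop_fa` mask, then followed bidirectionally
#' along the principal eigenvector looked up at the nearest voxel, with a
#' fixed step. A streamline terminates when it leaves the grid or the FA
#' mask, or when the turning angle between consecutive steps exceeds
#' `angle_deg`. Streamlines shorter than `min_length_mm` are discarded.
#'
#' Defaults mirror a whole-brain-seeded deterministic protocol: 10,000
#' seeds, 60 degree angular threshold, 30 mm minimum length, step equal to
#' half the smallest voxel dimension, stopping FA 0.15.
#'
#' @param tf a [tensor_field].
#' @param n_seeds number of seed points.
#' @param step_mm step size in mm; default half the minimum voxel size.
#' @param angle_deg angular threshold in degrees.
#' @param min_length_mm minimum retained streamline length in mm.
#' @param stop_fa FA stopping threshold (also defines the seed mask).
#' @param seed integer seed for seed placement.
#' @return a `tractogram`: list of world-coordinate polylines (mm), their
#'   lengths, and the tracking parameters.
#' @export
track <- function(tf, n_seeds = 10000, step_mm = NULL, angle_deg = 60,
                  min_length_mm = 30, stop_fa = 0.15, seed = 1) {
  stopifnot(inherits(tf, "tensor_field"))
  if (any(c(n_seeds, angle_deg, min_length_mm, stop_fa) <= 0)) {
    stop("tracking parameters must be positive", call. = FALSE)
  }
  geom <- tf$geometry
  dm <- geom$dim
  vox <- geom$voxel_mm
  if (is.null(step_mm)) step_mm <- min(vox) / 2
  maps <- scalar_maps(tf)
  mask <- as.vector(maps$fa > stop_fa & tf$mask)
  if (!any(mask)) stop("empty seeding mask (no voxel with FA > stop_fa)",
                       call. = FALSE)
  E1 <- matrix(array(tf$evecs, dim = c(prod(dm), 3, 3))[, , 1], ncol = 3)
  cos_thr <- cos(angle_deg * pi / 180)

  set.seed(seed)
  mask_idx <- which(mask)
  pick <- mask_idx[sample.int(length(mask_idx), n_seeds, replace = TRUE)]
  # 0-based voxel triples of the picked linear indices
  v0 <- pick - 1L
  vx <- v0 %% dm[1]
  vy <- (v0 %/% dm[1]) %% dm[2]
  vz <- v0 %/% (dm[1] * dm[2])
  u <- matrix(stats::runif(3 * n_seeds), ncol = 3)
  pos0 <- cbind((vx + u[, 1]) * vox[1], (vy + u[, 2]) * vox[2],
                (vz + u[, 3]) * vox[3])
  dir0 <- E1[pick, , drop = FALSE]

  max_steps <- ceiling(sqrt(sum((dm * vox)^2)) / step_mm) + 8L

  march <- function(pos, dir) {
    n <- nrow(pos)
    alive <- rep(TRUE, n)
    pts <- vector("list", max_steps)
    ids <- vector("list", max_steps)
    t <- 0L
    while (any(alive) && t < max_steps) {
      t <- t + 1L
      ia <- which(alive)
      p <- pos[ia, , drop = FALSE] + step_mm * dir[ia, , drop = FALSE]
      w <- cbind(floor(p[, 1] / vox[1]), floor(p[, 2] / vox[2]),
                 floor(p[, 3] / vox[3]))
      inside <- w[, 1] >= 0 & w[, 1] < dm[1] &
        w[, 2] >= 0 & w[, 2] < dm[2] & w[, 3] >= 0 & w[, 3] < dm[3]
      lin <- rep(NA_integer_, length(ia))
      lin[inside] <- 1L + w[inside, 1] + dm[1] * (w[inside, 2] + dm[2] * w[inside, 3])
      ok <- inside & mask[ifelse(is.na(lin), 1L, lin)]
      e1 <- matrix(0, length(ia), 3)
      e1[ok, ] <- E1[lin[ok], , drop = FALSE]
      dt <- rowSums(e1 * dir[ia, , drop = FALSE])
      flip <- dt < 0
      e1[flip, ] <- -e1[flip, , drop = FALSE]
      ok <- ok & abs(dt) >= cos_thr
      keep <- ia[ok]
      pos[keep, ] <- p[ok, , drop = FALSE]
      dir[keep, ] <- e1[ok, , drop = FALSE]
      alive[ia[!ok]] <- FALSE
      pts[[t]] <- p[ok, , drop = FALSE]
      ids[[t]] <- keep
    }
    list(pts = do.call(rbind, pts), ids = unlist(ids),
         step_no = rep(seq_len(t), vapply(ids[seq_len(t)], length, integer(1))))
  }

  fwd <- march(pos0, dir0)
  bwd <- march(pos0, -dir0)

  collect <- function(m, n) {
    out <- vector("list", n)
    if (is.null(m$pts) || length(m$ids) == 0) return(out)
    ord <- order(m$ids, m$step_no)
    split_rows <- split(ord, m$ids[ord])
    for (nm in names(split_rows)) {
      out[[as.integer(nm)]] <- m$pts[split_rows[[nm]], , drop = FALSE]
    }
    out
  }
  fpts <- collect(fwd, n_seeds)
  bpts <- collect(bwd, n_seeds)

  streamlines <- vector("list", n_seeds)
  lengths <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    b <- bpts[[i]]
    f <- fpts[[i]]
    sl <- rbind(if (!is.null(b)) b[rev(seq_len(nrow(b))), , drop = FALSE],
                pos0[i, , drop = FALSE], f)
    streamlines[[i]] <- sl
    lengths[i] <- (nrow(sl) - 1) * step_mm
  }
  retain <- lengths >= min_length_mm
  structure(list(
    streamlines = streamlines[retain],
    lengths = lengths[retain],
    step_mm = step_mm,
    n_seeds = n_seeds,
    n_retained = sum(retain),
    params = list(angle_deg = angle_deg, min_length_mm = min_length_mm,
                  stop_fa = stop_fa, seed = seed),
    geometry = geom
  ), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", x$n_retained, "/", x$n_seeds,
      " streamlines retained (step ", signif(x$step_mm, 3), " mm, min ",
      x$params$min_length_mm, " mm)\n", sep = "")
  invisible(x)
}

#' Voxels visited by at least one retained streamline
#' @param tract a [track()] result.
#' @return logical 3-D array over the tracking grid.
#' @export
visited_mask <- function(tract) {
  dm <- tract$geometry$dim
  vox <- tract$geometry$voxel_mm
  out <- array(FALSE, dim = dm)
  if (length(tract$streamlines) == 0) return(out)
  pts <- do.call(rbind, tract$streamlines)
  w <- cbind(floor(pts[, 1] / vox[1]), floor(pts[, 2] / vox[2]),
             floor(pts[, 3] / vox[3]))
  keep <- w[, 1] >= 0 & w[, 1] < dm[1] & w[, 2] >= 0 & w[, 2] < dm[2] &
    w[, 3] >= 0 & w[, 3] < dm[3]
  w <- w[keep, , drop = FALSE]
  out[unique(1L + w[, 1] + dm[1] * (w[, 2] + dm[2] * w[, 3]))] <- TRUE
  out
}

#' Write / read a tractogram as a plain-text polyline file
#'
#' Line 1: number of streamlines. Then for each streamline a line with its
#' point count followed by that many `x y z` lines (mm, full precision).
#'
#' @param tract a [track()] result.
#' @param path output path.
#' @export
write_tractogram <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(tract$streamlines)), con)
  for (sl in tract$streamlines) {
    writeLines(as.character(nrow(sl)), con)
    writeLines(apply(sl, 1, function(p) paste(format_num(p), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_tractogram
#' @param step_mm step size recorded with the re-read tractogram.
#' @param geometry the tracking grid geometry.
#' @export
read_tractogram <- function(path, step_mm, geometry) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  sls <- vector("list", n)
  cur <- 2L
  for (i in seq_len(n)) {
    k <- as.integer(lines[cur]); cur <- cur + 1L
    m <- matrix(scan(text = lines[cur:(cur + k - 1L)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
    sls[[i]] <- m
    cur <- cur + k
  }
  lengths <- vapply(sls, function(s) (nrow(s) - 1) * step_mm, numeric(1))
  structure(list(streamlines = sls, lengths = lengths, step_mm = step_mm,
                 n_seeds = NA_integer_, n_retained = n,
                 params = list(), geometry = geometry),
            class = "tractogram")
}
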