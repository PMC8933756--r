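test_that("dominant axis is the argmax component with x<y<z tie-break", {
  # e1 = z, e1 = tie between x and y, e1 strictly largest on y
  make_e1_field <- function(e1s) {
    # rank-one tensors whose principal eigenvector is the given e1
    field_from_tensors(lapply(e1s, function(e) {
      e <- e / sqrt(sum(e^2))
      1.4 * tcrossprod(e) + 0.1 * diag(3)
    }))
  }
  tf <- make_e1_field(list(c(0, 0, 1), c(1, 1, 0) / sqrt(2), c(0.3, 0.9, 0.1)))
  expect_equal(dominant_axis(tf, c(0, 0, 0)), "z")
  # exact tie (bitwise-equal |x| and |y| components) -> x by the fixed order
  tf$evecs[2, 1, 1, , 1] <- c(1, 1, 0) / sqrt(2)
  expect_equal(dominant_axis(tf, c(1, 0, 0)), "x")
  expect_equal(dominant_axis(tf, c(2, 0, 0)), "y")
  expect_error(dominant_axis(tf, c(5, 0, 0)), "out of grid")

  # brute-force argmax oracle on random unit vectors
  set.seed(21)
  e1s <- lapply(1:20, function(i) {
    v <- rnorm(3); v / sqrt(sum(v^2))
  })
  tf2 <- make_e1_field(e1s)
  for (i in seq_along(e1s)) {
    expect_equal(dominant_axis(tf2, c(i - 1, 0, 0)),
                 c("x", "y", "z")[which.max(abs(e1s[[i]]))])
  }
})

test_that("fiber-voxel selection follows the modal-orientation rule", {
  ph <- default_phantom()
  roi <- ph$roi_spec$left
  sel <- select_fiber_voxel(ph$tensor_field, roi$projection)
  expect_equal(sel$axis, "z")
  # uniform field: lexicographically first voxel of the box
  expect_equal(sel$vox, c(5, 10, 5))
  expect_equal(select_fiber_voxel(ph$tensor_field, roi$association)$axis, "y")
  expect_equal(select_fiber_voxel(ph$tensor_field, roi$subcortical)$axis, "x")

  # constructed 9-voxel box: 6 z-dominant, 3 y-dominant -> a z voxel wins
  e1s <- c(replicate(3, c(0, 0.2, 0.95), simplify = FALSE),
           replicate(3, c(0, 0.9, 0.3), simplify = FALSE),
           replicate(3, c(0, 0.1, 0.99), simplify = FALSE))
  tf <- field_from_tensors(lapply(e1s, function(e) {
    e <- e / sqrt(sum(e^2)); 1.4 * tcrossprod(e) + 0.1 * diag(3)
  }))
  sel2 <- select_fiber_voxel(tf, vox_box(c(0, 9), c(0, 1), c(0, 1)))
  expect_equal(sel2$axis, "z")
  # most aligned z voxel is among indices 6..8 (|e1_z| largest there)
  expect_true(sel2$vox[1] %in% 6:8)
  expect_error(select_fiber_voxel(tf, vox_box(c(0, 9), c(0, 1), c(5, 6))),
               "outside the grid")
})

test_that("the index formula and its guards match hand arithmetic", {
  expect_equal(compute_alps(1, 1, 1, 1), 1)
  expect_equal(compute_alps(1.2, 1.0, 0.6, 0.5), 2)
  c0 <- compute_alps(0.6, 0.55, 0.42, 0.38)
  expect_equal(compute_alps(3 * 0.6, 3 * 0.55, 3 * 0.42, 3 * 0.38), c0)
  expect_error(compute_alps(0, 1, 1, 1), "positive")
  expect_error(compute_alps(1, 1, -0.1, 1), "positive")
})

test_that("ROI specs enforce the shared axial band and disjointness", {
  b1 <- vox_box(c(0, 2), c(0, 2), c(0, 2))
  b2 <- vox_box(c(3, 5), c(0, 2), c(0, 3))
  expect_error(alps_roi_spec(b1, b2), "same z-range")
  b3 <- vox_box(c(1, 3), c(0, 2), c(0, 2))
  expect_error(alps_roi_spec(b1, b3), "overlap")
  expect_s3_class(alps_roi_spec(b1, vox_box(c(3, 5), c(0, 2), c(0, 2))),
                  "alps_roi_spec")
})

test_that("pipeline recovers phantom truth and is symmetric across hemispheres", {
  ph <- default_phantom()
  res <- alps_pipeline(ph$tensor_field, ph$roi_spec)
  expect_equal(res$index, ph$truth_alps, tolerance = 1e-12)
  # mirror-symmetric phantom: identical left and right indices
  expect_equal(res$hemispheres[[1]]$index, res$hemispheres[[2]]$index,
               tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(td$axis_proj, c("z", "z"))
  expect_equal(td$axis_assoc, c("y", "y"))
  expect_equal(glance(res)$index, res$index)
})

test_that("index is 1 on isotropic fields for any ROI placement", {
  geom <- volume_geometry(c(12, 12, 6), 2)
  tf <- make_phantom(list(), geom, background_adc = 0.8)
  placements <- list(
    alps_roi_spec(vox_box(c(0, 3), c(0, 3), c(0, 2)),
                  vox_box(c(4, 7), c(0, 3), c(0, 2))),
    alps_roi_spec(vox_box(c(6, 9), c(5, 9), c(3, 5)),
                  vox_box(c(1, 4), c(5, 9), c(3, 5)))
  )
  for (roi in placements) {
    expect_equal(alps_pipeline(tf, roi)$index, 1, tolerance = 1e-9)
  }
})

test_that("index increases strictly with the perivascular boost g", {
  gs <- seq(0, 0.5, by = 0.1)
  idx <- vapply(gs, function(g) {
    ph <- default_phantom(g = g)
    alps_pipeline(ph$tensor_field, ph$roi_spec)$index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
  expect_equal(idx, (0.4 + gs) / 0.4, tolerance = 1e-12)
})

test_that("index is invariant to uniform scaling of the tensor field", {
  ph <- default_phantom()
  tf2 <- tensor_field(ph$tensor_field$lower * 3.7, ph$geometry)
  expect_equal(alps_pipeline(tf2, ph$roi_spec)$index,
               alps_pipeline(ph$tensor_field, ph$roi_spec)$index,
               tolerance = 1e-12)
})

test_that("index is robust to measurement noise on the default phantom", {
  ph <- default_phantom()
  sch <- default_scheme()
  run_reps <- function(snr, n) {
    vapply(seq_len(n), function(s) {
      dwi <- simulate_dwi(ph$tensor_field, sch, snr = snr, seed = s)
      alps_pipeline(fit_tensor(dwi), ph$roi_spec)$index
    }, numeric(1))
  }
  # snr 50: coefficient of variation < 5%, and no systematic bias
  idx50 <- run_reps(50, 200)
  expect_lt(stats::sd(idx50) / mean(idx50), 0.05)
  expect_equal(mean(idx50), ph$truth_alps, tolerance = 0.02)
})
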