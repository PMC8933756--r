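test_that("noiseless fit recovers a known diagonal tensor to 1e-8", {
  tensors <- list(diag(c(1.7, 0.3, 0.3)))
  tf <- field_from_tensors(tensors)
  dwi <- simulate_dwi(tf, default_scheme(), snr = Inf)
  fit <- fit_tensor(dwi)
  D <- lower_to_mat(alpsdti:::tensor_at(fit, c(0, 0, 0)))
  expect_lt(max(abs(D - tensors[[1]])) / max(abs(tensors[[1]])), 1e-8)
  ev <- fit$evals[1, 1, 1, ]
  expect_equal(ev, c(1.7, 0.3, 0.3), tolerance = 1e-8)
})

test_that("noiseless isotropic voxel fits to equal eigenvalues and FA ~ 0", {
  tf <- field_from_tensors(list(diag(c(0.8, 0.8, 0.8))))
  fit <- fit_tensor(simulate_dwi(tf, default_scheme(), snr = Inf))
  ev <- fit$evals[1, 1, 1, ]
  expect_lt(max(abs(ev - 0.8)), 1e-8)
  expect_lt(scalar_maps(fit)$fa[1, 1, 1], 1e-6)
})

test_that("fit rejects underdetermined schemes and flags dead voxels", {
  tf <- field_from_tensors(list(diag(c(1, 1, 1))))
  dwi <- simulate_dwi(tf, default_scheme(n_dir = 5), snr = Inf)
  expect_error(fit_tensor(dwi), ">= 6")

  tf2 <- field_from_tensors(list(diag(c(1, 1, 1)), diag(c(1, 1, 1))))
  dwi2 <- simulate_dwi(tf2, default_scheme(), snr = Inf)
  dwi2$signal[2, 1, 1, ] <- 0  # all-zero voxel: invalid, not fatal
  fit <- fit_tensor(dwi2)
  expect_true(fit$mask[1, 1, 1])
  expect_false(fit$mask[2, 1, 1])
})

test_that("fit is equivariant under joint rotation of scheme and tensor", {
  set.seed(42)
  for (rep in 1:5) {
    D <- random_spd_mat()
    R <- random_rotation()
    Dr <- R %*% D %*% t(R)
    sch <- default_scheme()
    sch_r <- gradient_scheme(sch$bvalues, sch$directions %*% t(R))
    s1 <- simulate_dwi(field_from_tensors(list(D)), sch, snr = Inf)
    s2 <- simulate_dwi(field_from_tensors(list(Dr)), sch_r, snr = Inf)
    expect_equal(s1$signal, s2$signal, tolerance = 1e-12)
    fit <- fit_tensor(simulate_dwi(field_from_tensors(list(Dr)), sch,
                                   snr = Inf))
    Dhat <- lower_to_mat(alpsdti:::tensor_at(fit, c(0, 0, 0)))
    expect_lt(max(abs(Dhat - Dr)) / max(abs(Dr)), 1e-8)
  }
})

test_that("scalar maps match their closed forms", {
  # isotropy, stick limit, and a generic triple evaluated independently
  tf <- field_from_tensors(list(diag(c(1, 1, 1)),
                                diag(c(1, 1e-12, 1e-12)),
                                diag(c(1.7, 0.3, 0.2))))
  m <- scalar_maps(tf)
  expect_equal(m$fa[1, 1, 1], 0)
  expect_equal(m$md[1, 1, 1], 1)
  expect_equal(m$ad[1, 1, 1], 1)
  expect_equal(m$rd[1, 1, 1], 1)

  expect_equal(m$fa[2, 1, 1], 1, tolerance = 1e-9)
  expect_equal(m$md[2, 1, 1], 1 / 3, tolerance = 1e-9)
  expect_equal(m$rd[2, 1, 1], 0, tolerance = 1e-9)

  l <- c(1.7, 0.3, 0.2)
  fa_direct <- sqrt(0.5) *
    sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
    sqrt(sum(l^2))
  expect_equal(m$fa[3, 1, 1], fa_direct)
  expect_equal(m$md[3, 1, 1], mean(l))
  expect_equal(m$ad[3, 1, 1], 1.7)
  expect_equal(m$rd[3, 1, 1], 0.25)
  # map invariants
  expect_true(all(m$fa >= 0 & m$fa <= 1))
  expect_true(all(m$ad >= m$md - 1e-12 & m$md >= m$rd - 1e-12))
})

test_that("FA is scale-invariant, MD/AD/RD scale linearly", {
  set.seed(7)
  tensors <- replicate(10, random_spd_mat(), simplify = FALSE)
  tf1 <- field_from_tensors(tensors)
  tf2 <- field_from_tensors(lapply(tensors, function(D) 2.5 * D))
  m1 <- scalar_maps(tf1); m2 <- scalar_maps(tf2)
  expect_equal(m2$fa, m1$fa, tolerance = 1e-12)
  expect_equal(m2$md, 2.5 * m1$md, tolerance = 1e-12)
  expect_equal(m2$ad, 2.5 * m1$ad, tolerance = 1e-12)
  expect_equal(m2$rd, 2.5 * m1$rd, tolerance = 1e-12)
})

test_that("eigenvectors are orthonormal and eigenvalues sorted", {
  set.seed(8)
  tf <- field_from_tensors(replicate(20, random_spd_mat(), simplify = FALSE))
  E <- array(tf$evecs, dim = c(20, 3, 3))
  for (i in 1:20) {
    V <- matrix(E[i, , ], 3, 3)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-6)
    ev <- matrix(tf$evals, ncol = 3)[i, ]
    expect_true(all(diff(ev) <= 0))
  }
})

test_that("global summary is the plain voxel mean over the mask", {
  ph <- default_phantom()
  maps <- scalar_maps(ph$tensor_field)
  mask <- array(FALSE, dim = ph$geometry$dim)
  mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
  gs <- global_summary(maps, mask, "two-voxel")
  expect_equal(gs$fa, mean(c(maps$fa[1, 1, 1], maps$fa[2, 1, 1])))
  expect_equal(gs$n_voxels, 2L)
  expect_error(global_summary(maps, array(FALSE, ph$geometry$dim)), "empty")

  # uniform map => summary equals the constant
  iso <- scalar_maps(field_from_tensors(list(diag(c(1, 1, 1)) * 0.8,
                                             diag(c(1, 1, 1)) * 0.8)))
  expect_equal(global_summary(iso, array(TRUE, c(2, 1, 1)))$md, 0.8)
})

test_that("streamline-visited summary mask equals a brute-force point count", {
  ph <- slab_phantom(extent_mm = 40)
  tf <- fit_tensor(simulate_dwi(ph, default_scheme(), snr = Inf))
  tr <- track(tf, n_seeds = 300, seed = 2)
  vm <- visited_mask(tr)
  # brute force: rasterise every point
  dm <- tf$geometry$dim; vox <- tf$geometry$voxel_mm
  ref <- array(FALSE, dm)
  for (sl in tr$streamlines) for (r in seq_len(nrow(sl))) {
    w <- floor(sl[r, ] / vox)
    if (all(w >= 0) && all(w < dm)) ref[w[1] + 1, w[2] + 1, w[3] + 1] <- TRUE
  }
  expect_identical(vm, ref)
  maps <- scalar_maps(tf)
  gs <- global_summary(maps, vm, "tract-visited")
  expect_equal(gs$fa, mean(maps$fa[ref]))
})
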