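label_line_geometry <- function() {
  # three parcels along x, one voxel each, 2 mm voxels
  geom <- volume_geometry(c(3, 1, 1), 2)
  labels <- array(c(1L, 2L, 3L), dim = geom$dim)
  list(geom = geom, labels = labels)
}

line_stream <- function(x0, x1) {
  # straight two-point streamline between voxel centres
  rbind(c(x0 * 2 + 1, 1, 1), c(x1 * 2 + 1, 1, 1))
}

test_that("endpoint counting, thresholding and normalization are as specified", {
  lg <- label_line_geometry()
  tr <- toy_tract(c(replicate(3, line_stream(0, 1), simplify = FALSE),
                    list(line_stream(1, 2))), lg$geom)
  cm <- build_matrix(tr, lg$labels)
  W <- cm$weights
  expect_equal(W[1, 2], 1)       # count 3, max-normalized
  expect_equal(W[2, 3], 1 / 3)   # count 1
  expect_equal(W, t(W))
  expect_true(cm$thresholded && cm$normalized)

  # an edge below 0.001 of the total sum is zeroed before normalization
  tr2 <- toy_tract(c(replicate(1500, line_stream(1, 2), simplify = FALSE),
                     list(line_stream(0, 1))), lg$geom)
  W2 <- build_matrix(tr2, lg$labels)$weights
  expect_equal(W2[1, 2], 0)
  expect_equal(W2[2, 3], 1)
})

test_that("off-parcel endpoints are ignored and counted; empty input is safe", {
  lg <- label_line_geometry()
  lab <- lg$labels; lab[3, 1, 1] <- 0L
  tr <- toy_tract(list(line_stream(0, 1), line_stream(1, 2)), lg$geom)
  cm <- build_matrix(tr, lab)
  expect_equal(cm$n_ignored, 1L)
  expect_equal(cm$weights[1, 2], 1)

  empty <- toy_tract(list(), lg$geom)
  cm0 <- build_matrix(empty, lg$labels)
  expect_true(all(cm0$weights == 0))
  expect_true(cm0$normalized)
})

test_that("connectivity matrices reject asymmetric or negative input", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(connectivity_matrix(m), "symmetric")
  expect_error(connectivity_matrix(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(graph_metrics(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("complete and path graphs match closed forms", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  gm <- graph_metrics(K5, n_null = 2, seed = 1)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$path_length, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$local_efficiency, 1)
  expect_equal(gm$diameter, 1)
  expect_equal(gm$radius, 1)

  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  gm3 <- graph_metrics(P3, n_null = 2, seed = 1)
  expect_equal(gm3$path_length, 4 / 3)  # brute-force all-pairs mean
  expect_equal(gm3$clustering, 0)
  expect_equal(gm3$diameter, 2)
  expect_equal(gm3$radius, 1)
})

test_that("ring lattice with equal strengths flags assortativity undefined", {
  n <- 6
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- 1
  }
  gm <- graph_metrics(W, n_null = 2, seed = 1)
  expect_true(is.na(gm$assortativity))
  expect_false(gm$assortativity_defined)
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  for (s in 1:50) {
    n <- sample(4:8, 1)
    W <- make_random_connectome(n, density = runif(1, 0.3, 0.9),
                                seed = 1000 + s)$weights
    D_oracle <- fw_dist(W)
    expect_equal(alpsdti:::length_distances(W), D_oracle,
                 tolerance = 1e-12, ignore_attr = TRUE)
    cl <- onnela_brute(W)
    gm <- graph_metrics(W, n_null = 2, seed = s)
    expect_equal(gm$clustering, cl$mean, tolerance = 1e-12)
    expect_equal(gm$transitivity, cl$transitivity, tolerance = 1e-12)
    off <- D_oracle[row(D_oracle) != col(D_oracle)]
    expect_equal(gm$path_length, mean(off[is.finite(off)]), tolerance = 1e-12)
    expect_equal(gm$global_efficiency,
                 mean(ifelse(is.finite(off), 1 / off, 0)), tolerance = 1e-12)
    a_oracle <- assortativity_brute(W)
    if (is.na(a_oracle)) {
      expect_false(gm$assortativity_defined)
    } else {
      expect_equal(gm$assortativity, a_oracle, tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  W <- make_random_connectome(10, 0.4, seed = 3)$weights
  gm <- graph_metrics(W, n_null = 5, seed = 9)
  for (s in 1:5) {
    set.seed(s)
    p <- sample(10)
    gm_p <- graph_metrics(W[p, p], n_null = 5, seed = 9)
    for (col in c("assortativity", "clustering", "path_length", "diameter",
                  "radius", "global_efficiency", "local_efficiency",
                  "transitivity")) {
      expect_equal(gm_p[[col]], gm[[col]], tolerance = 1e-10)
    }
  }
})

test_that("uniform weight scaling acts as expected on each metric", {
  W <- make_random_connectome(9, 0.5, seed = 4)$weights
  g1 <- graph_metrics(W, n_null = 10, seed = 2)
  g2 <- graph_metrics(4 * W, n_null = 10, seed = 2)
  expect_equal(g2$clustering, g1$clustering, tolerance = 1e-12)
  expect_equal(g2$transitivity, g1$transitivity, tolerance = 1e-12)
  expect_equal(g2$assortativity, g1$assortativity, tolerance = 1e-12)
  expect_equal(g2$path_length, g1$path_length / 4, tolerance = 1e-12)
  expect_equal(g2$small_worldness, g1$small_worldness, tolerance = 1e-12)
})

test_that("degree-preserving nulls keep every degree and seed-reproduce", {
  W <- make_random_connectome(12, 0.3, seed = 6)$weights
  deg <- rowSums(W > 0)
  set.seed(11)
  for (r in 1:10) {
    Wn <- alpsdti:::rewired_null(W)
    expect_identical(rowSums(Wn > 0), deg)
    # weight multiset preserved
    expect_equal(sort(Wn[upper.tri(Wn) & Wn > 0]),
                 sort(W[upper.tri(W) & W > 0]))
  }
  expect_identical(graph_metrics(W, n_null = 5, seed = 42),
                   graph_metrics(W, n_null = 5, seed = 42))
})
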