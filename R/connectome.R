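#' Weighted connectivity matrix
#'
#' Symmetric nonnegative node-by-node matrix of streamline counts (or
#' normalized weights) with a zero diagonal, plus flags recording whether
#' the sum-threshold and max-normalization steps have been applied.
#'
#' @param weights symmetric numeric matrix, zero diagonal, nonnegative.
#' @param thresholded,normalized processing flags.
#' @param n_ignored streamlines dropped because an endpoint fell outside
#'   every parcel.
#' @export
connectivity_matrix <- function(weights, thresholded = FALSE,
                                normalized = FALSE, n_ignored = 0L) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("matrix must be square", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  structure(list(weights = weights, thresholded = thresholded,
                 normalized = normalized, n_ignored = as.integer(n_ignored)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$weights), " nodes, ",
      sum(x$weights[upper.tri(x$weights)] > 0), " edges",
      if (x$thresholded) ", thresholded", if (x$normalized) ", normalized",
      "\n", sep = "")
  invisible(x)
}

#' Build the connectivity matrix from streamline endpoints
#'
#' Edge (i, j) counts the streamlines whose two extreme points fall in
#' parcels i and j (i != j). Entries below `threshold_frac` times the total
#' pre-threshold matrix sum are then zeroed, and the matrix is divided by
#' its maximum entry so the largest weight is one. Streamlines with an
#' endpoint outside every parcel (label 0) are ignored and counted.
#'
#' @param tract a [track()] result.
#' @param labels 3-D integer parcellation array on the tracking grid
#'   (0 = no parcel).
#' @param threshold_frac sum-fraction threshold applied to edge counts.
#' @return a [connectivity_matrix()].
#' @export
build_matrix <- function(tract, labels, threshold_frac = 0.001) {
  geom <- tract$geometry
  dm <- geom$dim
  if (!all(dim(labels) == dm)) {
    stop("label volume does not match the tracking grid", call. = FALSE)
  }
  vox <- geom$voxel_mm
  n_lab <- max(labels)
  if (n_lab < 1) stop("label volume has no parcels", call. = FALSE)
  label_at <- function(p) {
    w <- floor(p / vox)
    if (any(w < 0) || any(w >= dm)) return(0L)
    labels[w[1] + 1L, w[2] + 1L, w[3] + 1L]
  }
  W <- matrix(0, n_lab, n_lab)
  n_ignored <- 0L
  for (sl in tract$streamlines) {
    a <- label_at(sl[1, ])
    b <- label_at(sl[nrow(sl), ])
    if (a == 0L || b == 0L || a == b) {
      n_ignored <- n_ignored + 1L
      next
    }
    W[a, b] <- W[a, b] + 1
    W[b, a] <- W[b, a] + 1
  }
  total <- sum(W)
  if (total > 0) W[W < threshold_frac * total] <- 0
  mx <- max(W)
  if (mx > 0) W <- W / mx
  dimnames(W) <- list(paste0("n", seq_len(n_lab)), paste0("n", seq_len(n_lab)))
  connectivity_matrix(W, thresholded = TRUE, normalized = TRUE,
                      n_ignored = n_ignored)
}

as_weight_matrix <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$weights else as.matrix(x)
}

# Onnela per-node weighted clustering: geometric-mean triangle intensity,
# weights scaled by the matrix maximum; nodes with binary degree < 2 get 0
onnela_clustering <- function(W) {
  k <- rowSums(W > 0)
  mx <- max(W)
  if (mx == 0) return(list(node = rep(0, nrow(W)), transitivity = 0))
  Wh <- (W / mx)^(1 / 3)
  cyc <- diag(Wh %*% Wh %*% Wh)  # 2 * sum of triangle intensities per node
  denom <- k * (k - 1)
  node <- ifelse(denom > 0, cyc / denom, 0)
  trans <- if (sum(denom) > 0) sum(cyc) / sum(denom) else 0
  list(node = node, transitivity = trans)
}

weighted_graph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

# all-pairs shortest path matrix on edge lengths 1/weight
length_distances <- function(W) {
  if (all(W == 0)) {
    D <- matrix(Inf, nrow(W), ncol(W)); diag(D) <- 0
    return(D)
  }
  g <- weighted_graph(W)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

path_summaries <- function(W) {
  n <- nrow(W)
  D <- length_distances(W)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  cpl <- if (any(finite)) mean(off[finite]) else NA_real_
  geff <- if (n > 1) mean(ifelse(finite, 1 / off, 0)) else 0
  # eccentricities on the largest connected component
  g <- weighted_graph(W)
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) > 1) {
    Dc <- D[big, big, drop = FALSE]
    ecc <- apply(Dc, 1, max)
    radius <- min(ecc); diameter <- max(ecc)
  } else {
    radius <- 0; diameter <- 0
  }
  list(cpl = cpl, geff = geff, radius = radius, diameter = diameter,
       n_disconnected_pairs = sum(!finite))
}

local_efficiency <- function(W) {
  n <- nrow(W)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    Dn <- length_distances(W[nb, nb, drop = FALSE])
    off <- Dn[row(Dn) != col(Dn)]
    eff[i] <- mean(ifelse(is.finite(off), 1 / off, 0))
  }
  mean(eff)
}

# Pearson correlation of node strengths across edge endpoints (both
# orientations); NA with a flag when either side has zero variance
strength_assortativity <- function(W) {
  s <- rowSums(W)
  e <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(list(value = NA_real_, defined = FALSE))
  x <- c(s[e[, 1]], s[e[, 2]])
  y <- c(s[e[, 2]], s[e[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(value = NA_real_, defined = FALSE))
  }
  list(value = stats::cor(x, y), defined = TRUE)
}

# one Maslov-Sneppen null: degree-preserving rewire of the binary graph,
# original weights shuffled onto the rewired edges
rewired_null <- function(W, n_swap_per_edge = 10) {
  g <- weighted_graph(W)
  deg0 <- igraph::degree(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    niter = n_swap_per_edge * igraph::ecount(g)))
  stopifnot(all(igraph::degree(g2) == deg0))  # degree preservation, per rewire
  w <- sample(igraph::E(g)$weight)
  A <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  idx <- which(upper.tri(A) & A > 0)
  A[] <- 0
  A[idx] <- w
  A + t(A)
}

#' Global weighted graph measures of a connectome
#'
#' Computes the nine global network measures under the weighted
#' conventions standard for brain networks built on normalized connection
#' strengths:
#' * mean clustering coefficient and transitivity: Onnela geometric-mean
#'   triangle intensities (weights scaled by the matrix maximum);
#' * characteristic path length, diameter, radius, global efficiency:
#'   shortest paths on edge lengths `1/weight`; path length averages over
#'   connected ordered pairs, disconnected pairs contribute 0 to global
#'   efficiency, eccentricities are taken over the largest connected
#'   component;
#' * local efficiency: mean over nodes of the global efficiency of each
#'   node's neighborhood subgraph;
#' * assortative coefficient: Pearson correlation of node strengths across
#'   edge endpoints (flagged undefined when strength variance is zero);
#' * small-worldness: `(C / C_rand) / (L / L_rand)` against
#'   degree-preserving rewired nulls with weights shuffled onto the
#'   rewired edges.
#'
#' @param cm a [connectivity_matrix()] or plain symmetric matrix.
#' @param n_null number of rewired null networks for small-worldness.
#' @param n_swap_per_edge rewiring swaps per edge in each null.
#' @param seed integer seed for the null ensemble.
#' @return a one-row tibble with the nine measures plus
#'   `assortativity_defined`.
#' @export
graph_metrics <- function(cm, n_null = 20, n_swap_per_edge = 10, seed = 1) {
  W <- as_weight_matrix(cm)
  if (nrow(W) != ncol(W) || any(W < 0) ||
      max(abs(W - t(W))) > 1e-12) {
    stop("input must be a symmetric nonnegative matrix", call. = FALSE)
  }
  diag(W) <- 0
  cl <- onnela_clustering(W)
  C <- mean(cl$node)
  ps <- path_summaries(W)
  ass <- strength_assortativity(W)
  leff <- local_efficiency(W)

  sw <- NA_real_
  if (sum(W > 0) > 0 && is.finite(ps$cpl) && C > 0) {
    set.seed(seed)
    Cr <- Lr <- numeric(n_null)
    for (r in seq_len(n_null)) {
      Wn <- rewired_null(W, n_swap_per_edge)
      Cr[r] <- mean(onnela_clustering(Wn)$node)
      Lr[r] <- path_summaries(Wn)$cpl
    }
    Cbar <- mean(Cr); Lbar <- mean(Lr, na.rm = TRUE)
    if (Cbar > 0 && is.finite(Lbar) && Lbar > 0 && ps$cpl > 0) {
      sw <- (C / Cbar) / (ps$cpl / Lbar)
    }
  }

  tibble::tibble(
    assortativity = ass$value,
    assortativity_defined = ass$defined,
    clustering = C,
    path_length = ps$cpl,
    diameter = ps$diameter,
    radius = ps$radius,
    global_efficiency = ps$geff,
    local_efficiency = leff,
    small_worldness = sw,
    transitivity = cl$transitivity
  )
}

#' Write / read a connectivity matrix as CSV
#' @param cm a [connectivity_matrix()].
#' @param path output path.
#' @export
write_matrix_csv <- function(cm, path) {
  utils::write.csv(as_weight_matrix(cm), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  connectivity_matrix(m, thresholded = NA, normalized = NA)
}
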