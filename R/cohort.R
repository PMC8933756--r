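#' Marginal distribution specification helpers
#'
#' Marginals used by the cohort generator's Gaussian copula. Each is a
#' quantile transform applied to a correlated latent normal.
#' `marg_normal` keeps Pearson correlations of the latents exactly;
#' `marg_truncnorm`, `marg_lognormal` and `marg_poisson` preserve rank
#' correlation (used for strictly positive or count variables).
#'
#' @param mean,sd normal parameters.
#' @param lower truncation bound.
#' @param meanlog,sdlog log-normal parameters.
#' @param lambda Poisson rate.
#' @name marginals
#' @export
marg_normal <- function(mean, sd) list(q = function(u) stats::qnorm(u, mean, sd))

#' @rdname marginals
#' @export
marg_truncnorm <- function(mean, sd, lower = 1) {
  plo <- stats::pnorm(lower, mean, sd)
  list(q = function(u) stats::qnorm(plo + u * (1 - plo), mean, sd))
}

#' @rdname marginals
#' @export
marg_lognormal <- function(meanlog, sdlog) {
  list(q = function(u) stats::qlnorm(u, meanlog, sdlog))
}

#' @rdname marginals
#' @export
marg_poisson <- function(lambda) {
  list(q = function(u) stats::qpois(u, lambda), integer = TRUE)
}

graph_metric_names <- c("assortativity", "clustering", "path_length",
                        "diameter", "radius", "global_efficiency",
                        "local_efficiency", "small_worldness", "transitivity")

default_marginals <- function(alps_sd = 0.18) {
  list(
    patient = list(
      alps = marg_normal(1.67, alps_sd),
      age = marg_truncnorm(38.2, 19.0, lower = 1),
      onset_age = marg_truncnorm(35.5, 24, lower = 1),
      days_to_mri = marg_lognormal(log(105), 1.84),
      seizure_count = marg_poisson(2.5),
      fa = marg_normal(0.352, 0.048), md = marg_normal(0.882, 0.053),
      ad = marg_normal(1.212, 0.055), rd = marg_normal(0.716, 0.067),
      assortativity = marg_normal(0.124, 0.090),
      clustering = marg_normal(0.145, 0.088),
      path_length = marg_normal(4.072, 0.423),
      diameter = marg_normal(3.822, 0.607),
      radius = marg_normal(2.024, 0.337),
      global_efficiency = marg_normal(1.053, 0.273),
      local_efficiency = marg_normal(1.444, 0.558),
      small_worldness = marg_normal(0.124, 0.109),
      transitivity = marg_normal(0.159, 0.107)
    ),
    control = list(
      alps = marg_normal(1.68, alps_sd),
      age = marg_truncnorm(41.5, 16.6, lower = 1),
      fa = marg_normal(0.339, 0.012), md = marg_normal(0.874, 0.026),
      ad = marg_normal(1.190, 0.027), rd = marg_normal(0.720, 0.026),
      assortativity = marg_normal(0.123, 0.094),
      clustering = marg_normal(0.140, 0.082),
      path_length = marg_normal(4.210, 0.542),
      diameter = marg_normal(3.760, 0.528),
      radius = marg_normal(1.996, 0.342),
      global_efficiency = marg_normal(1.075, 0.307),
      local_efficiency = marg_normal(1.517, 0.621),
      small_worldness = marg_normal(0.122, 0.101),
      transitivity = marg_normal(0.159, 0.101)
    )
  )
}

default_alps_cor <- function() {
  list(
    patient = c(age = -0.242, onset_age = -0.239, days_to_mri = 0.002,
                seizure_count = -0.026, fa = 0.257, md = -0.469, ad = -0.303,
                rd = -0.434, assortativity = 0.230, clustering = -0.050,
                path_length = -0.013, diameter = 0.012, radius = 0.071,
                global_efficiency = 0.101, local_efficiency = 0.046,
                small_worldness = -0.018, transitivity = -0.010),
    control = c(age = -0.226, fa = 0.198, md = -0.369, ad = -0.245,
                rd = -0.344, assortativity = 0.183, clustering = -0.001,
                path_length = 0.018, diameter = 0.010, radius = 0.047,
                global_efficiency = 0.077, local_efficiency = 0.062,
                small_worldness = 0.027, transitivity = 0.026)
  )
}

# arrowhead correlation matrix: first variable correlated with each other
# variable, remaining off-diagonals zero
arrowhead_cor <- function(vars, alps_cor) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (v in names(alps_cor)) {
    if (v %in% vars) R["alps", v] <- R[v, "alps"] <- alps_cor[[v]]
  }
  R
}

check_psd <- function(R) {
  if (max(abs(R - t(R))) > 1e-12 || any(abs(diag(R) - 1) > 1e-12)) {
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(R)
}

#' Cohort generator specification
#'
#' Defines the two-group synthetic cohort: group sizes, per-variable
#' marginals (per group), the within-group correlation structure of each
#' variable with the perivascular-space index, and the male proportion.
#' Defaults are a patient group of 109 and a control group of 88 with
#' published-scale demographic, DTI, and graph-metric marginals, and the
#' reported index correlations imposed (other off-diagonals zero, giving a
#' positive-semidefinite arrowhead matrix).
#'
#' @param n_patients,n_controls group sizes, each `>= 3`.
#' @param male_prop named numeric, male proportion per group.
#' @param alps_cor list with `patient` and `control` named vectors of
#'   target correlations with the index; ignored when `cor_matrix` given.
#' @param cor_matrix optional list of full correlation matrices per group
#'   (rows/cols named by variables, must include `"alps"`).
#' @param marginals marginal list as produced by the package defaults.
#' @export
cohort_spec <- function(n_patients = 109, n_controls = 88,
                        male_prop = c(patient = 0.532, control = 0.534),
                        alps_cor = default_alps_cor(),
                        cor_matrix = NULL,
                        marginals = default_marginals()) {
  if (n_patients < 3 || n_controls < 3) {
    stop("group sizes must be >= 3", call. = FALSE)
  }
  spec <- list(n = c(patient = as.integer(n_patients),
                     control = as.integer(n_controls)),
               male_prop = male_prop, marginals = marginals)
  spec$cor <- lapply(stats::setNames(nm = c("patient", "control")), function(grp) {
    vars <- names(marginals[[grp]])
    R <- if (!is.null(cor_matrix)) {
      cor_matrix[[grp]][vars, vars]
    } else {
      arrowhead_cor(vars, alps_cor[[grp]])
    }
    check_psd(R)
  })
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Draws each group from a Gaussian copula: latent standard normals with
#' the target correlation matrix, transformed through the per-variable
#' marginal quantile functions. Sex is drawn Bernoulli at the specified
#' proportion; count variables are integer valued; patient-only fields are
#' `NA` for controls.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical seed and spec give an identical
#'   table.
#' @return a tibble, one row per subject.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  all_vars <- names(spec$marginals$patient)
  draw_group <- function(grp, prefix) {
    n <- spec$n[[grp]]
    marg <- spec$marginals[[grp]]
    vars <- names(marg)
    L <- chol(spec$cor[[grp]] + diag(1e-10, length(vars)))
    Z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
    U <- stats::pnorm(Z)
    cols <- lapply(seq_along(vars), function(j) {
      v <- marg[[j]]$q(U[, j])
      if (isTRUE(marg[[j]]$integer)) v <- as.integer(v)
      v
    })
    names(cols) <- vars
    out <- tibble::as_tibble(cols)
    for (v in setdiff(all_vars, vars)) out[[v]] <- NA_real_
    out$sex <- ifelse(stats::runif(n) < spec$male_prop[[grp]], "male", "female")
    out$id <- sprintf("%s%03d", prefix, seq_len(n))
    out$group <- grp
    out
  }
  cohort <- dplyr::bind_rows(draw_group("patient", "P"),
                             draw_group("control", "C"))
  cohort <- dplyr::select(cohort, "id", "group", "age", "sex",
                          "onset_age", "days_to_mri", "seizure_count",
                          "alps", "fa", "md", "ad", "rd",
                          dplyr::all_of(graph_metric_names))
  cohort$group <- factor(cohort$group, levels = c("patient", "control"))
  validate_cohort(cohort)
}

#' Validate a cohort table
#'
#' Checks the schema and invariants: unique ids, positive ages,
#' nonnegative counts, and patient-only fields absent for controls.
#'
#' @param cohort a cohort tibble.
#' @return the cohort, invisibly validated.
#' @export
validate_cohort <- function(cohort) {
  need <- c("id", "group", "age", "sex", "alps", "fa", "md", "ad", "rd",
            graph_metric_names)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$id)) stop("duplicated subject id", call. = FALSE)
  if (any(cohort$age <= 0)) stop("ages must be positive", call. = FALSE)
  if ("seizure_count" %in% names(cohort)) {
    sc <- cohort$seizure_count
    if (any(sc[!is.na(sc)] < 0)) stop("seizure counts must be >= 0", call. = FALSE)
  }
  ctrl <- cohort$group == "control"
  for (v in intersect(c("onset_age", "days_to_mri", "seizure_count"),
                      names(cohort))) {
    if (any(!is.na(cohort[[v]][ctrl]))) {
      stop("patient-only field '", v, "' must be NA for controls", call. = FALSE)
    }
  }
  cohort
}

#' Write / read a cohort table as CSV
#' @param cohort a cohort tibble.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("patient", "control"))
  for (v in setdiff(names(df), c("id", "group", "sex"))) {
    df[[v]] <- as.numeric(df[[v]])
  }
  validate_cohort(tibble::as_tibble(df))
}
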