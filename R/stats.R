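#' Compare a variable between the two groups
#'
#' Continuous variables get an independent-samples t-test (pooled-variance
#' Student's t by default, Welch by option) with a two-tailed p; categorical
#' variables get a Pearson chi-square without continuity correction.
#' Presentation routing follows the usual convention: when both groups pass
#' Shapiro-Wilk normality at 0.05 the variable is summarised as mean (SD),
#' otherwise as median (IQR); both summaries are returned.
#'
#' @param cohort a cohort tibble with a two-level `group` column.
#' @param variable column name to compare.
#' @param categorical treat the variable as categorical; default guesses
#'   from the column type.
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @return a one-row tibble.
#' @export
compare_groups <- function(cohort, variable, categorical = NULL,
                           welch = FALSE) {
  x <- cohort[[variable]]
  if (is.null(x)) stop("no column '", variable, "' in cohort", call. = FALSE)
  g <- droplevels(factor(cohort$group))
  keep <- !is.na(x)
  x <- x[keep]; g <- g[keep]
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    stop("both groups need >= 2 observations of '", variable, "'",
         call. = FALSE)
  }
  if (is.null(categorical)) categorical <- is.character(x) || is.factor(x)

  if (categorical) {
    tab <- table(g, x)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 1)) {
      stop("expected cell count below 1; chi-square invalid", call. = FALSE)
    }
    if (any(exp_counts < 5)) {
      warning("expected cell count below 5 for '", variable, "'",
              call. = FALSE)
    }
    ts <- stats::chisq.test(tab, correct = FALSE)
    return(tibble::tibble(
      variable = variable, test = "chi-square",
      statistic = unname(ts$statistic), df = unname(ts$parameter),
      p_value = ts$p.value,
      mean_patient = NA_real_, sd_patient = NA_real_,
      mean_control = NA_real_, sd_control = NA_real_,
      median_patient = NA_real_, iqr_lo_patient = NA_real_,
      iqr_hi_patient = NA_real_, median_control = NA_real_,
      iqr_lo_control = NA_real_, iqr_hi_control = NA_real_,
      presentation = "count"
    ))
  }

  xs <- split(x, g)
  if (all(vapply(xs, stats::sd, numeric(1)) == 0)) {
    stop("zero variance in both groups for '", variable, "'", call. = FALSE)
  }
  normal <- vapply(xs, function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1))
  ts <- stats::t.test(x ~ g, var.equal = !welch)
  q1 <- stats::quantile(xs[[1]], c(0.25, 0.5, 0.75), names = FALSE)
  q2 <- stats::quantile(xs[[2]], c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    variable = variable,
    test = if (welch) "welch-t" else "student-t",
    statistic = unname(ts$statistic), df = unname(ts$parameter),
    p_value = ts$p.value,
    mean_patient = mean(xs[[1]]), sd_patient = stats::sd(xs[[1]]),
    mean_control = mean(xs[[2]]), sd_control = stats::sd(xs[[2]]),
    median_patient = q1[2], iqr_lo_patient = q1[1], iqr_hi_patient = q1[3],
    median_control = q2[2], iqr_lo_control = q2[1], iqr_hi_control = q2[3],
    presentation = if (all(normal)) "mean_sd" else "median_iqr"
  )
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation; the p-value comes from the exact t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of
#' freedom.
#'
#' @param cohort a data frame.
#' @param x,y column names.
#' @param group optional group level to filter on.
#' @return a one-row tibble with columns x, y, group, n, r, p_value.
#' @export
pearson_cor <- function(cohort, x, y, group = NULL) {
  df <- cohort
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  xv <- df[[x]]; yv <- df[[y]]
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in '", if (stats::sd(xv) == 0) x else y, "'",
         call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(x = x, y = y,
                 group = if (is.null(group)) "all" else as.character(group),
                 n = length(xv), r = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' Bonferroni per-comparison threshold
#'
#' Raw threshold `alpha / m`, plus the truncated three-decimal presentation
#' (floor), the form in which such thresholds are usually printed
#' (0.05/4 -> 0.012, 0.05/9 -> 0.005).
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param m number of comparisons, `>= 1`.
#' @return list with `raw` and `presented`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  raw <- alpha / m
  list(raw = raw, presented = floor(raw * 1000) / 1000)
}

#' Build the full cohort statistics report
#'
#' Produces the group-comparison and correlation layer of the analysis:
#' * `table1`: demographics (age t-test, sex chi-square) plus patient-only
#'   clinical descriptives;
#' * `table2_dti`: the four global DTI parameters with a Bonferroni family
#'   of m = 4;
#' * `table3_graph`: the nine graph measures with a family of m = 9;
#' * `fig3_correlations`: per-group Pearson correlations of the
#'   perivascular-space index against age, clinical variables, DTI
#'   parameters and graph measures.
#'
#' Significance flags use the raw `alpha/m` threshold; the truncated
#' presentation thresholds are carried alongside. The report is a pure
#' function of its inputs, with deterministic row ordering.
#'
#' @param cohort a cohort tibble (see [make_cohort()]).
#' @param config list of options: `alpha` (default 0.05) and `welch`.
#' @return an object of class `alps_stats_report`.
#' @export
build_report <- function(cohort, config = list()) {
  cohort <- validate_cohort(cohort)
  alpha <- config$alpha %||% 0.05
  welch <- isTRUE(config$welch)

  table1 <- dplyr::bind_rows(
    compare_groups(cohort, "age", welch = welch),
    compare_groups(cohort, "sex", categorical = TRUE)
  )

  dti_vars <- c("fa", "md", "ad", "rd")
  thr2 <- bonferroni_threshold(alpha, length(dti_vars))
  table2 <- dplyr::bind_rows(
    lapply(dti_vars, function(v) compare_groups(cohort, v, welch = welch)))
  table2$bonferroni_raw <- thr2$raw
  table2$bonferroni_presented <- thr2$presented
  table2$significant <- table2$p_value < thr2$raw

  thr3 <- bonferroni_threshold(alpha, length(graph_metric_names))
  table3 <- dplyr::bind_rows(
    lapply(graph_metric_names,
           function(v) compare_groups(cohort, v, welch = welch)))
  table3$bonferroni_raw <- thr3$raw
  table3$bonferroni_presented <- thr3$presented
  table3$significant <- table3$p_value < thr3$raw

  cor_vars_pat <- c("age", "onset_age", "days_to_mri", "seizure_count",
                    dti_vars, graph_metric_names)
  cor_vars_ctl <- c("age", dti_vars, graph_metric_names)
  fig3 <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(cor_vars_pat, function(v) {
      pearson_cor(cohort, "alps", v, group = "patient")
    })),
    dplyr::bind_rows(lapply(cor_vars_ctl, function(v) {
      pearson_cor(cohort, "alps", v, group = "control")
    }))
  )
  fig3$significant <- fig3$p_value < alpha

  structure(list(
    table1 = table1, table2_dti = table2, table3_graph = table3,
    fig3_correlations = fig3,
    thresholds = list(alpha = alpha, dti = thr2, graph = thr3),
    config = list(alpha = alpha, welch = welch),
    n = table(cohort$group)
  ), class = "alps_stats_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alps_stats_report <- function(x, ...) {
  cat("<alps_stats_report> patients n =", x$n[["patient"]],
      ", controls n =", x$n[["control"]], "\n")
  cat("DTI family threshold", x$thresholds$dti$presented,
      "| graph family threshold", x$thresholds$graph$presented, "\n")
  sig <- x$fig3_correlations[x$fig3_correlations$significant, ]
  cat(nrow(sig), "significant index correlation(s) at alpha =",
      x$thresholds$alpha, "\n")
  invisible(x)
}

#' @export
tidy.alps_stats_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$table1, table = "table1"),
    dplyr::mutate(x$table2_dti, table = "table2_dti"),
    dplyr::mutate(x$table3_graph, table = "table3_graph")
  )
}

#' @export
glance.alps_stats_report <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n[["patient"]], n_controls = x$n[["control"]],
    alpha = x$thresholds$alpha,
    dti_threshold = x$thresholds$dti$presented,
    graph_threshold = x$thresholds$graph$presented,
    n_significant_group_tests = sum(x$table2_dti$significant) +
      sum(x$table3_graph$significant),
    n_significant_correlations = sum(x$fig3_correlations$significant)
  )
}

#' Write the report tables to a directory
#' @param report an `alps_stats_report`.
#' @param dir output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table1, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table2_dti, file.path(dir, "table2_dti.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table3_graph, file.path(dir, "table3_graph.csv"),
                   row.names = FALSE)
  utils::write.csv(report$fig3_correlations,
                   file.path(dir, "fig3_correlations.csv"), row.names = FALSE)
  jsonlite::write_json(report$thresholds, file.path(dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
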