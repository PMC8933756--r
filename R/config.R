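#' Run configuration
#'
#' Named parameter bundle for a pipeline run. Every stochastic stage
#' consumes `seed` deterministically; the stage parameter defaults match
#' the documented tracking/threshold/statistics defaults.
#'
#' @param seed integer random seed.
#' @param ... stage parameters overriding the defaults.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    phantom = list(g = 0.2, snr = Inf, S0 = 100),
    tracking = list(n_seeds = 10000, angle_deg = 60, min_length_mm = 30,
                    stop_fa = 0.15),
    connectome = list(threshold_frac = 0.001, n_null = 20,
                      n_swap_per_edge = 10),
    stats = list(alpha = 0.05, welch = FALSE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Serialize / deserialize a run configuration (lossless JSON round-trip)
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  # Inf is not valid JSON; encode as string and decode on read
  x <- rapply(x, function(v) if (is.numeric(v) && any(is.infinite(v)))
    as.character(v) else v, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- rapply(x, function(v) {
    if (is.character(v) && all(v %in% c("Inf", "-Inf"))) as.numeric(v) else v
  }, how = "replace")
  x$seed <- as.integer(x$seed)
  structure(x, class = "run_config")
}
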