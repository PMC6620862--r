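.config_defaults <- list(
  k = 0, s = 1, L = 2 * pi, N = 100L,
  t = 0.3, M = 100L,
  E_s = 110, G_s = 40, nu_s = 0.3,
  eps_A = 0.001,
  fem_tol = 1e-8,
  min_area_frac = 0.001,
  out = "pcell_out"
)

#' Run configuration
#'
#' A validated bag of every tunable the command-line interface exposes, with
#' the same defaults. Unknown keys are rejected so that typos in config
#' files fail loudly, and a configuration round-trips losslessly through
#' \code{\link{writeRunConfig}} / \code{\link{readRunConfig}}.
#'
#' @param ... named overrides of the defaults (k, s, L, N, t, M, E_s, G_s,
#'   nu_s, eps_A, fem_tol, min_area_frac, out).
#' @return A \code{pcell_config} (named list).
#' @export
runConfig <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all configuration values must be named")
  }
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.config_defaults, over)
  cfg$N <- as.integer(cfg$N)
  cfg$M <- as.integer(cfg$M)
  structure(cfg, class = "pcell_config")
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' @rdname runConfig
#' @param config a \code{pcell_config}.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "pcell_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pcell_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
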