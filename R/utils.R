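#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr %>%
NULL

# Abort with a class so callers can condition on hetstab errors.
stop_hetstab <- function(msg, class = "hetstab_error", ...) {
  rlang::abort(msg, class = c(class, "hetstab_error"), ...)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hetstab(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_hetstab(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_hetstab(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Derive a stream-specific seed from a master seed
#'
#' Small deterministic offsets keep the generator streams of the different
#' data modalities decoupled while remaining a pure function of one master
#' seed. Results stay below `.Machine$integer.max`.
#'
#' @param seed Master integer seed.
#' @param stream Small non-negative integer offset identifying the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(stream, "stream", lower = 0)
  as.integer((as.numeric(seed) * 1009 + stream * 9973) %% 2147483647)
}

#' Read a run configuration file
#'
#' Configurations are flat YAML key-value files; every tunable threshold of
#' the analysis stages can be set here. Unknown keys are kept (stages pick
#' the keys they understand), so one file can configure a whole run.
#'
#' @param path Path to a YAML file, or `NULL` for an empty config.
#' @return A named list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    return(list())
  }
  if (!file.exists(path)) {
    stop_hetstab(sprintf("Config file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop_hetstab("Config file must contain a YAML mapping of key: value pairs.")
  }
  cfg
}

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

# INFO-level audit logging: inputs, seed, record counts. Silenced via
# options(hetstab.quiet = TRUE).
log_info <- function(fmt, ...) {
  if (isTRUE(getOption("hetstab.quiet", FALSE))) {
    return(invisible(NULL))
  }
  rlang::inform(paste0("[hetstab] ", sprintf(fmt, ...)))
  invisible(NULL)
}
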