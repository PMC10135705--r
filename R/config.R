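#' Run configuration
#'
#' Validated bundle of the tunable settings shared by the pipeline
#' entry points. Unknown keys are rejected up front so typos never
#' silently fall back to defaults.
#'
#' @param ... Settings to override. Recognised keys: `charge_overrides`
#'   (named numeric vector passed to [charge_table()]), `w_direct`,
#'   `w_adjacent` (see [score_weights()]), `aggregation` (`"max"` or
#'   `"mean"`), `chain` (`NULL`, `"TRA"` or `"TRB"`), `k` (fragment
#'   count), `normalize` (per-residue score normalization flag),
#'   `log2_expression`, `log_level` (`"quiet"`, `"info"` or `"debug"`),
#'   `outdir`, `seed`.
#' @return List with class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(
    charge_overrides = NULL,
    w_direct = 1,
    w_adjacent = 0.5,
    aggregation = "max",
    chain = NULL,
    k = 18L,
    normalize = FALSE,
    log2_expression = FALSE,
    log_level = "info",
    outdir = NULL,
    seed = NULL
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("run_config() settings must be named", call. = FALSE)
    unknown <- setdiff(names(ov), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    defaults[names(ov)] <- ov
  }
  cfg <- defaults
  cfg$aggregation <- match.arg(cfg$aggregation, c("max", "mean"))
  if (!is.null(cfg$chain))
    cfg$chain <- match.arg(cfg$chain, c("TRA", "TRB"))
  cfg$log_level <- match.arg(cfg$log_level, c("quiet", "info", "debug"))
  if (!is.numeric(cfg$k) || cfg$k < 1 || cfg$k != round(cfg$k))
    stop("'k' must be a positive integer", call. = FALSE)
  cfg$k <- as.integer(cfg$k)
  # constructors validate charge values and weight ordering
  cfg$table <- charge_table(cfg$charge_overrides)
  cfg$weights <- score_weights(cfg$w_direct, cfg$w_adjacent)
  structure(cfg, class = "run_config")
}

# Leveled logger for the pipeline stages.
cfg_log <- function(cfg, level = "info", ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[level]] <= ranks[[cfg$log_level]] && cfg$log_level != "quiet")
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Write a run manifest
#'
#' Records input paths, the full configuration, the package version and
#' the seed as JSON, sufficient to re-execute a run exactly.
#'
#' @param path Output JSON path.
#' @param inputs Named list or character vector of input identifiers.
#' @param config A [run_config()].
#' @param seed Seed used for any randomness in the run (or `NULL`).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, inputs, config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  cfg$table <- as.list(unclass(cfg$table))
  cfg$weights <- unclass(cfg$weights)
  manifest <- list(
    package = "tcrcs",
    version = as.character(utils::packageVersion("tcrcs")),
    inputs = as.list(inputs),
    config = cfg,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
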