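# Run configuration: validated key set shared by the screen pipeline and CLI.

config_domains <- list(
  exponent_sign = c("decay", "literal"),
  scoring_graph = c("disease", "background", "disease_plus_targets"),
  mica_rule     = c("mica", "literal_max"),
  aggregation   = c("max", "bma", "avg"),
  corpus_scope  = c("all_annotations", "target_union"),
  missing_3d    = c("zero", "skip_axis"),
  total_rule    = c("diagonal", "sum", "euclidean")
)

#' Default run configuration
#'
#' @return Named list: `exponent_sign` "decay", `scoring_graph` "disease",
#'   `damping` 0.85, `mica_rule` "mica", `aggregation` "max",
#'   `corpus_scope` "all_annotations", `q` 4, `sigma` 1.0, `missing_3d`
#'   "zero", `total_rule` "diagonal", `seed` NULL, `conf_level` 0.95.
#' @export
default_config <- function() {
  list(
    exponent_sign = "decay",
    scoring_graph = "disease",
    damping = 0.85,
    mica_rule = "mica",
    aggregation = "max",
    corpus_scope = "all_annotations",
    q = 4L,
    sigma = 1.0,
    missing_3d = "zero",
    total_rule = "diagonal",
    seed = NULL,
    conf_level = 0.95
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON file of configuration overrides on top of
#' [default_config()]. Every key is validated against its enumerated or
#' numeric domain; an unknown key is an error naming the key.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) ss_stop("io", sprintf("cannot read config '%s'", path))
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L) {
      ss_stop("config", sprintf(
        "unknown config key '%s' (allowed: %s)",
        unknown[1L], paste(names(cfg), collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (key in names(config_domains)) {
    val <- cfg[[key]]
    if (!is.character(val) || length(val) != 1L || !(val %in% config_domains[[key]])) {
      ss_stop("config", sprintf("config key '%s' must be one of: %s",
                                key, paste(config_domains[[key]], collapse = ", ")))
    }
  }
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(cfg$damping) || cfg$damping <= 0 || cfg$damping >= 1) {
    ss_stop("config", "config key 'damping' must be a number in (0, 1)")
  }
  if (!num_ok(cfg$q) || cfg$q < 1 || cfg$q != as.integer(cfg$q)) {
    ss_stop("config", "config key 'q' must be an integer >= 1")
  }
  cfg$q <- as.integer(cfg$q)
  if (!num_ok(cfg$sigma) || cfg$sigma <= 0) {
    ss_stop("config", "config key 'sigma' must be a positive number (Angstrom)")
  }
  if (!num_ok(cfg$conf_level) || cfg$conf_level <= 0 || cfg$conf_level >= 1) {
    ss_stop("config", "config key 'conf_level' must be in (0, 1)")
  }
  if (!is.null(cfg$seed)) {
    if (!num_ok(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
      ss_stop("config", "config key 'seed' must be an integer or null")
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  cfg
}
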