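# Run configuration (YAML), deterministic seed fan-out and JSON-lines run
# logging.

#' Default run configuration
#'
#' Nested stage blocks with every pipeline default (thresholds 0.5 and
#' -2.2 REU/aa; GA population 100, 20 offspring, 200 epochs, 800 founder
#' fragments of length 40; foldtuning 10,000 samples per round, top 100,
#' top_k 950, temperature 1.5, 5 rounds; 200 designs per funnel at a 0.60
#' identity threshold).
#'
#' @return Nested list of stage blocks.
#' @export
default_run_config <- function() {
  list(
    global = list(seed = 1L, backend = "surrogate"),
    sampler = list(n_replicas = 4L, t_min = 0.2, t_max = 2.0,
                   steps_per_replica = 500L, swap_interval = 10L,
                   likelihood_weight = 1.0, contact_weight = 1.0),
    ga = list(population_size = 100L, offspring_per_epoch = 20L,
              epochs = 200L, mutation_rate = 0.02, refine_steps = 100L,
              p_splice = 0.5, max_child_length = 250L,
              compactness_threshold = 0.5, tm_threshold = 0.5,
              fragment_length = 40L, library_size = 800L),
    foldtune = list(n_samples = 10000L, top_n = 100L, top_k = 950L,
                    temperature = 1.5, rounds = 5L,
                    compactness_threshold = 0.5, tm_threshold = 0.5),
    funnel = list(n_designs = 200L, identity_threshold = 0.60,
                  energy_threshold = -2.2, tm_threshold = 0.5),
    annotate = list(tm_threshold = 0.5, compactness_threshold = 0.5)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        stop(sprintf("configuration key %s must be a block (mapping)", here))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      val <- user[[key]]
      if (is.numeric(defaults[[key]]) && !is.numeric(val)) {
        stop(sprintf("configuration key %s must be numeric, got %s",
                     here, class(val)[1]))
      }
      if (is.character(defaults[[key]]) && !is.character(val)) {
        stop(sprintf("configuration key %s must be character, got %s",
                     here, class(val)[1]))
      }
      if (is.integer(defaults[[key]])) val <- as.integer(val)
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected with a message naming the key; missing keys
#' are filled from [default_run_config()]. An empty file yields all
#' defaults.
#'
#' @param path YAML file path.
#' @return Validated nested configuration list (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration root must be a mapping")
  cfg <- merge_config(default_run_config(), user)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration to YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive a stage seed from the global seed
#'
#' Deterministic fan-out of one user-facing seed into per-stage seeds:
#' the stage name is hashed (iterated 31-multiplier hash modulo 2^31 - 1)
#' and added to the global seed. Keeps parallel stages decorrelated while
#' remaining reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  as.integer((as.numeric(seed) %% m + h) %% m)
}

#' JSON-lines run logger
#'
#' Collects structured events in memory and (optionally) appends each as
#' a JSON line to a file. Events carry no wall-clock time, so two runs
#' with the same configuration and seed produce identical logs.
#'
#' @param path Optional file path for the JSON-lines stream.
#' @return An object of class `run_logger`.
#' @export
run_logger <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$path <- path
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(list(type = "header", format = "novelforge-log-v1"),
                                auto_unbox = TRUE), path)
  }
  structure(env, class = "run_logger")
}

#' Log an event
#'
#' @param logger A [run_logger()].
#' @param type Event type string.
#' @param data Named list payload (seeds of stochastic decisions belong
#'   here).
#' @export
log_event <- function(logger, type, data = list()) {
  stopifnot(inherits(logger, "run_logger"))
  ev <- c(list(type = type), data)
  logger$events[[length(logger$events) + 1L]] <- ev
  if (!is.null(logger$path)) {
    cat(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), "\n", sep = "",
        file = logger$path, append = TRUE)
  }
  invisible(logger)
}

#' Read a JSON-lines run log
#'
#' @param path Log file path.
#' @return List of event lists (header included).
#' @export
read_log <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Reconstruct GA epoch records from a run log
#'
#' @param events Events from [read_log()] or a logger's `$events`.
#' @return data.frame of epoch records.
#' @export
replay_epoch_records <- function(events) {
  rows <- Filter(function(e) identical(e$type, "epoch"), events)
  if (!length(rows)) {
    return(data.frame(epoch = integer(), mean_burial = numeric(),
                      cumulative_unique_cath = integer(),
                      cumulative_novel = integer(), n_new_novel = integer()))
  }
  do.call(rbind, lapply(rows, function(e) {
    data.frame(epoch = as.integer(e$epoch),
               mean_burial = as.numeric(e$mean_burial),
               cumulative_unique_cath = as.integer(e$cumulative_unique_cath),
               cumulative_novel = as.integer(e$cumulative_novel),
               n_new_novel = as.integer(e$n_new_novel))
  }))
}
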