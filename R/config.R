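# Layered run configuration: package defaults, optional YAML config file,
# command-line overrides. The fully resolved configuration is snapshotted
# into the run directory before execution.

#' Package default configuration
#'
#' @return Nested list of defaults: global `seed`, `marking` (method and
#'   marker tokens), `max_sequence_chars`, `classifier` (reference-backbone
#'   hyper-parameters), and `fixtures` (generator settings).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    run_dir = NULL,
    marking = list(
      method = "WRAP_TYPE_SE",
      tokens = marker_tokens()
    ),
    max_sequence_chars = 1000,
    classifier = list(
      backbone = "reference",
      peak_lr = 0.5,
      warm_rate = 0.05,
      batch_size = 32,
      max_steps = 300,
      hash_dim = 16384,
      ngram = 2,
      l2 = 0
    ),
    fixtures = list(
      n_docs = 100,
      sentences_min = 3,
      sentences_max = 6,
      n_chems = 40,
      n_genes = 40,
      p_negative_cooccurrence = 0.3,
      kb_coverage = 0.9,
      kb_noise = 50
    )
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (k in names(override)) {
    if (is.null(override[[k]])) next
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Resolve a layered run configuration
#'
#' Merges, in increasing precedence: [default_config()], an optional YAML
#' configuration file, and explicit overrides. When `run_dir` is set (by
#' any layer) the resolved configuration is snapshotted there as
#' `config_snapshot.yml` before anything else runs.
#'
#' @param config_file Optional path to a YAML file.
#' @param overrides Optional nested list of overrides.
#' @return The resolved configuration list, of class `run_config`.
#' @export
resolve_config <- function(config_file = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    cfg <- merge_config(cfg, yaml::read_yaml(config_file))
  }
  cfg <- merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  if (!is.null(cfg$run_dir)) {
    dir.create(cfg$run_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- unclass(cfg)
    yaml::write_yaml(snap, file.path(cfg$run_dir, "config_snapshot.yml"))
  }
  cfg
}

# Classifier config from a resolved run config.
classifier_config_from <- function(cfg, seed = cfg$seed,
                                   max_steps = cfg$classifier$max_steps) {
  cc <- cfg$classifier
  classifier_config(
    backbone = cc$backbone,
    marker_vocab = unlist(cfg$marking$tokens, use.names = FALSE),
    peak_lr = cc$peak_lr, warm_rate = cc$warm_rate,
    batch_size = cc$batch_size, max_steps = max_steps,
    hash_dim = cc$hash_dim, ngram = cc$ngram, l2 = cc$l2,
    seed = seed
  )
}

# Fixture config from a resolved run config.
fixture_config_from <- function(cfg, seed = cfg$seed) {
  fx <- cfg$fixtures
  fixture_config(
    n_docs = fx$n_docs,
    sentences_per_doc = c(fx$sentences_min, fx$sentences_max),
    n_chems = fx$n_chems, n_genes = fx$n_genes,
    p_negative_cooccurrence = fx$p_negative_cooccurrence,
    kb_coverage = fx$kb_coverage, kb_noise = fx$kb_noise,
    seed = seed
  )
}

# Line-oriented timestamped logging (to stderr, and to run_dir/run.log when
# a run directory is configured).
log_line <- function(cfg, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(cfg$run_dir)) {
    cat(line, "\n", sep = "",
        file = file.path(cfg$run_dir, "run.log"), append = TRUE)
  }
  invisible(line)
}
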