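#' Load a pipeline run configuration
#'
#' Reads a YAML key-value file and fills defaults for the pipeline
#' parameters: `k = 10`, `tau = 0.30`, `n_classifiers = 25`,
#' `sd_convention = "sample"`, `forced = []`, `seed = 1`,
#' `min_train_fraction = 0.5`, `max_iterations = 10`. Unknown keys are an
#' error (they are almost always typos).
#'
#' @param path YAML file path; `NULL` returns pure defaults.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- list(k = 10L, tau = 0.30, n_classifiers = 25L,
                   sd_convention = "sample", forced = character(0),
                   seed = 1L, min_train_fraction = 0.5,
                   max_iterations = 10L)
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  cfg$k <- as.integer(cfg$k)
  cfg$n_classifiers <- as.integer(cfg$n_classifiers)
  cfg$seed <- as.integer(cfg$seed)
  cfg$max_iterations <- as.integer(cfg$max_iterations)
  cfg$forced <- as.character(cfg$forced)
  if (!cfg$sd_convention %in% c("sample", "population"))
    stop("sd_convention must be 'sample' or 'population'", call. = FALSE)
  if (cfg$tau <= 0 || cfg$tau >= 1)
    stop("tau must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline on a raw panel
#'
#' Convenience umbrella: z-score (per sample, over base features), expand
#' with pairwise-difference metafeatures, run the pruning loop (entropy
#' filter, exact selection, classifier panel, disagreement pruning) and
#' return everything needed for reporting.
#'
#' @param raw_train Raw base-feature [panel_matrix()] of training samples.
#' @param raw_eval_sets Named list of raw evaluation panels (each z-scored
#'   and expanded with the same convention).
#' @param config A `run_config` from [load_run_config()].
#' @return List with `train` (expanded panel), `eval_sets`, `trace` (the
#'   [prune_run()] trace) and `config`.
#' @export
run_pipeline <- function(raw_train, raw_eval_sets = list(),
                         config = load_run_config()) {
  expand1 <- function(p)
    expand_metafeatures(zscore_rows(p, config$sd_convention))
  train <- expand1(raw_train)
  evals <- lapply(raw_eval_sets, expand1)
  pc <- prune_config(k = config$k, forced = config$forced,
                     tau = config$tau,
                     min_train_fraction = config$min_train_fraction,
                     max_iterations = config$max_iterations,
                     members = classifier_panel(config$n_classifiers))
  trace <- prune_run(train, evals, pc)
  list(train = train, eval_sets = evals, trace = trace, config = config)
}
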