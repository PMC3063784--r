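#' Disagreement flag threshold
#'
#' The smallest number of classifiers that constitutes "more than a fraction
#' tau of the panel": the smallest integer c with c > tau * N. For a
#' 25-member panel and tau = 0.30 this is 8 — samples contradicted by 8 or
#' more classifiers are flagged.
#'
#' @param n_classifiers Panel size N.
#' @param tau Disagreement fraction threshold (default 0.30).
#' @return Integer flag count c; samples with disagreement >= c are flagged.
#' @export
flag_threshold <- function(n_classifiers, tau = 0.30) {
  stopifnot(n_classifiers >= 1L, tau >= 0, tau < 1)
  as.integer(floor(tau * n_classifiers) + 1L)
}

#' Configuration of the data-pruning loop
#'
#' @param k Signature size (default 10).
#' @param forced Features forced into every signature (subject to passing
#'   the entropy filter at each iteration).
#' @param tau Disagreement fraction above which a training sample is
#'   removed (default 0.30).
#' @param min_train_fraction Stop when a removal would shrink the training
#'   set below this fraction of its original size (default 0.5).
#' @param max_iterations Hard iteration cap (default 10).
#' @param members Classifier roster, see [classifier_panel()].
#' @param node_limit Branch-and-bound node budget per solve.
#' @return A `prune_config` list.
#' @export
prune_config <- function(k = 10L, forced = character(0), tau = 0.30,
                         min_train_fraction = 0.5, max_iterations = 10L,
                         members = classifier_panel(),
                         node_limit = 5e7) {
  stopifnot(tau > 0, tau < 1,
            min_train_fraction > 0, min_train_fraction <= 1)
  structure(list(k = as.integer(k), forced = forced, tau = tau,
                 min_train_fraction = min_train_fraction,
                 max_iterations = as.integer(max_iterations),
                 members = members, node_limit = node_limit),
            class = "prune_config")
}

#' Iterative signature selection with training-set pruning
#'
#' Runs the four-step loop on the expanded continuous training panel:
#' (1) re-fit the entropy filter and select a signature by exact
#' (alpha,beta)-k-feature-set optimization, (2) fit the classifier panel on
#' the signature's continuous values, (3) count, per training sample, the
#' classifiers whose resubstitution prediction contradicts the observed
#' label, and (4) remove all samples contradicted by more than `tau` of the
#' panel — then repeat on the reduced set. The filter, alpha and beta are
#' re-derived from scratch every iteration, so a forced feature can drop
#' out mid-loop if sample removal makes the filter discard it.
#'
#' Stopping rules, in the order checked each iteration:
#' `signature-unchanged` (the reduced set reproduced the previous
#' signature), `no-sample-over-threshold`, `train-too-small` (a removal
#' would cross `min_train_fraction`), `max-iterations`.
#'
#' @param train Expanded [panel_matrix()] of training samples.
#' @param eval_sets Named list of evaluation panels passed through to the
#'   ensemble at every iteration.
#' @param config A [prune_config()].
#' @return A `prune_trace`: list with `iterations` (each holding
#'   `train_ids`, `signature`, `report`, `disagreement`, `flagged`,
#'   `removed`), `stop_reason`, `final_signature`, `removed_all`.
#' @export
prune_run <- function(train, eval_sets = list(), config = prune_config()) {
  stopifnot(inherits(train, "panel_matrix"),
            inherits(config, "prune_config"))
  n0 <- nrow(train$values)
  n_members <- nrow(config$members)
  cutoff <- flag_threshold(n_members, config$tau)
  cur <- train
  iterations <- list()
  prev_selected <- NULL
  stop_reason <- "max-iterations"

  for (it in seq_len(config$max_iterations)) {
    sig <- withCallingHandlers(
      select_signature(cur, config$k, config$forced,
                       node_limit = config$node_limit),
      warning = function(w) {
        message(sprintf("iteration %d: %s", it, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    report <- ensemble_fit_predict(cur, eval_sets, signature = sig,
                                   members = config$members)
    d <- disagreement_counts(report)
    flagged <- names(d)[d >= cutoff]
    iterations[[it]] <- list(
      train_ids = rownames(cur$values),
      signature = sig, report = report,
      disagreement = d, flagged = flagged,
      removed = character(0))

    if (!is.null(prev_selected) &&
        setequal(sig$selected, prev_selected)) {
      stop_reason <- "signature-unchanged"
      break
    }
    if (length(flagged) == 0L) {
      stop_reason <- "no-sample-over-threshold"
      break
    }
    n_next <- nrow(cur$values) - length(flagged)
    if (n_next < config$min_train_fraction * n0) {
      stop_reason <- "train-too-small"
      break
    }
    iterations[[it]]$removed <- flagged
    keep <- setdiff(rownames(cur$values), flagged)
    cur <- panel_subset(cur, samples = keep)
    prev_selected <- sig$selected
  }

  structure(list(
    iterations = iterations,
    stop_reason = stop_reason,
    final_signature = iterations[[length(iterations)]]$signature,
    removed_all = unlist(lapply(iterations, `[[`, "removed"),
                         use.names = FALSE)),
    class = "prune_trace")
}

#' @export
print.prune_trace <- function(x, ...) {
  cat(sprintf("prune_trace: %d iteration(s), stop: %s\n",
              length(x$iterations), x$stop_reason))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf(
      "  iter %d: n=%d, flagged: %s\n", i, length(it$train_ids),
      if (length(it$flagged)) paste(it$flagged, collapse = ", ")
      else "none"))
  }
  invisible(x)
}
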