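#' Stacked signature profile per sample
#'
#' The sum over the signature's columns of each sample's (z-score or
#' z-score-difference) values — the one-number-per-sample summary that makes
#' a good signature visible at a glance: samples of the depressed class sit
#' below the others.
#'
#' @param panel A [panel_matrix()] containing the signature columns.
#' @param signature A `signature` or character vector of feature names.
#' @param sample_order Optional vector of sample ids giving the display
#'   order; default preserves panel order.
#' @return A `stacked_profile` data frame: `sample_id`, `label`, `stacked`.
#' @export
stacked_profile <- function(panel, signature, sample_order = NULL) {
  stopifnot(inherits(panel, "panel_matrix"))
  feats <- if (inherits(signature, "signature")) signature$selected
           else signature
  sub <- panel_subset(panel, features = feats)
  prof <- data.frame(sample_id = rownames(sub$values),
                     label = sub$labels,
                     stacked = unname(rowSums(sub$values)),
                     stringsAsFactors = FALSE)
  if (!is.null(sample_order)) {
    idx <- match(sample_order, prof$sample_id)
    if (anyNA(idx)) stop("unknown sample id(s) in sample_order",
                         call. = FALSE)
    prof <- prof[idx, ]
    rownames(prof) <- NULL
  }
  class(prof) <- c("stacked_profile", "data.frame")
  prof
}

#' Disagreement histogram data
#'
#' Tabulates per-sample disagreement counts, omitting samples no classifier
#' disagreed on.
#'
#' @param report An [ensemble_fit_predict()] result.
#' @return Data frame `sample_id`, `count`, sorted by panel order, zero
#'   counts omitted.
#' @export
disagreement_histogram <- function(report) {
  d <- disagreement_counts(report)
  out <- data.frame(sample_id = names(d), count = as.integer(d),
                    stringsAsFactors = FALSE)
  out[out$count > 0L, , drop = FALSE]
}

#' Summary metric table across signatures
#'
#' Binds the per-set panel summaries of several ensemble reports into the
#' conventional comparison layout: one row per signature per evaluation
#' set, columns avg/stdev of accuracy, sensitivity, specificity (unweighted
#' over the classifier panel).
#'
#' @param reports Named list of [ensemble_fit_predict()] results (names are
#'   the signature labels).
#' @return Data frame with columns `signature`, `set`, `avg_acc`, `sd_acc`,
#'   `avg_sens`, `sd_sens`, `avg_spec`, `sd_spec`.
#' @export
metric_table <- function(reports) {
  stopifnot(length(names(reports)) == length(reports))
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    cbind(data.frame(signature = nm, stringsAsFactors = FALSE), s)
  }))
  rownames(out) <- NULL
  out
}

#' Plot a stacked signature profile
#'
#' @param profile A [stacked_profile()].
#' @param title Plot title.
#' @return A ggplot object: one bar per sample in display order, coloured
#'   by class.
#' @export
plot_stacked_profile <- function(profile, title = "Stacked signature values") {
  profile$sample_id <- factor(profile$sample_id,
                              levels = profile$sample_id)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$sample_id, y = .data$stacked,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(case = "#c23b22",
                                          control = "#2b6cb0",
                                          other = "#3f9b5a")) +
    ggplot2::labs(x = NULL, y = "stacked value", title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Plot a disagreement histogram
#'
#' @param report An [ensemble_fit_predict()] result.
#' @param tau Threshold fraction drawn as a reference line.
#' @return A ggplot object; samples with zero disagreement are omitted. An
#'   empty histogram yields a valid empty plot.
#' @export
plot_disagreement_histogram <- function(report, tau = 0.30) {
  h <- disagreement_histogram(report)
  n <- nrow(report$members)
  h$sample_id <- factor(h$sample_id, levels = h$sample_id)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$sample_id, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = flag_threshold(n, tau) - 0.5,
                        linetype = 2, colour = "#c23b22") +
    ggplot2::scale_y_continuous(limits = c(0, n)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("classifiers disagreeing (of %d)", n)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write report artifacts to a directory
#'
#' Serializes an ensemble report's metric table (TSV), prediction matrices
#' (TSV) and summary (JSON). Output content is deterministic: fixed column
#' order, no timestamps.
#'
#' @param report An [ensemble_fit_predict()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(report$predictions)) {
    p <- report$predictions[[s]]
    utils::write.table(
      data.frame(sample_id = rownames(p), p, check.names = FALSE),
      file.path(dir, sprintf("predictions_%s.tsv", s)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
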