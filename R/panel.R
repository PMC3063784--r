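#' Construct a panel matrix
#'
#' A `panel_matrix` is the central container of the package: a dense
#' samples-by-features numeric matrix together with a per-sample class label
#' and a per-feature provenance record saying whether a column is a measured
#' base protein or a pairwise-difference metafeature.
#'
#' Labels take values in `"case"`, `"control"` and `"other"`. The `"other"`
#' label marks samples (e.g. other-dementia controls) that are carried through
#' classification but excluded from all performance metrics.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row
#'   names are sample identifiers, column names feature names; both required
#'   and unique. No missing values are allowed.
#' @param labels Character or factor vector of length `nrow(values)` with
#'   values in `case`, `control`, `other`.
#' @param provenance Optional data frame with columns `name`, `kind`
#'   (`"base"` or `"metafeature"`), `member1`, `member2` (`NA` for base
#'   features), one row per column of `values`, in column order. Defaults to
#'   all-base provenance.
#' @return An object of class `panel_matrix`.
#' @export
panel_matrix <- function(values, labels, provenance = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and feature column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("`labels` must have one entry per sample", call. = FALSE)
  bad <- setdiff(unique(labels), c("case", "control", "other"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(provenance)) {
    provenance <- data.frame(
      name = colnames(values), kind = "base",
      member1 = NA_character_, member2 = NA_character_,
      stringsAsFactors = FALSE)
  }
  stopifnot(identical(provenance$name, colnames(values)),
            all(provenance$kind %in% c("base", "metafeature")))
  structure(
    list(values = values, labels = labels, provenance = provenance),
    class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  kinds <- table(factor(x$provenance$kind, c("base", "metafeature")))
  cat(sprintf(
    "panel_matrix: %d samples x %d features (%d base, %d metafeatures)\n",
    nrow(x$values), ncol(x$values), kinds[["base"]], kinds[["metafeature"]]))
  cat("labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                               table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.panel_matrix <- function(x) dim(x$values)

#' Subset a panel matrix
#'
#' @param panel A [panel_matrix()].
#' @param samples Sample ids or row indices to keep (default all).
#' @param features Feature names or column indices to keep (default all).
#' @return A `panel_matrix` restricted to the requested rows/columns.
#' @export
panel_subset <- function(panel, samples = NULL, features = NULL) {
  stopifnot(inherits(panel, "panel_matrix"))
  ri <- seq_len(nrow(panel$values))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, rownames(panel$values))
          else samples
    if (anyNA(ri)) stop("unknown sample id(s): ",
                        paste(samples[is.na(ri)], collapse = ", "),
                        call. = FALSE)
  }
  ci <- seq_len(ncol(panel$values))
  if (!is.null(features)) {
    ci <- if (is.character(features)) match(features, colnames(panel$values))
          else features
    if (anyNA(ci)) stop("unknown feature(s): ",
                        paste(features[is.na(ci)], collapse = ", "),
                        call. = FALSE)
  }
  panel_matrix(panel$values[ri, ci, drop = FALSE],
               panel$labels[ri],
               panel$provenance[ci, , drop = FALSE])
}

#' Write a panel matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first column is the
#' sample id, second column the class label, and remaining columns the
#' feature values at full precision.
#'
#' @param panel A [panel_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_matrix"))
  df <- data.frame(sample_id = rownames(panel$values),
                   class = panel$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(panel$values, check.names = FALSE)
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a panel matrix from TSV
#'
#' Inverse of [write_panel()]. Parse errors report the offending row and
#' column of the file.
#'
#' @param path File written by [write_panel()] (or any TSV with `sample_id`
#'   and `class` leading columns).
#' @return A [panel_matrix()] with all-base provenance (provenance is
#'   reconstructed by [expand_metafeatures()] when needed, or can be supplied
#'   via a sidecar by callers that track it).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("sample_id", "class")))
    stop("malformed panel file (line 1): expected leading columns ",
         "'sample_id' and 'class'", call. = FALSE)
  feat <- colnames(df)[-(1:2)]
  raw <- df[, -(1:2), drop = FALSE]
  values <- matrix(NA_real_, nrow(df), length(feat),
                   dimnames = list(df$sample_id, feat))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf(
        "non-numeric cell at line %d, column '%s' (value '%s')",
        i + 1L, feat[j], raw[[j]][i]), call. = FALSE)
    }
    values[, j] <- v
  }
  panel_matrix(values, df$class)
}
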