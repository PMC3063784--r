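#' Shannon class entropy (bits)
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits: 0 for a pure set, `log2(k)` for k equally
#'   frequent classes.
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0L) stop("empty label set", call. = FALSE)
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy of each row of a class-count matrix (vectorized over candidate cuts)
.ent_rows <- function(counts) {
  n <- rowSums(counts)
  p <- counts / n
  lg <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lg)
}

#' Best binary cut of a feature by class-entropy minimization
#'
#' Candidate cut points are midpoints between adjacent distinct sorted
#' values, restricted to class-boundary points (a midpoint is skipped only
#' when the value groups on both sides are pure with the same class, where a
#' cut can never be optimal). The cut minimizing the weighted child entropy
#' is returned; ties are broken toward the smallest cut value.
#'
#' @param values Numeric feature values (>= 2 samples).
#' @param labels Class labels aligned with `values`.
#' @return `NULL` when no candidate cut exists (e.g. all values identical),
#'   otherwise a list with `cut`, `gain` (parent entropy minus weighted child
#'   entropy, bits) and the child label splits `left`/`right` (as indices
#'   into the input).
#' @export
best_cut <- function(values, labels) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  y <- factor(labels[ord])
  splits <- which(v[-1L] > v[-n])          # split after position i
  if (length(splits) == 0L) return(NULL)

  # boundary-point restriction: group runs of equal values, drop splits
  # flanked by two pure groups of the same class
  grp <- cumsum(c(1L, as.integer(v[-1L] > v[-n])))
  K <- nlevels(y)
  grp_counts <- matrix(0L, max(grp), K)
  for (k in seq_len(K))
    grp_counts[, k] <- tabulate(grp[y == levels(y)[k]], nbins = max(grp))
  pure_cls <- ifelse(rowSums(grp_counts > 0L) == 1L,
                     max.col(grp_counts, ties.method = "first"), NA_integer_)
  g_left <- grp[splits]
  keep <- !(!is.na(pure_cls[g_left]) & !is.na(pure_cls[g_left + 1L]) &
              pure_cls[g_left] == pure_cls[g_left + 1L])
  splits <- splits[keep]
  if (length(splits) == 0L) return(NULL)

  onehot <- matrix(0L, n, K)
  onehot[cbind(seq_len(n), as.integer(y))] <- 1L
  cum <- apply(onehot, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  tot <- cum[n, ]
  cl <- cum[splits, , drop = FALSE]
  cr <- matrix(tot, length(splits), K, byrow = TRUE) - cl
  w <- splits / n
  e_t <- w * .ent_rows(cl) + (1 - w) * .ent_rows(cr)
  parent_ent <- class_entropy(y)
  gains <- parent_ent - e_t
  best <- which.max(gains)                  # splits ascend, so first max = smallest cut
  i <- splits[best]
  cut <- (v[i] + v[i + 1L]) / 2
  list(cut = cut, gain = gains[best],
       left = ord[seq_len(i)], right = ord[(i + 1L):n])
}

#' Minimum-description-length acceptance test for a cut
#'
#' A candidate cut of a sample set S into S1, S2 is accepted when its
#' information gain exceeds the MDL coding cost
#' `log2(N - 1)/N + Delta/N`, with
#' `Delta = log2(3^c - 2) - (c*Ent(S) - c1*Ent(S1) - c2*Ent(S2))`,
#' where N is the size of S and c, c1, c2 the numbers of distinct classes in
#' S, S1, S2. Cuts that fail this test are not worth their description
#' length and terminate the recursion.
#'
#' @param parent,left,right Class labels of S, S1, S2 (`left` and `right`
#'   together must be a permutation of `parent`).
#' @param gain Information gain of the split, in bits.
#' @return `TRUE` to accept the cut.
#' @export
mdl_accept <- function(parent, left, right, gain) {
  n <- length(parent)
  c0 <- length(unique(parent))
  c1 <- length(unique(left))
  c2 <- length(unique(right))
  delta <- log2(3^c0 - 2) -
    (c0 * class_entropy(parent) - c1 * class_entropy(left) -
       c2 * class_entropy(right))
  gain > (log2(n - 1) + delta) / n
}

#' Recursive MDLP discretization of one feature
#'
#' Applies [best_cut()] and [mdl_accept()] recursively to each induced
#' sub-interval until no further cut is accepted. An empty result means the
#' feature carries too little class information to justify even one cut and
#' is discarded by the filter.
#'
#' @param values Numeric feature values.
#' @param labels Aligned class labels.
#' @return Sorted numeric vector of accepted cut values (possibly empty).
#' @export
discretize_feature <- function(values, labels) {
  rec <- function(idx) {
    if (length(idx) < 2L) return(numeric(0))
    bc <- best_cut(values[idx], labels[idx])
    if (is.null(bc)) return(numeric(0))
    li <- idx[bc$left]; ri <- idx[bc$right]
    if (!mdl_accept(labels[idx], labels[li], labels[ri], bc$gain))
      return(numeric(0))
    c(rec(li), bc$cut, rec(ri))
  }
  rec(seq_along(values))
}

#' Entropy-filter and discretize a panel
#'
#' Runs MDLP discretization independently on every column of the panel using
#' the binary training labels. Features with no accepted cut are marked as
#' failed; the integer interval matrix is returned for passed features only
#' (a sample's interval index is the number of cuts strictly below its
#' value). The filter is a training-set construct: downstream classification
#' uses the continuous values, never the discretized ones.
#'
#' Samples labelled `"other"` are excluded from the fit.
#'
#' @param panel A [panel_matrix()] (base features and/or metafeatures).
#' @param labels Class labels to fit against; defaults to the panel's own.
#' @return A `discretization_scheme`: list with `cuts` (named list of cut
#'   vectors), `passed` (named logical), `discrete` (samples x passed
#'   features integer matrix), `labels` and `sample_ids` (training samples
#'   used), and the feature `provenance`.
#' @export
filter_matrix <- function(panel, labels = panel$labels) {
  stopifnot(inherits(panel, "panel_matrix"))
  keep <- labels %in% c("case", "control")
  x <- panel$values[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) < 2L)
    stop("need both classes present to fit the entropy filter",
         call. = FALSE)
  cuts <- lapply(seq_len(ncol(x)), function(j)
    discretize_feature(x[, j], y))
  names(cuts) <- colnames(x)
  passed <- vapply(cuts, function(cc) length(cc) > 0L, logical(1))
  disc <- matrix(0L, nrow(x), sum(passed),
                 dimnames = list(rownames(x), names(cuts)[passed]))
  for (j in which(passed))
    disc[, names(cuts)[j]] <- findInterval(x[, j], cuts[[j]])
  structure(list(cuts = cuts, passed = passed, discrete = disc,
                 labels = y, sample_ids = rownames(x),
                 provenance = panel$provenance),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat(sprintf("discretization_scheme: %d/%d features passed the MDL filter (%d samples)\n",
              sum(x$passed), length(x$passed), length(x$labels)))
  invisible(x)
}
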