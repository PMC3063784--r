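#' Per-sample z-score normalization
#'
#' Re-expresses every protein abundance relative to the rest of the panel in
#' the same sample: for sample i with panel mean mu_i and standard deviation
#' sigma_i over all base features, z_ij = (x_ij - mu_i) / sigma_i. After the
#' transform each value is the number of panel standard deviations the
#' protein sits above or below that sample's panel average, so a positive
#' value means excess abundance relative to the other panel members.
#'
#' @param panel A [panel_matrix()] of raw abundances, base features only.
#' @param sd_convention `"sample"` (denominator n-1, the default) or
#'   `"population"` (denominator n). Which convention the originating assay
#'   pipeline used is generally unstated, so both are supported.
#' @return A `panel_matrix` of z-scores with the same shape and labels.
#'   Every row has mean 0 and standard deviation 1 under the chosen
#'   convention.
#' @export
zscore_rows <- function(panel, sd_convention = c("sample", "population")) {
  stopifnot(inherits(panel, "panel_matrix"))
  sd_convention <- match.arg(sd_convention)
  if (any(panel$provenance$kind != "base"))
    stop("z-scoring applies to base features only; expand afterwards",
         call. = FALSE)
  x <- panel$values
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 features per sample", call. = FALSE)
  mu <- rowMeans(x)
  cent <- x - mu
  ss <- rowSums(cent^2)
  denom <- if (sd_convention == "sample") n - 1L else n
  sigma <- sqrt(ss / denom)
  degenerate <- sigma == 0
  if (any(degenerate))
    stop("degenerate sample(s) with constant abundance row: ",
         paste(rownames(x)[degenerate], collapse = ", "), call. = FALSE)
  panel_matrix(cent / sigma, panel$labels, panel$provenance)
}

#' Expand a z-scored panel with pairwise-difference metafeatures
#'
#' For every unordered pair of base features (a, b), with a preceding b in
#' panel column order, appends a metafeature column with value z_a - z_b.
#' Each metafeature makes the relative imbalance of two signalling proteins
#' an explicit variable: two proteins can separate two classes through their
#' difference even when neither does alone, because a shared per-sample
#' displacement cancels in the difference. The mirrored orientation (b, a)
#' carries the same information up to sign and is not generated.
#'
#' For n base features the output has n + n(n-1)/2 columns: the original
#' base features first, then metafeatures in lexicographic panel-position
#' order of their member pairs.
#'
#' @param panel A z-scored [panel_matrix()] containing only base features.
#' @param sep Separator used to build metafeature display names
#'   (`"a-b"` by default). The provenance table, not the name, is the
#'   authoritative record of the member pair.
#' @return A `panel_matrix` with base + metafeature columns and full
#'   provenance.
#' @export
expand_metafeatures <- function(panel, sep = "-") {
  stopifnot(inherits(panel, "panel_matrix"))
  if (any(panel$provenance$kind != "base"))
    stop("input already contains metafeatures", call. = FALSE)
  z <- panel$values
  n <- ncol(z)
  if (n < 2L) stop("need at least 2 base features to expand", call. = FALSE)
  pairs <- utils::combn(n, 2L)            # columns ordered (1,2),(1,3),...
  a <- pairs[1L, ]; b <- pairs[2L, ]
  meta <- z[, a, drop = FALSE] - z[, b, drop = FALSE]
  base_names <- colnames(z)
  meta_names <- paste(base_names[a], base_names[b], sep = sep)
  colnames(meta) <- meta_names
  prov <- rbind(
    panel$provenance,
    data.frame(name = meta_names, kind = "metafeature",
               member1 = base_names[a], member2 = base_names[b],
               stringsAsFactors = FALSE))
  panel_matrix(cbind(z, meta), panel$labels, prov)
}
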