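#' Configuration for the synthetic panel generator
#'
#' Describes a class-labelled protein panel with three planted signal types
#' on top of an uninformative background:
#'
#' * *single markers*: proteins whose raw abundance is shifted by
#'   `single_effect` in case samples — discriminative on their own;
#' * *imbalance pairs*: pairs of proteins that each receive the same
#'   per-sample random offset (standard deviation `shared_noise_sd`) plus an
#'   antisymmetric class shift of `imbalance_effect/2` with opposite sign on
#'   the two members. Each member alone has heavily overlapping class
#'   distributions (the shared offset drowns the shift) while the pairwise
#'   difference cancels the shared offset and separates the classes — the
#'   signal that pairwise-difference metafeatures exist to expose;
#' * *mislabelled samples*: a fraction `mislabel_fraction` of samples whose
#'   recorded (observed) label contradicts the label their data were
#'   generated under, emulating clinically uncertain diagnoses.
#'
#' All abundances are generated raw (baseline + effects + noise); the
#' pipeline's own z-score stage is always responsible for normalization.
#'
#' @param n_proteins Number of base proteins on the panel.
#' @param n_samples_per_class Samples per class; a single count used for both
#'   classes, or a length-2 vector `c(case, control)`. Class sizes are exact.
#' @param n_single_markers Number of planted singly discriminative proteins.
#' @param single_effect Raw-unit mean shift added to single markers in cases.
#' @param n_imbalance_pairs Number of planted imbalance pairs.
#' @param imbalance_effect Raw-unit class separation of each pair difference
#'   (each member is shifted by half this, with opposite signs).
#' @param shared_noise_sd Standard deviation of the per-sample offset shared
#'   by the two members of a pair.
#' @param background_sd Standard deviation of i.i.d. measurement noise on
#'   every protein.
#' @param mislabel_fraction Fraction of all samples whose observed label is
#'   flipped; the flipped count is `round(fraction * n_samples)`, drawn
#'   uniformly without replacement across both classes.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical datasets.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_proteins = 120L,
                             n_samples_per_class = c(43L, 40L),
                             n_single_markers = 5L,
                             single_effect = 1.5,
                             n_imbalance_pairs = 5L,
                             imbalance_effect = 2,
                             shared_noise_sd = 2,
                             background_sd = 1,
                             mislabel_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_samples_per_class = as.integer(rep(n_samples_per_class,
                                                   length.out = 2L)),
              n_single_markers = as.integer(n_single_markers),
              single_effect = single_effect,
              n_imbalance_pairs = as.integer(n_imbalance_pairs),
              imbalance_effect = imbalance_effect,
              shared_noise_sd = shared_noise_sd,
              background_sd = background_sd,
              mislabel_fraction = mislabel_fraction,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_single_markers + 2L * cfg$n_imbalance_pairs > cfg$n_proteins)
    stop("invalid config: n_single_markers + 2*n_imbalance_pairs ",
         "exceeds n_proteins", call. = FALSE)
  if (cfg$mislabel_fraction < 0 || cfg$mislabel_fraction > 1)
    stop("invalid config: mislabel_fraction must be in [0, 1]",
         call. = FALSE)
  if (any(cfg$n_samples_per_class < 1L))
    stop("invalid config: need at least 1 sample per class", call. = FALSE)
  if (cfg$background_sd <= 0)
    stop("invalid config: background_sd must be positive", call. = FALSE)
  if (cfg$shared_noise_sd < 0)
    stop("invalid config: shared_noise_sd must be non-negative",
         call. = FALSE)
  invisible(cfg)
}

# run expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic protein-panel dataset
#'
#' Draws raw abundances as `baseline_i + effects + noise`: each sample has a
#' common baseline (N(10, 1)) shared by all proteins, background proteins add
#' i.i.d. N(0, `background_sd`) noise, and planted structure is added per
#' [generator_config()]. Planted protein indices are drawn without
#' replacement, so marker and pair positions vary with the seed; the `truth`
#' element records them.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_dataset` list with elements `panel` (a
#'   [panel_matrix()] of raw abundances under the *observed* labels),
#'   `true_labels`, `observed_labels`, `truth` (list: `single_markers`,
#'   `imbalance_pairs` as a 2-column character matrix, `mislabelled` sample
#'   ids) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  with_seed(config$seed, {
    n_case <- config$n_samples_per_class[1L]
    n_ctrl <- config$n_samples_per_class[2L]
    n <- n_case + n_ctrl
    p <- config$n_proteins
    sample_ids <- sprintf("s%d", seq_len(n))
    proteins <- sprintf("P%03d", seq_len(p))
    true_labels <- c(rep("case", n_case), rep("control", n_ctrl))
    cls_sign <- ifelse(true_labels == "case", 1, -1)

    planted <- sample.int(p, config$n_single_markers +
                             2L * config$n_imbalance_pairs)
    singles <- planted[seq_len(config$n_single_markers)]
    pair_idx <- matrix(planted[config$n_single_markers + seq_len(
      2L * config$n_imbalance_pairs)], ncol = 2L, byrow = TRUE)

    baseline <- stats::rnorm(n, mean = 10, sd = 1)
    x <- baseline + matrix(stats::rnorm(n * p, 0, config$background_sd),
                           n, p, dimnames = list(sample_ids, proteins))
    if (config$n_single_markers > 0L)
      x[, singles] <- x[, singles] +
        config$single_effect * (true_labels == "case")
    if (config$n_imbalance_pairs > 0L) {
      for (r in seq_len(nrow(pair_idx))) {
        shared <- stats::rnorm(n, 0, config$shared_noise_sd)
        x[, pair_idx[r, 1L]] <- x[, pair_idx[r, 1L]] + shared +
          cls_sign * config$imbalance_effect / 2
        x[, pair_idx[r, 2L]] <- x[, pair_idx[r, 2L]] + shared -
          cls_sign * config$imbalance_effect / 2
      }
    }

    n_flip <- round(config$mislabel_fraction * n)
    flipped <- if (n_flip > 0L) sort(sample.int(n, n_flip)) else integer(0)
    observed <- true_labels
    observed[flipped] <- ifelse(true_labels[flipped] == "case",
                                "control", "case")

    structure(list(
      panel = panel_matrix(x, observed),
      true_labels = true_labels,
      observed_labels = observed,
      truth = list(
        single_markers = proteins[singles],
        imbalance_pairs = matrix(proteins[pair_idx], ncol = 2L,
                                 dimnames = list(NULL, c("m1", "m2"))),
        mislabelled = sample_ids[flipped]),
      config = config), class = "synthetic_dataset")
  })
}

#' Canonical metafeature names of the planted imbalance pairs
#'
#' Orients each planted pair in panel column order (the orientation
#' [expand_metafeatures()] generates) and returns the corresponding
#' metafeature display names.
#'
#' @param dataset A `synthetic_dataset`.
#' @param sep Name separator, matching [expand_metafeatures()].
#' @return Character vector of metafeature names, one per planted pair.
#' @export
planted_metafeatures <- function(dataset, sep = "-") {
  pr <- dataset$truth$imbalance_pairs
  if (NROW(pr) == 0L) return(character(0))
  a <- pmin(pr[, 1L], pr[, 2L])   # names are zero-padded, so order = panel order
  b <- pmax(pr[, 1L], pr[, 2L])
  paste(a, b, sep = sep)
}

#' Write / read a synthetic dataset
#'
#' `write_dataset()` stores the panel as the package's TSV format (observed
#' labels) plus a JSON sidecar `truth.json` holding the generating
#' configuration, true labels and planted-structure lists, so test harnesses
#' can score recovery. `read_dataset()` restores both.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Directory to write into (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `synthetic_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(dataset$panel, file.path(dir, "panel.tsv"))
  sidecar <- list(
    true_labels = dataset$true_labels,
    observed_labels = dataset$observed_labels,
    truth = list(
      single_markers = dataset$truth$single_markers,
      imbalance_pairs = apply(dataset$truth$imbalance_pairs, 1L, identity,
                              simplify = FALSE),
      mislabelled = dataset$truth$mislabelled),
    config = unclass(dataset$config))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  panel <- read_panel(file.path(dir, "panel.tsv"))
  sc <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  pairs <- sc$truth$imbalance_pairs
  pairs <- if (is.matrix(pairs)) pairs
           else if (length(pairs)) do.call(rbind, pairs)
           else matrix(character(0), ncol = 2L)
  colnames(pairs) <- c("m1", "m2")
  cfg <- do.call(generator_config, sc$config)
  structure(list(
    panel = panel,
    true_labels = sc$true_labels,
    observed_labels = sc$observed_labels,
    truth = list(single_markers = as.character(sc$truth$single_markers),
                 imbalance_pairs = pairs,
                 mislabelled = as.character(sc$truth$mislabelled)),
    config = cfg), class = "synthetic_dataset")
}
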