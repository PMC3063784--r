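# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the discretizer oracle evaluates every
# midpoint at every recursion level, and the selection oracle enumerates
# all feature subsets.

oracle_entropy <- function(y) {
  p <- as.vector(table(y)) / length(y)
  -sum(p * log2(p))
}

# naive exhaustive best cut: all midpoints between adjacent distinct values
oracle_best_cut <- function(v, y) {
  sv <- sort(unique(v))
  if (length(sv) < 2L) return(NULL)
  cuts <- (sv[-1L] + sv[-length(sv)]) / 2
  best <- NULL
  for (ct in cuts) {
    l <- y[v < ct]; r <- y[v > ct]
    e <- length(l) / length(y) * oracle_entropy(l) +
      length(r) / length(y) * oracle_entropy(r)
    g <- oracle_entropy(y) - e
    if (is.null(best) || g > best$gain + 1e-12)
      best <- list(cut = ct, gain = g)
  }
  best
}

oracle_mdl_accept <- function(parent, left, right, gain) {
  n <- length(parent)
  c0 <- length(unique(parent))
  c1 <- length(unique(left)); c2 <- length(unique(right))
  delta <- log2(3^c0 - 2) -
    (c0 * oracle_entropy(parent) - c1 * oracle_entropy(left) -
       c2 * oracle_entropy(right))
  gain > log2(n - 1) / n + delta / n
}

oracle_discretize <- function(v, y) {
  if (length(v) < 2L) return(numeric(0))
  bc <- oracle_best_cut(v, y)
  if (is.null(bc)) return(numeric(0))
  l <- v < bc$cut
  if (!oracle_mdl_accept(y, y[l], y[!l], bc$gain)) return(numeric(0))
  c(oracle_discretize(v[l], y[l]), bc$cut,
    oracle_discretize(v[!l], y[!l]))
}

# exhaustive optimum of the (alpha,beta)-k selection; NULL when infeasible
oracle_enum_signature <- function(instance, alpha, beta) {
  feats <- instance$features
  k <- instance$k
  fidx <- match(instance$forced, feats)
  free <- setdiff(seq_along(feats), fidx)
  best <- NULL
  combos <- utils::combn(free, k - length(fidx), simplify = FALSE)
  for (cb in combos) {
    sel <- c(fidx, cb)
    bsum <- rowSums(instance$between[, sel, drop = FALSE])
    if (any(bsum < alpha)) next
    if (beta > 0 && nrow(instance$within)) {
      wsum <- rowSums(instance$within[, sel, drop = FALSE])
      if (any(wsum < beta)) next
    }
    obj <- sum(instance$between[, sel, drop = FALSE]) +
      sum(instance$within[, sel, drop = FALSE])
    if (is.null(best) || obj > best$objective)
      best <- list(objective = obj, selected = sort(feats[sel]))
  }
  best
}

# wrap a discrete matrix + labels as a minimal discretization scheme so
# build_instance() can consume synthetic coverage instances directly
make_scheme <- function(discrete, labels) {
  stopifnot(is.matrix(discrete), nrow(discrete) == length(labels))
  if (is.null(rownames(discrete)))
    rownames(discrete) <- sprintf("s%d", seq_len(nrow(discrete)))
  if (is.null(colnames(discrete)))
    colnames(discrete) <- sprintf("F%d", seq_len(ncol(discrete)))
  structure(list(
    cuts = stats::setNames(rep(list(0.5), ncol(discrete)),
                           colnames(discrete)),
    passed = stats::setNames(rep(TRUE, ncol(discrete)),
                             colnames(discrete)),
    discrete = discrete,
    labels = labels,
    sample_ids = rownames(discrete),
    provenance = data.frame(name = colnames(discrete), kind = "base",
                            member1 = NA_character_,
                            member2 = NA_character_,
                            stringsAsFactors = FALSE)),
    class = "discretization_scheme")
}

# random coverage instance on a binary discrete matrix; regenerates until
# every between-class pair is separated by at least one feature
random_instance <- function(n_per_class, n_feat, k, seed,
                            forced = character(0)) {
  set.seed(seed)
  repeat {
    disc <- matrix(sample(0:1, 2L * n_per_class * n_feat, replace = TRUE),
                   2L * n_per_class, n_feat)
    labels <- rep(c("case", "control"), each = n_per_class)
    sch <- make_scheme(disc, labels)
    inst <- tryCatch(build_instance(sch, k = k, forced = forced),
                     error = function(e) NULL)
    if (!is.null(inst)) return(inst)
  }
}

# small helper: quick synthetic expanded panel for pipeline-level tests
make_expanded <- function(cfg) {
  ds <- generate_dataset(cfg)
  list(ds = ds, expanded = expand_metafeatures(zscore_rows(ds$panel)))
}
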