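#' Build an (alpha,beta)-k-feature-set coverage instance
#'
#' From the discretized training matrix, enumerates every pair of samples:
#' for a between-class pair p the explaining set D(p) is the set of passed
#' features whose interval indices differ on the two samples; for a
#' within-class pair q the agreeing set S(q) is the set of passed features
#' whose interval indices coincide. The selection problem will ask for k
#' features such that every between-class pair is explained by at least
#' alpha selected features and every within-class pair by at least beta.
#'
#' Forced features that failed the entropy filter are dropped from the
#' forced set with a warning (a feature that no longer discriminates after
#' pruning cannot be forced).
#'
#' @param scheme A `discretization_scheme` from [filter_matrix()].
#' @param k Signature size.
#' @param forced Character vector of feature names to force into the
#'   signature.
#' @return A `coverage_instance`: list with logical membership matrices
#'   `between` (pairs x features) and `within`, the pair sample-id tables,
#'   `features`, `k` and the surviving `forced` set.
#' @export
build_instance <- function(scheme, k, forced = character(0)) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  M <- scheme$discrete
  if (ncol(M) == 0L)
    stop("no features passed the entropy filter", call. = FALSE)
  if (length(forced)) {
    lost <- setdiff(forced, colnames(M))
    if (length(lost)) {
      warning("forced feature(s) dropped (failed the entropy filter): ",
              paste(lost, collapse = ", "), call. = FALSE)
      forced <- intersect(forced, colnames(M))
    }
  }
  if (k < length(forced))
    stop(sprintf("k = %d is smaller than the forced set (%d features)",
                 k, length(forced)), call. = FALSE)
  if (k > ncol(M))
    stop(sprintf("k = %d exceeds the %d features that passed the filter",
                 k, ncol(M)), call. = FALSE)
  y <- scheme$labels
  ids <- scheme$sample_ids
  case_i <- which(y == "case"); ctrl_i <- which(y == "control")
  if (length(case_i) < 1L || length(ctrl_i) < 1L)
    stop("need at least one sample per class", call. = FALSE)

  bi <- rep(case_i, times = length(ctrl_i))
  bj <- rep(ctrl_i, each = length(case_i))
  between <- M[bi, , drop = FALSE] != M[bj, , drop = FALSE]
  rownames(between) <- paste(ids[bi], ids[bj], sep = "|")

  wpair <- function(idx) {
    if (length(idx) < 2L) return(NULL)
    cmb <- utils::combn(idx, 2L)
    list(i = cmb[1L, ], j = cmb[2L, ])
  }
  wc <- wpair(case_i); wn <- wpair(ctrl_i)
  wi <- c(wc$i, wn$i); wj <- c(wc$j, wn$j)
  if (length(wi)) {
    within <- M[wi, , drop = FALSE] == M[wj, , drop = FALSE]
    rownames(within) <- paste(ids[wi], ids[wj], sep = "|")
  } else {
    within <- matrix(logical(0), 0L, ncol(M),
                     dimnames = list(NULL, colnames(M)))
  }

  empty <- rowSums(between) == 0L
  if (any(empty))
    stop("infeasible instance: no passed feature separates between-class ",
         "pair(s) ", paste(rownames(between)[empty], collapse = ", "),
         call. = FALSE)

  # solver cache: duplicate pair constraints collapse (identical rows bind
  # identically for any selection), and per-feature constraint lists are
  # precomputed once so repeated alpha/beta solves stay cheap
  uniq <- function(mat) {
    if (nrow(mat) < 2L) return(mat)
    key <- do.call(paste0, as.data.frame(mat * 1L))
    mat[!duplicated(key), , drop = FALSE]
  }
  bu <- uniq(between)
  wu <- uniq(within)
  comb <- rbind(bu, wu)
  fp <- lapply(seq_len(ncol(comb)), function(f) which(comb[, f]) - 1L)
  solver <- list(fp = fp, n_between = nrow(bu), n_within = nrow(wu),
                 comb = comb,
                 weights = colSums(between) + colSums(within))

  structure(list(between = between, within = within,
                 features = colnames(M), k = as.integer(k),
                 forced = forced, solver = solver),
            class = "coverage_instance")
}

#' @export
print.coverage_instance <- function(x, ...) {
  cat(sprintf(
    "coverage_instance: %d features, %d between-class pairs, %d within-class pairs, k=%d, %d forced\n",
    length(x$features), nrow(x$between), nrow(x$within), x$k,
    length(x$forced)))
  invisible(x)
}

#' Maximal feasible alpha
#'
#' The largest number of selected features that can be required to differ
#' on every between-class pair, ignoring beta. The minimum over
#' between-class pairs of the number of separating features, capped at k,
#' is an upper bound (a signature of size k cannot contain more than k
#' separating features, nor more than the hardest pair offers); alpha is
#' decremented from that cap until a size-k selection meeting it exists,
#' checked by the exact solver in feasibility mode with beta = 0. Alpha = 0
#' is always feasible, so this terminates.
#'
#' @param instance A [build_instance()] result.
#' @return Integer alpha.
#' @export
max_alpha <- function(instance) {
  stopifnot(inherits(instance, "coverage_instance"))
  cap <- min(instance$k, min(rowSums(instance$between)))
  for (a in seq.int(cap, 0L)) {
    st <- solve_signature(instance, a, 0L, feasible_only = TRUE)$status
    if (st %in% c("feasible", "optimal")) return(a)
  }
  stop("no feasible alpha >= 0; instance is unsatisfiable", call. = FALSE)
}

#' Maximal feasible beta given alpha
#'
#' Starting from the cap min(k, min over within-class pairs of agreeing
#' features), decrements beta until the joint problem (alpha, beta, k,
#' forced) admits a feasible solution, checked by the exact solver in
#' feasibility mode. The chosen beta therefore never forces a change of
#' alpha or k.
#'
#' @param instance A [build_instance()] result.
#' @param alpha The value from [max_alpha()].
#' @return Integer beta.
#' @export
max_beta <- function(instance, alpha) {
  stopifnot(inherits(instance, "coverage_instance"))
  cap <- if (nrow(instance$within) == 0L) instance$k
         else min(instance$k, min(rowSums(instance$within)))
  for (b in seq.int(cap, 0L)) {
    st <- solve_signature(instance, alpha, b, feasible_only = TRUE)$status
    if (st %in% c("feasible", "optimal")) return(b)
  }
  stop("no feasible beta >= 0 for alpha = ", alpha, call. = FALSE)
}

#' Exactly solve the (alpha,beta)-k-feature-set selection
#'
#' Selects k features (including all forced ones) maximizing the total pair
#' coverage — the number of (pair, feature) incidences over all
#' between-class pairs' explaining sets and within-class pairs' agreeing
#' sets — subject to every between-class pair being explained by at least
#' `alpha` selected features and every within-class pair agreed on by at
#' least `beta`. The optimum is found by a deterministic branch-and-bound
#' (see `src/fs_solver.cpp`); among multiple optima the first one reached
#' under the fixed variable order is reported, together with the objective
#' value so alternate optima remain detectable.
#'
#' @param instance A [build_instance()] result.
#' @param alpha,beta Coverage requirements per between- / within-class pair.
#' @param feasible_only If `TRUE`, stop at the first feasible solution
#'   (used for the beta search).
#' @param node_limit Branch-and-bound node budget; exceeding it raises an
#'   error carrying the best incumbent found (condition class
#'   `metasig_node_limit`).
#' @return A `signature` object: list with `selected` (feature names in
#'   panel column order), `objective`, `status`, `alpha`, `beta`, `k`,
#'   `forced`.
#' @export
solve_signature <- function(instance, alpha, beta,
                            feasible_only = FALSE, node_limit = 5e7) {
  stopifnot(inherits(instance, "coverage_instance"))
  feats <- instance$features
  k <- instance$k
  sv <- instance$solver
  weights <- sv$weights
  infeasible_sig <- function() structure(list(
    selected = character(0), objective = NA_real_, status = "infeasible",
    alpha = as.integer(alpha), beta = as.integer(beta), k = k,
    forced = instance$forced, nodes = 0), class = "signature")

  # requirement per (deduplicated) pair constraint; req = 0 is vacuous
  req <- c(rep.int(as.integer(alpha), sv$n_between),
           rep.int(as.integer(beta), sv$n_within))
  active <- req > 0L
  mm <- sv$comb[active, , drop = FALSE]
  reqa <- req[active]

  # propagation: a pair requiring coverage k forces every selected feature
  # into its set, so the feasible support is the intersection of such sets
  allowed <- rep(TRUE, length(feats))
  hard <- reqa == k
  if (any(hard))
    allowed <- colSums(mm[hard, , drop = FALSE]) == sum(hard)
  forced_pos <- match(instance$forced, feats)
  if (any(!allowed[forced_pos])) return(infeasible_sig())
  if (sum(allowed) < k) return(infeasible_sig())
  if (nrow(mm)) {
    cover <- if (all(allowed)) rowSums(mm)
             else rowSums(mm[, allowed, drop = FALSE])
    if (any(cover < reqa)) return(infeasible_sig())

    # counting bound: a selection's total pair misses sum(k - coverage_p)
    # cannot beat the k best-covering features, and must stay within the
    # total slack sum(k - req_p)
    miss <- nrow(mm) - colSums(mm)
    names(miss) <- feats
    forced_miss <- sum(miss[instance$forced])
    free_ok <- allowed & !(feats %in% instance$forced)
    free_miss <- sort(miss[free_ok])
    n_free <- k - length(instance$forced)
    min_total_miss <- forced_miss +
      if (n_free > 0L) sum(free_miss[seq_len(n_free)]) else 0
    if (min_total_miss > sum(k - reqa)) return(infeasible_sig())
  }

  # greedy candidate: forced features plus the heaviest allowed free
  # features; often feasible and optimal, and an excellent incumbent
  sel_feasible <- function(sel_idx) {
    (alpha == 0L || !nrow(instance$between) ||
       min(rowSums(instance$between[, sel_idx, drop = FALSE])) >= alpha) &&
      (beta == 0L || !nrow(instance$within) ||
         min(rowSums(instance$within[, sel_idx, drop = FALSE])) >= beta)
  }
  free_order <- setdiff(order(-weights, seq_along(feats)),
                        c(forced_pos, which(!allowed)))
  greedy_idx <- c(forced_pos, free_order[seq_len(k - length(forced_pos))])
  greedy_ok <- sel_feasible(greedy_idx)

  if (greedy_ok) {
    # the greedy selection attains the unconstrained objective bound
    # (forced weights plus the largest free weights), so feasibility
    # implies optimality outright
    sel <- sort(greedy_idx)
    return(structure(list(
      selected = feats[sel],
      objective = sum(weights[sel]),
      status = if (feasible_only) "feasible" else "optimal",
      alpha = as.integer(alpha), beta = as.integer(beta), k = k,
      forced = instance$forced, nodes = 0), class = "signature"))
  }

  req_full <- req            # vacuous rows keep req 0; solver skips them
  banned_idx <- which(!allowed) - 1L
  forced_idx <- forced_pos - 1L
  run_bb <- function(feas, incumbent)
    .fs_branch_and_bound(length(feats), sv$fp, req_full,
                         as.numeric(weights), k,
                         as.integer(forced_idx), as.integer(banned_idx),
                         feas, node_limit, as.integer(incumbent))
  if (feasible_only) {
    res <- run_bb(TRUE, integer(0))
  } else {
    # repair the greedy selection toward feasibility by swapping the
    # lightest selected feature outside a violated pair's set for the
    # heaviest unselected feature inside it; the result (or, failing
    # that, the solver's first feasible solution) seeds the optimizing
    # search so the objective bound prunes from the root
    sel <- greedy_idx
    incumbent <- NULL
    for (it in seq_len(100L)) {
      bc <- if (nrow(instance$between))
        rowSums(instance$between[, sel, drop = FALSE]) else numeric(0)
      wc <- if (nrow(instance$within))
        rowSums(instance$within[, sel, drop = FALSE]) else numeric(0)
      vb <- which(bc < alpha); vw <- which(wc < beta)
      if (!length(vb) && !length(vw)) { incumbent <- sel; break }
      if (length(vb)) {
        p <- vb[which.min(bc[vb])]
        inset <- instance$between[p, ]
      } else {
        p <- vw[which.min(wc[vw])]
        inset <- instance$within[p, ]
      }
      cand <- setdiff(which(inset & allowed), sel)
      cand <- cand[order(-weights[cand])]
      drop <- setdiff(sel[!inset[sel]], forced_pos)
      drop <- drop[order(weights[drop])]
      if (!length(cand) || !length(drop)) break
      sel <- c(setdiff(sel, drop[1L]), cand[1L])
    }
    if (!is.null(incumbent)) {
      res <- run_bb(FALSE, incumbent - 1L)
    } else {
      feas <- run_bb(TRUE, integer(0))
      res <- if (feas$status == "feasible")
        run_bb(FALSE, feas$selected) else feas
    }
  }
  if (res$status %in% c("node_limit", "node_limit_feasible")) {
    cond <- structure(
      class = c("metasig_node_limit", "error", "condition"),
      list(message = sprintf(
             "branch-and-bound node limit (%g) exceeded; best incumbent objective: %s",
             node_limit,
             if (res$status == "node_limit_feasible")
               format(res$objective) else "none"),
           call = sys.call(),
           incumbent = if (res$status == "node_limit_feasible")
             feats[res$selected + 1L] else character(0),
           objective = res$objective))
    stop(cond)
  }
  structure(list(
    selected = if (length(res$selected)) feats[res$selected + 1L]
               else character(0),
    objective = res$objective,
    status = res$status,
    alpha = as.integer(alpha), beta = as.integer(beta),
    k = instance$k, forced = instance$forced,
    nodes = res$nodes), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature (k=%d, alpha=%d, beta=%d, status=%s, objective=%s)\n",
              x$k, x$alpha, x$beta, x$status, format(x$objective)))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Verify a signature against its instance by direct set arithmetic
#'
#' Independent of the solver: recomputes |selected|, forced containment,
#' per-pair coverage and the objective straight from the membership
#' matrices.
#'
#' @param sig A [solve_signature()] result.
#' @param instance The [build_instance()] it was solved on.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_signature <- function(sig, instance) {
  sel <- match(sig$selected, instance$features)
  if (anyNA(sel)) stop("signature references unknown features")
  if (length(sel) != sig$k) stop("signature size differs from k")
  if (!all(sig$forced %in% sig$selected))
    stop("forced features missing from signature")
  if (sig$alpha > 0 && nrow(instance$between) &&
      min(rowSums(instance$between[, sel, drop = FALSE])) < sig$alpha)
    stop("alpha coverage violated")
  if (sig$beta > 0 && nrow(instance$within) &&
      min(rowSums(instance$within[, sel, drop = FALSE])) < sig$beta)
    stop("beta coverage violated")
  obj <- sum(instance$between[, sel, drop = FALSE]) +
    sum(instance$within[, sel, drop = FALSE])
  if (!isTRUE(all.equal(obj, sig$objective)))
    stop("objective mismatch: recomputed ", obj, " vs reported ",
         sig$objective)
  invisible(TRUE)
}

#' Select a signature from a panel in one call
#'
#' Convenience wrapper running [filter_matrix()], [build_instance()],
#' [max_alpha()], [max_beta()] and [solve_signature()] in sequence — the
#' feature-selection step of the pipeline.
#'
#' @param panel Expanded (base + metafeature) continuous [panel_matrix()]
#'   of training samples.
#' @param k Signature size.
#' @param forced Features to force into the signature (silently reduced to
#'   those passing the filter, with a warning).
#' @param node_limit Passed to [solve_signature()].
#' @return The `signature`, with the fitted `scheme` and `instance` attached
#'   as attributes `"scheme"` and `"instance"`.
#' @export
select_signature <- function(panel, k, forced = character(0),
                             node_limit = 5e7) {
  scheme <- filter_matrix(panel)
  instance <- build_instance(scheme, k, forced)
  alpha <- max_alpha(instance)
  beta <- max_beta(instance, alpha)
  sig <- solve_signature(instance, alpha, beta, node_limit = node_limit)
  attr(sig, "scheme") <- scheme
  attr(sig, "instance") <- instance
  sig
}

#' Drop single features from a mixed signature
#'
#' Post-processing step that keeps only the pairwise-difference metafeatures
#' of a signature, used to assess whether the imbalance information alone
#' carries the predictive signal.
#'
#' @param sig A `signature`.
#' @param provenance Feature provenance table (e.g.
#'   `panel$provenance`).
#' @return A `signature` whose `selected` retains only metafeatures (`k`
#'   adjusted accordingly; objective/alpha/beta are no longer meaningful and
#'   set to `NA`).
#' @export
strip_single_features <- function(sig, provenance) {
  kind <- provenance$kind[match(sig$selected, provenance$name)]
  if (anyNA(kind)) stop("signature features missing from provenance")
  keep <- sig$selected[kind == "metafeature"]
  structure(list(selected = keep, objective = NA_real_, status = sig$status,
                 alpha = NA_integer_, beta = NA_integer_,
                 k = length(keep),
                 forced = intersect(sig$forced, keep)),
            class = "signature")
}
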