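#' Default multi-family classifier panel
#'
#' A 25-member panel spanning six model families — (naive) Bayes and
#' Gaussian discriminants, linear/functional models, instance-based
#' learners, tree learners, ensemble/meta learners and a nearest-centroid
#' rule — mirroring the design principle that a consensus across classifiers
#' built on different mathematical principles is more trustworthy than any
#' single model. All members run with their implementation's default
#' hyperparameters (no tuning, no cross-validation); the only deliberate
#' settings are a second nearest-neighbour member with k = 2 to distinguish
#' it from the 1-NN member, and a nearest-centroid rule with zero shrinkage
#' so that it performs no feature selection of its own.
#'
#' @param size Number of members, counted off the front of the default
#'   roster (default 25, the full roster).
#' @param seed Base seed; member i runs under `seed + i`.
#' @return Data frame with columns `name`, `family`, `seed`.
#' @export
classifier_panel <- function(size = 25L, seed = 2000L) {
  roster <- data.frame(
    name = c("naive_bayes", "lda",
             "logistic", "probit", "multinom_logistic", "glmnet_ridge",
             "glmnet_lasso", "glmnet_enet",
             "svm_linear", "svm_rbf", "ksvm_rbf", "nnet_mlp",
             "knn1", "knn2", "knn3", "knn5",
             "rpart", "rpart_deep", "tree",
             "random_forest", "ranger_committee", "xgboost",
             "boosted_stumps", "bagged_rpart",
             "nearest_centroid"),
    family = c(rep("bayes", 2L),
               rep("functions", 10L),
               rep("lazy", 4L),
               rep("trees", 3L),
               rep("meta", 5L),
               "centroid"),
    stringsAsFactors = FALSE)
  if (size > nrow(roster))
    stop("roster has only ", nrow(roster), " members", call. = FALSE)
  out <- roster[seq_len(size), , drop = FALSE]
  out$seed <- seed + seq_len(size)
  rownames(out) <- NULL
  out
}

# class levels used throughout: control first so that "case" is the
# positive class and probability ties fall to control
.y_factor <- function(labels) factor(labels, levels = c("control", "case"))

# probability-of-case -> label, ties predict control
.p_to_label <- function(p) ifelse(p > 0.5, "case", "control")

# Nearest-centroid classifier (shrunken-centroid rule with the shrinkage
# threshold at zero): plain Euclidean distance to per-class mean profiles,
# ties to control.
.fit_nearest_centroid <- function(X, y) {
  cen <- rbind(control = colMeans(X[y == "control", , drop = FALSE]),
               case = colMeans(X[y == "case", , drop = FALSE]))
  function(newX) {
    d_ctrl <- colSums((t(newX) - cen["control", ])^2)
    d_case <- colSums((t(newX) - cen["case", ])^2)
    ifelse(d_case < d_ctrl, "case", "control")
  }
}

# Bagged classification trees: bootstrap-resampled rpart fits, majority
# vote, ties to control.
.fit_bagged_rpart <- function(X, y, n_bags = 25L) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fits <- lapply(seq_len(n_bags), function(b) {
    idx <- sample.int(nrow(df), replace = TRUE)
    # guard: a bootstrap sample must contain both classes
    while (length(unique(df$.y[idx])) < 2L)
      idx <- sample.int(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., df[idx, , drop = FALSE], method = "class")
  })
  function(newX) {
    nd <- data.frame(newX, check.names = FALSE)
    votes <- vapply(fits, function(f)
      predict(f, nd, type = "prob")[, "case"], numeric(nrow(nd)))
    if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
    .p_to_label(rowMeans(votes))
  }
}

# Fit one member and return a prediction closure newX -> character labels.
# Every stochastic fit runs under the member's seed; closures re-seed at
# prediction time so lazy learners are deterministic too. Feature names
# (metafeatures contain "-") are replaced by positional names so every
# formula-based backend accepts them; prediction inputs are renamed the
# same way.
.fit_member <- function(name, seed, X, y) {
  set.seed(seed)
  safe_names <- sprintf("V%d", seq_len(ncol(X)))
  colnames(X) <- safe_names
  df <- data.frame(.y = y, X, check.names = FALSE)
  predictor <- switch(
    name,
    naive_bayes = {
      fit <- e1071::naiveBayes(X, y)
      function(newX) .p_to_label(
        predict(fit, newX, type = "raw")[, "case"])
    },
    lda = {
      # collinear signature columns (metafeatures sharing a parent) are
      # routine; lda handles them, the warning is noise
      fit <- suppressWarnings(MASS::lda(X, grouping = y))
      function(newX) .p_to_label(
        predict(fit, newX)$posterior[, "case"])
    },
    probit = {
      fit <- suppressWarnings(
        stats::glm(.y ~ ., df, family = stats::binomial("probit")))
      function(newX) .p_to_label(suppressWarnings(
        predict(fit, data.frame(newX, check.names = FALSE),
                type = "response")))
    },
    multinom_logistic = {
      fit <- nnet::multinom(.y ~ ., df, trace = FALSE)
      function(newX) .p_to_label(
        as.numeric(predict(fit, data.frame(newX, check.names = FALSE),
                           type = "probs")))
    },
    logistic = {
      fit <- suppressWarnings(
        stats::glm(.y ~ ., df, family = stats::binomial()))
      function(newX) .p_to_label(suppressWarnings(
        predict(fit, data.frame(newX, check.names = FALSE),
                type = "response")))
    },
    glmnet_ridge = ,
    glmnet_lasso = ,
    glmnet_enet = {
      al <- c(glmnet_ridge = 0, glmnet_lasso = 1, glmnet_enet = 0.5)[[name]]
      lam <- c(glmnet_ridge = 0.1, glmnet_lasso = 0.05,
               glmnet_enet = 0.05)[[name]]
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = al,
                            lambda = lam)
      function(newX) .p_to_label(
        as.numeric(predict(fit, newX, type = "response")))
    },
    svm_linear = {
      fit <- e1071::svm(X, y, kernel = "linear")
      function(newX) as.character(predict(fit, newX))
    },
    svm_rbf = {
      fit <- e1071::svm(X, y, kernel = "radial")
      function(newX) as.character(predict(fit, newX))
    },
    ksvm_rbf = {
      fit <- kernlab::ksvm(X, y, kernel = "rbfdot")
      function(newX) as.character(kernlab::predict(fit, newX))
    },
    nnet_mlp = {
      fit <- nnet::nnet(X, as.numeric(y == "case"), size = 3L,
                        decay = 0.01, maxit = 200L, entropy = TRUE,
                        trace = FALSE)
      function(newX) .p_to_label(as.numeric(predict(fit, newX)))
    },
    knn1 = ,
    knn2 = ,
    knn3 = ,
    knn5 = {
      kk <- c(knn1 = 1L, knn2 = 2L, knn3 = 3L, knn5 = 5L)[[name]]
      function(newX) {
        set.seed(seed)
        pr <- class::knn(X, newX, y, k = kk, prob = TRUE)
        p_win <- attr(pr, "prob")
        out <- as.character(pr)
        out[p_win <= 0.5] <- "control"       # vote ties fall to control
        out
      }
    },
    rpart = {
      fit <- rpart::rpart(.y ~ ., df, method = "class")
      function(newX) .p_to_label(
        predict(fit, data.frame(newX, check.names = FALSE),
                type = "prob")[, "case"])
    },
    rpart_deep = {
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = 0,
                                                         minsplit = 4L))
      function(newX) .p_to_label(
        predict(fit, data.frame(newX, check.names = FALSE),
                type = "prob")[, "case"])
    },
    tree = {
      fit <- tree::tree(.y ~ ., df)
      function(newX) .p_to_label(
        predict(fit, data.frame(newX, check.names = FALSE))[, "case"])
    },
    random_forest = {
      fit <- randomForest::randomForest(X, y)
      function(newX) .p_to_label(
        predict(fit, newX, type = "prob")[, "case"])
    },
    ranger_committee = {
      fit <- ranger::ranger(x = X, y = y, probability = TRUE,
                            num.threads = 1L, seed = seed)
      function(newX) .p_to_label(
        predict(fit, newX, num.threads = 1L)$predictions[, "case"])
    },
    xgboost = ,
    boosted_stumps = {
      depth <- if (name == "xgboost") 6L else 1L
      eta <- if (name == "xgboost") 0.3 else 0.5
      fit <- xgboost::xgboost(X, y, nrounds = 50L, max_depth = depth,
                              learning_rate = eta, nthreads = 1L,
                              verbosity = 0)
      # predict() returns the probability of the last factor level ("case")
      function(newX) .p_to_label(as.numeric(predict(fit, newX)))
    },
    bagged_rpart = .fit_bagged_rpart(X, y),
    nearest_centroid = .fit_nearest_centroid(X, y),
    majority = {
      maj <- names(which.max(table(y)))    # baseline member used in tests
      function(newX) rep(maj, nrow(newX))
    },
    stop("unknown classifier: ", name, call. = FALSE))
  function(newX) {
    colnames(newX) <- safe_names
    predictor(newX)
  }
}

#' Fit the classifier panel and collect predictions and metrics
#'
#' Every member is fit once on the full training set (continuous values,
#' restricted to the signature if one is given) and produces predictions
#' for the training set itself (resubstitution, the basis of the
#' disagreement analysis) and for each supplied evaluation set. Samples
#' labelled `"other"` are excluded from training and from all metrics but
#' still receive predictions.
#'
#' @param train Training [panel_matrix()].
#' @param eval_sets Named list of [panel_matrix()] evaluation sets.
#' @param signature Optional `signature` (or character vector of feature
#'   names) to restrict all sets to.
#' @param members Panel roster from [classifier_panel()].
#' @return An `ensemble_report`: list with `members`, `predictions` (named
#'   list of samples x members character matrices, first element `train`),
#'   `metrics` (long data frame: set, member, family, accuracy, sensitivity,
#'   specificity), `summary` (per-set unweighted mean and sd over members)
#'   and `observed` (training labels used).
#' @export
ensemble_fit_predict <- function(train, eval_sets = list(),
                                 signature = NULL,
                                 members = classifier_panel()) {
  stopifnot(inherits(train, "panel_matrix"))
  feats <- if (inherits(signature, "signature")) signature$selected
           else signature
  if (!is.null(feats)) {
    train <- panel_subset(train, features = feats)
    eval_sets <- lapply(eval_sets, panel_subset, features = feats)
  }
  keep <- train$labels %in% c("case", "control")
  X <- train$values[keep, , drop = FALSE]
  y <- .y_factor(train$labels[keep])
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)

  sets <- c(list(train = X),
            lapply(eval_sets, function(p) p$values))
  preds <- lapply(sets, function(s)
    matrix(NA_character_, nrow(s), nrow(members),
           dimnames = list(rownames(s), members$name)))
  for (m in seq_len(nrow(members))) {
    fn <- .fit_member(members$name[m], members$seed[m], X, y)
    for (s in names(sets))
      preds[[s]][, m] <- fn(sets[[s]])
  }

  truth <- c(list(train = as.character(y)),
             lapply(eval_sets, function(p) p$labels))
  metrics <- do.call(rbind, lapply(names(sets), function(s) {
    mt <- t(vapply(seq_len(nrow(members)), function(m)
      classification_metrics(preds[[s]][, m], truth[[s]]), numeric(3)))
    data.frame(set = s, member = members$name, family = members$family,
               accuracy = mt[, 1L], sensitivity = mt[, 2L],
               specificity = mt[, 3L], stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(split(metrics, metrics$set), function(d)
    data.frame(set = d$set[1L],
               avg_acc = mean(d$accuracy), sd_acc = stats::sd(d$accuracy),
               avg_sens = mean(d$sensitivity),
               sd_sens = stats::sd(d$sensitivity),
               avg_spec = mean(d$specificity),
               sd_spec = stats::sd(d$specificity),
               stringsAsFactors = FALSE)))
  summary <- summary[match(names(sets), summary$set), ]
  rownames(summary) <- NULL

  structure(list(members = members, predictions = preds,
                 metrics = metrics, summary = summary,
                 observed = as.character(y)),
            class = "ensemble_report")
}

#' Accuracy, sensitivity and specificity of one prediction vector
#'
#' The case class is positive: sensitivity = TP/(TP+FN) over true cases,
#' specificity = TN/(TN+FP) over true controls. Samples labelled `"other"`
#' are excluded.
#'
#' @param pred Character predictions in `case`/`control`.
#' @param truth Character truth in `case`/`control`/`other`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(pred, truth) {
  keep <- truth %in% c("case", "control")
  pred <- pred[keep]; truth <- truth[keep]
  tp <- sum(pred == "case" & truth == "case")
  fn <- sum(pred == "control" & truth == "case")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "case" & truth == "control")
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Per-training-sample disagreement counts
#'
#' For each training sample, the number of panel members whose
#' resubstitution prediction contradicts the sample's observed clinical
#' label. Consistently contradicted samples are candidates for label noise.
#'
#' @param report An [ensemble_fit_predict()] result.
#' @return Named integer vector (training sample ids), each in `[0, N]`.
#' @export
disagreement_counts <- function(report) {
  stopifnot(inherits(report, "ensemble_report"))
  p <- report$predictions$train
  obs <- report$observed
  stats::setNames(as.integer(rowSums(p != obs)), rownames(p))
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("ensemble_report: %d members, sets: %s\n",
              nrow(x$members),
              paste(names(x$predictions), collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}
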