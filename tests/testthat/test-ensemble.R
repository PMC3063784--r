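# small separable panel reused across tests
sep_panel <- local({
  set.seed(81)
  n <- 40L
  y <- rep(c("case", "control"), each = 20L)
  X <- cbind(A = rnorm(n, ifelse(y == "case", 4, -4), 0.5),
             B = rnorm(n, ifelse(y == "case", -3, 3), 0.5),
             C = rnorm(n))
  rownames(X) <- sprintf("s%d", 1:n)
  panel_matrix(X, y)
})

test_that("the default roster has 25 deterministic members over >= 5 families", {
  panel <- classifier_panel()
  expect_identical(nrow(panel), 25L)
  expect_gte(length(unique(panel$family)), 5L)
  expect_identical(anyDuplicated(panel$name), 0L)
  expect_identical(panel, classifier_panel())
})

test_that("a perfectly separated panel yields unanimous correct predictions", {
  rep1 <- ensemble_fit_predict(sep_panel)
  expect_equal(rep1$summary$avg_acc, 1.0)
  expect_equal(rep1$summary$avg_sens, 1.0)
  expect_equal(rep1$summary$avg_spec, 1.0)
  expect_true(all(disagreement_counts(rep1) == 0L))
  expect_identical(nrow(disagreement_histogram(rep1)), 0L)
})

test_that("the ensemble is reproducible and honours signature restriction", {
  members <- classifier_panel(6L)
  r1 <- ensemble_fit_predict(sep_panel, members = members,
                             signature = c("A", "B"))
  r2 <- ensemble_fit_predict(sep_panel, members = members,
                             signature = c("A", "B"))
  expect_identical(r1$predictions, r2$predictions)
  expect_error(ensemble_fit_predict(sep_panel, signature = "nope"),
               "nope")
  one_class <- panel_matrix(sep_panel$values[1:20, ],
                            rep("case", 20L))
  expect_error(ensemble_fit_predict(one_class, members = members),
               "both classes")
})

test_that("metrics follow the confusion-matrix identities", {
  # TP=9, FN=1, TN=8, FP=2
  truth <- c(rep("case", 10L), rep("control", 10L))
  pred <- c(rep("case", 9L), "control", rep("control", 8L), "case", "case")
  m <- classification_metrics(pred, truth)
  expect_equal(unname(m["accuracy"]), 17 / 20)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  # samples labelled other never enter the metrics
  m2 <- classification_metrics(c(pred, "case", "control"),
                               c(truth, "other", "other"))
  expect_equal(m, m2)
})

test_that("disagreement counts equal a brute-force recount", {
  set.seed(82)
  members <- classifier_panel(8L)
  X <- sep_panel$values
  X[1:4, ] <- X[sample(21:24), ]           # corrupt some case samples
  noisy <- panel_matrix(X, sep_panel$labels)
  r <- ensemble_fit_predict(noisy, members = members)
  d <- disagreement_counts(r)
  p <- r$predictions$train
  for (s in rownames(p))
    expect_identical(unname(d[s]),
                     sum(p[s, ] != r$observed[match(s, rownames(p))]))
  h <- disagreement_histogram(r)
  expect_true(all(h$count > 0L))
  expect_setequal(h$sample_id, names(d)[d > 0L])
})

test_that("the nearest-centroid rule matches a hand-computed example", {
  X <- rbind(s1 = c(0, 0), s2 = c(2, 0), s3 = c(10, 0), s4 = c(12, 0))
  colnames(X) <- c("F1", "F2")
  y <- c("case", "case", "control", "control")
  p <- panel_matrix(X, y)
  members <- data.frame(name = "nearest_centroid", family = "centroid",
                        seed = 1L, stringsAsFactors = FALSE)
  newX <- rbind(q1 = c(3, 0), q2 = c(9, 0))
  colnames(newX) <- c("F1", "F2")
  r <- ensemble_fit_predict(
    p, eval_sets = list(new = panel_matrix(newX, c("case", "control"))),
    members = members)
  # centroids at x = 1 (case) and x = 11 (control): 3 -> case, 9 -> control
  expect_identical(unname(r$predictions$new[, 1L]), c("case", "control"))
})

test_that("adding a majority-class member shifts averages predictably", {
  members <- classifier_panel(5L)
  base <- ensemble_fit_predict(sep_panel, members = members)
  withmaj <- rbind(members,
                   data.frame(name = "majority", family = "baseline",
                              seed = 999L))
  r <- ensemble_fit_predict(sep_panel, members = withmaj)
  # majority member predicts one class for everything: accuracy = class
  # balance of the training set (20/40 here)
  maj_acc <- classification_metrics(r$predictions$train[, "majority"],
                                    r$observed)["accuracy"]
  expect_equal(unname(maj_acc), 0.5)
  n <- nrow(members)
  expect_equal(r$summary$avg_acc[r$summary$set == "train"],
               (n * base$summary$avg_acc[base$summary$set == "train"] +
                  maj_acc[[1L]]) / (n + 1L))
})

test_that("other-labelled evaluation samples get predictions but no metrics", {
  test <- panel_matrix(sep_panel$values[c(1:5, 21:25, 6:7), ],
                       c(rep("case", 5L), rep("control", 5L),
                         rep("other", 2L)))
  members <- classifier_panel(4L)
  r <- ensemble_fit_predict(sep_panel, eval_sets = list(ts = test),
                            members = members)
  expect_identical(nrow(r$predictions$ts), 12L)   # all samples predicted
  expect_equal(r$summary$avg_acc[r$summary$set == "ts"], 1.0)
})
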