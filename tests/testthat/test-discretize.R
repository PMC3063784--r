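test_that("class entropy matches the closed form", {
  expect_equal(class_entropy(rep("A", 4L)), 0)
  expect_equal(class_entropy(c("A", "A", "B", "B")), 1.0)
  expect_equal(class_entropy(c("A", "A", "A", "B")),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_equal(class_entropy(rep(c("A", "B", "C", "D"), 3L)), 2)
  expect_error(class_entropy(character(0)), "empty")
})

test_that("best cut minimizes weighted child entropy with smallest-cut ties", {
  bc <- best_cut(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(bc$cut, 2.5)
  expect_equal(bc$gain, 1.0)

  expect_null(best_cut(c(2, 2, 2), c("A", "B", "A")))

  # alternating labels: confirm against exhaustive evaluation of midpoints
  v <- c(1, 2, 3, 4); y <- c("A", "B", "A", "B")
  bc <- best_cut(v, y)
  or <- oracle_best_cut(v, y)
  expect_equal(bc$cut, or$cut)
  expect_equal(bc$gain, or$gain)
})

test_that("MDL acceptance reproduces the closed-form threshold", {
  # perfect split of 4 samples: gain 1.0 vs (log2 3 + log2 7 - 2)/4 = 0.598
  parent <- c("A", "A", "B", "B")
  expect_true(mdl_accept(parent, c("A", "A"), c("B", "B"), 1.0))
  thr <- (log2(3) + log2(7) - 2) / 4
  expect_false(mdl_accept(parent, c("A", "A"), c("B", "B"), thr - 1e-9))
  # a pure parent has gain 0, never accepted
  expect_false(mdl_accept(rep("A", 6L), rep("A", 3L), rep("A", 3L), 0))
  # random splits agree with an independent re-evaluation of the formula
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:30, 1L)
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2L) next
    sp <- sample(seq_len(n - 1L), 1L)
    g <- runif(1, 0, 1)
    expect_identical(mdl_accept(y, y[1:sp], y[(sp + 1L):n], g),
                     oracle_mdl_accept(y, y[1:sp], y[(sp + 1L):n], g))
  }
})

test_that("recursive discretization handles canonical shapes", {
  # perfectly separated: one boundary, pure children stop the recursion
  cuts <- discretize_feature(c(1, 2, 3, 10, 11, 12, 13),
                             c("A", "A", "A", "B", "B", "B", "B"))
  expect_length(cuts, 1L)
  expect_equal(cuts, 6.5)
  # constant feature: nothing to cut
  expect_length(discretize_feature(rep(1, 6L), rep(c("A", "B"), 3L)), 0L)
  # three clusters A | B | A with enough samples: two cuts, equal to the
  # brute-force recursive reference
  v <- c(1:20, 41:60, 81:100)
  y <- rep(c("A", "B", "A"), each = 20L)
  cuts <- discretize_feature(v, y)
  expect_length(cuts, 2L)
  expect_equal(cuts, oracle_discretize(v, y))
})

test_that("discretizer agrees with the brute-force oracle on random data", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(5:30, 1L)
    v <- rnorm(n)
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2L) y[1:2] <- c("A", "B")
    if (runif(1) < 0.5) v <- v + (y == "B") * runif(1, 0.5, 3)
    expect_equal(discretize_feature(v, y), oracle_discretize(v, y),
                 info = sprintf("instance %d", i))
  }
})

test_that("tied discrete values give the oracle's partition", {
  # grid-valued data exercises equal-gain ties; pass/fail and interval
  # assignment must match even if a tie could admit another cut position
  set.seed(23)
  for (i in 1:20) {
    n <- sample(8:30, 1L)
    v <- sample(1:5, n, replace = TRUE)
    y <- ifelse(v >= 4, "B", sample(c("A", "B"), n, replace = TRUE))
    if (length(unique(y)) < 2L) next
    cuts <- discretize_feature(v, y)
    ocuts <- oracle_discretize(v, y)
    expect_identical(length(cuts) > 0L, length(ocuts) > 0L)
    expect_identical(findInterval(v, cuts), findInterval(v, ocuts))
  }
})

test_that("discretization is invariant under monotone transforms", {
  set.seed(31)
  for (i in 1:10) {
    n <- 40L
    y <- rep(c("A", "B"), each = 20L)
    v <- rnorm(n) + (y == "B") * 1.8
    cuts <- discretize_feature(v, y)
    tv <- exp(v / 2)                        # strictly increasing
    tcuts <- discretize_feature(tv, y)
    expect_identical(length(cuts), length(tcuts))
    expect_identical(findInterval(v, cuts), findInterval(tv, tcuts))
  }
})

test_that("filter_matrix discretizes per column and demands two classes", {
  set.seed(41)
  n <- 60L
  y <- rep(c("case", "control"), each = 30L)
  vals <- cbind(strong = rnorm(n) + (y == "case") * 3,
                noise = rnorm(n))
  rownames(vals) <- sprintf("s%d", 1:n)
  p <- panel_matrix(vals, y)
  sch <- filter_matrix(p)
  expect_true(sch$passed[["strong"]])
  expect_false(sch$passed[["noise"]])
  expect_identical(colnames(sch$discrete), "strong")
  # interval index = number of cuts strictly below the value
  expect_identical(unname(sch$discrete[, "strong"]),
                   findInterval(vals[, "strong"], sch$cuts$strong))

  p1 <- panel_matrix(vals, rep("case", n))
  expect_error(filter_matrix(p1), "both classes")
})

test_that("the imbalance-pair scenario passes only through its metafeature", {
  # two proteins share a dominating per-sample offset; each alone fails the
  # entropy filter, their difference passes
  cfg <- generator_config(n_proteins = 60L, n_samples_per_class = c(40L, 40L),
                          n_single_markers = 0L, n_imbalance_pairs = 1L,
                          imbalance_effect = 1.2, shared_noise_sd = 5,
                          background_sd = 1, seed = 99L)
  me <- make_expanded(cfg)
  sch <- filter_matrix(me$expanded)
  members <- as.vector(me$ds$truth$imbalance_pairs)
  expect_false(any(sch$passed[members]))
  expect_true(sch$passed[[planted_metafeatures(me$ds)]])
})
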