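test_that("coverage instances enumerate pairs and explaining sets by hand", {
  # 2 samples per class, 3 features: 4 between-class and 2 within-class pairs
  disc <- rbind(s1 = c(0L, 1L, 0L),
                s2 = c(0L, 1L, 1L),
                s3 = c(1L, 0L, 0L),
                s4 = c(1L, 0L, 1L))
  colnames(disc) <- c("F1", "F2", "F3")
  labels <- c("case", "case", "control", "control")
  inst <- build_instance(make_scheme(disc, labels), k = 2L)
  expect_identical(nrow(inst$between), 4L)
  expect_identical(nrow(inst$within), 2L)
  # hand enumeration: s1-s3 differ on F1,F2; s1-s4 on F1,F2,F3;
  # s2-s3 on F1,F2,F3; s2-s4 on F1,F2
  expect_identical(unname(inst$between[c("s1|s3", "s1|s4",
                                         "s2|s3", "s2|s4"), ]),
                   rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                         c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE)))
  # within: s1-s2 agree on F1,F2; s3-s4 agree on F1,F2
  expect_identical(unname(inst$within[c("s1|s2", "s3|s4"), ]),
                   rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)))
})

test_that("identical rows in opposite classes are an infeasibility report", {
  disc <- rbind(s1 = c(1L, 0L), s2 = c(1L, 0L))
  colnames(disc) <- c("F1", "F2")
  expect_error(build_instance(make_scheme(disc, c("case", "control")),
                              k = 1L),
               "s1\\|s2")
})

test_that("forced features that failed the filter are dropped with a warning", {
  set.seed(51)
  n <- 40L
  y <- rep(c("case", "control"), each = 20L)
  vals <- cbind(good = rnorm(n) + (y == "case") * 8, junk = rnorm(n))
  rownames(vals) <- sprintf("s%d", 1:n)
  sch <- filter_matrix(panel_matrix(vals, y))
  expect_warning(inst <- build_instance(sch, k = 1L,
                                        forced = c("good", "junk")),
                 "junk")
  expect_identical(inst$forced, "good")
  expect_error(build_instance(sch, k = 0L, forced = "good"), "forced")
})

test_that("alpha equals the hardest pair's count when that count is feasible", {
  # features F1..F7 separate every between-class pair, F8..F12 none;
  # the hardest (indeed every) pair has exactly 7 explaining features
  disc <- cbind(matrix(rep(c(0L, 1L), each = 3L, times = 7L), 6L, 7L),
                matrix(0L, 6L, 5L))
  labels <- rep(c("case", "control"), each = 3L)
  inst <- build_instance(make_scheme(disc, labels), k = 10L)
  expect_identical(max_alpha(inst), 7L)
  # and with k = 1 on a single separating feature: alpha = beta = 1
  disc1 <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
  inst1 <- build_instance(make_scheme(disc1,
                                      rep(c("case", "control"),
                                          each = 2L)), k = 1L)
  expect_identical(max_alpha(inst1), 1L)
  expect_identical(max_beta(inst1, 1L), 1L)
})

test_that("beta can sit strictly below its cap when the joint problem binds", {
  # search random instances for one where the agreement cap is jointly
  # infeasible with alpha, then confirm both sides by subset enumeration
  found <- FALSE
  for (s in 1:80) {
    inst <- random_instance(3L, 8L, k = 3L, seed = 3000L + s)
    a <- max_alpha(inst)
    cap <- min(inst$k, min(rowSums(inst$within)))
    b <- max_beta(inst, a)
    expect_false(is.null(oracle_enum_signature(inst, a, b)))
    if (b < cap) {
      found <- TRUE
      expect_null(oracle_enum_signature(inst, a, b + 1L))
      break
    }
  }
  expect_true(found)
})

test_that("solver optimum equals exhaustive enumeration on random instances", {
  set.seed(61)
  for (i in 1:30) {
    npc <- sample(2:4, 1L)
    m <- sample(6:12, 1L)
    k <- sample(2:4, 1L)
    inst <- random_instance(npc, m, k, seed = 1000L + i)
    a <- max_alpha(inst)
    b <- max_beta(inst, a)
    sig <- solve_signature(inst, a, b)
    o <- oracle_enum_signature(inst, a, b)
    expect_identical(sig$status, "optimal")
    expect_equal(sig$objective, o$objective,
                 info = sprintf("instance %d", i))
    validate_signature(sig, inst)
  }
})

test_that("selecting every feature is trivially optimal", {
  inst <- random_instance(3L, 6L, k = 6L, seed = 77L)
  a <- max_alpha(inst); b <- max_beta(inst, a)
  sig <- solve_signature(inst, a, b)
  expect_setequal(sig$selected, inst$features)
  expect_equal(sig$objective, sum(inst$between) + sum(inst$within))
})

test_that("raising alpha never helps the objective nor restores feasibility", {
  set.seed(71)
  for (i in 1:8) {
    inst <- random_instance(3L, 8L, k = 3L, seed = 2000L + i)
    prev_obj <- Inf
    seen_infeasible <- FALSE
    for (a in 0:3) {
      sig <- solve_signature(inst, a, 0L)
      if (sig$status == "optimal") {
        expect_false(seen_infeasible)     # feasibility is monotone in alpha
        expect_lte(sig$objective, prev_obj)
        prev_obj <- sig$objective
      } else {
        seen_infeasible <- TRUE
      }
    }
  }
})

test_that("forced features appear in the solved signature", {
  cfg <- generator_config(n_proteins = 16L,
                          n_samples_per_class = c(30L, 30L),
                          n_single_markers = 3L, single_effect = 2.5,
                          n_imbalance_pairs = 2L, imbalance_effect = 1.5,
                          shared_noise_sd = 4, background_sd = 0.8,
                          seed = 13L)
  me <- make_expanded(cfg)
  forced <- me$ds$truth$single_markers
  sig <- select_signature(me$expanded, k = 6L, forced = forced)
  expect_identical(sig$status, "optimal")
  expect_length(sig$selected, 6L)
  expect_true(all(sig$forced %in% sig$selected))
  validate_signature(sig, attr(sig, "instance"))
})

test_that("stripping single features leaves only metafeatures", {
  prov <- data.frame(name = c("A", "B", "A-B", "B-C"),
                     kind = c("base", "base", "metafeature", "metafeature"),
                     member1 = c(NA, NA, "A", "B"),
                     member2 = c(NA, NA, "B", "C"),
                     stringsAsFactors = FALSE)
  sig <- structure(list(selected = c("A", "A-B", "B-C"), objective = 10,
                        status = "optimal", alpha = 1L, beta = 1L, k = 3L,
                        forced = "A"), class = "signature")
  s2 <- strip_single_features(sig, prov)
  expect_identical(s2$selected, c("A-B", "B-C"))
  expect_identical(s2$k, 2L)
})
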