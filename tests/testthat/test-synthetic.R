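test_that("generator configs are validated with the violated invariant named", {
  expect_error(generator_config(n_proteins = 5L, n_single_markers = 2L,
                                n_imbalance_pairs = 2L),
               "n_single_markers")
  expect_error(generator_config(mislabel_fraction = 1.2),
               "mislabel_fraction")
  expect_error(generator_config(background_sd = 0), "background_sd")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- generator_config(n_proteins = 15L, n_samples_per_class = c(8L, 7L),
                          mislabel_fraction = 0.1, seed = 5L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(generator_config(n_proteins = 15L,
                                          n_samples_per_class = c(8L, 7L),
                                          mislabel_fraction = 0.1,
                                          seed = 6L))
  expect_false(identical(d1$panel$values, d3$panel$values))
})

test_that("planted structure and mislabelling honour the config", {
  cfg <- generator_config(n_proteins = 20L,
                          n_samples_per_class = c(25L, 15L),
                          n_single_markers = 3L, n_imbalance_pairs = 2L,
                          mislabel_fraction = 0.125, seed = 2L)
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$panel$values), c(40L, 20L))
  expect_identical(sum(ds$observed_labels != ds$true_labels),
                   as.integer(round(0.125 * 40)))
  planted <- c(ds$truth$single_markers, as.vector(ds$truth$imbalance_pairs))
  expect_true(all(planted %in% colnames(ds$panel$values)))
  expect_identical(anyDuplicated(planted), 0L)
  expect_setequal(ds$truth$mislabelled,
                  rownames(ds$panel$values)[ds$observed_labels !=
                                              ds$true_labels])
})

test_that("generator moments match their closed forms", {
  # strong shared offset, modest antisymmetric shift: each pair member's
  # class separation equals imbalance_effect but is swamped by the shared
  # noise, while the member difference separates by 2*imbalance_effect with
  # only background noise
  cfg <- generator_config(n_proteins = 16L,
                          n_samples_per_class = c(300L, 300L),
                          n_single_markers = 0L, n_imbalance_pairs = 2L,
                          imbalance_effect = 1, shared_noise_sd = 5,
                          background_sd = 0.5, seed = 8L)
  ds <- generate_dataset(cfg)
  x <- ds$panel$values
  case <- ds$true_labels == "case"
  for (r in 1:2) {
    m1 <- ds$truth$imbalance_pairs[r, 1L]
    m2 <- ds$truth$imbalance_pairs[r, 2L]
    sep_m1 <- mean(x[case, m1]) - mean(x[!case, m1])
    d <- x[, m1] - x[, m2]
    sep_d <- mean(d[case]) - mean(d[!case])
    # member separation ~ imbalance_effect, sd sqrt(25.25) => wide tolerance
    expect_equal(sep_m1, 1, tolerance = 1)
    # difference separation ~ 2, sd sqrt(0.5) and n=300 per class
    expect_equal(sep_d, 2, tolerance = 0.25)
    expect_equal(sd(d[case]), sqrt(2 * 0.5^2), tolerance = 0.15)
    # member-level two-sample statistic far below the difference's
    t_m <- abs(t.test(x[case, m1], x[!case, m1])$statistic)
    t_d <- abs(t.test(d[case], d[!case])$statistic)
    expect_lt(t_m, qt(0.999, 500))
    expect_gt(t_d, 10)
  }
})

test_that("a null configuration produces no separating structure", {
  cfg <- generator_config(n_proteins = 20L,
                          n_samples_per_class = c(30L, 30L),
                          single_effect = 0, imbalance_effect = 0,
                          mislabel_fraction = 0, seed = 3L)
  ds <- generate_dataset(cfg)
  x <- zscore_rows(ds$panel)$values
  case <- ds$true_labels == "case"
  tt <- apply(x, 2L, function(col)
    t.test(col[case], col[!case])$p.value)
  expect_gt(min(tt), 1e-4)            # no feature separates beyond chance
})

test_that("null datasets rarely pass the entropy filter", {
  pass_frac <- vapply(1:20, function(s) {
    cfg <- generator_config(n_proteins = 12L,
                            n_samples_per_class = c(25L, 25L),
                            single_effect = 0, imbalance_effect = 0,
                            n_single_markers = 0L, n_imbalance_pairs = 0L,
                            seed = 100L + s)
    me <- make_expanded(cfg)
    sch <- filter_matrix(me$expanded)
    mean(sch$passed)
  }, numeric(1))
  expect_lt(mean(pass_frac), 0.05)
})

test_that("strong planted pairs pass the entropy filter almost surely", {
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(n_proteins = 12L,
                            n_samples_per_class = c(30L, 30L),
                            n_single_markers = 0L, n_imbalance_pairs = 1L,
                            imbalance_effect = 1.5, shared_noise_sd = 4,
                            background_sd = 0.5, seed = 200L + s)
    me <- make_expanded(cfg)
    sch <- filter_matrix(me$expanded)
    sch$passed[[planted_metafeatures(me$ds)]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("datasets round-trip through disk including truth", {
  cfg <- generator_config(n_proteins = 10L, n_samples_per_class = c(6L, 5L),
                          n_single_markers = 2L, n_imbalance_pairs = 1L,
                          mislabel_fraction = 0.2, seed = 12L)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$panel$values, ds$panel$values)
  expect_identical(back$panel$labels, ds$panel$labels)
  expect_identical(back$true_labels, ds$true_labels)
  expect_identical(back$truth$mislabelled, ds$truth$mislabelled)
  expect_identical(back$truth$imbalance_pairs, ds$truth$imbalance_pairs)
})

test_that("malformed panel files are parse errors naming the cell", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tP1\tP2", "s1\t1\t2"), f)   # label column missing
  expect_error(read_panel(f), "class")
  writeLines(c("sample_id\tclass\tP1\tP2",
               "s1\tcase\t1.5\t2.0",
               "s2\tcontrol\toops\t1.0"), f)
  expect_error(read_panel(f), "line 3.*P1")
})
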