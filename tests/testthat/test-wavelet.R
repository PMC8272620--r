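test_that("standardization yields exact zero mean and unit population sd", {
  expect_equal(standardize_signal(c(1, 2, 3)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_error(standardize_signal(c(5, 5, 5)), "zero variance")
  set.seed(4)
  x <- standardize_signal(rnorm(500, 10, 3))
  expect_lt(abs(mean(x)), 1e-9)
  expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-9)
})

test_that("the pyramid decomposition inverts exactly and follows the length recurrence", {
  set.seed(7)
  x <- rnorm(3000)
  for (wv in c("db4", "rbio3.1", "haar")) {
    dec <- dwt_decompose(x, wv, level = 5)
    expect_lt(max(abs(dwt_reconstruct(dec) - x)) / max(abs(x)), 1e-8)
    # level lengths follow n_k = floor((n_{k-1} + f - 1) / 2)
    f <- length(wavelet_filters(wv)$dec_lo)
    n <- length(x)
    for (k in 1:5) {
      n <- floor((n + f - 1) / 2)
      expect_length(dec$details[[k]], n)
    }
  }
  expect_error(dwt_decompose(rnorm(16), "db8", level = 3), "too short")
})

test_that("dwt_scalogram drops the finest bands and re-indexes the rest", {
  x <- rnorm(4096)
  sc <- dwt_scalogram(x, "db2", max_level = 9, drop_finest = 4)
  expect_s3_class(sc, "scalogram")
  expect_named(sc$levels, as.character(1:5))
  dec <- dwt_decompose(x, "db2", level = 9)
  expect_equal(sc$levels[["1"]], dec$details[[5]])
  expect_equal(sc$levels[["5"]], dec$details[[9]])
  # zero signal decomposes to all-zero retained coefficients
  sc0 <- dwt_scalogram(rep(0, 2048), "rbio3.1", drop_finest = 3)
  expect_true(all(abs(unlist(sc0$levels)) == 0))
  expect_error(dwt_scalogram(rnorm(64), "rbio3.1", drop_finest = 7),
               "at least")
})

test_that("a 20-minute recording at 1000 Sa/s leaves ~4700-sample coarse bands", {
  # 1.2e6 samples, rbio3.1, drop the 7 finest: the first retained band's
  # length follows from the level-length recurrence
  f <- 4
  n <- 1.2e6
  for (k in 1:8) n <- floor((n + f - 1) / 2)
  expect_gt(n, 4500 * 0.9)
  expect_lt(n, 4700 * 1.1)
  sc <- dwt_scalogram(numeric(1.2e6), "rbio3.1", max_level = 8, drop_finest = 7)
  expect_length(sc$levels[["1"]], n)
})

test_that("mother-wavelet ranking orders by mean scalogram IQR deterministically", {
  set.seed(21)
  sigs <- replicate(4, synthesize_signal(breathing_params(noise_sd = 0.05),
                                         duration_s = 120, rate = 125,
                                         seed = sample.int(1e6, 1)),
                    simplify = FALSE)
  r1 <- rank_mother_wavelets(sigs, c("db2", "haar", "rbio3.1", "sym4"),
                             drop_finest = 4)
  r2 <- rank_mother_wavelets(sigs, c("db2", "haar", "rbio3.1", "sym4"),
                             drop_finest = 4)
  expect_identical(r1, r2)
  expect_equal(r1$rank, 1:4)
  expect_true(all(diff(r1$mean_iqr) <= 0))
  expect_s3_class(attr(r1, "per_signal"), "tbl_df")
  # single candidate ranks first with its own mean IQR
  r3 <- rank_mother_wavelets(sigs, "db2", drop_finest = 4)
  expect_equal(r3$rank, 1)
  per <- attr(r3, "per_signal")
  expect_equal(r3$mean_iqr, mean(per$iqr))
  # a candidate that cannot decompose the signals is excluded with a warning
  short <- list(structure(rnorm(32), rate = 125, class = "resp_signal"))
  expect_warning(r4 <- rank_mother_wavelets(short, c("haar", "db10"),
                                            drop_finest = 2),
                 "excluded")
  expect_equal(r4$wavelet, "haar")
})

test_that("IQR criterion scales linearly with amplitude, so louder scalograms rank first", {
  # doubling the coefficients doubles the pooled IQR
  x <- rnorm(2048)
  sc <- dwt_scalogram(x, "db2", drop_finest = 3)
  pooled <- unlist(sc$levels)
  q <- quantile(pooled, c(0.25, 0.75), type = 7)
  q2 <- quantile(2 * pooled, c(0.25, 0.75), type = 7)
  expect_equal(diff(unname(q2)), 2 * diff(unname(q)))
  # translation invariance of the IQR descriptor
  q3 <- quantile(pooled + 5, c(0.25, 0.75), type = 7)
  expect_equal(diff(unname(q3)), diff(unname(q)))
})

test_that("quartile descriptors follow the linear-interpolation convention", {
  sc <- structure(list(wavelet = "rbio3.1", drop_finest = 7,
                       levels = list(`5` = as.numeric(1:100),
                                     `6` = rep(3.5, 10),
                                     `7` = rnorm(50))),
                  class = "scalogram")
  d <- extract_descriptors(sc, scales = 5:7)
  expect_equal(d$Scale5_q1, 25.75)
  expect_equal(d$Scale5_q2, 50.5)
  expect_equal(d$Scale5_q3, 75.25)
  expect_equal(d$Scale5_IQR, 49.5)
  # constant coefficient array
  expect_equal(unlist(d[c("Scale6_q1", "Scale6_q2", "Scale6_q3", "Scale6_IQR")],
                      use.names = FALSE), c(3.5, 3.5, 3.5, 0))
  # IQR = Q3 - Q1 exactly, and quartiles are ordered
  expect_equal(d$Scale7_IQR, d$Scale7_q3 - d$Scale7_q1)
  expect_true(d$Scale7_q1 <= d$Scale7_q2 && d$Scale7_q2 <= d$Scale7_q3)
  expect_error(extract_descriptors(sc, scales = 5:8), "lacks retained scale")
  # pure function: identical input, identical output
  expect_identical(extract_descriptors(sc), extract_descriptors(sc))
})

test_that("printed quartile pairs give the printed IQRs where self-consistent", {
  # periodic-like scale 6 and normal scale 7 sample descriptors
  expect_equal(30.95 - (-19.93), 50.88)
  expect_equal(5.01 - (-6.06), 11.07)
})

test_that("periodic-like signals have larger scale-6/7 IQR than normal ones", {
  per_iqr <- numeric(0)
  nor_iqr <- numeric(0)
  for (s in 1:20) {
    p_per <- breathing_params(breath_period_s = 4.5, modulation_depth = 0.85,
                              modulation_period_s = 60, noise_sd = 0.03)
    p_nor <- breathing_params(breath_period_s = 4.5, noise_sd = 0.03)
    d_per <- signal_descriptors(synthesize_signal(p_per, 300, rate = 125,
                                                  seed = 100 + s),
                                drop_finest = 4)
    d_nor <- signal_descriptors(synthesize_signal(p_nor, 300, rate = 125,
                                                  seed = 200 + s),
                                drop_finest = 4)
    per_iqr <- c(per_iqr, d_per$Scale6_IQR + d_per$Scale7_IQR)
    nor_iqr <- c(nor_iqr, d_nor$Scale6_IQR + d_nor$Scale7_IQR)
  }
  wt <- wilcox.test(per_iqr, nor_iqr, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("the decision table has the standard 16 + 1 column layout", {
  gc <- generate_graded_cohort(6, seed = 2, duration_s = 60, rate = 125)
  dt <- cohort_decision_table(gc$cohort, gc$signals, "normal",
                              drop_finest = drop_finest_for_rate(125))
  expect_equal(dim(dt), c(6, 17))
  expect_equal(names(dt),
               c("Scale5_q1", "Scale5_q2", "Scale5_q3", "Scale5_IQR",
                 "Scale6_q1", "Scale6_q2", "Scale6_q3", "Scale6_IQR",
                 "Scale7_q1", "Scale7_q2", "Scale7_q3", "Scale7_IQR",
                 "Age", "Sex", "BMI", "WHR", "decision"))
  expect_true(all(dt$decision %in% 0:10))
  feats <- dplyr::select(dplyr::mutate(dt, subject_id = gc$cohort$subject_id),
                         subject_id, dplyr::starts_with("Scale"))
  expect_error(build_decision_table(feats[-2], gc$cohort, "normal"),
               "missing attribute")
})

test_that("outcome discretization partitions the decile scale for every valid range", {
  expect_equal(as.character(discretize_outcome(c(0, 3, 6, 10), 3, 6)),
               c("A", "B", "C", "C"))
  ranges <- enumerate_outcome_ranges()
  expect_equal(nrow(ranges), 17)
  expect_true(all(ranges$d1 %in% 1:5 & (ranges$d2 - ranges$d1) %in% 2:5 &
                    ranges$d2 < 9))
  expect_true(nrow(dplyr::filter(ranges, d1 == 3, d2 == 8)) == 1)
  # width 2 gives the five pairs (1,3)..(5,7)
  w2 <- dplyr::filter(ranges, d2 - d1 == 2)
  expect_equal(w2$d1, 1:5)
  expect_equal(w2$d2, 3:7)
  # brute-force constraint enumeration oracle
  cnt <- 0
  for (d1 in 1:5) for (w in 2:5) if (d1 + w < 9) cnt <- cnt + 1
  expect_equal(nrow(ranges), cnt)
  for (i in seq_len(nrow(ranges))) {
    lab <- discretize_outcome(0:10, ranges$d1[i], ranges$d2[i])
    expect_false(anyNA(lab))
    expect_equal(sum(table(lab)), 11)
  }
  expect_error(discretize_outcome(0:10, 5, 10), "d2")
  expect_error(discretize_outcome(0:10, 0, 3), "d1")
})

test_that("zero-decile debiasing matches the stated arithmetic", {
  tb <- tibble::tibble(x = seq_len(70),
                       decision = c(rep(0L, 20), rep(1:10, each = 5)))
  out <- debias_subsample(tb, seed = 1)
  expect_equal(sum(out$decision == 0), 5)
  expect_equal(sum(out$decision > 0), 50)
  # already balanced: no-op
  tb2 <- tibble::tibble(x = 1:53, decision = c(rep(0L, 3), rep(1:10, each = 5)))
  expect_identical(debias_subsample(tb2, seed = 1), tb2)
  # determinism
  expect_identical(debias_subsample(tb, seed = 42), debias_subsample(tb, seed = 42))
  expect_error(debias_subsample(tibble::tibble(decision = c(0L, 0L))),
               "nonzero")
})
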