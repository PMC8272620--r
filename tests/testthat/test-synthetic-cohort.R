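test_that("a noise-free normal pattern is an exact train of identical triangles", {
  sig <- synthesize_signal(breathing_params(breath_period_s = 4),
                           duration_s = 40, rate = 100)
  expect_s3_class(sig, "resp_signal")
  expect_length(sig, 4000)
  peaks <- oracle_peaks(as.numeric(sig), min_gap = 200)
  expect_length(peaks, 10)
  amps <- as.numeric(sig)[peaks]
  expect_equal(amps, rep(amps[1], 10), tolerance = 1e-12)
  # triangles are identical up to sample alignment
  expect_equal(diff(peaks), rep(400, 9))
})

test_that("per-breath peaks trace the sinusoidal envelope", {
  p <- breathing_params(breath_period_s = 4, modulation_depth = 0.8,
                        modulation_period_s = 40)
  sig <- synthesize_signal(p, duration_s = 40, rate = 100)
  peaks <- oracle_peaks(as.numeric(sig), min_gap = 200)
  amps <- as.numeric(sig)[peaks]
  # expected peak amplitudes from the envelope at the sampled peak times
  t_peak <- (0:9) * 4 + 0.6 * 4 / 2
  expected <- 1 + 0.8 * sin(2 * pi * t_peak / 40)
  ratio <- max(amps) / min(amps)
  expect_equal(ratio, max(expected) / min(expected), tolerance = 0.05)
  # close to the nominal (1 + m) / (1 - m) = 9 up to envelope sampling
  expect_gt(ratio, 6)
  expect_lt(ratio, 9.5)
})

test_that("synthesis is bit-identical for a fixed seed and leaves the RNG alone", {
  p <- breathing_params(modulation_depth = 0.5, noise_sd = 0.05,
                        apnea_rate_per_min = 0.5)
  s1 <- synthesize_signal(p, duration_s = 120, rate = 50, seed = 11)
  set.seed(99)
  before <- .Random.seed
  s2 <- synthesize_signal(p, duration_s = 120, rate = 50, seed = 11)
  expect_identical(.Random.seed, before)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("invalid generator arguments are rejected", {
  expect_error(breathing_params(apnea_duration_cycles = 3), "exceed 3")
  expect_error(breathing_params(breath_period_s = 0), "positive")
  expect_error(breathing_params(triangle_duty = 1.5), "\\(0, 1\\]")
  expect_error(synthesize_signal(breathing_params(), duration_s = -1),
               "positive")
  expect_error(synthesize_signal(breathing_params(), duration_s = 10,
                                 rate = 0), "positive")
})

test_that("BMI and WHR recompute the printed cohort-table values", {
  a <- compute_anthropometrics(127.00, 190, 116, 121.0)
  expect_equal(a$bmi, 35.1801)
  expect_equal(a$whr, 0.9587)
  b <- compute_anthropometrics(87.00, 164, 90, 111.0)
  expect_equal(b$bmi, 32.3468)
  expect_equal(b$whr, 0.8108)
  c3 <- compute_anthropometrics(80.00, 170, 95, 100.0)
  expect_equal(c3$bmi, 27.6817)
  expect_equal(c3$whr, 0.9500)
  expect_error(compute_anthropometrics(-1, 170, 95, 100), "positive")
})

test_that("cohort records satisfy their construction invariants", {
  cs <- generate_cohort(18, duration_s = 60, rate = 50, seed = 5)
  co <- cs$cohort
  expect_equal(nrow(co), 18)
  expect_equal(co$bmi, co$weight_kg / (co$height_cm / 100)^2)
  expect_equal(co$whr, co$waist_cm / co$hip_cm)
  expect_true(all(co$contrib_periodic + co$contrib_intermediate +
                    co$contrib_normal == 10))
  # 70% labelling rule
  expect_true(all((co$expert_label == 1) == (co$contrib_normal >= 7)))
  expect_true(all((co$expert_label == 3) == (co$contrib_periodic >= 7)))
  inter <- co$expert_label == 2
  expect_true(all(co$contrib_normal[inter] < 7 & co$contrib_periodic[inter] < 7))
  # regeneration with the same seed is bit-exact
  cs2 <- generate_cohort(18, duration_s = 60, rate = 50, seed = 5)
  expect_identical(cs$cohort, cs2$cohort)
  expect_identical(lapply(cs$signals, as.numeric),
                   lapply(cs2$signals, as.numeric))
})

test_that("periodic-like and intermediate groups have higher WHR and male share", {
  whr_means <- sapply(1:10, function(s) {
    co <- generate_cohort(30, duration_s = 20, rate = 25, seed = s)$cohort
    c(normal = mean(co$whr[co$expert_label == 1]),
      periodic = mean(co$whr[co$expert_label == 3]),
      male_n = mean(co$sex[co$expert_label == 1] == "M"),
      male_p = mean(co$sex[co$expert_label == 3] == "M"))
  })
  expect_gt(mean(whr_means["periodic", ]), mean(whr_means["normal", ]))
  expect_gt(mean(whr_means["male_p", ]), mean(whr_means["male_n", ]))
})

test_that("degenerate class mixes are rejected", {
  expect_error(generate_cohort(0, seed = 1), ">= 1")
  expect_error(generate_cohort(5, class_mix = c(normal = 0.5, intermediate = 0.2,
                                                periodic = 0.2), seed = 1),
               "sum to 1")
  expect_error(generate_cohort(5, class_mix = c(a = 1, b = 0, c = 0), seed = 1),
               "named")
})

test_that("apnea detection recovers the inserted gap count exactly", {
  p <- breathing_params(breath_period_s = 4, apnea_rate_per_min = 0.4,
                        apnea_duration_cycles = 4)
  sig <- synthesize_signal(p, duration_s = 1200, rate = 25, seed = 2)
  truth <- attr(sig, "apneas")
  expect_equal(nrow(truth), 8)  # 0.4/min over 20 min
  det <- detect_apneas(sig, breath_period_s = 4)
  expect_equal(det$count, 8)
  expect_equal(det$per_min, 0.4)
  expect_gt(det$mean_duration_s, 3 * 4)
})

test_that("a pure normal signal has no apneas and a 3-cycle gap is not one", {
  sig <- synthesize_signal(breathing_params(breath_period_s = 4),
                           duration_s = 240, rate = 25)
  det <- detect_apneas(sig, breath_period_s = 4)
  expect_equal(det$count, 0)
  expect_equal(det$per_min, 0)
  expect_equal(det$mean_duration_s, 0)

  # hand-built train with a silence of exactly 3 cycles vs clearly longer;
  # the breath's idle tail (41 zero samples plus the triangle's two zero
  # endpoints) is part of the silent stretch and is accounted for
  rate <- 25
  tri <- c(seq(0, 1, length.out = 30), seq(1, 0, length.out = 30)[-1])
  breath <- c(tri, rep(0, 41))  # 4 s breath cycle at 25 Sa/s
  mk <- function(extra) {
    x <- c(rep(breath, 15), rep(0, extra), tri, rep(breath, 14))
    structure(x, rate = rate, class = "resp_signal")
  }
  silence_exact <- 3 * 4 * rate          # 300 samples of no activity
  expect_equal(detect_apneas(mk(silence_exact - 43), 4,
                             activity_threshold = 0.02)$count, 0)
  expect_equal(detect_apneas(mk(round(3.6 * 4 * rate) - 43), 4,
                             activity_threshold = 0.02)$count, 1)
  expect_error(detect_apneas(mk(10), breath_period_s = 1e6),
               "shorter than one breathing cycle")
})

test_that("cohort files round-trip exactly", {
  dir <- withr::local_tempdir()
  cs <- generate_cohort(3, duration_s = 20, rate = 25, seed = 9)
  write_cohort(cs$cohort, cs$signals, dir, seed = 9,
               params = list(duration_s = 20, rate = 25))
  files <- list.files(dir)
  expect_length(grep("^subject_\\d+\\.txt$", files), 3)
  expect_true(all(c("cohort.csv", "manifest.json") %in% files))
  rt <- read_cohort(dir)
  expect_equal(rt$cohort, cs$cohort)
  expect_equal(rt$manifest$seed, 9)
  expect_equal(rt$manifest$rate, 25)
  expect_equal(as.numeric(rt$signals[[1]]), as.numeric(cs$signals[[1]]),
               tolerance = 1e-9)
})

test_that("graded benchmark cohorts are reproducible and consistent", {
  gc <- generate_graded_cohort(12, seed = 3, duration_s = 60, rate = 50)
  co <- gc$cohort
  expect_equal(co$contrib_normal, rep(c(0L, 1L, 4L, 5L, 9L, 10L), 2))
  expect_true(all(co$contrib_periodic + co$contrib_normal == 10))
  gc2 <- generate_graded_cohort(12, seed = 3, duration_s = 60, rate = 50)
  expect_identical(as.numeric(gc$signals[[5]]), as.numeric(gc2$signals[[5]]))
})
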