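test_that("the five normalization schemes match their closed-form fixtures", {
  tb <- tibble::tibble(a = c(-2, 4), b = c(0, 5))
  expect_equal(normalize_features(tb, "maxabs")$a, c(-0.5, 1))
  tb2 <- tibble::tibble(a = c(0, 5, 10))
  expect_equal(normalize_features(tb2, "minmax")$a, c(-1, 0, 1))
  tb3 <- tibble::tibble(a = 3, b = 4)
  expect_equal(unlist(normalize_features(tb3, "row_unit")),
               c(a = 0.6, b = 0.8))
  tb4 <- tibble::tibble(a = c(1, 2, 3))
  expect_equal(normalize_features(tb4, "standardize")$a, c(-1, 0, 1))
  expect_identical(normalize_features(tb, "none"), tb)
  expect_warning(normalize_features(tibble::tibble(a = c(1, 1)), "standardize"),
                 "zero-variance")
  expect_warning(normalize_features(tibble::tibble(a = c(0, 1), b = c(0, 1)),
                                    "row_unit"), "zero-length")
  expect_error(normalize_features(tibble::tibble(a = c("x", "y")), "none"),
               "numeric")
})

test_that("Minkowski distances match the printed examples and metric axioms", {
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 1), 7)
  expect_equal(minkowski_distance(c(1, 2, 3), c(1, 2, 3), 1.5), 0)
  expect_error(minkowski_distance(c(0, 0), c(1, 1, 1), 2), "dimension")
  expect_error(minkowski_distance(c(0, 0), c(1, 1), 0.5), "p must be")
  # symmetry, identity of indiscernibles and triangle inequality
  set.seed(6)
  for (p in c(1, 1.25, 1.5, 1.75, 2)) {
    for (rep in 1:20) {
      x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
      dxy <- minkowski_distance(x, y, p)
      expect_equal(dxy, minkowski_distance(y, x, p))
      expect_gte(dxy, 0)
      expect_lte(dxy, minkowski_distance(x, z, p) +
                   minkowski_distance(z, y, p) + 1e-12)
    }
  }
})

test_that("k-NN with duplicated training points classifies those points perfectly", {
  set.seed(14)
  base <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  labels <- rep(c("A", "B"), each = 10)
  train <- dplyr::bind_rows(base, base)  # each point duplicated
  lab2 <- c(labels, labels)
  pred <- knn_classify(train, lab2, base, k = 2, p = 2)
  expect_equal(as.character(pred), labels)
  expect_error(knn_classify(base, labels, base, k = 1), "k must be")
})

test_that("5x2 cross-validation yields ten folds with coherent summaries", {
  set.seed(25)
  n <- 40
  feats <- tibble::tibble(x = c(rnorm(n / 2), rnorm(n / 2, 6)), y = rnorm(n))
  labels <- rep(c("A", "B"), each = n / 2)
  cv <- five_by_two_cv(feats, labels, k = 3, p = 2, seed = 10)
  folds <- attr(cv, "folds")
  expect_length(folds, 10)
  expect_equal(cv$f1_mean, mean(folds))
  expect_equal(cv$f1_min, min(folds))
  expect_equal(cv$f1_max, max(folds))
  expect_true(cv$f1_min <= cv$f1_mean && cv$f1_mean <= cv$f1_max)
  expect_equal(cv$ci_lo, cv$f1_mean - 1.96 * cv$f1_sd)
  expect_equal(cv$ci_hi, cv$f1_mean + 1.96 * cv$f1_sd)
  # deterministic under a fixed seed
  cv2 <- five_by_two_cv(feats, labels, k = 3, p = 2, seed = 10)
  expect_identical(attr(cv2, "folds"), folds)
  # identical folds give a zero-width interval
  const <- tibble::tibble(x = rep(c(0, 10), 10))
  cl <- rep(c("A", "B"), 10)
  cvc <- five_by_two_cv(const, cl, k = 2, p = 1, seed = 1)
  expect_equal(cvc$f1_sd, 0)
  expect_equal(cvc$ci_lo, cvc$ci_hi)
  expect_error(five_by_two_cv(feats[1:3, ], c("A", "A", "B"), seed = 1),
               "at least 2")
})

test_that("the Gaussian interval reproduces the published summary row", {
  # mean 0.617, sd 0.020 -> (0.578, 0.656) at display rounding
  expect_equal(round(0.617 - 1.96 * 0.020, 3), 0.578)
  expect_equal(round(0.617 + 1.96 * 0.020, 3), 0.656)
})

test_that("the full grid has the published cardinality and subgrids multiply out", {
  g <- knn_grid()
  expect_equal(nrow(g), 20825)
  expect_equal(nrow(g), 17 * 5 * 49 * 5)
  expect_equal(nrow(dplyr::distinct(g)), nrow(g))
  small <- knn_grid(ranges = tibble::tibble(d1 = 4, d2 = 8),
                    normalizations = "none", k = 2:3, p = 1)
  expect_equal(nrow(small), 2)
})

test_that("the grid search ranks configurations by their maximum F1", {
  set.seed(33)
  n <- 36
  dec <- rep(c(1L, 2L, 4L, 5L, 9L, 10L), length.out = n)
  tb <- tibble::tibble(
    Scale6_IQR = dec * 3 + rnorm(n, 0, 0.5),
    Age = round(runif(n, 30, 70)),
    Sex = sample(c("M", "F"), n, TRUE),
    decision = dec)
  grid <- knn_grid(ranges = tibble::tibble(d1 = c(3, 3), d2 = c(6, 6)),
                   normalizations = c("none", "standardize"),
                   k = c(3, 5), p = c(1, 2))
  res <- knn_grid_search(tb, grid[1:6, ], seed = 2)
  expect_equal(nrow(res), 6)
  expect_true(all(diff(res$f1_max) <= 0))
  expect_true(all(c("f1_min", "f1_mean", "f1_max", "f1_sd") %in% names(res)))
})

test_that("sex is encoded 0/1 and the F1 route agrees with the shared metrics", {
  tb <- tibble::tibble(Age = c(40, 50), Sex = c("M", "F"), decision = c(1, 9))
  enc <- encode_features(tb)
  expect_equal(enc$Sex, c(1, 0))
  expect_false("decision" %in% names(enc))
  # module-level F1 equals compute_metrics on shared fixtures
  truth <- c("A", "A", "B", "C", "C", "B")
  pred <- c("A", "B", "B", "C", "A", "B")
  m <- compute_metrics(truth, pred)
  o <- oracle_metrics(truth, pred, c("A", "B", "C"))
  expect_equal(m$f1_macro, o$f1_macro)
})

test_that("UMAP embeddings are reproducible and keep identical objects together", {
  skip_if_not_installed("uwot")
  set.seed(40)
  feats <- tibble::tibble(x = rnorm(30), y = rnorm(30), z = rnorm(30))
  feats[2, ] <- feats[1, ]  # duplicated object
  emb <- umap_embed(feats, seed = 7, labels = rep(c("A", "B"), 15))
  expect_equal(nrow(emb), 30)
  expect_named(emb, c("umap1", "umap2", "label"))
  emb2 <- umap_embed(feats, seed = 7, labels = rep(c("A", "B"), 15))
  expect_equal(emb$umap1, emb2$umap1)
  d_dup <- sqrt((emb$umap1[1] - emb$umap1[2])^2 +
                  (emb$umap2[1] - emb$umap2[2])^2)
  d_all <- sqrt((emb$umap1[1] - emb$umap1[-(1:2)])^2 +
                  (emb$umap2[1] - emb$umap2[-(1:2)])^2)
  expect_lt(d_dup, median(d_all))
  expect_error(umap_embed(feats[1:3, ]), "at least 4")
})
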