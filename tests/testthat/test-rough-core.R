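test_that("indiscernibility partitions match the pairwise-equality oracle", {
  set.seed(12)
  for (rep in 1:5) {
    tb <- tibble::tibble(
      a = sample(c("x", "y"), 8, replace = TRUE),
      b = sample(c("0", "1", "2"), 8, replace = TRUE),
      c = sample(c("p", "q"), 8, replace = TRUE),
      decision = sample(c("A", "B"), 8, replace = TRUE))
    for (attrs in list("a", c("a", "b"), c("a", "b", "c"), character(0))) {
      got <- canon_partition(compute_partition(tb, attrs))
      want <- canon_partition(oracle_partition(tb, attrs))
      expect_equal(got, want)
    }
  }
  # all rows distinct on attrs -> singletons; empty attrs -> one block
  tb2 <- tibble::tibble(a = as.character(1:5), decision = rep("A", 5))
  expect_length(compute_partition(tb2, "a"), 5)
  expect_length(compute_partition(tb2, character(0)), 1)
  expect_error(compute_partition(tb2, "nope"), "unknown attribute")
})

test_that("lower/upper approximations and their accuracy follow the set definitions", {
  tb <- toy_mixed_table()
  part <- compute_partition(tb, c("a", "b"))
  # block {1,2} pure A; block {3,4,5,6} mixed -> lower = {1,2}, upper = all
  apx <- approximate_class(part, which(tb$decision == "A"))
  expect_equal(apx$lower, c(1L, 2L))
  expect_equal(apx$upper, 1:6)
  expect_equal(apx$accuracy, 2 / 6)
  orc <- oracle_approx(part, which(tb$decision == "A"))
  expect_equal(apx$lower, orc$lower)
  expect_equal(apx$upper, orc$upper)
  # a 2-in-4 mixed block alone: lower 2, upper 4 -> accuracy 0.5
  tb3 <- tibble::tibble(a = c("x", "x", "y", "y"),
                        decision = c("A", "A", "A", "B"))
  p3 <- compute_partition(tb3, "a")
  apx3 <- approximate_class(p3, 1:3)
  expect_equal(length(apx3$lower), 2)
  expect_equal(length(apx3$upper), 4)
  expect_equal(apx3$accuracy, 0.5)
  # consistent table: lower = upper = class, accuracy 1
  tbc <- toy_consistent_table()
  pc <- compute_partition(tbc, c("a", "b"))
  for (cl in c("A", "B", "C")) {
    ap <- approximate_class(pc, which(tbc$decision == cl))
    expect_equal(ap$lower, ap$upper)
    expect_equal(ap$accuracy, 1)
  }
  # empty class is vacuously precise
  empty <- approximate_class(pc, integer(0))
  expect_equal(empty$lower, integer(0))
  expect_equal(empty$upper, integer(0))
  expect_equal(empty$accuracy, 1)
})

test_that("refining the attribute set never shrinks lower nor grows upper", {
  set.seed(3)
  for (rep in 1:10) {
    tb <- tibble::tibble(
      a = sample(c("x", "y"), 10, replace = TRUE),
      b = sample(c("0", "1"), 10, replace = TRUE),
      c = sample(c("p", "q"), 10, replace = TRUE),
      decision = sample(c("A", "B", "C"), 10, replace = TRUE))
    cls <- which(tb$decision == "A")
    coarse <- approximate_class(compute_partition(tb, "a"), cls)
    fine <- approximate_class(compute_partition(tb, c("a", "b", "c")), cls)
    expect_true(all(coarse$lower %in% fine$lower))
    expect_true(all(fine$upper %in% coarse$upper))
    expect_true(all(fine$lower %in% cls) && all(cls %in% fine$upper))
  }
})

test_that("unsupervised cut placement matches the closed-form examples", {
  tb <- tibble::tibble(x = c(0, 2, 7, 10), decision = c("A", "A", "B", "B"))
  cw <- discretize_attributes(tb, "intervals", cuts = 1)
  expect_equal(cw$cuts$x, 5)
  tb2 <- tibble::tibble(x = c(1, 2, 3, 4), decision = c("A", "A", "B", "B"))
  cf <- discretize_attributes(tb2, "quantiles", cuts = 1)
  expect_equal(cf$cuts$x, 2.5)
  # labels are left-closed right-open with Inf literals
  expect_equal(sort(unique(cw$table$x)), c("[-Inf,5)", "[5,Inf)"))
  # single-valued attribute: zero cuts and a warning
  tb3 <- tibble::tibble(x = rep(1, 4), y = c(1, 2, 3, 4),
                        decision = c("A", "A", "B", "B"))
  expect_warning(c3 <- discretize_attributes(tb3, "intervals", cuts = 2),
                 "single distinct value")
  expect_length(c3$cuts$x, 0)
  expect_equal(unique(c3$table$x), "[-Inf,Inf)")
})

test_that("global-discernibility cuts match exhaustive midpoint search", {
  # two classes perfectly separated at x = 4/6 boundary
  tb <- tibble::tibble(x = c(1, 2, 3, 4, 6, 7, 8, 9),
                       z = c(5, 5, 5, 5, 5, 5, 5, 5),
                       decision = rep(c("A", "B"), each = 4))
  suppressWarnings(cs <- discretize_attributes(tb, "discernibility", cuts = 1))
  expect_equal(cs$cuts$x, 5)
  # every cross-class pair is discerned by that single cut
  expect_equal(length(unique(cs$table$x[tb$decision == "A"])), 1)
  expect_true(all(cs$table$x[tb$decision == "A"] !=
                    cs$table$x[tb$decision == "B"]))
  # brute force: 5 is the midpoint maximizing separated pairs
  mids <- (sort(unique(tb$x))[-1] + sort(unique(tb$x))[-8]) / 2
  gains <- sapply(mids, function(v) {
    sum(outer(tb$x < v, tb$x < v, "!=") & outer(tb$decision, tb$decision, "!="))
  })
  expect_equal(mids[which.max(gains)], 5)
})

test_that("train-only cuts transfer to held-out rows without leakage", {
  set.seed(8)
  train <- tibble::tibble(x = rnorm(40), y = rnorm(40),
                          decision = sample(c("A", "B"), 40, TRUE))
  cs <- discretize_attributes(train, "quantiles", cuts = 2)
  test1 <- tibble::tibble(x = c(-10, 0, 10), y = c(0, 0, 0))
  test2 <- test1[c(3, 1, 2), ]
  d1 <- apply_cuts(cs, test1)
  d2 <- apply_cuts(cs, test2)
  expect_equal(d1$x[c(3, 1, 2)], d2$x)  # cuts independent of test rows
  # out-of-range values land in the unbounded edge intervals
  expect_match(d1$x[1], "^\\[-Inf")
  expect_match(d1$x[3], "Inf\\)$")
})

test_that("greedy reducts preserve the positive region and are minimal", {
  tb <- toy_functional_table()
  expect_equal(compute_reduct(tb, "greedy"), "attr1")
  set.seed(31)
  for (rep in 1:8) {
    tb <- tibble::tibble(
      a = sample(c("0", "1"), 10, TRUE), b = sample(c("0", "1"), 10, TRUE),
      c = sample(c("0", "1"), 10, TRUE), d = sample(c("0", "1"), 10, TRUE),
      decision = sample(c("A", "B"), 10, TRUE))
    red <- compute_reduct(tb, "greedy")
    full <- oracle_pos_size(tb, c("a", "b", "c", "d"))
    expect_equal(oracle_pos_size(tb, red), full)
    # minimality: no proper subset preserves the positive region
    if (length(red) > 1) {
      for (drop in red) {
        expect_lt(oracle_pos_size(tb, setdiff(red, drop)), full)
      }
    }
    # greedy output has the size of some exhaustive minimal reduct or is
    # at worst as small as the largest minimal one
    mins <- oracle_reducts(tb)
    expect_gte(length(red), min(lengths(mins)))
    expect_lte(length(red), max(lengths(mins)))
  }
  expect_error(compute_reduct(toy_functional_table()[0, ]), "empty")
})

test_that("the permutation-probe reduct keeps a pure-noise attribute out", {
  excluded <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 24
    a1 <- sample(c("l", "m", "h"), n, TRUE)
    tb <- tibble::tibble(
      attr1 = a1,
      noise = as.character(sample(seq_len(n))),  # singleton blocks
      decision = c(l = "A", m = "B", h = "C")[a1])
    red <- compute_reduct(tb, "daar", n_probes = 60, seed = 1000 + s)
    if (!"noise" %in% red) excluded <- excluded + 1L
    expect_equal(oracle_pos_size(tb, red), oracle_pos_size(tb, c("attr1", "noise")))
  }
  expect_gte(excluded, 18L)  # >= 90% of seeds
})

test_that("Laplace confidence follows the smoothed-precision formula", {
  expect_equal(laplace_confidence(9, 10, 3), 10 / 13)
  expect_equal(laplace_confidence(0, 0, 3), 1 / 3)
  expect_equal(laplace_confidence(50, 50, 3), 51 / 53)
  expect_error(laplace_confidence(5, 3, 3), "n_matching")
  expect_error(laplace_confidence(1, 2, 1), "k")
})

test_that("LEM2 rule coverages tile each class's lower approximation", {
  tb <- toy_consistent_table()
  rules <- induce_rules(tb, c("a", "b"), "LEM2")
  part <- compute_partition(tb, c("a", "b"))
  for (cl in c("A", "B", "C")) {
    lower <- approximate_class(part, which(tb$decision == cl))$lower
    cover <- sort(unique(unlist(lapply(
      which(rules$class == cl),
      function(i) which(respgran:::rule_matches(rules$conditions[[i]], tb))))))
    expect_equal(cover, lower)
  }
  # supports recomputed against training data equal stored supports
  for (i in seq_len(nrow(rules))) {
    m <- respgran:::rule_matches(rules$conditions[[i]], tb)
    expect_equal(rules$support[i], sum(m & tb$decision == rules$class[i]))
  }
})

test_that("IND induces one rule per block with block-majority consequents", {
  tb <- tibble::tibble(
    a = c("x", "x", "x", "y", "y", "z", "z", "w"),
    decision = c("A", "A", "B", "B", "B", "C", "C", "A"))
  rules <- induce_rules(tb, "a", "IND")
  expect_equal(nrow(rules), 4)
  expect_equal(sort(rules$class), c("A", "A", "B", "C"))
  # supports sum to the block-majority counts: 2 + 2 + 2 + 1
  expect_equal(sum(rules$support), 7)
})

test_that("single-class tables yield rules of that class covering everything", {
  tb <- tibble::tibble(a = c("x", "x", "y"), b = c("0", "1", "0"),
                       decision = rep("A", 3))
  for (m in c("LEM2", "CN2", "AQ", "IND")) {
    rules <- induce_rules(tb, c("a", "b"), m)
    expect_true(all(rules$class == "A"))
    cover <- sort(unique(unlist(lapply(seq_len(nrow(rules)), function(i) {
      which(respgran:::rule_matches(rules$conditions[[i]], tb))
    }))))
    expect_equal(cover, 1:3)
  }
})

test_that("a consistent table classified by its own rules is perfect", {
  set.seed(5)
  tb <- tibble::tibble(
    a = sample(c("0", "1", "2"), 18, TRUE),
    b = sample(c("x", "y"), 18, TRUE),
    decision = NA_character_)
  tb$decision <- paste0(tb$a, tb$b)  # decision is a function of (a, b)
  for (m in c("LEM2", "CN2", "AQ", "IND")) {
    rules <- induce_rules(tb, c("a", "b"), m)
    pred <- predict(rules, tb)
    expect_equal(as.character(pred), tb$decision,
                 label = paste("training accuracy of", m))
  }
})

test_that("rule filtration applies the two-rule, mean-confidence and cap criteria", {
  mk_rules <- function(lc, support = rep(5L, length(lc))) {
    structure(tibble::tibble(
      conditions = replicate(length(lc), c(a = "x"), simplify = FALSE),
      class = rep("A", length(lc)), length = 1L,
      support = support, laplace = lc),
      fallback = "A", method = "IND",
      class = c("rule_set", class(tibble::tibble())))
  }
  r1 <- filter_rules(mk_rules(0.9))
  expect_s3_class(r1, "rule_rejection")
  expect_equal(r1$reason, "too_few_rules")
  r2 <- filter_rules(mk_rules(c(0.5, 0.55, 0.6)))
  expect_s3_class(r2, "rule_rejection")
  expect_equal(r2$reason, "low_mean_laplace")
  lc <- seq(0.61, 0.99, length.out = 150)
  r3 <- filter_rules(mk_rules(lc))
  expect_s3_class(r3, "rule_set")
  expect_equal(nrow(r3), 100)
  expect_equal(sort(r3$laplace), sort(sort(lc, decreasing = TRUE)[1:100]))
})

test_that("classification is specificity-first with the documented tie-break chain", {
  # the printed contradicting-rules example: a 2-condition rule to C beats
  # a 1-condition rule to A on objects matching both
  rules <- structure(tibble::tibble(
    conditions = list(c(Scale5_q2 = "[-3.82,13.1)", Scale6_q2 = "[-3.37,9.08)"),
                      c(Scale5_q2 = "[-3.82,13.1)"),
                      c(Scale5_q1 = "[-41,-2.22)")),
    class = c("C", "A", "B"), length = c(2L, 1L, 1L),
    support = c(10L, 8L, 6L), laplace = c(0.8, 0.7, 0.7)),
    fallback = "B", method = "CN2",
    class = c("rule_set", class(tibble::tibble())))
  obj_both <- tibble::tibble(Scale5_q1 = "[-2.22,Inf)",
                             Scale5_q2 = "[-3.82,13.1)",
                             Scale6_q2 = "[-3.37,9.08)")
  expect_equal(as.character(predict(rules, obj_both)), "C")
  obj_second <- tibble::tibble(Scale5_q1 = "[-2.22,Inf)",
                               Scale5_q2 = "[-3.82,13.1)",
                               Scale6_q2 = "[9.08,Inf)")
  expect_equal(as.character(predict(rules, obj_second)), "A")
  obj_none <- tibble::tibble(Scale5_q1 = "[-2.22,Inf)",
                             Scale5_q2 = "[13.1,Inf)",
                             Scale6_q2 = "[9.08,Inf)")
  expect_equal(as.character(predict(rules, obj_none)), "B")  # fallback
  # equal specificity: higher Laplace wins
  rules2 <- structure(tibble::tibble(
    conditions = list(c(a = "x"), c(a = "x")),
    class = c("A", "B"), length = c(1L, 1L),
    support = c(3L, 3L), laplace = c(0.6, 0.9)),
    fallback = "A", method = "IND",
    class = c("rule_set", class(tibble::tibble())))
  expect_equal(as.character(predict(rules2, tibble::tibble(a = "x"))), "B")
})
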