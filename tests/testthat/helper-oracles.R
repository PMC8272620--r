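# Independent oracles and shared fixtures, deliberately written with
# different algorithms than the implementation they check.

# O(n^2) pairwise-equality closure: the partition as the transitive closure
# of "equal on every attribute of attrs".
oracle_partition <- function(table, attrs) {
  n <- nrow(table)
  assigned <- rep(NA_integer_, n)
  next_block <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    next_block <- next_block + 1L
    assigned[i] <- next_block
    if (i < n) {
      for (j in (i + 1):n) {
        same <- all(vapply(attrs, function(a) {
          identical(as.character(table[[a]][i]), as.character(table[[a]][j]))
        }, logical(1)))
        if (length(attrs) == 0L) same <- TRUE
        if (same && is.na(assigned[j])) assigned[j] <- next_block
      }
    }
  }
  unname(split(seq_len(n), assigned))
}

# canonicalize a partition for comparison
canon_partition <- function(blocks) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  blocks[order(vapply(blocks, min, integer(1)))]
}

# Direct set-based lower/upper approximations from a block list.
oracle_approx <- function(blocks, class_idx) {
  lower <- integer(0); upper <- integer(0)
  for (b in blocks) {
    if (all(b %in% class_idx)) lower <- c(lower, b)
    if (any(b %in% class_idx)) upper <- c(upper, b)
  }
  list(lower = sort(lower), upper = sort(upper))
}

oracle_pos_size <- function(table, attrs, decision = "decision") {
  blocks <- oracle_partition(table, attrs)
  sum(vapply(blocks, function(b) {
    if (length(unique(table[[decision]][b])) == 1L) length(b) else 0L
  }, integer(1)))
}

# Exhaustive minimal reducts: all attribute subsets preserving the
# full-attribute positive region, filtered to the minimal ones.
oracle_reducts <- function(table, decision = "decision") {
  attrs <- setdiff(names(table), decision)
  full <- oracle_pos_size(table, attrs, decision)
  subsets <- list()
  for (k in seq_along(attrs)) {
    for (comb in utils::combn(attrs, k, simplify = FALSE)) {
      if (oracle_pos_size(table, comb, decision) == full) {
        subsets <- c(subsets, list(comb))
      }
    }
  }
  is_min <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) {
      length(t) < length(s) && all(t %in% s)
    }, logical(1)))
  }, logical(1))
  subsets[is_min]
}

# Confusion-matrix metrics oracle, built from an explicit k x k matrix.
oracle_metrics <- function(truth, pred, classes) {
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    cm[as.character(truth[i]), as.character(pred[i])] <-
      cm[as.character(truth[i]), as.character(pred[i])] + 1
  }
  prec <- rec <- f1 <- numeric(length(classes))
  for (k in seq_along(classes)) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) == 0) 0 else tp / sum(cm[, k])
    rec[k] <- if (sum(cm[k, ]) == 0) 0 else tp / sum(cm[k, ])
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  list(accuracy = sum(diag(cm)) / length(truth),
       precision_macro = mean(prec), recall_macro = mean(rec),
       f1_macro = mean(f1))
}

# Local-maximum peak picking with a guard band, used to read per-breath
# amplitudes off a generated signal.
oracle_peaks <- function(x, min_gap) {
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE)
  idx <- which(is_peak & x > max(x) * 0.05)
  keep <- integer(0)
  last <- -Inf
  for (i in idx) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

# A 6-object discretized toy table with one mixed block:
# objects 1-2 (a=x,b=u) pure class A; 3-6 (a=y,b=v) classes A,B,A,B mixed;
# used for approximation arithmetic.
toy_mixed_table <- function() {
  tibble::tibble(
    a = c("x", "x", "y", "y", "y", "y"),
    b = c("u", "u", "v", "v", "v", "v"),
    decision = c("A", "A", "A", "B", "A", "B"))
}

# Consistent 3-class toy table over two binary attributes.
toy_consistent_table <- function() {
  tibble::tibble(
    a = c("0", "0", "1", "1", "0", "1"),
    b = c("0", "0", "0", "0", "1", "1"),
    decision = c("A", "A", "B", "B", "C", "C"))
}

# Decision table where the decision is a function of attr1 alone.
toy_functional_table <- function() {
  tibble::tibble(
    attr1 = c("l", "l", "m", "m", "h", "h"),
    attr2 = c("0", "1", "0", "1", "0", "1"),
    attr3 = c("p", "p", "q", "q", "p", "q"),
    decision = c("A", "A", "B", "B", "C", "C"))
}

# Benchmark decision table for parameter recovery: graded cohort plus the
# matched drop count for its sampling rate.
graded_table <- function(n, seed, pattern = "normal", ...) {
  gc <- generate_graded_cohort(n, pattern = pattern, seed = seed, ...)
  cohort_decision_table(gc$cohort, gc$signals, pattern,
                        drop_finest = drop_finest_for_rate(
                          signal_rate(gc$signals[[1]])))
}
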