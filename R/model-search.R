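# Experimental procedure: filtration, 85:15 splits, repeated runs per
# hyperparameter configuration, and the full grid search.

#' Classification metrics over the three outcome classes
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the fixed
#' class set; a class absent from predictions (or truth) contributes 0 to
#' the corresponding macro term.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class levels to average over (default A, B, C).
#' @return One-row tibble: \code{accuracy}, \code{precision_macro},
#'   \code{recall_macro}, \code{f1_macro}.
#' @export
compute_metrics <- function(truth, predicted, classes = c("A", "B", "C")) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  abort_if(length(truth) != length(predicted),
           "truth and predicted must have equal length")
  per <- purrr::map(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec = prec, rec = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  tibble::tibble(
    accuracy = mean(truth == predicted),
    precision_macro = mean(per[, "prec"]),
    recall_macro = mean(per[, "rec"]),
    f1_macro = mean(per[, "f1"]))
}

#' Hyperparameter configuration for one rough-set model
#'
#' @param cuts Number of attribute discretization cuts (1-3).
#' @param discretize \code{"quantiles"}, \code{"intervals"} or
#'   \code{"discernibility"}.
#' @param reduct \code{"greedy"} or \code{"daar"}.
#' @param rule \code{"LEM2"}, \code{"CN2"}, \code{"AQ"} or \code{"IND"}.
#' @param d1,d2 Outcome-range boundaries (see
#'   \code{\link{discretize_outcome}}).
#' @return One-row tibble of the validated configuration.
#' @export
hyperparams <- function(cuts = 2, discretize = "quantiles", reduct = "greedy",
                        rule = "LEM2", d1 = 3, d2 = 6) {
  abort_if(!cuts %in% 1:3, "cuts must be 1, 2 or 3")
  abort_if(!discretize %in% c("quantiles", "intervals", "discernibility"),
           "unknown discretization method")
  abort_if(!reduct %in% c("greedy", "daar"), "unknown reduct method")
  abort_if(!rule %in% c("LEM2", "CN2", "AQ", "IND"), "unknown rule method")
  abort_if(!d1 %in% 1:5 || !(d2 - d1) %in% 2:5 || d2 >= 9,
           "invalid outcome range (d1, d2)")
  tibble::tibble(cuts = as.integer(cuts), discretize = discretize,
                 reduct = reduct, rule = rule,
                 d1 = as.integer(d1), d2 = as.integer(d2))
}

#' Full hyperparameter grid
#'
#' @param cuts,discretize,reduct,rule Candidate values (defaults: the full
#'   sets).
#' @param ranges Tibble of (d1, d2) pairs, default all 17 valid pairs.
#' @return Tibble with one row per configuration.
#' @export
hp_grid <- function(cuts = 1:3,
                    discretize = c("quantiles", "intervals", "discernibility"),
                    reduct = c("greedy", "daar"),
                    rule = c("LEM2", "CN2", "AQ", "IND"),
                    ranges = enumerate_outcome_ranges()) {
  tidyr::expand_grid(cuts = as.integer(cuts), discretize = discretize,
                     reduct = reduct, rule = rule, ranges) |>
    dplyr::arrange(.data$cuts, .data$discretize, .data$reduct, .data$rule,
                   .data$d1, .data$d2)
}

# Stratified 85:15 split: the total training size is round(ratio * n),
# apportioned over outcome classes by largest remainder so no class is
# absent from training.
stratified_split <- function(labels, ratio = 0.85) {
  n <- length(labels)
  n_train <- round(ratio * n)
  classes <- unique(labels)
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  exact <- n_c * n_train / n
  base <- pmin(floor(exact), n_c)
  base <- pmax(base, pmin(1L, n_c))  # at least one training case per class
  rem <- n_train - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base))
    for (k in ord) {
      if (rem == 0) break
      add <- min(rem, n_c[k] - base[k])
      base[k] <- base[k] + add
      rem <- rem - add
    }
  } else if (rem < 0) {
    ord <- order(exact - base)
    for (k in ord) {
      if (rem == 0) break
      take <- min(-rem, base[k] - 1L)
      base[k] <- base[k] - take
      rem <- rem + take
    }
  }
  train <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    train <- c(train, sample(idx, base[k]))
  }
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

#' One training/evaluation run of the rough-set pipeline
#'
#' Runs the full procedure for one hyperparameter configuration:
#' zero-decile debiasing, outcome discretization to A/B/C, stratified 85:15
#' train/test split, attribute discretization fitted on the training part
#' only, reduct computation, rule induction, Laplace-confidence filtration
#' and test-set classification. A filtered-out model yields a rejected
#' result with zero metrics rather than an error.
#'
#' @param table Decision table for one pattern, decision in deciles 0-10.
#' @param hp One-row tibble from \code{\link{hyperparams}}.
#' @param seed Integer seed controlling filtration, split and probes;
#'   the run is fully deterministic for a fixed seed.
#' @return One-row tibble: the four metrics, \code{n_rules},
#'   \code{rejected}.
#' @export
run_once <- function(table, hp, seed = NULL) {
  abort_if(!all(c("cuts", "discretize", "reduct", "rule", "d1", "d2") %in%
                  names(hp)), "hp must come from hyperparams() or hp_grid()")
  rejected <- function(n_rules) {
    tibble::tibble(accuracy = 0, precision_macro = 0, recall_macro = 0,
                   f1_macro = 0, n_rules = n_rules, rejected = TRUE)
  }
  tab <- debias_subsample(table, seed = child_seed(seed, 1))
  tab$decision <- discretize_outcome(tab$decision, hp$d1, hp$d2)
  split <- with_seed(child_seed(seed, 2),
                     stratified_split(as.character(tab$decision)))
  train <- tab[split$train, ]
  test <- tab[split$test, ]
  cs <- discretize_attributes(train, method = hp$discretize, cuts = hp$cuts)
  train_d <- cs$table
  test_d <- apply_cuts(cs, test)
  red <- compute_reduct(train_d, method = hp$reduct,
                        seed = child_seed(seed, 3))
  if (length(red) == 0L) return(rejected(0L))
  rules <- induce_rules(train_d, red, method = hp$rule)
  rules <- filter_rules(rules)
  if (inherits(rules, "rule_rejection")) {
    return(rejected(if (is.null(rules$n_rules)) NA_integer_ else rules$n_rules))
  }
  pred <- predict(rules, test_d)
  dplyr::bind_cols(compute_metrics(test$decision, pred),
                   tibble::tibble(n_rules = nrow(rules), rejected = FALSE))
}

#' Repeated runs for one configuration
#'
#' Repeats \code{\link{run_once}} with independent random filtration and
#' splits and summarises the per-run accuracies as a boxplot-ready
#' five-number summary.
#'
#' @inheritParams run_once
#' @param repeats Number of repetitions (default 10).
#' @return Object of class \code{respgran_cv}: list with \code{runs} (one
#'   row per repeat) and \code{summary} (median and quartiles of accuracy,
#'   mean accuracy and macro-F1, median rule count).
#' @export
cross_validate <- function(table, hp, repeats = 10, seed = NULL) {
  abort_if(repeats < 2, "repeats must be >= 2")
  runs <- purrr::map(seq_len(repeats), function(r) {
    dplyr::bind_cols(tibble::tibble(repeat_id = r),
                     run_once(table, hp, seed = child_seed(seed, 100 + r)))
  }) |> dplyr::bind_rows()
  q <- quartiles(runs$accuracy)
  summary <- tibble::tibble(
    mean_accuracy = mean(runs$accuracy),
    median_accuracy = q[2], q1_accuracy = q[1], q3_accuracy = q[3],
    min_accuracy = min(runs$accuracy), max_accuracy = max(runs$accuracy),
    mean_f1 = mean(runs$f1_macro),
    median_n_rules = stats::median(runs$n_rules[!runs$rejected]),
    n_rejected = sum(runs$rejected))
  structure(list(hp = hp, runs = runs, summary = summary),
            class = "respgran_cv")
}

#' @export
print.respgran_cv <- function(x, ...) {
  cat(sprintf(
    "<cv: %d runs, mean acc %.3f, median acc %.3f, mean F1 %.3f>\n",
    nrow(x$runs), x$summary$mean_accuracy, x$summary$median_accuracy,
    x$summary$mean_f1))
  invisible(x)
}

#' Grid search over rough-set hyperparameters
#'
#' Evaluates every configuration with \code{\link{cross_validate}} and
#' returns the configuration maximizing mean accuracy (rejected runs score
#' 0, making fragile models costly; ties prefer fewer median rules, then
#' earlier grid order).
#'
#' @inheritParams run_once
#' @param grid Tibble of configurations (see \code{\link{hp_grid}}).
#' @param repeats Repeats per configuration.
#' @return Object of class \code{respgran_grid}: list with \code{best}
#'   (winning configuration row), \code{summary} (one row per
#'   configuration) and \code{runs} (every individual run).
#' @export
grid_search <- function(table, grid, repeats = 10, seed = NULL) {
  abort_if(nrow(grid) == 0L, "empty hyperparameter grid")
  cvs <- purrr::map(seq_len(nrow(grid)), function(g) {
    cross_validate(table, grid[g, ], repeats = repeats,
                   seed = child_seed(seed, 1000 + g))
  })
  summary <- purrr::map2(cvs, seq_len(nrow(grid)), function(cv, g) {
    dplyr::bind_cols(tibble::tibble(config = g), grid[g, ], cv$summary)
  }) |> dplyr::bind_rows()
  runs <- purrr::map2(cvs, seq_len(nrow(grid)), function(cv, g) {
    dplyr::bind_cols(tibble::tibble(config = g), grid[g, ], cv$runs)
  }) |> dplyr::bind_rows()
  if (all(summary$n_rejected == nrow(cvs[[1]]$runs))) {
    return(structure(list(best = NULL, summary = summary, runs = runs,
                          no_model = TRUE), class = "respgran_grid"))
  }
  ord <- order(-summary$mean_accuracy, summary$median_n_rules,
               summary$config)
  best <- summary[ord[1], ]
  structure(list(best = best, summary = summary, runs = runs,
                 no_model = FALSE), class = "respgran_grid")
}

#' @export
print.respgran_grid <- function(x, ...) {
  if (isTRUE(x$no_model)) {
    cat("<grid search: every configuration was rejected>\n")
  } else {
    cat(sprintf(
      "<grid search: %d configurations; best mean acc %.3f (cuts=%d, %s, %s, %s, d=(%d,%d))>\n",
      nrow(x$summary), x$best$mean_accuracy, x$best$cuts, x$best$discretize,
      x$best$reduct, x$best$rule, x$best$d1, x$best$d2))
  }
  invisible(x)
}

#' Pivot grid-search summaries into an outcome-range matrix
#'
#' Reshapes a per-configuration summary into the d1-by-d2 layout used to
#' report mean accuracies or F1 scores per outcome range: for each (d1, d2)
#' cell the best configuration's value is shown.
#'
#' @param search A \code{respgran_grid} result.
#' @param metric Summary column to pivot (default \code{"mean_accuracy"}).
#' @return Tibble with one row per d1 and one column per d2.
#' @export
result_matrix <- function(search, metric = "mean_accuracy") {
  abort_if(!inherits(search, "respgran_grid"), "not a grid-search result")
  search$summary |>
    dplyr::slice_max(.data[[metric]], n = 1, with_ties = FALSE,
                     by = c("d1", "d2")) |>
    dplyr::select("d1", "d2", dplyr::all_of(metric)) |>
    dplyr::arrange(.data$d1, .data$d2) |>
    tidyr::pivot_wider(names_from = "d2", values_from = dplyr::all_of(metric),
                       names_prefix = "d2_")
}
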