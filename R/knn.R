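# Minkowski k-nearest-neighbour baseline with 5x2 cross-validation and
# UMAP embedding export.

#' Normalize a feature table
#'
#' Five schemes: \code{none} (identity); \code{maxabs} (divide each column
#' by its maximum absolute value); \code{minmax} (rescale each column to
#' \[-1, 1\]); \code{standardize} (center and scale each column by its
#' standard deviation); \code{row_unit} (scale each row vector to unit
#' Euclidean length). Column schemes leave a zero-variance column at 0 with
#' a warning; \code{row_unit} leaves a zero row at 0 with a warning.
#'
#' @param features Tibble/data frame of numeric columns (encode sex as 0/1
#'   first, e.g. with \code{\link{encode_features}}).
#' @param method Normalization scheme.
#' @return Tibble of the same shape.
#' @export
normalize_features <- function(features,
                               method = c("none", "maxabs", "minmax",
                                          "standardize", "row_unit")) {
  method <- match.arg(method)
  abort_if(!all(vapply(features, is.numeric, logical(1))),
           "all feature columns must be numeric")
  x <- as.data.frame(features)
  if (method == "none") return(tibble::as_tibble(x))
  if (method == "row_unit") {
    m <- as.matrix(x)
    len <- sqrt(rowSums(m^2))
    if (any(len == 0)) {
      warning("zero-length row(s) left at 0 under row_unit", call. = FALSE)
      len[len == 0] <- 1
    }
    return(tibble::as_tibble(m / len))
  }
  for (j in seq_along(x)) {
    v <- x[[j]]
    x[[j]] <- switch(method,
      maxabs = {
        mx <- max(abs(v))
        if (mx == 0) v else v / mx
      },
      minmax = {
        r <- range(v)
        if (diff(r) == 0) v * 0 else 2 * (v - r[1]) / diff(r) - 1
      },
      standardize = {
        s <- stats::sd(v)
        if (s == 0) {
          warning("zero-variance column '", names(x)[j],
                  "' left at 0 under standardize", call. = FALSE)
          v * 0
        } else (v - mean(v)) / s
      })
  }
  tibble::as_tibble(x)
}

#' Minkowski distance
#'
#' \eqn{D(x, y) = (\sum_i |x_i - y_i|^p)^{1/p}}: Manhattan at p = 1,
#' Euclidean at p = 2.
#'
#' @param x,y Equal-length numeric vectors.
#' @param p Exponent, >= 1.
#' @return The distance.
#' @examples
#' minkowski_distance(c(0, 0), c(3, 4), 2) # 5
#' @export
minkowski_distance <- function(x, y, p) {
  abort_if(length(x) != length(y), "x and y must have equal dimension")
  abort_if(p < 1, "p must be >= 1")
  sum(abs(x - y)^p)^(1 / p)
}

#' Encode a decision table for distance-based analysis
#'
#' Keeps the numeric condition attributes and encodes \code{Sex} as 1 (M) /
#' 0 (F), yielding the all-numeric feature table the k-NN baseline and UMAP
#' consume.
#'
#' @param table Decision table (raw, undiscretized).
#' @return Tibble of numeric features (decision column dropped).
#' @export
encode_features <- function(table) {
  out <- table[setdiff(names(table), "decision")]
  if ("Sex" %in% names(out)) {
    out$Sex <- as.numeric(out$Sex == "M")
  }
  abort_if(!all(vapply(out, is.numeric, logical(1))),
           "non-numeric attribute(s) other than Sex present")
  tibble::as_tibble(out)
}

# Brute-force k-NN with uniform votes. Neighbour ties are resolved by
# training-row order (stable sort); class-vote ties by the smallest summed
# neighbour distance, then class order.
knn_predict_one <- function(train_m, labels, x, k, p) {
  d <- rowSums(abs(sweep(train_m, 2, x))^p)^(1 / p)
  nn <- order(d)[seq_len(min(k, length(d)))]
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(d[nn][labels[nn] == cl]), numeric(1))
    top <- top[order(sums, seq_along(top))][1]
  }
  top
}

#' k-nearest-neighbour classification
#'
#' @param train,test Numeric feature tables (same columns).
#' @param labels Training labels.
#' @param k Number of neighbours (>= 2).
#' @param p Minkowski exponent.
#' @return Factor of predicted labels for \code{test}.
#' @export
knn_classify <- function(train, labels, test, k, p = 2) {
  abort_if(k < 2, "k must be >= 2")
  train_m <- as.matrix(train)
  test_m <- as.matrix(test)
  abort_if(ncol(train_m) != ncol(test_m), "train and test columns differ")
  labels <- as.character(labels)
  out <- vapply(seq_len(nrow(test_m)), function(i) {
    knn_predict_one(train_m, labels, test_m[i, ], k, p)
  }, character(1))
  factor(out, levels = sort(unique(labels)))
}

#' Five-times-repeated twofold cross-validation of a k-NN model
#'
#' Five independent stratified 50:50 splits; each half is used once for
#' training and once for testing, yielding ten macro-F1 estimates that are
#' summarised by their minimum, mean, maximum, standard deviation and the
#' Gaussian 95\% confidence interval mean +/- 1.96 sd.
#'
#' @param features Numeric feature table.
#' @param labels Outcome labels (each class needs >= 2 objects).
#' @param k,p k-NN hyperparameters.
#' @param normalization Scheme applied to the features (fit globally; the
#'   schemes are rigid rescalings, see \code{\link{normalize_features}}).
#' @param seed Integer seed for the splits.
#' @return One-row tibble \code{f1_min}, \code{f1_mean}, \code{f1_max},
#'   \code{f1_sd}, \code{ci_lo}, \code{ci_hi}; the ten per-fold F1 values
#'   are attached as attribute \code{"folds"}.
#' @export
five_by_two_cv <- function(features, labels, k = 5, p = 2,
                           normalization = "none", seed = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  abort_if(any(tab < 2), "every class needs at least 2 objects for 5x2CV")
  feats <- normalize_features(features, normalization)
  f1s <- with_seed(seed, {
    unlist(lapply(seq_len(5L), function(r) {
      half <- stratified_split(labels, ratio = 0.5)
      vapply(list(c(tr = 1, te = 2), c(tr = 2, te = 1)), function(w) {
        tr <- if (w["tr"] == 1) half$train else half$test
        te <- setdiff(seq_along(labels), tr)
        pred <- knn_classify(feats[tr, ], labels[tr], feats[te, ], k, p)
        compute_metrics(labels[te], pred,
                        classes = sort(unique(labels)))$f1_macro
      }, numeric(1))
    }))
  })
  out <- tibble::tibble(
    f1_min = min(f1s), f1_mean = mean(f1s), f1_max = max(f1s),
    f1_sd = stats::sd(f1s),
    ci_lo = mean(f1s) - 1.96 * stats::sd(f1s),
    ci_hi = mean(f1s) + 1.96 * stats::sd(f1s))
  attr(out, "folds") <- f1s
  out
}

#' The k-NN hyperparameter grid
#'
#' @param ranges Tibble of outcome ranges (default: all 17 valid pairs).
#' @param normalizations Candidate normalization schemes (default all 5).
#' @param k Candidate neighbour counts (default 2..50).
#' @param p Candidate Minkowski exponents (default 1, 1.25, 1.5, 1.75, 2).
#' @return Tibble with one row per combination (17 x 5 x 49 x 5 = 20825 by
#'   default).
#' @export
knn_grid <- function(ranges = enumerate_outcome_ranges(),
                     normalizations = c("none", "maxabs", "minmax",
                                        "standardize", "row_unit"),
                     k = 2:50, p = c(1, 1.25, 1.5, 1.75, 2)) {
  tidyr::expand_grid(ranges, normalization = normalizations,
                     k = as.integer(k), p = p)
}

#' Grid search for the k-NN baseline
#'
#' Evaluates every configuration of the grid with
#' \code{\link{five_by_two_cv}} on the outcome labels induced by each
#' configuration's (d1, d2) range, and ranks configurations by their
#' maximum F1 score (descending).
#'
#' @param table Decision table with decision in deciles 0-10.
#' @param grid Configuration tibble from \code{\link{knn_grid}}.
#' @param seed Integer seed; each configuration uses a derived stream.
#' @return Tibble: the grid columns plus the \code{five_by_two_cv} summary
#'   columns, sorted by \code{f1_max} descending.
#' @export
knn_grid_search <- function(table, grid = knn_grid(), seed = NULL) {
  abort_if(nrow(grid) == 0L, "empty grid")
  feats <- encode_features(table)
  res <- purrr::map(seq_len(nrow(grid)), function(g) {
    cfg <- grid[g, ]
    labels <- discretize_outcome(table$decision, cfg$d1, cfg$d2)
    five_by_two_cv(feats, labels, k = cfg$k, p = cfg$p,
                   normalization = cfg$normalization,
                   seed = child_seed(seed, g))
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(grid, res) |>
    dplyr::arrange(dplyr::desc(.data$f1_max))
}

#' Two-dimensional UMAP embedding of a feature table
#'
#' Delegates to the uwot implementation of UMAP, fixing the RNG so a given
#' seed reproduces the embedding; intended for visual inspection of the
#' class structure seen by the k-NN baseline.
#'
#' @param features Numeric feature table (>= 4 objects).
#' @param normalization Scheme applied first.
#' @param labels Optional labels carried into the output.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (capped at n - 1).
#' @return Tibble with \code{umap1}, \code{umap2} and optionally
#'   \code{label}.
#' @export
umap_embed <- function(features, normalization = "none", labels = NULL,
                       seed = NULL, n_neighbors = 15) {
  abort_if(nrow(features) < 4L, "UMAP needs at least 4 objects")
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("umap_embed() requires the uwot package", call. = FALSE)
  }
  m <- as.matrix(normalize_features(features, normalization))
  emb <- with_seed(seed %||% 42L, {
    uwot::umap(m, n_neighbors = min(n_neighbors, nrow(m) - 1),
               n_threads = 1, n_sgd_threads = 1, batch = FALSE)
  })
  out <- tibble::tibble(umap1 = emb[, 1], umap2 = emb[, 2])
  if (!is.null(labels)) out$label <- labels
  out
}
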