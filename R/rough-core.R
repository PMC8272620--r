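# Rough-set machinery: indiscernibility partitions, approximations,
# attribute discretization, reducts, rule induction and classification.
# Everything operates on discretized decision tables: tibbles whose
# condition attributes hold categorical values (interval labels) and whose
# decision column holds the class.

#' Indiscernibility partition of a decision table
#'
#' Two objects are indiscernible with respect to an attribute subset P when
#' they agree on every attribute of P; the induced equivalence classes
#' partition the universe into atomic sets.
#'
#' @param table Discretized decision table (tibble).
#' @param attrs Character vector of attribute names (the empty set yields a
#'   single block containing every object).
#' @return Object of class \code{eq_partition}: a list of integer vectors
#'   (row indices), disjoint and covering all rows.
#' @export
compute_partition <- function(table, attrs) {
  unknown <- setdiff(attrs, names(table))
  abort_if(length(unknown) > 0,
           "unknown attribute(s): ", paste(unknown, collapse = ", "))
  n <- nrow(table)
  if (length(attrs) == 0L) {
    blocks <- list(seq_len(n))
  } else {
    key <- do.call(paste, c(lapply(unname(table[attrs]), as.character),
                            sep = "\r"))
    blocks <- unname(split(seq_len(n), key))
  }
  structure(blocks, class = "eq_partition")
}

#' Rough approximation of a decision class
#'
#' The lower approximation collects the blocks wholly contained in the
#' class (objects certainly in it); the upper approximation collects the
#' blocks intersecting it (objects possibly in it). Their size ratio is the
#' approximation accuracy, defined as 1 for an empty class (vacuously
#' precise).
#'
#' @param partition An \code{\link{eq_partition}}.
#' @param class_objects Integer vector of row indices forming the class.
#' @return List with \code{lower}, \code{upper} (sorted indices) and
#'   \code{accuracy}.
#' @export
approximate_class <- function(partition, class_objects) {
  abort_if(!inherits(partition, "eq_partition"), "not an eq_partition")
  inside <- vapply(partition, function(b) all(b %in% class_objects), logical(1))
  touches <- vapply(partition, function(b) any(b %in% class_objects), logical(1))
  lower <- sort(unlist(partition[inside], use.names = FALSE))
  upper <- sort(unlist(partition[touches], use.names = FALSE))
  acc <- if (length(upper) == 0L) 1 else length(lower) / length(upper)
  list(lower = as.integer(lower), upper = as.integer(upper), accuracy = acc)
}

# Size of the positive region: objects whose blocks are decision-pure.
positive_region_size <- function(table, attrs, decision) {
  part <- compute_partition(table, attrs)
  dec <- table[[decision]]
  sum(vapply(part, function(b) {
    if (length(unique(dec[b])) == 1L) length(b) else 0L
  }, integer(1)))
}

fmt_cut <- function(v) {
  ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
         trimws(formatC(v, format = "g", digits = 6)))
}

interval_labels <- function(cuts) {
  bounds <- c(-Inf, cuts, Inf)
  paste0("[", fmt_cut(bounds[-length(bounds)]), ",", fmt_cut(bounds[-1]), ")")
}

# Map numeric values to left-closed right-open interval labels.
cut_to_labels <- function(x, cuts) {
  if (length(cuts) == 0L) return(rep("[-Inf,Inf)", length(x)))
  idx <- findInterval(x, cuts) + 1L
  interval_labels(cuts)[idx]
}

# Greedy supervised cut selection: candidate cuts are midpoints between
# consecutive distinct sorted training values; the cut discerning the most
# not-yet-discerned pairs of objects with different decisions is chosen
# repeatedly, capped at `c` cuts per attribute.
discern_cuts <- function(table, attrs, decision, c_max, max_cand = 48L) {
  dec <- table[[decision]]
  pair <- which(outer(dec, dec, FUN = "!=") & upper.tri(diag(length(dec))),
                arr.ind = TRUE)
  cuts <- stats::setNames(vector("list", length(attrs)), attrs)
  for (a in attrs) cuts[[a]] <- numeric(0)
  if (nrow(pair) == 0L) return(cuts)
  alive <- rep(TRUE, nrow(pair))
  cand <- lapply(attrs, function(a) {
    v <- sort(unique(table[[a]]))
    if (length(v) < 2L) return(numeric(0))
    mid <- (v[-1] + v[-length(v)]) / 2
    if (length(mid) > max_cand) {
      mid <- unique(stats::quantile(mid, probs = seq_len(max_cand) /
                                      (max_cand + 1), names = FALSE, type = 7))
    }
    mid
  })
  names(cand) <- attrs
  repeat {
    if (!any(alive)) break
    best <- list(gain = 0L, attr = NULL, cut = NA_real_)
    i <- pair[alive, 1L]; j <- pair[alive, 2L]
    for (a in attrs) {
      if (length(cuts[[a]]) >= c_max) next
      xa <- table[[a]]
      for (v in cand[[a]]) {
        if (v %in% cuts[[a]]) next
        gain <- sum((xa[i] < v) != (xa[j] < v))
        if (gain > best$gain) best <- list(gain = gain, attr = a, cut = v)
      }
    }
    if (best$gain == 0L) break
    cuts[[best$attr]] <- sort(c(cuts[[best$attr]], best$cut))
    xa <- table[[best$attr]]
    sep <- (xa[pair[, 1L]] < best$cut) != (xa[pair[, 2L]] < best$cut)
    alive <- alive & !sep
  }
  cuts
}

#' Discretize the condition attributes of a decision table
#'
#' Fits \code{cuts} cut points per numeric condition attribute by one of
#' three schemes — equal-width intervals over the observed range, equal
#' frequency (quantiles), or supervised global discernibility (greedy
#' midpoint selection maximizing newly discerned pairs of objects with
#' different decisions) — and replaces values with left-closed right-open
#' interval labels such as \code{"[-Inf,0.921)"}. Non-numeric attributes
#' (e.g. Sex) pass through unchanged; an attribute with a single distinct
#' value gets zero cuts with a warning. Cuts are fitted on this (training)
#' table only; apply them to held-out data with \code{\link{apply_cuts}}.
#'
#' @param table Decision table with numeric condition attributes.
#' @param method \code{"quantiles"}, \code{"intervals"} or
#'   \code{"discernibility"}.
#' @param cuts Number of cuts per attribute, 1-3 (inducing 2-4 ranges).
#' @param decision Name of the decision column (excluded from
#'   discretization; required by the supervised method).
#' @return Object of class \code{cut_set}: list with \code{cuts} (named list
#'   of cut values), \code{method}, \code{table} (the discretized table).
#' @export
discretize_attributes <- function(table,
                                  method = c("quantiles", "intervals",
                                             "discernibility"),
                                  cuts = 2, decision = "decision") {
  method <- match.arg(method)
  abort_if(!cuts %in% 1:3, "cuts must be 1, 2 or 3")
  attrs <- setdiff(names(table), decision)
  num_attrs <- attrs[vapply(table[attrs], is.numeric, logical(1))]
  cut_list <- stats::setNames(vector("list", length(num_attrs)), num_attrs)

  if (method == "discernibility") {
    abort_if(is.null(table[[decision]]),
             "supervised discretization needs a decision column")
    cut_list <- discern_cuts(table, num_attrs, decision, cuts)
  } else {
    for (a in num_attrs) {
      x <- table[[a]]
      if (length(unique(x)) < 2L) {
        warning("attribute ", a, " has a single distinct value; no cuts",
                call. = FALSE)
        cut_list[[a]] <- numeric(0)
        next
      }
      cut_list[[a]] <- if (method == "intervals") {
        min(x) + seq_len(cuts) * diff(range(x)) / (cuts + 1)
      } else {
        unique(stats::quantile(x, probs = seq_len(cuts) / (cuts + 1),
                               names = FALSE, type = 7))
      }
    }
  }
  res <- structure(list(cuts = cut_list, method = method, decision = decision),
                   class = "cut_set")
  res$table <- apply_cuts(res, table)
  res
}

#' @rdname discretize_attributes
#' @param cut_set A fitted \code{cut_set}.
#' @param newdata Table with the same condition attributes (decision column
#'   optional).
#' @return \code{apply_cuts()}: the table with numeric attributes replaced
#'   by interval labels.
#' @export
apply_cuts <- function(cut_set, newdata) {
  abort_if(!inherits(cut_set, "cut_set"), "not a cut_set")
  out <- newdata
  for (a in names(cut_set$cuts)) {
    if (!a %in% names(out)) next
    out[[a]] <- cut_to_labels(out[[a]], cut_set$cuts[[a]])
  }
  out
}

#' Compute a decision reduct
#'
#' A reduct is a minimal attribute subset preserving the positive region
#' (the objects classifiable with certainty) of the full attribute set.
#' \code{"greedy"} adds the attribute with the largest positive-region gain
#' until the full positive region is reached, then drops redundant
#' attributes by backward elimination. \code{"daar"} (dynamically adjusted
#' approximate reduct) additionally subjects each candidate to a
#' permutation-probe test — the attribute is only accepted when its gain
#' beats the gain it achieves on a decision-permuted table in at least
#' \code{1 - alpha} of \code{n_probes} permutations — which keeps
#' noise-only attributes out; if no candidate passes while the positive
#' region is still short, the best-gain attribute is added regardless so
#' the returned set always preserves the full positive region.
#'
#' @param table Discretized decision table.
#' @param method \code{"greedy"} or \code{"daar"}.
#' @param decision Decision column name.
#' @param n_probes,alpha Permutation-probe parameters for \code{"daar"}.
#' @param seed Optional seed for the probes.
#' @return Character vector of attribute names.
#' @export
compute_reduct <- function(table, method = c("greedy", "daar"),
                           decision = "decision", n_probes = 100,
                           alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  abort_if(nrow(table) == 0L, "empty decision table")
  attrs <- setdiff(names(table), decision)
  full_pos <- positive_region_size(table, attrs, decision)

  with_seed(seed, {
    red <- character(0)
    cur <- positive_region_size(table, red, decision)
    remaining <- attrs
    while (cur < full_pos && length(remaining) > 0L) {
      gains <- vapply(remaining, function(a) {
        positive_region_size(table, c(red, a), decision) - cur
      }, numeric(1))
      ord <- order(-gains)  # stable: ties keep column order
      pick <- NULL
      if (method == "greedy") {
        if (gains[ord[1]] <= 0) ord <- ord[1]  # forced progress guard
        pick <- remaining[ord[1]]
      } else {
        for (k in ord) {
          if (gains[k] <= 0) break
          a <- remaining[k]
          probe_gains <- vapply(seq_len(n_probes), function(b) {
            perm <- table
            perm[[decision]] <- sample(perm[[decision]])
            base <- positive_region_size(perm, red, decision)
            positive_region_size(perm, c(red, a), decision) - base
          }, numeric(1))
          if (mean(gains[k] > probe_gains) >= 1 - alpha) {
            pick <- a
            break
          }
        }
        if (is.null(pick)) pick <- remaining[ord[1]]
      }
      red <- c(red, pick)
      remaining <- setdiff(remaining, pick)
      cur <- positive_region_size(table, red, decision)
    }
    # backward elimination of redundant attributes
    changed <- TRUE
    while (changed && length(red) > 1L) {
      changed <- FALSE
      for (a in red) {
        if (positive_region_size(table, setdiff(red, a), decision) == cur) {
          red <- setdiff(red, a)
          changed <- TRUE
          break
        }
      }
    }
    red
  })
}

#' Laplace confidence of a rule
#'
#' Smoothed rule precision \eqn{(n_K + 1) / (n + k)} where \eqn{n_K} is the
#' number of matching objects of the rule's class, \eqn{n} the number of
#' matching objects of any class, and \eqn{k} the number of classes.
#'
#' @param n_matching_class,n_matching Counts with
#'   \code{0 <= n_matching_class <= n_matching}.
#' @param k Number of classes (>= 2).
#' @return The Laplace confidence in (0, 1).
#' @examples
#' laplace_confidence(9, 10, 3) # 10/13
#' @export
laplace_confidence <- function(n_matching_class, n_matching, k) {
  abort_if(k < 2, "k must be >= 2")
  abort_if(n_matching_class < 0 || n_matching_class > n_matching,
           "need 0 <= n_matching_class <= n_matching")
  (n_matching_class + 1) / (n_matching + k)
}

rule_matches <- function(conditions, table) {
  m <- rep(TRUE, nrow(table))
  for (a in names(conditions)) {
    m <- m & (as.character(table[[a]]) == conditions[[a]])
  }
  m
}

#' Induce decision rules from a discretized table
#'
#' Generates IF-THEN rules over the reduct attributes with one of four
#' sequential-covering schemes: \code{LEM2} (covering each class's lower
#' approximation by minimal condition complexes), \code{CN2} (beam-search
#' best complex by class-entropy, unordered covering), \code{AQ}
#' (seed-example star generation against the negative examples) or
#' \code{IND} (one rule per indiscernibility block with the block-majority
#' decision). Every rule carries its support (matching objects of its own
#' class) and Laplace confidence.
#'
#' @param table Discretized decision table.
#' @param reduct Character vector of attributes to build antecedents from.
#' @param method \code{"LEM2"}, \code{"CN2"}, \code{"AQ"} or \code{"IND"}.
#' @param decision Decision column name.
#' @param beam Beam width for CN2 / star size for AQ.
#' @return A \code{rule_set}: tibble with list-column \code{conditions}
#'   (named character vector per rule), \code{class}, \code{length},
#'   \code{support}, \code{laplace}; attributes \code{fallback}
#'   (training-majority label) and \code{method}.
#' @export
induce_rules <- function(table, reduct, method = c("LEM2", "CN2", "AQ", "IND"),
                         decision = "decision", beam = 5L) {
  method <- match.arg(method)
  abort_if(length(reduct) == 0L, "empty reduct")
  abort_if(nrow(table) == 0L, "empty table")
  dec <- as.character(table[[decision]])
  classes <- if (is.factor(table[[decision]])) {
    intersect(levels(table[[decision]]), unique(dec))
  } else sort(unique(dec))

  res <- switch(method,
    IND = rules_ind(table, reduct, dec),
    LEM2 = rules_lem2(table, reduct, dec, classes),
    CN2 = rules_cn2(table, reduct, dec, beam),
    AQ = rules_aq(table, reduct, dec, classes, beam))

  k <- max(2L, length(unique(dec)))
  rows <- purrr::map2(res$conds, res$classes, function(cn, cl) {
    m <- rule_matches(cn, table)
    n_match <- sum(m)
    n_class <- sum(m & dec == cl)
    tibble::tibble(conditions = list(cn), class = cl,
                   length = length(cn), support = n_class,
                   laplace = laplace_confidence(n_class, n_match, k))
  })
  rules <- dplyr::bind_rows(rows)
  maj <- names(sort(table(dec), decreasing = TRUE))[1]
  structure(rules, fallback = maj, method = method, attributes_used = reduct,
            class = c("rule_set", class(tibble::tibble())))
}

rules_ind <- function(table, reduct, dec) {
  part <- compute_partition(table, reduct)
  conds <- list(); cls <- character(0)
  for (b in part) {
    cn <- vapply(reduct, function(a) as.character(table[[a]][b[1]]),
                 character(1))
    names(cn) <- reduct
    conds <- c(conds, list(cn))
    cls <- c(cls, names(sort(table(dec[b]), decreasing = TRUE))[1])
  }
  list(conds = conds, classes = cls)
}

# Canonical LEM2: cover each class's lower approximation with minimal
# complexes; selector choice maximizes overlap with the remaining goal,
# ties broken by smaller selector extent, then attribute order.
rules_lem2 <- function(table, reduct, dec, classes) {
  part <- compute_partition(table, reduct)
  n <- nrow(table)
  sel_ext <- list()  # extent of each (attr, value) selector
  for (a in reduct) {
    va <- as.character(table[[a]])
    for (v in unique(va)) sel_ext[[paste0(a, "\r", v)]] <- which(va == v)
  }
  sel_attr <- sub("\r.*$", "", names(sel_ext))
  sel_val <- sub("^.*\r", "", names(sel_ext))

  conds <- list(); cls <- character(0)
  for (cl in classes) {
    class_idx <- which(dec == cl)
    lower <- approximate_class(part, class_idx)$lower
    B <- lower
    while (length(B) > 0L) {
      T_idx <- integer(0)
      TG <- B
      covered <- seq_len(n)
      while (!(length(T_idx) > 0L && all(covered %in% lower))) {
        cand <- which(!(sel_attr %in% sel_attr[T_idx]))
        overlap <- vapply(cand, function(s) {
          length(intersect(sel_ext[[s]], TG))
        }, integer(1))
        if (!any(overlap > 0L)) break
        ext_size <- lengths(sel_ext[cand])
        pick <- cand[order(-overlap, ext_size)][1]
        T_idx <- c(T_idx, pick)
        TG <- intersect(TG, sel_ext[[pick]])
        covered <- Reduce(intersect, sel_ext[T_idx])
      }
      if (!all(covered %in% lower)) break  # inconsistent remainder
      # drop redundant selectors
      for (s in T_idx) {
        rest <- setdiff(T_idx, s)
        if (length(rest) > 0L &&
            all(Reduce(intersect, sel_ext[rest]) %in% lower)) {
          T_idx <- rest
        }
      }
      cn <- stats::setNames(sel_val[T_idx], sel_attr[T_idx])
      conds <- c(conds, list(cn))
      cls <- c(cls, cl)
      B <- setdiff(B, Reduce(intersect, sel_ext[T_idx]))
    }
  }
  list(conds = conds, classes = cls)
}

complex_entropy <- function(dec_covered) {
  p <- table(dec_covered) / length(dec_covered)
  -sum(p * log2(p + (p == 0)))
}

# CN2-style unordered covering with a width-`beam` search over conjunctions
# of attribute-value selectors, ranked by the class entropy of the full
# covered extent (ties: more uncovered examples captured), so a complex is
# driven to purity wherever the table allows it.
rules_cn2 <- function(table, reduct, dec, beam) {
  n <- nrow(table)
  selectors <- list()
  for (a in reduct) {
    va <- as.character(table[[a]])
    for (v in unique(va)) {
      selectors <- c(selectors, list(list(attr = a, val = v,
                                          ext = which(va == v))))
    }
  }
  remaining <- seq_len(n)
  conds <- list(); cls <- character(0)
  while (length(remaining) > 0L && length(conds) < 200L) {
    star <- list(list(conds = character(0), attrs = character(0),
                      ext = seq_len(n)))
    best <- NULL
    repeat {
      newc <- list()
      for (cx in star) {
        for (s in selectors) {
          if (s$attr %in% cx$attrs) next
          ext <- intersect(cx$ext, s$ext)
          cov <- intersect(ext, remaining)
          if (length(cov) == 0L) next
          cn <- c(cx$conds, stats::setNames(s$val, s$attr))
          newc <- c(newc, list(list(conds = cn, attrs = names(cn), ext = ext,
                                    score = complex_entropy(dec[ext]),
                                    ncov = length(cov))))
        }
      }
      if (length(newc) == 0L) break
      sc <- vapply(newc, `[[`, numeric(1), "score")
      nc <- vapply(newc, `[[`, numeric(1), "ncov")
      ord <- order(sc, -nc)
      newc <- newc[ord[seq_len(min(beam, length(newc)))]]
      top <- newc[[1]]
      if (is.null(best) || top$score < best$score ||
          (top$score == best$score && top$ncov > best$ncov)) {
        best <- top
        star <- newc
        if (best$score == 0) break
      } else break
    }
    if (is.null(best)) break
    cls <- c(cls, names(sort(table(dec[best$ext]), decreasing = TRUE))[1])
    conds <- c(conds, list(best$conds))
    remaining <- setdiff(remaining, best$ext)
  }
  list(conds = conds, classes = cls)
}

# AQ-style covering: grow a complex from an uncovered seed example,
# repeatedly adding the seed's selector that excludes the most remaining
# negative examples, then drop redundant selectors.
rules_aq <- function(table, reduct, dec, classes, beam) {
  n <- nrow(table)
  conds <- list(); cls <- character(0)
  for (cl in classes) {
    pos <- which(dec == cl)
    uncovered <- pos
    guard <- 0L
    while (length(uncovered) > 0L && guard < 200L) {
      guard <- guard + 1L
      seed <- uncovered[1]
      cn <- character(0)
      ext <- seq_len(n)
      repeat {
        neg <- setdiff(ext, pos)
        if (length(neg) == 0L) break
        cand_attrs <- setdiff(reduct, names(cn))
        if (length(cand_attrs) == 0L) break
        excl <- vapply(cand_attrs, function(a) {
          v <- as.character(table[[a]][seed])
          sum(as.character(table[[a]][neg]) != v)
        }, integer(1))
        a <- cand_attrs[which.max(excl)]
        v <- as.character(table[[a]][seed])
        cn[a] <- v
        ext <- ext[as.character(table[[a]][ext]) == v]
        if (max(excl) == 0L) break
      }
      # simplify while keeping the complex pure
      for (a in names(cn)) {
        rest <- cn[setdiff(names(cn), a)]
        if (length(rest) == 0L) next
        m <- which(rule_matches(rest, table))
        if (all(dec[m] == cl)) cn <- rest
      }
      conds <- c(conds, list(cn))
      cls <- c(cls, cl)
      covered <- which(rule_matches(cn, table))
      uncovered <- setdiff(uncovered, covered)
    }
  }
  list(conds = conds, classes = cls)
}

#' Filter a rule set by the Laplace-confidence criteria
#'
#' A model is rejected when it has fewer than \code{min_rules} rules (at
#' least two are needed to discriminate three classes) or when the mean
#' Laplace confidence over all its rules falls below
#' \code{mean_lc_threshold}. When more than \code{max_rules} rules remain,
#' only the \code{max_rules} highest-confidence rules are kept (ties by
#' support, then original order) — a larger rule base is considered
#' impractical.
#'
#' @param rules A \code{rule_set}.
#' @param min_rules,mean_lc_threshold,max_rules Filtration thresholds.
#' @return The (possibly capped) \code{rule_set}, or an object of class
#'   \code{rule_rejection} describing why the model was rejected.
#' @export
filter_rules <- function(rules, min_rules = 2, mean_lc_threshold = 0.6,
                         max_rules = 100) {
  abort_if(!inherits(rules, "rule_set"), "not a rule_set")
  if (nrow(rules) < min_rules) {
    return(structure(list(reason = "too_few_rules", n_rules = nrow(rules)),
                     class = "rule_rejection"))
  }
  mean_lc <- mean(rules$laplace)
  if (mean_lc < mean_lc_threshold) {
    return(structure(list(reason = "low_mean_laplace", mean_laplace = mean_lc),
                     class = "rule_rejection"))
  }
  if (nrow(rules) > max_rules) {
    keep <- order(-rules$laplace, -rules$support,
                  seq_len(nrow(rules)))[seq_len(max_rules)]
    att <- attributes(rules)
    rules <- rules[sort(keep), ]
    attr(rules, "fallback") <- att$fallback
    attr(rules, "method") <- att$method
    attr(rules, "attributes_used") <- att$attributes_used
    class(rules) <- c("rule_set", class(tibble::tibble()))
  }
  rules
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set: %d rules (%s), fallback %s>\n", nrow(x),
              attr(x, "method") %||% "?", attr(x, "fallback") %||% "?"))
  for (i in seq_len(min(nrow(x), 10L))) {
    cn <- x$conditions[[i]]
    cat(sprintf("  IF %s THEN %s  (support %d, Lc %.3f)\n",
                paste(names(cn), "is", cn, collapse = " AND "),
                x$class[i], x$support[i], x$laplace[i]))
  }
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Classify discretized objects with a rule set
#'
#' Among the rules matching an object, the most specific one (largest
#' antecedent) wins; remaining ties are resolved by higher Laplace
#' confidence, then larger support, then rule order. Objects matching no
#' rule — including objects whose values fall outside every training
#' interval — receive the fallback (training-majority) label.
#'
#' @param object A \code{rule_set}.
#' @param newdata Table discretized with the training \code{cut_set}.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.rule_set <- function(object, newdata, ...) {
  rules <- object
  fb <- attr(rules, "fallback")
  n <- nrow(newdata)
  match_mat <- vapply(rules$conditions, rule_matches, logical(n),
                      table = newdata)
  match_mat <- matrix(match_mat, nrow = n)
  pri <- order(-rules$length, -rules$laplace, -rules$support,
               seq_len(nrow(rules)))
  out <- character(n)
  for (i in seq_len(n)) {
    hit <- pri[match_mat[i, pri]][1]
    out[i] <- if (is.na(hit)) fb else rules$class[hit]
  }
  factor(out, levels = sort(unique(c(rules$class, fb, out))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
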