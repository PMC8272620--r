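# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rule set
#'
#' @param x A \code{rule_set}.
#' @param ... Unused.
#' @return Tibble with one row per rule: a readable \code{rule} string, the
#'   consequent \code{class}, antecedent \code{length}, \code{support} and
#'   \code{laplace} confidence.
#' @method tidy rule_set
#' @export
tidy.rule_set <- function(x, ...) {
  tibble::tibble(
    rule = vapply(x$conditions, function(cn) {
      paste("IF", paste(names(cn), "is", cn, collapse = " AND "))
    }, character(1)),
    class = x$class,
    length = x$length,
    support = x$support,
    laplace = x$laplace)
}

#' @rdname tidy.rule_set
#' @return \code{glance()}: one-row tibble with \code{n_rules},
#'   \code{mean_laplace}, \code{mean_length}, \code{fallback}.
#' @method glance rule_set
#' @export
glance.rule_set <- function(x, ...) {
  tibble::tibble(n_rules = nrow(x),
                 mean_laplace = mean(x$laplace),
                 mean_length = mean(x$length),
                 fallback = attr(x, "fallback"))
}

#' Tidy repeated-run results
#'
#' @param x A \code{respgran_cv} object.
#' @param ... Unused.
#' @return \code{tidy()}: the per-repeat run tibble. \code{glance()}: the
#'   one-row summary (mean/median/quartile accuracy, mean macro-F1, median
#'   rule count, rejections).
#' @method tidy respgran_cv
#' @export
tidy.respgran_cv <- function(x, ...) x$runs

#' @rdname tidy.respgran_cv
#' @method glance respgran_cv
#' @export
glance.respgran_cv <- function(x, ...) dplyr::bind_cols(x$hp, x$summary)

#' Tidy grid-search results
#'
#' @param x A \code{respgran_grid} object.
#' @param ... Unused.
#' @return \code{tidy()}: one row per configuration with its summary.
#'   \code{glance()}: the winning configuration row (or a zero-row tibble
#'   when every configuration was rejected).
#' @method tidy respgran_grid
#' @export
tidy.respgran_grid <- function(x, ...) x$summary

#' @rdname tidy.respgran_grid
#' @method glance respgran_grid
#' @export
glance.respgran_grid <- function(x, ...) {
  if (isTRUE(x$no_model)) return(x$summary[0, ])
  x$best
}

#' Export a rule set as JSON
#'
#' Serializes the rules in the printed interval dialect, together with the
#' fallback label and (optionally) the training cuts, so a model can be
#' inspected or applied outside R.
#'
#' @param rules A \code{rule_set}.
#' @param path Output file.
#' @param cut_set Optional \code{cut_set} whose cut values are embedded.
#' @return \code{path}, invisibly.
#' @export
write_rules_json <- function(rules, path, cut_set = NULL) {
  obj <- list(
    rules = purrr::pmap(list(rules$conditions, rules$class, rules$support,
                             rules$laplace), function(cn, cl, sup, lc) {
      list(`if` = as.list(cn), then = cl, support = sup, laplace = lc)
    }),
    fallback = attr(rules, "fallback"),
    cuts = if (!is.null(cut_set)) cut_set$cuts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
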