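#' Standardize a signal to zero mean and unit variance
#'
#' Centers and scales a signal by its population standard deviation
#' (divide-by-n), the convention used before every wavelet decomposition in
#' this package so that coefficient magnitudes are comparable across
#' subjects and recording gains.
#'
#' @param signal A \code{resp_signal} or numeric vector of length >= 2.
#' @return The standardized signal, same class as the input.
#' @examples
#' standardize_signal(c(1, 2, 3))
#' @export
standardize_signal <- function(signal) {
  x <- as.numeric(signal)
  abort_if(length(x) < 2L, "need at least 2 samples to standardize")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  abort_if(sdev == 0, "degenerate input: constant signal has zero variance")
  out <- (x - mu) / sdev
  if (inherits(signal, "resp_signal")) {
    attributes(out) <- attributes(signal)
  }
  out
}

# Single-level DWT with half-point symmetric boundary extension. Returns
# floor((n + f - 1) / 2) coefficients per band, the standard decimated
# filter-bank convention.
dwt_step <- function(x, flt) {
  f <- length(flt$dec_lo)
  n <- length(x)
  abort_if(n < f, "signal too short for this wavelet's filter length (", f, ")")
  ext <- c(x[(f - 1):1], x, x[n:(n - f + 2)])
  # correlation with the reversed filter, accumulated tap by tap (filters
  # are short, so this beats FFT convolution on long signals)
  conv_valid <- function(g) {
    L <- length(ext) - f + 1L
    v <- numeric(L)
    for (i in seq_len(f)) {
      v <- v + g[f - i + 1L] * ext[i:(i + L - 1L)]
    }
    v[seq(2, L, by = 2)]
  }
  list(a = conv_valid(flt$dec_lo), d = conv_valid(flt$dec_hi))
}

# Inverse of dwt_step: upsample, convolve with the synthesis filters, trim
# the boundary transient and truncate to the original length.
idwt_step <- function(a, d, flt, out_len) {
  f <- length(flt$rec_lo)
  up <- function(c) {
    u <- numeric(2 * length(c))
    u[seq(1, length(u), by = 2)] <- c
    u
  }
  conv_full <- function(x, g) {
    s <- numeric(length(x) + f - 1L)
    for (i in seq_len(f)) {
      idx <- i:(i + length(x) - 1L)
      s[idx] <- s[idx] + g[i] * x
    }
    s
  }
  s <- conv_full(up(a), flt$rec_lo) + conv_full(up(d), flt$rec_hi)
  s <- s[(f - 1):(length(s) - (f - 2))]
  s[seq_len(out_len)]
}

#' Maximum useful DWT decomposition depth
#'
#' @param n Signal length.
#' @param wavelet Wavelet name.
#' @return Largest level for which the decimated signal still spans the
#'   analysis filter, \code{floor(log2(n / (f - 1)))} for filter length f.
#' @export
dwt_max_level <- function(n, wavelet) {
  f <- length(wavelet_filters(wavelet)$dec_lo)
  if (n < f) return(0L)
  as.integer(floor(log2(n / (f - 1))))
}

#' Multilevel DWT decomposition and reconstruction
#'
#' \code{dwt_decompose()} runs the pyramid algorithm to the requested depth,
#' returning every detail band plus the final approximation;
#' \code{dwt_reconstruct()} inverts it exactly (up to floating-point error),
#' which also serves as a self-check of the filter bank.
#'
#' @param x Numeric vector.
#' @param wavelet Wavelet name (see \code{\link{list_wavelets}}).
#' @param level Decomposition depth; defaults to \code{dwt_max_level()}.
#' @return \code{dwt_decompose()}: list with \code{details} (list, finest
#'   first), \code{approx}, \code{lengths} (input length at each level),
#'   \code{wavelet}. \code{dwt_reconstruct()}: the reconstructed numeric
#'   vector.
#' @export
dwt_decompose <- function(x, wavelet, level = NULL) {
  x <- as.numeric(x)
  flt <- wavelet_filters(wavelet)
  f <- length(flt$dec_lo)
  maxlev <- dwt_max_level(length(x), wavelet)
  if (is.null(level)) level <- maxlev
  abort_if(level < 1, "level must be >= 1")
  abort_if(level > maxlev,
           "signal too short for a depth-", level, " decomposition with ",
           wavelet, ": needs at least ", (f - 1) * 2^level, " samples")
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (k in seq_len(level)) {
    lengths[k] <- length(a)
    st <- dwt_step(a, flt)
    details[[k]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a, lengths = lengths, wavelet = wavelet)
}

#' @rdname dwt_decompose
#' @param dec A decomposition from \code{dwt_decompose()}.
#' @export
dwt_reconstruct <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (k in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[k]], flt, dec$lengths[k])
  }
  a
}

#' Scalogram: retained DWT detail bands of a respiratory signal
#'
#' Decomposes a signal with the discrete wavelet transform and discards the
#' \code{drop_finest} smallest-scale detail bands, which at 1000 Sa/s carry
#' only sub-breath noise; the retained bands are re-indexed 1..K from the
#' finest retained scale. With the default \code{drop_finest = 7}, a 20-min
#' recording at 1000 Sa/s yields a first retained band of roughly 4700
#' coefficients, and retained scales 5-7 span roughly 4-16 s, bracketing the
#' breathing period.
#'
#' @param signal \code{resp_signal} or numeric vector.
#' @param wavelet Mother wavelet name (default \code{"rbio3.1"}).
#' @param max_level Total decomposition depth; defaults to the maximum depth
#'   the signal supports.
#' @param drop_finest Number of finest detail bands to discard (default 7 at
#'   1000 Sa/s; lower it by \code{log2(1000/rate)} for downsampled signals to
#'   keep the retained scales at the same time spans).
#' @return An object of class \code{scalogram}: list with \code{wavelet},
#'   \code{drop_finest}, and \code{levels}, a list mapping retained-scale
#'   index (as character) to its coefficient array.
#' @examples
#' sig <- synthesize_signal(breathing_params(), duration_s = 120, rate = 125)
#' sc <- dwt_scalogram(standardize_signal(sig), drop_finest = 4)
#' lengths(sc$levels)
#' @export
dwt_scalogram <- function(signal, wavelet = "rbio3.1", max_level = NULL,
                          drop_finest = 7) {
  x <- as.numeric(signal)
  abort_if(drop_finest < 0, "drop_finest must be >= 0")
  maxlev <- dwt_max_level(length(x), wavelet)
  if (is.null(max_level)) max_level <- maxlev
  abort_if(max_level <= drop_finest,
           "signal supports only ", maxlev, " levels with ", wavelet,
           "; need more than drop_finest = ", drop_finest,
           " (at least ",
           (length(wavelet_filters(wavelet)$dec_lo) - 1) * 2^(drop_finest + 1),
           " samples)")
  dec <- dwt_decompose(x, wavelet, level = max_level)
  kept <- dec$details[(drop_finest + 1):max_level]
  names(kept) <- as.character(seq_along(kept))
  structure(list(wavelet = wavelet, drop_finest = drop_finest, levels = kept),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram: %s, %d retained scales (dropped %d finest)>\n",
              x$wavelet, length(x$levels), x$drop_finest))
  invisible(x)
}

#' Rank mother wavelets by the scalogram interquartile-range criterion
#'
#' For standardized signals, a better-matched mother wavelet spreads the
#' scalogram over a broader range of values. Each candidate is scored by the
#' IQR of its pooled retained-scale coefficients per signal, averaged over
#' signals; candidates are returned sorted by descending mean IQR (ties
#' broken lexicographically by name). Candidates that fail to decompose any
#' signal are excluded with a warning.
#'
#' @param signals List of \code{resp_signal}s or numeric vectors.
#' @param candidates Character vector of wavelet names.
#' @param drop_finest Passed to \code{\link{dwt_scalogram}}.
#' @return A tibble with columns \code{wavelet}, \code{mean_iqr},
#'   \code{rank}; the per-signal IQRs are attached as attribute
#'   \code{"per_signal"} (long tibble) for boxplot display.
#' @export
rank_mother_wavelets <- function(signals, candidates = list_wavelets(),
                                 drop_finest = 7) {
  abort_if(length(signals) < 1, "need at least one signal")
  abort_if(length(candidates) < 1, "need at least one candidate wavelet")
  per <- purrr::map(candidates, function(wv) {
    iqrs <- tryCatch(
      vapply(signals, function(s) {
        sc <- dwt_scalogram(standardize_signal(s), wavelet = wv,
                            drop_finest = drop_finest)
        iqr_of(unlist(sc$levels, use.names = FALSE))
      }, numeric(1)),
      error = function(e) {
        warning("wavelet ", wv, " failed and was excluded from the ranking: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(iqrs)) return(NULL)
    tibble::tibble(wavelet = wv, signal = seq_along(iqrs), iqr = unname(iqrs))
  })
  per <- dplyr::bind_rows(per)
  abort_if(nrow(per) == 0, "every candidate failed to decompose the signals")
  ranking <- per |>
    dplyr::summarise(mean_iqr = mean(.data$iqr), .by = "wavelet") |>
    dplyr::arrange(dplyr::desc(.data$mean_iqr), .data$wavelet) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(ranking, "per_signal") <- per
  ranking
}

#' Quartile descriptors of the retained wavelet scales
#'
#' Granulates each requested retained scale of a scalogram into four
#' descriptors — the quartiles Q1, Q2, Q3 (linear-interpolation convention)
#' and the interquartile range IQR = Q3 - Q1 — a fixed-size summary that is
#' independent of the signal length. High IQR at scales 6-7 is the signature
#' of periodic-like breathing.
#'
#' @param scalogram A \code{\link{dwt_scalogram}} result.
#' @param scales Retained-scale indices to summarise (default 5:7).
#' @return A one-row tibble with columns \code{Scale<s>_q1}, \code{_q2},
#'   \code{_q3}, \code{_IQR} for each scale.
#' @export
extract_descriptors <- function(scalogram, scales = 5:7) {
  abort_if(!inherits(scalogram, "scalogram"), "not a scalogram")
  missing <- setdiff(as.character(scales), names(scalogram$levels))
  abort_if(length(missing) > 0,
           "scalogram lacks retained scale(s) ", paste(missing, collapse = ", "),
           "; increase the decomposition depth or the signal length")
  vals <- purrr::map(scales, function(s) {
    q <- quartiles(scalogram$levels[[as.character(s)]])
    stats::setNames(c(q, q[3] - q[1]),
                    paste0("Scale", s, c("_q1", "_q2", "_q3", "_IQR")))
  })
  tibble::as_tibble(as.list(unlist(vals)))
}

#' Compute wavelet descriptors for one signal
#'
#' Convenience composition of \code{\link{standardize_signal}},
#' \code{\link{dwt_scalogram}} and \code{\link{extract_descriptors}}.
#'
#' @inheritParams dwt_scalogram
#' @inheritParams extract_descriptors
#' @return One-row tibble of 4 x \code{length(scales)} descriptors.
#' @export
signal_descriptors <- function(signal, wavelet = "rbio3.1", scales = 5:7,
                               drop_finest = 7) {
  sc <- dwt_scalogram(standardize_signal(signal), wavelet = wavelet,
                      max_level = drop_finest + max(scales),
                      drop_finest = drop_finest)
  extract_descriptors(sc, scales = scales)
}

#' Build the decision table for one breathing pattern
#'
#' Joins the 12 wavelet descriptors with the anthropometric condition
#' attributes (Age, Sex, BMI, WHR) and sets the decision to the chosen
#' pattern's contribution decile, in the standard column order
#' \code{Scale5_q1 ... Scale7_IQR, Age, Sex, BMI, WHR, decision}.
#'
#' @param features Tibble with \code{subject_id} and the 12 descriptor
#'   columns (one row per subject).
#' @param cohort Cohort tibble (see \code{\link{generate_cohort}}).
#' @param pattern One of \code{"periodic"}, \code{"intermediate"},
#'   \code{"normal"}.
#' @return A tibble with 16 condition attributes plus a \code{decision}
#'   column holding deciles 0-10.
#' @export
build_decision_table <- function(features, cohort,
                                 pattern = c("periodic", "intermediate",
                                             "normal")) {
  pattern <- match.arg(pattern)
  desc_cols <- as.vector(outer(paste0("Scale", 5:7),
                               c("_q1", "_q2", "_q3", "_IQR"), paste0))
  desc_cols <- desc_cols[order(rep(5:7, 4))]
  missing <- setdiff(c("subject_id", desc_cols), names(features))
  abort_if(length(missing) > 0,
           "features is missing attribute(s): ", paste(missing, collapse = ", "))
  need <- c("subject_id", "age", "sex", "bmi", "whr",
            paste0("contrib_", pattern))
  missing <- setdiff(need, names(cohort))
  abort_if(length(missing) > 0,
           "cohort is missing column(s): ", paste(missing, collapse = ", "))
  dplyr::inner_join(features, cohort[need], by = "subject_id") |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(desc_cols)),
      Age = .data$age, Sex = .data$sex, BMI = .data$bmi, WHR = .data$whr,
      decision = as.integer(.data[[paste0("contrib_", pattern)]]))
}

#' Decision table straight from a cohort
#'
#' Runs \code{\link{signal_descriptors}} over every subject's signal and
#' assembles the pattern's decision table.
#'
#' @inheritParams build_decision_table
#' @param signals Named list of signals aligned with the cohort.
#' @inheritParams signal_descriptors
#' @return See \code{\link{build_decision_table}}.
#' @export
cohort_decision_table <- function(cohort, signals, pattern,
                                  wavelet = "rbio3.1", scales = 5:7,
                                  drop_finest = 7) {
  feats <- purrr::map2(cohort$subject_id, signals, function(id, s) {
    dplyr::bind_cols(tibble::tibble(subject_id = id),
                     signal_descriptors(s, wavelet = wavelet, scales = scales,
                                        drop_finest = drop_finest))
  }) |> dplyr::bind_rows()
  build_decision_table(feats, cohort, pattern)
}

#' Discretize the decile outcome into three classes
#'
#' Maps decile contributions 0-10 onto the labels A, B, C via the ranges
#' \code{[0, d1)}, \code{[d1, d2)}, \code{[d2, 10]}: the top interval is
#' closed so that decile 10 belongs to C. Valid boundary pairs have
#' \code{d1} in 1..5, width \code{d2 - d1} in 2..5 and \code{d2 < 9}.
#'
#' @param decile Integer vector of deciles in 0..10.
#' @param d1,d2 Lower and upper decile boundaries.
#' @return Factor with levels A, B, C.
#' @examples
#' discretize_outcome(c(0, 3, 6, 10), 3, 6)
#' @export
discretize_outcome <- function(decile, d1, d2) {
  abort_if(!d1 %in% 1:5, "d1 must be in 1..5")
  abort_if(!(d2 - d1) %in% 2:5 || d2 >= 9,
           "d2 must equal d1 + width with width in 2..5 and d2 < 9")
  abort_if(any(decile < 0 | decile > 10 | decile != round(decile)),
           "deciles must be integers in 0..10")
  factor(ifelse(decile < d1, "A", ifelse(decile < d2, "B", "C")),
         levels = c("A", "B", "C"))
}

#' All valid outcome-range pairs
#'
#' @return Tibble of the valid \code{(d1, d2)} boundary pairs in
#'   lexicographic order (17 pairs).
#' @export
enumerate_outcome_ranges <- function() {
  tidyr::expand_grid(d1 = 1:5, width = 2:5) |>
    dplyr::mutate(d2 = .data$d1 + .data$width) |>
    dplyr::filter(.data$d2 < 9) |>
    dplyr::select("d1", "d2") |>
    dplyr::arrange(.data$d1, .data$d2)
}

#' Reduce the zero-decile bias by subsampling
#'
#' Recordings with a zero decile for the modelled pattern dominate the
#' table; this stratification step randomly removes zero-decile rows until
#' their count matches the rounded average count of deciles 1..10 (a no-op
#' when already at or below that average).
#'
#' @param table Decision table whose \code{decision} column still holds
#'   deciles 0-10.
#' @param seed Optional seed for the uniform removal.
#' @param decision Name of the decision column.
#' @return The subsampled table (original row order preserved).
#' @export
debias_subsample <- function(table, seed = NULL, decision = "decision") {
  dec <- table[[decision]]
  abort_if(is.null(dec), "no decision column '", decision, "'")
  abort_if(all(dec == 0), "table has no nonzero-decile cases")
  target <- round(sum(dec > 0) / 10)
  zero_idx <- which(dec == 0)
  if (length(zero_idx) <= target) return(table)
  keep <- with_seed(seed, sample(zero_idx, target))
  table[sort(c(which(dec > 0), keep)), , drop = FALSE]
}
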