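#' Breathing-pattern generator parameters
#'
#' Bundles the morphological parameters of a synthetic respiratory-belt
#' signal: a train of triangular inhale-exhale events of person-consistent
#' shape, optionally amplitude-modulated by a slow sinusoidal envelope
#' (the waxing and waning characteristic of periodic-like breathing), with
#' optional apneas inserted as silent gaps longer than three breathing
#' cycles.
#'
#' @param breath_period_s Breathing period in seconds (typically 3-6 s).
#' @param breath_amplitude Peak chest-excursion amplitude, arbitrary units.
#' @param triangle_duty Fraction of the period occupied by the triangular
#'   inhale-exhale event, in (0, 1].
#' @param modulation_depth Depth of the sinusoidal amplitude envelope in
#'   \[0, 1\]; 0 gives a pure normal pattern.
#' @param modulation_period_s Period of the envelope in seconds (slow,
#'   e.g. 30-90 s).
#' @param apnea_rate_per_min Expected inserted apneas per minute (>= 0).
#' @param apnea_duration_cycles Apnea length in breathing cycles; must be
#'   strictly greater than 3, since shorter pauses do not count as apneas.
#' @param noise_sd Additive Gaussian noise standard deviation, as a fraction
#'   of \code{breath_amplitude}.
#'
#' @return An object of class \code{breathing_params}.
#' @examples
#' breathing_params(breath_period_s = 4, modulation_depth = 0.8)
#' @export
breathing_params <- function(breath_period_s = 4,
                             breath_amplitude = 1,
                             triangle_duty = 0.6,
                             modulation_depth = 0,
                             modulation_period_s = 60,
                             apnea_rate_per_min = 0,
                             apnea_duration_cycles = 4,
                             noise_sd = 0) {
  abort_if(breath_period_s <= 0, "breath_period_s must be positive")
  abort_if(breath_amplitude <= 0, "breath_amplitude must be positive")
  abort_if(triangle_duty <= 0 || triangle_duty > 1,
           "triangle_duty must lie in (0, 1]")
  abort_if(modulation_depth < 0 || modulation_depth > 1,
           "modulation_depth must lie in [0, 1]")
  abort_if(modulation_period_s <= 0, "modulation_period_s must be positive")
  abort_if(apnea_rate_per_min < 0, "apnea_rate_per_min must be >= 0")
  abort_if(apnea_duration_cycles <= 3,
           "apnea_duration_cycles must exceed 3: a pause only counts as an ",
           "apnea when no respiratory activity lasts longer than three cycles")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(
    list(breath_period_s = breath_period_s,
         breath_amplitude = breath_amplitude,
         triangle_duty = triangle_duty,
         modulation_depth = modulation_depth,
         modulation_period_s = modulation_period_s,
         apnea_rate_per_min = apnea_rate_per_min,
         apnea_duration_cycles = apnea_duration_cycles,
         noise_sd = noise_sd),
    class = "breathing_params")
}

new_resp_signal <- function(samples, rate, apneas = NULL) {
  abort_if(length(samples) < 1L, "a signal needs at least one sample")
  abort_if(rate <= 0, "sampling rate must be positive")
  structure(as.numeric(samples), rate = rate,
            apneas = apneas, class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  rate <- attr(x, "rate")
  cat(sprintf("<resp_signal: %d samples @ %g Sa/s (%.1f s)>\n",
              length(x), rate, length(x) / rate))
  invisible(x)
}

#' Sampling rate of a respiratory signal
#' @param signal A \code{resp_signal}.
#' @return Sampling rate in Sa/s.
#' @export
signal_rate <- function(signal) {
  r <- attr(signal, "rate")
  if (is.null(r)) stop("not a resp_signal: missing sampling rate", call. = FALSE)
  r
}

#' Synthesize a respiratory-belt signal
#'
#' Builds a train of symmetric triangular inhale-exhale events at the given
#' breathing period. With \code{modulation_depth > 0} the per-breath peak
#' amplitude follows a slow sinusoidal envelope,
#' \eqn{a_i = A (1 + m \sin(2\pi t_i / T))}, emulating the waxing and waning
#' of periodic-like breathing. Apneas are inserted as silent (noise-only)
#' gaps spanning \code{apnea_duration_cycles} breathing cycles, placed at
#' breath onsets with at least four undisturbed cycles between consecutive
#' gaps; their ground-truth locations are retained in the \code{"apneas"}
#' attribute.
#'
#' @param params A \code{\link{breathing_params}} object.
#' @param duration_s Signal duration in seconds (> 0).
#' @param rate Sampling rate in Sa/s (default 1000, the acquisition rate of
#'   the respiratory belt this package targets).
#' @param seed Optional integer seed; the same seed reproduces the signal
#'   bit-exactly and the caller's RNG stream is left untouched.
#'
#' @return A \code{resp_signal}: numeric vector with attributes \code{rate}
#'   and \code{apneas} (a tibble of inserted gap onsets/durations).
#' @examples
#' sig <- synthesize_signal(breathing_params(), duration_s = 40, rate = 100)
#' length(sig)
#' @export
synthesize_signal <- function(params, duration_s, rate = 1000, seed = NULL) {
  abort_if(!inherits(params, "breathing_params"),
           "params must be created with breathing_params()")
  abort_if(!is.numeric(duration_s) || duration_s <= 0,
           "duration_s must be positive")
  abort_if(!is.numeric(rate) || rate <= 0, "rate must be positive")
  with_seed(seed, {
    p <- params
    n <- round(duration_s * rate)
    y <- numeric(n)
    width <- p$triangle_duty * p$breath_period_s
    onsets <- if (duration_s >= width) {
      seq(0, duration_s - width, by = p$breath_period_s)
    } else numeric(0)  # segment shorter than one breath event

    # place apneas at breath onsets, separated by >= 4 breathing cycles
    ap_dur <- p$apnea_duration_cycles * p$breath_period_s
    n_ap <- round(p$apnea_rate_per_min * duration_s / 60)
    ap_start <- numeric(0)
    if (n_ap > 0) {
      cand <- onsets[onsets >= p$breath_period_s &
                       onsets + ap_dur <= duration_s - p$breath_period_s]
      for (s in sample(cand)) {
        if (length(ap_start) >= n_ap) break
        if (all(abs(s - ap_start) >= ap_dur + 4 * p$breath_period_s)) {
          ap_start <- c(ap_start, s)
        }
      }
      if (length(ap_start) < n_ap) {
        warning("could only place ", length(ap_start), " of ", n_ap,
                " requested apneas", call. = FALSE)
      }
      ap_start <- sort(ap_start)
    }

    suppressed <- rep(FALSE, length(onsets))
    for (s in ap_start) {
      suppressed <- suppressed |
        (onsets + width > s & onsets < s + ap_dur)
    }

    for (t0 in onsets[!suppressed]) {
      t_peak <- t0 + width / 2
      amp <- p$breath_amplitude *
        (1 + p$modulation_depth * sin(2 * pi * t_peak / p$modulation_period_s))
      i0 <- floor(t0 * rate) + 1L
      i1 <- min(n, ceiling((t0 + width) * rate))
      if (i0 > n) next
      tt <- (seq(i0, i1) - 1) / rate
      tri <- amp * pmax(0, 1 - abs(tt - t_peak) / (width / 2))
      y[i0:i1] <- y[i0:i1] + tri
    }

    if (p$noise_sd > 0) {
      y <- y + stats::rnorm(n, 0, p$noise_sd * p$breath_amplitude)
    }
    apneas <- tibble::tibble(onset_s = ap_start,
                             duration_s = rep(ap_dur, length(ap_start)))
    new_resp_signal(y, rate, apneas = apneas)
  })
}

#' Body mass index and waist-to-hip ratio
#'
#' @param weight_kg,height_cm,waist_cm,hip_cm Positive anthropometric
#'   measurements (vectorized).
#' @return A tibble with columns \code{bmi} (kg/m^2) and \code{whr},
#'   rounded to four decimals as reported in cohort tables.
#' @examples
#' compute_anthropometrics(127, 190, 116, 121) # bmi 35.1801, whr 0.9587
#' @export
compute_anthropometrics <- function(weight_kg, height_cm, waist_cm, hip_cm) {
  abort_if(any(c(weight_kg, height_cm, waist_cm, hip_cm) <= 0, na.rm = FALSE) ||
             anyNA(c(weight_kg, height_cm, waist_cm, hip_cm)),
           "all anthropometric inputs must be positive")
  tibble::tibble(
    bmi = round(weight_kg / (height_cm / 100)^2, 4),
    whr = round(waist_cm / hip_cm, 4))
}

# Contribution deciles for one subject given its expert label; deciles sum
# to 10 and the dominant pattern of a normal/periodic label reaches >= 7
# (70%), while under an intermediate label no pattern reaches 7.
sample_contributions <- function(label) {
  if (label == "normal") {
    dn <- sample(7:10, 1)
    dp <- sample(0:(10 - dn), 1)
    di <- 10 - dn - dp
  } else if (label == "periodic") {
    dp <- sample(7:10, 1)
    dn <- sample(0:(10 - dp), 1)
    di <- 10 - dp - dn
  } else {
    di <- sample(4:6, 1)
    dp <- sample(0:(10 - di), 1)
    dn <- 10 - di - dp
  }
  c(periodic = dp, intermediate = di, normal = dn)
}

# Label-conditional segment parameters used when assembling a subject's
# signal from its contribution deciles.
segment_params <- function(pattern, period, amplitude, mod_period, noise_sd,
                           apnea_rates) {
  breathing_params(
    breath_period_s = period,
    breath_amplitude = amplitude,
    triangle_duty = 0.6,
    modulation_depth = switch(pattern, normal = 0, intermediate = 0.45,
                              periodic = 0.85),
    modulation_period_s = mod_period,
    apnea_rate_per_min = apnea_rates[[pattern]],
    apnea_duration_cycles = 4,
    noise_sd = noise_sd)
}

#' Generate a synthetic study cohort
#'
#' Draws \code{n} subjects with expert pattern labels in the requested
#' proportions, label-conditional anthropometrics (the periodic-like and
#' intermediate groups have stochastically higher weight, waist, BMI and WHR
#' and a larger male fraction than the normal group), contribution deciles
#' consistent with the 70\% labelling rule, and one respiratory-belt signal
#' per subject assembled from ten pattern segments matching the subject's
#' contribution deciles (in shuffled order, emulating patterns changing
#' during a recording).
#'
#' @param n Number of subjects (>= 1).
#' @param class_mix Named proportions over \code{normal}, \code{intermediate},
#'   \code{periodic}; must sum to 1.
#' @param duration_s Recording length per subject in seconds (default 1200,
#'   i.e. 20 minutes).
#' @param rate Sampling rate in Sa/s (default 1000).
#' @param noise_sd Per-signal additive noise, fraction of amplitude.
#' @param apnea_rates Named list of per-minute apnea insertion rates per
#'   segment pattern.
#' @param seed Integer master seed; each subject consumes an independent
#'   derived stream, so the cohort is reproducible bit-exactly.
#'
#' @return A list with \code{cohort} (tibble, one row per subject in the
#'   standard column layout) and \code{signals} (named list of
#'   \code{resp_signal} objects, aligned by \code{subject_id}).
#' @examples
#' cs <- generate_cohort(4, duration_s = 60, rate = 50, seed = 1)
#' cs$cohort
#' @export
generate_cohort <- function(n,
                            class_mix = c(normal = 1/3, intermediate = 1/3,
                                          periodic = 1/3),
                            duration_s = 1200, rate = 1000,
                            noise_sd = 0.03,
                            apnea_rates = list(normal = 0, intermediate = 0.1,
                                               periodic = 0.3),
                            seed = NULL) {
  abort_if(!is.numeric(n) || n < 1, "n must be >= 1")
  abort_if(is.null(names(class_mix)) ||
             !setequal(names(class_mix), c("normal", "intermediate", "periodic")),
           "class_mix must be named with normal/intermediate/periodic")
  abort_if(any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8,
           "class_mix proportions must be nonnegative and sum to 1")
  mix <- class_mix[c("normal", "intermediate", "periodic")]

  # largest-remainder apportionment of labels, shuffled per seed
  base <- floor(mix * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(mix * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  labels <- with_seed(child_seed(seed, 0), sample(rep(names(mix), base)))

  male_prob <- c(normal = 0.45, intermediate = 0.62, periodic = 0.70)
  bmi_mu <- c(normal = 26.5, intermediate = 29.5, periodic = 30.5)
  whr_mu <- c(normal = 0.885, intermediate = 0.925, periodic = 0.945)

  rows <- vector("list", n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    res <- with_seed(child_seed(seed, i), {
      sex <- if (stats::runif(1) < male_prob[[lab]]) "M" else "F"
      age <- round(min(max(stats::rnorm(1, 51.4, 11), 18), 85))
      height <- round(min(max(stats::rnorm(1, if (sex == "M") 176 else 164, 7),
                              145), 205))
      bmi_t <- min(max(stats::rnorm(1, bmi_mu[[lab]], 4), 17), 45)
      weight <- round(bmi_t * (height / 100)^2, 2)
      hip <- round(min(max(stats::rnorm(1, if (sex == "M") 103 else 106, 7),
                           80), 140), 1)
      whr_t <- min(max(stats::rnorm(1, whr_mu[[lab]] +
                                      if (sex == "M") 0.03 else -0.03, 0.055),
                       0.65), 1.15)
      waist <- round(whr_t * hip)

      contrib <- sample_contributions(lab)
      period <- stats::runif(1, 3, 6)
      amplitude <- stats::runif(1, 0.8, 1.25)
      mod_period <- stats::runif(1, 40, 80)

      seg_patterns <- sample(rep(names(contrib), contrib))
      seg_dur <- duration_s / 10
      segs <- lapply(seg_patterns, function(pt) {
        synthesize_signal(
          segment_params(pt, period, amplitude, mod_period, noise_sd,
                         apnea_rates),
          duration_s = seg_dur, rate = rate)
      })
      samples <- unlist(lapply(segs, as.numeric), use.names = FALSE)
      ap <- dplyr::bind_rows(lapply(seq_along(segs), function(k) {
        a <- attr(segs[[k]], "apneas")
        if (nrow(a)) a$onset_s <- a$onset_s + (k - 1) * seg_dur
        a
      }))
      sig <- new_resp_signal(samples, rate, apneas = ap)

      row <- tibble::tibble(
        subject_id = i, age = age, sex = sex,
        weight_kg = weight, height_cm = height,
        waist_cm = waist, hip_cm = hip,
        bmi = weight / (height / 100)^2,
        whr = waist / hip,
        apnea_count = nrow(ap),
        apneas_per_min = nrow(ap) / (duration_s / 60),
        apnea_mean_dur_s = if (nrow(ap)) mean(ap$duration_s) else 0,
        contrib_periodic = contrib[["periodic"]],
        contrib_intermediate = contrib[["intermediate"]],
        contrib_normal = contrib[["normal"]],
        expert_label = c(normal = 1L, intermediate = 2L, periodic = 3L)[[lab]])
      list(row = row, sig = sig)
    })
    rows[[i]] <- res$row
    signals[[i]] <- res$sig
  }
  names(signals) <- sprintf("subject_%03d", seq_len(n))
  list(cohort = dplyr::bind_rows(rows), signals = signals)
}

#' Drop-count matched to a sampling rate
#'
#' The seven finest DWT detail bands are discarded at the reference rate of
#' 1000 Sa/s; for signals generated at a lower rate the same time scales sit
#' \code{log2(reference_rate / rate)} levels earlier, so fewer bands are
#' dropped to keep the retained scales 5-7 spanning the same 4-16 s range
#' that brackets the breathing period.
#'
#' @param rate Sampling rate in Sa/s.
#' @param reference_drop,reference_rate Drop count and rate they refer to.
#' @return Integer drop count for \code{\link{dwt_scalogram}}.
#' @examples
#' drop_finest_for_rate(125) # 4
#' @export
drop_finest_for_rate <- function(rate, reference_drop = 7,
                                 reference_rate = 1000) {
  abort_if(rate <= 0, "rate must be positive")
  d <- reference_drop - round(log2(reference_rate / rate))
  abort_if(d < 0, "rate too low for the reference drop count")
  as.integer(d)
}

#' Generate a graded benchmark cohort
#'
#' A parameter-recovery design: subjects' contribution deciles for the
#' chosen pattern are assigned round-robin from \code{deciles} (default
#' \{0, 1, 4, 5, 9, 10\} — low, medium and high contributions with a clear
#' margin from the usual outcome cuts), the complement of each recording is
#' purely periodic-like (purely normal when \code{pattern = "periodic"}),
#' and the anthropometric attributes are drawn independently of the outcome
#' so that only the signal carries class information. This produces a
#' decision table with unambiguous A/B/C structure against which the
#' rule-learning pipeline's recovery can be measured.
#'
#' @param n Number of subjects.
#' @param pattern Pattern whose contribution is graded
#'   (\code{"normal"} or \code{"periodic"}).
#' @param deciles Decile values cycled over subjects.
#' @param duration_s,rate Recording length and sampling rate (defaults 600 s
#'   at 125 Sa/s, a decimated emulation keeping the same breathing-period
#'   time scales; pair with \code{drop_finest_for_rate(rate)} downstream).
#' @param noise_sd Additive noise, fraction of amplitude.
#' @param seed Integer master seed.
#' @return As \code{\link{generate_cohort}}: list with \code{cohort} and
#'   \code{signals}.
#' @export
generate_graded_cohort <- function(n, pattern = c("normal", "periodic"),
                                   deciles = c(0, 1, 4, 5, 9, 10),
                                   duration_s = 600, rate = 125,
                                   noise_sd = 0.03, seed = NULL) {
  pattern <- match.arg(pattern)
  abort_if(n < 1, "n must be >= 1")
  abort_if(any(deciles < 0 | deciles > 10), "deciles must lie in 0..10")
  other <- if (pattern == "normal") "periodic" else "normal"
  dec <- rep(as.integer(deciles), length.out = n)
  rates0 <- list(normal = 0, intermediate = 0, periodic = 0)
  rows <- vector("list", n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(child_seed(seed, i), {
      period <- stats::runif(1, 3, 6)
      amplitude <- stats::runif(1, 0.8, 1.25)
      mod_period <- stats::runif(1, 40, 80)
      k <- dec[i]
      pats <- sample(c(rep(pattern, k), rep(other, 10L - k)))
      segs <- lapply(pats, function(pt) {
        synthesize_signal(
          segment_params(pt, period, amplitude, mod_period, noise_sd, rates0),
          duration_s = duration_s / 10, rate = rate)
      })
      sig <- new_resp_signal(unlist(lapply(segs, as.numeric),
                                    use.names = FALSE), rate,
                             apneas = tibble::tibble(onset_s = numeric(0),
                                                     duration_s = numeric(0)))
      sex <- sample(c("M", "F"), 1)
      height <- round(stats::runif(1, 155, 190))
      weight <- round(stats::runif(1, 22, 35) * (height / 100)^2, 2)
      hip <- round(stats::runif(1, 90, 120), 1)
      waist <- round(stats::runif(1, 0.75, 1.05) * hip)
      contrib <- stats::setNames(c(k, 0L, 10L - k),
                                 paste0("contrib_", c(pattern, "intermediate",
                                                      other)))
      lab <- if (contrib[["contrib_normal"]] >= 7) 1L
             else if (contrib[["contrib_periodic"]] >= 7) 3L else 2L
      row <- tibble::tibble(
        subject_id = i,
        age = round(stats::runif(1, 30, 70)), sex = sex,
        weight_kg = weight, height_cm = height,
        waist_cm = waist, hip_cm = hip,
        bmi = weight / (height / 100)^2, whr = waist / hip,
        apnea_count = 0L, apneas_per_min = 0, apnea_mean_dur_s = 0,
        contrib_periodic = contrib[["contrib_periodic"]],
        contrib_intermediate = 0L,
        contrib_normal = contrib[["contrib_normal"]],
        expert_label = lab)
      list(row = row, sig = sig)
    })
    rows[[i]] <- res$row
    signals[[i]] <- res$sig
  }
  names(signals) <- sprintf("subject_%03d", seq_len(n))
  list(cohort = dplyr::bind_rows(rows), signals = signals)
}

#' Detect apneas in a respiratory signal
#'
#' An apnea is operationalized as an interval with no respiratory activity
#' lasting longer than three breathing cycles. The standardized signal's
#' moving range (max minus min over a one-breath-period window) serves as an
#' activity envelope; maximal runs where it stays below
#' \code{activity_threshold} times its median, after compensating the
#' window's smearing of gap edges, are flagged when their extent exceeds
#' three breathing periods (with a two-sample discretization guard, so a gap
#' of exactly three cycles is not counted).
#'
#' @param signal A \code{resp_signal}.
#' @param breath_period_s The subject's breathing period in seconds.
#' @param activity_threshold Fraction of the median envelope below which the
#'   signal counts as inactive (default 0.1).
#' @return A one-row tibble: \code{count}, \code{per_min},
#'   \code{mean_duration_s} (0 when no apnea is found).
#' @export
detect_apneas <- function(signal, breath_period_s, activity_threshold = 0.1) {
  abort_if(!is.numeric(breath_period_s) || breath_period_s <= 0,
           "breath_period_s must be positive")
  rate <- signal_rate(signal)
  n <- length(signal)
  abort_if(n < breath_period_s * rate,
           "signal shorter than one breathing cycle")
  x <- as.numeric(standardize_signal(signal))
  w <- max(2L, round(breath_period_s * rate))
  env <- moving_range(x, w)
  thr <- activity_threshold * stats::median(env)
  below <- env < thr

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # a silent gap of S samples yields S - w + 1 inactive windows
  gap_samples <- r$lengths[runs] + w - 1L
  min_gap <- 3 * breath_period_s * rate + 2
  keep <- gap_samples > min_gap
  count <- sum(keep)
  durations <- gap_samples[keep] / rate
  tibble::tibble(
    count = count,
    per_min = count / (n / rate / 60),
    mean_duration_s = if (count) mean(durations) else 0)
}

#' Write and read a synthetic cohort on disk
#'
#' \code{write_cohort()} stores the cohort table as CSV (standard column
#' layout), one plain-text signal file per subject (one ASCII sample per
#' line) and a JSON manifest holding the sampling rate, the generator seed
#' and any extra parameters. \code{read_cohort()} reverses it.
#'
#' @param cohort Cohort tibble as produced by \code{\link{generate_cohort}}.
#' @param signals Named list of \code{resp_signal}s aligned with
#'   \code{cohort$subject_id}.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param params Extra generator parameters recorded in the manifest.
#' @return \code{write_cohort()}: the directory, invisibly.
#'   \code{read_cohort()}: list with \code{cohort}, \code{signals},
#'   \code{manifest}.
#' @export
write_cohort <- function(cohort, signals, dir, seed = NULL, params = list()) {
  abort_if(nrow(cohort) != length(signals),
           "cohort rows and signals must be aligned")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    abort_if(!ok, "cannot create directory ", dir)
  }
  readr::write_csv(cohort, file.path(dir, "cohort.csv"))
  rate <- signal_rate(signals[[1]])
  for (i in seq_along(signals)) {
    f <- file.path(dir, sprintf("subject_%03d.txt", cohort$subject_id[i]))
    writeLines(sprintf("%.10g", as.numeric(signals[[i]])), f)
  }
  manifest <- list(rate = rate, seed = seed, n = nrow(cohort), params = params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  abort_if(!dir.exists(dir), "no such directory: ", dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              sex = readr::col_character(),
                              .default = readr::col_double()))
  int_cols <- c("subject_id", "apnea_count", "contrib_periodic",
                "contrib_intermediate", "contrib_normal", "expert_label")
  cohort <- dplyr::mutate(cohort,
                          dplyr::across(dplyr::all_of(int_cols), as.integer))
  signals <- lapply(cohort$subject_id, function(id) {
    f <- file.path(dir, sprintf("subject_%03d.txt", id))
    new_resp_signal(as.numeric(readLines(f)), manifest$rate)
  })
  names(signals) <- sprintf("subject_%03d", cohort$subject_id)
  list(cohort = cohort, signals = signals, manifest = manifest)
}
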