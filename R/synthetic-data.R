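# Synthetic RR-interval series and longitudinal cohort generation.
#
# The generator exists so the full analysis chain (spectral features ->
# composite index -> rank-based tests) can be exercised end-to-end and
# calibrated (type-I error, power, frequency recovery) without clinical data.

#' Parameters for the synthetic RR-series generator
#'
#' Describes a beat-to-beat interval series as a mean level modulated by two
#' sinusoidal rhythms — a low-frequency (Mayer-wave-like, ~0.1 Hz) and a
#' high-frequency (respiration-like, ~0.25 Hz) oscillation — plus white
#' gaussian noise. These are the two rhythms the autoregressive spectral
#' decomposition is expected to resolve.
#'
#' @param duration_s total duration of the series in seconds.
#' @param mean_rr mean interbeat interval in ms.
#' @param lf_freq,hf_freq modulation frequencies in Hz; must satisfy
#'   `0 < lf_freq < hf_freq` and lie below half the mean beat rate.
#' @param lf_amp,hf_amp modulation amplitudes in ms (>= 0).
#' @param noise_sd standard deviation of additive white gaussian noise, ms.
#' @param seed integer seed; identical seeds give identical series. `NULL`
#'   draws from the current RNG stream.
#' @return an object of class `rr_gen_params`.
#' @export
#' @examples
#' p <- rr_gen_params(duration_s = 120, lf_amp = 25, hf_amp = 20, seed = 1)
#' rr <- generate_rr_series(p)
#' length(rr$intervals)
rr_gen_params <- function(duration_s = 300, mean_rr = 900,
                          lf_freq = 0.1, lf_amp = 25,
                          hf_freq = 0.25, hf_amp = 20,
                          noise_sd = 5, seed = NULL) {
  stop_if_not_scalar_number(duration_s, "duration_s", positive = TRUE)
  stop_if_not_scalar_number(mean_rr, "mean_rr", positive = TRUE)
  stop_if_not_scalar_number(lf_freq, "lf_freq", positive = TRUE)
  stop_if_not_scalar_number(hf_freq, "hf_freq", positive = TRUE)
  stop_if_not_scalar_number(lf_amp, "lf_amp", nonnegative = TRUE)
  stop_if_not_scalar_number(hf_amp, "hf_amp", nonnegative = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  if (lf_freq >= hf_freq) {
    stop("'lf_freq' must be below 'hf_freq'", call. = FALSE)
  }
  # rhythms faster than half the mean beat rate cannot be represented in a
  # beat-by-beat series (beat-domain Nyquist limit)
  nyquist_beats <- 0.5 * 1000 / mean_rr
  if (hf_freq >= nyquist_beats) {
    stop(sprintf(
      "'hf_freq' (%.3f Hz) is at or above half the mean beat rate (%.3f Hz)",
      hf_freq, nyquist_beats), call. = FALSE)
  }
  structure(list(duration_s = duration_s, mean_rr = mean_rr,
                 lf_freq = lf_freq, lf_amp = lf_amp,
                 hf_freq = hf_freq, hf_amp = hf_amp,
                 noise_sd = noise_sd, seed = seed),
            class = "rr_gen_params")
}

#' Generate a synthetic RR-interval series
#'
#' Beats are laid down sequentially: the k-th interval equals
#' `mean_rr + lf_amp * sin(2*pi*lf_freq*t) + hf_amp * sin(2*pi*hf_freq*t + phi)`
#' plus gaussian noise, evaluated at the cumulative beat time `t` (seconds)
#' reached so far, until the series spans at least `duration_s`. The phase
#' `phi` of the respiratory rhythm is randomized per seed so tests cannot
#' phase-lock by accident.
#'
#' @param params an [rr_gen_params()] object.
#' @param subject_id,time,phase,posture optional labels attached to the
#'   series (used when writing files and assembling cohorts).
#' @return an object of class `rr_series`: a list with `intervals` (ms) and
#'   the label fields.
#' @export
generate_rr_series <- function(params, subject_id = NA_character_,
                               time = NA_character_, phase = NA_character_,
                               posture = c("rest", "stand")) {
  stopifnot(inherits(params, "rr_gen_params"))
  posture <- match.arg(posture)
  intervals <- with_seed(params$seed, {
    phi <- stats::runif(1L, 0, 2 * pi)
    # upper bound on beats needed, then trim to duration
    slack <- max(params$lf_amp + params$hf_amp + 6 * params$noise_sd, 0)
    min_rr <- max(params$mean_rr - slack, params$mean_rr / 4)
    n_max <- ceiling(params$duration_s * 1000 / min_rr) + 16L
    noise <- stats::rnorm(n_max, 0, params$noise_sd)
    rr <- numeric(n_max)
    t_s <- 0
    n <- 0L
    for (k in seq_len(n_max)) {
      val <- params$mean_rr +
        params$lf_amp * sin(2 * pi * params$lf_freq * t_s) +
        params$hf_amp * sin(2 * pi * params$hf_freq * t_s + phi) +
        noise[k]
      if (val <= 0) {
        stop("generated a non-positive RR interval; reduce amplitudes/noise",
             call. = FALSE)
      }
      n <- k
      rr[k] <- val
      t_s <- t_s + val / 1000
      if (t_s >= params$duration_s) break
    }
    rr[seq_len(n)]
  })
  structure(list(intervals = intervals, subject_id = subject_id,
                 time = time, phase = phase, posture = posture),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats, %.1f s, mean RR %.1f ms\n",
              length(x$intervals), sum(x$intervals) / 1000,
              mean(x$intervals)))
  invisible(x)
}

#' Write / read plain-text RR-interval files
#'
#' One interbeat interval in milliseconds per line, no header — the common
#' exchange format of HRV tools.
#'
#' @param rr an `rr_series` object or a numeric vector of intervals in ms.
#' @param path file path.
#' @rdname rr_series_io
#' @export
write_rr_series <- function(rr, path) {
  intervals <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  writeLines(formatC(intervals, format = "f", digits = 6), path)
  invisible(path)
}

#' @param subject_id,time,phase,posture labels attached to the series read.
#' @rdname rr_series_io
#' @export
read_rr_series <- function(path, subject_id = NA_character_,
                           time = NA_character_, phase = NA_character_,
                           posture = c("rest", "stand")) {
  posture <- match.arg(posture)
  intervals <- as.numeric(readLines(path))
  if (anyNA(intervals)) stop("non-numeric line in RR file: ", path,
                             call. = FALSE)
  if (any(intervals <= 0)) stop("non-positive RR interval in file: ", path,
                                call. = FALSE)
  structure(list(intervals = intervals, subject_id = subject_id,
                 time = time, phase = phase, posture = posture),
            class = "rr_series")
}

# default baseline levels, chosen near the typical mid-life resting values of
# an adult cohort with obesity; spreads give realistic between-subject
# heterogeneity.  The within-subject (occasion-to-occasion) spread defaults
# to half the between-subject spread, i.e. intraclass correlation 0.8.
default_baselines <- function() {
  list(
    means = c(rr_mean = 900, rr_tp = 1400, rr_lfa = 300, rr_hfa = 300,
              delta_lfnu = 24, sap = 120, dap = 80),
    sds   = c(rr_mean = 80, rr_tp = 700, rr_lfa = 220, rr_hfa = 220,
              delta_lfnu = 15, sap = 8, dap = 5)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Emulates a two-arm cold-stimulation study: `n_treat1` subjects exposed at
#' -55 degC and `n_treat2` at -110 degC, each measured at the first (T1) and
#' last (T10) session, before (pre) and after (post) exposure — a complete
#' F1-LD-F2 layout of 4 occasions per subject.
#'
#' Each core variable is generated as
#' `subject baseline + treatment/time/phase shifts + occasion noise`, where
#' the subject baseline is drawn once per subject
#' (`N(baseline_means, baseline_sds)`) and occasion noise has standard
#' deviation `within_sds`. The normalized spectral indices are derived from
#' the absolute powers (`rr_lfnu = 100*lfa/(lfa+hfa)`, `rr_hfnu = 100 -
#' rr_lfnu`, `rr_lfhf = lfa/hfa`) so the normalization identity holds by
#' construction.
#'
#' @param n_treat1,n_treat2 subjects per treatment arm (>= 2 each).
#' @param age_range two-element integer range of ages (years), inclusive.
#' @param sex_probability probability a subject is female.
#' @param baseline_means,baseline_sds named numeric vectors over the core
#'   variables `rr_mean, rr_tp, rr_lfa, rr_hfa, delta_lfnu, sap, dap`;
#'   partial vectors override the defaults.
#' @param within_sds occasion-level noise sds; default `baseline_sds / 2`.
#' @param phase_effects,time_effects,treatment_effects named numeric vectors
#'   of additive shifts applied, respectively, at phase = post, time = T10,
#'   and in the second treatment arm. Default all zero (global null).
#' @param seed integer seed for reproducibility.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_treat1 = 15, n_treat2 = 8,
                          age_range = c(20, 69), sex_probability = 18 / 23,
                          baseline_means = NULL, baseline_sds = NULL,
                          within_sds = NULL,
                          phase_effects = NULL, time_effects = NULL,
                          treatment_effects = NULL, seed = NULL) {
  if (n_treat1 < 2 || n_treat2 < 2) {
    stop("need at least 2 subjects per treatment group (rank procedures ",
         "degenerate below that)", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop("'age_range' must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (sex_probability < 0 || sex_probability > 1) {
    stop("'sex_probability' must be in [0, 1]", call. = FALSE)
  }
  base <- default_baselines()
  merge_named <- function(defaults, user, what, nonneg = FALSE) {
    if (is.null(user)) return(defaults)
    if (is.null(names(user)) || !all(names(user) %in% names(defaults))) {
      stop(sprintf("'%s' must be named with a subset of: %s", what,
                   paste(names(defaults), collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(user))) stop(sprintf("'%s' must be finite", what),
                                    call. = FALSE)
    if (nonneg && any(user < 0)) stop(sprintf("'%s' must be >= 0", what),
                                      call. = FALSE)
    defaults[names(user)] <- user
    defaults
  }
  means <- merge_named(base$means, baseline_means, "baseline_means")
  sds <- merge_named(base$sds, baseline_sds, "baseline_sds", nonneg = TRUE)
  wsds <- merge_named(sds / 2, within_sds, "within_sds", nonneg = TRUE)
  zero <- setNames(numeric(length(means)), names(means))
  structure(list(
    n_treat1 = as.integer(n_treat1), n_treat2 = as.integer(n_treat2),
    age_range = as.integer(age_range), sex_probability = sex_probability,
    baseline_means = means, baseline_sds = sds, within_sds = wsds,
    phase_effects = merge_named(zero, phase_effects, "phase_effects"),
    time_effects = merge_named(zero, time_effects, "time_effects"),
    treatment_effects = merge_named(zero, treatment_effects,
                                    "treatment_effects"),
    seed = seed), class = "cohort_config")
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces a long-format cohort table with one row per subject x time
#' (T1/T10) x phase (pre/post), carrying the full analysis variable set.
#' Absolute spectral powers and RR variance are floored at a small positive
#' value. When `add_ansi = TRUE` the composite ANSI column is computed from
#' the generated `rr_mean`, `rr_tp` and `delta_lfnu` with [compute_ansi()].
#'
#' @param config a [cohort_config()] object.
#' @param add_ansi compute the ANSI column (default `TRUE`).
#' @return a `data.frame` with columns `subject_id, treatment, age, sex,
#'   time, phase` followed by the variables of [hrv_variables()].
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' nrow(coh)  # 23 subjects x 4 occasions
generate_cohort <- function(config, add_ansi = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_treat1 + config$n_treat2
  core <- names(config$baseline_means)
  cohort <- with_seed(config$seed, {
    subject_id <- sprintf("S%02d", seq_len(n))
    treatment <- rep(design_levels$treatment, c(config$n_treat1,
                                                config$n_treat2))
    age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    sex <- ifelse(stats::runif(n) < config$sex_probability, "F", "M")
    grid <- expand.grid(phase = design_levels$phase,
                        time = design_levels$time,
                        subject = seq_len(n), stringsAsFactors = FALSE)
    out <- data.frame(
      subject_id = subject_id[grid$subject],
      treatment = treatment[grid$subject],
      age = age[grid$subject], sex = sex[grid$subject],
      time = grid$time, phase = grid$phase,
      stringsAsFactors = FALSE)
    for (v in core) {
      baseline <- stats::rnorm(n, config$baseline_means[[v]],
                               config$baseline_sds[[v]])
      val <- baseline[grid$subject] +
        stats::rnorm(nrow(out), 0, config$within_sds[[v]]) +
        config$phase_effects[[v]] * (out$phase == "post") +
        config$time_effects[[v]] * (out$time == "T10") +
        config$treatment_effects[[v]] * (out$treatment == "-110C")
      if (v %in% c("rr_tp", "rr_lfa", "rr_hfa")) val <- pmax(val, 1)
      out[[v]] <- val
    }
    out$rr_lfnu <- 100 * out$rr_lfa / (out$rr_lfa + out$rr_hfa)
    out$rr_hfnu <- 100 - out$rr_lfnu
    out$rr_lfhf <- out$rr_lfa / out$rr_hfa
    out
  })
  if (add_ansi) cohort$ansi <- compute_ansi(cohort)$ansi
  keep <- intersect(hrv_variables(include_ansi = add_ansi),
                    names(cohort))
  cohort[, c("subject_id", "treatment", "age", "sex", "time", "phase", keep)]
}

#' Read / write long-format cohort CSV files
#'
#' The schema is `subject_id, treatment, age, sex, time, phase` followed by
#' variable columns (see [hrv_variables()]).
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort(cohort, require_complete = FALSE)
}

#' Read a cohort-generator configuration from YAML
#'
#' Top-level keys mirror the arguments of [cohort_config()]; named mappings
#' (e.g. `phase_effects: {rr_mean: 50}`) become named vectors.
#'
#' @param path YAML file path.
#' @return a `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  vecs <- c("baseline_means", "baseline_sds", "within_sds", "phase_effects",
            "time_effects", "treatment_effects")
  for (v in intersect(vecs, names(raw))) raw[[v]] <- unlist(raw[[v]])
  if ("age_range" %in% names(raw)) raw$age_range <- unlist(raw$age_range)
  do.call(cohort_config, raw)
}
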