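# Time-domain and autoregressive frequency-domain HRV features.
#
# The spectral path follows standard short-term HRV practice: the beat-by-
# beat tachogram is resampled onto a uniform grid, mean- and trend-removed,
# fit with an autoregressive model, and the AR spectrum is split into
# oscillatory components by factoring the AR polynomial into poles and
# attributing power to each pole (pair) through residue decomposition.
# Component powers are then aggregated into the conventional LF and HF bands.

#' @noRd
as_intervals <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(x) && any(!is.finite(x) | x <= 0)) {
    stop("RR intervals must be finite and positive", call. = FALSE)
  }
  x
}

#' Time-domain HRV indices
#'
#' The two classical vagal markers: the mean RR interval (ms) and the total
#' power of RR variability, i.e. the sample variance of the intervals (ms^2,
#' n-1 denominator).
#'
#' @param rr an `rr_series` object or numeric vector of RR intervals in ms.
#' @return a list with `rr_mean` and `rr_tp`.
#' @export
#' @examples
#' time_domain(c(800, 1000, 1200))  # mean 1000, variance 40000
time_domain <- function(rr) {
  x <- as_intervals(rr)
  if (length(x) == 0L) stop("empty RR series", call. = FALSE)
  if (length(x) < 2L) stop("variance needs at least 2 beats", call. = FALSE)
  list(rr_mean = mean(x), rr_tp = stats::var(x))
}

# Conventional short-term HRV band edges (Hz): VLF below lf[1], LF in
# [lf_lo, lf_hi), HF in [lf_hi, hf_hi].
#' Default spectral band edges
#' @return named numeric vector `c(lf_lo, lf_hi, hf_hi)` in Hz.
#' @export
hrv_bands <- function() c(lf_lo = 0.04, lf_hi = 0.15, hf_hi = 0.40)

#' @noRd
classify_band <- function(freq, bands) {
  ifelse(freq < bands[["lf_lo"]], "VLF",
         ifelse(freq < bands[["lf_hi"]], "LF",
                ifelse(freq <= bands[["hf_hi"]], "HF", "outside")))
}

#' Autoregressive spectral decomposition of an RR series
#'
#' Resamples the tachogram at `fs` Hz (cubic spline on the cumulative beat
#' times), removes the mean and a linear trend, fits an AR(`order`) model by
#' the Yule-Walker (Levinson-Durbin) solution, and decomposes the modelled
#' variance into spectral components: each real pole or complex-conjugate
#' pole pair of the AR polynomial contributes one component whose central
#' frequency is the pole angle and whose power is the (pairwise-summed)
#' residue of the AR spectral density at that pole. Component powers add up
#' to the modelled process variance.
#'
#' @param rr an `rr_series` or numeric vector of RR intervals in ms; at
#'   least 64 beats.
#' @param order AR model order (>= 4); fixed, no automatic selection, so
#'   outputs are deterministic given the input.
#' @param fs resampling rate in Hz.
#' @param bands band edges as in [hrv_bands()].
#' @return a `data.frame` of components sorted by central frequency, with
#'   columns `central_freq` (Hz), `power` (ms^2) and `band`
#'   (`VLF`/`LF`/`HF`/`outside`).
#' @export
ar_spectrum <- function(rr, order = 12, fs = 4, bands = hrv_bands()) {
  x <- as_intervals(rr)
  if (length(x) < 64L) {
    stop("spectral analysis needs at least 64 beats, got ", length(x),
         call. = FALSE)
  }
  stop_if_not_scalar_number(order, "order", positive = TRUE)
  if (order < 4) stop("'order' must be at least 4", call. = FALSE)
  order <- as.integer(order)

  # resample the tachogram onto a uniform grid; beat k is placed at the end
  # of its interval
  beat_t <- cumsum(x) / 1000
  grid_t <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / fs)
  if (length(grid_t) <= 4L * order) {
    stop("series too short for AR order ", order, call. = FALSE)
  }
  fun <- stats::splinefun(beat_t, x, method = "natural")
  y <- fun(grid_t)

  # remove mean and linear trend (drift would inflate the VLF band)
  y <- stats::residuals(stats::lm(y ~ grid_t))

  if (stats::var(y) < 1e-12 * max(mean(x)^2, 1)) {
    # flat series: no oscillatory power to attribute
    return(data.frame(central_freq = numeric(0), power = numeric(0),
                      band = character(0), stringsAsFactors = FALSE))
  }

  fit <- stats::ar.yw(y, aic = FALSE, order.max = order, demean = TRUE)
  comp <- ar_component_powers(fit$ar, fit$var.pred, fs)
  comp$band <- classify_band(comp$central_freq, bands)
  comp
}

# Residue decomposition of an AR spectrum into per-pole powers.
#
# For an AR(p) model x_t = sum a_k x_{t-k} + e_t with innovation variance
# s2, the process variance is the unit-circle contour integral of
# s2 / (z A(z) A(1/z)) with A(z) = prod(1 - z_m / z). Its residue at the
# pole z_m (|z_m| < 1) is
#   s2 * z_m^{p-1} / ( prod_{k != m}(z_m - z_k) * prod_k(1 - z_k z_m) ),
# and the residues sum to the variance. A complex-conjugate pair is reported
# as one component (sum of the two residues, which is real); its central
# frequency is fs * arg(z_m) / (2 pi).
#' @noRd
ar_component_powers <- function(a, s2, fs) {
  p <- length(a)
  # poles: roots of z^p - a_1 z^{p-1} - ... - a_p
  poles <- polyroot(c(-rev(a), 1))
  if (any(Mod(poles) >= 1 - 1e-10)) {
    stop("unstable AR fit at order ", p,
         " (pole at or outside the unit circle)", call. = FALSE)
  }
  residue <- function(m) {
    zm <- poles[m]
    denom <- prod(zm - poles[-m]) * prod(1 - poles * zm)
    s2 * zm^(p - 1) / denom
  }
  res <- vapply(seq_len(p), residue, complex(1))
  ang <- Arg(poles)
  # keep one representative per conjugate pair: angle in [0, pi]
  keep <- which(ang > -1e-12)
  used <- rep(FALSE, p)
  central_freq <- numeric(0)
  power <- numeric(0)
  for (m in keep) {
    if (used[m]) next
    used[m] <- TRUE
    pw <- res[m]
    if (ang[m] > 1e-12 && ang[m] < pi - 1e-12) {
      # find the conjugate partner
      mate <- which(!used & abs(poles - Conj(poles[m])) < 1e-8)
      if (length(mate)) {
        mate <- mate[1]
        used[mate] <- TRUE
        pw <- pw + res[mate]
      } else {
        pw <- 2 * Re(pw)  # numerical fallback: double the real part
      }
    }
    central_freq <- c(central_freq, fs * ang[m] / (2 * pi))
    # residues of weak components can come out marginally negative; clamp
    power <- c(power, max(Re(pw), 0))
  }
  ord <- order(central_freq)
  data.frame(central_freq = central_freq[ord], power = power[ord],
             stringsAsFactors = FALSE)
}

#' Band powers and normalized units from spectral components
#'
#' Sums component powers over the LF and HF bands and derives the
#' normalized units: `lf_nu = 100 * lf_a / (lf_a + hf_a)` (analogously
#' `hf_nu`) and the sympathovagal ratio `lf_hf = lf_a / hf_a`. The VLF band
#' is excluded from normalization. When no LF or HF power exists the
#' normalized units are `NA`; when `hf_a` is zero with `lf_a > 0` the ratio
#' is `Inf` but the normalized units remain defined.
#'
#' @param components a component `data.frame` from [ar_spectrum()].
#' @return a list with `lf_a`, `hf_a` (ms^2), `lf_nu`, `hf_nu` (0-100) and
#'   `lf_hf`.
#' @export
#' @examples
#' comps <- data.frame(central_freq = c(0.10, 0.25), power = c(300, 100),
#'                     band = c("LF", "HF"))
#' band_powers(comps)  # lf_nu 75, hf_nu 25, lf_hf 3
band_powers <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("central_freq", "power", "band") %in% names(components)))
  if (nrow(components) && any(components$power < 0)) {
    stop("component powers must be non-negative", call. = FALSE)
  }
  lf_a <- sum(components$power[components$band == "LF"])
  hf_a <- sum(components$power[components$band == "HF"])
  tot <- lf_a + hf_a
  if (tot > 0) {
    lf_nu <- 100 * lf_a / tot
    hf_nu <- 100 * hf_a / tot
    lf_hf <- if (hf_a > 0) lf_a / hf_a else Inf
  } else {
    lf_nu <- hf_nu <- lf_hf <- NA_real_
  }
  list(lf_a = lf_a, hf_a = hf_a, lf_nu = lf_nu, hf_nu = hf_nu, lf_hf = lf_hf)
}

#' Full HRV record for one recording
#'
#' Convenience wrapper combining [time_domain()], [ar_spectrum()] and
#' [band_powers()] for a single RR series.
#'
#' @inheritParams ar_spectrum
#' @return a list of class `hrv_record` with fields `rr_mean`, `rr_tp`,
#'   `lf_a`, `hf_a`, `lf_nu`, `hf_nu`, `lf_hf` plus the series labels.
#' @export
hrv_record <- function(rr, order = 12, fs = 4, bands = hrv_bands()) {
  td <- time_domain(rr)
  bp <- band_powers(ar_spectrum(rr, order = order, fs = fs, bands = bands))
  meta <- if (inherits(rr, "rr_series")) {
    rr[c("subject_id", "time", "phase", "posture")]
  } else {
    list(subject_id = NA_character_, time = NA_character_,
         phase = NA_character_, posture = NA_character_)
  }
  structure(c(td, bp, meta), class = "hrv_record")
}

#' Orthostatic change in normalized LF power
#'
#' The stand-minus-rest difference in `lf_nu`, an index of the sympathetic
#' activation produced by active standing.
#'
#' @param rest,stand `hrv_record` objects (or lists with `lf_nu` and label
#'   fields) from the supine-rest and standing recordings of the same
#'   subject and occasion.
#' @return `stand$lf_nu - rest$lf_nu` (possibly `NA` if either is missing).
#' @export
delta_lfnu <- function(rest, stand) {
  for (fld in c("subject_id", "time", "phase")) {
    a <- rest[[fld]] %||% NA
    b <- stand[[fld]] %||% NA
    if (!is.na(a) && !is.na(b) && a != b) {
      stop(sprintf("rest and stand records disagree on '%s' (%s vs %s)",
                   fld, a, b), call. = FALSE)
    }
  }
  if (identical(rest$posture, "stand") || identical(stand$posture, "rest")) {
    stop("records passed in the wrong posture order (expected rest, stand)",
         call. = FALSE)
  }
  stand$lf_nu - rest$lf_nu
}

#' HRV feature extraction for a set of RR files
#'
#' Reads paired rest/stand plain-text RR files listed in a metadata table
#' and assembles cohort rows: time-domain indices and absolute/normalized
#' spectral powers from the rest recording, plus the orthostatic
#' `delta_lfnu` when a standing recording is present.
#'
#' @param metadata a `data.frame` with columns `subject_id, treatment, age,
#'   sex, time, phase, rest_file` and optionally `stand_file` (paths to RR
#'   files).
#' @param order,fs,bands spectral settings, see [ar_spectrum()].
#' @return a cohort `data.frame` (without `ansi`, `sap`, `dap`).
#' @export
hrv_from_files <- function(metadata, order = 12, fs = 4,
                           bands = hrv_bands()) {
  need <- c("subject_id", "treatment", "age", "sex", "time", "phase",
            "rest_file")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    rest <- hrv_record(read_rr_series(m$rest_file,
                                      subject_id = m$subject_id,
                                      time = m$time, phase = m$phase,
                                      posture = "rest"),
                       order = order, fs = fs, bands = bands)
    dl <- NA_real_
    if (!is.null(metadata$stand_file) && !is.na(m$stand_file) &&
        nzchar(m$stand_file)) {
      stand <- hrv_record(read_rr_series(m$stand_file,
                                         subject_id = m$subject_id,
                                         time = m$time, phase = m$phase,
                                         posture = "stand"),
                          order = order, fs = fs, bands = bands)
      dl <- delta_lfnu(rest, stand)
    }
    data.frame(subject_id = m$subject_id, treatment = m$treatment,
               age = m$age, sex = m$sex, time = m$time, phase = m$phase,
               rr_mean = rest$rr_mean, rr_tp = rest$rr_tp,
               rr_lfa = rest$lf_a, rr_hfa = rest$hf_a,
               rr_lfnu = rest$lf_nu, rr_hfnu = rest$hf_nu,
               rr_lfhf = rest$lf_hf, delta_lfnu = dl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
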