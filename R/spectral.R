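#' Frequency band scheme
#'
#' The six canonical rodent LFP bands — delta 0–3, theta 4–7, alpha 8–12,
#' beta 13–30, gamma 31–80 and high gamma 81–150 Hz — plus the two composite
#' bands used by the high-to-low-power ratio: `low` = 0–12 Hz
#' (delta/theta/alpha) and `high` = 31–150 Hz (gamma/high gamma). Band
#' intervals are closed on the 1 Hz analysis grid; the printed band edges
#' leave 1 Hz gaps (3 to 4, 7 to 8, 12 to 13, 30 to 31 Hz) which are kept
#' literally.
#'
#' @param bands data.frame with columns `band`, `lo`, `hi` (Hz) for the
#'   named (non-composite) bands.
#' @param low,high numeric length-2 composite band edges in Hz.
#' @return object of class `band_scheme`.
#' @export
band_scheme <- function(bands = NULL, low = c(0, 12), high = c(31, 150)) {
  if (is.null(bands))
    bands <- data.frame(
      band = c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"),
      lo = c(0, 4, 8, 13, 31, 81),
      hi = c(3, 7, 12, 30, 80, 150))
  stopifnot(all(c("band", "lo", "hi") %in% names(bands)))
  bands <- bands[order(bands$lo), , drop = FALSE]
  if (any(bands$hi < bands$lo)) stop("band with hi < lo")
  if (nrow(bands) > 1L && any(bands$lo[-1L] <= bands$hi[-nrow(bands)]))
    stop("named bands must not overlap")
  structure(list(bands = bands, low = low, high = high),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>\n")
  print(x$bands, row.names = FALSE)
  cat(sprintf("composites: low %g-%g Hz, high %g-%g Hz\n",
              x$low[1], x$low[2], x$high[1], x$high[2]))
  invisible(x)
}

## second-order IIR notch (biquad) at f0 with quality factor q
.notch_coefs <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Preprocess a raw trace
#'
#' Applies a 4th-order Butterworth low-pass at `lp_cutoff` (default 200 Hz)
#' and second-order IIR notch filters (default 60 and 120 Hz, Q = 30), all
#' forward-backward (zero phase) so that 1-s segment boundaries stay exactly
#' aligned with the behavioural clock.
#'
#' @param trace an [lfp_trace()]; `fs` must exceed twice the low-pass
#'   cutoff.
#' @param lp_cutoff low-pass cutoff frequency in Hz.
#' @param notch_freqs notch centre frequencies in Hz (set `NULL` to skip).
#' @param notch_q notch quality factor.
#' @return the filtered [lfp_trace()], same length.
#' @export
preprocess <- function(trace, lp_cutoff = 200, notch_freqs = c(60, 120),
                       notch_q = 30) {
  stopifnot(inherits(trace, "lfp_trace"))
  fs <- trace$fs
  if (fs <= 2 * lp_cutoff)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz low-pass", fs,
                 lp_cutoff))
  bf <- signal::butter(4, lp_cutoff / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, trace$samples)
  for (f0 in notch_freqs) {
    nc <- .notch_coefs(f0, fs, notch_q)
    x <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), x)
  }
  trace$samples <- x
  trace
}

#' Segment a trace into 1-s blocks
#'
#' @param trace an [lfp_trace()] of duration at least 1 s.
#' @return numeric matrix with `fs` rows and `floor(duration)` columns; any
#'   trailing partial second is discarded.
#' @export
segment_1s <- function(trace) {
  fs <- round(trace$fs)
  n_seg <- length(trace$samples) %/% fs
  if (n_seg < 1L) stop("trace shorter than one second")
  matrix(trace$samples[seq_len(n_seg * fs)], nrow = fs)
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

## one-sided Hamming-windowed PSD of every column of `blocks` (nrow = fs).
## With 1-s blocks the single full-length window makes Welch's method a
## modified periodogram on an exact 1 Hz grid, the coarsest grid that still
## resolves the 0-3 Hz delta band.
.psd_blocks <- function(blocks, fs) {
  n <- nrow(blocks)
  w <- .hamming(n)
  ft <- stats::mvfft(blocks * w)
  nf <- n %/% 2 + 1L
  p <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  p * dbl
}

#' Welch power spectral density of a 1-s block
#'
#' Hamming-windowed one-sided PSD (density scaling, units^2/Hz) on a 1 Hz
#' frequency grid from 0 to `fs/2`. The window spans the full block: for 1-s
#' blocks Welch's method with a single window, equivalent to a modified
#' periodogram, is used so the delta band stays resolvable.
#'
#' @param block numeric vector of exactly `fs` samples.
#' @param fs sampling rate in Hz.
#' @return data.frame with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(block, fs) {
  if (length(block) != round(fs))
    stop(sprintf("block has %d samples but fs = %g: 1-s blocks required",
                 length(block), fs))
  p <- .psd_blocks(matrix(block, ncol = 1L), fs)
  data.frame(freq = seq(0, fs / 2, length.out = nrow(p)), power = p[, 1L])
}

#' Session-averaged PSD
#'
#' Arithmetic mean of the per-1-s-segment Welch PSDs over a whole trace
#' (optionally restricted to a subset of seconds, e.g. one behavioural
#' state).
#'
#' @param trace an [lfp_trace()].
#' @param seconds optional integer vector of 1-based seconds to include.
#' @return data.frame with columns `freq` and `power`.
#' @export
session_psd <- function(trace, seconds = NULL) {
  blocks <- segment_1s(trace)
  if (!is.null(seconds)) {
    seconds <- seconds[seconds >= 1 & seconds <= ncol(blocks)]
    if (length(seconds) == 0L) stop("no seconds selected")
    blocks <- blocks[, seconds, drop = FALSE]
  }
  p <- .psd_blocks(blocks, trace$fs)
  data.frame(freq = seq(0, trace$fs / 2, length.out = nrow(p)),
             power = rowMeans(p))
}

## mean PSD density over lo <= f <= hi, DC bin excluded
.band_mean <- function(power, freq, lo, hi, fs) {
  if (hi > fs / 2) stop(sprintf("band %g-%g Hz exceeds Nyquist %g Hz", lo,
                                hi, fs / 2))
  sel <- freq >= lo & freq <= hi & freq > 0
  if (!any(sel)) stop(sprintf("no PSD bins inside band %g-%g Hz", lo, hi))
  mean(power[sel])
}

#' Per-band average power of a PSD
#'
#' Mean PSD density over the bins with `lo <= f <= hi` for each band of the
#' scheme, plus the `low` and `high` composites. The 0 Hz bin is excluded
#' everywhere: DC reflects amplifier offset, not neural activity.
#'
#' @param psd data.frame from [welch_psd()] / [session_psd()].
#' @param scheme a [band_scheme()].
#' @param fs sampling rate (defaults to twice the top PSD frequency).
#' @return named numeric vector: one entry per named band plus `low`,
#'   `high`.
#' @export
band_powers <- function(psd, scheme = band_scheme(), fs = NULL) {
  if (is.null(fs)) fs <- 2 * max(psd$freq)
  b <- scheme$bands
  out <- vapply(seq_len(nrow(b)), function(i)
    .band_mean(psd$power, psd$freq, b$lo[i], b$hi[i], fs), 0)
  names(out) <- b$band
  c(out,
    low = .band_mean(psd$power, psd$freq, scheme$low[1], scheme$low[2], fs),
    high = .band_mean(psd$power, psd$freq, scheme$high[1], scheme$high[2], fs))
}

#' Per-second band-power series of a trace
#'
#' Segments the trace at 1 s, computes the Welch PSD of every segment and
#' averages the PSD density inside each band. Powers are unnormalised
#' (arbitrary units^2/Hz); the robust-scaled spectrogram is for display only
#' and never feeds the HLR.
#'
#' @param trace an [lfp_trace()] (normally already passed through
#'   [preprocess()]).
#' @param scheme a [band_scheme()].
#' @return a `band_power_series` data.frame with columns `subject_id`,
#'   `second`, one column per band, `low`, `high` and `valid`; metadata
#'   (`cohort_id`, `condition`) kept as attributes.
#' @export
band_power_series <- function(trace, scheme = band_scheme()) {
  blocks <- segment_1s(trace)
  fs <- trace$fs
  p <- .psd_blocks(blocks, fs)
  freq <- seq(0, fs / 2, length.out = nrow(p))
  b <- scheme$bands
  cols <- lapply(seq_len(nrow(b)), function(i) {
    sel <- freq >= b$lo[i] & freq <= b$hi[i] & freq > 0
    colMeans(p[sel, , drop = FALSE])
  })
  names(cols) <- b$band
  sel_lo <- freq >= scheme$low[1] & freq <= scheme$low[2] & freq > 0
  sel_hi <- freq >= scheme$high[1] & freq <= scheme$high[2] & freq > 0
  cols$low <- colMeans(p[sel_lo, , drop = FALSE])
  cols$high <- colMeans(p[sel_hi, , drop = FALSE])
  df <- data.frame(subject_id = trace$subject_id, second = seq_len(ncol(p)),
                   cols, check.names = FALSE)
  df$valid <- Reduce(`&`, lapply(cols, is.finite))
  structure(df, cohort_id = trace$cohort_id, condition = trace$condition,
            scheme = scheme, class = c("band_power_series", "data.frame"))
}

#' High-to-low-power ratio series
#'
#' The HLR of a 1-s segment is its average high-band (31–150 Hz) power
#' divided by its average low-band (0–12 Hz) power, computed from the
#' unnormalised band powers. Segments with zero low-band power (or invalid
#' band powers) are marked invalid rather than raising an error; downstream
#' correlations skip them pairwise.
#'
#' @param series a `band_power_series` (from [band_power_series()] or the
#'   synthetic generator).
#' @return an `hlr_series` data.frame with columns `subject_id`, `second`,
#'   `hlr`, `valid`; provenance attributes carried over.
#' @export
hlr <- function(series) {
  stopifnot(is.data.frame(series), all(c("low", "high") %in% names(series)))
  valid <- series$valid & is.finite(series$low) & is.finite(series$high) &
    series$low > 0
  r <- ifelse(valid, series$high / series$low, NA_real_)
  structure(
    data.frame(subject_id = series$subject_id, second = series$second,
               hlr = r, valid = valid),
    cohort_id = attr(series, "cohort_id"),
    condition = attr(series, "condition"),
    class = c("hlr_series", "data.frame"))
}

#' Band-band Pearson correlation matrix
#'
#' Per subject, the Pearson correlation between the per-second power time
#' series of every pair of named bands, then averaged element-wise across
#' subjects. This is the summary behind the broadband-modulation heatmap:
#' low bands (delta/theta/alpha) correlate strongly with each other and
#' anti-correlate with gamma/high gamma.
#'
#' @param series_list list of `band_power_series`, one per subject/session.
#' @param scheme a [band_scheme()] naming the bands.
#' @return symmetric matrix with unit diagonal; entries undefined for every
#'   subject (constant series) are `NA`.
#' @export
band_correlation_matrix <- function(series_list, scheme = band_scheme()) {
  if (inherits(series_list, "band_power_series"))
    series_list <- list(series_list)
  bands <- scheme$bands$band
  mats <- lapply(series_list, function(s) {
    stopifnot(all(bands %in% names(s)))
    x <- as.matrix(s[s$valid, bands, drop = FALSE])
    if (nrow(x) < 2L) stop("need at least 2 valid segments per subject")
    sds <- apply(x, 2L, stats::sd)
    m <- suppressWarnings(stats::cor(x))
    m[sds == 0, ] <- NA  # constant series: correlation undefined
    m[, sds == 0] <- NA
    diag(m) <- 1
    m
  })
  arr <- simplify2array(mats)
  out <- apply(arr, c(1L, 2L), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  dimnames(out) <- list(bands, bands)
  out
}

#' Spectrogram of a trace
#'
#' Per-second Welch PSDs assembled as a frequency-by-time matrix.
#' @param trace an [lfp_trace()].
#' @return matrix (rows = 0..fs/2 Hz, columns = seconds).
#' @export
spectrogram_1s <- function(trace) {
  p <- .psd_blocks(segment_1s(trace), trace$fs)
  rownames(p) <- seq(0, trace$fs / 2, length.out = nrow(p))
  p
}

#' Robust-scale a spectrogram for display
#'
#' Each frequency row is centred by its median and scaled by its
#' interquartile range over time, which renders the banded structure of the
#' session spectrogram. Rows with zero IQR are set to `NA` and flagged.
#' Display/export only: the HLR always uses unnormalised powers.
#'
#' @param spec matrix (frequency x time), at least 2 time bins.
#' @return scaled matrix with attribute `invalid_rows`.
#' @export
robust_scale_spectrogram <- function(spec) {
  stopifnot(is.matrix(spec), ncol(spec) >= 2L)
  med <- apply(spec, 1L, stats::median)
  iqr <- apply(spec, 1L, stats::IQR)
  bad <- iqr == 0
  out <- sweep(spec, 1L, med, `-`)
  out <- sweep(out, 1L, ifelse(bad, NA_real_, iqr), `/`)
  attr(out, "invalid_rows") <- which(bad)
  out
}
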