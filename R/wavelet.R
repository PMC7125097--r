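#' Configuration for the wavelet semblance indices
#'
#' Parameters of the coherence-gated wavelet phase method. Defaults follow
#' the slow-wave autoregulation literature: the vasogenic band 0.007-0.05 Hz,
#' 800-s moving windows updated every 10 s with ~500 s rejected at the window
#' edges (leaving a central 300 s, matching the correlation-index window
#' length), and a wavelet coherence threshold of 0.46 below which phase
#' estimates are treated as unreliable and discarded.
#'
#' @param band analysis frequency band in Hz (low, high); must lie within the
#'   epoch-rate Nyquist (0.05 Hz for 10-s epochs).
#' @param window_s moving-window length in seconds.
#' @param edge_reject_s total seconds rejected per window (split evenly
#'   between the two edges).
#' @param step_s window update interval in seconds (one epoch).
#' @param coherence_threshold minimum magnitude-squared coherence for a
#'   (scale, time) phase estimate to be retained, in [0, 1].
#' @param voices_per_octave scale resolution of the wavelet transform.
#' @param omega0 centre angular frequency of the complex Morlet mother
#'   wavelet.
#' @param time_smooth width of the coherence time-smoothing Gaussian, as a
#'   multiple of scale (the kernel SD is `time_smooth * scale` seconds).
#'   The default is calibrated so that, together with `scale_smooth_oct`,
#'   independent noise exceeds the 0.46 coherence threshold at only ~4-5% of
#'   scale-time points (so the gate behaves as a significance test).
#' @param scale_smooth_oct width (octaves) of the boxcar smoothing across
#'   scales.
#' @param max_missing_frac maximum fraction of missing epochs tolerated in a
#'   window before its output is set missing.
#' @param min_retained_frac minimum fraction of in-band (scale, time) points
#'   in the averaging region that must pass the coherence threshold; below
#'   it the window's phase average is deemed unsupported and set missing.
#' @param scale_weighted if TRUE, average cos(phase) across scales with
#'   weights proportional to frequency (1/scale) instead of uniformly.
#' @return a `wavelet_config` list.
#' @export
wavelet_config <- function(band = c(0.007, 0.05),
                           window_s = 800,
                           edge_reject_s = 500,
                           step_s = 10,
                           coherence_threshold = 0.46,
                           voices_per_octave = 12L,
                           omega0 = 6,
                           time_smooth = 3,
                           scale_smooth_oct = 0.6,
                           max_missing_frac = 0.25,
                           min_retained_frac = 0.1,
                           scale_weighted = FALSE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            coherence_threshold >= 0, coherence_threshold <= 1,
            window_s > edge_reject_s, step_s > 0)
  structure(list(band = band, window_s = window_s,
                 edge_reject_s = edge_reject_s, step_s = step_s,
                 coherence_threshold = coherence_threshold,
                 voices_per_octave = as.integer(voices_per_octave),
                 omega0 = omega0, time_smooth = time_smooth,
                 scale_smooth_oct = scale_smooth_oct,
                 max_missing_frac = max_missing_frac,
                 min_retained_frac = min_retained_frac,
                 scale_weighted = scale_weighted),
            class = "wavelet_config")
}

# Fourier wavelength factor of the Morlet wavelet: period = factor * scale.
.morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Wavelet scale grid covering a frequency band
#'
#' Log-spaced scales (voices per octave) whose equivalent Fourier frequencies
#' span `band`.
#'
#' @param band frequency band (Hz pair).
#' @param voices scales per octave.
#' @param omega0 Morlet centre frequency.
#' @return list with `scales` (seconds) and `freqs` (Hz), ordered from high
#'   to low frequency.
#' @export
wavelet_scales <- function(band, voices = 12L, omega0 = 6) {
  ff <- .morlet_fourier_factor(omega0)
  s0 <- (1 / band[2]) / ff                       # smallest scale
  s1 <- (1 / band[1]) / ff
  n_oct <- log2(s1 / s0)
  j <- 0:ceiling(n_oct * voices)
  scales <- s0 * 2^(j / voices)
  scales <- scales[scales <= s1 * (1 + 1e-9)]
  list(scales = scales, freqs = 1 / (ff * scales))
}

#' Complex continuous wavelet transform (Morlet)
#'
#' FFT-based continuous wavelet transform of a uniformly sampled series with
#' the complex Morlet mother wavelet, on the scale grid covering
#' `config$band`. Missing samples are linearly interpolated for the
#' transform (callers keep track of the missing mask). The series is
#' demeaned and zero-padded to the next power of two.
#'
#' @param x numeric vector of 10-s epoch values (NA allowed).
#' @param dt sample spacing in seconds (10 for slow-wave epochs).
#' @param config a [wavelet_config()].
#' @return A `scale_time_plane`: list with complex matrix `coef`
#'   (scales x time), `scales`, `freqs`, `dt`, and logical `coi` matrix
#'   (TRUE where the estimate is inside the cone of influence, i.e. valid).
#' @export
cwt_complex <- function(x, dt, config = wavelet_config()) {
  n <- length(x)
  if (config$band[2] > 1 / (2 * dt) + 1e-12)
    stop("configuration error: band exceeds the epoch-rate Nyquist",
         call. = FALSE)
  if (n < 4L) stop("input error: series too short", call. = FALSE)
  sg <- wavelet_scales(config$band, config$voices_per_octave, config$omega0)
  scales <- sg$scales
  if (n < config$window_s / dt)
    stop("input error: fewer epochs than one analysis window", call. = FALSE)

  xi <- x
  if (anyNA(xi)) {
    if (all(is.na(xi))) xi <- numeric(n)
    else xi <- stats::approx(seq_len(n), xi, xout = seq_len(n), rule = 2)$y
  }
  xi <- xi - mean(xi)

  npad <- 2^ceiling(log2(n))
  xp <- c(xi, numeric(npad - n))
  xh <- stats::fft(xp)
  omega <- 2 * pi * c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * dt)

  coef <- matrix(0i, nrow = length(scales), ncol = n)
  norm0 <- pi^(-0.25)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-(s * omega[pos] - config$omega0)^2 / 2)
    w <- stats::fft(xh * psi_hat, inverse = TRUE) / npad
    coef[k, ] <- w[seq_len(n)]
  }

  # cone of influence: e-folding time sqrt(2)*scale from either record end
  tt <- (seq_len(n) - 1) * dt
  efold <- sqrt(2) * scales
  coi <- outer(efold, tt, function(e, t0) t0 >= e) &
    outer(efold, tt, function(e, t0) (n - 1) * dt - t0 >= e)

  structure(list(coef = coef, scales = scales, freqs = sg$freqs,
                 dt = dt, coi = coi),
            class = "scale_time_plane")
}

# Gaussian smoothing in time with scale-proportional width, per scale row.
.smooth_time <- function(m, scales, dt, g = 3) {
  out <- m
  n <- ncol(m)
  for (k in seq_along(scales)) {
    sdk <- g * scales[k]
    half <- min(max(1L, ceiling(3 * sdk / dt)), n - 1L)
    tker <- (-half:half) * dt
    ker <- exp(-tker^2 / (2 * sdk^2))
    ker <- ker / sum(ker)
    row <- m[k, ]
    # pad by reflection to avoid shrinking the record ends toward zero
    padded <- c(rev(row[seq_len(half)]), row, rev(row[(n - half + 1):n]))
    sm <- stats::filter(padded, ker, sides = 2)
    out[k, ] <- sm[(half + 1):(half + n)]
  }
  out
}

# Boxcar smoothing across scales (width in octaves).
.smooth_scale <- function(m, voices, octaves = 0.6) {
  w <- max(1L, round(octaves * voices))
  if (w %% 2 == 0) w <- w + 1L
  if (w <= 1L || nrow(m) == 1L) return(m)
  half <- (w - 1L) / 2L
  ns <- nrow(m)
  out <- m
  for (k in seq_len(ns)) {
    rows <- max(1L, k - half):min(ns, k + half)
    out[k, ] <- colMeans(m[rows, , drop = FALSE])
  }
  out
}

#' Smoothed wavelet coherence and phase difference
#'
#' Magnitude-squared wavelet coherence and cross-spectral phase between two
#' scale-time planes, using scale-proportional Gaussian smoothing in time and
#' a 0.6-octave boxcar across scales (without smoothing, wavelet coherence is
#' identically 1).
#'
#' @param px,py `scale_time_plane`s from [cwt_complex()] on the same grid.
#' @param voices voices per octave of the scale grid (for the scale smoother).
#' @param time_smooth,scale_smooth_oct smoothing widths (see
#'   [wavelet_config()]).
#' @return A `scale_time_plane` with matrices `coherence` in [0, 1], `phase`
#'   in (-pi, pi], `cos_phase`, plus the shared `scales`, `freqs`, `dt` and
#'   combined `coi`.
#' @export
coherence_phase <- function(px, py, voices = 12L, time_smooth = 3,
                            scale_smooth_oct = 0.6) {
  if (!identical(dim(px$coef), dim(py$coef)) ||
      max(abs(px$scales - py$scales)) > 1e-9)
    stop("input error: scale/time grids do not match", call. = FALSE)
  cross <- px$coef * Conj(py$coef)
  sxx <- Mod(px$coef)^2
  syy <- Mod(py$coef)^2

  sm <- function(m) .smooth_scale(.smooth_time(m, px$scales, px$dt, time_smooth),
                                  voices, scale_smooth_oct)
  s_cross_re <- sm(Re(cross))
  s_cross_im <- sm(Im(cross))
  s_xx <- sm(sxx)
  s_yy <- sm(syy)

  denom <- s_xx * s_yy
  coh <- (s_cross_re^2 + s_cross_im^2) / pmax(denom, .Machine$double.eps)
  coh <- pmin(pmax(coh, 0), 1)
  dim(coh) <- dim(s_xx)
  phase <- atan2(s_cross_im, s_cross_re)
  amp <- sqrt(s_cross_re^2 + s_cross_im^2)
  cosph <- ifelse(amp > 0, s_cross_re / pmax(amp, .Machine$double.eps), NA_real_)

  structure(list(coherence = coh, phase = phase, cos_phase = cosph,
                 scales = px$scales, freqs = px$freqs, dt = px$dt,
                 coi = px$coi & py$coi),
            class = "scale_time_plane")
}

#' Coherence-gated wavelet semblance index
#'
#' Computes a wavelet autoregulation index (wPRx, wCOx, wHVx) between two
#' 10-s-mean channels: the cosine of the wavelet phase difference (semblance),
#' averaged over all in-band (scale, time) points whose smoothed coherence
#' reaches `config$coherence_threshold`, within the central
#' `window_s - edge_reject_s` seconds of each trailing `window_s` window
#' (edges rejected against transform edge effects), one value per epoch step.
#'
#' The transform and coherence are computed once over the whole record and
#' the moving window enters as the aggregation region; points inside the
#' record-end cone of influence are excluded. A window with more than
#' `max_missing_frac` missing epochs, or with no point passing the coherence
#' threshold, yields NA.
#'
#' @param sw a `slow_waves_df` from [block_average()].
#' @param ch_x,ch_y channel names.
#' @param config a [wavelet_config()].
#' @param name index label stored on the result.
#' @return an `index_series` (window-end `time_s`, `value` in [-1, 1] or NA).
#' @export
semblance_index <- function(sw, ch_x, ch_y, config = wavelet_config(),
                            name = NULL) {
  for (ch in c(ch_x, ch_y)) if (is.null(sw[[ch]]))
    stop("input error: channel '", ch, "' not present", call. = FALSE)
  dt <- attr(sw, "epoch_s") %||% 10
  x <- sw[[ch_x]]; y <- sw[[ch_y]]
  n <- length(x)
  win <- as.integer(round(config$window_s / dt))
  edge <- as.integer(round(config$edge_reject_s / dt / 2))  # per side
  if (n < win)
    stop("input error: fewer epochs than one analysis window", call. = FALSE)

  px <- cwt_complex(x, dt, config)
  py <- cwt_complex(y, dt, config)
  cp <- coherence_phase(px, py, config$voices_per_octave,
                        config$time_smooth, config$scale_smooth_oct)

  missing <- !(is.finite(x) & is.finite(y))
  keep <- cp$coherence >= config$coherence_threshold & cp$coi &
    !matrix(missing, nrow = nrow(cp$coherence), ncol = n, byrow = TRUE)

  wts <- if (config$scale_weighted) 1 / cp$scales else rep(1, length(cp$scales))
  cosw <- cp$cos_phase * keep * wts
  cosw[!keep] <- 0
  num_e <- colSums(cosw)                  # per-epoch weighted sum of cos(phase)
  den_e <- colSums(keep * wts)            # per-epoch retained weight

  # moving sums over the central region of each trailing window
  cnum <- cumsum(num_e)
  cden <- cumsum(den_e)
  cmiss <- cumsum(as.numeric(missing))
  msum <- function(cs, from, to) cs[to] - ifelse(from > 1, cs[from - 1], 0)

  ends <- win:n
  c_from <- ends - win + 1L + edge
  c_to <- ends - edge
  vals <- rep(NA_real_, length(ends))
  nmiss <- msum(cmiss, ends - win + 1L, ends)
  dsum <- msum(cden, c_from, c_to)
  nsum <- msum(cnum, c_from, c_to)
  tot_w <- sum(wts) * (win - 2L * edge)          # full-support weight
  ok <- nmiss <= config$max_missing_frac * win &
    dsum > config$min_retained_frac * tot_w
  vals[ok] <- nsum[ok] / dsum[ok]
  vals <- pmin(1, pmax(-1, vals))

  out <- data.frame(time_s = sw$time_s[ends], value = vals)
  attr(out, "index") <- name %||% paste0("w_", ch_x, "_", ch_y)
  class(out) <- c("index_series", "data.frame")
  out
}
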