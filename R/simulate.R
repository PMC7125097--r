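#' Simulation configuration for a synthetic piglet recording
#'
#' Builds the parameter set for [generate_recording()]. The defaults emulate
#' the experimental preparation the pipeline is designed for: a piglet whose
#' arterial blood pressure (ABP) is held at baseline and then slowly lowered
#' over a few hours until it falls below the lower limit of autoregulation
#' (LLA), while laser-Doppler flux (LDF), intracranial pressure (ICP) and
#' NIRS channels (rSO2, rTHb) are recorded continuously.
#'
#' The signal model, per channel (all couplings act on the band-limited slow
#' waves; see the methods vignette for the rationale behind each magnitude):
#' \itemize{
#'   \item ABP: baseline hold + linear ramp from `abp_start` to `abp_end`,
#'     plus slow vasogenic waves in `slow_wave_band` (SD `slow_wave_amp`),
#'     plus white noise.
#'   \item LDF: Lassen autoregulation curve of the ramp (plateau above the
#'     LLA, pressure-passive slope below), plus a slow-wave component whose
#'     amplitude is fully pressure-passive below the LLA and shrinks to a
#'     residual `leak_min` at `abpopt_true`, and whose phase lag relative to
#'     the ABP waves grows from 0 (passive) to a quarter-to-half cycle as
#'     autoregulation engages — the true optimal ABP is the argmin of flow
#'     pressure-passivity by construction.
#'   \item rTHb/ICP: coupled to the ABP slow waves with a phase lag that is
#'     0 (pressure-passive, in phase) below the LLA and reaches half a cycle
#'     (anti-phase, active vasoreactivity) at `abpopt_true`; the cosine of
#'     the planted lag equals the reactivity profile c(ABP), so both the
#'     correlation and the semblance of (ABP, rTHb) track c(ABP).
#'   \item rSO2: affine in clean LDF, clamped to [0, 100], plus noise.
#' }
#'
#' Couplings are realized with the quadrature pair of the slow waves:
#' a channel with cosine-profile c receives `c * s + sqrt(1 - c^2) * q`,
#' where q is the quarter-cycle-delayed copy of s — a pure, smoothly varying
#' phase lag `acos(c)` at every in-band frequency.
#'
#' @param duration_s total recording length in seconds.
#' @param sample_rate_hz declared output sampling rate (Hz). Signals are
#'   generated on a 1-Hz grid and sample-held to this rate; all analysis
#'   consumes 10-s means, which the hold leaves unchanged.
#' @param abp_start,abp_end ramp endpoints (mmHg); `abp_end < lla_true < abp_start`.
#' @param hold_frac fraction of the recording spent at `abp_start` before the
#'   ramp begins.
#' @param lla_true true lower limit of autoregulation (mmHg).
#' @param abpopt_true ABP of strongest vasoreactivity (mmHg), `> lla_true`.
#' @param plateau_flow LDF on the autoregulated plateau (a.u.).
#' @param passive_slope pressure-passive LDF slope below the LLA (a.u./mmHg).
#' @param slow_wave_band frequency band (Hz) of the vasogenic slow waves.
#' @param slow_wave_amp standard deviation (mmHg) of the ABP slow-wave component.
#' @param n_components number of sinusoids summed to form the slow waves.
#' @param env_depth depth of the slow waxing/waning amplitude envelope of the
#'   vasogenic waves (SD of the modulation; 0 disables). Vasogenic slow waves
#'   are intermittent in real recordings, and the envelope is shared by all
#'   coupled channels.
#' @param env_period_s periods (seconds) of the sinusoids composing the
#'   envelope.
#' @param noise_sd named vector of white-noise SDs on the 1-Hz generation grid
#'   (`abp`, `icp`, `rso2`, `rthb`, `ldf`), in each channel's units.
#' @param drift_sd named vector of slow non-vasogenic drift SDs per channel
#'   (same units): smooth, channel-independent wanders below the analysis
#'   band (periods ~8-80 min) from systemic physiology (CO2, temperature,
#'   oximeter baseline, probe coupling). They corrupt time-domain
#'   correlations but lie outside the 0.007-0.05 Hz band.
#' @param drift_band frequency band (Hz) of the drift processes.
#' @param artifact_rate_per_h expected number of broadband artifact bursts
#'   (movement, interventions, probe disturbance) per hour; bursts hit all
#'   channels simultaneously with white noise `artifact_scale` times each
#'   channel's `noise_sd`. 0 disables.
#' @param artifact_dur_s range (seconds) of individual burst durations.
#' @param artifact_scale noise multiplier during a burst.
#' @param phase_disp_exp frequency dependence of the autoregulatory phase
#'   lag: the planted lag at slow-wave component frequency f is scaled by
#'   `(f_ref / f)^phase_disp_exp` (f_ref the band's geometric centre), so
#'   slower waves lead more — the documented high-pass character of
#'   autoregulation. 0 gives the same lag at every frequency.
#' @param reactivity_gain rTHb slow-wave coupling gain (a.u./mmHg).
#' @param icp_gain ICP slow-wave coupling gain (mmHg/mmHg).
#' @param rso2_gain rSO2 units per fractional LDF deviation from plateau.
#' @param leak_max maximum fraction of the passive slope that leaks into LDF
#'   above the LLA (imperfect autoregulation away from `abpopt_true`).
#' @param leak_min residual passive fraction at `abpopt_true` (autoregulation
#'   is imperfect even at the optimum).
#' @param activity_sd width (mmHg) of the Gaussian vasoreactivity peak
#'   centred at `abpopt_true`, for the volume-coupled channels (rTHb, ICP).
#' @param flow_activity_sd width (mmHg) of the flow-channel (LDF/rSO2)
#'   autoregulation peak.
#' @param react_base volume-channel lag cosine far from the optimum (where
#'   vasoreactive activity has decayed); the planted lag interpolates from
#'   `react_base` toward `react_min` as the activity peak is approached.
#' @param flow_base,flow_min flow-channel lag cosine far from the optimum
#'   and at the optimum (0 = quarter-cycle lead of fully engaged
#'   autoregulation).
#' @param react_min cosine of the volume-channel (rTHb, ICP) phase lag at
#'   `abpopt_true` — the deepest planted reactivity (-1 would be full
#'   anti-phase; observed phase shifts rarely reach full inversion, and the
#'   reactivity contrast across the autoregulated range is modest).
#' @param transition_w logistic width (mmHg) of the passive/active transition
#'   at the LLA.
#' @param icp_baseline mean ICP (mmHg).
#' @param rthb_baseline mean rTHb (a.u.).
#' @param seed integer RNG seed; fixed seed gives bit-identical recordings.
#' @param animal_id,group,temperature character metadata carried through.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [generate_recording()], [lassen_flow()]
#' @export
sim_config <- function(duration_s = 14400,
                       sample_rate_hz = 1,
                       abp_start = 85,
                       abp_end = 25,
                       hold_frac = 0.25,
                       lla_true = 45,
                       abpopt_true = lla_true + 20,
                       plateau_flow = 100,
                       passive_slope = 2,
                       slow_wave_band = c(0.007, 0.05),
                       slow_wave_amp = 3,
                       n_components = 8,
                       env_depth = 0.5,
                       env_period_s = c(1300, 2100, 3400),
                       noise_sd = c(abp = 6, icp = 1.5, rso2 = 0.7,
                                    rthb = 4, ldf = 3),
                       drift_sd = c(abp = 2, icp = 1.5, rso2 = 3.5,
                                    rthb = 3.5, ldf = 3.5),
                       drift_band = c(2e-4, 2e-3),
                       artifact_rate_per_h = 0,
                       artifact_dur_s = c(30, 120),
                       artifact_scale = 6,
                       phase_disp_exp = 0.15,
                       reactivity_gain = 0.8,
                       icp_gain = 0.3,
                       rso2_gain = 20,
                       leak_max = 1,
                       leak_min = 0.3,
                       activity_sd = 25,
                       flow_activity_sd = 15,
                       react_base = 0.6,
                       react_min = -1,
                       flow_base = 1,
                       flow_min = 0,
                       transition_w = 2,
                       icp_baseline = 10,
                       rthb_baseline = 50,
                       seed = 1L,
                       animal_id = "sim01",
                       group = c("arrest", "sham"),
                       temperature = "normothermia") {
  group <- match.arg(group)
  cfg <- list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    abp_start = abp_start, abp_end = abp_end, hold_frac = hold_frac,
    lla_true = lla_true, abpopt_true = abpopt_true,
    plateau_flow = plateau_flow, passive_slope = passive_slope,
    slow_wave_band = slow_wave_band, slow_wave_amp = slow_wave_amp,
    n_components = n_components, env_depth = env_depth,
    env_period_s = env_period_s, noise_sd = noise_sd,
    drift_sd = drift_sd, drift_band = drift_band,
    artifact_rate_per_h = artifact_rate_per_h,
    artifact_dur_s = artifact_dur_s, artifact_scale = artifact_scale,
    phase_disp_exp = phase_disp_exp,
    reactivity_gain = reactivity_gain, icp_gain = icp_gain,
    rso2_gain = rso2_gain, leak_max = leak_max, leak_min = leak_min,
    activity_sd = activity_sd, flow_activity_sd = flow_activity_sd,
    react_base = react_base, react_min = react_min,
    flow_base = flow_base, flow_min = flow_min,
    transition_w = transition_w,
    icp_baseline = icp_baseline, rthb_baseline = rthb_baseline,
    seed = as.integer(seed), animal_id = animal_id, group = group,
    temperature = temperature
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$sample_rate_hz > 0)
  if (!(cfg$abp_end < cfg$lla_true && cfg$lla_true < cfg$abp_start))
    stop("configuration error: need abp_end < lla_true < abp_start",
         call. = FALSE)
  band <- cfg$slow_wave_band
  if (!(length(band) == 2 && band[1] > 0 && band[1] < band[2]))
    stop("configuration error: malformed slow_wave_band", call. = FALSE)
  # slow waves are synthesized on the 1-Hz generation grid
  if (band[2] > 0.5)
    stop("configuration error: slow_wave_band above the 1-Hz generation Nyquist",
         call. = FALSE)
  if (any(cfg$noise_sd < 0))
    stop("configuration error: noise_sd must be non-negative", call. = FALSE)
  if (cfg$abpopt_true <= cfg$lla_true)
    stop("configuration error: abpopt_true must exceed lla_true", call. = FALSE)
  invisible(cfg)
}

#' Lassen autoregulation curve
#'
#' Static pressure-flow relationship of an autoregulating cerebral
#' circulation: flow is held at `plateau` for ABP at or above the lower limit
#' `lla`, and falls pressure-passively with slope `passive_slope` below it
#' (floored at zero). Continuous at `abp = lla`.
#'
#' @param abp arterial blood pressure (mmHg), vectorized.
#' @param lla lower limit of autoregulation (mmHg), positive.
#' @param plateau plateau flow (a.u.), positive.
#' @param passive_slope flow loss per mmHg below the LLA (a.u./mmHg).
#' @return flow (a.u.), same length as `abp`.
#' @examples
#' lassen_flow(c(60, 45, 35), lla = 45, plateau = 100, passive_slope = 2)
#' @export
lassen_flow <- function(abp, lla, plateau, passive_slope) {
  if (!is.finite(lla) || lla <= 0 || !is.finite(plateau) || plateau <= 0)
    stop("configuration error: lla and plateau must be positive", call. = FALSE)
  pmax(0, ifelse(abp >= lla, plateau, plateau - passive_slope * (lla - abp)))
}

# Logistic passive->active transition at the LLA: ~0 below, ~1 above.
.active_fraction <- function(abp, lla, w) stats::plogis((abp - lla) / w)

# Vasoreactivity strength in (0, 1], peaking at abpopt.
.activity <- function(abp, abpopt, sd) exp(-(abp - abpopt)^2 / (2 * sd^2))

# Reactivity profile (cosine of planted lag) for volume-coupled channels
# (rTHb, ICP): +1 pressure-passive below the LLA; above it, interpolates
# from react_base (far from the optimum) down to react_min at abpopt.
.reactivity_profile <- function(abp, cfg) {
  s <- .active_fraction(abp, cfg$lla_true, cfg$transition_w)
  a <- .activity(abp, cfg$abpopt_true, cfg$activity_sd)
  1 - s * ((1 - cfg$react_base) + (cfg$react_base - cfg$react_min) * a)
}

# Residual pressure-passivity of flow: 1 below the LLA, minimum leak_min at
# abpopt (autoregulation is never perfect), at most leak_max above the LLA.
.passivity_profile <- function(abp, cfg) {
  s <- .active_fraction(abp, cfg$lla_true, cfg$transition_w)
  a <- .activity(abp, cfg$abpopt_true, cfg$flow_activity_sd)
  (1 - s) + s * (cfg$leak_min + (cfg$leak_max - cfg$leak_min) * (1 - a))
}

# Cosine of the ABP->flow phase lag: 1 (in phase) below the LLA; above it,
# interpolates from flow_base down to flow_min (quarter-cycle) at abpopt.
.flow_phase_profile <- function(abp, cfg) {
  s <- .active_fraction(abp, cfg$lla_true, cfg$transition_w)
  a <- .activity(abp, cfg$abpopt_true, cfg$flow_activity_sd)
  1 - s * ((1 - cfg$flow_base) + (cfg$flow_base - cfg$flow_min) * a)
}

#' Generate a synthetic piglet recording with known ground truth
#'
#' Synthesizes the five monitored channels on a 1-Hz grid (then sample-held to
#' `sample_rate_hz`) under the model described in [sim_config()], and returns
#' both the raw recording and the simulator's ground truth (true LLA, true
#' optimal ABP, time of LLA crossing, per-epoch regime labels).
#'
#' Slow waves are a sum of `n_components` sinusoids with log-spaced
#' frequencies inside `slow_wave_band` and uniform random phases, scaled so
#' the component SD equals `slow_wave_amp`. All randomness is governed by
#' `cfg$seed`: the same seed reproduces the recording bit for bit.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with elements `recording` (class `raw_recording`: a list of
#'   channel vectors `abp`, `icp`, `rso2`, `rthb`, `ldf`, plus `time_s`,
#'   `sample_rate_hz` and metadata) and `truth` (class `ground_truth`).
#' @export
generate_recording <- function(cfg) {
  validate_sim_config(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  t1 <- seq(0, cfg$duration_s - 1)            # 1-Hz generation grid
  n <- length(t1)

  hold_s <- cfg$hold_frac * cfg$duration_s
  ramp <- ifelse(
    t1 < hold_s, cfg$abp_start,
    cfg$abp_start + (cfg$abp_end - cfg$abp_start) *
      (t1 - hold_s) / (cfg$duration_s - hold_s)
  )

  comp <- .slow_components(n, band = cfg$slow_wave_band,
                           amp = cfg$slow_wave_amp, k = cfg$n_components)
  env <- rep(1, n)
  if (cfg$env_depth > 0) {
    ph <- stats::runif(length(cfg$env_period_s), 0, 2 * pi)
    e <- colSums(sin(outer(2 * pi / cfg$env_period_s, t1) + ph)) *
      sqrt(2 / length(cfg$env_period_s))
    env <- pmax(0.15, 1 + cfg$env_depth * e)
  }
  slow <- comp$s_sum * env

  abp_clean <- ramp + slow
  cvr <- .reactivity_profile(abp_clean, cfg)    # volume-channel cos-profile
  pas <- .passivity_profile(abp_clean, cfg)     # flow-wave amplitude
  cfl <- .flow_phase_profile(abp_clean, cfg)    # flow-channel cos-profile

  # phase-lagged copy of the slow waves: component k of a channel with
  # cos-profile cp is delayed by acos(cp) * d_k, d_k = (f_ref/f_k)^disp
  f_ref <- exp(mean(log(cfg$slow_wave_band)))
  d_k <- (f_ref / comp$f)^cfg$phase_disp_exp
  lagged <- function(cp) {
    phi <- acos(pmin(1, pmax(-1, cp)))
    out <- numeric(n)
    for (k in seq_along(comp$f)) {
      pk <- phi * d_k[k]
      out <- out + comp$a * (cos(pk) * comp$sin_th[k, ] -
                               sin(pk) * comp$cos_th[k, ])
    }
    out * env
  }

  # broadband artifact bursts, shared across channels (amplitude per channel)
  burst_gain <- numeric(n)
  if (cfg$artifact_rate_per_h > 0) {
    nb <- stats::rpois(1, cfg$artifact_rate_per_h * cfg$duration_s / 3600)
    if (nb > 0) {
      t0 <- stats::runif(nb, 0, cfg$duration_s)
      dur <- stats::runif(nb, cfg$artifact_dur_s[1], cfg$artifact_dur_s[2])
      for (b in seq_len(nb)) {
        idx <- which(t1 >= t0[b] & t1 < t0[b] + dur[b])
        burst_gain[idx] <- cfg$artifact_scale - 1
      }
    }
  }
  nz <- function(ch) if (cfg$noise_sd[[ch]] > 0)
    stats::rnorm(n, 0, cfg$noise_sd[[ch]]) * (1 + burst_gain) else numeric(n)
  # smooth sub-band drift, independent per channel
  drift <- function(ch) {
    sdd <- cfg$drift_sd[[ch]]
    if (sdd <= 0) return(numeric(n))
    f <- exp(seq(log(cfg$drift_band[1]), log(cfg$drift_band[2]),
                 length.out = 6))
    ph <- stats::runif(6, 0, 2 * pi)
    colSums(sdd * sqrt(2 / 6) * sin(outer(2 * pi * f, t1) + ph))
  }

  ldf_clean <- lassen_flow(ramp, cfg$lla_true, cfg$plateau_flow,
                           cfg$passive_slope) +
    cfg$passive_slope * pas * lagged(cfl)
  ldf <- ldf_clean + drift("ldf") + nz("ldf")
  abp <- abp_clean + drift("abp") + nz("abp")
  icp <- cfg$icp_baseline + cfg$icp_gain * lagged(cvr) + drift("icp") +
    nz("icp")
  rthb <- cfg$rthb_baseline + cfg$reactivity_gain * lagged(cvr) +
    drift("rthb") + nz("rthb")
  rso2 <- pmin(100, pmax(0, 50 + cfg$rso2_gain *
                           (ldf_clean - cfg$plateau_flow) / cfg$plateau_flow +
                           drift("rso2") + nz("rso2")))

  hold <- max(1L, as.integer(round(cfg$sample_rate_hz)))
  up <- function(x) if (hold == 1L) x else rep(x, each = hold)
  time_s <- if (hold == 1L) t1 else seq(0, cfg$duration_s - 1 / hold, by = 1 / hold)

  rec <- structure(list(
    time_s = time_s,
    abp = up(abp), icp = up(icp), rso2 = up(rso2),
    rthb = up(rthb), ldf = up(ldf),
    sample_rate_hz = hold, animal_id = cfg$animal_id,
    group = cfg$group, temperature = cfg$temperature
  ), class = "raw_recording")

  # regime labels from the clean 10-s mean ABP (ground truth, noise-free)
  epoch_abp <- block_means(abp_clean, 10L)
  crossing <- which(ramp < cfg$lla_true)[1]
  truth <- structure(list(
    lla_true = cfg$lla_true,
    abpopt_true = cfg$abpopt_true,
    time_of_lla_crossing = if (is.na(crossing)) NA_real_ else t1[crossing],
    regime = ifelse(epoch_abp >= cfg$lla_true, "above", "below"),
    epoch_time_s = seq_along(epoch_abp) * 10
  ), class = "ground_truth")

  list(recording = rec, truth = truth)
}

#' Band-limited vasogenic slow waves
#'
#' Sum of `k` sinusoids with log-spaced frequencies inside `band` and uniform
#' random phases, scaled to standard deviation `amp`. Uses the current RNG
#' stream (callers control the seed).
#'
#' @param n number of 1-Hz samples.
#' @param band frequency band (Hz pair).
#' @param amp target standard deviation of the summed component.
#' @param k number of sinusoids.
#' @return numeric vector of length `n`.
#' @export
slow_waves <- function(n, band = c(0.007, 0.05), amp = 3, k = 8) {
  .slow_components(n, band, amp, k)$s_sum
}

# Slow-wave components with their quadrature parts, sharing one draw of
# random phases so phase-lagged couplings are exact per component.
.slow_components <- function(n, band = c(0.007, 0.05), amp = 3, k = 8) {
  t1 <- seq_len(n) - 1
  if (amp == 0) {
    z <- matrix(0, 1, n)
    return(list(f = exp(mean(log(band))), a = 0, sin_th = z, cos_th = z,
                s_sum = numeric(n)))
  }
  f <- exp(seq(log(band[1]), log(band[2]), length.out = k))
  ph <- stats::runif(k, 0, 2 * pi)
  # each sinusoid has variance a^2/2; k of them sum to amp^2
  a <- amp * sqrt(2 / k)
  theta <- outer(2 * pi * f, t1) + ph
  list(f = f, a = a, sin_th = sin(theta), cos_th = cos(theta),
       s_sum = colSums(a * sin(theta)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a raw recording to CSV
#'
#' Columns: `time_s, abp_mmhg, icp_mmhg, rso2_pct, rthb_au, ldf_au`.
#'
#' @param rec a `raw_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(time_s = rec$time_s, abp_mmhg = rec$abp,
                   icp_mmhg = rec$icp, rso2_pct = rec$rso2,
                   rthb_au = rec$rthb, ldf_au = rec$ldf)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw recording from CSV
#'
#' Expects the schema written by [write_recording_csv()]; missing values may
#' be blank or NaN. The sample rate is inferred from the time column.
#'
#' @param path CSV file path.
#' @param animal_id,group,temperature metadata to attach.
#' @return a `raw_recording`.
#' @export
read_recording_csv <- function(path, animal_id = basename(path),
                               group = "arrest", temperature = "normothermia") {
  df <- utils::read.csv(path)
  need <- c("time_s", "abp_mmhg", "icp_mmhg", "rso2_pct", "rthb_au", "ldf_au")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cn in need) if (!is.numeric(df[[cn]]))
    stop("schema error: non-numeric column ", cn, call. = FALSE)
  dt <- stats::median(diff(df$time_s))
  structure(list(
    time_s = df$time_s, abp = df$abp_mmhg, icp = df$icp_mmhg,
    rso2 = df$rso2_pct, rthb = df$rthb_au, ldf = df$ldf_au,
    sample_rate_hz = 1 / dt, animal_id = animal_id, group = group,
    temperature = temperature
  ), class = "raw_recording")
}

#' Write simulator ground truth to JSON
#' @param truth a `ground_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
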