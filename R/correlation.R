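#' Pearson product-moment correlation with missing-safe semantics
#'
#' Thin wrapper around the textbook product-moment formula with the policy
#' the moving indices need: pairs with a missing member are dropped, and a
#' window whose remaining vectors are constant (zero variance) yields NA
#' rather than an error.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum complete pairs required (default 3).
#' @return correlation in [-1, 1], or NA.
#' @export
pearson_r <- function(x, y, min_n = 3L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- stats::cov(x, y) / (sx * sy)
  min(1, max(-1, r))
}

#' Moving-correlation autoregulation index
#'
#' Computes a correlation index (PRx, COx, HVx) as the moving Pearson
#' correlation between two 10-s-mean channels over trailing windows of
#' `window_n` epochs (default 30 epochs = 300 s), advancing one epoch
#' (10 s) per step. A window with more than `max_missing_frac` missing
#' epochs — or one left with zero variance — yields a missing value.
#'
#' @param sw a `slow_waves_df` from [block_average()].
#' @param ch_x,ch_y channel names (columns of `sw`), e.g. `"abp"`, `"icp"`.
#' @param window_n epochs per window.
#' @param max_missing_frac maximum tolerated fraction of missing epochs.
#' @param name index label stored on the result.
#' @return An `index_series`: data.frame with `time_s` (window-end epoch
#'   times) and `value` in [-1, 1] or NA; the label is in `attr(, "index")`.
#' @export
moving_index <- function(sw, ch_x, ch_y, window_n = 30L,
                         max_missing_frac = 0.25, name = NULL) {
  for (ch in c(ch_x, ch_y)) if (is.null(sw[[ch]]))
    stop("input error: channel '", ch, "' not present", call. = FALSE)
  x <- sw[[ch_x]]; y <- sw[[ch_y]]
  n <- length(x)
  window_n <- as.integer(window_n)
  if (n < window_n)
    stop("input error: fewer epochs than one window", call. = FALSE)
  max_miss <- floor(max_missing_frac * window_n)
  starts <- seq_len(n - window_n + 1L)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + window_n - 1L)
    xm <- x[idx]; ym <- y[idx]
    if (sum(!(is.finite(xm) & is.finite(ym))) > max_miss) return(NA_real_)
    pearson_r(xm, ym)
  }, numeric(1))
  out <- data.frame(time_s = sw$time_s[starts + window_n - 1L], value = vals)
  attr(out, "index") <- name %||% paste0("r_", ch_x, "_", ch_y)
  class(out) <- c("index_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute all six autoregulation indices of a recording
#'
#' PRx/COx/HVx as moving correlations (ABP vs ICP / rSO2 / rTHb) and
#' wPRx/wCOx/wHVx as coherence-gated wavelet semblance of the same channel
#' pairs.
#'
#' @param sw a `slow_waves_df`.
#' @param wconfig a [wavelet_config()] for the semblance indices.
#' @param window_n correlation window length in epochs.
#' @return named list of six `index_series`
#'   (`PRx`, `COx`, `HVx`, `wPRx`, `wCOx`, `wHVx`).
#' @export
all_indices <- function(sw, wconfig = wavelet_config(), window_n = 30L) {
  pairs <- list(PRx = "icp", COx = "rso2", HVx = "rthb")
  out <- list()
  for (nm in names(pairs))
    out[[nm]] <- moving_index(sw, "abp", pairs[[nm]], window_n, name = nm)
  for (nm in names(pairs))
    out[[paste0("w", nm)]] <-
      semblance_index(sw, "abp", pairs[[nm]], wconfig,
                      name = paste0("w", nm))
  out
}

#' Write an index series to CSV
#' @param ix an `index_series`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(ix, path) {
  df <- as.data.frame(ix)
  names(df)[2] <- attr(ix, "index") %||% "value"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
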