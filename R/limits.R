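#' Lower limit of autoregulation by two-segment piecewise regression
#'
#' Dichotomizes the (ABP, LDF) 10-s-mean pairs at every candidate breakpoint
#' on a 1-mmHg grid across the observed ABP range (at least `min_pts` points
#' per side), fits ordinary least-squares lines to each side, and keeps the
#' split with the lowest combined squared error. The LLA is the x-coordinate
#' of the intersection of the two fitted lines. Pairs are ABP-sorted; ties in
#' combined SSE break toward the lower-ABP breakpoint.
#'
#' @param sw a `slow_waves_df` with `abp` and `ldf` columns (or any
#'   data.frame with those columns).
#' @param grid_mmhg candidate-breakpoint spacing (mmHg).
#' @param min_pts minimum points per segment.
#' @param min_span_mmhg minimum observed ABP span required.
#' @return An `lla_estimate`: list with `lla` (mmHg), `breakpoint` (the
#'   winning split), `left`/`right` (slope, intercept, n), `sse`, `n`.
#' @export
find_lla <- function(sw, grid_mmhg = 1, min_pts = 3L, min_span_mmhg = 15) {
  ok <- is.finite(sw$abp) & is.finite(sw$ldf)
  abp <- sw$abp[ok]; ldf <- sw$ldf[ok]
  if (length(abp) < 20L)
    stop("no-LLA error: fewer than 20 valid epochs", call. = FALSE)
  if (diff(range(abp)) < min_span_mmhg)
    stop("no-LLA error: ABP span below ", min_span_mmhg, " mmHg",
         call. = FALSE)
  o <- order(abp)
  x <- abp[o]; y <- ldf[o]
  n <- length(x)

  # prefix sums give O(1) OLS statistics for any split
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x * x)
  cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg_stats <- function(i1, i2) {
    m <- i2 - i1 + 1
    sx <- cx[i2] - ifelse(i1 > 1, cx[i1 - 1], 0)
    sy <- cy[i2] - ifelse(i1 > 1, cy[i1 - 1], 0)
    sxx <- cxx[i2] - ifelse(i1 > 1, cxx[i1 - 1], 0)
    sxy <- cxy[i2] - ifelse(i1 > 1, cxy[i1 - 1], 0)
    syy <- cyy[i2] - ifelse(i1 > 1, cyy[i1 - 1], 0)
    vxx <- sxx - sx^2 / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy^2 / m
    slope <- if (vxx > 0) vxy / vxx else 0
    intercept <- (sy - slope * sx) / m
    sse <- max(0, vyy - if (vxx > 0) vxy^2 / vxx else 0)
    list(slope = slope, intercept = intercept, sse = sse, n = m)
  }

  cand <- seq(ceiling(min(x) / grid_mmhg) * grid_mmhg,
              floor(max(x) / grid_mmhg) * grid_mmhg, by = grid_mmhg)
  best <- NULL
  for (cpt in cand) {
    nl <- findInterval(cpt - 1e-12, x)       # points with abp < cpt
    if (nl < min_pts || n - nl < min_pts) next
    left <- seg_stats(1L, nl)
    right <- seg_stats(nl + 1L, n)
    sse <- left$sse + right$sse
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(breakpoint = cpt, left = left, right = right, sse = sse)
    }
  }
  if (is.null(best))
    stop("no-LLA error: no admissible breakpoint", call. = FALSE)

  dslope <- best$left$slope - best$right$slope
  scale <- max(abs(c(best$left$slope, best$right$slope, 1)))
  if (abs(dslope) < 1e-8 * scale)
    stop("degenerate-intersection error: fitted segments are parallel",
         call. = FALSE)
  lla <- (best$right$intercept - best$left$intercept) / dslope

  structure(list(lla = lla, breakpoint = best$breakpoint,
                 left = best$left, right = best$right,
                 sse = best$sse, n = n),
            class = "lla_estimate")
}

#' Median-ABP / mean-index samples over 5-minute windows
#'
#' Pairs each non-overlapping 5-minute window's median ABP with the mean of
#' the index's valid values in that window. Windows are formed over the rows
#' of `sw` in time order; rows can be pre-filtered (e.g. to the above-LLA
#' period) before calling.
#'
#' @param sw a `slow_waves_df` (or filtered subset) with an `abp` column.
#' @param index an `index_series` aligned on `time_s`, or NULL for
#'   ABP-medians only.
#' @param window_s window length in seconds (default 300).
#' @return data.frame with one row per complete window: `abp_median`,
#'   `index_mean` (NA when no valid index value), `n_index`.
#' @export
median_abp_epochs <- function(sw, index = NULL, window_s = 300) {
  eps <- attr(sw, "epoch_s") %||% 10
  per <- as.integer(round(window_s / eps))
  n <- nrow(sw)
  nw <- n %/% per
  if (nw == 0L)
    return(data.frame(abp_median = numeric(0), index_mean = numeric(0),
                      n_index = integer(0)))
  iv <- if (is.null(index)) rep(NA_real_, n) else
    index$value[match(sw$time_s, index$time_s)]
  out <- lapply(seq_len(nw), function(w) {
    idx <- ((w - 1L) * per + 1L):(w * per)
    vals <- iv[idx]
    vals <- vals[is.finite(vals)]
    data.frame(abp_median = stats::median(sw$abp[idx], na.rm = TRUE),
               index_mean = if (length(vals)) mean(vals) else NA_real_,
               n_index = length(vals))
  })
  do.call(rbind, out)
}

#' Bin Fisher-transformed index samples into 5-mmHg ABP bins
#'
#' Sorts (median ABP, mean index) samples into half-open 5-mmHg bins spanning
#' 20-100 mmHg, Fisher-transforms the index values (clipped to |r| <= 0.99 to
#' keep atanh finite), and returns per-bin mean, standard error, and count.
#' Samples outside the ABP range, or without an index value, are discarded.
#'
#' @param samples data.frame from [median_abp_epochs()].
#' @param bin_width bin width in mmHg.
#' @param range ABP limits (mmHg) for the binning.
#' @param clip Fisher-transform clipping bound on |r|.
#' @return A `binned_index_curve`: data.frame with `bin_lo`, `bin_hi`,
#'   `bin_center`, `mean_z`, `sem_z`, `n` for occupied bins.
#' @export
bin_index_curve <- function(samples, bin_width = 5, range = c(20, 100),
                            clip = 0.99) {
  ok <- is.finite(samples$abp_median) & is.finite(samples$index_mean) &
    samples$abp_median >= range[1] & samples$abp_median < range[2]
  s <- samples[ok, , drop = FALSE]
  edges <- seq(range[1], range[2], by = bin_width)
  z <- atanh(pmin(clip, pmax(-clip, s$index_mean)))
  bin <- findInterval(s$abp_median, edges, rightmost.closed = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    zi <- z[bin == b]
    data.frame(bin_lo = edges[b], bin_hi = edges[b] + bin_width,
               bin_center = edges[b] + bin_width / 2,
               mean_z = mean(zi),
               sem_z = if (length(zi) > 1) stats::sd(zi) / sqrt(length(zi))
                       else NA_real_,
               n = length(zi))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
               bin_center = numeric(0), mean_z = numeric(0),
               sem_z = numeric(0), n = integer(0))
  class(out) <- c("binned_index_curve", "data.frame")
  out
}

#' Quadratic U-curve fit of a binned index curve
#'
#' Least-squares quadratic through the occupied bins' (centre, mean z)
#' points, weighted by bin count. The curve-fit error is the square root of
#' the mean squared difference between the bin means and the fitted values
#' (unweighted over occupied bins). Shape classes: `full_u` when curvature is
#' positive and the vertex lies strictly inside the occupied span; `half_u`
#' when curvature is positive but the vertex sits at or beyond the span edge
#' (reported vertex clamped to the span); `none` otherwise.
#'
#' @param curve a `binned_index_curve` with >= 4 occupied bins.
#' @return list with `vertex` (mmHg or NA), `fit_error` (z units), `shape`
#'   (`"full_u"`, `"half_u"`, `"none"`), and coefficients `a`, `b`, `c`.
#' @export
fit_u_vertex <- function(curve) {
  if (nrow(curve) < 4L)
    stop("no-fit: fewer than 4 occupied bins", call. = FALSE)
  x <- curve$bin_center; z <- curve$mean_z; w <- curve$n
  X <- cbind(1, x, x^2)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% z)
  a <- beta[3]; b <- beta[2]; c0 <- beta[1]
  fitted <- drop(X %*% beta)
  fit_error <- sqrt(mean((z - fitted)^2))

  span <- range(x)
  curv_tol <- 1e-10 * max(1, max(abs(z)))
  if (a > curv_tol) {
    v <- -b / (2 * a)
    if (v > span[1] && v < span[2]) {
      shape <- "full_u"; vertex <- v
    } else {
      shape <- "half_u"; vertex <- min(max(v, span[1]), span[2])
    }
  } else {
    shape <- "none"; vertex <- NA_real_
  }
  list(vertex = vertex, fit_error = fit_error, shape = shape,
       a = a, b = b, c = c0)
}

#' Multi-window weighted optimal ABP
#'
#' Identifies the recording's optimal ABP (ABPopt) for one index: the index's
#' 5-minute (median ABP, mean value) samples over the above-LLA period are
#' taken over twelve nested windows of nominal length 2-4 h (uniformly
#' spaced, each the most recent such span of above-LLA data); each window's
#' samples are binned ([bin_index_curve()]) and fitted ([fit_u_vertex()]),
#' and the final ABPopt is the weighted average of the windows' vertices with
#' weight `w_len * w_err * w_shape`:
#' \itemize{
#'   \item `w_len`: 1.0 for a 2-h window falling linearly to 0.5 at 4 h
#'     (shorter, more recent windows count more);
#'   \item `w_err`: `1 / (1 + fit_error)` (better fits count more);
#'   \item `w_shape`: 1 for a full U, 0.5 for a half U, 0 for no U.
#' }
#'
#' @param index an `index_series`.
#' @param sw the recording's `slow_waves_df` (for concurrent ABP).
#' @param lla the LLA (mmHg) — an `lla_estimate` or a number; only epochs
#'   with ABP above it enter the calculation.
#' @param n_windows number of window lengths.
#' @param window_range_h nominal window lengths (hours, min and max).
#' @param bin_width,range passed to [bin_index_curve()].
#' @param min_h minimum hours of above-LLA data required.
#' @return An `abpopt_estimate`: list with `abpopt` (mmHg or NA), `windows`
#'   (per-window data.frame: nominal hours, samples used, vertex, fit_error,
#'   shape, weight), and `n_samples`.
#' @export
multiwindow_abpopt <- function(index, sw, lla, n_windows = 12L,
                               window_range_h = c(2, 4),
                               bin_width = 5, range = c(20, 100),
                               min_h = 2) {
  lla_v <- if (inherits(lla, "lla_estimate")) lla$lla else as.numeric(lla)
  above <- sw[is.finite(sw$abp) & sw$abp > lla_v, , drop = FALSE]
  attr(above, "epoch_s") <- attr(sw, "epoch_s") %||% 10
  samples <- median_abp_epochs(above, index)
  samples <- samples[is.finite(samples$index_mean), , drop = FALSE]
  per_h <- 12L                                  # 5-min samples per hour
  if (nrow(samples) < min_h * per_h)
    return(structure(list(abpopt = NA_real_, windows = NULL,
                          n_samples = nrow(samples)),
                     class = "abpopt_estimate"))

  lens <- seq(window_range_h[1], window_range_h[2], length.out = n_windows)
  recs <- lapply(lens, function(L) {
    take <- min(nrow(samples), as.integer(round(L * per_h)))
    s <- samples[(nrow(samples) - take + 1L):nrow(samples), , drop = FALSE]
    curve <- bin_index_curve(s, bin_width = bin_width, range = range)
    if (nrow(curve) < 4L)
      return(data.frame(hours = L, n_samples = take, vertex = NA_real_,
                        fit_error = NA_real_, shape = "none", weight = 0))
    fit <- fit_u_vertex(curve)
    w_len <- 1 - 0.25 * (L - window_range_h[1])
    w_err <- 1 / (1 + fit$fit_error)
    w_shape <- switch(fit$shape, full_u = 1, half_u = 0.5, none = 0)
    data.frame(hours = L, n_samples = take,
               vertex = ifelse(is.na(fit$vertex), NA_real_, fit$vertex),
               fit_error = fit$fit_error, shape = fit$shape,
               weight = w_len * w_err * w_shape)
  })
  wdf <- do.call(rbind, recs)
  use <- is.finite(wdf$vertex) & wdf$weight > 0
  abpopt <- if (any(use)) sum(wdf$weight[use] * wdf$vertex[use]) /
    sum(wdf$weight[use]) else NA_real_
  structure(list(abpopt = abpopt, windows = wdf, n_samples = nrow(samples)),
            class = "abpopt_estimate")
}
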