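#' Block means of a sampled signal
#'
#' Means of consecutive non-overlapping blocks of `block` samples; a trailing
#' partial block is discarded. Any non-finite sample marks its whole block as
#' missing (NA).
#'
#' @param x numeric vector.
#' @param block samples per block (positive integer).
#' @return numeric vector of `floor(length(x)/block)` block means.
#' @export
block_means <- function(x, block) {
  block <- as.integer(block)
  stopifnot(block >= 1L)
  nb <- length(x) %/% block
  if (nb == 0L)
    stop("empty-series error: input shorter than one block", call. = FALSE)
  m <- matrix(x[seq_len(nb * block)], nrow = block)
  out <- colMeans(m)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Reduce a raw recording to 10-second slow-wave means
#'
#' Averages every channel in consecutive, non-overlapping blocks of
#' `block_s` seconds, removing pulse and respiratory waveforms and leaving the
#' slow vasogenic oscillations that carry the autoregulation signal. Blocks
#' containing invalid (non-finite) samples become missing epochs.
#'
#' @param rec a `raw_recording` (see [generate_recording()],
#'   [read_recording_csv()]).
#' @param block_s block length in seconds (default 10).
#' @return A `slow_waves_df`: a data.frame with `time_s` (epoch end times,
#'   `block_s` apart) and one column per channel (`abp`, `icp`, `rso2`,
#'   `rthb`, `ldf`), NA where a block contained invalid samples. The epoch
#'   spacing is stored in `attr(, "epoch_s")`.
#' @export
block_average <- function(rec, block_s = 10) {
  block <- as.integer(round(block_s * rec$sample_rate_hz))
  if (block < 1L || length(rec$abp) < block)
    stop("empty-series error: recording shorter than one block", call. = FALSE)
  chans <- c("abp", "icp", "rso2", "rthb", "ldf")
  vals <- lapply(chans, function(ch) block_means(rec[[ch]], block))
  names(vals) <- chans
  nb <- length(vals$abp)
  out <- data.frame(time_s = seq_len(nb) * block_s, vals)
  attr(out, "epoch_s") <- block_s
  class(out) <- c("slow_waves_df", "data.frame")
  out
}

#' Write / read a slow-wave series as CSV
#'
#' @param sw a `slow_waves_df` from [block_average()].
#' @param path file path.
#' @return `path` (writer) or a `slow_waves_df` (reader).
#' @export
write_slow_waves_csv <- function(sw, path) {
  utils::write.csv(as.data.frame(sw), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slow_waves_csv
#' @export
read_slow_waves_csv <- function(path) {
  df <- utils::read.csv(path)
  eps <- stats::median(diff(df$time_s))
  attr(df, "epoch_s") <- eps
  class(df) <- c("slow_waves_df", "data.frame")
  df
}
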