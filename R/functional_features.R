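#' Frequency-domain band-pass filter
#'
#' Retains FFT bins whose absolute frequency lies in `[low, high]` and
#' inverts back to a real-valued series, row-wise. This mirrors the
#' band-limiting applied in resting-state preprocessing.
#'
#' @param ts Matrix (regions x time) or numeric vector.
#' @param low,high Band edges in Hz; `0 <= low < high <=` Nyquist.
#' @param tr Sampling interval in seconds.
#' @return Filtered matrix (or vector) of the same shape.
#' @export
bandpass_filter <- function(ts, low, high, tr) {
  vec <- is.null(dim(ts))
  ts <- rbind(ts)
  nyq <- 1 / (2 * tr)
  if (low < 0 || high <= low || high > nyq + 1e-12)
    stop(sprintf("band must satisfy 0 <= low < high <= Nyquist (%.4g Hz)",
                 nyq))
  tp <- ncol(ts)
  f <- seq(0, tp - 1) / (tp * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f >= low & f <= high
  out <- t(apply(ts, 1, function(x) {
    xf <- stats::fft(x)
    xf[!keep] <- 0
    Re(stats::fft(xf, inverse = TRUE)) / tp
  }))
  if (vec) drop(out) else out
}

#' Seed-based connectivity map
#'
#' Correlates every non-seed region's time course with the mean time
#' course over the (bilateral) seed regions and converts to a
#' standardized Fisher z, \eqn{z = \mathrm{atanh}(r)\sqrt{T-3}}, so a
#' conventional threshold of 2.3 has its usual one-sided normal
#' interpretation. Correlations are clipped to \eqn{\pm(1 - 10^{-12})}
#' before `atanh` so degenerate (perfectly correlated) simulations stay
#' finite.
#'
#' @param ts Matrix, regions x time.
#' @param seed_idx Non-empty integer vector of seed region indices; these
#'   rows form the reference and are excluded from the output.
#' @return Named numeric vector of z-values over non-seed regions.
#' @export
seed_connectivity_map <- function(ts, seed_idx) {
  ts <- as.matrix(ts)
  if (length(seed_idx) < 1) stop("seed set must be non-empty")
  ref <- colMeans(ts[seed_idx, , drop = FALSE])
  if (stats::sd(ref) == 0) stop("seed reference time course is constant")
  rest <- setdiff(seq_len(nrow(ts)), seed_idx)
  r <- drop(stats::cor(t(ts[rest, , drop = FALSE]), ref))
  r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
  z <- atanh(r) * sqrt(ncol(ts) - 3)
  names(z) <- rownames(ts)[rest]
  z
}

#' Summarize a connectivity z-map into (N, Z)
#'
#' The two per-seed features: `N`, the number of regions whose z-value
#' strictly exceeds the threshold (positive tail only; anti-correlations
#' are not counted), and `Z`, the mean z over those suprathreshold
#' regions. When nothing survives, `Z` is recorded as 0 and flagged.
#'
#' @param zmap Numeric vector of z-values.
#' @param z_threshold Positive threshold (default 2.3).
#' @param seed_name Label carried along.
#' @return A `seed_summary`: list with `seed_name`, `n_suprathreshold`,
#'   `mean_z`, `z_threshold`, `empty` (flag).
#' @export
summarize_seed_map <- function(zmap, z_threshold = 2.3,
                               seed_name = "seed") {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  above <- zmap > z_threshold
  n <- sum(above)
  structure(list(seed_name = seed_name, n_suprathreshold = n,
                 mean_z = if (n > 0) mean(zmap[above]) else 0,
                 z_threshold = z_threshold, empty = n == 0),
            class = "seed_summary")
}

#' Homotopic (mirrored) connectivity summary
#'
#' Correlates each left/right homotopic ROI pair's time courses, converts
#' to standardized Fisher z, and summarizes like a seed map: `N` pairs
#' exceed the threshold, `Z` is their mean z. The region-level analogue of
#' voxel-mirrored homotopic connectivity.
#'
#' @param ts Matrix, regions x time.
#' @param pairs Two-column index matrix of homotopic pairs.
#' @param z_threshold Positive threshold (default 2.3).
#' @return A `seed_summary` with `seed_name = "vmhc"` plus the per-pair
#'   z-vector as attribute `z`.
#' @export
vmhc <- function(ts, pairs, z_threshold = 2.3) {
  ts <- as.matrix(ts)
  pairs <- rbind(pairs)
  if (nrow(pairs) < 1) stop("pairs must be non-empty")
  z <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- ts[pairs[i, 1], ]
    b <- ts[pairs[i, 2], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("constant member in homotopic pair ", i)
    r <- stats::cor(a, b)
    r <- min(1 - 1e-12, max(-1 + 1e-12, r))
    atanh(r) * sqrt(ncol(ts) - 3)
  }, numeric(1))
  out <- summarize_seed_map(z, z_threshold, seed_name = "vmhc")
  attr(out, "z") <- z
  out
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Per region: the sum of FFT amplitudes over positive-frequency bins in
#' `[band_low, band_high]` divided by the sum over all positive-frequency
#' bins, computed on the demeaned series. Values lie in \[0, 1\]; for a
#' flat (white) spectrum the expectation is the band's share of the
#' positive-frequency axis.
#'
#' @param ts Matrix (regions x time) or vector; at least 8 timepoints.
#' @param band_low,band_high Band in Hz (defaults 0.01 / 0.08).
#' @param tr Sampling interval in seconds.
#' @return A `falff_result`: named numeric vector of per-region values
#'   with the band recorded as attributes.
#' @export
falff <- function(ts, band_low = 0.01, band_high = 0.08, tr = 2) {
  ts <- rbind(ts)
  tp <- ncol(ts)
  if (tp < 8) stop("need at least 8 timepoints")
  nyq <- 1 / (2 * tr)
  if (band_low < 0 || band_high <= band_low || band_high > nyq + 1e-12)
    stop("invalid band")
  kmax <- floor(tp / 2)
  f <- seq_len(kmax) / (tp * tr)
  in_band <- f >= band_low & f <= band_high
  vals <- apply(ts, 1, function(x) {
    amp <- Mod(stats::fft(x - mean(x)))[1 + seq_len(kmax)]
    tot <- sum(amp)
    if (tot == 0) stop("constant series has no spectral amplitude")
    sum(amp[in_band]) / tot
  })
  structure(vals, band_low = band_low, band_high = band_high,
            class = "falff_result")
}

#' Per-subject quantitative functional feature row
#'
#' Computes the functional entries of the canonical feature table for one
#' subject: N and mean Z for the four seed maps, global homotopic N and
#' mean Z, and mean fALFF over the three seed sets.
#'
#' @param ts ROI x time matrix.
#' @param seed_sets Named list of seed ROI index vectors (`caudate`,
#'   `ifg_oper`, `ifg_tri`, `dmn`).
#' @param pairs Homotopic ROI pair index matrix.
#' @param tr Sampling interval (s).
#' @param z_threshold Threshold for N/Z summaries.
#' @return Named numeric vector of 13 functional features.
#' @export
functional_feature_row <- function(ts, seed_sets, pairs, tr = 2,
                                   z_threshold = 2.3) {
  out <- c()
  for (nm in c("caudate", "ifg_oper", "ifg_tri", "dmn")) {
    sm <- summarize_seed_map(seed_connectivity_map(ts, seed_sets[[nm]]),
                             z_threshold, seed_name = nm)
    out[paste0("fc_", nm, "_N")] <- sm$n_suprathreshold
    out[paste0("fc_", nm, "_Z")] <- sm$mean_z
  }
  fa <- falff(ts, tr = tr)
  for (nm in c("caudate", "ifg_oper", "ifg_tri"))
    out[paste0("falff_", nm)] <- mean(fa[seed_sets[[nm]]])
  hv <- vmhc(ts, pairs, z_threshold)
  out["vmhc_N"] <- hv$n_suprathreshold
  out["vmhc_Z"] <- hv$mean_z
  out
}

#' @export
print.seed_summary <- function(x, ...) {
  cat(sprintf("<seed_summary> %s: N = %d, Z = %.3f (threshold %.2f%s)\n",
              x$seed_name, x$n_suprathreshold, x$mean_z, x$z_threshold,
              if (x$empty) ", empty" else ""))
  invisible(x)
}
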