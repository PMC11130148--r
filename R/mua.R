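#' Multielectrode array layout
#'
#' Positions of the recording channels on a regular 2D grid over the superior
#' colliculus surface: 56 channels arranged 7 x 8 at 0.35 mm tip spacing by
#' default. Channels are numbered column-major over the grid (`[ix, iy]`).
#'
#' @param n_x,n_y Grid dimensions (channels = n_x * n_y).
#' @param spacing Tip-to-tip spacing (mm).
#' @param bad_channels Integer indices of channels to be zeroed by
#'   [zero_bad_channels()].
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(n_x = 7, n_y = 8, spacing = 0.35,
                             bad_channels = integer()) {
  stopifnot(n_x >= 2, n_y >= 2, spacing > 0)
  n <- n_x * n_y
  bad_channels <- as.integer(bad_channels)
  if (length(bad_channels) && (any(bad_channels < 1) || any(bad_channels > n)))
    stop("bad_channels out of range 1..", n)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 spacing = spacing, n_channels = n,
                 bad_channels = bad_channels),
            class = "electrode_layout")
}

#' @rdname electrode_layout
#' @param layout An `electrode_layout`.
#' @return `layout_positions`: n_channels x 2 matrix of (x, y) mm, centered.
#' @export
layout_positions <- function(layout) {
  xs <- (seq_len(layout$n_x) - (layout$n_x + 1) / 2) * layout$spacing
  ys <- (seq_len(layout$n_y) - (layout$n_y + 1) / 2) * layout$spacing
  cbind(x = rep(xs, times = layout$n_y), y = rep(ys, each = layout$n_x))
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d x %d = %d channels, %g mm spacing, %d bad\n",
              x$n_x, x$n_y, x$n_channels, x$spacing, length(x$bad_channels)))
  invisible(x)
}

#' Synthetic stimulus-locked recording specification
#'
#' Parameters of the synthetic multichannel recording: active channels
#' receive a band-limited burst (amplitude-modulated Gaussian noise in
#' `burst_band`, Hann envelope of `burst_ms`) starting `latency_ms` after
#' each stimulus onset; every channel carries white noise of `noise_uv` RMS.
#'
#' @param burst_uv Burst envelope peak amplitude (uV, RMS of the carrier at
#'   the envelope peak).
#' @param latency_ms Response latency after stimulus onset (ms).
#' @param burst_band Burst carrier band c(lo, hi) in Hz, within (500, 7000).
#' @param burst_ms Burst duration (ms).
#' @param noise_uv Additive white-noise RMS (uV).
#' @param active_mask Logical vector (one per channel) of responding channels.
#' @param carrier "noise" (band-limited Gaussian noise, the default model of
#'   aggregate spiking) or "tone" (random-phase tone at the band center, whose
#'   rectified envelope is deterministic -- useful for calibration).
#' @param seed Integer RNG seed; generation is bit-reproducible.
#' @return An object of class `synth_ephys_spec`.
#' @export
synth_ephys_spec <- function(burst_uv = 50, latency_ms = 30,
                             burst_band = c(1000, 3000), burst_ms = 60,
                             noise_uv = 5, active_mask = NULL,
                             carrier = c("noise", "tone"), seed = 1L) {
  stopifnot(burst_uv >= 0, latency_ms >= 0, burst_ms > 0, noise_uv >= 0,
            length(burst_band) == 2L, burst_band[1] > 500, burst_band[2] < 7000,
            burst_band[1] < burst_band[2])
  structure(list(burst_uv = burst_uv, latency_ms = latency_ms,
                 burst_band = burst_band, burst_ms = burst_ms,
                 noise_uv = noise_uv, active_mask = active_mask,
                 carrier = match.arg(carrier), seed = as.integer(seed)),
            class = "synth_ephys_spec")
}

#' Synthesize a stimulus-locked multichannel recording
#'
#' @param spec A [synth_ephys_spec()].
#' @param layout An [electrode_layout()].
#' @param n_trials Number of stimulus repetitions (>= 1).
#' @param fs Sampling rate (Hz), default 30 kHz.
#' @param trial_ms Record length per trial (ms).
#' @return Object of class `mua_recording`: `samples` (channels x time, uV),
#'   `fs`, `onsets` (sample indices of stimulus starts), `layout`.
#' @export
synth_mua <- function(spec, layout = electrode_layout(), n_trials = 8,
                      fs = 30000, trial_ms = 400) {
  stopifnot(inherits(spec, "synth_ephys_spec"), n_trials >= 1,
            fs > 2 * 7000)
  mask <- spec$active_mask
  if (is.null(mask)) mask <- rep(TRUE, layout$n_channels)
  if (length(mask) != layout$n_channels)
    stop("active_mask length must equal the channel count (",
         layout$n_channels, ")")
  nt <- round(trial_ms / 1000 * fs)
  total <- nt * n_trials
  onsets <- (seq_len(n_trials) - 1L) * nt + 1L
  old <- .Random.seed_save()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old))
  samples <- matrix(stats::rnorm(layout$n_channels * total, sd = spec$noise_uv),
                    layout$n_channels, total)
  nb <- round(spec$burst_ms / 1000 * fs)
  env <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))  # Hann
  bp <- signal::butter(4, spec$burst_band / (fs / 2), type = "pass")
  lag <- round(spec$latency_ms / 1000 * fs)
  for (tr in seq_len(n_trials)) {
    at <- onsets[tr] + lag
    idx <- at:(at + nb - 1L)
    if (max(idx) > total) stop("burst extends beyond the trial record")
    for (ch in which(mask)) {
      carrier <- if (spec$carrier == "tone") {
        fc <- mean(spec$burst_band)
        sqrt(2) * cos(2 * pi * fc * seq_len(nb) / fs + stats::runif(1, 0, 2 * pi))
      } else {
        x <- signal::filtfilt(bp, stats::rnorm(nb + 600))[301:(300 + nb)]
        x / stats::sd(x)
      }
      samples[ch, idx] <- samples[ch, idx] + spec$burst_uv * env * carrier
    }
  }
  structure(list(samples = samples, fs = fs, onsets = onsets, layout = layout,
                 trial_len = nt),
            class = "mua_recording")
}

#' @export
print.mua_recording <- function(x, ...) {
  cat(sprintf("<mua_recording> %d channels x %d samples @ %g Hz, %d trials\n",
              nrow(x$samples), ncol(x$samples), x$fs, length(x$onsets)))
  invisible(x)
}

#' Multi-unit activity amplitude per channel
#'
#' The MUA extraction chain: zero-phase 500-7000 Hz band-pass, full-wave
#' rectification, zero-phase 10-200 Hz band-pass of the rectified signal,
#' then the maximal peak value within the post-stimulus window, per trial,
#' averaged across trials. Filters are 4th-order Butterworth applied
#' forward-backward.
#'
#' @param recording A `mua_recording`.
#' @param window_ms Post-onset analysis window c(start, end) in ms.
#' @return Matrix channels x trials of amplitudes (uV) with attribute
#'   `mean` = per-channel trial average.
#' @export
mua_amplitude <- function(recording, window_ms = c(0, 200)) {
  stopifnot(inherits(recording, "mua_recording"),
            length(window_ms) == 2L, window_ms[1] >= 0,
            window_ms[2] > window_ms[1])
  fs <- recording$fs
  if (diff(window_ms) < 100)
    warning("window shorter than the 10 Hz settling time; amplitudes may be biased")
  w0 <- round(window_ms / 1000 * fs)
  if (any(recording$onsets + w0[2] > ncol(recording$samples)))
    stop("analysis window extends beyond the record")
  bp1 <- signal::butter(4, c(500, 7000) / (fs / 2), type = "pass")
  # 10-200 Hz band-pass as a high-pass/low-pass cascade: the direct
  # transfer-function band-pass is numerically unstable at this narrow
  # relative band (poles round outside the unit circle)
  lp2 <- signal::butter(4, 200 / (fs / 2), type = "low")
  hp2 <- signal::butter(4, 10 / (fs / 2), type = "high")
  n_ch <- nrow(recording$samples)
  n_tr <- length(recording$onsets)
  out <- matrix(0, n_ch, n_tr)
  for (ch in seq_len(n_ch)) {
    x <- recording$samples[ch, ]
    env <- signal::filtfilt(hp2, signal::filtfilt(lp2, abs(signal::filtfilt(bp1, x))))
    for (tr in seq_len(n_tr)) {
      idx <- (recording$onsets[tr] + w0[1]):(recording$onsets[tr] + w0[2])
      out[ch, tr] <- max(env[idx])
    }
  }
  structure(out, mean = rowMeans(out))
}

#' Zero out manually flagged bad channels
#'
#' @param amplitudes Numeric vector of per-channel amplitudes.
#' @param layout An [electrode_layout()] whose `bad_channels` are zeroed.
#' @return Amplitudes with bad channels set to 0 (idempotent).
#' @export
zero_bad_channels <- function(amplitudes, layout) {
  stopifnot(length(amplitudes) == layout$n_channels)
  if (length(layout$bad_channels)) amplitudes[layout$bad_channels] <- 0
  amplitudes
}

#' Map channel amplitudes to an interpolated activation image
#'
#' Arranges the per-channel amplitudes on the layout grid and applies
#' modified-Akima cubic interpolation separably along each axis at 4x grid
#' refinement (per axis: n nodes -> 4 (n - 1) + 1 samples, nodes included,
#' through which the interpolant passes exactly).
#'
#' @param amplitudes Per-channel amplitude vector (column-major over the grid).
#' @param layout An [electrode_layout()].
#' @param factor Refinement factor (default 4).
#' @return Object of class `activation_map` with `channel_grid` (n_x x n_y),
#'   `image` (refined), `layout`, `factor`.
#' @export
map_sc_response <- function(amplitudes, layout = electrode_layout(), factor = 4) {
  stopifnot(length(amplitudes) == layout$n_channels, all(is.finite(amplitudes)),
            factor >= 1)
  grid <- matrix(amplitudes, layout$n_x, layout$n_y)
  img <- makima_refine_2d(grid, factor)
  structure(list(channel_grid = grid, image = img, layout = layout,
                 factor = factor),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d x %d channels -> %d x %d image, max = %.3g uV\n",
              nrow(x$channel_grid), ncol(x$channel_grid),
              nrow(x$image), ncol(x$image), max(x$image)))
  invisible(x)
}

#' Modified Akima (makima) cubic interpolation
#'
#' Piecewise-cubic Hermite interpolant with the modified Akima slope weights
#' w1 = |d(i+1) - d(i)| + |d(i+1) + d(i)|/2 (and symmetrically w2), which
#' damps the overshoot of plain cubic splines near flat regions while
#' remaining exact at the nodes. `makima_refine_2d` applies it separably
#' (rows, then columns) at integer refinement.
#'
#' @param x Node positions (strictly increasing).
#' @param y Node values.
#' @param xi Query positions.
#' @return Interpolated values at `xi`.
#' @export
makima <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n, all(diff(x) > 0))
  if (n == 2) return(y[1] + (y[2] - y[1]) * (xi - x[1]) / (x[2] - x[1]))
  d <- diff(y) / diff(x)                       # n-1 secant slopes
  dd <- c(2 * d[1] - d[2], d, 2 * d[n - 1] - d[n - 2])
  dd <- c(2 * dd[1] - dd[2], dd, 2 * dd[length(dd)] - dd[length(dd) - 1])
  # dd[i + 2] corresponds to interval i; node i uses intervals i-2..i+1
  s <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- dd[i]; d2 <- dd[i + 1]; d3 <- dd[i + 2]; d4 <- dd[i + 3]
    w1 <- abs(d4 - d3) + abs(d4 + d3) / 2
    w2 <- abs(d2 - d1) + abs(d2 + d1) / 2
    s[i] <- if (w1 + w2 == 0) (d2 + d3) / 2 else (w1 * d2 + w2 * d3) / (w1 + w2)
  }
  iv <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  h <- x[iv + 1L] - x[iv]
  t <- (xi - x[iv]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[iv] + h10 * h * s[iv] + h01 * y[iv + 1L] + h11 * h * s[iv + 1L]
}

# Separable 2D modified-Akima refinement of a node grid.
makima_refine_2d <- function(grid, factor) {
  refine_axis <- function(m) {
    n <- nrow(m)
    xi <- seq(1, n, by = 1 / factor)
    apply(m, 2, function(col) makima(seq_len(n), col, xi))
  }
  t(refine_axis(t(refine_axis(grid))))
}

#' Similarity between an activation map and a target pattern
#'
#' Resamples the target image to the interpolated map's shape (bilinear),
#' min-max normalizes both, and delegates to [pattern_similarity()].
#'
#' @param map An `activation_map`.
#' @param target A [target_pattern()] or a numeric matrix.
#' @return SSIM value.
#' @export
response_similarity <- function(map, target) {
  stopifnot(inherits(map, "activation_map"))
  timg <- if (inherits(target, "target_pattern")) target$image else as.matrix(target)
  res <- bilinear_resize(timg, dim(map$image))
  norm01 <- function(m) {
    rg <- range(m)
    if (diff(rg) == 0) m * 0 else (m - rg[1]) / diff(rg)
  }
  pattern_similarity(norm01(map$image), norm01(res))
}

# Bilinear resize of a matrix to target dims.
bilinear_resize <- function(m, dims) {
  interp_axis <- function(mm, n_out) {
    n <- nrow(mm)
    xi <- seq(1, n, length.out = n_out)
    i0 <- pmin(floor(xi), n - 1L)
    t <- xi - i0
    mm[i0, , drop = FALSE] * (1 - t) + mm[i0 + 1L, , drop = FALSE] * t
  }
  t(interp_axis(t(interp_axis(m, dims[1])), dims[2]))
}
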