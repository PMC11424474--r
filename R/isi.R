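#' Intrinsic-signal recording container
#'
#' A frame stack (height x width x time array of relative reflectance
#' change), the post-binning frame rate and the periodic-stimulus frequency,
#' plus an eye label. The stack must span an integer number of stimulus
#' cycles (to within one frame) so that the single-bin Fourier estimator is
#' unbiased.
#'
#' @param frames numeric array `height x width x n_frames`.
#' @param frame_rate frames per second after temporal binning.
#' @param stim_freq stimulus frequency in Hz (`< frame_rate / 2`).
#' @param eye `"contra"` or `"ipsi"`.
#' @param truth optional list of ground-truth maps carried by the simulator.
#' @return object of class `isi_recording`.
#' @export
isi_recording <- function(frames, frame_rate, stim_freq,
                          eye = c("contra", "ipsi"), truth = NULL) {
  eye <- match.arg(eye)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (stim_freq <= 0 || stim_freq >= frame_rate / 2)
    stop("stim_freq must lie in (0, frame_rate / 2)")
  n <- dim(frames)[3]
  cycles <- n * stim_freq / frame_rate
  if (abs(cycles - round(cycles)) * frame_rate / stim_freq > 1 + 1e-9)
    stop("frame stack does not span an integer number of stimulus cycles ",
         "(within one frame); trim the recording to whole cycles")
  structure(list(frames = frames, frame_rate = frame_rate,
                 stim_freq = stim_freq, eye = eye, truth = truth),
            class = "isi_recording")
}

#' @export
print.isi_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "ISI recording (%s eye): %d x %d px, %d frames @ %.3g Hz, stimulus %.3g Hz (%.1f cycles)\n",
    x$eye, d[1], d[2], d[3], x$frame_rate, x$stim_freq,
    d[3] * x$stim_freq / x$frame_rate))
  invisible(x)
}

#' Simulate a periodic-stimulus intrinsic-signal recording
#'
#' Each pixel's time series is
#' `amp(i,j) * cos(2 pi f t + phase(i,j)) + drift + noise`, where the
#' amplitude map is the configured per-eye response map, the phase advances
#' linearly along the column axis at `phase_gradient` radians per pixel
#' (emulating retinotopy under a sweeping bar), the drift is a linear trend
#' of total excursion `drift_amp` across the recording and the noise is
#' i.i.d. Gaussian per pixel and frame. The stack spans exactly
#' `n_cycles` stimulus cycles. Ground-truth amplitude and phase maps are
#' returned in the `truth` field.
#'
#' @param config an [isi_sim_config()].
#' @param eye which eye's amplitude map to use.
#' @return an [isi_recording()].
#' @export
simulate_isi_recording <- function(config, eye = c("contra", "ipsi")) {
  stopifnot(inherits(config, "isi_sim_config"))
  eye <- match.arg(eye)
  amp <- if (eye == "contra") config$contra_amp_map else config$ipsi_amp_map
  h <- config$grid_height; w <- config$grid_width
  n <- round(config$n_cycles * config$frame_rate / config$stim_freq)
  if (abs(n - config$n_cycles * config$frame_rate / config$stim_freq) > 1)
    stop("frame_rate / stim_freq does not allow whole stimulus cycles ",
         "within one frame")
  t <- (seq_len(n) - 1) / config$frame_rate
  phase <- matrix(rep(config$phase_gradient * (seq_len(w) - 1), each = h),
                  h, w)
  phase <- ((phase + pi) %% (2 * pi)) - pi

  # outer product structure: vec(pixel) x time
  ang <- outer(as.vector(phase), 2 * pi * config$stim_freq * t, "+")
  sig <- as.vector(amp) * cos(ang)
  drift <- config$drift_amp * (t / max(t[2], t[n]) - 0.5)
  sig <- sweep(sig, 2, drift, "+")
  if (config$noise_sd > 0)
    sig <- sig + with_seed(
      config$seed + match(eye, c("contra", "ipsi")),
      matrix(stats::rnorm(length(sig), sd = config$noise_sd), nrow(sig)))
  frames <- array(sig, dim = c(h, w, n))
  isi_recording(frames, config$frame_rate, config$stim_freq, eye = eye,
                truth = list(amplitude = amp, phase = phase))
}

#' Per-pixel response amplitude and phase at the stimulus frequency
#'
#' Fourier analysis of the frame stack: each pixel's time series is
#' projected onto the discrete Fourier bin at the stimulus frequency after
#' removal of a per-pixel linear trend (slow haemodynamic/photobleaching
#' drift). The trend and the quadrature pair at the stimulus bin are fit
#' jointly by least squares, so neither leaks into the other: a pure cosine
#' of amplitude `A` returns exactly `A` (in the same relative-reflectance
#' units as the input) and a pure linear ramp returns amplitude 0. Phase is
#' reported in `[-pi, pi)`. The estimator requires the stimulus frequency to
#' sit on the frequency grid of the recording (cycle-aligned stack);
#' otherwise an error asks for cycle-aligned trimming.
#'
#' @param recording an [isi_recording()].
#' @return object of class `response_map`: list with matrices `amplitude`
#'   (>= 0) and `phase`.
#' @export
fourier_response <- function(recording) {
  stopifnot(inherits(recording, "isi_recording"))
  d <- dim(recording$frames)
  n <- d[3]
  k <- n * recording$stim_freq / recording$frame_rate
  # misalignment expressed in frames: one frame of slack, as on construction
  if (abs(k - round(k)) * recording$frame_rate / recording$stim_freq >
        1 + 1e-9)
    stop("stimulus frequency is off the recording's frequency grid; trim ",
         "the stack to an integer number of stimulus cycles")
  k <- round(k)

  x <- matrix(recording$frames, nrow = d[1] * d[2], ncol = n)
  tc <- seq_len(n) - (n + 1) / 2            # centered time index
  w <- 2 * pi * k * (seq_len(n) - 1) / n
  X <- cbind(1, tc, cos(w), sin(w))
  B <- x %*% X %*% solve(crossprod(X))      # per-pixel LS coefficients
  a <- B[, 3]; b <- B[, 4]                  # x ~ a cos(wt) + b sin(wt) + trend
  amplitude <- matrix(sqrt(a^2 + b^2), d[1], d[2])
  ph <- atan2(-b, a)                        # A cos(wt + phi): phi = atan2(-b, a)
  phase <- matrix(((ph + pi) %% (2 * pi)) - pi, d[1], d[2])
  structure(list(amplitude = amplitude, phase = phase,
                 stim_freq = recording$stim_freq, eye = recording$eye),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "Response map (%s eye, %.3g Hz): %d x %d px, peak amplitude %.4g\n",
    x$eye, x$stim_freq, nrow(x$amplitude), ncol(x$amplitude),
    max(x$amplitude)))
  invisible(x)
}

#' Average response-amplitude maps across measurements
#'
#' Response amplitude is taken as the per-pixel arithmetic mean of repeated
#' measurements; at least four are expected, and a warning is emitted below
#' that.
#'
#' @param maps list of amplitude matrices (or `response_map` objects) of
#'   identical dimensions.
#' @return averaged amplitude matrix.
#' @export
average_amplitude <- function(maps) {
  maps <- lapply(maps, function(m)
    if (inherits(m, "response_map")) m$amplitude else m)
  if (length(maps) < 1) stop("at least one map required")
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("amplitude maps differ in shape")
  if (length(maps) < 4)
    warning("fewer than 4 measurements averaged (", length(maps), ")")
  Reduce(`+`, maps) / length(maps)
}

#' Smooth a map with a 5 x 5 uniform kernel
#'
#' Low-pass filtering by a moving average over a 5 x 5 pixel window, the
#' smoothing applied before thresholding the binocular region of interest.
#' Borders are handled by reflect padding, which preserves the map mean and
#' makes masks bit-reproducible.
#'
#' @param map numeric matrix, at least 5 x 5.
#' @param k odd kernel width (default 5).
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_map <- function(map, k = 5L) {
  stopifnot(is.matrix(map), k %% 2 == 1)
  r <- (k - 1L) %/% 2L
  if (nrow(map) < k || ncol(map) < k)
    stop("map must be at least ", k, " x ", k)
  ri <- c(r:1, seq_len(nrow(map)), nrow(map) - seq_len(r) + 1L)
  ci <- c(r:1, seq_len(ncol(map)), ncol(map) - seq_len(r) + 1L)
  pad <- map[ri, ci, drop = FALSE]
  # summed-area table; window sums via corner differences
  sat <- apply(apply(pad, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  i1 <- seq_len(nrow(map)); j1 <- seq_len(ncol(map))
  win <- sat[i1 + k, j1 + k, drop = FALSE] - sat[i1, j1 + k, drop = FALSE] -
    sat[i1 + k, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
  win / (k * k)
}

#' Binocular region of interest from the ipsilateral response map
#'
#' The binocularly responsive ROI is defined on the ipsilateral-eye response
#' map after 5 x 5 uniform smoothing, by thresholding at 40% of the peak
#' response amplitude; pixels equal to the threshold are included. The mask
#' is invariant to positive rescaling of the map.
#'
#' @param ipsi_amplitude non-negative amplitude matrix (ipsilateral eye).
#' @param threshold_frac fraction of the smoothed peak (default 0.4).
#' @param smooth apply [smooth_map()] first (default `TRUE`).
#' @return logical matrix mask.
#' @export
binocular_roi <- function(ipsi_amplitude, threshold_frac = 0.4,
                          smooth = TRUE) {
  if (any(ipsi_amplitude < 0)) stop("amplitude map must be non-negative")
  m <- if (smooth) smooth_map(ipsi_amplitude) else ipsi_amplitude
  peak <- max(m)
  if (peak <= 0) stop("all-zero response map: ROI is empty")
  m >= threshold_frac * peak
}

#' Ocular dominance score map and index
#'
#' For every ROI pixel the ocular dominance score `(C - I) / (C + I)` is
#' computed from the contralateral- and ipsilateral-eye response magnitudes;
#' the ocular dominance index (ODI) is the mean score over all responsive
#' pixels. Scores lie in `[-1, 1]`: positive values indicate contralateral
#' dominance. Pixels with `C + I = 0` are excluded and counted.
#'
#' @param contra,ipsi amplitude matrices of identical shape.
#' @param roi logical mask (e.g. from [binocular_roi()]).
#' @return object of class `od_result`: `odi`, `score` (matrix, NA outside
#'   the ROI), `roi`, `c_mean`, `i_mean`, `n_roi_pixels`, `n_excluded`.
#' @export
ocular_dominance <- function(contra, ipsi, roi) {
  if (!identical(dim(contra), dim(ipsi)) || !identical(dim(contra), dim(roi)))
    stop("contra, ipsi and roi must have identical dimensions")
  if (!any(roi)) stop("empty ROI")
  s <- contra + ipsi
  use <- roi & s > 0
  n_excl <- sum(roi) - sum(use)
  score <- matrix(NA_real_, nrow(contra), ncol(contra))
  score[use] <- (contra[use] - ipsi[use]) / s[use]
  structure(list(odi = mean(score[use]), score = score, roi = roi,
                 c_mean = mean(contra[roi]), i_mean = mean(ipsi[roi]),
                 n_roi_pixels = sum(roi), n_excluded = n_excl),
            class = "od_result")
}

#' @export
print.od_result <- function(x, ...) {
  cat(sprintf("Ocular dominance: ODI = %.4f over %d ROI pixels\n",
              x$odi, x$n_roi_pixels))
  cat(sprintf("  mean amplitudes: contra %.4g, ipsi %.4g; %d zero-response pixel(s) excluded\n",
              x$c_mean, x$i_mean, x$n_excluded))
  invisible(x)
}

#' Write and read intrinsic-signal stacks as multi-frame TIFF
#'
#' Frames are stored one per TIFF directory as 32-bit float. Because float
#' storage is only well defined on `[0, 1]`, values are affinely mapped to
#' that range and the offset/scale recorded in a JSON sidecar (same path,
#' `.json` extension) together with `frame_rate`, `stim_freq` and the eye
#' label; the reader inverts the mapping, so round-trips are exact to
#' float32 precision.
#'
#' @param recording an [isi_recording()] (or a plain h x w x t array plus
#'   `frame_rate`/`stim_freq` arguments).
#' @param path TIFF file path.
#' @return `write_isi_tiff` returns `path` invisibly; `read_isi_tiff` an
#'   [isi_recording()].
#' @export
write_isi_tiff <- function(recording, path) {
  stopifnot(inherits(recording, "isi_recording"))
  fr <- recording$frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  frames01 <- lapply(seq_len(dim(fr)[3]),
                     function(i) (fr[, , i] - lo) / scale)
  tiff::writeTIFF(frames01, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(frame_rate = recording$frame_rate,
               stim_freq = recording$stim_freq, eye = recording$eye,
               offset = lo, scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_isi_tiff
#' @export
read_isi_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fr <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(fr), dim = c(dim(fr[[1]]), length(fr)))
  arr <- arr * meta$scale + meta$offset
  isi_recording(arr, meta$frame_rate, meta$stim_freq, eye = meta$eye)
}
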