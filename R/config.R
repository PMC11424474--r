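#' Configuration for the synthetic spine-dataset generator
#'
#' Bundles and validates every parameter of [simulate_spine_dataset()]. The
#' defaults describe a typical longitudinal experiment on apical dendrites of
#' layer-bound pyramidal neurons: daily imaging sessions on days -3..4 with a
#' manipulation (e.g. monocular deprivation) between day 0 and day 1, spine
#' densities around 0.4 per micrometre, and modest daily addition and
#' elimination.
#'
#' @param n_dendrites number of dendritic segments to simulate.
#' @param dendrite_length segment length in micrometres.
#' @param spine_rate Poisson intensity of spine placement (spines per
#'   micrometre) before hard-core thinning.
#' @param min_spacing minimum distance between two spines in micrometres
#'   (hard-core constraint).
#' @param sessions ordered integer day labels; day 0 is the last session
#'   before the manipulation.
#' @param baseline_sessions subset of `sessions` forming the baseline; must be
#'   a non-empty prefix of `sessions`.
#' @param addition_rate,elimination_rate per-session probabilities of spine
#'   addition and elimination (applied from the second session onward).
#' @param size_log_mean,size_log_sd log-normal parameters of the baseline
#'   true spine size (shaft-normalized units, so `size_log_mean = 0` puts the
#'   median spine at the brightness of its shaft).
#' @param global_shift mean of the true normalized size change after the
#'   manipulation; negative values emulate deprivation-driven weakening.
#' @param change_sd standard deviation of the true normalized change. The
#'   default 0.13 is calibrated so that, together with the default
#'   measurement noise, the control-condition (zero-shift) window-averaged
#'   change has a standard deviation of about 0.14 — the classification
#'   threshold, which is defined as one s.d. of control variability.
#' @param neighbor_rho spatial correlation in `[0, 1]` of true change values
#'   between adjacent spines along the dendrite.
#' @param noise_cv coefficient of variation of the multiplicative (log-normal)
#'   measurement noise applied to fluorescence intensities.
#' @param mechanism correlation mechanism for [simulate_clustered_changes()]:
#'   `"ar1"` (first-order autoregression along position order; lag-1
#'   correlation equals `neighbor_rho`) or `"gp"` (squared-exponential
#'   Gaussian-process kernel whose length scale is mapped so that correlation
#'   at the mean nearest-neighbour spacing equals `neighbor_rho`).
#' @param seed integer root seed; per-dendrite substreams are derived from it
#'   so generation is reproducible.
#'
#' @return an object of class `spine_sim_config` (a validated list).
#' @seealso [simulate_spine_dataset()], [simulate_clustered_changes()]
#' @export
spine_sim_config <- function(n_dendrites = 100,
                             dendrite_length = 20,
                             spine_rate = 0.4,
                             min_spacing = 0.5,
                             sessions = -3:4,
                             baseline_sessions = -3:0,
                             addition_rate = 0.05,
                             elimination_rate = 0.05,
                             size_log_mean = 0,
                             size_log_sd = 0.5,
                             global_shift = 0,
                             change_sd = 0.13,
                             neighbor_rho = 0,
                             noise_cv = 0.1,
                             mechanism = c("ar1", "gp"),
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  cfg <- list(
    n_dendrites = as.integer(n_dendrites),
    dendrite_length = as.numeric(dendrite_length),
    spine_rate = as.numeric(spine_rate),
    min_spacing = as.numeric(min_spacing),
    sessions = as.integer(sessions),
    baseline_sessions = as.integer(baseline_sessions),
    addition_rate = as.numeric(addition_rate),
    elimination_rate = as.numeric(elimination_rate),
    size_log_mean = as.numeric(size_log_mean),
    size_log_sd = as.numeric(size_log_sd),
    global_shift = as.numeric(global_shift),
    change_sd = as.numeric(change_sd),
    neighbor_rho = as.numeric(neighbor_rho),
    noise_cv = as.numeric(noise_cv),
    mechanism = mechanism,
    seed = as.integer(seed)
  )
  validate_spine_sim_config(cfg)
  structure(cfg, class = "spine_sim_config")
}

validate_spine_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_dendrites >= 1,
    cfg$dendrite_length > 0,
    cfg$spine_rate >= 0,
    cfg$min_spacing >= 0,
    cfg$size_log_sd >= 0,
    cfg$change_sd >= 0,
    cfg$noise_cv >= 0
  )
  if (cfg$addition_rate < 0 || cfg$addition_rate > 1 ||
      cfg$elimination_rate < 0 || cfg$elimination_rate > 1)
    stop("addition_rate and elimination_rate must lie in [0, 1]")
  if (cfg$neighbor_rho < 0 || cfg$neighbor_rho > 1)
    stop("neighbor_rho must lie in [0, 1]")
  if (length(cfg$sessions) < 2 || is.unsorted(cfg$sessions, strictly = TRUE))
    stop("sessions must be at least 2 strictly increasing day labels")
  nb <- length(cfg$baseline_sessions)
  if (nb < 1 || !identical(cfg$baseline_sessions, cfg$sessions[seq_len(nb)]))
    stop("baseline_sessions must be a non-empty prefix of sessions")
  if (nb >= length(cfg$sessions))
    stop("at least one post-baseline session is required")
  invisible(cfg)
}

#' @export
print.spine_sim_config <- function(x, ...) {
  cat("Spine simulation config\n")
  cat(sprintf("  %d dendrites of %.1f um, rate %.2f spines/um (min spacing %.2f um)\n",
              x$n_dendrites, x$dendrite_length, x$spine_rate, x$min_spacing))
  cat(sprintf("  sessions: %s (baseline: %s)\n",
              paste(x$sessions, collapse = " "),
              paste(x$baseline_sessions, collapse = " ")))
  cat(sprintf("  add/elim rates: %.3f / %.3f per session\n",
              x$addition_rate, x$elimination_rate))
  cat(sprintf("  change: shift %.3f, sd %.3f, neighbor rho %.2f (%s), noise CV %.3f\n",
              x$global_shift, x$change_sd, x$neighbor_rho, x$mechanism,
              x$noise_cv))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Configuration for the synthetic intrinsic-signal recording generator
#'
#' Parameters of [simulate_isi_recording()]. The defaults emulate a typical
#' acquisition: frames captured at 30 Hz and temporally binned by four
#' (effective 7.5 Hz), a drifting-bar stimulus sweeping periodically at
#' 0.125 Hz, and a Gaussian patch of responsive cortex with a retinotopic
#' phase gradient.
#'
#' @param grid_height,grid_width image dimensions in pixels.
#' @param frame_rate frames per second after temporal binning.
#' @param n_cycles integer number of stimulus cycles recorded.
#' @param stim_freq stimulus frequency in Hz; must satisfy
#'   `stim_freq < frame_rate / 2`.
#' @param contra_amp_map,ipsi_amp_map non-negative per-pixel response
#'   amplitude matrices (`grid_height` x `grid_width`), in relative
#'   reflectance-change units. Defaults are Gaussian patches with the
#'   contralateral map twice the ipsilateral one.
#' @param phase_gradient retinotopic phase advance in radians per pixel along
#'   the column (x) axis.
#' @param noise_sd standard deviation of additive per-frame Gaussian noise.
#' @param drift_amp amplitude of a slow linear drift spanning the recording.
#' @param seed integer seed for the noise stream.
#'
#' @return an object of class `isi_sim_config`.
#' @seealso [simulate_isi_recording()], [fourier_response()]
#' @export
isi_sim_config <- function(grid_height = 32,
                           grid_width = 32,
                           frame_rate = 7.5,
                           n_cycles = 5,
                           stim_freq = 0.125,
                           contra_amp_map = NULL,
                           ipsi_amp_map = NULL,
                           phase_gradient = 0.1,
                           noise_sd = 0.05,
                           drift_amp = 0.1,
                           seed = 1L) {
  grid_height <- as.integer(grid_height)
  grid_width <- as.integer(grid_width)
  if (is.null(ipsi_amp_map))
    ipsi_amp_map <- gaussian_patch(grid_height, grid_width, peak = 1)
  if (is.null(contra_amp_map))
    contra_amp_map <- 2 * ipsi_amp_map
  cfg <- list(
    grid_height = grid_height,
    grid_width = grid_width,
    frame_rate = as.numeric(frame_rate),
    n_cycles = as.integer(n_cycles),
    stim_freq = as.numeric(stim_freq),
    contra_amp_map = contra_amp_map,
    ipsi_amp_map = ipsi_amp_map,
    phase_gradient = as.numeric(phase_gradient),
    noise_sd = as.numeric(noise_sd),
    drift_amp = as.numeric(drift_amp),
    seed = as.integer(seed)
  )
  validate_isi_sim_config(cfg)
  structure(cfg, class = "isi_sim_config")
}

validate_isi_sim_config <- function(cfg) {
  stopifnot(cfg$grid_height >= 1, cfg$grid_width >= 1,
            cfg$frame_rate > 0, cfg$n_cycles >= 1, cfg$noise_sd >= 0)
  if (cfg$stim_freq <= 0 || cfg$stim_freq >= cfg$frame_rate / 2)
    stop("stim_freq must lie in (0, frame_rate / 2)")
  for (nm in c("contra_amp_map", "ipsi_amp_map")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || nrow(m) != cfg$grid_height ||
        ncol(m) != cfg$grid_width)
      stop(nm, " must be a grid_height x grid_width matrix")
    if (any(m < 0)) stop(nm, " must be non-negative")
  }
  invisible(cfg)
}

# Smooth unimodal amplitude map used as the default responsive region.
gaussian_patch <- function(h, w, peak = 1, center = c(h / 2, w / 2),
                           sigma = min(h, w) / 4) {
  r <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+")
  peak * exp(-r / (2 * sigma^2))
}

#' Configuration for the clustered-plasticity analysis
#'
#' Parameters of [cluster_test()] and the spine classification. The defaults
#' are the analysis conventions of the underlying study: a classification
#' threshold of 0.14 normalized-change units (one standard deviation of
#' baseline size changes in control animals), nearest-neighbour pairs retained
#' at path distances between 1.0 um (avoids overlapping ROIs) and 3.5 um
#' inclusive, and 10,000 permutation pools.
#'
#' @param tau classification threshold in normalized-change units; spines with
#'   average change above `tau` are "increasing", below `-tau` "decreasing",
#'   otherwise "stable" (the boundary is stable).
#' @param d_min,d_max inclusive distance bounds in micrometres for retained
#'   nearest-neighbour pairs.
#' @param n_pools number of within-dendrite permutation pools for the Monte
#'   Carlo null.
#' @param window integer day labels over which the per-spine change is
#'   averaged before classification; `NULL` means all post-baseline sessions.
#' @param tail tail convention for the Monte Carlo p-value: `"auto"` takes the
#'   tail on the side of the observed deviation from the shuffled median
#'   (reported per metric), `"upper"` the exceedance tail, `"lower"` the
#'   deficit tail.
#' @param correction `"none"` for the plain tail proportion (observed counted
#'   among ties), `"add_one"` for the (k + 1)/(n + 1) permutation correction.
#' @param persistent_only if `TRUE` (default) only persistent spines (present
#'   at every baseline and window session, hence with a defined average
#'   change) enter the pairing and the shuffle.
#' @param seed integer seed for the permutation stream.
#'
#' @return an object of class `clustering_config`.
#' @export
clustering_config <- function(tau = 0.14,
                              d_min = 1.0,
                              d_max = 3.5,
                              n_pools = 10000,
                              window = NULL,
                              tail = c("auto", "upper", "lower"),
                              correction = c("none", "add_one"),
                              persistent_only = TRUE,
                              seed = 1L) {
  tail <- match.arg(tail)
  correction <- match.arg(correction)
  cfg <- list(
    tau = as.numeric(tau),
    d_min = as.numeric(d_min),
    d_max = as.numeric(d_max),
    n_pools = as.integer(n_pools),
    window = if (!is.null(window)) as.integer(window),
    tail = tail,
    correction = correction,
    persistent_only = isTRUE(persistent_only),
    seed = as.integer(seed)
  )
  if (cfg$tau <= 0) stop("tau must be positive")
  if (cfg$d_min < 0 || cfg$d_min >= cfg$d_max)
    stop("distance bounds must satisfy 0 <= d_min < d_max")
  if (cfg$n_pools < 1) stop("n_pools must be at least 1")
  structure(cfg, class = "clustering_config")
}
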