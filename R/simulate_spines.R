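#' Simulate spatially correlated spine size changes along a dendrite
#'
#' Draws one true normalized size change per spine position. Marginally each
#' value is Normal(`global_shift`, `change_sd`^2); the correlation between
#' adjacent spines is controlled by `neighbor_rho`. Two mechanisms are
#' available: a first-order autoregression along the position order (lag-1
#' correlation exactly `neighbor_rho`, the default) and a squared-exponential
#' Gaussian-process kernel whose length scale is chosen so that the
#' correlation at the dendrite's mean nearest-neighbour spacing equals
#' `neighbor_rho`. At `neighbor_rho = 1` every spine on the dendrite receives
#' the same value; at 0 the values are i.i.d.
#'
#' Values are clipped to (-0.99, 0.99) so that the implied post-manipulation
#' size `v * (1 + c) / (1 - c)` stays positive and finite; with the default
#' `change_sd = 0.2` clipping is a > 4.4-sigma event and statistically
#' negligible.
#'
#' @param positions sorted ascending spine positions in micrometres.
#' @param config a [spine_sim_config()].
#' @return numeric vector of change values, one per position (empty input
#'   gives an empty output).
#' @export
simulate_clustered_changes <- function(positions, config) {
  stopifnot(inherits(config, "spine_sim_config"))
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  rho <- config$neighbor_rho

  if (n == 1L) {
    z <- stats::rnorm(1)
  } else if (rho >= 1) {
    z <- rep(stats::rnorm(1), n)
  } else if (config$mechanism == "ar1" || rho == 0) {
    # z_k = rho z_{k-1} + sqrt(1 - rho^2) eps_k keeps the marginal N(0,1)
    innov <- c(stats::rnorm(1), sqrt(1 - rho^2) * stats::rnorm(n - 1))
    z <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  } else {
    nn_dist <- nearest_gap(positions)
    sbar <- mean(nn_dist)
    ell <- sbar / sqrt(-2 * log(rho))
    d2 <- outer(positions, positions, "-")^2
    K <- exp(-d2 / (2 * ell^2)) + diag(1e-10, n)
    z <- drop(crossprod(chol(K), stats::rnorm(n)))
  }
  ch <- config$global_shift + config$change_sd * z
  pmin(pmax(ch, -0.99), 0.99)
}

# per-point distance to its nearest neighbour, for sorted positions
nearest_gap <- function(positions) {
  d <- diff(positions)
  if (length(d) == 0) return(numeric(0))
  pmin(c(Inf, d), c(d, Inf))
}

#' Simulate a longitudinal spine-imaging dataset with known ground truth
#'
#' Generates `n_dendrites` dendritic segments. On each, spine positions come
#' from a Poisson process thinned to a hard-core minimum spacing; baseline
#' true sizes are log-normal; each session after the first applies random
#' eliminations and additions at the configured per-session probabilities
#' (eliminations are terminal; a geometrically saturated segment accepts
#' fewer additions than drawn, since no position respecting the minimum
#' spacing remains); true normalized changes with configurable
#' spatial correlation (see [simulate_clustered_changes()]) take effect after
#' day 0, the last pre-manipulation session: a spine with baseline size `v`
#' and true change `c` has post-manipulation size `v (1 + c) / (1 - c)`, so
#' the downstream normalized change recovers `c` exactly when noise is off.
#'
#' Measured intensities emulate the annotation workflow: a background region,
#' an adjacent-shaft region and the spine ROI, each carrying independent
#' multiplicative log-normal noise with coefficient of variation `noise_cv`
#' (the shaft-normalized size therefore carries a noise ratio with CV of
#' about `sqrt(2) * noise_cv`). With `noise_cv = 0`,
#' `(spine - background) / (shaft - background)` equals the true size
#' exactly.
#'
#' Reproducibility: the root `config$seed` seeds a stream that draws one
#' sub-seed per dendrite, so the dataset is bit-identical for a given config
#' and individual dendrites are invariant to `n_dendrites`.
#'
#' @param config a [spine_sim_config()].
#' @return a [spine_dataset()] whose spine table carries `true_size` and
#'   `true_change` ground-truth columns.
#' @export
simulate_spine_dataset <- function(config) {
  stopifnot(inherits(config, "spine_sim_config"))
  validate_spine_sim_config(config)
  parts <- with_seed(config$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_dendrites)
    lapply(seq_len(config$n_dendrites), function(d) {
      set.seed(sub_seeds[d])
      simulate_dendrite(sprintf("d%03d", d), config)
    })
  })
  spines <- do.call(rbind, parts)
  rownames(spines) <- NULL
  dendrites <- data.frame(
    dendrite_id = sprintf("d%03d", seq_len(config$n_dendrites)),
    length_um = config$dendrite_length,
    stringsAsFactors = FALSE)
  spine_dataset(spines, config$sessions, config$baseline_sessions,
                dendrites = dendrites, config = config)
}

simulate_dendrite <- function(dendrite_id, config) {
  sessions <- config$sessions
  n_sess <- length(sessions)
  positions <- place_spines(stats::rpois(1, config$spine_rate *
                                           config$dendrite_length),
                            config$dendrite_length, config$min_spacing)
  positions <- sort(positions)
  n0 <- length(positions)

  # presence matrix grows as spines are added over sessions
  present <- matrix(FALSE, nrow = n0, ncol = n_sess)
  if (n0 > 0) present[, 1] <- TRUE
  for (s in seq_len(n_sess)[-1]) {
    alive_prev <- which(present[, s - 1])
    n_prev <- length(alive_prev)
    if (n_prev > 0) {
      surv <- stats::runif(n_prev) >= config$elimination_rate
      present[alive_prev[surv], s] <- TRUE
      n_add <- stats::rbinom(1, n_prev, config$addition_rate)
      if (n_add > 0) {
        # a saturated segment accepts fewer additions than drawn
        new_pos <- place_spines(n_add, config$dendrite_length,
                                config$min_spacing, existing = positions)
        if (length(new_pos)) {
          positions <- c(positions, new_pos)
          grow <- matrix(FALSE, nrow = length(new_pos), ncol = n_sess)
          grow[, s] <- TRUE
          present <- rbind(present, grow)
        }
      }
    }
  }
  n_spines <- length(positions)
  if (n_spines == 0) return(NULL)

  base_size <- stats::rlnorm(n_spines, config$size_log_mean,
                             config$size_log_sd)
  # correlated changes for the initial cohort (ordered by position);
  # later additions draw independent marginal values
  change <- numeric(n_spines)
  if (n0 > 0) {
    ord <- order(positions[seq_len(n0)])
    change[seq_len(n0)][ord] <-
      simulate_clustered_changes(sort(positions[seq_len(n0)]), config)
  }
  if (n_spines > n0) {
    extra <- config$global_shift +
      config$change_sd * stats::rnorm(n_spines - n0)
    change[(n0 + 1):n_spines] <- pmin(pmax(extra, -0.99), 0.99)
  }
  post_size <- base_size * (1 + change) / (1 - change)

  rows <- expand.grid(spine = seq_len(n_spines), sess = seq_len(n_sess))
  day <- sessions[rows$sess]
  pres <- present[cbind(rows$spine, rows$sess)]
  true_size <- ifelse(day > max(config$baseline_sessions),
                      post_size[rows$spine], base_size[rows$spine])
  nmul <- function(n) noise_mult(n, config$noise_cv)
  nr <- nrow(rows)
  bg <- 100 * nmul(nr)
  shaft <- bg + 1000 * nmul(nr)
  spine_int <- bg + true_size * 1000 * nmul(nr)
  df <- data.frame(
    dendrite_id = dendrite_id,
    spine_id = sprintf("s%03d", rows$spine),
    position_um = positions[rows$spine],
    day = day,
    present = pres,
    spine_intensity = ifelse(pres, spine_int, NA_real_),
    shaft_intensity = ifelse(pres, shaft, NA_real_),
    background_intensity = ifelse(pres, bg, NA_real_),
    true_size = ifelse(pres, true_size, NA_real_),
    true_change = change[rows$spine],
    stringsAsFactors = FALSE)
  df[order(df$spine_id, df$day), , drop = FALSE]
}

# Hard-core placement. With no pre-existing spines the configuration space
# (sorted points with consecutive gaps >= min_spacing) maps affinely onto
# uniform order statistics on [0, L - (n-1) s], which is sampled exactly:
# no rejection, no jamming at high occupancy. Additions next to existing
# spines sample uniformly from the exact free set instead.
place_spines <- function(n, length_um, min_spacing, existing = numeric(0)) {
  if (n == 0) return(numeric(0))
  if (length(existing) == 0) {
    slack <- length_um - (n - 1) * min_spacing
    if (slack < 0)
      stop("impossible geometry: cannot place ", n, " spines at spacing >= ",
           min_spacing, " um on a ", length_um, " um segment")
    return(sort(stats::runif(n, 0, slack)) +
             (seq_len(n) - 1) * min_spacing)
  }
  out <- numeric(0)
  for (i in seq_len(n)) {
    p <- sample_free_position(c(existing, out), length_um, min_spacing)
    if (is.na(p)) break  # segment saturated: add as many as fit
    out <- c(out, p)
  }
  out
}

# uniform draw from [0, L] minus the union of (p - s, p + s) exclusion
# zones; NA when the segment is saturated
sample_free_position <- function(occupied, length_um, min_spacing) {
  lo <- pmax(sort(occupied) - min_spacing, 0)
  hi <- pmin(sort(occupied) + min_spacing, length_um)
  free_start <- c(0, hi)
  free_end <- c(lo, length_um)
  # merge overlapping exclusion zones by keeping only positive-length gaps
  keep <- which(free_end - free_start > 0 &
                  free_start >= cummax(c(0, hi))[seq_along(free_start)])
  starts <- free_start[keep]
  widths <- (free_end - free_start)[keep]
  total <- sum(widths)
  if (total <= 0) return(NA_real_)
  u <- stats::runif(1, 0, total)
  cw <- cumsum(widths)
  j <- which(u <= cw)[1]
  starts[j] + u - c(0, cw)[j]
}

# multiplicative log-normal noise with mean 1 and the requested CV
noise_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# evaluate code under a fixed seed, restoring the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
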