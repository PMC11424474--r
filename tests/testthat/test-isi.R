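make_recording <- function(amp, phase, frame_rate = 7.5, stim_freq = 0.125,
                           n_cycles = 3, drift = 0, noise_sd = 0,
                           eye = "contra") {
  h <- nrow(amp); w <- ncol(amp)
  n <- round(n_cycles * frame_rate / stim_freq)
  t <- (seq_len(n) - 1) / frame_rate
  x <- vapply(seq_len(n), function(i)
    amp * cos(2 * pi * stim_freq * t[i] + phase) + drift * t[i] / max(t),
    matrix(0, h, w))
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  isi_recording(array(x, dim = c(h, w, n)), frame_rate, stim_freq, eye = eye)
}

test_that("fourier response recovers amplitude and phase exactly", {
  amps <- c(0.3, 1, 2.5)
  phases <- c(-2.5, -1, 0, 1.2, 3)
  for (A in amps) for (ph in phases) {
    rec <- make_recording(matrix(A, 6, 6), matrix(ph, 6, 6))
    rm <- fourier_response(rec)
    expect_lt(max(abs(rm$amplitude - A)) / A, 0.01)
    dphi <- atan2(sin(rm$phase - ph), cos(rm$phase - ph))
    expect_lt(max(abs(dphi)), 0.01)
  }
})

test_that("constant and pure-drift stacks give zero amplitude", {
  const <- isi_recording(array(3.7, dim = c(5, 5, 180)), 7.5, 0.125)
  expect_equal(max(fourier_response(const)$amplitude), 0)
  ramp <- make_recording(matrix(0, 5, 5), matrix(0, 5, 5), drift = 4)
  expect_lt(max(fourier_response(ramp)$amplitude), 1e-6 * 4)
})

test_that("pure noise stays at the noise floor", {
  cfg <- isi_sim_config(grid_height = 16, grid_width = 16,
                        contra_amp_map = matrix(0, 16, 16),
                        ipsi_amp_map = matrix(0, 16, 16),
                        noise_sd = 0.3, drift_amp = 0, seed = 2)
  rm <- fourier_response(simulate_isi_recording(cfg))
  n <- round(cfg$n_cycles * cfg$frame_rate / cfg$stim_freq)
  sigma <- cfg$noise_sd * sqrt(2 / n)
  expect_lt(mean(rm$amplitude), 3 * cfg$noise_sd / sqrt(n))
  expect_lt(max(rm$amplitude), sigma * sqrt(2 * log(256 * 1e4)))
})

test_that("retinotopic phase gradient is recovered", {
  cfg <- isi_sim_config(noise_sd = 0, drift_amp = 0.2, phase_gradient = 0.1)
  rec <- simulate_isi_recording(cfg)
  rm <- fourier_response(rec)
  # along each row, the recovered phase advances by the gradient
  d <- diff(rm$phase[16, ])
  d <- atan2(sin(d), cos(d))
  expect_true(all(abs(d - 0.1) < 1e-6))
  # circular correlation with the generated truth
  tr <- rec$truth$phase
  cc <- abs(cor(exp(1i * as.vector(rm$phase)) |> Re(),
                exp(1i * as.vector(tr)) |> Re()))
  expect_gt(cc, 0.99)
})

test_that("misaligned stacks are rejected with trimming advice", {
  expect_error(isi_recording(array(0, dim = c(4, 4, 100)), 7.5, 0.13),
               "integer number of stimulus cycles")
  rec <- isi_recording(array(rnorm(4 * 4 * 180), dim = c(4, 4, 180)),
                       7.5, 0.125)
  rec$stim_freq <- 0.1111  # off-grid after construction
  expect_error(fourier_response(rec), "trim")
})

test_that("amplitude averaging behaves like a mean", {
  m <- matrix(runif(25), 5, 5)
  expect_warning(avg <- average_amplitude(list(m, m)), "fewer than 4")
  expect_equal(avg, m)
  expect_equal(suppressWarnings(
    average_amplitude(list(matrix(0, 2, 2), matrix(2, 2, 2)))),
    matrix(1, 2, 2))
  expect_error(suppressWarnings(
    average_amplitude(list(matrix(0, 2, 2), matrix(0, 3, 3)))), "shape")
  # averaging k i.i.d. noise maps shrinks the sd by sqrt(k)
  set.seed(12)
  one <- replicate(300, sd(matrix(rnorm(64), 8, 8)))
  four <- replicate(300, sd(average_amplitude(
    lapply(1:4, function(i) matrix(rnorm(64), 8, 8)))))
  expect_equal(mean(four) / mean(one), 0.5, tolerance = 0.05)
})

test_that("uniform smoothing kernel is exact and mean-preserving", {
  expect_equal(smooth_map(matrix(2.2, 8, 8)), matrix(2.2, 8, 8))
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  sm <- smooth_map(imp)
  expect_equal(sum(sm > 0), 25)
  expect_equal(unique(sm[sm > 0]), 1 / 25)
  set.seed(13)
  m <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(mean(smooth_map(m)), mean(m), tolerance = 1e-12)
  expect_error(smooth_map(matrix(1, 3, 3)), "at least")
})

test_that("binocular ROI thresholds at 40% of the smoothed peak", {
  u <- matrix(0.7, 10, 10)
  expect_true(all(binocular_roi(u)))
  m <- matrix(0.1, 20, 20); m[8:12, 8:12] <- 1
  roi <- binocular_roi(m, smooth = FALSE)
  expect_equal(roi, m >= 0.4)
  # relative threshold: invariant to positive rescaling
  expect_equal(binocular_roi(3.7 * m), binocular_roi(m))
  # monotone in the threshold fraction
  r40 <- binocular_roi(m, 0.4); r60 <- binocular_roi(m, 0.6)
  expect_true(all(!r60 | r40))
  expect_error(binocular_roi(matrix(0, 8, 8)), "empty")
})

test_that("ocular dominance index follows its closed forms", {
  roi <- matrix(TRUE, 6, 6)
  c1 <- matrix(2, 6, 6)
  expect_equal(ocular_dominance(c1, c1, roi)$odi, 0)
  expect_equal(ocular_dominance(matrix(3, 6, 6), matrix(1, 6, 6), roi)$odi,
               0.5)
  expect_equal(ocular_dominance(c1, matrix(0, 6, 6), roi)$odi, 1)
  # antisymmetry and joint scale invariance
  set.seed(14)
  A <- matrix(runif(36, 0.1, 2), 6, 6); B <- matrix(runif(36, 0.1, 2), 6, 6)
  expect_equal(ocular_dominance(A, B, roi)$odi,
               -ocular_dominance(B, A, roi)$odi, tolerance = 1e-12)
  expect_equal(ocular_dominance(5 * A, 5 * B, roi)$odi,
               ocular_dominance(A, B, roi)$odi, tolerance = 1e-12)
  od <- ocular_dominance(A, B, roi)
  expect_true(all(abs(od$score) <= 1))
  expect_true(abs(od$odi) <= 1)
  # zero-response pixels are excluded and counted
  A0 <- A; A0[1, 1] <- 0; B0 <- B; B0[1, 1] <- 0
  od0 <- ocular_dominance(A0, B0, roi)
  expect_equal(od0$n_excluded, 1)
  expect_error(ocular_dominance(A, B, matrix(FALSE, 6, 6)), "empty ROI")
})

test_that("simulated recordings round-trip through multi-frame TIFF", {
  cfg <- isi_sim_config(grid_height = 8, grid_width = 8, n_cycles = 2,
                        noise_sd = 0.02, seed = 3)
  rec <- simulate_isi_recording(cfg, eye = "ipsi")
  path <- file.path(tempdir(), "rec.tif")
  write_isi_tiff(rec, path)
  back <- read_isi_tiff(path)
  expect_equal(back$frames, rec$frames, tolerance = 1e-5)
  expect_equal(back$frame_rate, rec$frame_rate)
  expect_equal(back$stim_freq, rec$stim_freq)
  expect_equal(back$eye, "ipsi")
})

test_that("end-to-end ODI recovery from simulated movies", {
  cfg <- isi_sim_config(noise_sd = 0.01, seed = 6)
  contra <- fourier_response(simulate_isi_recording(cfg, "contra"))
  ipsi <- fourier_response(simulate_isi_recording(cfg, "ipsi"))
  roi <- binocular_roi(ipsi$amplitude)
  od <- ocular_dominance(contra$amplitude, ipsi$amplitude, roi)
  # contra map is twice ipsi: per-pixel score (2-1)/(2+1) = 1/3
  expect_equal(od$odi, 1 / 3, tolerance = 0.02)
  expect_gt(od$n_roi_pixels, 10)
})
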