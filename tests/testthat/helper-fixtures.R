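# Brute-force nearest-neighbour oracle: all pairwise distances, per-spine
# argmin (ties toward the smaller position), deduplicate, filter inclusive.
# Independent of the package's sorted-adjacency implementation.
oracle_nn_pairs <- function(positions, d_min = 1.0, d_max = 3.5) {
  n <- length(positions)
  if (n < 2)
    return(data.frame(a = integer(0), b = integer(0), distance = numeric(0)))
  rows <- lapply(seq_len(n), function(i) {
    d <- abs(positions - positions[i])
    d[i] <- Inf
    cand <- which(d == min(d))
    j <- cand[order(positions[cand])][1]
    c(min(i, j), max(i, j), min(d))
  })
  m <- unique(do.call(rbind, rows))
  keep <- m[, 3] >= d_min & m[, 3] <= d_max
  out <- data.frame(a = as.integer(m[keep, 1]), b = as.integer(m[keep, 2]),
                    distance = m[keep, 3])
  out[order(out$a, out$b), , drop = FALSE]
}

# distinct positions on a 0.5 um grid, so equidistant ties and exact
# boundary distances (1.0, 3.5) occur often
random_grid_positions <- function(n, grid = seq(0, 15, by = 0.5)) {
  sort(sample(grid, n))
}

# hand-built longitudinal dataset from a presence matrix and per-session
# size matrix (NA = absent); intensities encode size with bg 10, shaft 110
make_dataset <- function(presence, sizes = NULL, positions = NULL,
                         days = seq_len(ncol(presence)) - 1L,
                         baseline_days = days[1],
                         dendrite_id = "d1", length_um = 20) {
  n <- nrow(presence)
  if (is.null(positions)) positions <- seq(2, by = 2, length.out = n)
  if (is.null(sizes)) {
    sizes <- matrix(1, n, ncol(presence))
    sizes[!presence] <- NA
  }
  rows <- expand.grid(spine = seq_len(n), sess = seq_along(days))
  pres <- presence[cbind(rows$spine, rows$sess)]
  sz <- sizes[cbind(rows$spine, rows$sess)]
  df <- data.frame(
    dendrite_id = dendrite_id,
    spine_id = sprintf("s%02d", rows$spine),
    position_um = positions[rows$spine],
    day = days[rows$sess],
    present = pres,
    spine_intensity = ifelse(pres, 10 + 100 * sz, NA_real_),
    shaft_intensity = ifelse(pres, 110, NA_real_),
    background_intensity = ifelse(pres, 10, NA_real_))
  spine_dataset(df, sessions = days, baseline_sessions = baseline_days,
                dendrites = data.frame(dendrite_id = dendrite_id,
                                       length_um = length_um))
}

# size-change table built directly from per-spine averaged changes, for
# clustering tests that need full control of classes and positions
make_change_table <- function(dendrite_id, position_um, dbar, tau = 0.14) {
  data.frame(dendrite_id = dendrite_id,
             spine_id = sprintf("s%03d", seq_along(position_um)),
             position_um = position_um,
             dbar = dbar,
             persistent = TRUE,
             class = classify_spine(dbar, tau))
}
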