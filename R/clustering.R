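#' Classify a spine by its window-averaged size change
#'
#' Spines are increasing when the average normalized change exceeds `tau`,
#' decreasing below `-tau`, and stable otherwise; the boundary
#' `|change| == tau` is stable. The default threshold 0.14 is one standard
#' deviation of baseline size changes measured in control animals (see
#' [derive_threshold()]).
#'
#' @param dbar window-averaged normalized change (vectorized; NA gives NA).
#' @param tau positive threshold.
#' @return character vector in `{"increasing", "decreasing", "stable"}`.
#' @export
classify_spine <- function(dbar, tau = 0.14) {
  if (tau <= 0) stop("tau must be positive")
  out <- rep(NA_character_, length(dbar))
  ok <- !is.na(dbar)
  out[ok] <- ifelse(dbar[ok] > tau, "increasing",
                    ifelse(dbar[ok] < -tau, "decreasing", "stable"))
  out
}

#' Derive the classification threshold from control baseline variability
#'
#' The threshold is the sample standard deviation (n - 1 denominator) of
#' baseline-session normalized changes in the control group — the
#' variability a stable spine shows in the absence of any manipulation.
#'
#' @param deltas baseline-session normalized change values from control
#'   data (at least 2).
#' @param fallback value returned (with a warning) when the input is
#'   insufficient or degenerate.
#' @return scalar threshold.
#' @export
derive_threshold <- function(deltas, fallback = 0.14) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 2) {
    warning("fewer than 2 baseline changes; falling back to tau = ", fallback)
    return(fallback)
  }
  tau <- stats::sd(deltas)
  if (tau == 0) {
    warning("degenerate baseline changes (all equal); falling back to tau = ",
            fallback)
    return(fallback)
  }
  tau
}

#' Nearest-neighbour spine pairs along a dendrite
#'
#' For every spine, finds its closest neighbour by distance along the traced
#' dendritic path. Each unordered pair enters the list once only. Pairs are
#' then excluded when their distance is below `d_min` (overlapping ROIs) or
#' above `d_max`; boundary distances are retained. Ties between two
#' equidistant neighbours break deterministically toward the neighbour at
#' the smaller position (then the earlier identifier).
#'
#' @param positions spine positions in micrometres along the path.
#' @param ids optional identifiers (default: integer indices).
#' @param d_min,d_max inclusive distance bounds in micrometres.
#' @return data.frame with columns `a`, `b` (identifiers, `a` is the member
#'   with the smaller position), `distance`. Zero rows when fewer than two
#'   spines are supplied or no pair survives the distance filter.
#' @export
nearest_neighbor_pairs <- function(positions, ids = NULL,
                                   d_min = 1.0, d_max = 3.5) {
  n <- length(positions)
  if (is.null(ids)) ids <- seq_len(n)
  empty <- data.frame(a = ids[0], b = ids[0], distance = numeric(0))
  if (n < 2) return(empty)

  ord <- order(positions, ids)
  p <- positions[ord]
  gap_left <- c(Inf, diff(p))
  gap_right <- c(diff(p), Inf)
  # nearest neighbour of a spine along a 1-D path is one of its two sorted
  # neighbours; ties (equal gaps) break toward the smaller position
  take_left <- gap_left <= gap_right
  partner <- ifelse(take_left, seq_len(n) - 1L, seq_len(n) + 1L)
  dist <- pmin(gap_left, gap_right)

  i <- pmin(seq_len(n), partner)
  j <- pmax(seq_len(n), partner)
  keep <- !duplicated(paste(i, j))
  i <- i[keep]; j <- j[keep]; d <- dist[keep]
  retained <- d >= d_min & d <= d_max
  out <- data.frame(a = ids[ord][i[retained]], b = ids[ord][j[retained]],
                    distance = d[retained])
  rownames(out) <- NULL
  out
}

#' Directional fractions of nearest-neighbour spine pairs
#'
#' Of the retained pairs, the percentages in which both spines increase,
#' both decrease, both change in the same direction (the union of the
#' former two), or the two change in opposite directions. Pairs containing
#' a stable spine count toward no directional metric, so same + opposite
#' need not reach 100.
#'
#' @param pairs data.frame from [nearest_neighbor_pairs()].
#' @param classes named character vector mapping spine identifiers to
#'   `"increasing"`/`"decreasing"`/`"stable"`.
#' @return named numeric vector of percentages: `both_increase`,
#'   `both_decrease`, `same_direction`, `opposite_direction`, plus
#'   attribute `"n_pairs"`.
#' @export
pair_fractions <- function(pairs, classes) {
  n <- nrow(pairs)
  if (n == 0) stop("no retained pairs")
  ca <- classes[as.character(pairs$a)]
  cb <- classes[as.character(pairs$b)]
  if (any(is.na(ca)) || any(is.na(cb)))
    stop("pair member without a class label")
  bi <- sum(ca == "increasing" & cb == "increasing")
  bd <- sum(ca == "decreasing" & cb == "decreasing")
  op <- sum((ca == "increasing" & cb == "decreasing") |
              (ca == "decreasing" & cb == "increasing"))
  out <- 100 * c(both_increase = bi, both_decrease = bd,
                 same_direction = bi + bd, opposite_direction = op) / n
  attr(out, "n_pairs") <- n
  out
}

#' Shuffle change values along the spine positions of each dendrite
#'
#' The permutation null of the clustering test: within every dendrite
#' independently, the multiset of change values (or class labels) of its
#' spines is permuted uniformly at random over that dendrite's spine
#' positions. Positions, presence and hence the nearest-neighbour pair
#' structure are untouched.
#'
#' @param values vector of per-spine values (changes or classes).
#' @param dendrite dendrite identifier per spine.
#' @return `values` permuted within each dendrite.
#' @export
shuffle_changes <- function(values, dendrite) {
  stopifnot(length(values) == length(dendrite))
  f <- as.integer(factor(dendrite))
  ord <- order(f)
  # order(block, runif) yields an independent uniform permutation inside
  # every contiguous block
  perm <- order(f[ord], stats::runif(length(values)))
  out <- values
  out[ord] <- values[ord][perm]
  out
}

#' Monte Carlo test of spatially clustered spine plasticity
#'
#' Tests whether neighbouring spines change size together more (or less)
#' than chance. Observed statistic: over all dendrites, nearest-neighbour
#' pairs are built from persistent spines ([nearest_neighbor_pairs()]),
#' distance-filtered, pooled, and the four directional pair fractions
#' computed ([pair_fractions()]). Null: in each of `n_pools` permutation
#' pools the change classes are shuffled along the spine positions within
#' every dendrite ([shuffle_changes()]) and the pooled fractions recomputed.
#' The p-value for each metric is the plain proportion of shuffled fractions
#' at or beyond the observed value (ties count) on the configured tail;
#' `tail = "auto"` uses the side of the observed deviation from the shuffled
#' median and reports the side chosen.
#'
#' @param changes a [size_change_table()] (or data.frame with columns
#'   `dendrite_id`, `spine_id`, `position_um`, `dbar`, `class`,
#'   `persistent`).
#' @param config a [clustering_config()]; its `tau` re-classifies spines
#'   only when `changes` lacks a `class` column.
#' @return object of class `cluster_test`: `observed` (percentages),
#'   `p_value`, `tail_used`, `null` (`n_pools` x 4 matrix of shuffled
#'   percentages), `n_pairs`, `n_dendrites_paired`, `per_dendrite`
#'   (data.frame of per-dendrite fractions for group-level comparison),
#'   `pairs`, `config`.
#' @export
cluster_test <- function(changes, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  df <- as.data.frame(changes)
  need <- c("dendrite_id", "spine_id", "position_um", "dbar")
  if (!all(need %in% names(df)))
    stop("changes must carry columns ", paste(need, collapse = ", "))
  if (!"class" %in% names(df)) df$class <- classify_spine(df$dbar, config$tau)
  if (config$persistent_only && "persistent" %in% names(df))
    df <- df[df$persistent & !is.na(df$dbar), ]
  else df <- df[!is.na(df$dbar), ]
  if (config$n_pools < 100)
    warning("n_pools < 100 gives poor p-value resolution")

  df <- df[order(df$dendrite_id, df$position_um, df$spine_id), ]
  df$uid <- paste(df$dendrite_id, df$spine_id, sep = "/")

  pairs <- do.call(rbind, lapply(split(df, df$dendrite_id), function(dd) {
    pr <- nearest_neighbor_pairs(dd$position_um, ids = dd$uid,
                                 d_min = config$d_min, d_max = config$d_max)
    if (nrow(pr) == 0) return(NULL)
    pr$dendrite_id <- dd$dendrite_id[1]
    pr
  }))
  rownames(pairs) <- NULL
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no nearest-neighbour pair survives the distance filter")

  cls_levels <- c("increasing", "decreasing", "stable")
  cls <- match(df$class, cls_levels)
  ai <- match(pairs$a, df$uid)
  bi <- match(pairs$b, df$uid)
  dend <- as.integer(factor(df$dendrite_id))  # df sorted: blocks contiguous
  n_spines <- nrow(df)
  m <- nrow(pairs)

  frac4 <- function(cl) {
    a <- cl[ai]; b <- cl[bi]
    bi_ <- sum(a == 1L & b == 1L)
    bd_ <- sum(a == 2L & b == 2L)
    op_ <- sum((a == 1L & b == 2L) | (a == 2L & b == 1L))
    100 * c(bi_, bd_, bi_ + bd_, op_) / m
  }
  observed <- frac4(cls)
  metric_names <- c("both_increase", "both_decrease", "same_direction",
                    "opposite_direction")
  names(observed) <- metric_names

  null_mat <- with_seed(config$seed, {
    out <- matrix(NA_real_, nrow = config$n_pools, ncol = 4)
    for (p in seq_len(config$n_pools)) {
      perm <- order(dend, stats::runif(n_spines))
      out[p, ] <- frac4(cls[perm])
    }
    out
  })
  colnames(null_mat) <- metric_names

  med <- apply(null_mat, 2, stats::median)
  tail_used <- character(4)
  p_value <- numeric(4)
  for (k in 1:4) {
    side <- switch(config$tail,
                   upper = "upper", lower = "lower",
                   auto = if (observed[k] < med[k]) "lower" else "upper")
    k_tail <- if (side == "upper") sum(null_mat[, k] >= observed[k])
              else sum(null_mat[, k] <= observed[k])
    p_value[k] <- if (config$correction == "add_one")
      (k_tail + 1) / (config$n_pools + 1) else k_tail / config$n_pools
    tail_used[k] <- side
  }
  names(p_value) <- names(tail_used) <- metric_names

  per_dendrite <- do.call(rbind, lapply(
    split(seq_len(m), pairs$dendrite_id), function(rows) {
      pr <- pairs[rows, ]
      fr <- pair_fractions(pr, stats::setNames(df$class, df$uid))
      data.frame(dendrite_id = pr$dendrite_id[1], n_pairs = length(rows),
                 t(as.numeric(fr)) |> `colnames<-`(metric_names),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_dendrite) <- NULL

  structure(list(observed = observed, p_value = p_value,
                 tail_used = tail_used, null = null_mat,
                 n_pairs = m, n_spines = n_spines,
                 n_dendrites_paired = nrow(per_dendrite),
                 per_dendrite = per_dendrite, pairs = pairs,
                 class_counts = table(factor(df$class, cls_levels)),
                 config = config),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Nearest-neighbour clustered-plasticity test\n")
  cat(sprintf("  %d spine pairs on %d dendrites (%d persistent spines)\n",
              x$n_pairs, x$n_dendrites_paired, x$n_spines))
  cat(sprintf("  %d permutation pools, tau = %.3g, distances [%.1f, %.1f] um\n",
              x$config$n_pools, x$config$tau, x$config$d_min, x$config$d_max))
  tab <- data.frame(observed_pct = round(x$observed, 2),
                    null_median_pct = round(apply(x$null, 2, stats::median), 2),
                    p = signif(x$p_value, 3), tail = x$tail_used)
  print(tab)
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  print(object)
  cat("\nSpine classes: ",
      paste(names(object$class_counts), object$class_counts,
            sep = " = ", collapse = ", "), "\n")
  cat("Per-dendrite fractions (mean over dendrites with >= 1 pair):\n")
  print(round(colMeans(object$per_dendrite[, 3:6]), 2))
  invisible(object)
}

#' Plot the permutation null distributions of a clustering test
#'
#' One histogram per directional metric with the observed pooled percentage
#' marked; the tail at or beyond the mark is what the Monte Carlo p-value
#' sums.
#'
#' @param x a [cluster_test()] result.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cluster_test <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in colnames(x$null)) {
    graphics::hist(x$null[, k], breaks = 30, main = k,
                   xlab = "% of pairs (shuffled)", col = "grey85",
                   border = "grey60",
                   xlim = range(c(x$null[, k], x$observed[k])), ...)
    graphics::abline(v = x$observed[k], col = "firebrick", lwd = 2)
    graphics::mtext(sprintf("p = %.3g (%s)", x$p_value[k], x$tail_used[k]),
                    side = 3, line = -1.2, cex = 0.7)
  }
  invisible(x)
}
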