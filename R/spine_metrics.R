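#' Shaft-normalized spine size
#'
#' Spine fluorescence is a proxy for synaptic strength, but absolute
#' intensities vary with daily imaging conditions. The raw spine size is
#' therefore the background-subtracted spine ROI intensity normalized to the
#' background-subtracted adjacent-shaft intensity:
#' `(spine - background) / (shaft - background)`. Values where the spine ROI
#' is dimmer than the background clip to 0: sizes are non-negative by
#' definition and the bounds of the normalized change depend on that.
#'
#' @param spine_intensity,shaft_intensity,background_intensity numeric
#'   vectors (recycled to common length).
#' @param id optional spine identifiers used in error messages.
#' @return numeric vector of dimensionless sizes (>= 0).
#' @export
raw_spine_size <- function(spine_intensity, shaft_intensity,
                           background_intensity, id = NULL) {
  denom <- shaft_intensity - background_intensity
  bad <- which(!is.na(denom) & denom <= 0)
  if (length(bad)) {
    lab <- if (!is.null(id)) paste(id[bad], collapse = ", ")
           else paste("element", paste(bad, collapse = ", "))
    stop("degenerate denominator (shaft <= background) for spine(s): ", lab)
  }
  pmax((spine_intensity - background_intensity) / denom, 0)
}

#' Baseline-referenced normalized size change
#'
#' The change of a spine's size on day d relative to its baseline is
#' `(v_d - v_base) / (v_d + v_base)`: the baseline is subtracted and the
#' difference divided over the sum of the baseline and the respective
#' imaging-day value. For non-negative sizes this bounds every change in
#' `[-1, +1]`, with -1 attained exactly at full elimination (`v_d = 0`) and
#' +1 at formation from nothing (`v_base = 0`). Both sizes zero leaves the
#' change undefined and returns `NA` with a warning; table-level code
#' excludes such spine-sessions with a logged reason.
#'
#' @param v_d spine size on the imaging day (>= 0).
#' @param v_base baseline spine size (>= 0).
#' @return numeric vector of changes in `[-1, 1]` (NA where undefined).
#' @export
normalized_change <- function(v_d, v_base) {
  if (any(v_d < 0, na.rm = TRUE) || any(v_base < 0, na.rm = TRUE))
    stop("sizes must be non-negative")
  s <- v_d + v_base
  und <- !is.na(s) & s == 0
  if (any(und))
    warning(sum(und), " spine-session(s) with both sizes zero: change undefined")
  out <- (v_d - v_base) / s
  out[und] <- NA_real_
  out
}

#' Mean baseline size of a spine
#'
#' Arithmetic mean of the raw shaft-normalized sizes over the baseline
#' sessions at which the spine is present. A spine absent at every baseline
#' session has no baseline and yields `NA`; such spines are flagged
#' non-persistent and excluded from size-change analyses.
#'
#' @param sizes raw sizes, one per baseline session (NA where absent).
#' @return scalar baseline size, or `NA` if absent throughout baseline.
#' @export
baseline_size <- function(sizes) {
  if (all(is.na(sizes))) return(NA_real_)
  mean(sizes, na.rm = TRUE)
}

#' Per-spine normalized size changes and classification
#'
#' Computes, for every spine in the dataset, the raw shaft-normalized size at
#' each session where present, the mean baseline size, the per-session
#' normalized change for post-baseline sessions, the window-averaged change
#' (default window: all post-baseline sessions, i.e. days 1-4 under the
#' default schedule) and the increasing / decreasing / stable class at
#' threshold `tau`.
#'
#' Eligibility: the averaged change and class are defined only for
#' *persistent* spines, present at every baseline session and every window
#' session. Spines that appear or disappear contribute to turnover metrics
#' instead. The window average is taken over per-session changes, not over
#' paired-session presentation averages.
#'
#' @param dataset a [spine_dataset()].
#' @param window integer day labels to average changes over; `NULL` (default)
#'   uses all post-baseline sessions.
#' @param tau classification threshold in normalized-change units (default
#'   0.14, one standard deviation of baseline changes in control animals);
#'   the boundary `|change| == tau` classifies as stable.
#' @return a data.frame of class `size_change_table`, one row per spine:
#'   `dendrite_id`, `spine_id`, `position_um`, `baseline_size`, `persistent`,
#'   `dbar` (window-averaged change), `class`. Attribute `"session_changes"`
#'   holds the long per-session table (`day`, `size`, `delta`); attribute
#'   `"excluded"` logs spines without a defined average change and why.
#' @export
size_change_table <- function(dataset, window = NULL, tau = 0.14) {
  stopifnot(inherits(dataset, "spine_dataset"))
  sp <- dataset$spines
  base_days <- dataset$baseline_sessions
  post_days <- setdiff(dataset$sessions, base_days)
  if (is.null(window)) window <- post_days
  window <- as.integer(window)
  if (!all(window %in% post_days))
    stop("window must be a subset of the post-baseline sessions")

  sp$size <- NA_real_
  pres <- which(sp$present)
  sp$size[pres] <- raw_spine_size(
    sp$spine_intensity[pres], sp$shaft_intensity[pres],
    sp$background_intensity[pres],
    id = paste0(sp$dendrite_id[pres], "/", sp$spine_id[pres]))

  # spine x session matrices (rows in first-appearance order of the key)
  key <- paste(sp$dendrite_id, sp$spine_id, sep = "/")
  ukey <- unique(key)
  si <- match(key, ukey)
  di <- match(sp$day, dataset$sessions)
  ns <- length(ukey)
  nd <- length(dataset$sessions)
  size_mat <- matrix(NA_real_, ns, nd)
  pres_mat <- matrix(FALSE, ns, nd)
  size_mat[cbind(si, di)] <- sp$size
  pres_mat[cbind(si, di)] <- sp$present

  b_cols <- match(base_days, dataset$sessions)
  w_cols <- match(window, dataset$sessions)
  post_cols <- match(post_days, dataset$sessions)
  vbase <- rowMeans(size_mat[, b_cols, drop = FALSE], na.rm = TRUE)
  vbase[is.nan(vbase)] <- NA_real_
  base_full <- rowSums(pres_mat[, b_cols, drop = FALSE]) == length(b_cols)
  win_full <- rowSums(pres_mat[, w_cols, drop = FALSE]) == length(w_cols)
  persistent <- base_full & win_full

  delta_mat <- matrix(NA_real_, ns, nd)
  for (j in post_cols) {
    ok <- pres_mat[, j] & !is.na(vbase) & (size_mat[, j] + vbase) > 0
    delta_mat[ok, j] <- (size_mat[ok, j] - vbase[ok]) /
      (size_mat[ok, j] + vbase[ok])
  }
  dbar <- rowMeans(delta_mat[, w_cols, drop = FALSE])
  dbar[!persistent] <- NA_real_

  first <- match(ukey, key)
  out <- data.frame(
    dendrite_id = sp$dendrite_id[first], spine_id = sp$spine_id[first],
    position_um = sp$position_um[first], baseline_size = vbase,
    persistent = persistent, dbar = dbar,
    class = classify_spine(dbar, tau), stringsAsFactors = FALSE)
  ord <- order(out$dendrite_id, out$spine_id)
  out <- out[ord, ]
  rownames(out) <- NULL

  reason <- rep(NA_character_, ns)
  reason[!persistent & is.na(vbase)] <- "absent at all baseline sessions"
  reason[!persistent & !is.na(vbase) & !base_full] <-
    "absent at a baseline session"
  reason[!persistent & !is.na(vbase) & base_full] <-
    "absent at a window session"
  excluded <- data.frame(dendrite_id = sp$dendrite_id[first],
                         spine_id = sp$spine_id[first],
                         reason = reason,
                         stringsAsFactors = FALSE)[ord, ][!out$persistent, ]
  rownames(excluded) <- NULL

  attr(out, "session_changes") <- data.frame(
    dendrite_id = sp$dendrite_id, spine_id = sp$spine_id, day = sp$day,
    size = sp$size, delta = delta_mat[cbind(si, di)],
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "tau") <- tau
  attr(out, "window") <- window
  class(out) <- c("size_change_table", "data.frame")
  out
}

#' Spine addition, elimination and turnover rates
#'
#' For every dendrite and every session with a predecessor: the number of
#' newly added and newly eliminated spines divided by the total number of
#' spines on that dendritic segment at the previous session. The turnover
#' ratio is the sum of the addition and elimination rates. Dendrite-sessions
#' with no spines at the previous session have undefined rates and are
#' returned as `NA` with a message.
#'
#' @param dataset a [spine_dataset()].
#' @return data.frame with one row per dendrite and session transition:
#'   `dendrite_id`, `day`, `n_prev`, `n_added`, `n_eliminated`,
#'   `addition_rate`, `elimination_rate`, `turnover`.
#' @export
turnover_rates <- function(dataset) {
  stopifnot(inherits(dataset, "spine_dataset"))
  sp <- dataset$spines
  sessions <- dataset$sessions
  res <- list()
  for (did in unique(sp$dendrite_id)) {
    rows <- sp[sp$dendrite_id == did, ]
    pres <- tapply(rows$present, list(rows$spine_id, rows$day), any)
    pres <- pres[, as.character(sessions), drop = FALSE]
    pres[is.na(pres)] <- FALSE
    for (s in seq_along(sessions)[-1]) {
      prev <- pres[, s - 1]
      cur <- pres[, s]
      n_prev <- sum(prev)
      n_added <- sum(cur & !prev)
      n_elim <- sum(prev & !cur)
      if (n_prev == 0) {
        message("dendrite ", did, ", day ", sessions[s],
                ": no spines at previous session; rates undefined")
        ar <- er <- to <- NA_real_
      } else {
        ar <- n_added / n_prev
        er <- n_elim / n_prev
        to <- ar + er
      }
      res[[length(res) + 1]] <- data.frame(
        dendrite_id = did, day = sessions[s], n_prev = n_prev,
        n_added = n_added, n_eliminated = n_elim,
        addition_rate = ar, elimination_rate = er, turnover = to,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Spine density per dendrite and session
#'
#' Number of spines present divided by the traced segment length.
#'
#' @param dataset a [spine_dataset()].
#' @return data.frame `dendrite_id`, `day`, `n_present`, `length_um`,
#'   `density` (spines per micrometre).
#' @export
spine_density <- function(dataset) {
  stopifnot(inherits(dataset, "spine_dataset"))
  sp <- dataset$spines
  len <- stats::setNames(dataset$dendrites$length_um,
                         dataset$dendrites$dendrite_id)
  agg <- stats::aggregate(present ~ dendrite_id + day, data = sp, FUN = sum)
  names(agg)[names(agg) == "present"] <- "n_present"
  agg$length_um <- as.numeric(len[agg$dendrite_id])
  agg$density <- agg$n_present / agg$length_um
  agg[order(agg$dendrite_id, agg$day), , drop = FALSE]
}

#' Average a per-day series over adjacent session pairs
#'
#' Longitudinal metrics are presented as the average of values from two
#' adjacent imaging sessions (-3 and -2, -1 and 0, 1 and 2, and so on) to
#' increase clarity. Sessions are paired in schedule order; an odd leftover
#' session is dropped with a warning by default, or kept as a singleton.
#'
#' @param series named numeric vector, names are integer day labels.
#' @param leftover `"drop"` (default) or `"keep"` for an unpaired final
#'   session.
#' @return named numeric vector keyed by concatenated day labels
#'   (e.g. `"-3/-2"`).
#' @export
paired_session_average <- function(series, leftover = c("drop", "keep")) {
  leftover <- match.arg(leftover)
  days <- as.integer(names(series))
  ord <- order(days)
  series <- series[ord]
  days <- days[ord]
  n <- length(series)
  n_pairs <- n %/% 2
  out <- numeric(0)
  if (n_pairs > 0) {
    i <- seq_len(n_pairs) * 2L - 1L
    out <- (series[i] + series[i + 1]) / 2
    names(out) <- paste(days[i], days[i + 1], sep = "/")
  }
  if (n %% 2 == 1) {
    if (leftover == "keep") {
      out <- c(out, stats::setNames(series[n], as.character(days[n])))
    } else {
      warning("odd session count: dropping unpaired day ", days[n])
    }
  }
  out
}
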