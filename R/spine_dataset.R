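#' Longitudinal spine dataset
#'
#' Container for a longitudinal spine-annotation experiment: a long-format
#' table with one row per spine and imaging session, the ordered session day
#' labels, the baseline subset, and per-dendrite segment lengths. This is the
#' unit all spine analyses operate on; [simulate_spine_dataset()] produces it
#' and [read_spine_csv()] reads the same schema from annotation exports.
#'
#' @param spines data.frame with columns `dendrite_id`, `spine_id`,
#'   `position_um`, `day`, `present`, `spine_intensity`, `shaft_intensity`,
#'   `background_intensity` and optionally `true_size`, `true_change`
#'   (ground truth carried by the simulator). Intensity fields may be `NA`
#'   where `present` is `FALSE`.
#' @param sessions strictly increasing integer day labels.
#' @param baseline_sessions non-empty prefix of `sessions`.
#' @param dendrites data.frame with columns `dendrite_id`, `length_um`. If
#'   `NULL`, lengths default to the maximum annotated position per dendrite.
#' @param config optional `spine_sim_config` the data were generated from.
#' @param allow_readdition if `FALSE` (default), a spine that disappears and
#'   later reappears is rejected: eliminations are terminal.
#'
#' @return an object of class `spine_dataset`.
#' @export
spine_dataset <- function(spines, sessions, baseline_sessions,
                          dendrites = NULL, config = NULL,
                          allow_readdition = FALSE) {
  required <- c("dendrite_id", "spine_id", "position_um", "day", "present",
                "spine_intensity", "shaft_intensity", "background_intensity")
  missing_cols <- setdiff(required, names(spines))
  if (length(missing_cols))
    stop("spine table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  sessions <- as.integer(sessions)
  baseline_sessions <- as.integer(baseline_sessions)
  if (is.unsorted(sessions, strictly = TRUE))
    stop("session day labels must be strictly increasing")
  nb <- length(baseline_sessions)
  if (nb < 1 || !identical(baseline_sessions, sessions[seq_len(nb)]))
    stop("baseline_sessions must be a non-empty prefix of sessions")
  if (!all(spines$day %in% sessions))
    stop("spine table contains day labels not in sessions")
  spines$present <- as.logical(spines$present)

  if (!allow_readdition) {
    key <- paste(spines$dendrite_id, spines$spine_id, sep = "/")
    ord <- order(key, spines$day)
    pr <- spines$present[ord]
    k <- key[ord]
    n <- length(pr)
    if (n > 1) {
      same <- c(FALSE, k[-1] == k[-n])
      cs <- cumsum(pr)
      # count of present rows strictly before i, within i's spine
      start_cs <- cumsum(c(0, pr))[!same][cumsum(!same)]
      seen_before <- (c(0, cs[-n]) - start_cs) > 0
      # present again after an absence that followed a presence: re-addition
      bad <- same & pr & !c(FALSE, pr[-n]) & seen_before
      if (any(bad))
        stop("presence gap (spine absent then present again) found for spine ",
             k[which(bad)[1]],
             "; eliminations are terminal unless allow_readdition = TRUE")
    }
  }

  if (is.null(dendrites)) {
    len <- tapply(spines$position_um, spines$dendrite_id, max)
    dendrites <- data.frame(dendrite_id = names(len),
                            length_um = as.numeric(len),
                            stringsAsFactors = FALSE)
  }
  structure(list(spines = spines,
                 sessions = sessions,
                 baseline_sessions = baseline_sessions,
                 dendrites = dendrites,
                 config = config),
            class = "spine_dataset")
}

#' @export
print.spine_dataset <- function(x, ...) {
  n_sp <- length(unique(interaction(x$spines$dendrite_id, x$spines$spine_id)))
  cat(sprintf("Spine dataset: %d dendrites, %d spines, %d sessions\n",
              nrow(x$dendrites), n_sp, length(x$sessions)))
  cat(sprintf("  days: %s (baseline: %s)\n",
              paste(x$sessions, collapse = " "),
              paste(x$baseline_sessions, collapse = " ")))
  invisible(x)
}

#' @export
summary.spine_dataset <- function(object, ...) {
  dens <- spine_density(object)
  tr <- turnover_rates(object)
  cat(sprintf("Spine dataset: %d dendrites, %d sessions\n",
              nrow(object$dendrites), length(object$sessions)))
  cat(sprintf("  mean density: %.3f spines/um\n",
              mean(dens$density, na.rm = TRUE)))
  cat(sprintf("  mean turnover: %.3f per session\n",
              mean(tr$turnover, na.rm = TRUE)))
  invisible(list(density = dens, turnover = tr))
}

#' Write and read the spine-dataset CSV interchange format
#'
#' One row per spine and session with columns `dendrite_id`, `spine_id`,
#' `position_um`, `day`, `present`, `spine_intensity`, `shaft_intensity`,
#' `background_intensity` (plus `true_size`/`true_change` when simulated), a
#' comma-separated UTF-8 file with a header row and `.` decimal. A JSON
#' sidecar (same path with extension `.json`) stores the session schedule,
#' baseline subset, dendrite lengths and, when available, the generating
#' configuration, so `read_spine_csv(write_spine_csv(x))` is lossless.
#'
#' @param dataset a `spine_dataset`.
#' @param path CSV file path.
#' @param sidecar write (or read) the JSON sidecar; on read, when the sidecar
#'   is absent, `sessions`/`baseline_sessions` must be supplied.
#' @return `write_spine_csv` returns `path` invisibly; `read_spine_csv`
#'   returns a `spine_dataset`.
#' @export
write_spine_csv <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "spine_dataset"))
  utils::write.csv(dataset$spines, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(sessions = dataset$sessions,
                 baseline_sessions = dataset$baseline_sessions,
                 dendrites = dataset$dendrites)
    if (!is.null(dataset$config))
      meta$config <- unclass(dataset$config)[setdiff(
        names(dataset$config), c("contra_amp_map", "ipsi_amp_map"))]
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_spine_csv
#' @param baseline_sessions,sessions session metadata used when no sidecar is
#'   available (e.g. real annotation exports).
#' @param allow_readdition passed to [spine_dataset()].
#' @export
read_spine_csv <- function(path, sidecar = TRUE, sessions = NULL,
                           baseline_sessions = NULL,
                           allow_readdition = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dendrite_id", "spine_id", "position_um", "day", "present",
                "spine_intensity", "shaft_intensity", "background_intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(required, "true_size", "true_change"))
  if (length(extra))
    warning(path, ": ignoring unknown columns: ",
            paste(extra, collapse = ", "))
  if (!is.numeric(df$day) || any(df$day != as.integer(df$day)))
    stop(path, ": 'day' column must be integer day labels")
  df$day <- as.integer(df$day)
  if (is.character(df$present))
    df$present <- toupper(df$present) %in% c("TRUE", "T", "1")

  dendrites <- NULL
  cfg <- NULL
  sp <- sidecar_path(path)
  if (sidecar && file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(sessions)) sessions <- meta$sessions
    if (is.null(baseline_sessions)) baseline_sessions <- meta$baseline_sessions
    if (!is.null(meta$dendrites)) dendrites <- meta$dendrites
    cfg <- meta$config
  }
  if (is.null(sessions)) sessions <- sort(unique(df$day))
  if (is.null(baseline_sessions))
    stop("baseline_sessions must be given when no JSON sidecar is present")
  spine_dataset(df, sessions, baseline_sessions, dendrites = dendrites,
                config = cfg, allow_readdition = allow_readdition)
}

sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", ".json", path)
}
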