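#' Run the full synthetic spine-plasticity pipeline
#'
#' One-command replication of the synthetic experiment: simulate a
#' longitudinal spine dataset, write it to CSV, compute the per-dendrite
#' metric tables (density, turnover, size changes), run the
#' nearest-neighbour clustering Monte Carlo test, and write a JSON summary
#' plus a run manifest with seeds and file checksums. Re-running with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a [spine_sim_config()].
#' @param cluster_config a [clustering_config()].
#' @param stages character subset of `c("simulate", "metrics", "cluster")`
#'   to execute; later stages read the CSV written by earlier ones, and a
#'   missing upstream file raises an error naming the stage to run first.
#' @param input_csv spine CSV to use when `"simulate"` is not among the
#'   stages.
#' @param quiet suppress per-stage progress messages.
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(out_dir,
                         sim_config = spine_sim_config(),
                         cluster_config = clustering_config(),
                         stages = c("simulate", "metrics", "cluster"),
                         input_csv = NULL,
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  outputs <- list()
  csv_path <- if (!is.null(input_csv)) input_csv
              else file.path(out_dir, "spines.csv")

  if ("simulate" %in% stages) {
    say("simulate: generating ", sim_config$n_dendrites, " dendrites")
    ds <- simulate_spine_dataset(sim_config)
    write_spine_csv(ds, csv_path)
    outputs$spines_csv <- csv_path
  } else if (!file.exists(csv_path)) {
    stop("input CSV ", csv_path, " not found; run the 'simulate' stage ",
         "first or supply input_csv")
  } else {
    ds <- read_spine_csv(csv_path)
  }

  sct <- NULL
  if ("metrics" %in% stages) {
    sct <- size_change_table(ds, window = cluster_config$window,
                             tau = cluster_config$tau)
    dens <- spine_density(ds)
    turn <- suppressMessages(turnover_rates(ds))
    say(sprintf("metrics: %d spines (%d persistent), %d excluded from size analyses",
                nrow(sct), sum(sct$persistent), nrow(attr(sct, "excluded"))))
    utils::write.csv(as.data.frame(sct), file.path(out_dir, "size_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(dens, file.path(out_dir, "density.csv"),
                     row.names = FALSE)
    utils::write.csv(turn, file.path(out_dir, "turnover.csv"),
                     row.names = FALSE)
    outputs$size_changes_csv <- file.path(out_dir, "size_changes.csv")
    outputs$density_csv <- file.path(out_dir, "density.csv")
    outputs$turnover_csv <- file.path(out_dir, "turnover.csv")
  }

  if ("cluster" %in% stages) {
    if (is.null(sct)) {
      p <- file.path(out_dir, "size_changes.csv")
      if (!file.exists(p))
        stop("size-change table not found; run the 'metrics' stage first")
      sct <- utils::read.csv(p, stringsAsFactors = FALSE)
    }
    ct <- cluster_test(sct, cluster_config)
    say(sprintf("cluster: %d pairs on %d dendrites; p(both_decrease) = %.4g",
                ct$n_pairs, ct$n_dendrites_paired,
                ct$p_value["both_decrease"]))
    utils::write.csv(ct$pairs, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(ct$per_dendrite,
                     file.path(out_dir, "per_dendrite_fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ct$null),
                     file.path(out_dir, "null_fractions.csv"),
                     row.names = FALSE)
    summary_json <- lapply(names(ct$observed), function(k)
      list(observed = ct$observed[[k]], p = ct$p_value[[k]],
           tail = ct$tail_used[[k]]))
    names(summary_json) <- names(ct$observed)
    jsonlite::write_json(
      list(metrics = summary_json, n_pairs = ct$n_pairs,
           n_dendrites = ct$n_dendrites_paired,
           n_pools = cluster_config$n_pools),
      file.path(out_dir, "cluster_summary.json"),
      auto_unbox = TRUE, digits = NA)
    outputs$pairs_csv <- file.path(out_dir, "pairs.csv")
    outputs$per_dendrite_csv <- file.path(out_dir,
                                          "per_dendrite_fractions.csv")
    outputs$cluster_summary_json <- file.path(out_dir, "cluster_summary.json")
  }

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(sim = unclass(sim_config),
                            cluster = unclass(cluster_config)),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = paste("spineclust",
                 as.character(utils::packageVersion("spineclust"))),
    stages = stages,
    seeds = list(sim = sim_config$seed, cluster = cluster_config$seed),
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
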