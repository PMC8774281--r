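#' Pipeline configuration
#'
#' Every constant of the analysis in one declarative list, with the
#' method's defaults baked in. A YAML file with a subset of the keys can
#' override them.
#'
#' @param path optional YAML file whose keys override the defaults.
#' @param ... named overrides applied after the file.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    min_frames = 20L, max_gap = 3L, dt = DEFAULT_DT,
    scales = 1:50, a_tilde = 20L, r = 0.8,
    axis_combine = "or", normalization = "linear",
    corridor_factor = 1.27, corridor_min_um = 0.4, max_turn_deg = 120,
    corr_thresh = 0.7, dist_thresh_um = 1, min_overlap = 20L,
    msd_t_min = 0, msd_t_max = 4, msd_max_lag = 20L,
    xmin_policy = "sample_min")
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("PipelineConfig", "list"))
}

analyzeChannel <- function(ts, cfg) {
  params <- activeDetectionParams(a_tilde = cfg$a_tilde, r = cfg$r,
                                  axis_combine = cfg$axis_combine)
  labels <- list(); runs <- list(); flights <- list(); curves <- list()
  rejected <- character(0)
  for (tr in ts$trajectories) {
    maps <- cwtTrajectory(tr, scales = cfg$scales,
                          normalization = cfg$normalization)
    lab <- tryCatch(classifyActive(maps$x, maps$y, params),
                    error = function(e) NULL)
    if (is.null(lab)) { rejected <- c(rejected, trackId(tr)); next }
    labels[[trackId(tr)]] <- lab
    rr <- extractRuns(lab, tr)
    runs[[trackId(tr)]] <- rr
    ff <- mergeRunsToFlights(rr, tr, cfg$corridor_factor,
                             cfg$corridor_min_um, cfg$max_turn_deg)
    flights[[trackId(tr)]] <- ff
    curves[[trackId(tr)]] <-
      timeAveragedMSD(tr, max_lag = min(nrow(tr) - 1L, cfg$msd_max_lag))
  }
  runs_df <- do.call(rbind, c(runs, list(make.row.names = FALSE)))
  flights_df <- do.call(rbind, c(flights, list(make.row.names = FALSE)))
  list(labels = labels, runs = runs_df, flights = flights_df,
       curves = curves, rejected = rejected)
}

labelsTable <- function(labels) {
  do.call(rbind, c(lapply(labels, function(l) {
    data.frame(track_id = l$track_id, idx = seq_along(l$state),
               state = as.character(l$state))
  }), list(make.row.names = FALSE)))
}

lengthFitsTable <- function(x, kind, xmin = min(x)) {
  cmpr <- compareLengthModels(x, xmin = xmin)
  do.call(rbind, lapply(cmpr$fits, function(f) {
    data.frame(kind = kind, model = f$model,
               params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                              collapse = ";"),
               xmin = f$xmin, loglik = f$loglik, AIC = f$AIC,
               weight = unname(cmpr$weights[f$model]),
               winner = cmpr$winner == f$model)
  }))
}

#' Run the full trajectory-analysis pipeline for one cell
#'
#' read -> filter -> gap-fill -> CWT -> active-transport segmentation ->
#' (optional) co-movement split -> MSD fit -> heavy-tailed length-model
#' comparison, returning all tables and (optionally) writing them as CSV
#' plus a YAML run manifest.
#'
#' @param lyso_path organelle-channel track table (CSV; see [readTracks()]),
#'   or an already-parsed `TrackSet`.
#' @param cargo_path optional cargo-channel table or `TrackSet`; when
#'   absent, the co-movement stages are skipped (noted in the manifest).
#' @param config a `PipelineConfig`.
#' @param out_dir optional output directory for the CSV tables and
#'   manifest.
#' @param cell_id cell identifier (default from the organelle input).
#' @return A list of class `PipelineResult`: `labels`, `runs`, `flights`,
#'   `pairs` (or `NULL`), `msd` (pooled curve), `msd_fit`, `length_fits`,
#'   `summary` (one-row per-cell table), `manifest`.
#' @export
runPipeline <- function(lyso_path, cargo_path = NULL,
                        config = pipelineConfig(), out_dir = NULL,
                        cell_id = NULL) {
  lyso_raw <- if (inherits(lyso_path, "TrackSet")) lyso_path
              else readTracks(lyso_path, "organelle", cell_id, config$dt)
  if (is.null(cell_id)) cell_id <- lyso_raw$cell_id
  n_in <- length(lyso_raw)
  lyso <- fillGapsAll(filterTracks(lyso_raw, config$min_frames,
                                   config$max_gap), config$max_gap)

  have_cargo <- !is.null(cargo_path)
  pairs <- NULL
  groups <- list(all = lyso)
  if (have_cargo) {
    cargo_raw <- if (inherits(cargo_path, "TrackSet")) cargo_path
                 else readTracks(cargo_path, "cargo", cell_id, config$dt)
    cargo <- fillGapsAll(filterTracks(cargo_raw, config$min_frames,
                                      config$max_gap), config$max_gap)
    pairs <- detectComovement(lyso, cargo, scales = config$scales,
                              corr_thresh = config$corr_thresh,
                              dist_thresh = config$dist_thresh_um,
                              min_overlap = config$min_overlap)
    split <- splitByComovement(lyso, pairs)
    groups <- list(all = lyso, cargo_bearing = split$cargo_bearing,
                   remainder = split$remainder)
  }

  ch <- analyzeChannel(lyso, config)
  pooled <- pooledMSD(ch$curves)
  fit <- fitMSD(pooled, config$msd_t_min, config$msd_t_max)
  pct <- percentTimeActive(ch$labels)

  run_lengths <- ch$runs$l_um[ch$runs$l_um > 0]
  flight_lengths <- ch$flights$L_um[ch$flights$L_um > 0]
  length_fits <- rbind(
    if (length(run_lengths) >= 10) lengthFitsTable(run_lengths, "run"),
    if (length(flight_lengths) >= 10)
      lengthFitsTable(flight_lengths, "flight"))

  summary_df <- data.frame(
    cell_id = cell_id, n_tracks_in = n_in, n_tracks = length(lyso),
    n_runs = nrow(ch$runs), n_flights = nrow(ch$flights),
    pct_active = pct, alpha = fit$alpha, D_um2_s = fit$D, msd_r2 = fit$r2,
    mean_run_um = mean(ch$runs$l_um), mean_flight_um = mean(ch$flights$L_um),
    n_cargo_bearing = if (have_cargo) length(groups$cargo_bearing) else NA,
    pct_cargo_bearing = if (have_cargo && length(lyso) > 0)
      100 * length(groups$cargo_bearing) / length(lyso) else NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lysotraj")),
    cell_id = cell_id,
    config = lapply(unclass(config), function(v)
      if (length(v) > 1) paste(range(v), collapse = ":") else v),
    inputs = list(
      lyso = if (is.character(lyso_path)) lyso_path else "<TrackSet>",
      cargo = if (have_cargo && is.character(cargo_path)) cargo_path
              else if (have_cargo) "<TrackSet>" else NULL),
    comovement_stage = if (have_cargo) "run" else "skipped (no cargo channel)",
    counts = list(tracks_in = n_in, tracks_analyzed = length(lyso),
                  tracks_rejected_short = length(ch$rejected),
                  runs = nrow(ch$runs), flights = nrow(ch$flights),
                  pairs = if (have_cargo) nrow(pairs) else 0L))

  res <- structure(list(labels = labelsTable(ch$labels), runs = ch$runs,
                        flights = ch$flights, pairs = pairs, msd = pooled,
                        msd_fit = fit, length_fits = length_fits,
                        summary = summary_df, manifest = manifest,
                        groups = groups),
                   class = "PipelineResult")
  if (!is.null(out_dir)) writePipelineResult(res, out_dir)
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult '%s': %d tracks, %d runs, %d flights\n",
              x$summary$cell_id, x$summary$n_tracks, x$summary$n_runs,
              x$summary$n_flights))
  cat(sprintf("  alpha = %.3f, D = %.4g um^2/s, %.1f%% time active\n",
              x$summary$alpha, x$summary$D_um2_s, x$summary$pct_active))
  invisible(x)
}

writeCsvNum <- function(df, path) {
  # fixed 15-significant-digit formatting keeps re-runs byte-identical
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write all tables of a pipeline result
#'
#' @param res a `PipelineResult`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
writePipelineResult <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeCsvNum(res$labels, file.path(out_dir, "labels.csv"))
  writeCsvNum(res$runs, file.path(out_dir, "runs.csv"))
  writeCsvNum(res$flights, file.path(out_dir, "flights.csv"))
  if (!is.null(res$pairs))
    writeCsvNum(res$pairs, file.path(out_dir, "pairs.csv"))
  writeCsvNum(as.data.frame(res$msd), file.path(out_dir, "msd.csv"))
  if (!is.null(res$length_fits))
    writeCsvNum(res$length_fits, file.path(out_dir, "length_fits.csv"))
  writeCsvNum(res$summary, file.path(out_dir, "summary.csv"))
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Summarize and compare groups of per-cell results
#'
#' Takes a table of per-cell summaries (one row per cell, as produced by
#' [runPipeline()]) with a grouping column, reports per-group means of the
#' movement metrics, and tests each metric between two groups — the
#' Wilcoxon-Mann-Whitney test for unpaired groups, the two-tailed paired
#' t-test (matched by cell id) for paired ones.
#'
#' @param cells data.frame of per-cell summaries with columns `cell_id`, a
#'   grouping column and the metric columns.
#' @param group_col name of the grouping column.
#' @param metrics metric columns to summarize.
#' @param paired use the paired t-test (groups matched by `cell_id`).
#' @return List with `means` (group x metric table) and `tests` (data.frame
#'   of pairwise test results; empty, with a warning, when a group has
#'   fewer than 2 cells).
#' @export
summarizeGroups <- function(cells, group_col = "group",
                            metrics = c("alpha", "D_um2_s", "pct_active",
                                        "mean_run_um", "mean_flight_um"),
                            paired = FALSE) {
  metrics <- intersect(metrics, names(cells))
  g <- factor(cells[[group_col]])
  means <- stats::aggregate(cells[metrics], by = list(group = g), FUN = mean)
  tests <- data.frame(group_a = character(), group_b = character(),
                      metric = character(), test = character(),
                      statistic = numeric(), p_value = numeric())
  lev <- levels(g)
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    a <- cells[g == lev[i], , drop = FALSE]
    b <- cells[g == lev[j], , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L) {
      warning(sprintf("group comparison %s vs %s skipped: fewer than 2 cells",
                      lev[i], lev[j]))
      next
    }
    for (m in metrics) {
      tr <- if (paired)
        groupTest(a[[m]][order(a$cell_id)], b[[m]][order(b$cell_id)],
                  paired = TRUE, ids_a = sort(a$cell_id),
                  ids_b = sort(b$cell_id))
      else groupTest(a[[m]], b[[m]])
      tests <- rbind(tests, data.frame(group_a = lev[i], group_b = lev[j],
                                       metric = m, test = tr$test,
                                       statistic = tr$statistic,
                                       p_value = tr$p_value))
    }
  }
  list(means = means, tests = tests)
}
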