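#' @keywords internal
"_PACKAGE"

# Nominal frame interval of the acquisition this toolkit targets: resonant
# confocal time-lapse at ~5.11 frames per second.
DEFAULT_DT <- 0.1957

TRACK_COLS <- c("track_id", "frame", "time_s", "x_um", "y_um")

#' Construct a Trajectory object
#'
#' A `Trajectory` is a data.frame with columns `frame` (integer, >= 0),
#' `t` (seconds), `x`, `y` (micrometres) and `interpolated` (logical),
#' ordered by frame, carrying attributes `track_id` and `dt` (nominal frame
#' interval in seconds).
#'
#' @param frame integer frame indices, strictly increasing.
#' @param x,y coordinates in micrometres.
#' @param t time stamps in seconds; defaults to `frame * dt`.
#' @param track_id identifier for the track.
#' @param dt nominal frame interval in seconds.
#' @param interpolated logical flag per point; gap-filled points are TRUE.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(frame, x, y, t = NULL, track_id = "track",
                       dt = DEFAULT_DT, interpolated = FALSE) {
  frame <- as.integer(frame)
  if (length(frame) == 0L) stop("trajectory must have at least one point")
  if (any(frame < 0L)) stop("frame indices must be >= 0")
  if (is.unsorted(frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (is.null(t)) t <- frame * dt
  if (is.unsorted(t, strictly = TRUE))
    stop("time stamps must be strictly increasing with frame")
  interpolated <- rep_len(as.logical(interpolated), length(frame))
  if (interpolated[1L] || interpolated[length(frame)])
    stop("interpolated points cannot be first or last in a trajectory")
  out <- data.frame(frame = frame, t = as.numeric(t), x = as.numeric(x),
                    y = as.numeric(y), interpolated = interpolated)
  attr(out, "track_id") <- track_id
  attr(out, "dt") <- dt
  class(out) <- c("Trajectory", "data.frame")
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d points, frames %d-%d, dt = %.4g s\n",
              trackId(x), nrow(x), x$frame[1L], x$frame[nrow(x)],
              attr(x, "dt")))
  invisible(x)
}

#' Accessors for trajectory objects
#'
#' @param tr a `Trajectory`.
#' @return `trackId` returns the track identifier; `frameSpan` the temporal
#'   extent in frames (`last - first + 1`); `nPoints` the number of stored
#'   points.
#' @export
trackId <- function(tr) attr(tr, "track_id")

#' @rdname trackId
#' @export
frameSpan <- function(tr) tr$frame[nrow(tr)] - tr$frame[1L] + 1L

#' @rdname trackId
#' @export
nPoints <- function(tr) nrow(tr)

#' Construct a TrackSet
#'
#' A `TrackSet` bundles the trajectories of one imaging channel of one cell.
#'
#' @param trajectories list of `Trajectory` objects with unique track ids.
#' @param cell_id cell identifier.
#' @param channel `"organelle"` or `"cargo"`.
#' @return An object of class `TrackSet`.
#' @export
trackSet <- function(trajectories, cell_id = "cell",
                     channel = c("organelle", "cargo")) {
  channel <- match.arg(channel)
  ids <- vapply(trajectories, trackId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate track_id within a TrackSet: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trajectories) <- ids
  out <- list(cell_id = cell_id, channel = channel,
              trajectories = trajectories)
  class(out) <- "TrackSet"
  out
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet '%s' (%s channel): %d trajectories\n",
              x$cell_id, x$channel, length(x$trajectories)))
  invisible(x)
}

#' @export
length.TrackSet <- function(x) length(x$trajectories)

#' Read a trajectory table
#'
#' Reads a comma-separated track table with header
#' `track_id,frame,time_s,x_um,y_um` (the `time_s` column is optional; when
#' absent, times are reconstructed as `frame * dt`). One file holds all
#' tracks of one channel of one cell. Rows are grouped by `track_id` and
#' sorted by `frame`; no filtering is applied.
#'
#' @param path path to the CSV file.
#' @param channel channel tag, `"organelle"` or `"cargo"`.
#' @param cell_id cell identifier; defaults to the file name.
#' @param dt nominal frame interval used when `time_s` is absent.
#' @return A `TrackSet` with all parsed trajectories.
#' @export
readTracks <- function(path, channel = c("organelle", "cargo"),
                       cell_id = NULL, dt = DEFAULT_DT) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_time <- "time_s" %in% names(df)
  need <- setdiff(TRACK_COLS, "time_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed track table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(trackSet(list(), cell_id = cell_id, channel = channel))

  num_cols <- intersect(c("frame", "time_s", "x_um", "y_um"), names(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed row %d in %s: non-numeric or missing '%s'",
                   bad[1L] + 1L, path, cc))  # +1 for the header line
    df[[cc]] <- v
  }
  if (any(df$frame != round(df$frame)))
    stop("frame indices must be integers in ", path)

  dup <- duplicated(df[c("track_id", "frame")])
  if (any(dup)) {
    stop(sprintf("duplicate (track_id, frame) at row %d in %s",
                 which(dup)[1L] + 1L, path))
  }

  trajs <- lapply(split(df, factor(df$track_id, levels = unique(df$track_id))),
                  function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    tvec <- if (has_time) g$time_s else NULL
    this_dt <- if (has_time && nrow(g) > 1L)
      stats::median(diff(g$time_s) / diff(g$frame)) else dt
    trajectory(frame = g$frame, x = g$x_um, y = g$y_um, t = tvec,
               track_id = as.character(g$track_id[1L]), dt = this_dt)
  })
  trackSet(unname(trajs), cell_id = cell_id, channel = channel)
}

#' Write trajectories to a track table
#'
#' Inverse of [readTracks()]: writes the `track_id,frame,time_s,x_um,y_um`
#' dialect. Interpolated points are written like observed ones, so a
#' read-write-read cycle round-trips exactly.
#'
#' @param ts a `TrackSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(ts, path) {
  rows <- lapply(ts$trajectories, function(tr) {
    data.frame(track_id = trackId(tr), frame = tr$frame, time_s = tr$t,
               x_um = tr$x, y_um = tr$y)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(track_id = character(), frame = integer(),
                     time_s = numeric(), x_um = numeric(), y_um = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

maxGap <- function(tr) {
  if (nrow(tr) < 2L) return(0L)
  max(diff(tr$frame)) - 1L
}

#' Filter trajectories by span and gap size
#'
#' Retains trajectories whose temporal extent (`last - first + 1` frames) is
#' at least `min_frames` and whose internal gaps never exceed `max_gap`
#' missing frames. Order is preserved and the operation is idempotent.
#'
#' @param ts a `TrackSet`.
#' @param min_frames minimum frame span (default 20 frames, about 4 s at
#'   5.11 fps).
#' @param max_gap maximum number of consecutive missing frames (default 3).
#' @return The filtered `TrackSet`.
#' @export
filterTracks <- function(ts, min_frames = 20L, max_gap = 3L) {
  keep <- vapply(ts$trajectories, function(tr) {
    frameSpan(tr) >= min_frames && maxGap(tr) <= max_gap
  }, logical(1))
  trackSet(unname(ts$trajectories[keep]), cell_id = ts$cell_id,
           channel = ts$channel)
}

#' Fill frame gaps by linear interpolation
#'
#' Inserts the missing frames of a trajectory (all gaps must be at most
#' `max_gap` missing frames, i.e. the track must have passed
#' [filterTracks()]) by linear interpolation of `x`, `y` and `t`. Inserted
#' points carry `interpolated = TRUE`; observed points are untouched.
#'
#' @param tr a `Trajectory`.
#' @param max_gap largest tolerated gap (default 3 missing frames).
#' @return A `Trajectory` with consecutive frames.
#' @export
fillGaps <- function(tr, max_gap = 3L) {
  g <- maxGap(tr)
  if (g > max_gap)
    stop(sprintf("trajectory '%s' has a %d-frame gap (> %d); filter first",
                 trackId(tr), g, max_gap))
  if (g == 0L) return(tr)
  full <- seq(tr$frame[1L], tr$frame[nrow(tr)])
  x <- stats::approx(tr$frame, tr$x, xout = full)$y
  y <- stats::approx(tr$frame, tr$y, xout = full)$y
  t <- stats::approx(tr$frame, tr$t, xout = full)$y
  interp <- !(full %in% tr$frame)
  trajectory(frame = full, x = x, y = y, t = t, track_id = trackId(tr),
             dt = attr(tr, "dt"), interpolated = interp)
}

#' Fill gaps for every trajectory of a TrackSet
#'
#' @param ts a `TrackSet`.
#' @param max_gap largest tolerated gap.
#' @return A `TrackSet` of gap-free trajectories.
#' @export
fillGapsAll <- function(ts, max_gap = 3L) {
  trackSet(lapply(unname(ts$trajectories), fillGaps, max_gap = max_gap),
           cell_id = ts$cell_id, channel = ts$channel)
}
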