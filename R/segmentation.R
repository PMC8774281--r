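#' Parameters for active-transport detection
#'
#' @param a_tilde detection scale (frames) at which coefficients are
#'   thresholded; default 20.
#' @param r threshold pre-factor; default 0.8.
#' @param noise_scale wavelet scale used for the noise estimate; fixed at 2
#'   in the detection method.
#' @param mad_const consistency constant 0.6745 (the 0.75 normal quantile)
#'   turning a median absolute coefficient into a standard-deviation
#'   estimate.
#' @param axis_combine how the x and y axis thresholds combine: `"or"`
#'   (default; a point is active if either axis exceeds its own threshold)
#'   or `"norm"` (vector magnitude of the two coefficients against a
#'   combined threshold).
#' @return A list of class `ActiveDetectionParams`.
#' @export
activeDetectionParams <- function(a_tilde = 20L, r = 0.8, noise_scale = 2L,
                                  mad_const = 0.6745,
                                  axis_combine = c("or", "norm")) {
  axis_combine <- match.arg(axis_combine)
  if (r <= 0) stop("r must be > 0")
  if (a_tilde < 2L) stop("a_tilde must be >= 2")
  structure(list(a_tilde = as.integer(a_tilde), r = r,
                 noise_scale = as.integer(noise_scale),
                 mad_const = mad_const, axis_combine = axis_combine),
            class = "ActiveDetectionParams")
}

#' Robust noise estimate from scale-2 wavelet coefficients
#'
#' Estimates the standard deviation of the noise at scale 2 as
#' `median(|C[2, ]|) / 0.6745`.
#'
#' @param map a `WaveletMap` containing scale `noise_scale`.
#' @param noise_scale scale of the coefficients used; default 2.
#' @param mad_const consistency constant; default 0.6745.
#' @return Non-negative noise estimate.
#' @export
noiseSigma2 <- function(map, noise_scale = 2L, mad_const = 0.6745) {
  stats::median(abs(mapRow(map, noise_scale))) / mad_const
}

#' Universal threshold projected to the detection scale
#'
#' The wavelet-denoising universal threshold `r * sigma2 * sqrt(2 log N)`,
#' projected from scale 2 to scale `a_tilde`: `delta = r * sigma2 *
#' sqrt(2 log N) * sqrt(a_tilde / 2)`. Under the default `1/a` map
#' normalization the `sqrt(a_tilde / 2)` factor slightly over-tracks the
#' empirical scale growth of diffusive (random-walk) coordinate signals
#' (about `0.82 * sqrt(a/2)`), which is what keeps detection conservative
#' on passive motion.
#'
#' @param sigma2 noise estimate at scale 2 (see [noiseSigma2()]).
#' @param N number of data points of the trajectory after edge exclusion.
#' @param params an `ActiveDetectionParams`.
#' @return The threshold `delta >= 0`.
#' @export
universalThreshold <- function(sigma2, N, params = activeDetectionParams()) {
  if (N <= 1) stop("N must be > 1")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  params$r * sigma2 * sqrt(2 * log(N)) * sqrt(params$a_tilde / 2)
}

#' Classify trajectory points as active or passive
#'
#' Thresholds the scale-`a_tilde` wavelet coefficients of both axes against
#' per-axis universal thresholds computed from per-axis scale-2 noise
#' estimates and the shared point count `N` (points excluding the
#' `a_tilde`-point edge zone). The first and last `floor(a_tilde / 2)` time
#' points are excluded from classification (edge effects of the transform).
#'
#' @param map_x,map_y `WaveletMap`s of the two coordinate axes (identical
#'   shape).
#' @param params an `ActiveDetectionParams`.
#' @return An `ActiveLabels` object: list with `track_id`, factor `state`
#'   (`active` / `passive` / `excluded`, one per time point), the per-axis
#'   `sigma2` and `delta`, and `N`.
#' @export
classifyActive <- function(map_x, map_y, params = activeDetectionParams()) {
  if (!identical(dim(map_x$C), dim(map_y$C)))
    stop("x and y maps must share shape")
  T <- ncol(map_x$C)
  h <- params$a_tilde %/% 2L
  N <- T - 2L * h
  if (N <= 1L)
    stop(sprintf("track too short for detection at a_tilde = %d (T = %d)",
                 params$a_tilde, T))
  sx <- noiseSigma2(map_x, params$noise_scale, params$mad_const)
  sy <- noiseSigma2(map_y, params$noise_scale, params$mad_const)
  cx <- mapRow(map_x, params$a_tilde)
  cy <- mapRow(map_y, params$a_tilde)
  if (params$axis_combine == "or") {
    dx <- universalThreshold(sx, N, params)
    dy <- universalThreshold(sy, N, params)
    act <- abs(cx) > dx | abs(cy) > dy
    delta <- c(x = dx, y = dy)
  } else {
    dn <- universalThreshold(sqrt(sx^2 + sy^2), N, params)
    act <- sqrt(cx^2 + cy^2) > dn
    delta <- c(norm = dn)
  }
  state <- rep("passive", T)
  state[act] <- "active"
  if (h > 0L) state[c(seq_len(h), seq.int(T - h + 1L, T))] <- "excluded"
  structure(list(track_id = map_x$track_id,
                 state = factor(state,
                                levels = c("active", "passive", "excluded")),
                 sigma2 = c(x = sx, y = sy), delta = delta, N = N,
                 params = params),
            class = "ActiveLabels")
}

#' @export
print.ActiveLabels <- function(x, ...) {
  tab <- table(x$state)
  cat(sprintf(
    "ActiveLabels '%s': %d active / %d passive / %d excluded points\n",
    x$track_id, tab[["active"]], tab[["passive"]], tab[["excluded"]]))
  invisible(x)
}

# Perpendicular distances of points (px, py) from the line through A and B;
# degenerate chord (A == B) falls back to distance from A.
chordDistances <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  abs(dx * (py - ay) - dy * (px - ax)) / len
}

#' Extract runs from active labels
#'
#' Maximal contiguous stretches of `active` points (at least 2 points, so
#' the run has a chord) become runs. The run length `l` is the Euclidean
#' start-to-end displacement; `w_max` is the maximum perpendicular distance
#' of the run's points from the start-end chord.
#'
#' @param labels an `ActiveLabels`.
#' @param tr the aligned gap-filled `Trajectory`.
#' @return A data.frame with one row per run: `track_id`, `run_id`,
#'   `start_idx`, `end_idx` (1-based time indices), start/end coordinates,
#'   `l_um`, `duration_s`, `w_max_um`.
#' @export
extractRuns <- function(labels, tr) {
  if (length(labels$state) != nrow(tr))
    stop("labels and trajectory are not aligned")
  act <- labels$state == "active"
  r <- rle(as.vector(act))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(starts)
  out <- data.frame(track_id = rep(trackId(tr), n), run_id = seq_len(n),
                    start_idx = starts, end_idx = ends,
                    x0 = tr$x[starts], y0 = tr$y[starts],
                    x1 = tr$x[ends], y1 = tr$y[ends],
                    l_um = numeric(n), duration_s = numeric(n),
                    w_max_um = numeric(n))
  if (n == 0L) return(out)
  out$l_um <- sqrt((out$x1 - out$x0)^2 + (out$y1 - out$y0)^2)
  out$duration_s <- tr$t[ends] - tr$t[starts]
  for (i in seq_len(n)) {
    idx <- seq.int(starts[i], ends[i])
    out$w_max_um[i] <- max(chordDistances(tr$x[idx], tr$y[idx],
                                          out$x0[i], out$y0[i],
                                          out$x1[i], out$y1[i]))
  }
  out
}

# Angle in degrees [0, 180] between two 2D vectors; NA if either is null.
vectorAngle <- function(ux, uy, vx, vy) {
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- (ux * vx + uy * vy) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Merge runs into flights by the error-radius corridor method
#'
#' Greedy, time-ordered chain growth: the next run joins the current flight
#' iff (i) the turning angle between the start-end vectors of the flight's
#' last run and the candidate run is at most `max_turn`, and (ii) every
#' coordinate point of the candidate run lies within a corridor about the
#' line through the current flight's start and the candidate run's end. The
#' corridor's full width is `max(corridor_factor * W, corridor_min)`, where
#' `W` is the maximum perpendicular width of the current flight's points
#' about the flight's own start-end chord. Otherwise the candidate starts a
#' new flight. Every run belongs to exactly one flight; a lone run is a
#' one-run flight. The flight length `L` is the Euclidean distance from
#' flight start to flight end.
#'
#' @param runs run table of one track (see [extractRuns()]), time-ordered.
#' @param tr the aligned gap-filled `Trajectory`.
#' @param corridor_factor corridor width as a multiple of the flight's
#'   maximum width; default 1.27.
#' @param corridor_min lower bound on the corridor width in micrometres;
#'   default 0.4.
#' @param max_turn largest turning angle (degrees) allowed between
#'   consecutive runs of one flight; default 120.
#' @return A data.frame with one row per flight: `track_id`, `flight_id`,
#'   `n_runs`, `run_ids` (comma-separated member run ids), start/end
#'   coordinates, `L_um`, `corridor_width_um` (corridor in force when the
#'   last member joined; `corridor_min` for one-run flights).
#' @export
mergeRunsToFlights <- function(runs, tr, corridor_factor = 1.27,
                               corridor_min = 0.4, max_turn = 120) {
  n <- nrow(runs)
  empty <- data.frame(track_id = character(), flight_id = integer(),
                      n_runs = integer(), run_ids = character(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), L_um = numeric(),
                      corridor_width_um = numeric())
  if (n == 0L) return(empty)
  if (is.unsorted(runs$start_idx, strictly = TRUE) ||
      any(runs$end_idx[-n] >= runs$start_idx[-1]))
    stop("runs must be time-ordered and non-overlapping")

  flights <- list()
  cur <- list(members = 1L, width = corridor_min)
  flightWidth <- function(members) {
    # max perpendicular width of all member-run points about the chord from
    # the flight start to the last member's end
    idx <- unlist(lapply(members, function(m)
      seq.int(runs$start_idx[m], runs$end_idx[m])))
    a <- members[1L]; b <- members[length(members)]
    max(chordDistances(tr$x[idx], tr$y[idx],
                       runs$x0[a], runs$y0[a], runs$x1[b], runs$y1[b]))
  }
  closeFlight <- function(cur) {
    m <- cur$members
    a <- m[1L]; b <- m[length(m)]
    data.frame(track_id = runs$track_id[a], flight_id = NA_integer_,
               n_runs = length(m),
               run_ids = paste(runs$run_id[m], collapse = ","),
               x0 = runs$x0[a], y0 = runs$y0[a],
               x1 = runs$x1[b], y1 = runs$y1[b],
               L_um = sqrt((runs$x1[b] - runs$x0[a])^2 +
                           (runs$y1[b] - runs$y0[a])^2),
               corridor_width_um = cur$width)
  }
  for (i in seq_len(n)[-1]) {
    last <- cur$members[length(cur$members)]
    ang <- vectorAngle(runs$x1[last] - runs$x0[last],
                       runs$y1[last] - runs$y0[last],
                       runs$x1[i] - runs$x0[i],
                       runs$y1[i] - runs$y0[i])
    W <- flightWidth(cur$members)
    width <- max(corridor_factor * W, corridor_min)
    fs <- cur$members[1L]
    idx <- seq.int(runs$start_idx[i], runs$end_idx[i])
    d <- chordDistances(tr$x[idx], tr$y[idx],
                        runs$x0[fs], runs$y0[fs], runs$x1[i], runs$y1[i])
    if (!is.na(ang) && ang <= max_turn && all(d <= width / 2)) {
      cur$members <- c(cur$members, i)
      cur$width <- width
    } else {
      flights[[length(flights) + 1L]] <- closeFlight(cur)
      cur <- list(members = i, width = corridor_min)
    }
  }
  flights[[length(flights) + 1L]] <- closeFlight(cur)
  out <- do.call(rbind, flights)
  out$flight_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Percentage of time spent in active transport
#'
#' Pooled over the labelled tracks of one cell: `100 * active points /
#' (active + passive points)` — excluded edge points do not count toward
#' the denominator.
#'
#' @param labels_list list of `ActiveLabels` (one per track).
#' @return Percentage in `[0, 100]`.
#' @export
percentTimeActive <- function(labels_list) {
  if (inherits(labels_list, "ActiveLabels")) labels_list <- list(labels_list)
  states <- unlist(lapply(labels_list, function(l) as.character(l$state)))
  n_act <- sum(states == "active")
  n_tot <- sum(states != "excluded")
  if (n_tot == 0L) stop("no non-excluded points")
  100 * n_act / n_tot
}

#' Turning angles between consecutive runs
#'
#' One angle per consecutive run pair within each track (irrespective of
#' what happens between the runs), pooled across tracks.
#'
#' @param runs run table (possibly several tracks; see [extractRuns()]).
#' @return Numeric vector of angles in degrees, each in `[0, 180]`.
#' @export
turningAngles <- function(runs) {
  out <- numeric(0)
  for (id in unique(runs$track_id)) {
    g <- runs[runs$track_id == id, , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      ang <- vectorAngle(g$x1[i] - g$x0[i], g$y1[i] - g$y0[i],
                         g$x1[i + 1L] - g$x0[i + 1L],
                         g$y1[i + 1L] - g$y0[i + 1L])
      if (!is.na(ang)) out <- c(out, ang)
    }
  }
  out
}
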