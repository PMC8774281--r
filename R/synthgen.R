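#' Configuration for the synthetic trajectory generator
#'
#' Bundles every knob of the stop-and-go simulator. Defaults emulate the
#' acquisition and motion regime the analysis targets: ~5.11 frames/s
#' sampling, lognormal run lengths traversed at ~1 um/s by motor transport,
#' exponential diffusive pauses long enough that roughly 10-15% of time is
#' active, slow passive diffusion, and sub-pixel localization noise.
#'
#' @param seed integer seed fixing the output bit-for-bit; `NULL` leaves the
#'   RNG state untouched.
#' @param dt frame interval in seconds (default 0.1957, i.e. 5.11 fps).
#' @param n_steps number of trajectory points.
#' @param sigma_loc localization noise s.d. per axis in micrometres
#'   (default 0.03, sub-pixel confocal tracking).
#' @param D_passive diffusion coefficient of passive phases in um^2/s
#'   (default 0.005).
#' @param speed run speed in um/s (default 1).
#' @param run_model run-length model: list with `name`
#'   (`"lognormal"`, `"stretched_exponential"`, `"power_law"`,
#'   `"exponential"`) and its parameters (defaults: lognormal mu = -0.193,
#'   sigma = 0.804, the regime of measured lysosomal runs).
#' @param pause_model pause-duration model: list with `name`
#'   (`"exponential"`) and `mean_s` (default 8 s, giving ~12% active time).
#' @param turn_sd_deg s.d. (degrees) of the wrapped-normal rotation between
#'   consecutive run directions (default 30; large values, e.g. 150, give a
#'   reversal-heavy regime).
#' @param offset_scale stationary RMS distance (um) of the mean-reverting
#'   cargo offset for co-moving pairs (default 0.3).
#' @param offset_relax_s relaxation time (s) of the offset (default 0.6).
#' @param track_id identifier given to generated tracks.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = NULL, dt = 0.1957, n_steps = 1000L,
                      sigma_loc = 0.03, D_passive = 0.005, speed = 1,
                      run_model = list(name = "lognormal", mu = -0.193,
                                       sigma = 0.804),
                      pause_model = list(name = "exponential", mean_s = 8),
                      turn_sd_deg = 30, offset_scale = 0.3,
                      offset_relax_s = 0.6, track_id = "sim") {
  stopifnot(dt > 0, n_steps >= 2, sigma_loc >= 0, D_passive >= 0,
            speed > 0, offset_scale >= 0, offset_relax_s > 0)
  structure(list(seed = seed, dt = dt, n_steps = as.integer(n_steps),
                 sigma_loc = sigma_loc, D_passive = D_passive,
                 speed = speed, run_model = run_model,
                 pause_model = pause_model, turn_sd_deg = turn_sd_deg,
                 offset_scale = offset_scale,
                 offset_relax_s = offset_relax_s, track_id = track_id),
            class = "SimConfig")
}

applySeed <- function(cfg) if (!is.null(cfg$seed)) set.seed(cfg$seed)

drawRunLength <- function(m, n = 1L) {
  switch(m$name,
    lognormal = stats::rlnorm(n, m$mu, m$sigma),
    stretched_exponential = rStretchedExp(n, m$lambda, m$beta),
    power_law = rPowerLaw(n, m$gamma, m$xmin),
    exponential = stats::rexp(n, m$lambda),
    stop("unknown run-length model: ", m$name))
}

drawPauseDuration <- function(m, n = 1L) {
  switch(m$name,
    exponential = stats::rexp(n, 1 / m$mean_s),
    constant = rep(m$mean_s, n),
    stop("unknown pause-duration model: ", m$name))
}

finishTrack <- function(x, y, cfg, track_id = cfg$track_id) {
  n <- length(x)
  if (cfg$sigma_loc > 0) {
    x <- x + stats::rnorm(n, 0, cfg$sigma_loc)
    y <- y + stats::rnorm(n, 0, cfg$sigma_loc)
  }
  trajectory(frame = 0:(n - 1L), x = x, y = y, track_id = track_id,
             dt = cfg$dt)
}

#' Simulate a free 2D Brownian trajectory
#'
#' Gaussian increments with per-axis variance `2 * D_passive * dt`, plus
#' i.i.d. localization noise on every point.
#'
#' @param cfg a `SimConfig`.
#' @return A `Trajectory`.
#' @export
simBrownian <- function(cfg = simConfig()) {
  applySeed(cfg)
  sd_step <- sqrt(2 * cfg$D_passive * cfg$dt)
  x <- cumsum(c(0, stats::rnorm(cfg$n_steps - 1L, 0, sd_step)))
  y <- cumsum(c(0, stats::rnorm(cfg$n_steps - 1L, 0, sd_step)))
  finishTrack(x, y, cfg)
}

#' Simulate a constant-velocity (ballistic) trajectory
#'
#' @param cfg a `SimConfig` (`speed` is the velocity magnitude).
#' @param direction_deg direction of motion in degrees (default 35).
#' @return A `Trajectory`.
#' @export
simBallistic <- function(cfg = simConfig(), direction_deg = 35) {
  applySeed(cfg)
  th <- direction_deg * pi / 180
  t <- (0:(cfg$n_steps - 1L)) * cfg$dt
  finishTrack(cfg$speed * t * cos(th), cfg$speed * t * sin(th), cfg)
}

#' Simulate Brownian motion confined to a reflecting disc
#'
#' Free Gaussian steps; whenever a step leaves the disc of the given radius
#' (centered at the start), the position is reflected radially back inside.
#'
#' @param cfg a `SimConfig`.
#' @param radius disc radius in micrometres.
#' @return A `Trajectory`.
#' @export
simConfined <- function(cfg = simConfig(), radius = 0.3) {
  if (radius <= 0) stop("radius must be > 0")
  applySeed(cfg)
  sd_step <- sqrt(2 * cfg$D_passive * cfg$dt)
  x <- numeric(cfg$n_steps); y <- numeric(cfg$n_steps)
  for (i in seq_len(cfg$n_steps - 1L)) {
    px <- x[i] + stats::rnorm(1, 0, sd_step)
    py <- y[i] + stats::rnorm(1, 0, sd_step)
    r <- sqrt(px^2 + py^2)
    while (r > radius) {
      f <- (2 * radius - r) / r   # radial reflection about the boundary
      if (f < 0) f <- 0           # pathological huge step: clamp to center
      px <- px * f; py <- py * f
      r <- sqrt(px^2 + py^2)
    }
    x[i + 1L] <- px; y[i + 1L] <- py
  }
  finishTrack(x, y, cfg)
}

#' Simulate a stop-and-go trajectory with ground truth
#'
#' Alternating phases: an active run whose length is drawn from the
#' configured run-length model, traversed in a straight line at the
#' configured speed (each run's direction is the previous one rotated by a
#' wrapped-normal angle), then a passive Brownian pause of a drawn
#' duration. The per-point ground-truth state and the planted run
#' boundaries/lengths are recorded; localization noise is added last.
#'
#' @param cfg a `SimConfig`.
#' @param start_phase `"pause"` (default) or `"run"`.
#' @return List with `trajectory` (a `Trajectory`) and `truth`: list with
#'   `states` (`"run"`/`"passive"` per point, on the noiseless path),
#'   `runs` (data.frame `start_idx`, `end_idx`, `length_um` of planted
#'   runs; `length_um` is the realized chord, equal to the drawn length
#'   unless truncated by the track end) and `drawn_lengths` (all lengths
#'   drawn, including a possibly truncated final one).
#' @export
simStopAndGo <- function(cfg = simConfig(), start_phase = c("pause", "run")) {
  start_phase <- match.arg(start_phase)
  applySeed(cfg)
  n <- cfg$n_steps
  x <- numeric(n); y <- numeric(n)
  state <- character(n); state[1L] <- "passive"
  sd_step <- sqrt(2 * cfg$D_passive * cfg$dt)
  theta <- stats::runif(1, 0, 2 * pi)
  turn_sd <- cfg$turn_sd_deg * pi / 180
  runs <- list(); drawn <- numeric(0)
  i <- 1L
  running <- start_phase == "run"
  first <- TRUE
  while (i < n) {
    if (running) {
      l <- drawRunLength(cfg$run_model)
      drawn <- c(drawn, l)
      if (!first) theta <- theta + stats::rnorm(1, 0, turn_sd)
      k <- max(2L, round((l / cfg$speed) / cfg$dt))  # steps in this run
      step <- l / k
      k_eff <- min(k, n - i)
      for (j in seq_len(k_eff)) {
        x[i + j] <- x[i + j - 1L] + step * cos(theta)
        y[i + j] <- y[i + j - 1L] + step * sin(theta)
      }
      # each point after the first is labelled by the phase of the step
      # arriving at it, so state counts match phase durations exactly
      state[i + seq_len(k_eff)] <- "run"
      runs[[length(runs) + 1L]] <-
        data.frame(start_idx = i, end_idx = i + k_eff,
                   length_um = step * k_eff)
      i <- i + k_eff
    } else {
      dur <- drawPauseDuration(cfg$pause_model)
      k <- max(1L, round(dur / cfg$dt))
      k_eff <- min(k, n - i)
      x[i + seq_len(k_eff)] <- x[i] + cumsum(stats::rnorm(k_eff, 0, sd_step))
      y[i + seq_len(k_eff)] <- y[i] + cumsum(stats::rnorm(k_eff, 0, sd_step))
      state[i + seq_len(k_eff)] <- "passive"
      i <- i + k_eff
    }
    running <- !running
    first <- FALSE
  }
  truth <- list(states = state,
                runs = if (length(runs)) do.call(rbind, runs)
                       else data.frame(start_idx = integer(),
                                       end_idx = integer(),
                                       length_um = numeric()),
                drawn_lengths = drawn)
  list(trajectory = finishTrack(x, y, cfg), truth = truth)
}

# Ornstein-Uhlenbeck updates with stationary per-axis s.d. `sd_stat` and
# relaxation time `tau`.
ouSeries <- function(n, dt, tau, sd_stat, init = NULL) {
  phi <- exp(-dt / tau)
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  o <- numeric(n)
  o[1L] <- if (is.null(init)) stats::rnorm(1, 0, sd_stat) else init
  for (i in seq_len(n - 1L))
    o[i + 1L] <- o[i] * phi + stats::rnorm(1, 0, innov_sd)
  o
}

#' Simulate an organelle-cargo trajectory pair with ground truth
#'
#' Co-moving pairs: the cargo follows the organelle's (noiseless)
#' stop-and-go path plus a mean-reverting (Ornstein-Uhlenbeck) offset with
#' stationary RMS distance `offset_scale`, plus independent localization
#' noise — so wavelet correlations are high but below 1. Independent pairs:
#' two independently fluctuating tracks; the hard-negative variant anchors
#' both as confined motions whose anchors sit `target_dist` apart, so the
#' mean center-to-center distance stays below the co-movement distance gate
#' while the motions share nothing.
#'
#' @param cfg a `SimConfig`.
#' @param comoving generate a truly co-moving pair?
#' @param target_dist anchor separation (um) for the independent
#'   hard-negative pair; default 0.8.
#' @param confinement_sd per-axis stationary s.d. (um) of the hard-negative
#'   confined motions; default 0.2.
#' @return List with `lyso` and `cargo` `Trajectory` objects and `truth`
#'   (list with `comoving` flag).
#' @export
simPair <- function(cfg = simConfig(), comoving = TRUE, target_dist = 0.8,
                    confinement_sd = 0.2) {
  applySeed(cfg)
  n <- cfg$n_steps
  if (comoving) {
    base_cfg <- cfg; base_cfg$seed <- NULL; base_cfg$sigma_loc <- 0
    sg <- simStopAndGo(base_cfg)
    bx <- sg$trajectory$x; by <- sg$trajectory$y
    sd_axis <- cfg$offset_scale / sqrt(2)
    ox <- ouSeries(n, cfg$dt, cfg$offset_relax_s, sd_axis)
    oy <- ouSeries(n, cfg$dt, cfg$offset_relax_s, sd_axis)
    lyso <- finishTrack(bx, by, cfg, paste0(cfg$track_id, "_lyso"))
    cargo <- finishTrack(bx + ox, by + oy, cfg,
                         paste0(cfg$track_id, "_cargo"))
  } else {
    # two independent confined (OU) motions about anchors target_dist apart
    ang <- stats::runif(1, 0, 2 * pi)
    ax <- target_dist * cos(ang); ay <- target_dist * sin(ang)
    tau <- 2  # seconds; slow enough to put power at many wavelet scales
    lx <- ouSeries(n, cfg$dt, tau, confinement_sd)
    ly <- ouSeries(n, cfg$dt, tau, confinement_sd)
    cx <- ax + ouSeries(n, cfg$dt, tau, confinement_sd)
    cy <- ay + ouSeries(n, cfg$dt, tau, confinement_sd)
    lyso <- finishTrack(lx, ly, cfg, paste0(cfg$track_id, "_lyso"))
    cargo <- finishTrack(cx, cy, cfg, paste0(cfg$track_id, "_cargo"))
  }
  list(lyso = lyso, cargo = cargo, truth = list(comoving = comoving))
}

#' Generate a TrackSet of simulated trajectories
#'
#' @param n_tracks number of trajectories.
#' @param cfg a `SimConfig`; its `seed` (if any) seeds the whole set.
#' @param kind `"stopgo"`, `"brownian"`, `"ballistic"` or `"confined"`.
#' @param cell_id,channel passed to [trackSet()].
#' @param ... extra arguments for the chosen simulator.
#' @return List with `tracks` (a `TrackSet`) and `truths` (per-track ground
#'   truth for `"stopgo"`, else `NULL`).
#' @export
simTrackSet <- function(n_tracks, cfg = simConfig(),
                        kind = c("stopgo", "brownian", "ballistic",
                                 "confined"),
                        cell_id = "simcell", channel = "organelle", ...) {
  kind <- match.arg(kind)
  applySeed(cfg)
  cfg$seed <- NULL
  trajs <- vector("list", n_tracks)
  truths <- if (kind == "stopgo") vector("list", n_tracks) else NULL
  for (i in seq_len(n_tracks)) {
    cfg$track_id <- sprintf("%s_%03d", kind, i)
    if (kind == "stopgo") {
      sg <- simStopAndGo(cfg)
      trajs[[i]] <- sg$trajectory
      truths[[i]] <- sg$truth
    } else {
      trajs[[i]] <- switch(kind, brownian = simBrownian(cfg),
                           ballistic = simBallistic(cfg, ...),
                           confined = simConfined(cfg, ...))
    }
  }
  list(tracks = trackSet(trajs, cell_id = cell_id, channel = channel),
       truths = truths)
}
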