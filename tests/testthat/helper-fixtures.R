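# Shared helpers: small programmatic fixtures and independent oracles.

# Write a track-table CSV from vectors; returns the path.
writeTrackFixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Three-track fixture with 25 / 19 / 40 frames (track B spans 19 frames).
threeTrackFixture <- function() {
  mk <- function(id, frames) data.frame(track_id = id, frame = frames,
                                        time_s = frames * 0.1957,
                                        x_um = frames * 0.01,
                                        y_um = -frames * 0.02)
  writeTrackFixture(rbind(mk("A", 0:24), mk("B", 0:18), mk("C", 0:39)))
}

# Independent brute-force CWT oracle: explicit double loop over (scale, t0)
# with the centered, cell-integrated Haar kernel.
naiveCWT <- function(s, scales, normalization = "linear") {
  T <- length(s); P <- max(scales)
  padded <- c(numeric(P), s, numeric(P))
  C <- matrix(0, length(scales), T)
  for (i in seq_along(scales)) {
    a <- scales[i]; h <- a %/% 2
    w <- if (a %% 2 == 0) c(rep(1, h), rep(-1, h))
         else c(rep(1, h), 0, rep(-1, h))
    norm <- switch(normalization, none = 1, sqrt = sqrt(a), linear = a)
    for (t0 in seq_len(T)) {
      idx <- (t0 - h):(t0 - h + a - 1)
      C[i, t0] <- sum(w * padded[idx + P]) / norm
    }
  }
  C
}

# Hand-rolled ActiveLabels for geometry tests.
makeLabels <- function(states, track_id = "T") {
  structure(list(track_id = track_id,
                 state = factor(states,
                                levels = c("active", "passive", "excluded"))),
            class = "ActiveLabels")
}

# Trajectory straight from coordinate vectors (consecutive frames).
makeTraj <- function(x, y, track_id = "T", dt = 0.1957) {
  trajectory(frame = seq_along(x) - 1L, x = x, y = y, track_id = track_id,
             dt = dt)
}

# Turning angles between consecutive flights of one flight table.
flightTurningAngles <- function(fl) {
  if (nrow(fl) < 2) return(numeric(0))
  vapply(seq_len(nrow(fl) - 1L), function(i) {
    u <- c(fl$x1[i] - fl$x0[i], fl$y1[i] - fl$y0[i])
    v <- c(fl$x1[i + 1] - fl$x0[i + 1], fl$y1[i + 1] - fl$y0[i + 1])
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(NA_real_)
    acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
  }, numeric(1))
}

# Build a mixed synthetic "cell": n_pairs organelle-cargo pairs (first
# n_comoving truly co-moving) plus n_solo unpaired stop-and-go organelles.
makePairedCell <- function(n_pairs = 6, n_comoving = 3, n_solo = 4,
                           n_steps = 400, seed_base = 500) {
  lyso <- list(); cargo <- list()
  cfg0 <- simConfig(n_steps = n_steps)
  for (i in seq_len(n_pairs)) {
    cfg <- cfg0; cfg$seed <- seed_base + i
    cfg$track_id <- sprintf("pair%02d", i)
    p <- simPair(cfg, comoving = i <= n_comoving)
    lyso[[length(lyso) + 1L]] <- p$lyso
    cargo[[length(cargo) + 1L]] <- p$cargo
  }
  for (i in seq_len(n_solo)) {
    cfg <- cfg0; cfg$seed <- seed_base + 100 + i
    cfg$track_id <- sprintf("solo%02d", i)
    lyso[[length(lyso) + 1L]] <- simStopAndGo(cfg)$trajectory
  }
  list(lyso = trackSet(lyso, cell_id = "simcell", channel = "organelle"),
       cargo = trackSet(cargo, cell_id = "simcell", channel = "cargo"),
       comoving_ids = sprintf("pair%02d_lyso", seq_len(n_comoving)))
}
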