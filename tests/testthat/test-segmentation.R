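test_that("scale-2 noise estimate matches its defining formula", {
  # craft a map whose scale-2 row has known absolute coefficients
  mkmap <- function(row2) {
    C <- rbind(0, row2)
    structure(list(C = C, edge = C == Inf, scales = 1:2,
                   normalization = "linear", track_id = "m", axis = "x"),
              class = "WaveletMap")
  }
  expect_equal(noiseSigma2(mkmap(rep(c(0.6745, -0.6745), 10))), 1)
  expect_equal(noiseSigma2(mkmap(rep(0, 20))), 0)
  expect_error(noiseSigma2(cwtSeries(rnorm(30), scales = c(1, 3))),
               "scale 2")

  # i.i.d. Gaussian positions: scale-2 coefficient is (s[t-1]-s[t])/2,
  # so sigma2 estimates sigma/sqrt(2) (MAD consistency at the median)
  set.seed(41)
  sigma <- 3
  m <- cwtSeries(rnorm(1e4, sd = sigma), 1:2)
  expect_equal(noiseSigma2(m), sigma / sqrt(2), tolerance = 0.05)
})

test_that("universal threshold follows the projected formula", {
  p1 <- activeDetectionParams(r = 1)
  expect_equal(universalThreshold(1, 100, p1),
               sqrt(2 * log(100)) * sqrt(10), tolerance = 1e-12)
  expect_equal(universalThreshold(0, 100, p1), 0)
  # proportional in r; monotone in N and a_tilde
  p2 <- activeDetectionParams(r = 2)
  expect_equal(universalThreshold(1.3, 50, p2),
               2 * universalThreshold(1.3, 50, p1))
  expect_gt(universalThreshold(1, 1000, p1), universalThreshold(1, 100, p1))
  expect_gt(universalThreshold(1, 100, activeDetectionParams(a_tilde = 30)),
            universalThreshold(1, 100, activeDetectionParams(a_tilde = 20)))
  expect_error(universalThreshold(1, 1, p1), "N")
})

test_that("directed motion is detected against noise, noise stays passive", {
  # a ballistic segment embedded in localization noise: the noise sets the
  # threshold and the whole segment interior is flagged active
  set.seed(8)
  n <- 300
  x <- rnorm(n, sd = 0.02); y <- rnorm(n, sd = 0.02)
  seg <- 100:200
  x[seg] <- x[seg] + (seq_along(seg) - 1) * 0.1957 * cos(0.6)
  y[seg] <- y[seg] + (seq_along(seg) - 1) * 0.1957 * sin(0.6)
  tr <- makeTraj(x, y)
  maps <- cwtTrajectory(tr)
  lab <- classifyActive(maps$x, maps$y)
  expect_equal(sum(lab$state == "excluded"), 20L)
  expect_equal(mean(lab$state[110:190] == "active"), 1)
  expect_lt(mean(lab$state[c(11:85, 215:290)] == "active"), 0.05)

  # on a short track the threshold's sqrt(2 log N) factor is small enough
  # that even uniform noiseless motion exceeds it everywhere
  trb <- simBallistic(simConfig(seed = 3, n_steps = 50, sigma_loc = 0))
  mapsb <- cwtTrajectory(trb)
  expect_equal(percentTimeActive(classifyActive(mapsb$x, mapsb$y)), 100)

  # pure localization noise around a fixed point: conservative detection
  set.seed(9)
  trn <- makeTraj(rnorm(1000, sd = 0.03), rnorm(1000, sd = 0.03))
  mapsn <- cwtTrajectory(trn)
  labn <- classifyActive(mapsn$x, mapsn$y)
  expect_lt(percentTimeActive(labn), 5)

  # the vector-norm axis combination is available and also conservative
  labv <- classifyActive(mapsn$x, mapsn$y,
                         activeDetectionParams(axis_combine = "norm"))
  expect_lt(percentTimeActive(labv), 5)
})

test_that("false-positive active fraction on free diffusion is small", {
  fps <- vapply(1:8, function(i) {
    tr <- simBrownian(simConfig(seed = 700 + i, n_steps = 1000))
    maps <- cwtTrajectory(tr)
    percentTimeActive(classifyActive(maps$x, maps$y))
  }, numeric(1))
  expect_lt(mean(fps), 5)
  expect_lt(max(fps), 5)
})

test_that("runs are extracted with chord length and maximum width", {
  # straight 2 um active stretch along x
  states <- c(rep("excluded", 3), rep("passive", 2), rep("active", 5),
              rep("passive", 2), rep("excluded", 3))
  tr <- makeTraj(x = c(0, 0, 0, 0, 0, 0, 0.5, 1, 1.5, 2, 2, 2, 2, 2, 2),
                 y = rep(0, 15))
  rr <- extractRuns(makeLabels(states), tr)
  expect_equal(nrow(rr), 1L)
  expect_equal(rr$start_idx, 6L)
  expect_equal(rr$end_idx, 10L)
  expect_equal(rr$l_um, 2)
  expect_equal(rr$w_max_um, 0)
  expect_equal(rr$duration_s, 4 * 0.1957)

  # right-angle "L" of two 1 um legs: chord sqrt(2), corner point at
  # distance 1/sqrt(2) from the chord
  trL <- makeTraj(x = c(0, 1, 1), y = c(0, 0, 1))
  rrL <- extractRuns(makeLabels(rep("active", 3)), trL)
  expect_equal(rrL$l_um, sqrt(2))
  expect_equal(rrL$w_max_um, 1 / sqrt(2))

  # no active points -> empty table; singleton active points are dropped
  expect_equal(nrow(extractRuns(makeLabels(rep("passive", 5)),
                                makeTraj(1:5, 1:5))), 0L)
  expect_equal(nrow(extractRuns(
    makeLabels(c("passive", "active", "passive")), makeTraj(1:3, 1:3))), 0L)
})

test_that("corridor merging joins collinear runs and rejects turns/offsets", {
  # two collinear runs separated by a short pause on the same line
  x <- c(0, 1, 2, 2.1, 2.2, 3.2, 4.2)
  tr <- makeTraj(x, rep(0, 7))
  states <- c("active", "active", "active", "passive", "active", "active",
              "active")
  rr <- extractRuns(makeLabels(states), tr)
  expect_equal(nrow(rr), 2L)
  fl <- mergeRunsToFlights(rr, tr)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$n_runs, 2L)
  expect_equal(fl$L_um, 4.2)

  # a 150-degree turn exceeds the 120-degree filter: no merge
  x2 <- c(0, 1, 2, 2, 2 + cos(150 * pi / 180), 2 + 2 * cos(150 * pi / 180))
  y2 <- c(0, 0, 0, 0, sin(150 * pi / 180), 2 * sin(150 * pi / 180))
  tr2 <- makeTraj(x2, y2)
  rr2 <- extractRuns(makeLabels(c("active", "active", "active", "passive",
                                  "active", "active")), tr2)
  expect_equal(nrow(rr2), 2L)
  expect_equal(nrow(mergeRunsToFlights(rr2, tr2)), 2L)

  # second run laterally offset 1 um from a straight, thin first run:
  # corridor max(1.27 * ~0, 0.4)/2 = 0.2 um cannot reach it
  x3 <- c(0, 1, 2, 2, 2.5, 3.5)
  y3 <- c(0, 0, 0, 1, 1, 1)
  tr3 <- makeTraj(x3, y3)
  rr3 <- extractRuns(makeLabels(c("active", "active", "active", "passive",
                                  "active", "active")), tr3)
  expect_equal(nrow(mergeRunsToFlights(rr3, tr3)), 2L)

  # empty input stays empty
  expect_equal(nrow(mergeRunsToFlights(rr3[0, ], tr3)), 0L)
})

test_that("flight partition conserves runs on simulated tracks", {
  for (s in c(21, 22, 23)) {
    sg <- simStopAndGo(simConfig(seed = s, n_steps = 800))
    maps <- cwtTrajectory(sg$trajectory)
    rr <- extractRuns(classifyActive(maps$x, maps$y), sg$trajectory)
    if (nrow(rr) == 0) next
    fl <- mergeRunsToFlights(rr, sg$trajectory)
    expect_equal(sum(fl$n_runs), nrow(rr))
    members <- unlist(strsplit(fl$run_ids, ","))
    expect_setequal(as.integer(members), rr$run_id)
    expect_false(anyDuplicated(members) > 0)
    # lone runs become one-run flights, so every flight has >= 1 member
    expect_true(all(fl$n_runs >= 1))
  }
})

test_that("percent time active is pooled simple arithmetic", {
  l1 <- makeLabels(c(rep("excluded", 2), rep("active", 10),
                     rep("passive", 10), rep("excluded", 2)))
  l2 <- makeLabels(c(rep("excluded", 2), rep("active", 20),
                     rep("passive", 20), rep("excluded", 2)))
  expect_equal(percentTimeActive(list(l1, l2)), 50)
  expect_equal(percentTimeActive(makeLabels(rep("active", 5))), 100)
  expect_equal(percentTimeActive(makeLabels(rep("passive", 5))), 0)
  expect_error(percentTimeActive(makeLabels(rep("excluded", 4))),
               "non-excluded")
})

test_that("turning angles between consecutive runs span [0, 180]", {
  runsDF <- function(coords) {
    do.call(rbind, lapply(seq_along(coords), function(i) {
      cc <- coords[[i]]
      data.frame(track_id = "T", run_id = i, start_idx = 2 * i,
                 end_idx = 2 * i + 1, x0 = cc[1], y0 = cc[2], x1 = cc[3],
                 y1 = cc[4], l_um = NA, duration_s = NA, w_max_um = NA)
    }))
  }
  collinear <- runsDF(list(c(0, 0, 1, 0), c(2, 0, 3, 0)))
  expect_equal(turningAngles(collinear), 0)
  reversal <- runsDF(list(c(0, 0, 1, 0), c(1, 0, 0, 0)))
  expect_equal(turningAngles(reversal), 180)
  perp <- runsDF(list(c(0, 0, 1, 0), c(1, 0, 1, 1)))
  expect_equal(turningAngles(perp), 90)
  # fewer than two runs: no angles
  expect_length(turningAngles(collinear[1, ]), 0L)
})

test_that("planted runs above the detectability floor are recovered", {
  # the universal threshold sets a chord floor ~2*delta (~0.6-0.7 um at the
  # default noise level); runs clearly above it must be found, with the
  # a_tilde/2 boundary tolerance of the detection scale
  hits <- c(); n_runs <- 0L
  for (s in 1:10) {
    sg <- simStopAndGo(simConfig(seed = 100 + s, n_steps = 1000))
    maps <- cwtTrajectory(sg$trajectory)
    lab <- classifyActive(maps$x, maps$y)
    act <- lab$state == "active"
    pr <- sg$truth$runs
    pr <- pr[pr$start_idx > 10 & pr$end_idx < 990 & pr$length_um >= 1, ]
    if (nrow(pr) == 0) next
    h <- mapply(function(s0, e0) any(act[max(1, s0 - 10):min(1000, e0 + 10)]),
                pr$start_idx, pr$end_idx)
    hits <- c(hits, h); n_runs <- n_runs + nrow(pr)
  }
  expect_gt(n_runs, 50)
  expect_gte(mean(hits), 0.9)
})

test_that("stop-and-go detection lands in the reported active-time range", {
  pct <- vapply(1:8, function(s) {
    sg <- simStopAndGo(simConfig(seed = 100 + s, n_steps = 1000))
    maps <- cwtTrajectory(sg$trajectory)
    percentTimeActive(classifyActive(maps$x, maps$y))
  }, numeric(1))
  # generator plants ~12% active time; detection should land nearby,
  # inside the 5-30% band reported for intracellular vesicles
  expect_gt(mean(pct), 5)
  expect_lt(mean(pct), 30)
})

test_that("default corridor factor minimizes flight turning-angle memory", {
  acByFactor <- function(cf) {
    xs <- c(); ys <- c()
    for (s in 1:60) {
      sg <- simStopAndGo(simConfig(seed = 4000 + s, n_steps = 1000,
                                   pause_model = list(name = "exponential",
                                                      mean_s = 1.5),
                                   turn_sd_deg = 25))
      maps <- cwtTrajectory(sg$trajectory)
      rr <- extractRuns(classifyActive(maps$x, maps$y), sg$trajectory)
      fl <- mergeRunsToFlights(rr, sg$trajectory, corridor_factor = cf)
      ta <- flightTurningAngles(fl)
      ta <- ta[!is.na(ta)]
      if (length(ta) >= 2) {
        xs <- c(xs, ta[-length(ta)]); ys <- c(ys, ta[-1])
      }
    }
    stats::cor(xs, ys)
  }
  ac_def <- acByFactor(1.27)
  expect_lte(ac_def, acByFactor(0.8) + 1e-12)
  expect_lte(ac_def, acByFactor(2.0) + 1e-12)
})
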