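#' Time-averaged mean square displacement of one trajectory
#'
#' For each lag `k = 0..max_lag` frames, the mean over all start frames `i`
#' of `(x[i+k] - x[i])^2 + (y[i+k] - y[i])^2`. Lag 0 is included with MSD 0
#' by convention.
#'
#' @param tr a gap-filled `Trajectory`.
#' @param max_lag largest lag in frames; default `min(span - 1, 20)` so
#'   short tracks still contribute to small lags (20 frames is about 4 s at
#'   5.11 fps, the standard fit window).
#' @return An `MSDCurve`: data.frame with `lag_s`, `msd_um2`, `n_tracks`
#'   (all 1 here) and attribute `dt`.
#' @export
timeAveragedMSD <- function(tr, max_lag = NULL) {
  n <- nrow(tr)
  if (n > 1L && any(diff(tr$frame) != 1L))
    stop("trajectory has gaps; run fillGaps() first")
  if (is.null(max_lag)) max_lag <- min(n - 1L, 20L)
  if (max_lag >= n) stop("max_lag must be smaller than the track span")
  dt <- attr(tr, "dt")
  msd <- vapply(seq_len(max_lag), function(k) {
    i <- seq_len(n - k)
    mean((tr$x[i + k] - tr$x[i])^2 + (tr$y[i + k] - tr$y[i])^2)
  }, numeric(1))
  out <- data.frame(lag_s = c(0, seq_len(max_lag)) * dt,
                    msd_um2 = c(0, msd), n_tracks = 1L)
  attr(out, "dt") <- dt
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Pool MSD curves across tracks
#'
#' Unweighted mean across tracks at each lag of the shared grid; lags
#' reached by only part of the tracks are averaged over the contributing
#' tracks, with `n_tracks` recording how many.
#'
#' @param curves list of `MSDCurve`s on a common `dt` grid.
#' @return A pooled `MSDCurve`.
#' @export
pooledMSD <- function(curves) {
  if (!length(curves)) stop("no curves to pool")
  dts <- vapply(curves, function(cv) attr(cv, "dt"), numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("curves must share the lag grid (equal dt)")
  lags <- sort(unique(unlist(lapply(curves, function(cv) cv$lag_s))))
  acc <- numeric(length(lags)); cnt <- integer(length(lags))
  for (cv in curves) {
    i <- match(cv$lag_s, lags)
    acc[i] <- acc[i] + cv$msd_um2
    cnt[i] <- cnt[i] + 1L
  }
  out <- data.frame(lag_s = lags, msd_um2 = acc / cnt, n_tracks = cnt)
  attr(out, "dt") <- dts[1L]
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Fit MSD ~ t^alpha by log-log least squares
#'
#' Fits a straight line to `(log t, log MSD)` over lags in
#' `(t_min, t_max]`. The slope is the anomalous-diffusion exponent `alpha`;
#' the generalized diffusion coefficient uses the 2D convention
#' `MSD = 4 D t^alpha`, i.e. `D = exp(intercept) / 4`.
#'
#' @param curve an `MSDCurve`.
#' @param t_min,t_max fit window in seconds; defaults 0 and 4 (the interval
#'   where experimental curves are straight before confinement bends them).
#' @return An `MSDFit`: list with `alpha`, `D` (um^2/s), `r2`, `t_min`,
#'   `t_max`, `n_lags`.
#' @export
fitMSD <- function(curve, t_min = 0, t_max = 4) {
  sel <- curve$lag_s > t_min & curve$lag_s <= t_max
  if (sum(sel) < 3L) stop("need at least 3 lags inside the fit window")
  if (any(curve$msd_um2[sel] <= 0))
    stop("MSD must be positive on the fit window")
  lt <- log(curve$lag_s[sel]); lm_ <- log(curve$msd_um2[sel])
  fit <- stats::lm(lm_ ~ lt)
  co <- stats::coef(fit)
  ss_tot <- sum((lm_ - mean(lm_))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(alpha = unname(co[2L]), D = exp(unname(co[1L])) / 4,
                 r2 = r2,
                 t_min = t_min, t_max = t_max, n_lags = sum(sel)),
            class = "MSDFit")
}

#' @export
print.MSDFit <- function(x, ...) {
  cat(sprintf(
    "MSD fit over (%g, %g] s (%d lags): alpha = %.3f, D = %.4g um^2/s, R2 = %.4f\n",
    x$t_min, x$t_max, x$n_lags, x$alpha, x$D, x$r2))
  invisible(x)
}
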