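#' Haar mother wavelet
#'
#' The square-shaped, zero-mean kernel: +1 on the first half of its unit
#' support, -1 on the second half, 0 elsewhere.
#'
#' @param u dimensionless coordinate (vectorized).
#' @return +1 for `0 <= u < 1/2`, -1 for `1/2 <= u < 1`, 0 otherwise.
#' @export
haarWavelet <- function(u) {
  ifelse(u >= 0 & u < 0.5, 1, ifelse(u >= 0.5 & u < 1, -1, 0))
}

# Discrete Haar kernel of width `a`, centered on the anchor point: unit
# weights +1 on the half-support before the anchor, -1 on the half after.
# Weights are the exact integrals of the scaled wavelet over the sample
# cells, which keeps every kernel zero-sum: even widths give a/2 positive
# then a/2 negative unit weights; odd widths get a zero weight on the
# anchor cell itself (and width 1 is identically zero). Zero-sum kernels
# make the coefficient map invariant to the mean level of the signal.
haarKernel <- function(a) {
  if (a < 1L) stop("scale must be >= 1")
  h <- a %/% 2L
  if (a %% 2L == 0L) c(rep(1, h), rep(-1, h)) else c(rep(1, h), 0, rep(-1, h))
}

#' Continuous wavelet transform of a uniformly sampled series
#'
#' Computes the Haar-kernel wavelet coefficient map `C[a, t0]` of a series:
#' for each integer scale `a` and time point `t0`, the inner product of the
#' signal with the Haar kernel of width `a` centered at `t0` (positive
#' half-support before `t0`, negative half after), scaled by the `1/a`
#' prefactor. The coefficient is thus the difference of the local signal
#' averages over the two half-windows, halved — a local displacement probe
#' at time scale `a`. Columns whose kernel support extends past either end
#' of the series are computed on the zero-padded signal and flagged
#' edge-affected per scale (columns within `a/2` of an edge).
#'
#' @param s numeric series, uniformly sampled.
#' @param scales integer scales, default `1:50`.
#' @param normalization `"linear"` (default; prefactor `1/a`), `"sqrt"`
#'   (prefactor `1/sqrt(a)`) or `"none"` (unnormalized sum). Offered for
#'   sensitivity checks; active-transport detection assumes `"linear"`,
#'   under which the scale-`a` row of a diffusive (random-walk) signal has
#'   standard deviation close to (about 0.82 times) `sqrt(a/2)` times the
#'   scale-2 row's — the projection [universalThreshold()] uses. For i.i.d.
#'   noise the unnormalized rows grow as `sqrt(a)`.
#' @param track_id,axis labels stored in the map.
#' @return A `WaveletMap`: list with matrix `C` (rows = scales, columns =
#'   time points), logical matrix `edge` of the same shape, `scales`,
#'   `normalization`, `track_id` and `axis`.
#' @export
cwtSeries <- function(s, scales = 1:50,
                      normalization = c("linear", "sqrt", "none"),
                      track_id = NA_character_, axis = NA_character_) {
  normalization <- match.arg(normalization)
  scales <- as.integer(scales)
  if (any(scales < 1L)) stop("scales must be positive integers")
  T <- length(s)
  if (T < max(scales))
    stop(sprintf("series length (%d) shorter than largest scale (%d)",
                 T, max(scales)))
  P <- max(scales)
  padded <- c(numeric(P), s, numeric(P))
  # prefix sums over padded: sum of padded[i..j] = cs[j + 1] - cs[i]
  cs <- c(0, cumsum(padded))
  sumS <- function(i, j) cs[j + P + 1L] - cs[i + P]  # i..j in signal index
  C <- matrix(0, nrow = length(scales), ncol = T,
              dimnames = list(scale = scales, NULL))
  edge <- matrix(FALSE, nrow = length(scales), ncol = T)
  t0 <- seq_len(T)
  for (i in seq_along(scales)) {
    a <- scales[i]
    h <- a %/% 2L
    if (h > 0L) {
      pos <- sumS(t0 - h, t0 - 1L)                       # half before t0
      neg <- if (a %% 2L == 0L) sumS(t0, t0 + h - 1L)    # half after
             else sumS(t0 + 1L, t0 + h)                  # skip anchor cell
      C[i, ] <- pos - neg
    }
    norm <- switch(normalization, none = 1, sqrt = sqrt(a), linear = a)
    if (norm != 1) C[i, ] <- C[i, ] / norm
    edge[i, ] <- t0 <= h | t0 > T - h
  }
  structure(list(C = C, edge = edge, scales = scales,
                 normalization = normalization,
                 track_id = track_id, axis = axis),
            class = "WaveletMap")
}

#' @export
print.WaveletMap <- function(x, ...) {
  cat(sprintf("WaveletMap (track '%s', axis %s): %d scales x %d time points\n",
              x$track_id, x$axis, nrow(x$C), ncol(x$C)))
  invisible(x)
}

# Row of the coefficient matrix at a given scale; errors if absent.
mapRow <- function(map, scale) {
  i <- match(scale, map$scales)
  if (is.na(i)) stop("scale ", scale, " not present in WaveletMap")
  map$C[i, ]
}

#' Wavelet maps of a trajectory
#'
#' Applies [cwtSeries()] independently to the x and y coordinate series of a
#' gap-filled trajectory.
#'
#' @param tr a `Trajectory` with consecutive frames (see [fillGaps()]).
#' @param scales integer scales, default `1:50`.
#' @param normalization passed to [cwtSeries()].
#' @return A list with elements `x` and `y`, each a `WaveletMap` of
#'   identical shape.
#' @export
cwtTrajectory <- function(tr, scales = 1:50,
                          normalization = c("linear", "sqrt", "none")) {
  normalization <- match.arg(normalization)
  if (nrow(tr) > 1L && any(diff(tr$frame) != 1L))
    stop("trajectory '", trackId(tr), "' has gaps; run fillGaps() first")
  list(x = cwtSeries(tr$x, scales, normalization, trackId(tr), "x"),
       y = cwtSeries(tr$y, scales, normalization, trackId(tr), "y"))
}

#' Export a wavelet map as CSV
#'
#' Rows are scales, columns time indices.
#'
#' @param map a `WaveletMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWaveletMap <- function(map, path) {
  df <- as.data.frame(map$C)
  names(df) <- paste0("t", seq_len(ncol(map$C)))
  df <- cbind(scale = map$scales, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
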