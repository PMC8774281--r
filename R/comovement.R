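#' Find temporally overlapping organelle-cargo pairs
#'
#' For every pair of one organelle-channel and one cargo-channel track from
#' the same cell, returns the shared frame interval (both tracks gap-filled,
#' so the intersection of their frame ranges) and the per-frame
#' center-to-center distances, for pairs overlapping at least `min_overlap`
#' frames.
#'
#' @param lyso,cargo gap-filled `TrackSet`s of the two channels.
#' @param min_overlap minimum overlap in frames (default 20, the
#'   track-length floor of the upstream filter).
#' @return A list of `PairOverlap` objects: lists with `lyso_id`,
#'   `cargo_id`, `frames` (shared frame indices) and `dist` (per-frame
#'   distances, micrometres).
#' @export
findPairOverlaps <- function(lyso, cargo, min_overlap = 20L) {
  out <- list()
  for (lt in lyso$trajectories) {
    for (ct in cargo$trajectories) {
      f0 <- max(lt$frame[1L], ct$frame[1L])
      f1 <- min(lt$frame[nrow(lt)], ct$frame[nrow(ct)])
      if (f1 - f0 + 1L < min_overlap) next
      frames <- seq.int(f0, f1)
      li <- match(frames, lt$frame)
      ci <- match(frames, ct$frame)
      d <- sqrt((lt$x[li] - ct$x[ci])^2 + (lt$y[li] - ct$y[ci])^2)
      out[[length(out) + 1L]] <-
        structure(list(lyso_id = trackId(lt), cargo_id = trackId(ct),
                       frames = frames, dist = d),
                  class = "PairOverlap")
    }
  }
  out
}

#' Pearson correlation of two wavelet coefficient maps
#'
#' Restricts both maps to the given overlap columns and correlates the
#' flattened coefficient matrices (all scales by overlap time points).
#' Symmetric in its arguments. With `per_scale = TRUE` the per-scale row
#' correlations are averaged instead.
#'
#' @param map_a,map_b `WaveletMap`s of the same axis.
#' @param cols_a,cols_b column indices of the overlap within each map (equal
#'   length); default all columns.
#' @param per_scale average per-scale correlations instead of flattening.
#' @return Correlation in `[-1, 1]`.
#' @export
waveletCorrelation <- function(map_a, map_b, cols_a = NULL, cols_b = NULL,
                               per_scale = FALSE) {
  if (is.null(cols_a)) cols_a <- seq_len(ncol(map_a$C))
  if (is.null(cols_b)) cols_b <- seq_len(ncol(map_b$C))
  A <- map_a$C[, cols_a, drop = FALSE]
  B <- map_b$C[, cols_b, drop = FALSE]
  if (!identical(dim(A), dim(B)))
    stop("overlap submatrices must have identical shape")
  if (per_scale) {
    rs <- vapply(seq_len(nrow(A)), function(i) {
      if (stats::sd(A[i, ]) == 0 || stats::sd(B[i, ]) == 0) NA_real_
      else stats::cor(A[i, ], B[i, ])
    }, numeric(1))
    if (all(is.na(rs))) stop("undefined correlation: zero variance")
    return(mean(rs, na.rm = TRUE))
  }
  if (stats::sd(as.vector(A)) == 0 || stats::sd(as.vector(B)) == 0)
    stop("undefined correlation: zero variance in a coefficient matrix")
  stats::cor(as.vector(A), as.vector(B))
}

#' Classify one organelle-cargo pair as co-moving or not
#'
#' A pair is co-moving iff the same-axis wavelet-map correlations satisfy
#' `Px > corr_thresh` and `Py > corr_thresh` and the time-averaged
#' center-to-center distance is below `dist_thresh`.
#'
#' @param po a `PairOverlap` (see [findPairOverlaps()]).
#' @param lyso_maps,cargo_maps lists with `x` and `y` `WaveletMap`s of the
#'   two tracks (see [cwtTrajectory()]).
#' @param lyso_tr,cargo_tr the gap-filled trajectories (used to map shared
#'   frames to map columns).
#' @param corr_thresh correlation threshold; default 0.7.
#' @param dist_thresh distance threshold in micrometres; default 1.
#' @param per_scale passed to [waveletCorrelation()].
#' @return A one-row data.frame (`PairResult`): `lyso_id`, `cargo_id`,
#'   `overlap_start`, `overlap_end` (frames), `n_overlap`, `Px`, `Py`,
#'   `mean_dist_um`, `is_comoving`.
#' @export
classifyPair <- function(po, lyso_maps, cargo_maps, lyso_tr, cargo_tr,
                         corr_thresh = 0.7, dist_thresh = 1,
                         per_scale = FALSE) {
  li <- match(po$frames, lyso_tr$frame)
  ci <- match(po$frames, cargo_tr$frame)
  if (anyNA(li) || anyNA(ci))
    stop("overlap frames missing from a trajectory; gap-fill first")
  Px <- waveletCorrelation(lyso_maps$x, cargo_maps$x, li, ci, per_scale)
  Py <- waveletCorrelation(lyso_maps$y, cargo_maps$y, li, ci, per_scale)
  md <- mean(po$dist)
  data.frame(lyso_id = po$lyso_id, cargo_id = po$cargo_id,
             overlap_start = po$frames[1L],
             overlap_end = po$frames[length(po$frames)],
             n_overlap = length(po$frames),
             Px = Px, Py = Py, mean_dist_um = md,
             is_comoving = Px > corr_thresh & Py > corr_thresh &
                           md < dist_thresh)
}

#' Detect co-movement for all pairs of two channels
#'
#' Convenience wrapper: finds overlaps, computes wavelet maps and classifies
#' every pair.
#'
#' @param lyso,cargo gap-filled `TrackSet`s.
#' @param scales wavelet scales; default `1:50`.
#' @param corr_thresh,dist_thresh,min_overlap,per_scale see
#'   [classifyPair()] and [findPairOverlaps()].
#' @return A data.frame of `PairResult` rows (zero rows if no pair
#'   overlaps). Pairs whose correlation is undefined (zero variance) are
#'   dropped with a warning.
#' @export
detectComovement <- function(lyso, cargo, scales = 1:50, corr_thresh = 0.7,
                             dist_thresh = 1, min_overlap = 20L,
                             per_scale = FALSE) {
  pos <- findPairOverlaps(lyso, cargo, min_overlap)
  lmaps <- lapply(lyso$trajectories, cwtTrajectory, scales = scales)
  cmaps <- lapply(cargo$trajectories, cwtTrajectory, scales = scales)
  rows <- list()
  for (po in pos) {
    res <- tryCatch(
      classifyPair(po, lmaps[[po$lyso_id]], cmaps[[po$cargo_id]],
                   lyso$trajectories[[po$lyso_id]],
                   cargo$trajectories[[po$cargo_id]],
                   corr_thresh, dist_thresh, per_scale),
      error = function(e) {
        warning(sprintf("pair (%s, %s) skipped: %s", po$lyso_id,
                        po$cargo_id, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    return(data.frame(lyso_id = character(), cargo_id = character(),
                      overlap_start = integer(), overlap_end = integer(),
                      n_overlap = integer(), Px = numeric(), Py = numeric(),
                      mean_dist_um = numeric(), is_comoving = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split organelle tracks by cargo-bearing status
#'
#' An organelle is cargo-bearing iff it is co-moving with at least one cargo
#' track. The partition is exhaustive and disjoint.
#'
#' @param lyso organelle `TrackSet`.
#' @param results `PairResult` data.frame (see [detectComovement()]).
#' @return List with `cargo_bearing` and `remainder` `TrackSet`s.
#' @export
splitByComovement <- function(lyso, results) {
  bearing_ids <- unique(results$lyso_id[results$is_comoving])
  is_bearing <- names(lyso$trajectories) %in% bearing_ids
  list(cargo_bearing = trackSet(unname(lyso$trajectories[is_bearing]),
                                cell_id = lyso$cell_id,
                                channel = lyso$channel),
       remainder = trackSet(unname(lyso$trajectories[!is_bearing]),
                            cell_id = lyso$cell_id,
                            channel = lyso$channel))
}
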