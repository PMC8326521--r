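#' Matching cost weights
#'
#' Weights of the x-displacement, y-displacement and area-change terms of
#' the pairing cost. The defaults (1, 0.5, 1) reflect channel flow along x:
#' islets advance a predictable distance per frame along the channel axis,
#' drift little across it, and keep a near-constant area, so lateral
#' displacement is down-weighted relative to the other two terms.
#'
#' @param w_x,w_y,w_area Non-negative weights.
#' @return A named numeric vector of class `cost_weights`.
#' @export
cost_weights <- function(w_x = 1.0, w_y = 0.5, w_area = 1.0) {
  w <- c(w_x = w_x, w_y = w_y, w_area = w_area)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and >= 0")
  structure(w, class = "cost_weights")
}

#' Pairing cost between two detections
#'
#' Weighted L2 distance between the feature vectors (x, y, area) of two
#' detections in consecutive frames:
#' `J = w_x |x1-x2| / min(r1, r2) + w_y |y1-y2| / min(r1, r2) +
#'  w_area |a1-a2| / min(a1, a2)`,
#' where each detection's radius r is the equivalent radius sqrt(area/pi)
#' of its pixel area. Identical detections score 0; the smaller the score,
#' the more plausible the pair.
#'
#' @param a,b Detection rows (lists/data.frames with `centroid_x`,
#'   `centroid_y`, `area_px`).
#' @param weights A [cost_weights()] vector.
#' @return Dimensionless cost.
#' @export
pair_cost <- function(a, b, weights = cost_weights()) {
  if (a$area_px <= 0 || b$area_px <= 0) stop("detection area must be > 0")
  r_min <- sqrt(min(a$area_px, b$area_px) / pi)
  weights[["w_x"]] * abs(a$centroid_x - b$centroid_x) / r_min +
    weights[["w_y"]] * abs(a$centroid_y - b$centroid_y) / r_min +
    weights[["w_area"]] * abs(a$area_px - b$area_px) /
      min(a$area_px, b$area_px)
}

#' Match one frame's detections to the active tracks
#'
#' Candidate (track, detection) pairs are those with cost `J <= j_max`.
#' The default `greedy` solver consumes candidate pairs in ascending cost
#' order, each track and detection used at most once (shortest-distance
#' matching); the `optimal` solver instead finds the assignment minimising
#' total cost over the same candidate set. Unmatched detections start new
#' tracks; unmatched tracks accrue a missed frame.
#'
#' @param tracks List of track objects (as built by [track_detections()]).
#' @param det Detections data.frame for one frame (non-degenerate rows).
#' @param weights A [cost_weights()] vector.
#' @param j_max Maximum admissible cost (default 2).
#' @param solver `"greedy"` or `"optimal"`.
#' @return List with `assignment` (integer vector over tracks: detection row
#'   matched to each track, NA if none) and `unmatched_detections` (row
#'   indices of `det` starting new tracks).
#' @export
match_frame <- function(tracks, det, weights = cost_weights(),
                        j_max = 2.0, solver = c("greedy", "optimal")) {
  solver <- match.arg(solver)
  nt <- length(tracks); nd <- nrow(det)
  assignment <- rep(NA_integer_, nt)
  if (nt == 0L || nd == 0L)
    return(list(assignment = assignment,
                unmatched_detections = seq_len(nd)))
  last <- do.call(rbind, lapply(tracks, function(tr) tr$last))
  r_t <- sqrt(last$area_px / pi)
  r_d <- sqrt(det$area_px / pi)
  J <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    r_min <- pmin(r_t[i], r_d)
    a_min <- pmin(last$area_px[i], det$area_px)
    J[i, ] <- weights[["w_x"]] * abs(last$centroid_x[i] - det$centroid_x) /
        r_min +
      weights[["w_y"]] * abs(last$centroid_y[i] - det$centroid_y) / r_min +
      weights[["w_area"]] * abs(last$area_px[i] - det$area_px) / a_min
  }
  J[J > j_max] <- Inf
  if (solver == "greedy") {
    ord <- order(J)
    used_d <- logical(nd)
    for (k in ord) {
      if (!is.finite(J[k])) break
      i <- (k - 1L) %% nt + 1L
      j <- (k - 1L) %/% nt + 1L
      if (is.na(assignment[i]) && !used_d[j] ) {
        assignment[i] <- j
        used_d[j] <- TRUE
      }
    }
  } else {
    assignment <- assign_optimal(J, j_max)
  }
  list(assignment = assignment,
       unmatched_detections = setdiff(seq_len(nd),
                                      assignment[!is.na(assignment)]))
}

# Minimum-cost assignment allowing non-assignment: square augmented matrix
# where leaving a track or detection unmatched costs j_max, so a pair is
# preferred over two non-assignments exactly when J <= 2 * j_max, and
# forbidden pairs (Inf) are never chosen.
assign_optimal <- function(J, j_max) {
  nt <- nrow(J); nd <- ncol(J)
  n <- nt + nd
  big <- 1e9
  C <- matrix(0, n, n)
  C[seq_len(nt), seq_len(nd)] <- ifelse(is.finite(J), J, big)
  C[seq_len(nt), nd + seq_len(nt)] <- big
  C[cbind(seq_len(nt), nd + seq_len(nt))] <- j_max
  C[nt + seq_len(nd), seq_len(nd)] <- big
  C[cbind(nt + seq_len(nd), seq_len(nd))] <- j_max
  sol <- hungarian(C)
  assignment <- rep(NA_integer_, nt)
  for (i in seq_len(nt)) if (sol[i] <= nd && is.finite(J[i, sol[i]]))
    assignment[i] <- sol[i]
  assignment
}

# O(n^3) Hungarian algorithm (shortest augmenting path with potentials).
# Returns, for each row, the assigned column of the square cost matrix.
hungarian <- function(C) {
  n <- nrow(C)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- C[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

#' Track detections across a whole video
#'
#' Processes frames in order, matching each frame's non-degenerate
#' detections to the active tracks with [match_frame()]. A track missing
#' its match for more than `max_missed` consecutive frames is closed (the
#' islet has left the field of view).
#'
#' @param detections Detections data.frame for all frames (as produced by
#'   [measure_regions()] rows bound together), or a list of per-frame
#'   data.frames.
#' @param weights A [cost_weights()] vector.
#' @param j_max Maximum admissible matching cost (default 2).
#' @param max_missed Consecutive unmatched frames tolerated before a track
#'   closes (default 2).
#' @param solver Matching solver, `"greedy"` (default) or `"optimal"`.
#' @return List of track objects: each a list with `track_id`,
#'   `detections` (data.frame of this track's detections, strictly
#'   increasing `frame_index`), `missed`, `active`.
#' @export
track_detections <- function(detections, weights = cost_weights(),
                             j_max = 2.0, max_missed = 2,
                             solver = "greedy") {
  if (is.data.frame(detections)) {
    detections <- detections[!detections$degenerate, , drop = FALSE]
    by_frame <- split(detections, detections$frame_index)
  } else {
    by_frame <- lapply(detections, function(d)
      d[!d$degenerate, , drop = FALSE])
    names(by_frame) <- vapply(by_frame, function(d)
      as.character(d$frame_index[1] %||% NA), character(1))
  }
  frame_ids <- sort(as.numeric(names(by_frame)))
  tracks <- list()
  closed <- list()
  next_id <- 1L
  for (fi in frame_ids) {
    det <- by_frame[[as.character(fi)]]
    m <- match_frame(tracks, det, weights, j_max, solver)
    keep <- logical(length(tracks))
    for (i in seq_along(tracks)) {
      j <- m$assignment[i]
      if (!is.na(j)) {
        tracks[[i]]$detections <- rbind(tracks[[i]]$detections,
                                        det[j, , drop = FALSE])
        tracks[[i]]$last <- det[j, c("centroid_x", "centroid_y", "area_px")]
        tracks[[i]]$missed <- 0L
        keep[i] <- TRUE
      } else {
        tracks[[i]]$missed <- tracks[[i]]$missed + 1L
        if (tracks[[i]]$missed > max_missed) {
          tracks[[i]]$active <- FALSE
          closed[[length(closed) + 1L]] <- tracks[[i]]
        } else keep[i] <- TRUE
      }
    }
    tracks <- tracks[keep]
    for (j in m$unmatched_detections) {
      tracks[[length(tracks) + 1L]] <- list(
        track_id = next_id,
        detections = det[j, , drop = FALSE],
        last = det[j, c("centroid_x", "centroid_y", "area_px")],
        missed = 0L, active = TRUE)
      next_id <- next_id + 1L
    }
  }
  for (tr in tracks) {
    tr$active <- FALSE
    closed[[length(closed) + 1L]] <- tr
  }
  closed[order(vapply(closed, function(tr) tr$track_id, numeric(1)))]
}

#' Finalise tracks into the sample islet count
#'
#' Keeps tracks observed in at least `min_track_length` frames that have at
#' least one detection fully inside the field of view (not touching the
#' raster border). The length of the returned list is the islet count:
#' each physical islet contributes exactly one finalised track.
#'
#' @param tracks List of tracks from [track_detections()].
#' @param min_track_length Minimum detections per track (default 2;
#'   single-frame blobs are treated as debris).
#' @return Filtered list of tracks.
#' @export
finalize_tracks <- function(tracks, min_track_length = 2) {
  Filter(function(tr) {
    nrow(tr$detections) >= min_track_length &&
      any(!tr$detections$touches_edge)
  }, tracks)
}

#' Flatten tracks to a table
#'
#' @param tracks List of tracks.
#' @return data.frame with `track_id`, `frame_index`, `x`, `y`, `area_px`.
#' @export
tracks_table <- function(tracks) {
  if (length(tracks) == 0)
    return(data.frame(track_id = integer(), frame_index = integer(),
                      x = numeric(), y = numeric(), area_px = numeric()))
  do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id,
               frame_index = tr$detections$frame_index,
               x = tr$detections$centroid_x,
               y = tr$detections$centroid_y,
               area_px = tr$detections$area_px)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
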