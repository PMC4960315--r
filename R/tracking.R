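# Exact minimum-cost assignment (Hungarian algorithm, Jonker-Volgonant-style
# shortest augmenting paths, O(n^3)). `cost` is a square matrix of finite
# costs; returns the column assigned to each row. Used by the linker; small
# matrices only (a few dozen objects per frame).
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

# Optimal frame-to-frame correspondence between active track heads and new
# detections (Crocker-Grier-style cost). Pairs farther apart than `max_disp`
# are forbidden; leaving a track or a detection unmatched costs max_disp^2,
# so a link is made exactly when it is cheaper than two "unmatched" outcomes.
# Returns an integer vector: for each detection, the matched track row index
# or NA.
match_frame <- function(track_xy, det_xy, max_disp) {
  nA <- nrow(track_xy); nB <- nrow(det_xy)
  if (nB == 0L) return(integer(0))
  if (nA == 0L) return(rep(NA_integer_, nB))
  P <- max_disp^2
  d2 <- outer(track_xy[, 1], det_xy[, 1], "-")^2 +
        outer(track_xy[, 2], det_xy[, 2], "-")^2
  BIG <- (nA + nB + 1) * P + 1
  d2[d2 > P] <- BIG
  n <- nA + nB
  cost <- matrix(0, n, n)
  cost[seq_len(nA), seq_len(nB)] <- d2
  cost[seq_len(nA), nB + seq_len(nA)] <- BIG
  cost[nA + seq_len(nB), seq_len(nB)] <- BIG
  for (i in seq_len(nA)) cost[i, nB + i] <- P       # track i unmatched
  for (j in seq_len(nB)) cost[nA + j, j] <- P       # detection j unmatched
  assign_col <- hungarian_assign(cost)
  out <- rep(NA_integer_, nB)
  for (i in seq_len(nA)) {
    j <- assign_col[i]
    if (j <= nB && d2[i, j] < BIG) out[j] <- i
  }
  out
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame assignment minimizing total squared displacement among
#' pairings within `max_link_displacement_px` (the classic particle-tracking
#' cost); unmatched detections start new tracks, and a track missing a
#' detection is kept alive for up to `gap_memory_frames` frames before it is
#' closed. Assignments are solved exactly per frame pair with the Hungarian
#' algorithm, so on small instances the linking cost equals the
#' exhaustive-search optimum. Track ids are assigned in order of first
#' appearance (frame, then detection order), making the output deterministic.
#'
#' @param detections Tibble from [detect_movie()] (`frame`, `x_px`, `y_px`).
#' @param params [analysis_params()].
#' @return A track tibble (`track_id`, `frame`, `x_px`, `y_px`,
#'   `interpolated = FALSE`), detected samples only.
#' @export
link_detections <- function(detections, params) {
  stopifnot(inherits(params, "analysis_params"))
  empty <- tibble::tibble(track_id = integer(0), frame = integer(0),
                          x_px = double(0), y_px = double(0),
                          interpolated = logical(0))
  if (nrow(detections) == 0L) return(empty)
  detections <- dplyr::arrange(detections, .data$frame)
  frames_present <- unique(detections$frame)
  f_lo <- min(frames_present); f_hi <- max(frames_present)
  # active track state
  tr_id <- integer(0); tr_x <- double(0); tr_y <- double(0)
  tr_last <- integer(0)
  next_id <- 1L
  out <- vector("list", f_hi - f_lo + 1L)
  det_split <- split(detections, detections$frame)
  for (f in f_lo:f_hi) {
    dets <- det_split[[as.character(f)]]
    if (is.null(dets) || nrow(dets) == 0L) next
    alive <- which(f - tr_last <= params$gap_memory_frames + 1L)
    m <- match_frame(cbind(tr_x[alive], tr_y[alive]),
                     cbind(dets$x_px, dets$y_px),
                     params$max_link_displacement_px)
    ids <- integer(nrow(dets))
    for (j in seq_len(nrow(dets))) {
      if (!is.na(m[j])) {
        k <- alive[m[j]]
        ids[j] <- tr_id[k]
        tr_x[k] <- dets$x_px[j]; tr_y[k] <- dets$y_px[j]; tr_last[k] <- f
      } else {
        ids[j] <- next_id
        tr_id <- c(tr_id, next_id)
        tr_x <- c(tr_x, dets$x_px[j]); tr_y <- c(tr_y, dets$y_px[j])
        tr_last <- c(tr_last, f)
        next_id <- next_id + 1L
      }
    }
    out[[f - f_lo + 1L]] <- tibble::tibble(
      track_id = ids, frame = as.integer(f),
      x_px = dets$x_px, y_px = dets$y_px, interpolated = FALSE)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$track_id, .data$frame)
}

#' Discard short tracks
#'
#' Keeps only tracks longer than `min_track_frames` detected frames
#' (strictly greater: with the default of 10, a 10-frame track is removed
#' and an 11-frame track kept). Interpolated samples do not count towards
#' the bound.
#'
#' @param tracks A track tibble.
#' @param params [analysis_params()].
#' @return The filtered track tibble.
#' @export
filter_short_tracks <- function(tracks, params) {
  stopifnot(inherits(params, "analysis_params"))
  if (nrow(tracks) == 0L) return(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(sum(!.data$interpolated) > params$min_track_frames) |>
    dplyr::ungroup()
}

#' Fill single- and multi-frame gaps by linear interpolation
#'
#' Every missing interior frame of a track receives a sample linearly
#' interpolated in x and y between the nearest flanking detections and is
#' flagged `interpolated = TRUE`. Endpoints are never extrapolated, and
#' detected samples are preserved bit-exactly.
#'
#' @param tracks A track tibble (one or many tracks).
#' @return The track tibble with consecutive frame indices within each
#'   track.
#' @export
fill_gaps <- function(tracks) {
  if (nrow(tracks) == 0L) return(tracks)
  fill_one <- function(tr) {
    if (nrow(tr) < 2L) {
      warning("track ", tr$track_id[1],
              " has a single sample; returned unchanged")
      return(tr)
    }
    tr <- dplyr::arrange(tr, .data$frame)
    full <- seq(min(tr$frame), max(tr$frame))
    miss <- setdiff(full, tr$frame)
    if (!length(miss)) return(tr)
    xi <- stats::approx(tr$frame, tr$x_px, xout = miss)$y
    yi <- stats::approx(tr$frame, tr$y_px, xout = miss)$y
    add <- tibble::tibble(track_id = tr$track_id[1], frame = as.integer(miss),
                          x_px = xi, y_px = yi, interpolated = TRUE)
    dplyr::arrange(dplyr::bind_rows(tr, add), .data$frame)
  }
  tracks |>
    dplyr::group_split(.data$track_id) |>
    purrr::map_dfr(fill_one) |>
    dplyr::arrange(.data$track_id, .data$frame)
}
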