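#' Estimate lateral (xy) drift by cross-correlation with the first frame
#'
#' For every frame, the integer-pixel offset `(dx, dy)` maximizing the
#' cross-correlation with frame 0 is found. Frames are mean-subtracted and
#' zero-padded before the (FFT-based) correlation, so the estimate is a
#' linear, not cyclic, correlation peak. Ties in the correlation peak are
#' broken by smallest `|dx| + |dy|`, then lexicographically by `(dx, dy)`,
#' which makes the output deterministic. A constant (zero-variance) frame
#' yields offset `(0, 0)` with a warning.
#'
#' The convention is that frame `t` looks like frame 0 translated by
#' `(+dx, +dy)` pixels (x = column, y = row).
#'
#' @param movie A [movie_stack()].
#' @return A tibble (`frame`, `dx_px`, `dy_px`), one row per frame, with
#'   entry 0 equal to `(0, 0)`.
#' @export
estimate_drift <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- frame_dim(movie)
  H <- d[1]; W <- d[2]
  PH <- 2 * H; PW <- 2 * W
  f0 <- movie$frames[[1]]
  f0c <- f0 - mean(f0)
  if (all(f0c == 0)) {
    warning("reference frame has zero variance; drift set to (0, 0)")
    return(tibble::tibble(frame = seq_len(n_frames(movie)) - 1L,
                          dx_px = 0, dy_px = 0))
  }
  pad <- function(m) {
    out <- matrix(0, PH, PW)
    out[seq_len(H), seq_len(W)] <- m
    out
  }
  F0c <- Conj(fft(pad(f0c)))
  # shift value corresponding to each (0-based) index of the correlation grid
  dy_of <- ifelse(seq_len(PH) - 1 < H, seq_len(PH) - 1, seq_len(PH) - 1 - PH)
  dx_of <- ifelse(seq_len(PW) - 1 < W, seq_len(PW) - 1, seq_len(PW) - 1 - PW)
  res <- matrix(0, n_frames(movie), 2)
  for (t in seq_len(n_frames(movie))[-1]) {
    ft <- movie$frames[[t]]
    ftc <- ft - mean(ft)
    if (all(ftc == 0)) {
      warning("frame ", t - 1, " has zero variance; drift set to (0, 0)")
      next
    }
    cc <- Re(fft(fft(pad(ftc)) * F0c, inverse = TRUE)) / (PH * PW)
    peak <- max(cc)
    # candidate peaks within numerical tolerance of the maximum
    tol <- max(1e-9, 1e-9 * abs(peak))
    idx <- which(cc >= peak - tol, arr.ind = TRUE)
    dys <- dy_of[idx[, 1]]
    dxs <- dx_of[idx[, 2]]
    ord <- order(abs(dxs) + abs(dys), dxs, dys)
    res[t, ] <- c(dxs[ord[1]], dys[ord[1]])
  }
  tibble::tibble(frame = seq_len(n_frames(movie)) - 1L,
                 dx_px = res[, 1], dy_px = res[, 2])
}

#' Correct lateral drift
#'
#' Translates frame `t` by `-(dx, dy)`; pixels vacated by the translation
#' are filled with 0. After correction, [estimate_drift()] returns all-zero
#' offsets.
#'
#' @param movie A [movie_stack()].
#' @param drift A drift tibble from [estimate_drift()] (one row per frame,
#'   integer offsets).
#' @return A drift-corrected [movie_stack()].
#' @export
correct_drift <- function(movie, drift) {
  stopifnot(inherits(movie, "movie_stack"))
  if (nrow(drift) != n_frames(movie))
    stop("drift table has ", nrow(drift), " rows for ", n_frames(movie),
         " frames", call. = FALSE)
  out <- movie
  for (t in seq_len(n_frames(movie))) {
    out$frames[[t]] <- translate_frame(movie$frames[[t]],
                                       -drift$dx_px[t], -drift$dy_px[t])
  }
  out
}

# integer translation with zero fill; (dx, dy) moves content right/down
translate_frame <- function(f, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  H <- nrow(f); W <- ncol(f)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dy   # out[r, c] = f[r - dy, c - dx]
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
  out
}

#' Median filter a frame
#'
#' Square-window median filter (window `w x w`, `w` odd) with replicate
#' border padding, as applied before thresholding in cell detection.
#' Backed by `EBImage::medianFilter()`; intensities are rescaled to the
#' `[0, 1]` range it requires and back, so arbitrary nonnegative intensity
#' units are accepted.
#'
#' @param frame Numeric matrix.
#' @param window_px Odd window size in pixels (1 = identity).
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter <- function(frame, window_px = 5) {
  stopifnot(is.matrix(frame))
  window_px <- as.integer(window_px)
  if (window_px < 1 || window_px %% 2 == 0)
    stop("window_px must be odd and >= 1", call. = FALSE)
  if (window_px == 1) return(frame)
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) return(frame)
  scaled <- (frame - lo) / (hi - lo)
  filt <- EBImage::medianFilter(scaled, (window_px - 1L) %/% 2L)
  as.matrix(filt) * (hi - lo) + lo
}

# 8-connected components of a logical mask; returns an integer label matrix
# (0 = background), components numbered in order of their first pixel in
# column-major order.
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  pos <- match(idx, idx)  # identity, vertices 1..n
  edges_from <- integer(0); edges_to <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1]; cc <- c + off[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    nb <- match((cc[ok] - 1L) * H + rr[ok], idx)
    hit <- !is.na(nb)
    edges_from <- c(edges_from, which(ok)[hit])
    edges_to <- c(edges_to, nb[hit])
  }
  g <- igraph::make_graph(rbind(edges_from, edges_to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel deterministically by first occurrence in column-major order
  lab[idx] <- match(memb, unique(memb))
  lab
}

#' Detect cells in a single frame
#'
#' Applies the published detection recipe: median filter (window
#' `median_window_px`, default 5 px), threshold the filtered image at the
#' manual `intensity_threshold`, take 8-connected components, discard
#' components below `min_object_area_px`, and report each remaining
#' component's centroid. The centroid is the unweighted mean of the
#' component's pixel coordinates by default (`centroid_weighting =
#' "binary"`); an intensity-weighted variant is available as a parameter
#' switch.
#'
#' @param frame Numeric matrix (one movie frame, drift-corrected).
#' @param params [analysis_params()] with `intensity_threshold` set.
#' @param frame_index 0-based frame index recorded in the output.
#' @return A tibble (`frame`, `x_px`, `y_px`, `area_px`, `mean_intensity`),
#'   one row per detection, with 0-based real-valued centroids.
#' @export
detect_cells <- function(frame, params, frame_index = 0L) {
  stopifnot(inherits(params, "analysis_params"))
  if (is.na(params$intensity_threshold))
    stop("intensity_threshold is not set (the detection cutoff is manual)",
         call. = FALSE)
  filt <- median_filter(frame, params$median_window_px)
  mask <- filt > params$intensity_threshold
  empty <- tibble::tibble(frame = integer(0), x_px = double(0),
                          y_px = double(0), area_px = integer(0),
                          mean_intensity = double(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  H <- nrow(frame)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(comp)
  keep <- which(area >= params$min_object_area_px)
  if (!length(keep)) return(empty)
  inten <- filt[idx]
  if (params$centroid_weighting == "intensity") {
    wsum <- rowsum_by(inten, comp)
    cx <- rowsum_by(inten * (cc - 1), comp) / wsum
    cy <- rowsum_by(inten * (rr - 1), comp) / wsum
  } else {
    cx <- rowsum_by(cc - 1, comp) / area
    cy <- rowsum_by(rr - 1, comp) / area
  }
  mi <- rowsum_by(inten, comp) / area
  tibble::tibble(frame = as.integer(frame_index),
                 x_px = cx[keep], y_px = cy[keep],
                 area_px = as.integer(area[keep]),
                 mean_intensity = mi[keep])
}

rowsum_by <- function(x, g) {
  as.vector(rowsum(x, g)[as.character(seq_len(max(g))), 1])
}

#' Detect cells in every frame of a movie
#'
#' @param movie A (drift-corrected) [movie_stack()].
#' @param params [analysis_params()].
#' @return A tibble of detections across frames (see [detect_cells()]).
#' @export
detect_movie <- function(movie, params) {
  stopifnot(inherits(movie, "movie_stack"))
  purrr::map_dfr(seq_len(n_frames(movie)), function(t)
    detect_cells(movie$frames[[t]], params, frame_index = t - 1L))
}

#' Otsu threshold initializer
#'
#' Convenience starting point for the manual detection cutoff: the Otsu
#' threshold of a (median-filtered) frame. Never applied implicitly —
#' detection requires an explicit `intensity_threshold`.
#'
#' @param frame Numeric matrix.
#' @param levels Number of histogram levels.
#' @return A scalar threshold in the frame's intensity units.
#' @export
otsu_threshold <- function(frame, levels = 256L) {
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) return(lo)
  scaled <- (frame - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                      levels = levels)
  th * (hi - lo) + lo
}
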