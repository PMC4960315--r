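#' Euclidean distance field of a niche region
#'
#' Exact Euclidean distance transform of the complement of a region mask,
#' scaled to micrometres: each pixel holds the distance to the nearest
#' region pixel, 0 inside the region. The transform is computed with
#' `EBImage::distmap()`, which is exact for this use (verified against a
#' brute-force nearest-pixel scan in the test suite).
#'
#' @param mask Logical (or 0/1) `H x W` matrix; must contain at least one
#'   region pixel.
#' @param pixel_size_um Micrometres per pixel.
#' @param label Region label stored with the field (`"vascular"` or
#'   `"endosteal"`).
#' @return A numeric matrix of class `"distance_field"` with attributes
#'   `pixel_size_um` and `label`.
#' @export
distance_field <- function(mask, pixel_size_um,
                           label = c("vascular", "endosteal")) {
  label <- match.arg(label)
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask))
    stop("region undefined: the ", label, " mask is empty, distance ",
         "queries are refused", call. = FALSE)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  d <- as.matrix(EBImage::distmap(1 - mask)) * pixel_size_um
  structure(d, pixel_size_um = pixel_size_um, label = label,
            class = c("distance_field", "matrix", "array"))
}

#' Distance fields for both regions of a region map
#'
#' @param region_map A [region_map()]; both masks must be nonempty.
#' @return A list with elements `vascular` and `endosteal`, each a
#'   [distance_field()].
#' @export
region_distance_fields <- function(region_map) {
  stopifnot(inherits(region_map, "region_map"))
  list(
    vascular = distance_field(region_map$vascular_mask,
                              region_map$pixel_size_um, "vascular"),
    endosteal = distance_field(region_map$endosteal_mask,
                               region_map$pixel_size_um, "endosteal")
  )
}

# Bilinear interpolation of a field at real-valued 0-based pixel
# coordinates; positions outside the grid are clamped to the border.
bilinear_sample <- function(field, x, y) {
  H <- nrow(field); W <- ncol(field)
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- pmin(floor(x), max(W - 2, 0))
  y0 <- pmin(floor(y), max(H - 2, 0))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- field[cbind(y0 + 1, x0 + 1)]
  i01 <- field[cbind(y0 + 1, x1 + 1)]
  i10 <- field[cbind(y1 + 1, x0 + 1)]
  i11 <- field[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample niche distances along tracks
#'
#' For every track sample, the distances to the vascular and endosteal
#' regions are obtained by bilinear interpolation of the two distance
#' fields at the real-valued centroid (centroids are subpixel; the
#' interpolation error is bounded by one pixel). Time is attached as
#' `t_s = frame * frame_interval_s`.
#'
#' @param tracks A track tibble (gap-filled).
#' @param fields A list with `vascular` and `endosteal` [distance_field()]s
#'   (see [region_distance_fields()]).
#' @param params [analysis_params()].
#' @return A zone-series tibble (`track_id`, `frame`, `t_s`, `d_v_um`,
#'   `d_e_um`).
#' @export
sample_distances <- function(tracks, fields, params) {
  stopifnot(inherits(params, "analysis_params"))
  stopifnot(inherits(fields$vascular, "distance_field"),
            inherits(fields$endosteal, "distance_field"))
  tibble::tibble(
    track_id = tracks$track_id,
    frame = tracks$frame,
    t_s = tracks$frame * params$frame_interval_s,
    d_v_um = bilinear_sample(fields$vascular, tracks$x_px, tracks$y_px),
    d_e_um = bilinear_sample(fields$endosteal, tracks$x_px, tracks$y_px)
  )
}

#' Classify a distance into contact / proximal / distal zones
#'
#' Zone boundaries are closed above: `d <= d_c` is contact ("within 5 um"
#' includes 5), `d_c < d <= d_p` proximal, `d > d_p` distal.
#'
#' @param d_um Nonnegative distance(s) in micrometres.
#' @param params [analysis_params()] carrying `contact_cutoff_um` and
#'   `proximal_cutoff_um`.
#' @return A character vector in `c("contact", "proximal", "distal")`.
#' @export
classify_zone <- function(d_um, params) {
  stopifnot(inherits(params, "analysis_params"))
  if (any(d_um < 0, na.rm = TRUE))
    stop("distances must be nonnegative", call. = FALSE)
  ifelse(d_um <= params$contact_cutoff_um, "contact",
         ifelse(d_um <= params$proximal_cutoff_um, "proximal", "distal"))
}
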