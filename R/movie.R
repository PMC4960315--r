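#' Movie stack container
#'
#' A time-ordered stack of single-channel 2D intensity frames with physical
#' calibration. Frames are numeric `H x W` matrices (rows = y, columns = x);
#' positions elsewhere in the package use 0-based pixel coordinates with
#' `x` = column and `y` = row, origin at the top-left.
#'
#' @param frames A list of numeric matrices, all of identical dimensions, or
#'   a 3D array `T x H x W`.
#' @param pixel_size_um Micrometres per pixel (isotropic), > 0.
#' @param frame_interval_s Seconds between frames, > 0.
#' @param channel_name Free-text channel description.
#' @return An object of class `"movie_stack"`.
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_s,
                        channel_name = "") {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  if (!is.list(frames) || length(frames) < 1)
    stop("frames must be a non-empty list of matrices", call. = FALSE)
  dims <- dim(frames[[1]])
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (!is.matrix(f) || !is.numeric(f))
      stop("frame ", t, " is not a numeric matrix", call. = FALSE)
    if (!identical(dim(f), dims))
      stop("frame ", t, " has dimensions ", paste(dim(f), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"), call. = FALSE)
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0", call. = FALSE)
  structure(
    list(frames = frames,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         channel_name = as.character(channel_name)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<movie_stack> %d frames of %dx%d px, %.3g um/px, %.3g s/frame%s\n",
    length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval_s,
    if (nzchar(x$channel_name)) paste0(" [", x$channel_name, "]") else ""))
  invisible(x)
}

n_frames <- function(movie) length(movie$frames)
frame_dim <- function(movie) dim(movie$frames[[1]])

#' Read a multi-page TIFF movie
#'
#' Loads a single-channel time-lapse movie stored as a multi-page TIFF.
#' Pixel values are read as-is (bit-exact integer intensities); physical
#' calibration is supplied by the caller rather than parsed from TIFF tags,
#' because tag dialects vary between microscope exporters.
#'
#' @param path Path to a multi-page TIFF file.
#' @inheritParams movie_stack
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_s,
                       channel_name = "") {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, tiff_page_to_matrix)
  movie_stack(pages, pixel_size_um, frame_interval_s, channel_name)
}

tiff_page_to_matrix <- function(p) {
  if (length(dim(p)) == 3) p <- p[, , 1]   # collapse greyscale-with-channels
  storage.mode(p) <- "double"
  p
}

#' Write a movie stack as a 16-bit multi-page TIFF
#'
#' Intensities must be integer-valued in `[0, 65535]`; this guarantees a
#' bit-exact round trip through [read_movie()].
#'
#' @param movie A [movie_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  for (t in seq_along(movie$frames)) {
    f <- movie$frames[[t]]
    if (any(f != round(f)) || any(f < 0) || any(f > 65535))
      stop("frame ", t, " intensities must be integers in [0, 65535] for ",
           "16-bit TIFF output", call. = FALSE)
  }
  tiff::writeTIFF(lapply(movie$frames, function(f) f / 65535), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Niche region map container
#'
#' Binary masks of the hand-annotated vascular and endosteal domains on the
#' movie's pixel grid. A mask may be empty, but distance queries against an
#' empty mask are refused by [distance_field()].
#'
#' @param vascular_mask,endosteal_mask Logical or 0/1 numeric `H x W`
#'   matrices on the same grid; any nonzero pixel counts as inside.
#' @param pixel_size_um Micrometres per pixel.
#' @return An object of class `"region_map"` with logical masks and
#'   emptiness flags.
#' @export
region_map <- function(vascular_mask, endosteal_mask, pixel_size_um) {
  v <- binarize_mask(vascular_mask, "vascular")
  e <- binarize_mask(endosteal_mask, "endosteal")
  if (!identical(dim(v), dim(e)))
    stop("vascular and endosteal masks have different dimensions (",
         paste(dim(v), collapse = "x"), " vs ",
         paste(dim(e), collapse = "x"), ")", call. = FALSE)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  structure(
    list(vascular_mask = v, endosteal_mask = e,
         pixel_size_um = as.numeric(pixel_size_um),
         vascular_empty = !any(v), endosteal_empty = !any(e)),
    class = "region_map"
  )
}

binarize_mask <- function(m, what) {
  if (!is.matrix(m)) stop(what, " mask must be a matrix", call. = FALSE)
  out <- m != 0
  if (anyNA(out)) stop(what, " mask contains NA", call. = FALSE)
  out
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "<region_map> %dx%d px @ %.3g um/px; vascular: %d px%s, endosteal: %d px%s\n",
    nrow(x$vascular_mask), ncol(x$vascular_mask), x$pixel_size_um,
    sum(x$vascular_mask), if (x$vascular_empty) " (empty)" else "",
    sum(x$endosteal_mask), if (x$endosteal_empty) " (empty)" else ""))
  invisible(x)
}

#' Read vascular/endosteal region annotations
#'
#' Each mask is an image on the movie's pixel grid; any nonzero pixel is
#' inside the region (annotation tools export 8-bit masks inconsistently,
#' so no particular foreground value is assumed).
#'
#' @param vascular_path,endosteal_path Paths to single-page mask TIFFs.
#' @param pixel_size_um Micrometres per pixel.
#' @param expected_dim Optional `c(H, W)` of the movie grid; a mismatch is a
#'   dimension error.
#' @return A [region_map()].
#' @export
read_region_maps <- function(vascular_path, endosteal_path, pixel_size_um,
                             expected_dim = NULL) {
  read_one <- function(path, what) {
    if (!file.exists(path))
      stop(what, " mask file not found: ", path, call. = FALSE)
    m <- tiff::readTIFF(path, all = FALSE, as.is = TRUE)
    tiff_page_to_matrix(m)
  }
  v <- read_one(vascular_path, "vascular")
  e <- read_one(endosteal_path, "endosteal")
  rm <- region_map(v, e, pixel_size_um)
  if (!is.null(expected_dim) &&
      !identical(dim(rm$vascular_mask), as.integer(expected_dim)))
    stop("region masks are ", paste(dim(rm$vascular_mask), collapse = "x"),
         " px but the movie grid is ", paste(expected_dim, collapse = "x"),
         " px", call. = FALSE)
  rm
}

#' Write region masks as 8-bit TIFFs
#'
#' @param region_map A [region_map()].
#' @param vascular_path,endosteal_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_region_maps <- function(region_map, vascular_path, endosteal_path) {
  stopifnot(inherits(region_map, "region_map"))
  tiff::writeTIFF(region_map$vascular_mask * 1, vascular_path,
                  bits.per.sample = 8)
  tiff::writeTIFF(region_map$endosteal_mask * 1, endosteal_path,
                  bits.per.sample = 8)
  invisible(c(vascular_path, endosteal_path))
}
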