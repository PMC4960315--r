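#' Read a track table from CSV
#'
#' The on-disk schema is `track_id,frame,x_px,y_px,interpolated` with a
#' header row, UTF-8, '.' decimal separator — one row per tracked cell per
#' timepoint, coordinates in 0-based pixel units. Rows are sorted by
#' `(track_id, frame)` on read; duplicate `(track_id, frame)` pairs are a
#' schema error.
#'
#' @param path CSV file path.
#' @return A tibble with columns `track_id` (integer), `frame` (integer),
#'   `x_px`, `y_px` (double), `interpolated` (logical).
#' @export
read_tracks <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(),
    frame = readr::col_integer(),
    x_px = readr::col_double(),
    y_px = readr::col_double(),
    interpolated = readr::col_logical()
  ))
  validate_track_table(tab)
}

validate_track_table <- function(tab) {
  need <- c("track_id", "frame", "x_px", "y_px", "interpolated")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("track table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- dplyr::arrange(tibble::as_tibble(tab), .data$track_id, .data$frame)
  if (anyDuplicated(tab[, c("track_id", "frame")]))
    stop("duplicate (track_id, frame) rows in track table", call. = FALSE)
  if (!all(is.finite(tab$x_px)) || !all(is.finite(tab$y_px)))
    stop("track coordinates must be finite", call. = FALSE)
  tab
}

#' Write a track table to CSV
#'
#' @param tracks A track tibble (see [read_tracks()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- validate_track_table(tracks)
  readr::write_csv(tracks[, c("track_id", "frame", "x_px", "y_px",
                              "interpolated")], path)
  invisible(path)
}

#' Read / write interaction event tables
#'
#' Schema: `track_id,label,zone,start_s,end_s,duration_s,duration_class`.
#' `label` is one of `vascular`, `endosteal`, `none`; `zone` is `contact`,
#' `proximal` or empty for no-interaction periods; `duration_class` is
#' `short`, `long` or empty.
#'
#' @param path CSV file path.
#' @return A tibble of interaction events.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(),
    label = readr::col_character(),
    zone = readr::col_character(),
    start_s = readr::col_double(),
    end_s = readr::col_double(),
    duration_s = readr::col_double(),
    duration_class = readr::col_character()
  ))
  tibble::as_tibble(ev)
}

#' @rdname read_events
#' @param events An event tibble.
#' @export
write_events <- function(events, path) {
  need <- c("track_id", "label", "zone", "start_s", "end_s", "duration_s",
            "duration_class")
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop("event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  readr::write_csv(events[, need], path)
  invisible(path)
}
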