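#' Label timepoints by nearest niche region with hysteresis
#'
#' Per frame, the candidate label is the region with the smaller distance
#' (ties keep the previous frame's label, or default to vascular at the
#' first frame). The zone of that distance follows [classify_zone()], with
#' flicker suppression implemented as exit-side hysteresis (a Schmitt
#' trigger, the reading of the published "+/- 1 um automatic adjustment"):
#' entering a tighter state uses the nominal cutoff (contact at
#' `d <= d_c`, interaction at `d <= d_p`), while leaving a state requires
#' the distance to pass the cutoff by more than `hysteresis_um` (leave
#' contact only at `d > d_c + eps`, lose the interaction only at
#' `d > d_p + eps`). The first frame uses nominal cutoffs. `label = "none"`
#' means both distances exceed the proximal cutoff (after hysteresis), and
#' only then is the zone undefined.
#'
#' @param zone_series Tibble from [sample_distances()] (`track_id`, `frame`,
#'   `t_s`, `d_v_um`, `d_e_um`); distances must be present at every frame.
#' @param params [analysis_params()].
#' @return The series with `label` (`vascular`/`endosteal`/`none`) and
#'   `zone` (`contact`/`proximal`/`NA`) columns appended.
#' @export
label_timepoints <- function(zone_series, params) {
  stopifnot(inherits(params, "analysis_params"))
  if (anyNA(zone_series$d_v_um) || anyNA(zone_series$d_e_um))
    stop("missing distance in zone series", call. = FALSE)
  zone_series |>
    dplyr::group_split(.data$track_id) |>
    purrr::map_dfr(label_one_track, params = params)
}

label_one_track <- function(ts, params) {
  ts <- dplyr::arrange(ts, .data$frame)
  d_c <- params$contact_cutoff_um
  d_p <- params$proximal_cutoff_um
  eps <- params$hysteresis_um
  n <- nrow(ts)
  label <- character(n)
  zone <- rep(NA_character_, n)
  dv <- ts$d_v_um; de <- ts$d_e_um
  prev_label <- "none"; prev_zone <- NA_character_
  for (i in seq_len(n)) {
    # candidate label: nearest region; exact ties stay with the previous
    # region label, defaulting to vascular
    if (dv[i] < de[i]) {
      cand <- "vascular"
    } else if (de[i] < dv[i]) {
      cand <- "endosteal"
    } else {
      cand <- if (prev_label %in% c("vascular", "endosteal")) prev_label
              else "vascular"
    }
    dcand <- if (cand == "vascular") dv[i] else de[i]
    if (i == 1L || prev_label == "none") {
      # nominal cutoffs: no state to defend yet
      if (dcand <= d_p) {
        label[i] <- cand
        zone[i] <- if (dcand <= d_c) "contact" else "proximal"
      } else {
        label[i] <- "none"
      }
    } else if (cand != prev_label) {
      # the nearest region switched; entering the new region is nominal,
      # but abandoning interaction altogether still requires the old
      # region's distance to clear the proximal cutoff by more than eps
      if (dcand <= d_p) {
        label[i] <- cand
        zone[i] <- if (dcand <= d_c) "contact" else "proximal"
      } else {
        dprev <- if (prev_label == "vascular") dv[i] else de[i]
        if (dprev > d_p + eps) {
          label[i] <- "none"
        } else {
          label[i] <- prev_label
          zone[i] <- "proximal"
        }
      }
    } else {
      # same nearest region: Schmitt trigger on its distance
      if (prev_zone == "contact") {
        if (dcand > d_p + eps) {
          label[i] <- "none"
        } else if (dcand > d_c + eps) {
          label[i] <- cand; zone[i] <- "proximal"
        } else {
          label[i] <- cand; zone[i] <- "contact"
        }
      } else {  # proximal
        if (dcand <= d_c) {
          label[i] <- cand; zone[i] <- "contact"
        } else if (dcand > d_p + eps) {
          label[i] <- "none"
        } else {
          label[i] <- cand; zone[i] <- "proximal"
        }
      }
    }
    prev_label <- label[i]; prev_zone <- zone[i]
  }
  ts$label <- label
  ts$zone <- zone
  ts
}

#' Segment a labelled series into interaction events
#'
#' Maximal runs of constant `(label, zone)` become events; runs with
#' `label = "none"` become no-interaction periods. Event times tile each
#' track's observed span: `start_s`/`end_s` are the first/last frame times
#' of the run and `duration_s = end_s - start_s + frame_interval_s` (each
#' frame contributes one frame interval).
#'
#' @param labelled Output of [label_timepoints()].
#' @param frame_interval_s Seconds between frames.
#' @return An event tibble (`track_id`, `label`, `zone`, `start_s`, `end_s`,
#'   `duration_s`, `duration_class = NA`), time-ordered within each track.
#' @export
segment_events <- function(labelled, frame_interval_s) {
  empty <- tibble::tibble(track_id = integer(0), label = character(0),
                          zone = character(0), start_s = double(0),
                          end_s = double(0), duration_s = double(0),
                          duration_class = character(0))
  if (nrow(labelled) == 0L) return(empty)
  labelled |>
    dplyr::group_split(.data$track_id) |>
    purrr::map_dfr(function(ts) {
      ts <- dplyr::arrange(ts, .data$frame)
      key <- paste(ts$label, ifelse(is.na(ts$zone), "", ts$zone), sep = "|")
      r <- rle(key)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(
        track_id = ts$track_id[1],
        label = ts$label[starts],
        zone = dplyr::na_if(sub("^[^|]*\\|", "", r$values), ""),
        start_s = ts$t_s[starts],
        end_s = ts$t_s[ends],
        duration_s = ts$t_s[ends] - ts$t_s[starts] + frame_interval_s,
        duration_class = NA_character_
      )
    })
}

#' Merge transient interaction periods
#'
#' Iteratively absorbs any event shorter than `merge_window_s` (default
#' 200 s, strict) into its neighbours: when both neighbours carry the same
#' `(label, zone)`, the three fuse into one event with that labelling; a
#' transient at a track edge is absorbed into its only neighbour; a
#' transient flanked by two different labellings is kept. Repeats until no
#' short event has an eligible neighbour, so the operation is idempotent,
#' never increases the event count, and conserves each track's total
#' observed time exactly.
#'
#' @param events Event tibble from [segment_events()] (tiling each track's
#'   span).
#' @param params [analysis_params()].
#' @return The merged event tibble.
#' @export
merge_transients <- function(events, params) {
  stopifnot(inherits(params, "analysis_params"))
  if (nrow(events) == 0L) return(events)
  events |>
    dplyr::group_split(.data$track_id) |>
    purrr::map_dfr(merge_one_track, tau = params$merge_window_s)
}

merge_one_track <- function(ev, tau) {
  ev <- dplyr::arrange(ev, .data$start_s)
  repeat {
    n <- nrow(ev)
    if (n <= 1L) break
    short <- which(ev$duration_s < tau)
    done <- TRUE
    for (k in short) {
      if (k == 1L) {
        keep <- 2L
      } else if (k == n) {
        keep <- n - 1L
      } else if (ev$label[k - 1L] == ev$label[k + 1L] &&
                 identical(ev$zone[k - 1L], ev$zone[k + 1L])) {
        keep <- k - 1L   # fuse k-1, k, k+1 into the flanking labelling
      } else {
        next
      }
      if (keep == k - 1L && k < n) {
        lo <- k - 1L; hi <- k + 1L
      } else if (keep > k) {
        lo <- k; hi <- keep
      } else {
        lo <- keep; hi <- k
      }
      fused <- ev[keep, ]
      fused$start_s <- ev$start_s[lo]
      fused$end_s <- ev$end_s[hi]
      fused$duration_s <- sum(ev$duration_s[lo:hi])
      ev <- dplyr::bind_rows(
        if (lo > 1L) ev[seq_len(lo - 1L), ],
        fused,
        if (hi < n) ev[seq(hi + 1L, n), ]
      )
      done <- FALSE
      break
    }
    if (done) break
  }
  ev
}

#' Assign short/long duration classes
#'
#' Interaction events (label not `"none"`) shorter than `long_duration_min`
#' minutes are classed `"short"`, the rest `"long"` (the boundary itself is
#' long, since the short class is strictly "< 60 min"). No-interaction
#' periods get no class.
#'
#' @param events Merged event tibble.
#' @param params [analysis_params()].
#' @return The event tibble with `duration_class` filled in.
#' @export
classify_durations <- function(events, params) {
  stopifnot(inherits(params, "analysis_params"))
  cutoff_s <- params$long_duration_min * 60
  dplyr::mutate(events, duration_class = dplyr::case_when(
    label == "none" ~ NA_character_,
    duration_s < cutoff_s ~ "short",
    TRUE ~ "long"
  ))
}

#' Count interaction and no-interaction periods
#'
#' @param events Merged, classified event tibble (may span many cells).
#' @return A one-row tibble (`n_interaction`, `n_no_interaction`).
#' @export
count_periods <- function(events) {
  tibble::tibble(
    n_interaction = sum(events$label %in% c("vascular", "endosteal")),
    n_no_interaction = sum(events$label == "none")
  )
}

#' Full per-frame classification for a set of tracks
#'
#' Convenience wrapper: samples distances, labels timepoints with
#' hysteresis, segments into events, merges transients and assigns
#' duration classes.
#'
#' @param tracks Gap-filled track tibble.
#' @param fields Distance fields from [region_distance_fields()].
#' @param params [analysis_params()].
#' @return A list with `series` (labelled zone series) and `events`
#'   (merged, classified event tibble).
#' @export
classify_interactions <- function(tracks, fields, params) {
  series <- sample_distances(tracks, fields, params) |>
    label_timepoints(params)
  events <- segment_events(series, params$frame_interval_s) |>
    merge_transients(params) |>
    classify_durations(params)
  list(series = series, events = events)
}
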