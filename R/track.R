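#' Parameters for LAP-style nuclear tracking
#'
#' Defaults mirror a confluent epithelial monolayer imaged at 10x with one
#' frame every 10 minutes (frame-to-frame nuclear displacements of a few
#' pixels): generous link radius, short gaps, and a minimum track length to
#' suppress spurious one-off detections.
#'
#' @param max_link_distance_px Maximum frame-to-frame link distance, px.
#' @param max_gap_frames Maximum number of missing frames a closed gap may
#'   span.
#' @param max_gap_distance_px Maximum displacement across a closed gap, px.
#' @param min_track_length Minimum number of detections for a track to be
#'   kept.
#' @return A list of class `tracking_params`.
#' @export
tracking_params <- function(max_link_distance_px = 15,
                            max_gap_frames = 2L,
                            max_gap_distance_px = 15,
                            min_track_length = 3L) {
  p <- list(
    max_link_distance_px = as.numeric(max_link_distance_px),
    max_gap_frames = as.integer(max_gap_frames),
    max_gap_distance_px = as.numeric(max_gap_distance_px),
    min_track_length = as.integer(min_track_length)
  )
  stopifnot(p$max_link_distance_px > 0, p$max_gap_frames >= 0,
            p$max_gap_distance_px > 0, p$min_track_length >= 1)
  structure(p, class = "tracking_params")
}

# minimum-total-cost one-to-one assignment with an opt-out alternative.
# cost: n x m matrix; feasible: logical n x m; alt: cost of leaving a row or
# column unassigned. Returns integer vector of length n (matched column or
# NA). Solved as a (n+m) x (n+m) linear assignment problem in the standard
# augmented form, so links are only made when they beat the alternative.
.lap_assign <- function(cost, feasible, alt) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  big <- max(alt, cost[feasible], 0) * (n + m + 1) + 1
  C <- matrix(big, n + m, n + m)
  C[seq_len(n), seq_len(m)] <- ifelse(feasible, cost, big)
  C[cbind(seq_len(n), m + seq_len(n))] <- alt
  C[cbind(n + seq_len(m), seq_len(m))] <- alt
  C[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- as.integer(clue::solve_LSAP(C))
  out <- sol[seq_len(n)]
  out[out > m] <- NA_integer_
  # guard: never return an infeasible link
  hit <- which(!is.na(out))
  bad <- hit[!feasible[cbind(hit, out[hit])]]
  out[bad] <- NA_integer_
  out
}

#' Link detections between two consecutive frames
#'
#' Minimum-total-cost one-to-one assignment on Euclidean centroid distance,
#' with links longer than `max_dist` forbidden. Detections that stay
#' unmatched mark track ends (in `a`) and track starts (in `b`).
#'
#' @param dets_a,dets_b Detection tibbles (columns `x`, `y`) for frames `t`
#'   and `t + 1`.
#' @param max_dist Maximum link distance, px (links at exactly `max_dist`
#'   are allowed).
#' @return A list with `pairs` (tibble of row indices `a`, `b` and `dist`),
#'   `unmatched_a`, and `unmatched_b` (integer row indices).
#' @export
link_frames <- function(dets_a, dets_b, max_dist) {
  n <- nrow(dets_a)
  m <- nrow(dets_b)
  if (n == 0 || m == 0) {
    return(list(pairs = tibble(a = integer(), b = integer(), dist = numeric()),
                unmatched_a = seq_len(n), unmatched_b = seq_len(m)))
  }
  D <- sqrt(outer(dets_a$x, dets_b$x, "-")^2 +
              outer(dets_a$y, dets_b$y, "-")^2)
  feasible <- D <= max_dist
  assign <- .lap_assign(D, feasible, alt = max_dist * (1 + 1e-9) + 1e-9)
  hit <- which(!is.na(assign))
  list(
    pairs = tibble(a = hit, b = assign[hit], dist = D[cbind(hit, assign[hit])]),
    unmatched_a = which(is.na(assign)),
    unmatched_b = setdiff(seq_len(m), assign[hit])
  )
}

#' Build per-channel tracks from frame-sorted detections
#'
#' Sequential frame-to-frame LAP linking produces track stubs; a second
#' global LAP reconnects stub ends to stub starts across gaps of at most
#' `max_gap_frames` missing frames when the jump is within
#' `max_gap_distance_px`. Tracks with fewer than `min_track_length`
#' detections are discarded. Track ids are deterministic: ordered by start
#' frame, then `y`, then `x` of the first detection.
#'
#' @param detections Tibble with at least `frame`, `x`, `y` (typically from
#'   [detect_stack()]).
#' @param params A [tracking_params()].
#' @return A tibble of track points: `track_id`, `frame`, `x`, `y`, plus any
#'   of `area`, `perimeter`, `mean_intensity`, `channel` present in the
#'   input, and `detected = TRUE` (see [interpolate_track_gaps()]).
#' @export
build_tracks <- function(detections, params = tracking_params()) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- dplyr::arrange(detections, .data$frame)
  if (!nrow(det)) return(.empty_tracks(det))

  frames <- sort(unique(det$frame))
  rows_by_frame <- split(seq_len(nrow(det)), det$frame)

  stubs <- list()                     # integer row-index vectors
  open_idx <- integer()               # stubs whose last frame == current
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- rows_by_frame[[as.character(f)]]
    prev_open <- if (fi > 1 && frames[fi - 1] == f - 1) open_idx else integer()
    if (length(prev_open)) {
      last_rows <- vapply(stubs[prev_open], function(s) s[length(s)], integer(1))
      lk <- link_frames(det[last_rows, ], det[rows, ],
                        params$max_link_distance_px)
      new_open <- integer()
      if (nrow(lk$pairs)) {
        for (k in seq_len(nrow(lk$pairs))) {
          si <- prev_open[lk$pairs$a[k]]
          stubs[[si]] <- c(stubs[[si]], rows[lk$pairs$b[k]])
          new_open <- c(new_open, si)
        }
      }
      for (b in lk$unmatched_b) {
        stubs[[length(stubs) + 1L]] <- rows[b]
        new_open <- c(new_open, length(stubs))
      }
      open_idx <- new_open
    } else {
      open_idx <- integer()
      for (r in rows) {
        stubs[[length(stubs) + 1L]] <- r
        open_idx <- c(open_idx, length(stubs))
      }
    }
  }

  # gap closing: global LAP between stub ends and stub starts
  if (length(stubs) > 1 && params$max_gap_frames >= 0) {
    ns <- length(stubs)
    end_row <- vapply(stubs, function(s) s[length(s)], integer(1))
    start_row <- vapply(stubs, function(s) s[1L], integer(1))
    fe <- det$frame[end_row]
    fs <- det$frame[start_row]
    D <- sqrt(outer(det$x[end_row], det$x[start_row], "-")^2 +
                outer(det$y[end_row], det$y[start_row], "-")^2)
    miss <- outer(fe, fs, function(e, s) s - e - 1)
    feasible <- miss >= 0 & miss <= params$max_gap_frames &
      D <= params$max_gap_distance_px
    if (any(feasible)) {
      nxt <- .lap_assign(D, feasible,
                         alt = params$max_gap_distance_px * (1 + 1e-9) + 1e-9)
      is_head <- !(seq_len(ns) %in% nxt[!is.na(nxt)])
      merged <- list()
      for (h in which(is_head)) {
        chain <- stubs[[h]]
        cur <- h
        while (!is.na(nxt[cur])) {
          cur <- nxt[cur]
          chain <- c(chain, stubs[[cur]])
        }
        merged[[length(merged) + 1L]] <- chain
      }
      stubs <- merged
    }
  }

  stubs <- stubs[vapply(stubs, length, integer(1)) >= params$min_track_length]
  if (!length(stubs)) return(.empty_tracks(det))

  ord <- order(
    vapply(stubs, function(s) det$frame[s[1L]], numeric(1)),
    vapply(stubs, function(s) det$y[s[1L]], numeric(1)),
    vapply(stubs, function(s) det$x[s[1L]], numeric(1))
  )
  stubs <- stubs[ord]
  keep_cols <- intersect(c("frame", "x", "y", "area", "perimeter",
                           "mean_intensity", "channel"), names(det))
  out <- purrr::map_dfr(seq_along(stubs), function(i) {
    rows <- det[stubs[[i]], keep_cols]
    rows$track_id <- i
    rows
  })
  out$detected <- TRUE
  dplyr::relocate(out, "track_id")
}

.empty_tracks <- function(det) {
  keep_cols <- intersect(c("frame", "x", "y", "area", "perimeter",
                           "mean_intensity", "channel"), names(det))
  out <- det[integer(), keep_cols, drop = FALSE]
  out$track_id <- integer()
  out$detected <- logical()
  dplyr::relocate(tibble::as_tibble(out), "track_id")
}

#' Fill closed gaps in tracks by linear interpolation
#'
#' Adds one row per missing frame inside each track with linearly
#' interpolated position, `detected = FALSE`, and `NA` morphology. Used
#' before computing track similarities, fused phases and velocities so that
#' gap-closed frames count as observations.
#'
#' @param tracks A track tibble from [build_tracks()].
#' @return The same tibble with interpolated rows inserted, ordered by
#'   `track_id` then `frame`.
#' @export
interpolate_track_gaps <- function(tracks) {
  if (!nrow(tracks)) return(tracks)
  if (!"detected" %in% names(tracks)) tracks$detected <- TRUE
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$frame)
      all_frames <- seq(min(df$frame), max(df$frame))
      if (length(all_frames) == nrow(df)) return(df)
      out <- df[match(all_frames, df$frame), ]
      out$frame <- all_frames
      missing <- is.na(out$detected)
      out$detected[missing] <- FALSE
      out$x <- stats::approx(df$frame, df$x, xout = all_frames)$y
      out$y <- stats::approx(df$frame, df$y, xout = all_frames)$y
      if ("channel" %in% names(out)) out$channel <- df$channel[1]
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$track_id, .data$frame)
}
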