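#' Parameters for red/green track fusion
#'
#' A cell's cdt1 (red) and geminin (green) reporter tracks coexist only
#' around the G1/S transition, so pairing is decided on their temporal
#' overlap: candidate pairs are pre-filtered on a coarse occupancy grid,
#' scored by the average per-frame center distance `s_ij`, and accepted when
#' `s_ij` is strictly below `similarity_threshold`.
#'
#' @param grid_n The FOV is split into `grid_n x grid_n` equal squares for
#'   the candidate pre-filter; 10 works well for a 10x field.
#' @param similarity_threshold Maximum average per-overlapping-frame center
#'   distance, px; pairs at or above it are rejected (strict inequality).
#'   The default of 2 px suits 10x imaging and should be scaled with
#'   magnification.
#' @param min_overlap_frames Minimum number of shared frames for a pair to
#'   be scored; guards against spurious single-frame coincidences.
#' @param transition_criterion Where in the YELLOW (co-expression) window to
#'   place the G1-to-S transition: `"window_mid"` (floor of the midpoint,
#'   default), `"window_start"`, or `"window_end"`.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(grid_n = 10L,
                          similarity_threshold = 2,
                          min_overlap_frames = 2L,
                          transition_criterion = c("window_mid",
                                                   "window_start",
                                                   "window_end")) {
  p <- list(
    grid_n = as.integer(grid_n),
    similarity_threshold = as.numeric(similarity_threshold),
    min_overlap_frames = as.integer(min_overlap_frames),
    transition_criterion = match.arg(transition_criterion)
  )
  stopifnot(p$grid_n >= 1, p$similarity_threshold > 0,
            p$min_overlap_frames >= 1)
  structure(p, class = "fusion_params")
}

# half-open grid square of each position; the far FOV edges close the last
# row/column so every in-FOV point maps to exactly one square
.grid_square <- function(v, fov, n) {
  pmin(floor(v / (fov / n)), n - 1L)
}

#' Pre-filter red/green track pairs on a coarse occupancy grid
#'
#' The FOV is partitioned into `grid_n x grid_n` equal half-open squares; a
#' red and a green track form a candidate pair iff some square is visited by
#' both at any time during their trajectories.
#'
#' @param red_tracks,green_tracks Track tibbles ([build_tracks()] format).
#' @param grid_n Squares per FOV side.
#' @param fov_size_px Side of the square FOV, px.
#' @return A tibble of candidates: `red_id`, `green_id`.
#' @export
grid_prefilter <- function(red_tracks, green_tracks, grid_n, fov_size_px) {
  occ <- function(tr) {
    tr |>
      dplyr::transmute(
        track_id = .data$track_id,
        ix = .grid_square(.data$x, fov_size_px, grid_n),
        iy = .grid_square(.data$y, fov_size_px, grid_n)
      ) |>
      dplyr::distinct()
  }
  if (!nrow(red_tracks) || !nrow(green_tracks)) {
    return(tibble(red_id = integer(), green_id = integer()))
  }
  dplyr::inner_join(occ(red_tracks), occ(green_tracks),
                    by = c("ix", "iy"), relationship = "many-to-many") |>
    dplyr::distinct(red_id = .data$track_id.x, green_id = .data$track_id.y) |>
    dplyr::arrange(.data$red_id, .data$green_id)
}

# score a candidate table in one pass; tracks are gap-interpolated first so
# closed gaps count as observations
.score_candidates <- function(red_tracks, green_tracks, candidates,
                              min_overlap_frames) {
  if (!nrow(candidates)) {
    return(tibble(red_id = integer(), green_id = integer(),
                  n_overlap = integer(), s_ij = numeric()))
  }
  red_i <- interpolate_track_gaps(red_tracks) |>
    dplyr::select(red_id = "track_id", "frame", rx = "x", ry = "y")
  green_i <- interpolate_track_gaps(green_tracks) |>
    dplyr::select(green_id = "track_id", "frame", gx = "x", gy = "y")
  candidates |>
    dplyr::inner_join(red_i, by = "red_id", relationship = "many-to-many") |>
    dplyr::inner_join(green_i, by = c("green_id", "frame"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$red_id, .data$green_id) |>
    dplyr::summarise(
      n_overlap = dplyr::n(),
      s_ij = mean(sqrt((.data$rx - .data$gx)^2 + (.data$ry - .data$gy)^2)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_overlap >= min_overlap_frames) |>
    dplyr::arrange(.data$red_id, .data$green_id)
}

#' Similarity between one red and one green track
#'
#' `s_ij` is the average Euclidean distance between the two nucleus centers
#' over the frames present in both tracks (after linear interpolation of
#' closed gaps). Pairs sharing fewer than `min_overlap_frames` frames are
#' not scored.
#'
#' @param red_track,green_track Single-track tibbles (columns `track_id`,
#'   `frame`, `x`, `y`).
#' @param min_overlap_frames Minimum shared frames.
#' @return A one-row tibble (`red_id`, `green_id`, `n_overlap`, `s_ij`), or
#'   a zero-row tibble if the overlap is insufficient.
#' @export
track_similarity <- function(red_track, green_track, min_overlap_frames = 2L) {
  .score_candidates(
    red_track, green_track,
    tibble(red_id = red_track$track_id[1], green_id = green_track$track_id[1]),
    min_overlap_frames
  )
}

#' One-to-one matching of scored candidate pairs
#'
#' Pairs with `s_ij >= similarity_threshold` are discarded (strict
#' inequality at the boundary); surviving pairs are accepted greedily in
#' ascending `s_ij` order, skipping any pair whose red or green track is
#' already taken. Ties are broken by lower red id, then lower green id, so
#' the matching is deterministic.
#'
#' @param candidates Scored candidates (columns `red_id`, `green_id`,
#'   `s_ij`, and optionally `n_overlap`).
#' @param similarity_threshold Acceptance threshold, px.
#' @return The accepted subset of `candidates`, one row per matched pair.
#' @export
match_pairs <- function(candidates, similarity_threshold = 2) {
  surv <- candidates |>
    dplyr::filter(.data$s_ij < similarity_threshold) |>
    dplyr::arrange(.data$s_ij, .data$red_id, .data$green_id)
  if (!nrow(surv)) return(surv[integer(), ])
  taken_red <- character()
  taken_green <- character()
  keep <- logical(nrow(surv))
  for (k in seq_len(nrow(surv))) {
    r <- as.character(surv$red_id[k])
    g <- as.character(surv$green_id[k])
    if (!(r %in% taken_red) && !(g %in% taken_green)) {
      keep[k] <- TRUE
      taken_red <- c(taken_red, r)
      taken_green <- c(taken_green, g)
    }
  }
  surv[keep, ]
}

#' Fuse a matched red/green track pair into one cell-cycle track
#'
#' Per-frame phase follows the FUCCI reporter logic: RED where only the red
#' track has an observation, YELLOW where both do, GREEN where only the
#' green one does. The fused position is the red centroid on red-only
#' frames, the green centroid on green-only frames and the mean of both on
#' YELLOW frames; morphology is carried per channel. Either track may be
#' `NULL`, giving a single-phase track (so unmatched nuclei still enter
#' tissue-level counts).
#'
#' @param red_track,green_track Single-track tibbles or `NULL`.
#' @return A per-frame tibble: `frame`, `x`, `y`, `phase`, `source`
#'   (`"red_only"`, `"both"`, `"green_only"`), per-channel `area_red`,
#'   `perimeter_red`, `area_green`, `perimeter_green`.
#' @export
fuse_tracks <- function(red_track = NULL, green_track = NULL) {
  has_red <- !is.null(red_track) && nrow(red_track) > 0
  has_green <- !is.null(green_track) && nrow(green_track) > 0
  if (!has_red && !has_green) {
    stop("at least one track must be provided", call. = FALSE)
  }
  prep <- function(tr, side) {
    tr <- interpolate_track_gaps(tr)
    for (col in c("area", "perimeter")) {
      if (!col %in% names(tr)) tr[[col]] <- NA_real_
    }
    tr <- tr[, c("frame", "x", "y", "area", "perimeter")]
    names(tr) <- c("frame", paste0(c("x_", "y_", "area_", "perimeter_"), side))
    tr
  }
  if (has_red && has_green) {
    joined <- dplyr::full_join(prep(red_track, "red"),
                               prep(green_track, "green"), by = "frame") |>
      dplyr::arrange(.data$frame)
    in_red <- !is.na(joined$x_red)
    in_green <- !is.na(joined$x_green)
    if (!any(in_red & in_green)) {
      stop("matched pair has no overlapping frames; upstream matching ",
           "contract violated", call. = FALSE)
    }
    phase <- dplyr::case_when(
      in_red & in_green ~ "YELLOW",
      in_red ~ "RED",
      TRUE ~ "GREEN"
    )
    x <- ifelse(in_red & in_green, (joined$x_red + joined$x_green) / 2,
                ifelse(in_red, joined$x_red, joined$x_green))
    y <- ifelse(in_red & in_green, (joined$y_red + joined$y_green) / 2,
                ifelse(in_red, joined$y_red, joined$y_green))
    out <- tibble(
      frame = joined$frame, x = x, y = y,
      phase = .phase_factor(phase, .VISIBLE_PHASES),
      source = dplyr::case_when(
        in_red & in_green ~ "both",
        in_red ~ "red_only",
        TRUE ~ "green_only"
      ),
      area_red = joined$area_red, perimeter_red = joined$perimeter_red,
      area_green = joined$area_green, perimeter_green = joined$perimeter_green
    )
    return(out)
  }
  side <- if (has_red) "red" else "green"
  tr <- prep(if (has_red) red_track else green_track, side)
  tibble(
    frame = tr$frame,
    x = tr[[paste0("x_", side)]], y = tr[[paste0("y_", side)]],
    phase = .phase_factor(if (has_red) "RED" else "GREEN", .VISIBLE_PHASES),
    source = paste0(side, "_only"),
    area_red = if (has_red) tr$area_red else NA_real_,
    perimeter_red = if (has_red) tr$perimeter_red else NA_real_,
    area_green = if (has_green) tr$area_green else NA_real_,
    perimeter_green = if (has_green) tr$perimeter_green else NA_real_
  )
}

#' Locate the G1-to-S transition of a fused track
#'
#' The transition is placed inside the YELLOW (co-expression) window in a
#' user-independent way: its first frame (`"window_start"`), its last frame
#' (`"window_end"`), or the floor of its midpoint (`"window_mid"`).
#'
#' @param fused_records Per-frame tibble from [fuse_tracks()] (columns
#'   `frame`, `phase`).
#' @param criterion Transition criterion, see [fusion_params()].
#' @return Integer frame, or `NA` if the track has no YELLOW interval.
#' @export
g1s_transition <- function(fused_records,
                           criterion = c("window_mid", "window_start",
                                         "window_end")) {
  criterion <- match.arg(criterion)
  yf <- fused_records$frame[fused_records$phase == "YELLOW"]
  if (!length(yf)) return(NA_integer_)
  switch(criterion,
         window_start = as.integer(min(yf)),
         window_end = as.integer(max(yf)),
         window_mid = as.integer(floor((min(yf) + max(yf)) / 2)))
}

.phase_interval <- function(records, ph, side) {
  f <- records$frame[records$phase == ph]
  if (!length(f)) return(NA_integer_)
  as.integer(if (side == "first") min(f) else max(f))
}

#' Pair and fuse all red and green tracks of a movie
#'
#' Runs the whole pairing pipeline: grid pre-filter, similarity scoring,
#' strict-threshold one-to-one matching, fusion of matched pairs, and
#' retention of unmatched tracks as single-phase cells. Cell ids are
#' deterministic: ordered by start frame, then `y`, then `x` of the first
#' fused record.
#'
#' @param red_tracks,green_tracks Track tibbles ([build_tracks()] format).
#' @param params A [fusion_params()].
#' @param fov_size_px Side of the square FOV, px (needed by the grid
#'   pre-filter).
#' @return An object of class `fucci_cells`: a list with
#'   \describe{
#'     \item{records}{per-(cell, frame) tibble: `cell_id`, `frame`, `x`,
#'       `y`, `phase`, `source`, per-channel morphology;}
#'     \item{cells}{per-cell summary: source track ids, `s_ij`,
#'       `n_overlap`, phase intervals (`red_first` ... `green_last`) and
#'       `g1s_frame`;}
#'     \item{params, fov_size_px}{the inputs.}
#'   }
#'   [tidy()] returns the per-cell summary, [glance()] one-row totals.
#' @export
fuse_all <- function(red_tracks, green_tracks, params = fusion_params(),
                     fov_size_px) {
  stopifnot(inherits(params, "fusion_params"))
  candidates <- grid_prefilter(red_tracks, green_tracks,
                               params$grid_n, fov_size_px)
  scored <- .score_candidates(red_tracks, green_tracks, candidates,
                              params$min_overlap_frames)
  matched <- match_pairs(scored, params$similarity_threshold)

  red_ids <- unique(red_tracks$track_id)
  green_ids <- unique(green_tracks$track_id)
  split_red <- split(red_tracks, red_tracks$track_id)
  split_green <- split(green_tracks, green_tracks$track_id)

  pieces <- list()
  meta <- list()
  if (nrow(matched)) {
    for (k in seq_len(nrow(matched))) {
      rid <- matched$red_id[k]
      gid <- matched$green_id[k]
      pieces[[length(pieces) + 1L]] <-
        fuse_tracks(split_red[[as.character(rid)]],
                    split_green[[as.character(gid)]])
      meta[[length(meta) + 1L]] <-
        list(red_track_id = rid, green_track_id = gid,
             s_ij = matched$s_ij[k], n_overlap = matched$n_overlap[k])
    }
  }
  for (rid in setdiff(red_ids, matched$red_id)) {
    pieces[[length(pieces) + 1L]] <- fuse_tracks(split_red[[as.character(rid)]], NULL)
    meta[[length(meta) + 1L]] <- list(red_track_id = rid,
                                      green_track_id = NA_integer_,
                                      s_ij = NA_real_, n_overlap = NA_integer_)
  }
  for (gid in setdiff(green_ids, matched$green_id)) {
    pieces[[length(pieces) + 1L]] <- fuse_tracks(NULL, split_green[[as.character(gid)]])
    meta[[length(meta) + 1L]] <- list(red_track_id = NA_integer_,
                                      green_track_id = gid,
                                      s_ij = NA_real_, n_overlap = NA_integer_)
  }

  if (!length(pieces)) {
    records <- tibble(
      cell_id = integer(), frame = integer(), x = numeric(), y = numeric(),
      phase = .phase_factor(character(), .VISIBLE_PHASES), source = character(),
      area_red = numeric(), perimeter_red = numeric(),
      area_green = numeric(), perimeter_green = numeric()
    )
    cells <- tibble(
      cell_id = integer(), red_track_id = integer(), green_track_id = integer(),
      s_ij = numeric(), n_overlap = integer(),
      start_frame = integer(), end_frame = integer(),
      red_first = integer(), red_last = integer(),
      yellow_first = integer(), yellow_last = integer(),
      green_first = integer(), green_last = integer(),
      g1s_frame = integer()
    )
    return(structure(list(records = records, cells = cells, params = params,
                          fov_size_px = fov_size_px),
                     class = "fucci_cells"))
  }

  ord <- order(
    vapply(pieces, function(p) min(p$frame), numeric(1)),
    vapply(pieces, function(p) p$y[which.min(p$frame)], numeric(1)),
    vapply(pieces, function(p) p$x[which.min(p$frame)], numeric(1))
  )
  pieces <- pieces[ord]
  meta <- meta[ord]

  records <- purrr::map_dfr(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    p$cell_id <- i
    dplyr::relocate(p, "cell_id")
  })
  cells <- purrr::map_dfr(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    m <- meta[[i]]
    tibble(
      cell_id = i,
      red_track_id = as.integer(m$red_track_id),
      green_track_id = as.integer(m$green_track_id),
      s_ij = m$s_ij, n_overlap = as.integer(m$n_overlap),
      start_frame = as.integer(min(p$frame)),
      end_frame = as.integer(max(p$frame)),
      red_first = .phase_interval(p, "RED", "first"),
      red_last = .phase_interval(p, "RED", "last"),
      yellow_first = .phase_interval(p, "YELLOW", "first"),
      yellow_last = .phase_interval(p, "YELLOW", "last"),
      green_first = .phase_interval(p, "GREEN", "first"),
      green_last = .phase_interval(p, "GREEN", "last"),
      g1s_frame = g1s_transition(p, params$transition_criterion)
    )
  })
  structure(list(records = records, cells = cells, params = params,
                 fov_size_px = fov_size_px),
            class = "fucci_cells")
}

#' @export
print.fucci_cells <- function(x, ...) {
  g <- glance(x)
  cat("<fucci_cells> ", g$n_cells, " cells (", g$n_matched, " matched pairs, ",
      g$n_red_only, " red-only, ", g$n_green_only, " green-only), frames ",
      min(x$records$frame), "-", max(x$records$frame), "\n", sep = "")
  invisible(x)
}

#' @rdname fuse_all
#' @param x A `fucci_cells` object.
#' @param ... Unused.
#' @method tidy fucci_cells
#' @export
tidy.fucci_cells <- function(x, ...) x$cells

#' @rdname fuse_all
#' @method glance fucci_cells
#' @export
glance.fucci_cells <- function(x, ...) {
  cells <- x$cells
  matched <- !is.na(cells$red_track_id) & !is.na(cells$green_track_id)
  tibble(
    n_cells = nrow(cells),
    n_matched = sum(matched),
    n_red_only = sum(!is.na(cells$red_track_id) & is.na(cells$green_track_id)),
    n_green_only = sum(is.na(cells$red_track_id) & !is.na(cells$green_track_id)),
    median_s_ij = stats::median(cells$s_ij, na.rm = TRUE),
    median_yellow_frames = stats::median(
      cells$yellow_last - cells$yellow_first + 1, na.rm = TRUE
    )
  )
}
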