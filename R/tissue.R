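#' Voronoi tessellation of nucleus centers in one frame
#'
#' Approximates each cell's footprint in a confluent monolayer by the
#' Voronoi region of its nucleus center, clipped to the FOV rectangle.
#' Regions touching the FOV boundary are flagged (`is_border`); their
#' clipped areas are biased and are excluded from downstream statistics by
#' default. The approximation is only meaningful in dense, confluent
#' conditions.
#'
#' @param centers Tibble with columns `x`, `y` (0-based px) and optionally
#'   `cell_id`; typically the pooled red+green fused records of one frame.
#' @param fov_size_px Side of the square FOV, px.
#' @param frame Optional 0-based frame index recorded in the output (also
#'   used in error messages).
#' @return A tibble with one row per center: `cell_id`, `frame`, `x`, `y`
#'   (the seed), `area` (px^2), `perimeter` (px), `is_border`, and the
#'   clipped polygon as a WKT string (`polygon`).
#' @export
voronoi_frame <- function(centers, fov_size_px, frame = NA_integer_) {
  stopifnot(all(c("x", "y") %in% names(centers)))
  n <- nrow(centers)
  if (n < 1) stop("voronoi_frame() needs at least one center", call. = FALSE)
  if (any(centers$x < 0 | centers$x > fov_size_px |
            centers$y < 0 | centers$y > fov_size_px)) {
    stop("centers must lie inside the FOV", call. = FALSE)
  }
  key <- paste(round(centers$x, 9), round(centers$y, 9))
  if (anyDuplicated(key)) {
    stop("duplicate nucleus centers (< 1e-9 px apart) in frame ",
         frame, call. = FALSE)
  }
  ids <- if ("cell_id" %in% names(centers)) centers$cell_id else seq_len(n)

  poly_row <- function(i, px, py) {
    # close the polygon, compute perimeter and WKT
    wkt <- paste0("POLYGON ((",
                  paste(sprintf("%.6f %.6f", c(px, px[1]), c(py, py[1])),
                        collapse = ", "), "))")
    per <- sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
    border <- any(abs(px) < 1e-9 | abs(px - fov_size_px) < 1e-9 |
                    abs(py) < 1e-9 | abs(py - fov_size_px) < 1e-9)
    list(perimeter = per, is_border = border, polygon = wkt)
  }

  if (n == 1) {
    L <- fov_size_px
    pr <- poly_row(1, c(0, L, L, 0), c(0, 0, L, L))
    return(tibble(
      cell_id = ids, frame = as.integer(frame),
      x = centers$x, y = centers$y,
      area = as.numeric(L)^2, perimeter = pr$perimeter,
      is_border = pr$is_border, polygon = pr$polygon
    ))
  }

  dd <- deldir::deldir(centers$x, centers$y,
                       rw = c(0, fov_size_px, 0, fov_size_px),
                       suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  pt <- vapply(tl, function(t) t$ptNum, integer(1))
  out <- purrr::map_dfr(seq_along(tl), function(k) {
    t <- tl[[k]]
    pr <- poly_row(k, t$x, t$y)
    tibble(
      cell_id = ids[pt[k]], frame = as.integer(frame),
      x = centers$x[pt[k]], y = centers$y[pt[k]],
      area = t$area, perimeter = pr$perimeter,
      is_border = pr$is_border, polygon = pr$polygon
    )
  })
  dplyr::arrange(out, .data$cell_id)
}

#' Voronoi cells for every frame of a fused-track set
#'
#' Pools all nucleus centers (both channels) present in each frame and
#' tessellates frame by frame.
#'
#' @param records Fused per-frame records ([fuse_all()]`$records`) or any
#'   tibble with `cell_id`, `frame`, `x`, `y`.
#' @param fov_size_px Side of the square FOV, px.
#' @return A tibble of [voronoi_frame()] rows over all frames.
#' @export
voronoi_cells <- function(records, fov_size_px) {
  if (inherits(records, "fucci_cells")) records <- records$records
  purrr::map_dfr(sort(unique(records$frame)), function(f) {
    voronoi_frame(records[records$frame == f, ], fov_size_px, frame = f)
  })
}

#' Unit conversions and sampling parameters for tissue kinematics
#'
#' @param bin_side_fraction Velocity-averaging bin side as a fraction of the
#'   FOV length (default 1/10).
#' @param grid_row_spacing_fraction Row spacing (and inter-row horizontal
#'   offset) of the triangular sampling lattice as a fraction of the FOV
#'   length (default 1/20); its reciprocal must be an even integer.
#' @param velocity_window_frames Number of frames pooled per velocity field.
#' @param px_per_um Pixels per micrometre (1 keeps px units).
#' @param min_per_frame Minutes per frame (1 keeps frame units).
#' @return A list of class `kinematics_params`.
#' @export
kinematics_params <- function(bin_side_fraction = 1 / 10,
                              grid_row_spacing_fraction = 1 / 20,
                              velocity_window_frames = 1L,
                              px_per_um = 1,
                              min_per_frame = 1) {
  p <- list(
    bin_side_fraction = as.numeric(bin_side_fraction),
    grid_row_spacing_fraction = as.numeric(grid_row_spacing_fraction),
    velocity_window_frames = as.integer(velocity_window_frames),
    px_per_um = as.numeric(px_per_um),
    min_per_frame = as.numeric(min_per_frame)
  )
  stopifnot(p$bin_side_fraction > 0, p$bin_side_fraction <= 1,
            p$grid_row_spacing_fraction > 0,
            p$grid_row_spacing_fraction <= 0.25,
            p$velocity_window_frames >= 1,
            p$px_per_um > 0, p$min_per_frame > 0)
  structure(p, class = "kinematics_params")
}

#' Per-frame tangential velocity of tracked nuclei
#'
#' Forward differences of the (gap-interpolated) positions:
#' `v(t) = (r(t + 1) - r(t)) / dframes`; the last frame of each track
#' carries the previous vector. Tracks observed in a single frame get `NA`
#' velocities.
#'
#' @param records Tibble with `frame`, `x`, `y` and an id column (`cell_id`
#'   or `track_id`), e.g. [fuse_all()]`$records`.
#' @return The input with `vx`, `vy` columns appended (px/frame).
#' @export
tangential_velocity <- function(records) {
  if (inherits(records, "fucci_cells")) records <- records$records
  id_col <- if ("cell_id" %in% names(records)) "cell_id" else "track_id"
  records |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      vx = (dplyr::lead(.data$x) - .data$x) /
        (dplyr::lead(.data$frame) - .data$frame),
      vy = (dplyr::lead(.data$y) - .data$y) /
        (dplyr::lead(.data$frame) - .data$frame),
      vx = ifelse(is.na(.data$vx) & dplyr::n() > 1,
                  dplyr::lag(.data$vx), .data$vx),
      vy = ifelse(is.na(.data$vy) & dplyr::n() > 1,
                  dplyr::lag(.data$vy), .data$vy)
    ) |>
    dplyr::ungroup()
}

#' Triangular sampling lattice for the Eulerian velocity field
#'
#' Alternating-row triangular lattice centered in the square FOV: "full"
#' rows with in-row spacing of 1/10 of the FOV length interleaved with
#' offset rows shifted by 1/20, with rows 1/20 of the FOV length apart. The
#' default fractions give 10 full rows of 10 points and 9 offset rows of 9
#' points: 181 sample points, all strictly inside the FOV.
#'
#' @param fov_size_px Side of the square FOV, px.
#' @param params A [kinematics_params()].
#' @return A tibble: `point_id`, `x`, `y`.
#' @export
velocity_grid <- function(fov_size_px, params = kinematics_params()) {
  L <- as.numeric(fov_size_px)
  f <- params$grid_row_spacing_fraction
  m <- round(1 / (2 * f))
  if (abs(1 / (2 * f) - m) > 1e-9 || m < 2) {
    stop("grid_row_spacing_fraction must be 1 / (2 m) for integer m >= 2",
         call. = FALSE)
  }
  s <- L * f
  rows <- purrr::map_dfr(0:(2 * m - 2), function(r) {
    y <- (r + 1) * s
    if (r %% 2 == 0) {
      x <- (2 * seq_len(m) - 1) * s
    } else {
      x <- (2 * seq_len(m - 1)) * s
    }
    tibble(x = x, y = y)
  })
  if (any(rows$x <= 0 | rows$x >= L | rows$y <= 0 | rows$y >= L)) {
    stop("sampling lattice exceeds the FOV", call. = FALSE)
  }
  dplyr::mutate(rows, point_id = dplyr::row_number(), .before = 1)
}

#' Eulerian velocity field on the triangular sampling lattice
#'
#' For each lattice point, averages the tangential velocity vectors of all
#' nuclei whose positions within the frame window fall inside the square
#' bin of side `bin_side_fraction * FOV` centered at the point. Bins are
#' wider than the point spacing by construction, so neighbouring samples
#' overlap; this is intended smoothing. Empty bins are flagged undefined.
#'
#' @param records Fused records (or a `fucci_cells` object, or any tibble
#'   with an id column, `frame`, `x`, `y`).
#' @param frames Frames pooled into this field (0-based); defaults to all.
#' @param fov_size_px Side of the square FOV, px.
#' @param params A [kinematics_params()]; `px_per_um` and `min_per_frame`
#'   convert the output to um/min when not 1.
#' @return A tibble of class `fucci_velocity_field`: `point_id`, `x`, `y`,
#'   `vx`, `vy`, `n` (nuclei in the bin), `defined`. Attributes record the
#'   FOV, frame window, bin side and units.
#' @export
velocity_field <- function(records, frames = NULL, fov_size_px,
                           params = kinematics_params()) {
  if (inherits(records, "fucci_cells")) records <- records$records
  v <- tangential_velocity(records)
  if (is.null(frames)) frames <- sort(unique(v$frame))
  v <- v[v$frame %in% frames & !is.na(v$vx), ]
  grid <- velocity_grid(fov_size_px, params)
  b <- fov_size_px * params$bin_side_fraction
  scale <- (1 / params$px_per_um) / params$min_per_frame
  units <- if (params$px_per_um == 1 && params$min_per_frame == 1) {
    "px/frame"
  } else {
    "um/min"
  }
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    inside <- abs(v$x - grid$x[k]) <= b / 2 & abs(v$y - grid$y[k]) <= b / 2
    n <- sum(inside)
    tibble(
      point_id = grid$point_id[k], x = grid$x[k], y = grid$y[k],
      vx = if (n) mean(v$vx[inside]) * scale else NA_real_,
      vy = if (n) mean(v$vy[inside]) * scale else NA_real_,
      n = n, defined = n > 0
    )
  })
  structure(res,
            class = c("fucci_velocity_field", class(res)),
            fov_size_px = fov_size_px, frames = frames,
            bin_side_px = b, units = units)
}

#' Tissue-level phase counts and fractions over time
#'
#' Counts fused cells by phase label (RED/YELLOW/GREEN) in every frame;
#' fractions are counts over the total number of cells present.
#'
#' @param records Fused records or a `fucci_cells` object.
#' @return A tibble of class `fucci_phase_counts`, one row per frame:
#'   `frame`, `n_red`, `n_yellow`, `n_green`, `total`, `frac_red`,
#'   `frac_yellow`, `frac_green`.
#' @export
phase_counts <- function(records) {
  if (inherits(records, "fucci_cells")) records <- records$records
  records$phase <- .phase_factor(records$phase, .VISIBLE_PHASES)
  out <- records |>
    dplyr::count(.data$frame, .data$phase) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "n",
                       values_fill = 0L,
                       names_expand = TRUE) |>
    dplyr::rename(n_red = "RED", n_yellow = "YELLOW", n_green = "GREEN") |>
    dplyr::mutate(
      total = .data$n_red + .data$n_yellow + .data$n_green,
      frac_red = ifelse(.data$total > 0, .data$n_red / .data$total, NA_real_),
      frac_yellow = ifelse(.data$total > 0, .data$n_yellow / .data$total, NA_real_),
      frac_green = ifelse(.data$total > 0, .data$n_green / .data$total, NA_real_)
    ) |>
    dplyr::arrange(.data$frame)
  structure(out, class = c("fucci_phase_counts", class(out)))
}

#' Mean Voronoi area per phase over time, with 95% confidence intervals
#'
#' Joins Voronoi cell areas to fused phase labels on `(cell_id, frame)` and
#' summarises per frame and phase: mean area, sd, and a normal-approximation
#' 95% interval (`mean +/- 1.96 sd / sqrt(n)`, undefined for `n < 2`).
#' Border-touching Voronoi cells are excluded by default because their
#' clipped areas are biased.
#'
#' @param voronoi Tibble from [voronoi_cells()].
#' @param records Fused records or a `fucci_cells` object.
#' @param exclude_border Drop cells whose Voronoi polygon touches the FOV
#'   boundary.
#' @return A tibble of class `fucci_area_by_phase`: `frame`, `phase`, `n`,
#'   `mean_area`, `sd_area`, `ci_low`, `ci_high` (areas in px^2).
#' @export
area_by_phase <- function(voronoi, records, exclude_border = TRUE) {
  if (inherits(records, "fucci_cells")) records <- records$records
  if (exclude_border) voronoi <- voronoi[!voronoi$is_border, ]
  out <- voronoi |>
    dplyr::inner_join(
      dplyr::select(records, "cell_id", "frame", "phase"),
      by = c("cell_id", "frame")
    ) |>
    dplyr::group_by(.data$frame, .data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_area = mean(.data$area),
      sd_area = stats::sd(.data$area),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = ifelse(.data$n >= 2,
                      .data$mean_area - 1.96 * .data$sd_area / sqrt(.data$n),
                      NA_real_),
      ci_high = ifelse(.data$n >= 2,
                       .data$mean_area + 1.96 * .data$sd_area / sqrt(.data$n),
                       NA_real_)
    ) |>
    dplyr::arrange(.data$frame, .data$phase)
  structure(out, class = c("fucci_area_by_phase", class(out)))
}
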