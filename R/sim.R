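#' Configuration for the synthetic FUCCI monolayer simulator
#'
#' Bundles and validates every knob of the synthetic movie generator. The
#' defaults emulate a confluent MDCK-like monolayer imaged at 10x with one
#' frame every 10 minutes: a ~10 h movie of a few hundred densely packed,
#' collectively drifting nuclei whose FUCCI reporters progress
#' COLORLESS -> RED (cdt1 high, G0/G1) -> YELLOW (co-expression around the
#' G1/S transition) -> GREEN (geminin high, S/G2/M) -> division.
#'
#' @param fov_size_px Side of the square field of view, pixels (>= 64).
#' @param n_frames Number of frames to simulate.
#' @param dt_min Minutes per frame (metadata only; the clock runs in frames).
#' @param n_cells_init Number of cells at frame 0.
#' @param motility_speed Persistent-random-walk step length, px/frame.
#' @param persistence Directional persistence in `[0, 1]`; 1 keeps the
#'   heading fixed, 0 redraws it uniformly each frame.
#' @param drift Uniform advection of the whole sheet, px/frame (length-2).
#' @param repulsion_radius Soft-disk repulsion range, px. Cells closer than
#'   this push apart; initial seeding enforces it as a minimum spacing and
#'   keeps nucleus centers at least `repulsion_radius / 2` from the walls.
#' @param phase_durations Named vector/list with mean durations in frames for
#'   `red`, `yellow`, `green` and `colorless`.
#' @param phase_duration_cv Coefficient of variation of the per-cell phase
#'   durations (drawn once per cell from a normal truncated at 1 frame).
#' @param nucleus_sigma_px Gaussian-spot radius used when rendering nuclei.
#' @param peak_intensity Named vector/list with `red` and `green` peak
#'   amplitudes, camera counts.
#' @param background Additive background level, counts.
#' @param noise_sd Gaussian read-noise standard deviation, counts.
#' @param division_enabled When `TRUE` a cell whose GREEN phase expires is
#'   replaced by two COLORLESS daughters offset by `repulsion_radius / 2`
#'   along a random axis; when `FALSE` cells hold GREEN indefinitely.
#' @param init_phase `"random"` places each initial cell at a uniformly
#'   random point of its own cycle; alternatively one of `"COLORLESS"`,
#'   `"RED"`, `"YELLOW"`, `"GREEN"` starts every cell at the beginning of
#'   that phase.
#' @param rng_seed Integer seed; all stochastic draws flow from one stream
#'   seeded here, so equal configs give byte-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(fov_size_px = 512L,
                       n_frames = 60L,
                       dt_min = 10,
                       n_cells_init = 150L,
                       motility_speed = 1,
                       persistence = 0.7,
                       drift = c(0, 0),
                       repulsion_radius = 12,
                       phase_durations = c(red = 25, yellow = 8, green = 25, colorless = 3),
                       phase_duration_cv = 0.15,
                       nucleus_sigma_px = 3,
                       peak_intensity = c(red = 1000, green = 1000),
                       background = 10,
                       noise_sd = 5,
                       division_enabled = TRUE,
                       init_phase = "random",
                       rng_seed = 1L) {
  phase_durations <- unlist(phase_durations)
  peak_intensity <- unlist(peak_intensity)
  cfg <- list(
    fov_size_px = as.integer(fov_size_px),
    n_frames = as.integer(n_frames),
    dt_min = as.numeric(dt_min),
    n_cells_init = as.integer(n_cells_init),
    motility_speed = as.numeric(motility_speed),
    persistence = as.numeric(persistence),
    drift = as.numeric(drift),
    repulsion_radius = as.numeric(repulsion_radius),
    phase_durations = phase_durations[c("red", "yellow", "green", "colorless")],
    phase_duration_cv = as.numeric(phase_duration_cv),
    nucleus_sigma_px = as.numeric(nucleus_sigma_px),
    peak_intensity = peak_intensity[c("red", "green")],
    background = as.numeric(background),
    noise_sd = as.numeric(noise_sd),
    division_enabled = isTRUE(division_enabled),
    init_phase = match.arg(init_phase, c("random", .PHASES)),
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$fov_size_px >= 64,
    cfg$n_frames >= 1,
    cfg$n_cells_init >= 1,
    cfg$motility_speed >= 0,
    cfg$persistence >= 0, cfg$persistence <= 1,
    length(cfg$drift) == 2,
    cfg$repulsion_radius >= 0,
    !anyNA(cfg$phase_durations), all(cfg$phase_durations >= 1),
    cfg$phase_duration_cv >= 0,
    cfg$nucleus_sigma_px > 0,
    !anyNA(cfg$peak_intensity), all(cfg$peak_intensity >= 0),
    cfg$background >= 0,
    cfg$noise_sd >= 0
  )
  if (cfg$n_cells_init * cfg$repulsion_radius^2 > cfg$fov_size_px^2) {
    stop("over-packed configuration: n_cells_init * repulsion_radius^2 ",
         "exceeds the FOV area", call. = FALSE)
  }
  if (cfg$repulsion_radius >= cfg$fov_size_px) {
    stop("repulsion_radius must be smaller than the FOV", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$fov_size_px, "x", x$fov_size_px, " px, ",
      x$n_frames, " frames, ", x$n_cells_init, " initial cells, seed ",
      x$rng_seed, "\n", sep = "")
  invisible(x)
}

# per-cell phase durations, drawn once (normal truncated at 1 frame, rounded)
.draw_durations <- function(cfg) {
  mu <- cfg$phase_durations[c("colorless", "red", "yellow", "green")]
  if (cfg$phase_duration_cv == 0) {
    return(round(unname(mu)))
  }
  pmax(1, round(rnorm(4, mean = mu, sd = cfg$phase_duration_cv * mu)))
}

# reporter amplitudes for a cell at `elapsed` frames into phase `idx`
# (1 = COLORLESS, 2 = RED, 3 = YELLOW, 4 = GREEN). Piecewise linear,
# evaluated at the frame midpoint so both reporters stay strictly positive
# throughout YELLOW.
.reporter_intensity <- function(idx, elapsed, dur, peak_red, peak_green) {
  f <- (elapsed + 0.5) / dur[idx]
  red <- switch(idx, 0, peak_red * f, peak_red * (1 - f), 0)
  green <- switch(idx, 0, 0, peak_green * f, peak_green)
  c(red = red, green = green)
}

# dart-throwing placement with a hard minimum spacing and a wall margin
.seed_positions <- function(n, fov, min_dist, margin) {
  lo <- margin
  hi <- fov - margin
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " cells at spacing ", min_dist,
           " in a ", fov, " px FOV", call. = FALSE)
    }
    x <- runif(1, lo, hi)
    y <- runif(1, lo, hi)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= min_dist^2) {
      placed <- placed + 1L
      xs[placed] <- x
      ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

.reflect_into <- function(p, lo, hi) {
  # reflect a coordinate into [lo, hi]
  span <- hi - lo
  if (span <= 0) return(rep((lo + hi) / 2, length(p)))
  for (i in seq_along(p)) {
    while (p[i] < lo || p[i] > hi) {
      if (p[i] < lo) p[i] <- 2 * lo - p[i]
      if (p[i] > hi) p[i] <- 2 * hi - p[i]
    }
  }
  p
}

#' Simulate a confluent FUCCI monolayer with ground truth
#'
#' Runs a persistent random walk with soft pairwise repulsion, uniform drift
#' and reflecting walls for every nucleus, while a per-cell phase clock
#' advances COLORLESS -> RED -> YELLOW -> GREEN with durations drawn once per
#' cell. On GREEN expiry (if `division_enabled`) the cell is replaced by two
#' COLORLESS daughters. Deterministic for a fixed `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble of ground-truth records, one row per (cell, frame):
#'   `cell_id`, `frame` (0-based), `x`, `y` (px), `phase`
#'   (factor COLORLESS/RED/YELLOW/GREEN), `red_intensity`, `green_intensity`
#'   (spot peak amplitudes, counts) and `parent_id` (`NA` for founder cells).
#'   The config is attached as attribute `"config"`.
#' @export
#' @examples
#' truth <- simulate_monolayer(sim_config(
#'   fov_size_px = 128, n_frames = 10, n_cells_init = 8, rng_seed = 42
#' ))
#' dplyr::count(truth, frame)
simulate_monolayer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  .with_seed(cfg$rng_seed, {
    L <- cfg$fov_size_px
    margin <- cfg$repulsion_radius / 2
    lo <- margin
    hi <- L - margin
    n0 <- cfg$n_cells_init

    pos <- .seed_positions(n0, L, cfg$repulsion_radius, margin)
    cells <- vector("list", n0)
    for (i in seq_len(n0)) {
      dur <- .draw_durations(cfg)
      if (cfg$init_phase == "random") {
        u <- runif(1, 0, sum(dur))
        idx <- findInterval(u, cumsum(dur), left.open = TRUE) + 1L
        elapsed <- floor(u - c(0, cumsum(dur))[idx])
      } else {
        idx <- match(cfg$init_phase, .PHASES)
        elapsed <- 0L
      }
      cells[[i]] <- list(
        id = i, x = pos[i, 1], y = pos[i, 2],
        theta = runif(1, -pi, pi),
        dur = dur, idx = idx, elapsed = elapsed,
        parent = NA_integer_
      )
    }
    next_id <- n0 + 1L

    out <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames) - 1L) {
      n <- length(cells)
      ids <- vapply(cells, `[[`, integer(1), "id")
      xs <- vapply(cells, `[[`, numeric(1), "x")
      ys <- vapply(cells, `[[`, numeric(1), "y")
      idxs <- vapply(cells, `[[`, integer(1), "idx")
      elap <- vapply(cells, `[[`, numeric(1), "elapsed")
      inten <- t(vapply(seq_len(n), function(i) {
        .reporter_intensity(cells[[i]]$idx, cells[[i]]$elapsed, cells[[i]]$dur,
                            cfg$peak_intensity[["red"]], cfg$peak_intensity[["green"]])
      }, numeric(2)))
      out[[t + 1L]] <- tibble(
        cell_id = ids, frame = t, x = xs, y = ys,
        phase = .PHASES[idxs],
        red_intensity = inten[, 1], green_intensity = inten[, 2],
        parent_id = vapply(cells, `[[`, integer(1), "parent")
      )
      if (t == cfg$n_frames - 1L) break

      # phase clock
      dividing <- logical(n)
      for (i in seq_len(n)) {
        c_i <- cells[[i]]
        c_i$elapsed <- c_i$elapsed + 1
        while (c_i$idx < 4L && c_i$elapsed >= c_i$dur[c_i$idx]) {
          c_i$elapsed <- c_i$elapsed - c_i$dur[c_i$idx]
          c_i$idx <- c_i$idx + 1L
        }
        if (c_i$idx == 4L && c_i$elapsed >= c_i$dur[4L]) {
          if (cfg$division_enabled) {
            dividing[i] <- TRUE
          } else {
            c_i$elapsed <- c_i$dur[4L] - 1  # hold GREEN
          }
        }
        cells[[i]] <- c_i
      }

      # motion: persistent random walk + drift + soft repulsion, then reflect
      push_x <- numeric(n)
      push_y <- numeric(n)
      if (cfg$repulsion_radius > 0 && n > 1) {
        dx <- outer(xs, xs, "-")
        dy <- outer(ys, ys, "-")
        dmat <- sqrt(dx^2 + dy^2)
        close <- which(dmat < cfg$repulsion_radius & upper.tri(dmat), arr.ind = TRUE)
        if (nrow(close)) {
          for (k in seq_len(nrow(close))) {
            i <- close[k, 1]; j <- close[k, 2]
            d <- dmat[i, j]
            if (d < 1e-9) {
              ang <- runif(1, -pi, pi)
              ux <- cos(ang); uy <- sin(ang)
            } else {
              ux <- (xs[i] - xs[j]) / d
              uy <- (ys[i] - ys[j]) / d
            }
            f <- 0.25 * (cfg$repulsion_radius - d)
            push_x[i] <- push_x[i] + f * ux
            push_y[i] <- push_y[i] + f * uy
            push_x[j] <- push_x[j] - f * ux
            push_y[j] <- push_y[j] - f * uy
          }
        }
      }
      dtheta <- rnorm(n, 0, (1 - cfg$persistence) * pi)
      for (i in seq_len(n)) {
        c_i <- cells[[i]]
        c_i$theta <- c_i$theta + dtheta[i]
        c_i$x <- c_i$x + cfg$motility_speed * cos(c_i$theta) +
          cfg$drift[1] + push_x[i]
        c_i$y <- c_i$y + cfg$motility_speed * sin(c_i$theta) +
          cfg$drift[2] + push_y[i]
        c_i$x <- .reflect_into(c_i$x, lo, hi)
        c_i$y <- .reflect_into(c_i$y, lo, hi)
        cells[[i]] <- c_i
      }

      # divisions: parent removed, two COLORLESS daughters appear next frame
      if (any(dividing)) {
        keep <- cells[!dividing]
        for (i in which(dividing)) {
          p <- cells[[i]]
          ang <- runif(1, -pi, pi)
          off <- cfg$repulsion_radius / 2
          for (s in c(-1, 1)) {
            d <- list(
              id = next_id,
              x = .reflect_into(p$x + s * off * cos(ang), lo, hi),
              y = .reflect_into(p$y + s * off * sin(ang), lo, hi),
              theta = runif(1, -pi, pi),
              dur = .draw_durations(cfg),
              idx = 1L, elapsed = 0L,
              parent = p$id
            )
            next_id <- next_id + 1L
            keep <- c(keep, list(d))
          }
        }
        cells <- keep
      }
    }
    records <- dplyr::bind_rows(out)
    records$phase <- .phase_factor(records$phase)
    attr(records, "config") <- cfg
    records
  })
}

#' Render ground-truth records into red/green fluorescence stacks
#'
#' Each nucleus becomes an isotropic Gaussian spot (sd `nucleus_sigma_px`)
#' centered at its ground-truth position with peak amplitude equal to the
#' record's reporter intensity. An additive uniform background and optional
#' Gaussian read noise complete the camera model; negative values are clipped
#' to zero. COLORLESS cells contribute to neither channel.
#'
#' @param records Ground truth from [simulate_monolayer()].
#' @param config The matching [sim_config()]; defaults to the config attached
#'   to `records`.
#' @return A list with elements `red` and `green`, each an `H x W x T` array
#'   of counts (`H = W = fov_size_px`, `T = n_frames`).
#' @export
render_channels <- function(records, config = attr(records, "config")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$fov_size_px
  TT <- cfg$n_frames
  red <- array(cfg$background, dim = c(L, L, TT))
  green <- array(cfg$background, dim = c(L, L, TT))
  sg <- cfg$nucleus_sigma_px
  win <- ceiling(4 * sg)

  add_spot <- function(mat, x, y, amp) {
    # x, y are 0-based; matrix is [row = y + 1, col = x + 1]
    r0 <- max(1L, floor(y + 1 - win)); r1 <- min(L, ceiling(y + 1 + win))
    c0 <- max(1L, floor(x + 1 - win)); c1 <- min(L, ceiling(x + 1 + win))
    if (r0 > r1 || c0 > c1) return(mat)
    ry <- exp(-((r0:r1 - 1 - y)^2) / (2 * sg^2))
    cx <- exp(-((c0:c1 - 1 - x)^2) / (2 * sg^2))
    mat[r0:r1, c0:c1] <- mat[r0:r1, c0:c1] + amp * outer(ry, cx)
    mat
  }

  for (t in seq_len(TT) - 1L) {
    fr <- records[records$frame == t, ]
    if (!nrow(fr)) next
    rmat <- red[, , t + 1L]
    gmat <- green[, , t + 1L]
    for (i in seq_len(nrow(fr))) {
      if (fr$red_intensity[i] > 0) {
        rmat <- add_spot(rmat, fr$x[i], fr$y[i], fr$red_intensity[i])
      }
      if (fr$green_intensity[i] > 0) {
        gmat <- add_spot(gmat, fr$x[i], fr$y[i], fr$green_intensity[i])
      }
    }
    red[, , t + 1L] <- rmat
    green[, , t + 1L] <- gmat
  }

  if (cfg$noise_sd > 0) {
    # separate, reproducible stream so rendering never perturbs the
    # trajectory draws
    .with_seed(cfg$rng_seed + 1L, {
      red <- red + array(rnorm(length(red), 0, cfg$noise_sd), dim = dim(red))
      green <- green + array(rnorm(length(green), 0, cfg$noise_sd), dim = dim(green))
    })
  }
  red[red < 0] <- 0
  green[green < 0] <- 0
  list(red = red, green = green)
}

#' Convert ground-truth records to per-channel track tables
#'
#' A cell's red track covers its RED and YELLOW frames (cdt1 reporter
#' present); its green track covers YELLOW and GREEN frames. Useful to feed
#' the fusion and tissue stages directly from simulated truth, bypassing
#' segmentation and tracking.
#'
#' @param records Ground truth from [simulate_monolayer()].
#' @return A list with `red` and `green` track tibbles in the format of
#'   [build_tracks()] (`track_id` equals the ground-truth `cell_id`).
#' @export
truth_to_tracks <- function(records) {
  mk <- function(phases, channel, intensity_col) {
    records |>
      dplyr::filter(.data$phase %in% phases) |>
      dplyr::transmute(
        track_id = .data$cell_id, frame = .data$frame,
        x = .data$x, y = .data$y,
        area = NA_real_, perimeter = NA_real_,
        mean_intensity = .data[[intensity_col]],
        channel = channel, detected = TRUE
      ) |>
      dplyr::arrange(.data$track_id, .data$frame)
  }
  list(
    red = mk(c("RED", "YELLOW"), "RED", "red_intensity"),
    green = mk(c("YELLOW", "GREEN"), "GREEN", "green_intensity")
  )
}

#' Write / read ground-truth records as CSV
#'
#' One row per (cell, frame) with the schema of [simulate_monolayer()];
#' an empty record set yields a header-only file.
#'
#' @param records Ground-truth tibble.
#' @param path Output file.
#' @return `export_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the records tibble.
#' @export
export_ground_truth <- function(records, path) {
  cols <- c("cell_id", "frame", "x", "y", "phase",
            "red_intensity", "green_intensity", "parent_id")
  readr::write_csv(records[cols], path)
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           cell_id = readr::col_integer(),
                           frame = readr::col_integer(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           phase = readr::col_character(),
                           red_intensity = readr::col_double(),
                           green_intensity = readr::col_double(),
                           parent_id = readr::col_integer()
                         ))
  out$phase <- .phase_factor(out$phase)
  out
}
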