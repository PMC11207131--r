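# shared in-code fixtures and independent oracles

# a track tibble from explicit coordinates
make_track <- function(id, frames, x, y, channel = NA_character_) {
  tibble::tibble(
    track_id = as.integer(id), frame = as.integer(frames),
    x = as.numeric(x), y = as.numeric(y),
    area = NA_real_, perimeter = NA_real_, mean_intensity = NA_real_,
    channel = channel, detected = TRUE
  )
}

# an image with isotropic Gaussian spots at 0-based (x, y)
spot_image <- function(size, x, y, amp, sigma, background = 0) {
  img <- matrix(background, size, size)
  for (k in seq_along(x)) {
    ry <- exp(-((seq_len(size) - 1 - y[k])^2) / (2 * sigma^2))
    cx <- exp(-((seq_len(size) - 1 - x[k])^2) / (2 * sigma^2))
    img <- img + amp[k] * outer(ry, cx)
  }
  img
}

# brute-force minimum total cost over all partial one-to-one matchings,
# where every unmatched row/column pays `alt`; infeasible links excluded.
# Independent oracle for the LAP-based linker (tiny n only).
brute_force_lap_cost <- function(cost, feasible, alt) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  recurse <- function(i, used_cols, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- min(best, acc + alt * (m - length(used_cols)))
      return()
    }
    recurse(i + 1, used_cols, acc + alt) # row i unmatched
    for (j in setdiff(seq_len(m), used_cols)) {
      if (feasible[i, j]) recurse(i + 1, c(used_cols, j), acc + cost[i, j])
    }
  }
  recurse(1, integer(), 0)
  best
}

# independent mean-center-distance similarity on shared frames (no
# interpolation; use on gap-free tracks only)
brute_force_similarity <- function(red, green) {
  shared <- intersect(red$frame, green$frame)
  if (!length(shared)) return(list(n = 0L, s = NA_real_))
  r <- red[match(shared, red$frame), ]
  g <- green[match(shared, green$frame), ]
  list(n = length(shared), s = mean(sqrt((r$x - g$x)^2 + (r$y - g$y)^2)))
}

# independent all-pairs matcher: score every red x green pair directly,
# apply the strict threshold and the greedy ascending-s acceptance rule
brute_force_match <- function(red_tracks, green_tracks, threshold = 2,
                              min_overlap = 2) {
  reds <- split(red_tracks, red_tracks$track_id)
  greens <- split(green_tracks, green_tracks$track_id)
  rows <- list()
  for (r in reds) {
    for (g in greens) {
      sc <- brute_force_similarity(r, g)
      if (sc$n >= min_overlap && sc$s < threshold) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          red_id = r$track_id[1], green_id = g$track_id[1], s_ij = sc$s
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(red_id = integer(), green_id = integer()))
  }
  cand <- dplyr::arrange(dplyr::bind_rows(rows), s_ij, red_id, green_id)
  taken_r <- integer(); taken_g <- integer(); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$red_id[k] %in% taken_r) && !(cand$green_id[k] %in% taken_g)) {
      keep[k] <- TRUE
      taken_r <- c(taken_r, cand$red_id[k])
      taken_g <- c(taken_g, cand$green_id[k])
    }
  }
  cand[keep, c("red_id", "green_id")]
}

# random co-moving red/green track instance for matcher equivalence tests:
# roughly half the green tracks shadow a red track at sub-threshold offset,
# the rest are independent walks
random_track_instance <- function(seed, n_red = 30, fov = 200) {
  set.seed(seed)
  mk_walk <- function(id, channel) {
    len <- sample(5:20, 1)
    f0 <- sample(0:10, 1)
    x <- cumsum(c(runif(1, 5, fov - 5), rnorm(len - 1)))
    y <- cumsum(c(runif(1, 5, fov - 5), rnorm(len - 1)))
    make_track(id, f0 + seq_len(len) - 1, pmin(pmax(x, 0), fov),
               pmin(pmax(y, 0), fov), channel)
  }
  red <- dplyr::bind_rows(lapply(seq_len(n_red), mk_walk, channel = "RED"))
  greens <- list()
  gid <- 0L
  for (rid in seq_len(n_red)) {
    gid <- gid + 1L
    if (rid %% 2 == 0) {
      r <- red[red$track_id == rid, ]
      keep <- seq(max(1, nrow(r) - sample(2:6, 1)), nrow(r))
      g <- r[keep, ]
      g$track_id <- gid
      g$x <- pmin(pmax(g$x + rnorm(nrow(g), 0, 0.5), 0), fov)
      g$y <- pmin(pmax(g$y + rnorm(nrow(g), 0, 0.5), 0), fov)
      g$channel <- "GREEN"
      greens[[gid]] <- g
    } else {
      greens[[gid]] <- mk_walk(gid, "GREEN")
    }
  }
  list(red = red, green = dplyr::bind_rows(greens))
}

# small noiseless, well-separated simulation used by several suites
tiny_sim_config <- function(seed = 11, ...) {
  args <- list(
    fov_size_px = 192, n_frames = 16, n_cells_init = 12, rng_seed = seed,
    noise_sd = 0, motility_speed = 0.5, persistence = 0.8,
    repulsion_radius = 24,
    phase_durations = c(red = 6, yellow = 4, green = 6, colorless = 2),
    phase_duration_cv = 0, division_enabled = FALSE
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
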