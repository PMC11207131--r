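test_that("grid pre-filter keeps co-occupying pairs and drops disjoint ones", {
  # grid_n = 1: everything is a candidate
  red <- make_track(1, 0:2, x = c(5, 6, 7), y = c(5, 5, 5), "RED")
  green <- make_track(1, 0:2, x = c(90, 91, 92), y = c(90, 90, 90), "GREEN")
  expect_equal(nrow(grid_prefilter(red, green, 1, 100)), 1)
  # grid_n = 10: opposite corners never share a square
  expect_equal(nrow(grid_prefilter(red, green, 10, 100)), 0)

  # red visits squares (2,3) and (2,4); green only (2,4) -> candidate
  red2 <- make_track(2, 0:1, x = c(25, 25), y = c(35, 45), "RED")
  green2 <- make_track(2, 5:6, x = c(28, 28), y = c(47, 48), "GREEN")
  expect_equal(grid_prefilter(red2, green2, 10, 100),
               tibble::tibble(red_id = 2L, green_id = 2L))
})

test_that("grid pre-filter equals a brute-force occupancy intersection", {
  inst <- random_track_instance(99, n_red = 12, fov = 100)
  got <- grid_prefilter(inst$red, inst$green, 10, 100)
  sq <- function(tr) unique(paste(pmin(floor(tr$x / 10), 9),
                                  pmin(floor(tr$y / 10), 9)))
  expected <- list()
  for (r in split(inst$red, inst$red$track_id)) {
    for (g in split(inst$green, inst$green$track_id)) {
      if (length(intersect(sq(r), sq(g)))) {
        expected[[length(expected) + 1]] <-
          tibble::tibble(red_id = r$track_id[1], green_id = g$track_id[1])
      }
    }
  }
  expected <- dplyr::arrange(dplyr::bind_rows(expected), red_id, green_id)
  expect_equal(as.data.frame(got), as.data.frame(expected))
})

test_that("similarity matches hand-computed values", {
  red <- make_track(1, 0:4, x = 10 + 0:4, y = rep(20, 5), "RED")
  ident <- make_track(7, 0:4, x = 10 + 0:4, y = rep(20, 5), "GREEN")
  s <- track_similarity(red, ident)
  expect_equal(s$s_ij, 0)
  expect_equal(s$n_overlap, 5L)

  offset <- dplyr::mutate(ident, x = x + 3, y = y + 4)
  expect_equal(track_similarity(red, offset)$s_ij, 5)

  red3 <- make_track(1, 0:2, x = c(0, 10, 20), y = c(0, 0, 0), "RED")
  green3 <- make_track(2, 0:2, x = c(0, 10, 20), y = c(1, 3, 1), "GREEN")
  expect_equal(track_similarity(red3, green3)$s_ij, 5 / 3)

  # a single shared frame is below the default minimum overlap
  short <- make_track(3, 2, x = 20, y = 0, "GREEN")
  expect_equal(nrow(track_similarity(red3, short)), 0)
  expect_equal(nrow(track_similarity(red3, short, min_overlap_frames = 1)), 1)
})

test_that("similarity is symmetric, non-negative and translation-invariant", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    red <- make_track(1, 0:(n - 1), x = runif(n, 0, 50), y = runif(n, 0, 50))
    green <- make_track(2, 2:(n + 1), x = runif(n, 0, 50), y = runif(n, 0, 50))
    s1 <- track_similarity(red, green)$s_ij
    s2 <- track_similarity(dplyr::rename(green, x = x, y = y), red)$s_ij
    expect_gte(s1, 0)
    expect_equal(s1, s2)
    shift <- function(tr) dplyr::mutate(tr, x = x + 13.7, y = y - 4.2)
    expect_equal(track_similarity(shift(red), shift(green))$s_ij, s1,
                 tolerance = 1e-12)
  }
})

test_that("matching applies the strict threshold and greedy ascending order", {
  one <- tibble::tibble(red_id = 1L, green_id = 1L, s_ij = 0.5)
  expect_equal(nrow(match_pairs(one, 2)), 1)
  boundary <- tibble::tibble(red_id = 1L, green_id = 1L, s_ij = 2.0)
  expect_equal(nrow(match_pairs(boundary, 2)), 0)   # strictly smaller than 2

  cand <- tibble::tibble(
    red_id = c(1L, 1L, 2L), green_id = c(1L, 2L, 1L),
    s_ij = c(0.4, 0.6, 0.3)
  )
  got <- dplyr::arrange(match_pairs(cand, 2), red_id)
  expect_equal(got$red_id, c(1L, 2L))
  expect_equal(got$green_id, c(2L, 1L))
  # equals the minimum-total-s one-to-one matching over all alternatives
  # ({R2-G1, R1-G2}: 0.9 beats {R1-G1}: 0.4 + two unmatched)
  expect_equal(sum(got$s_ij), 0.9)
})

test_that("fusion follows FUCCI phase semantics and midpoint positions", {
  red <- make_track(1, 0:10, x = 10 + 0:10, y = rep(10, 11), "RED")
  green <- make_track(2, 8:20, x = 8 + 8:20, y = rep(10, 13), "GREEN")
  fused <- fuse_tracks(red, green)
  expect_equal(fused$frame, 0:20)
  expect_equal(as.character(fused$phase),
               rep(c("RED", "YELLOW", "GREEN"), c(8, 3, 10)))
  # on a YELLOW frame the fused position is the centroid mean
  y8 <- fused[fused$frame == 8, ]
  expect_equal(y8$x, (18 + 16) / 2)
  expect_equal(y8$source, "both")

  solo <- fuse_tracks(NULL, make_track(5, 3:9, x = 1:7, y = 1:7, "GREEN"))
  expect_true(all(solo$phase == "GREEN"))
  expect_equal(solo$frame, 3:9)
  expect_true(is.na(g1s_transition(solo)))
  expect_error(fuse_tracks(NULL, NULL), "at least one")

  disjoint_red <- make_track(1, 0:3, x = 1:4, y = 1:4, "RED")
  disjoint_green <- make_track(2, 10:13, x = 1:4, y = 1:4, "GREEN")
  expect_error(fuse_tracks(disjoint_red, disjoint_green), "overlapping")
})

test_that("G1-to-S criteria pick the window start, middle and end", {
  rec <- tibble::tibble(
    frame = 0:15,
    phase = factor(rep(c("RED", "YELLOW", "GREEN"), c(8, 3, 5)),
                   levels = c("RED", "YELLOW", "GREEN"))
  )
  expect_equal(g1s_transition(rec, "window_start"), 8L)
  expect_equal(g1s_transition(rec, "window_mid"), 9L)
  expect_equal(g1s_transition(rec, "window_end"), 10L)

  single <- dplyr::mutate(rec, phase = replace(phase, frame %in% 8:10, "GREEN"),
                          phase = replace(phase, frame == 7, "YELLOW"))
  expect_equal(g1s_transition(single, "window_mid"), 7L)
  expect_equal(g1s_transition(single, "window_start"), 7L)

  none <- rec[rec$phase != "YELLOW", ]
  expect_true(is.na(g1s_transition(none)))
})

test_that("fuse_all matches brute-force all-pairs matching on small instances", {
  for (seed in c(3, 14)) {
    inst <- random_track_instance(seed, n_red = 15, fov = 200)
    fc <- fuse_all(inst$red, inst$green, fusion_params(), 200)
    got <- fc$cells |>
      dplyr::filter(!is.na(red_track_id), !is.na(green_track_id)) |>
      dplyr::arrange(red_track_id) |>
      dplyr::select(red_id = red_track_id, green_id = green_track_id)
    expected <- dplyr::arrange(brute_force_match(inst$red, inst$green),
                               red_id)
    expect_equal(as.data.frame(got), as.data.frame(expected))
  }
})

test_that("fuse_all handles empty input and a single clean pair", {
  empty <- make_track(integer(), integer(), numeric(), numeric())
  fc0 <- fuse_all(empty, empty, fusion_params(), 100)
  expect_equal(nrow(fc0$records), 0)
  expect_equal(nrow(fc0$cells), 0)

  red <- make_track(1, 0:6, x = 10 + 0:6, y = rep(40, 7), "RED")
  green <- make_track(1, 4:12, x = 14 + 0:8 + 0.5, y = rep(40, 9), "GREEN")
  fc <- fuse_all(red, green, fusion_params(), 100)
  expect_equal(nrow(fc$cells), 1)
  cell <- fc$cells[1, ]
  expect_equal(cell$red_first, 0L)
  expect_equal(cell$yellow_first, 4L)
  expect_equal(cell$yellow_last, 6L)
  expect_equal(cell$green_first, 7L)
  expect_equal(cell$g1s_frame, 5L)
  expect_equal(glance(fc)$n_matched, 1)
})

test_that("fused pairing and YELLOW windows recover simulated ground truth", {
  cfg <- tiny_sim_config(61, n_frames = 20, motility_speed = 1)
  truth <- simulate_monolayer(cfg)
  tracks <- truth_to_tracks(truth)
  fc <- fuse_all(tracks$red, tracks$green, fusion_params(), cfg$fov_size_px)
  matched <- fc$cells[!is.na(fc$cells$red_track_id) &
                        !is.na(fc$cells$green_track_id), ]
  # every ground-truth cell with >= 2 YELLOW frames must be paired with
  # itself (track ids equal ground-truth cell ids here)
  yellows <- dplyr::count(truth[truth$phase == "YELLOW", ], cell_id)
  expect_setequal(matched$red_track_id, yellows$cell_id[yellows$n >= 2])
  expect_equal(matched$red_track_id, matched$green_track_id)
  # YELLOW windows equal the ground-truth co-expression windows exactly
  for (k in seq_len(nrow(matched))) {
    gt_y <- truth$frame[truth$cell_id == matched$red_track_id[k] &
                          truth$phase == "YELLOW"]
    expect_equal(matched$yellow_first[k], min(gt_y))
    expect_equal(matched$yellow_last[k], max(gt_y))
    expect_equal(matched$g1s_frame[k],
                 as.integer(floor((min(gt_y) + max(gt_y)) / 2)))
  }
  # matching is one-to-one over all cells
  expect_equal(anyDuplicated(stats::na.omit(fc$cells$red_track_id)), 0)
  expect_equal(anyDuplicated(stats::na.omit(fc$cells$green_track_id)), 0)
})
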