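#' Parameters for the classical nuclear segmentation baseline
#'
#' A deliberately simple, dependency-light pipeline (Gaussian smoothing,
#' global threshold, hole filling, optional distance-transform watershed
#' split, area filter) standing in for external deep-learning segmenters.
#' Label masks produced elsewhere can replace it via
#' [load_external_masks()].
#'
#' @param smoothing_sigma_px Gaussian pre-filter scale, px (0 disables).
#' @param threshold_method `"otsu"` (global Otsu) or `"fixed"`.
#' @param fixed_threshold Threshold in camera counts, used when
#'   `threshold_method = "fixed"`.
#' @param min_area_px2 Components smaller than this (px^2) are discarded.
#' @param split_touching Split touching nuclei by seeded watershed on the
#'   distance transform.
#' @param watershed_min_distance_px Minimum separation between distance-map
#'   local maxima used as watershed seeds.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_px = 2,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0,
                                min_area_px2 = 9L,
                                split_touching = TRUE,
                                watershed_min_distance_px = 5L) {
  p <- list(
    smoothing_sigma_px = as.numeric(smoothing_sigma_px),
    threshold_method = match.arg(threshold_method),
    fixed_threshold = as.numeric(fixed_threshold),
    min_area_px2 = as.integer(min_area_px2),
    split_touching = isTRUE(split_touching),
    watershed_min_distance_px = as.integer(watershed_min_distance_px)
  )
  stopifnot(p$smoothing_sigma_px >= 0, p$min_area_px2 >= 1,
            p$watershed_min_distance_px >= 1)
  structure(p, class = "segmentation_params")
}

#' Segment nuclei in a single fluorescence frame
#'
#' Gaussian smooth, threshold (Otsu or fixed), fill holes, optionally split
#' touching nuclei with a seeded watershed on the distance transform (seeds
#' are distance-map local maxima separated by at least
#' `watershed_min_distance_px`), and discard components below
#' `min_area_px2`. A constant frame under Otsu yields an empty mask by
#' convention.
#'
#' @param image Numeric matrix of intensities (finite, non-negative);
#'   `[row = y + 1, col = x + 1]`.
#' @param params A [segmentation_params()].
#' @return Integer label matrix, background 0, labels `1..n` in raster order
#'   of first occurrence.
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  img <- as.matrix(image)
  if (!all(is.finite(img)) || any(img < 0)) {
    stop("image must be finite and non-negative", call. = FALSE)
  }
  if (params$smoothing_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = params$smoothing_sigma_px))
  }
  rng <- range(img)
  if (params$threshold_method == "otsu") {
    if (diff(rng) <= 0) {
      return(matrix(0L, nrow(img), ncol(img)))
    }
    thr_norm <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)),
                              range = c(0, 1))
    thr <- rng[1] + thr_norm * diff(rng)
  } else {
    thr <- params$fixed_threshold
  }
  binary <- img > thr
  if (!any(binary)) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  binary <- as.matrix(EBImage::fillHull(EBImage::Image(binary))) > 0

  if (params$split_touching) {
    d <- EBImage::distmap(EBImage::Image(binary))
    w <- params$watershed_min_distance_px
    brush <- EBImage::makeBrush(2L * w + 1L, shape = "disc")
    dil <- EBImage::dilate(d, brush)
    maxima <- (as.matrix(d) >= as.matrix(dil)) & binary
    seeds <- EBImage::bwlabel(EBImage::Image(maxima))
    lab <- EBImage::propagate(d, seeds, mask = binary)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(binary)))
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))

  counts <- tabulate(lab)
  keep <- which(counts >= params$min_area_px2)
  if (!length(keep)) {
    return(matrix(0L, nrow(lab), ncol(lab)))
  }
  # compact relabel in raster order of first occurrence
  lut <- integer(max(lab))
  first_seen <- keep[order(match(keep, lab[lab %in% keep]))]
  lut[first_seen] <- seq_along(first_seen)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0 & lab %in% keep
  out[nz] <- lut[lab[nz]]
  out
}

#' Segment every frame of an intensity stack
#'
#' @param stack `H x W x T` numeric array (see [read_stack()]).
#' @param params A [segmentation_params()].
#' @return Integer label array of the same dimensions.
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  stopifnot(length(dim(stack)) == 3)
  out <- array(0L, dim = dim(stack))
  for (t in seq_len(dim(stack)[3])) {
    out[, , t] <- segment_frame(stack[, , t], params)
  }
  out
}

# closed-polygon length of a label's boundary pixel chain
.contour_perimeter <- function(xy) {
  if (nrow(xy) < 2) return(0)
  closed <- rbind(xy, xy[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Measure per-nucleus detections from a label mask
#'
#' Centroids are unweighted pixel-coordinate means (0-based `x` = column,
#' `y` = row), area is the pixel count, mean intensity is averaged over the
#' label's pixels, and the perimeter is the length of the closed polygon
#' through the label's boundary pixel centers.
#'
#' @param mask Integer label matrix (0 = background).
#' @param image Intensity matrix of the same shape.
#' @param frame 0-based frame index recorded in the output.
#' @param channel `"RED"` or `"GREEN"`.
#' @param contours If `TRUE`, add a list-column `contour` holding each
#'   label's boundary polygon as an `n x 2` matrix of 0-based `(x, y)`.
#' @return A tibble with one row per label: `frame`, `channel`, `label_id`,
#'   `x`, `y`, `area`, `perimeter`, `mean_intensity` (and optionally
#'   `contour`).
#' @export
extract_detections <- function(mask, image, frame = 0L,
                               channel = c("RED", "GREEN"),
                               contours = FALSE) {
  channel <- match.arg(channel)
  stopifnot(identical(dim(mask), dim(image)))
  idx <- which(mask > 0)
  if (!length(idx)) {
    out <- tibble(
      frame = integer(), channel = character(), label_id = integer(),
      x = numeric(), y = numeric(), area = numeric(), perimeter = numeric(),
      mean_intensity = numeric()
    )
    if (contours) out$contour <- list()
    return(out)
  }
  lab <- mask[idx]
  rc <- arrayInd(idx, dim(mask))
  labs <- sort(unique(lab))
  grp <- match(lab, labs)
  area <- tabulate(grp, length(labs))
  x <- as.numeric(tapply(rc[, 2] - 1, grp, mean))
  y <- as.numeric(tapply(rc[, 1] - 1, grp, mean))
  mean_int <- as.numeric(tapply(image[idx], grp, mean))

  # relabel compactly so ocontour's sequential object index matches labs;
  # coordinates come back 0-based with the first image dimension (our y)
  # first
  compact <- matrix(0L, nrow(mask), ncol(mask))
  compact[idx] <- grp
  oc <- EBImage::ocontour(EBImage::Image(compact))
  contour_list <- lapply(seq_along(labs), function(i) {
    xy <- oc[[i]]
    cbind(x = xy[, 2], y = xy[, 1])
  })
  perim <- vapply(contour_list, .contour_perimeter, numeric(1))

  out <- tibble(
    frame = as.integer(frame), channel = channel, label_id = as.integer(labs),
    x = x, y = y, area = as.numeric(area), perimeter = perim,
    mean_intensity = mean_int
  )
  if (contours) out$contour <- contour_list
  out
}

#' Measure detections across a whole label stack
#'
#' @param label_stack Integer label array `H x W x T`.
#' @param intensity_stack Matching intensity array.
#' @inheritParams extract_detections
#' @return A tibble of detections over all frames (0-based `frame`).
#' @export
detect_stack <- function(label_stack, intensity_stack,
                         channel = c("RED", "GREEN"), contours = FALSE) {
  channel <- match.arg(channel)
  stopifnot(identical(dim(label_stack), dim(intensity_stack)))
  purrr::map_dfr(seq_len(dim(label_stack)[3]), function(t) {
    extract_detections(label_stack[, , t], intensity_stack[, , t],
                       frame = t - 1L, channel = channel, contours = contours)
  })
}

#' Load externally produced label masks
#'
#' Reads a multi-page 16-bit label TIFF (for example masks produced by a
#' deep-learning segmenter) and validates its shape against a reference
#' intensity stack; labels are passed through verbatim.
#'
#' @param path Multi-page label TIFF.
#' @param reference Optional intensity stack whose dimensions the masks must
#'   match.
#' @return Integer label array `H x W x T`.
#' @export
load_external_masks <- function(path, reference = NULL) {
  masks <- read_stack(path)
  storage.mode(masks) <- "integer"
  if (!is.null(reference) && !identical(dim(masks), dim(reference))) {
    stop("label stack dimensions (", paste(dim(masks), collapse = "x"),
         ") do not match the intensity stack (",
         paste(dim(reference), collapse = "x"), ")", call. = FALSE)
  }
  masks
}
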