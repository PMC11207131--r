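#' Read / write multi-page TIFF intensity stacks
#'
#' `read_stack()` reads an 8/16-bit multi-page TIFF (single page gives
#' `T = 1`) into an `H x W x T` array of integer counts and checks that all
#' pages share one shape. `write_stack()` writes such an array as an
#' unsigned 16-bit multi-page TIFF, clipping to `[0, 65535]` and rounding.
#'
#' @param path TIFF file.
#' @return `read_stack()` returns the `H x W x T` array; `write_stack()`
#'   returns `path` invisibly.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!length(pages)) stop("no pages in TIFF: ", path, call. = FALSE)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent page shapes in TIFF: ", path, call. = FALSE)
  }
  if (length(dim(pages[[1]])) > 2) {
    stop("expected single-channel (greyscale) TIFF pages: ", path,
         call. = FALSE)
  }
  out <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) out[, , t] <- pages[[t]]
  out
}

#' @rdname read_stack
#' @param stack `H x W x T` numeric array of counts.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(t) {
    m <- round(stack[, , t])
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write / read the tabular artifacts of the pipeline
#'
#' Thin, schema-stable CSV wrappers. `write_tracks()` drops list-columns
#' (contours); `read_tracks()` restores column types.
#'
#' @param tracks,path Tibble and file path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- tracks[, !vapply(tracks, is.list, logical(1))]
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("track_id" %in% names(out)) out$track_id <- as.integer(out$track_id)
  if ("frame" %in% names(out)) out$frame <- as.integer(out$frame)
  if (!"detected" %in% names(out)) out$detected <- TRUE
  out
}

#' @rdname write_tracks
#' @param records Fused per-frame records.
#' @export
write_fused_records <- function(records, path) {
  records$phase <- as.character(records$phase)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_fused_records <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$phase <- .phase_factor(out$phase, .VISIBLE_PHASES)
  out$cell_id <- as.integer(out$cell_id)
  out$frame <- as.integer(out$frame)
  out
}
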