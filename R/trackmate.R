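#' Import tracks from a TrackMate XML file
#'
#' Reads the schema subset written by TrackMate (and by
#' [export_trackmate_xml()]): `Spot` elements carrying `ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`, and `Edge` elements carrying
#' `SPOT_SOURCE_ID` / `SPOT_TARGET_ID` inside `Track` elements. Tracks are
#' reconstructed as connected components of the edge graph; spots that
#' belong to no edge are ignored, and unknown elements are skipped.
#' Positions are taken as pixel units.
#'
#' @param path XML file.
#' @param channel Optional channel tag (`"RED"`/`"GREEN"`) stored in the
#'   output.
#' @return A track tibble in the format of [build_tracks()].
#' @export
import_trackmate_xml <- function(path, channel = NA_character_) {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  spot_id <- xml2::xml_attr(spots, "ID")
  spot_tbl <- tibble(
    id = spot_id,
    frame = as.integer(xml2::xml_attr(spots, "FRAME")),
    x = as.numeric(xml2::xml_attr(spots, "POSITION_X")),
    y = as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  )
  if (anyNA(spot_tbl$id) || anyNA(spot_tbl$frame) ||
      anyNA(spot_tbl$x) || anyNA(spot_tbl$y)) {
    stop("malformed TrackMate XML: Spot elements must carry ID, FRAME, ",
         "POSITION_X and POSITION_Y", call. = FALSE)
  }
  edges <- xml2::xml_find_all(doc, ".//Edge")
  if (!length(edges)) {
    return(.empty_tracks(tibble(frame = integer(), x = numeric(),
                                y = numeric(), channel = character())))
  }
  src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
  tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
  missing <- setdiff(c(src, tgt), spot_tbl$id)
  if (length(missing)) {
    stop("TrackMate XML edge references unknown spot id(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }

  # union-find over spots joined by edges
  parent <- seq_len(nrow(spot_tbl))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  si <- match(src, spot_tbl$id)
  ti <- match(tgt, spot_tbl$id)
  for (k in seq_along(si)) {
    a <- find(si[k]); b <- find(ti[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(nrow(spot_tbl)), find, integer(1))
  in_track <- unique(c(si, ti))
  spot_tbl <- spot_tbl[in_track, ]
  comp <- comp[in_track]

  groups <- split(seq_len(nrow(spot_tbl)), comp)
  first <- t(vapply(groups, function(g) {
    g <- g[order(spot_tbl$frame[g])]
    c(spot_tbl$frame[g[1]], spot_tbl$y[g[1]], spot_tbl$x[g[1]])
  }, numeric(3)))
  groups <- groups[order(first[, 1], first[, 2], first[, 3])]

  purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[[i]][order(spot_tbl$frame[groups[[i]]])]
    tibble(
      track_id = i,
      frame = spot_tbl$frame[g], x = spot_tbl$x[g], y = spot_tbl$y[g],
      area = NA_real_, perimeter = NA_real_, mean_intensity = NA_real_,
      channel = channel, detected = TRUE
    )
  })
}

#' Export tracks to a minimal TrackMate-style XML file
#'
#' Writes the `Spot`/`Edge` subset consumed by [import_trackmate_xml()];
#' intended for interoperability tests and round-tripping, not as a full
#' TrackMate session file.
#'
#' @param tracks A track tibble from [build_tracks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_trackmate_xml <- function(tracks, path) {
  doc <- xml2::xml_new_root("TrackMate")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel",
                               timeunits = "frame")
  allspots <- xml2::xml_add_child(model, "AllSpots")
  alltracks <- xml2::xml_add_child(model, "AllTracks")
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  tracks$spot_id <- seq_len(nrow(tracks)) - 1L
  for (f in sort(unique(tracks$frame))) {
    sif <- xml2::xml_add_child(allspots, "SpotsInFrame", frame = as.character(f))
    rows <- tracks[tracks$frame == f, ]
    for (k in seq_len(nrow(rows))) {
      xml2::xml_add_child(sif, "Spot",
                          ID = as.character(rows$spot_id[k]),
                          FRAME = as.character(rows$frame[k]),
                          POSITION_X = format(rows$x[k], digits = 17),
                          POSITION_Y = format(rows$y[k], digits = 17))
    }
  }
  for (tid in unique(tracks$track_id)) {
    rows <- tracks[tracks$track_id == tid, ]
    trk <- xml2::xml_add_child(alltracks, "Track", TRACK_ID = as.character(tid))
    if (nrow(rows) > 1) {
      for (k in seq_len(nrow(rows) - 1)) {
        xml2::xml_add_child(trk, "Edge",
                            SPOT_SOURCE_ID = as.character(rows$spot_id[k]),
                            SPOT_TARGET_ID = as.character(rows$spot_id[k + 1]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
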