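#' Assemble and validate a full pipeline configuration
#'
#' Collects paths and per-stage parameter sets for [run_pipeline()]. Stages
#' are substitutable: provide `masks_red`/`masks_green` (label TIFFs) to
#' skip segmentation, or `tracks_red`/`tracks_green` (CSV or TrackMate XML)
#' to skip segmentation and tracking.
#'
#' @param red_stack,green_stack Intensity stack TIFFs (required unless both
#'   track tables are given).
#' @param out_dir Output directory (created if missing).
#' @param masks_red,masks_green Optional label TIFFs replacing segmentation.
#' @param tracks_red,tracks_green Optional track tables (`.csv` or `.xml`)
#'   replacing segmentation + tracking.
#' @param segmentation,tracking,fusion,kinematics Stage parameter objects.
#' @param velocity_frames Frames pooled into the exported velocity field;
#'   defaults to all frames.
#' @param fov_size_px FOV side; inferred from the stacks when omitted.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(red_stack = NULL, green_stack = NULL, out_dir,
                            masks_red = NULL, masks_green = NULL,
                            tracks_red = NULL, tracks_green = NULL,
                            segmentation = segmentation_params(),
                            tracking = tracking_params(),
                            fusion = fusion_params(),
                            kinematics = kinematics_params(),
                            velocity_frames = NULL,
                            fov_size_px = NULL) {
  cfg <- list(
    red_stack = red_stack, green_stack = green_stack, out_dir = out_dir,
    masks_red = masks_red, masks_green = masks_green,
    tracks_red = tracks_red, tracks_green = tracks_green,
    segmentation = segmentation, tracking = tracking, fusion = fusion,
    kinematics = kinematics, velocity_frames = velocity_frames,
    fov_size_px = fov_size_px
  )
  have_tracks <- !is.null(tracks_red) && !is.null(tracks_green)
  if (!have_tracks && (is.null(red_stack) || is.null(green_stack))) {
    stop("either both intensity stacks or both track tables are required",
         call. = FALSE)
  }
  for (p in c("red_stack", "green_stack", "masks_red", "masks_green",
              "tracks_red", "tracks_green")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input file for '", p, "' not found: ", cfg[[p]], call. = FALSE)
    }
  }
  if (have_tracks && is.null(fov_size_px)) {
    stop("fov_size_px is required when starting from track tables",
         call. = FALSE)
  }
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(tracking, "tracking_params"),
            inherits(fusion, "fusion_params"),
            inherits(kinematics, "kinematics_params"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `segmentation`, `tracking`, `fusion` and `kinematics` maps override the
#' corresponding parameter defaults, and a `simulate` map (see
#' [sim_config()]) is passed through for the `simulate` entry point.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return A list of class `pipeline_config` (with a `simulate` element when
#'   present).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw),
                        c("red_stack", "green_stack", "out_dir",
                          "masks_red", "masks_green",
                          "tracks_red", "tracks_green",
                          "velocity_frames", "fov_size_px"))]
  for (stage in c("segmentation", "tracking", "fusion", "kinematics")) {
    ctor <- get(paste0(ifelse(stage == "kinematics", "kinematics",
                              stage), "_params"))
    args[[stage]] <- do.call(ctor, as.list(raw[[stage]]))
  }
  cfg <- do.call(pipeline_config, args)
  if (!is.null(raw$simulate)) {
    cfg$simulate <- do.call(sim_config, as.list(raw$simulate))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains every stage headlessly: read stacks, segment both channels,
#' measure detections, build per-channel tracks, fuse red/green tracks into
#' cell-cycle tracks, and derive tissue-level outputs (Voronoi areas, phase
#' counts, area by phase, velocity field). Every stage's table is written to
#' `out_dir` as CSV together with a machine-readable `manifest.json` (config
#' echo, package version, row counts). Identical inputs and configuration
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`detections`,
#'   `tracks`, `cells`, `voronoi`, `phase_counts`, `area_by_phase`,
#'   `velocity_field`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  counts <- list()
  art <- function(name) file.path(config$out_dir, name)

  get_channel_tracks <- function(channel) {
    key <- tolower(channel)
    tr_path <- config[[paste0("tracks_", key)]]
    if (!is.null(tr_path)) {
      tr <- if (grepl("\\.xml$", tr_path, ignore.case = TRUE)) {
        import_trackmate_xml(tr_path, channel = channel)
      } else {
        read_tracks(tr_path)
      }
      tr$channel <- channel
      return(list(tracks = tr, detections = NULL, fov = config$fov_size_px))
    }
    stack <- read_stack(config[[paste0(key, "_stack")]])
    d <- dim(stack)
    if (d[1] != d[2]) {
      stop("pipeline requires a square FOV; got ", d[1], "x", d[2],
           call. = FALSE)
    }
    mask_path <- config[[paste0("masks_", key)]]
    labels <- if (!is.null(mask_path)) {
      load_external_masks(mask_path, reference = stack)
    } else {
      segment_stack(stack, config$segmentation)
    }
    dets <- detect_stack(labels, stack, channel = channel)
    list(tracks = build_tracks(dets, config$tracking),
         detections = dets, fov = d[1])
  }

  red <- get_channel_tracks("RED")
  green <- get_channel_tracks("GREEN")
  fov <- config$fov_size_px
  if (is.null(fov)) fov <- red$fov
  if (!is.null(green$fov) && !is.null(red$fov) && green$fov != red$fov) {
    stop("red and green stacks have different FOV sizes", call. = FALSE)
  }

  for (side in c("red", "green")) {
    ch <- get(side)
    if (!is.null(ch$detections)) {
      paths[[paste0("detections_", side)]] <-
        write_tracks(ch$detections, art(paste0("detections_", side, ".csv")))
      counts[[paste0("detections_", side)]] <- nrow(ch$detections)
    }
    paths[[paste0("tracks_", side)]] <-
      write_tracks(ch$tracks, art(paste0("tracks_", side, ".csv")))
    counts[[paste0("tracks_", side)]] <- nrow(ch$tracks)
  }

  cells <- fuse_all(red$tracks, green$tracks, config$fusion, fov)
  paths$cell_records <- write_fused_records(cells$records,
                                            art("cell_records.csv"))
  paths$cells <- {
    readr::write_csv(cells$cells, art("cells.csv"))
    art("cells.csv")
  }
  counts$cell_records <- nrow(cells$records)
  counts$cells <- nrow(cells$cells)

  vor <- voronoi_cells(cells$records, fov)
  paths$voronoi <- { readr::write_csv(vor, art("voronoi.csv")); art("voronoi.csv") }
  counts$voronoi <- nrow(vor)

  pc <- phase_counts(cells$records)
  paths$phase_counts <- {
    readr::write_csv(pc, art("phase_counts.csv")); art("phase_counts.csv")
  }
  counts$phase_counts <- nrow(pc)

  abp <- area_by_phase(vor, cells$records)
  abp_out <- dplyr::mutate(abp, phase = as.character(.data$phase))
  paths$area_by_phase <- {
    readr::write_csv(abp_out, art("area_by_phase.csv")); art("area_by_phase.csv")
  }
  counts$area_by_phase <- nrow(abp)

  vf <- velocity_field(cells$records, frames = config$velocity_frames,
                       fov_size_px = fov, params = config$kinematics)
  paths$velocity_field <- {
    readr::write_csv(as_tibble(vf), art("velocity_field.csv"))
    art("velocity_field.csv")
  }
  counts$velocity_field <- nrow(vf)

  manifest <- list(
    package = "fuccitrackr",
    version = as.character(utils::packageVersion("fuccitrackr")),
    fov_size_px = fov,
    units = list(position = "px, 0-based, x = column, y = row",
                 time = "frames, 0-based",
                 velocity = attr(vf, "units"),
                 area = "px^2"),
    parameters = list(
      segmentation = unclass(config$segmentation),
      tracking = unclass(config$tracking),
      fusion = unclass(config$fusion),
      kinematics = unclass(config$kinematics)
    ),
    inputs = Filter(Negate(is.null),
                    config[c("red_stack", "green_stack", "masks_red",
                             "masks_green", "tracks_red", "tracks_green")]),
    row_counts = counts
  )
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- art("manifest.json")

  invisible(list(
    detections = list(red = red$detections, green = green$detections),
    tracks = list(red = red$tracks, green = green$tracks),
    cells = cells, voronoi = vor, phase_counts = pc, area_by_phase = abp,
    velocity_field = vf, paths = paths
  ))
}

#' Simulate a movie and write its artifacts
#'
#' Convenience entry point pairing [simulate_monolayer()] and
#' [render_channels()] with disk output: writes `red.tif`, `green.tif` and
#' `ground_truth.csv` into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `records`, the rendered `stacks`, and the
#'   written `paths`.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- simulate_monolayer(config)
  stacks <- render_channels(records, config)
  paths <- list(
    red = file.path(out_dir, "red.tif"),
    green = file.path(out_dir, "green.tif"),
    truth = file.path(out_dir, "ground_truth.csv")
  )
  write_stack(stacks$red, paths$red)
  write_stack(stacks$green, paths$green)
  export_ground_truth(records, paths$truth)
  invisible(list(records = records, stacks = stacks, paths = paths))
}
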