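# Frame sequences go to 16-bit multi-page TIFF (one page per frame) with a
# JSON sidecar carrying the scale factor, the encoding plan, sheet depths
# and seeds; volumes go to 32-bit float multi-page TIFF (one page per depth
# plane) with the depth axis and processing log in the sidecar.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame sequence as multi-page TIFF + JSON sidecar
#'
#' Pages are 16-bit; continuous (noiseless) data are scaled to use the full
#' range and the scale is recorded in the sidecar so [read_frames()] is
#' lossless up to quantisation.
#'
#' @param fs a [render_frames()] sequence.
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  d <- dim(fs$frames)
  top <- max(fs$frames, 1e-12)
  pages <- lapply(seq_len(d[1]), function(i) {
    matrix(fs$frames[i, , ], d[2], d[3]) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    kind = "frame_sequence",
    frame_rate = fs$frame_rate, duration_s = fs$duration_s,
    n_frames = d[1], scale = top,
    plan = fs$metadata$plan[c("N", "f_L", "f_H", "delta_f", "f_vol", "f_cam",
                              "waveform", "phases_rad")],
    sheet_depths_um = fs$metadata$lsa$depth_z_um,
    seed = fs$metadata$seed, noiseless = fs$metadata$noiseless
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame sequence written by [write_frames()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return A `frame_sequence` with the plan and sheet depths restored in the
#'   metadata.
#' @export
read_frames <- function(path) {
  if (!file.exists(path) || !file.exists(sidecar_path(path))) {
    clam_abort("io", "missing %s or its .json sidecar", path)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d2 <- dim(pages[[1]])
  frames <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * meta$scale
  plan <- make_plan(meta$plan$f_cam, meta$plan$f_vol, meta$plan$N,
                    meta$plan$f_H, meta$plan$waveform,
                    phases = meta$plan$phases_rad)
  lsa <- NULL
  if (!is.null(meta$sheet_depths_um)) {
    lsa <- list(depth_z_um = meta$sheet_depths_um)
  }
  structure(
    list(frames = frames, frame_rate = meta$frame_rate,
         duration_s = meta$duration_s,
         metadata = list(plan = plan, lsa = lsa, seed = meta$seed,
                         noiseless = meta$noiseless)),
    class = "frame_sequence"
  )
}

#' Write a reconstructed volume as 32-bit float TIFF + JSON sidecar
#'
#' @param rv a `recon_volume`.
#' @param path output TIFF path.
#' @param config optional resolved run configuration to embed for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_volume <- function(rv, path, config = NULL) {
  stopifnot(inherits(rv, "recon_volume"))
  d <- dim(rv$volume)
  top <- max(rv$volume, 1e-12)
  pages <- lapply(seq_len(d[1]), function(i) {
    matrix(rv$volume[i, , ], d[2], d[3]) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "recon_volume", depth_axis_um = rv$depth_axis_um,
               scale = top, log = rv$log, config = config)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path with sidecar.
#' @return A `recon_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path) || !file.exists(sidecar_path(path))) {
    clam_abort("io", "missing %s or its .json sidecar", path)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d2 <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d2[1], d2[2]))
  scale <- meta$scale %||% 1
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]] * scale
  structure(list(volume = vol, depth_axis_um = meta$depth_axis_um,
                 log = meta$log),
            class = "recon_volume")
}
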