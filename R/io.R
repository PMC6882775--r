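# On-disk layout: waveforms.csv (t,pao,peso,pga,flow,volume @ fs_wave),
# eadi.csv (t,eadi @ fs_eadi), frames.tiff (multi-page 16-bit, stored
# value = HU + 1024), mask.tiff (0/1), sidecar YAML with geometry and
# offsets, ground-truth JSON.

HU_TIFF_OFFSET <- 1024L
HU_TIFF_MAX <- 65535

#' Write a waveform set to CSV
#'
#' Writes the 200 Hz channels to `waveforms.csv` (columns `t`, `pao`,
#' `peso`, `pga`, `flow`, `volume`) and the EAdi channel to `eadi.csv`
#' (columns `t`, `eadi`), with full double precision.
#'
#' @param waves A `waveform_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_waveforms <- function(waves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf <- data.frame(t = waves$t, pao = waves$pao, peso = waves$peso,
                   pga = waves$pga, flow = waves$flow,
                   volume = waves$volume)
  utils::write.csv(format(wf, digits = 17, trim = TRUE, scientific = FALSE),
                   file.path(dir, "waveforms.csv"), row.names = FALSE,
                   quote = FALSE)
  ea <- data.frame(t = waves$eadi_t, eadi = waves$eadi)
  utils::write.csv(format(ea, digits = 17, trim = TRUE, scientific = FALSE),
                   file.path(dir, "eadi.csv"), row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(list(fs_wave = waves$fs, fs_eadi = waves$fs_eadi,
                        peep = waves$peep),
                   file.path(dir, "waveforms.yaml"))
  invisible(dir)
}

#' Read a waveform set written by [write_waveforms()]
#'
#' @param dir Directory containing `waveforms.csv` and (optionally)
#'   `eadi.csv` plus the `waveforms.yaml` sidecar.
#' @return A `waveform_set`.  When `eadi.csv` is absent the EAdi fields
#'   are empty and a warning is raised.
#' @export
read_waveforms <- function(dir) {
  wf_path <- file.path(dir, "waveforms.csv")
  stop_if_not(file.exists(wf_path), paste("missing", wf_path))
  wf <- utils::read.csv(wf_path)
  side <- file.path(dir, "waveforms.yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  fs <- meta$fs_wave %||% round(1 / stats::median(diff(wf$t)))
  ea_path <- file.path(dir, "eadi.csv")
  if (file.exists(ea_path)) {
    ea <- utils::read.csv(ea_path)
    eadi_t <- ea$t; eadi <- ea$eadi
    fs_eadi <- meta$fs_eadi %||% round(1 / stats::median(diff(ea$t)))
  } else {
    warning("eadi.csv not found; EAdi statistics will be unavailable")
    eadi_t <- numeric(); eadi <- numeric(); fs_eadi <- NA_real_
  }
  structure(list(t = wf$t, pao = wf$pao, peso = wf$peso, pga = wf$pga,
                 flow = wf$flow, volume = wf$volume, fs = fs,
                 peep = meta$peep %||% NA_real_,
                 eadi_t = eadi_t, eadi = eadi, fs_eadi = fs_eadi),
            class = "waveform_set")
}

#' Write a CT sequence as multi-page 16-bit TIFF
#'
#' Stored pixel value is `HU + 1024` (so -1000 HU maps to 24); the offset
#' and geometry are recorded in a YAML sidecar.  The mask is written as a
#' single-page 0/1 TIFF.
#'
#' @param seq A `ct_sequence`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ct_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- ncol(seq$hu)
  pages <- lapply(seq_len(nf), function(i) {
    m <- matrix(0L, nrow(seq$mask), ncol(seq$mask))
    m[seq$px_index] <- seq$hu[, i] + HU_TIFF_OFFSET
    m / HU_TIFF_MAX
  })
  tiff::writeTIFF(pages, file.path(dir, "frames.tiff"),
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(matrix(as.numeric(seq$mask), nrow(seq$mask)),
                  file.path(dir, "mask.tiff"), bits.per.sample = 8L)
  yaml::write_yaml(list(hu_offset = HU_TIFF_OFFSET,
                        pixel_size = as.list(seq$pixel_size),
                        slice_thickness = seq$slice_thickness,
                        frame_rate = seq$frame_rate,
                        timestamps = as.list(seq$timestamps)),
                   file.path(dir, "frames.yaml"))
  invisible(dir)
}

#' Read a CT sequence written by [write_ct_sequence()]
#'
#' @param dir Directory with `frames.tiff`, `mask.tiff`, `frames.yaml`.
#' @return A `ct_sequence`.
#' @export
read_ct_sequence <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "frames.yaml"))
  pages <- tiff::readTIFF(file.path(dir, "frames.tiff"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- tiff::readTIFF(file.path(dir, "mask.tiff")) > 0.5
  px_index <- which(mask)
  hu <- vapply(pages, function(p) {
    as.integer(round(p[px_index] * HU_TIFF_MAX)) - meta$hu_offset
  }, integer(length(px_index)))
  if (is.null(dim(hu))) hu <- matrix(hu, nrow = length(px_index))
  ps <- unlist(meta$pixel_size)
  structure(list(hu = hu, mask = mask, px_index = px_index,
                 timestamps = unlist(meta$timestamps),
                 pixel_size = ps,
                 slice_thickness = meta$slice_thickness,
                 frame_rate = meta$frame_rate,
                 voxel_volume_ml = prod(ps) * meta$slice_thickness / 1000),
            class = "ct_sequence")
}
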