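#' Construct a CT frame
#'
#' @param attenuation Numeric matrix of Hounsfield-unit values.
#' @param pixel_size In-plane pixel edge lengths, mm (length-2).
#' @param slice_thickness Slice thickness, mm.
#' @param timestamp Acquisition time of the frame, s.
#' @return An object of class `ct_frame`.
#' @export
ct_frame <- function(attenuation, pixel_size = c(0.5, 0.5),
                     slice_thickness = 5, timestamp = NA_real_) {
  stop_if_not(is.matrix(attenuation) && all(is.finite(attenuation)),
              "`attenuation` must be a finite numeric matrix")
  stop_if_not(all(pixel_size > 0) && slice_thickness > 0,
              "voxel dimensions must be > 0")
  structure(list(attenuation = attenuation,
                 pixel_size = pixel_size,
                 slice_thickness = slice_thickness,
                 timestamp = timestamp),
            class = "ct_frame")
}

voxel_volume_ml <- function(frame) {
  # mm^3 -> ml
  prod(frame$pixel_size) * frame$slice_thickness / 1000
}

check_mask <- function(frame, mask) {
  stop_if_not(is.matrix(mask) && all(dim(mask) == dim(frame$attenuation)),
              "`mask` must be a matrix congruent with the frame")
  m <- mask != 0
  stop_if_not(any(m), "`mask` selects no pixels")
  m
}

# Compartment order used throughout.
AERATION_LEVELS <- c("non", "poor", "normal", "hyper")

# Band assignment for a numeric HU vector already clamped to [-1000, 100].
# Boundaries resolve half-open downward: a value shared by two printed
# ranges belongs to the denser band (-100 -> non, -500 -> poor,
# -900 -> normal).
hu_band <- function(hu) {
  out <- character(length(hu))
  out[hu >= -100] <- "non"
  out[hu >= -500 & hu < -100] <- "poor"
  out[hu >= -900 & hu < -500] <- "normal"
  out[hu < -900] <- "hyper"
  out
}

#' Classify voxels of a masked CT frame into aeration compartments
#'
#' Assigns each in-mask voxel to one of the four standard quantitative-CT
#' aeration compartments by its attenuation: non-inflated (-100 to +100
#' HU), poorly inflated (-500 to -100 HU), normally inflated (-900 to -500
#' HU) and hyperinflated (-1000 to -900 HU).  Shared printed boundaries are
#' resolved toward the denser band.  In-mask values outside
#' [-1000, +100] are clamped and counted (reported via the
#' `"clamped"` attribute with a warning).
#'
#' @param frame A [ct_frame()].
#' @param mask Binary matrix congruent with the frame; nonzero = lung.
#' @return A character matrix over `{"non","poor","normal","hyper",
#'   "excluded"}` with attribute `clamped` (number of clamped voxels).
#' @export
classify_voxels <- function(frame, mask) {
  m <- check_mask(frame, mask)
  hu <- frame$attenuation[m]
  n_clamp <- sum(hu < -1000 | hu > 100)
  if (n_clamp > 0) {
    warning(sprintf("%d in-mask HU value(s) outside [-1000, 100] clamped",
                    n_clamp))
    hu <- clamp(hu, -1000, 100)
  }
  lab <- matrix("excluded", nrow(mask), ncol(mask))
  lab[m] <- hu_band(hu)
  attr(lab, "clamped") <- n_clamp
  lab
}

#' Compute the four-compartment aeration profile of a masked CT frame
#'
#' For each aeration compartment returns the voxel count, volume (ml) and
#' tissue weight (g), together with slice totals: lung volume, tissue
#' weight and gas volume.  Uses the linear quantitative-CT mixing model:
#' voxel density (g/ml) = (HU + 1000)/1000 clamped to [0, 1.1]; gas
#' fraction = -HU/1000 clamped to [0, 1].
#'
#' @inheritParams classify_voxels
#' @return An object of class `aeration_profile`: a list with a
#'   `compartments` data.frame (compartment, voxel_count, volume_ml,
#'   weight_g) and scalars `lung_volume_ml`, `tissue_weight_g`,
#'   `gas_volume_ml`, `voxel_volume_ml`, `n_clamped`, `timestamp`.
#' @export
compute_aeration_profile <- function(frame, mask) {
  m <- check_mask(frame, mask)
  hu <- frame$attenuation[m]
  n_clamp <- sum(hu < -1000 | hu > 100)
  if (n_clamp > 0) {
    warning(sprintf("%d in-mask HU value(s) outside [-1000, 100] clamped",
                    n_clamp))
    hu <- clamp(hu, -1000, 100)
  }
  vv <- voxel_volume_ml(frame)
  band <- factor(hu_band(hu), levels = AERATION_LEVELS)
  density <- clamp((hu + 1000) / 1000, 0, 1.1)
  gasfrac <- clamp(-hu / 1000, 0, 1)

  counts <- as.integer(table(band))
  wt <- as.numeric(tapply(density, band, sum, default = 0)) * vv
  comp <- data.frame(
    compartment = AERATION_LEVELS,
    voxel_count = counts,
    volume_ml = counts * vv,
    weight_g = wt,
    stringsAsFactors = FALSE
  )
  structure(list(
    compartments = comp,
    lung_volume_ml = length(hu) * vv,
    tissue_weight_g = sum(density) * vv,
    gas_volume_ml = sum(gasfrac) * vv,
    voxel_volume_ml = vv,
    n_clamped = n_clamp,
    timestamp = frame$timestamp
  ), class = "aeration_profile")
}

#' @export
print.aeration_profile <- function(x, ...) {
  cat(sprintf("<aeration_profile> lung %.2f ml, tissue %.2f g, gas %.2f ml\n",
              x$lung_volume_ml, x$tissue_weight_g, x$gas_volume_ml))
  print(x$compartments, row.names = FALSE)
  invisible(x)
}

# Vectorized profile over a ct_sequence (in-mask HU matrix: npx x nframes).
# Returns a data.frame, one row per frame, used by the pipeline and the
# gas-series computation.  Equivalent to calling compute_aeration_profile
# on each reconstructed frame.
profile_sequence <- function(seq) {
  hu <- clamp(seq$hu, -1000, 100)
  vv <- seq$voxel_volume_ml
  non <- colSums(hu >= -100)
  poor <- colSums(hu >= -500 & hu < -100)
  normal <- colSums(hu >= -900 & hu < -500)
  hyper <- colSums(hu < -900)
  density_sum <- colSums(clamp((hu + 1000) / 1000, 0, 1.1))
  gas_sum <- colSums(clamp(-hu / 1000, 0, 1))
  data.frame(
    frame = seq_len(ncol(hu)),
    timestamp = seq$timestamps,
    non_ml = non * vv, poor_ml = poor * vv,
    normal_ml = normal * vv, hyper_ml = hyper * vv,
    non_g = colSums(clamp((hu + 1000) / 1000, 0, 1.1) * (hu >= -100)) * vv,
    lung_volume_ml = nrow(hu) * vv,
    tissue_weight_g = density_sum * vv,
    gas_volume_ml = gas_sum * vv
  )
}
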