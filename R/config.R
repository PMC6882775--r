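#' Configuration for the breathing-waveform simulator
#'
#' Bundles the physiological and acquisition parameters of the
#' single-compartment breathing model used by [simulate_breathing()].
#' The respiratory drive follows the PEEP-dependent pattern seen during
#' assisted spontaneous breathing after surfactant depletion: respiratory
#' rate falls linearly with PEEP while tidal volume rises linearly.
#'
#' @param rrs Respiratory (lung pathway) resistance, cmH2O s/L.
#' @param ers Lung elastance, cmH2O/L.
#' @param ecw Chest-wall elastance, cmH2O/L.
#' @param nava_level Assist gain: ventilator pressure above PEEP per uV of
#'   phasic diaphragm electrical activity (cmH2O/uV).
#' @param k_eadi Neuromechanical coupling: muscle pressure generated per uV
#'   of phasic EAdi (cmH2O/uV).
#' @param eadi_tonic Tonic (end-expiratory) EAdi baseline, uV.
#' @param peep_sequence Numeric vector of PEEP levels (cmH2O) making up the
#'   protocol; defaults to the 11-step 0-15-0 ramp in steps of 3.
#' @param rr_intercept,rr_slope Linear respiratory-rate drive model
#'   `RR(PEEP) = rr_intercept + rr_slope * PEEP` (breaths/min and
#'   breaths/min per cmH2O); the generated rate is floored at 1/min.
#' @param tv_intercept,tv_slope Linear tidal-volume drive model
#'   `TV(PEEP) = tv_intercept + tv_slope * PEEP` (L and L/cmH2O).
#' @param ti_frac Inspiratory fraction of the breath period.
#' @param tv_jitter_frac Fractional breath-to-breath variability of the
#'   inspiratory effort amplitude (multiplicative Gaussian, truncated).
#' @param peso_baseline Constant esophageal pressure offset, cmH2O.
#' @param noise_sd_frac Additive Gaussian channel noise, expressed as a
#'   fraction of each clean channel's dynamic range.
#' @param fs_wave Sampling rate of the pressure/flow channels, Hz.
#' @param fs_eadi Sampling rate of the EAdi channel, Hz.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(rrs = 16.7,
                       ers = 30,
                       ecw = 8,
                       nava_level = 2.0,
                       k_eadi = 2.0,
                       eadi_tonic = 0.5,
                       peep_sequence = generate_protocol(15, 3)$peep,
                       rr_intercept = 95.47,
                       rr_slope = -5.8,
                       tv_intercept = 0.06,
                       tv_slope = 0.0206,
                       ti_frac = 0.35,
                       tv_jitter_frac = 0.2,
                       peso_baseline = 0,
                       noise_sd_frac = 0.02,
                       fs_wave = 200,
                       fs_eadi = 100,
                       seed = 1L) {
  cfg <- list(rrs = rrs, ers = ers, ecw = ecw,
              nava_level = nava_level, k_eadi = k_eadi,
              eadi_tonic = eadi_tonic,
              peep_sequence = peep_sequence,
              rr_intercept = rr_intercept, rr_slope = rr_slope,
              tv_intercept = tv_intercept, tv_slope = tv_slope,
              ti_frac = ti_frac, tv_jitter_frac = tv_jitter_frac,
              peso_baseline = peso_baseline,
              noise_sd_frac = noise_sd_frac,
              fs_wave = fs_wave, fs_eadi = fs_eadi,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$rrs > 0, "`rrs` must be > 0")
  stop_if_not(cfg$ers > 0, "`ers` must be > 0")
  stop_if_not(cfg$ecw >= 0, "`ecw` must be >= 0")
  stop_if_not(cfg$nava_level >= 0, "`nava_level` must be >= 0")
  stop_if_not(cfg$k_eadi > 0, "`k_eadi` must be > 0")
  stop_if_not(all(cfg$peep_sequence >= 0), "all PEEP levels must be >= 0")
  stop_if_not(cfg$ti_frac > 0 && cfg$ti_frac < 1,
              "`ti_frac` must be in (0, 1)")
  stop_if_not(cfg$noise_sd_frac >= 0, "`noise_sd_frac` must be >= 0")
  stop_if_not(cfg$fs_wave > 0 && cfg$fs_eadi > 0,
              "sampling rates must be > 0")
  invisible(cfg)
}

#' Configuration for the dynamic CT lung phantom
#'
#' Describes a two-dimensional lung slice phantom whose recruitable regions
#' open and close with airway-driven distending pressure (hysteresis: a
#' region opens when regional pressure reaches its opening pressure and
#' closes when pressure falls to its closing pressure).  Closed regions take
#' the attenuation of collapsed tissue; open regions track instantaneous
#' regional gas content on the linear Hounsfield mixing scale.
#'
#' @param grid_shape Integer vector `c(rows, cols)` of the pixel grid.
#' @param pixel_size In-plane pixel edge lengths, mm (length-2 vector).
#' @param slice_thickness Slice thickness, mm.
#' @param mask_shape `"ellipse"` for an inscribed elliptical lung mask or
#'   `"full"` for the whole grid.
#' @param recruitable_fraction Fraction of lung pixels exhibiting cyclic
#'   recruitment/derecruitment behavior (exact count = round(fraction x
#'   lung pixels)).
#' @param n_regions Number of spatially coherent regions the lung is split
#'   into; all pixels of a region share its opening/closing pressures.
#' @param closing_pressure_mean,closing_pressure_sd Mean and standard
#'   deviation (cmH2O) of the regional closing-pressure distribution,
#'   modeled as lognormal (strictly positive, right-skewed, as observed
#'   for airway closing pressures in surfactant-depleted lungs).
#' @param opening_offset_mean,opening_offset_sd Opening-minus-closing
#'   pressure gap distribution, cmH2O (Gaussian truncated at 0.5 so
#'   closing is always strictly below opening).
#' @param close_dwell Time (s) a region's pressure must stay at or below
#'   its closing pressure before it derecruits; models the finite time
#'   constant of airspace collapse (opening is instantaneous).
#' @param hu_nonaerated Attenuation of collapsed (non-aerated) tissue, HU.
#' @param hu_gas_gain HU decrease per unit regional gas fraction (the
#'   linear mixing slope; 1000 maps gas fraction 1 to -1000 HU).
#' @param gas_frac_range Range of baseline gas fractions assigned to
#'   aerated pixels (uniform draw per pixel).
#' @param gas_frac_per_l Increase in regional gas fraction per liter of
#'   instantaneous lung volume above end-expiration.
#' @param frame_rate Frame acquisition rate, Hz.
#' @param duration Acquisition duration, s.
#' @param ct_lag Constant offset added to emitted frame timestamps so that
#'   the synchronization stage has a known clock skew to recover, s.
#' @param seed Integer seed; identical seeds give bit-identical frames.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L),
                           pixel_size = c(0.5, 0.5),
                           slice_thickness = 5,
                           mask_shape = c("ellipse", "full"),
                           recruitable_fraction = 0.12,
                           n_regions = 1800L,
                           closing_pressure_mean = 4,
                           closing_pressure_sd = 4.5,
                           opening_offset_mean = 2,
                           opening_offset_sd = 0.5,
                           close_dwell = 0.1,
                           hu_nonaerated = -20,
                           hu_gas_gain = 1000,
                           gas_frac_range = c(0.35, 0.75),
                           gas_frac_per_l = 0.5,
                           frame_rate = 20,
                           duration = 100,
                           ct_lag = 0.35,
                           seed = 1L) {
  mask_shape <- match.arg(mask_shape)
  cfg <- list(grid_shape = as.integer(grid_shape),
              pixel_size = pixel_size,
              slice_thickness = slice_thickness,
              mask_shape = mask_shape,
              recruitable_fraction = recruitable_fraction,
              n_regions = as.integer(n_regions),
              closing_pressure_mean = closing_pressure_mean,
              closing_pressure_sd = closing_pressure_sd,
              opening_offset_mean = opening_offset_mean,
              opening_offset_sd = opening_offset_sd,
              close_dwell = close_dwell,
              hu_nonaerated = hu_nonaerated,
              hu_gas_gain = hu_gas_gain,
              gas_frac_range = gas_frac_range,
              gas_frac_per_l = gas_frac_per_l,
              frame_rate = frame_rate,
              duration = duration,
              ct_lag = ct_lag,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stop_if_not(length(cfg$grid_shape) == 2L && all(cfg$grid_shape >= 4L),
              "`grid_shape` must be two integers >= 4")
  stop_if_not(all(cfg$pixel_size > 0) && cfg$slice_thickness > 0,
              "voxel dimensions must be > 0")
  stop_if_not(cfg$recruitable_fraction >= 0 && cfg$recruitable_fraction <= 1,
              "`recruitable_fraction` must be in [0, 1]")
  stop_if_not(cfg$hu_nonaerated >= -100 && cfg$hu_nonaerated <= 100,
              "`hu_nonaerated` must lie in the non-aerated band [-100, 100]")
  stop_if_not(cfg$frame_rate > 0 && cfg$duration > 0,
              "`frame_rate` and `duration` must be > 0")
  stop_if_not(cfg$close_dwell >= 0, "`close_dwell` must be >= 0")
  stop_if_not(cfg$gas_frac_range[1] >= 0.11 && cfg$gas_frac_range[2] <= 0.99,
              "`gas_frac_range` must stay inside (0.11, 0.99) so aerated pixels never enter the non-aerated band")
  invisible(cfg)
}
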