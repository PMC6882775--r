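prof_comp <- function(profile, comp, field) {
  cc <- profile$compartments
  cc[[field]][match(comp, cc$compartment)]
}

#' Per-breath tidal recruitment/derecruitment from an end-expiratory and
#' end-inspiratory aeration profile
#'
#' Tidal R/D is the difference in non-aerated lung between end-expiration
#' and end-inspiration of the same breathing cycle, in ml and g, and
#' normalized to the end-expiratory lung volume (total masked slice
#' volume, tissue plus gas, by default; gas volume via
#' `denominator = "gas"`) and end-expiratory lung weight.  End-expiratory
#' atelectasis (the non-aerated compartment of the end-expiratory frame)
#' is reported alongside.  Negative R/D (more non-aerated lung at
#' end-inspiration) is retained and flagged, not clipped.
#'
#' @param profile_ee,profile_ei [compute_aeration_profile()] results for
#'   the breath's end-expiratory and end-inspiratory frames.
#' @param breath Optional breath id recorded in the output.
#' @param peep,direction Optional protocol annotations (cmH2O; "up"/"down").
#' @param denominator `"total"` (tissue + gas volume of the ee slice) or
#'   `"gas"` (ee gas volume) for the %eeLV normalization.
#' @return A one-row data.frame of class `rd_measure`: `rd_volume_ml`,
#'   `rd_weight_g`, `rd_pct_eelv`, `rd_pct_eelw`, `atelectasis_ee_ml`,
#'   `atelectasis_ee_g`, `atelectasis_pct_eelw`, `eelv_ml`, `eelw_g`,
#'   `negative_rd` flag, plus the annotations.
#' @export
compute_rd <- function(profile_ee, profile_ei, breath = NA_integer_,
                       peep = NA_real_, direction = NA_character_,
                       denominator = c("total", "gas")) {
  denominator <- match.arg(denominator)
  non_ee <- prof_comp(profile_ee, "non", "volume_ml")
  non_ei <- prof_comp(profile_ei, "non", "volume_ml")
  nonw_ee <- prof_comp(profile_ee, "non", "weight_g")
  nonw_ei <- prof_comp(profile_ei, "non", "weight_g")
  eelv <- switch(denominator,
                 total = profile_ee$lung_volume_ml,
                 gas = profile_ee$gas_volume_ml)
  eelw <- profile_ee$tissue_weight_g
  stop_if_not(eelv > 0, "end-expiratory lung volume is zero")
  stop_if_not(eelw > 0, "end-expiratory lung weight is zero")
  rd_v <- non_ee - non_ei
  rd_w <- nonw_ee - nonw_ei
  out <- data.frame(
    breath = breath, peep = peep, direction = direction,
    rd_volume_ml = rd_v, rd_weight_g = rd_w,
    rd_pct_eelv = 100 * rd_v / eelv,
    rd_pct_eelw = 100 * rd_w / eelw,
    atelectasis_ee_ml = non_ee, atelectasis_ee_g = nonw_ee,
    atelectasis_pct_eelw = 100 * nonw_ee / eelw,
    eelv_ml = eelv, eelw_g = eelw,
    negative_rd = rd_v < 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rd_measure", "data.frame")
  out
}

#' Aggregate R/D measures by PEEP level and ramp direction
#'
#' Emits two groupings: per (PEEP, direction) and pooled per PEEP
#' (ascending and descending limbs merged).  Means and standard
#' deviations (n-1 denominator) of the R/D and atelectasis fields;
#' single-observation groups report `sd = NA` with `n = 1`.
#'
#' @param measures A data.frame of stacked [compute_rd()] rows with
#'   `peep` and `direction` filled in.
#' @param fields Columns to summarize.
#' @return A list with data.frames `by_peep_direction` and `pooled`,
#'   each with `<field>_mean`, `<field>_sd` and `n` columns.
#' @export
aggregate_by_peep <- function(measures,
                              fields = c("rd_volume_ml", "rd_weight_g",
                                         "rd_pct_eelv", "rd_pct_eelw",
                                         "atelectasis_ee_ml",
                                         "atelectasis_ee_g",
                                         "atelectasis_pct_eelw")) {
  stop_if_not(nrow(measures) >= 1L, "no measures to aggregate")
  fields <- intersect(fields, names(measures))
  summarize <- function(df, keys) {
    split_keys <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
    parts <- split(df, split_keys)
    rows <- lapply(parts, function(p) {
      out <- p[1L, keys, drop = FALSE]
      for (f in fields) {
        out[[paste0(f, "_mean")]] <- mean(p[[f]])
        out[[paste0(f, "_sd")]] <- if (nrow(p) > 1L) stats::sd(p[[f]]) else NA_real_
      }
      out$n <- nrow(p)
      out
    })
    res <- do.call(rbind, rows)
    res[order(res$peep), , drop = FALSE]
  }
  list(by_peep_direction = summarize(measures, c("peep", "direction")),
       pooled = summarize(measures, "peep"))
}
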