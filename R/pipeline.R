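## End-to-end orchestration and ROI/trend analytics.
##
## Coordinate conventions, used everywhere: pixel coordinates are 0-based and
## row-major; ROI rectangles c(row0, row1, col0, col1) are half-open.

#' Run the full SFDI processing chain on one acquisition
#'
#' demodulate (DC and AC) -> calibrate against the phantom -> invert to
#' optical properties per wavelength -> unmix water/lipid.  Inputs are the
#' raw PhaseImageSets of the sample and of the calibration phantom as
#' produced by \code{\link{renderRaw}} or read back via
#' \code{\link{readRawDir}}.
#'
#' @param raw list with \code{sample} and \code{phantom} PhaseImageSet lists,
#'   keyed "w{wavelength}_fx{fx}"
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param table an \linkS4class{ExtinctionTable}
#' @param phantom a \linkS4class{CalibrationPhantomSpec}
#' @param wavelengths nm
#' @param fx_ac AC spatial frequency (default 0.1 mm^-1)
#' @param noise_floor_frac calibration noise floor (see
#'   \code{\link{calibrateReflectance}})
#' @param out_dir if given, per-wavelength property maps and the chromophore
#'   maps are persisted there as CSV
#' @return list with \code{props} (per-wavelength
#'   \linkS4class{OpticalPropertyMap}s), \code{chromo}
#'   (\linkS4class{ChromophoreMap}), \code{reflectance} (calibrated images)
#'   and a \code{log} of invalid-pixel fractions
#' @export
runPipeline <- function(raw, lut, table, phantom, wavelengths = c(970, 1050, 1200),
                        fx_ac = 0.1, noise_floor_frac = 0.01, out_dir = NULL) {
  props <- list(); refl <- list(); log <- list()
  for (wl in wavelengths) {
    key_dc <- sprintf("w%g_fx%g", wl, 0)
    key_ac <- sprintf("w%g_fx%g", wl, fx_ac)
    for (k in c(key_dc, key_ac)) {
      if (is.null(raw$sample[[k]]))
        stop("pipeline stage demodulate: missing sample frames for ", k)
      if (is.null(raw$phantom[[k]]))
        stop("pipeline stage calibrate: missing phantom frames for ", k)
    }
    m_s_dc <- demodulateDC(raw$sample[[key_dc]])
    m_p_dc <- demodulateDC(raw$phantom[[key_dc]])
    m_s_ac <- demodulateAC(raw$sample[[key_ac]])
    m_p_ac <- demodulateAC(raw$phantom[[key_ac]])
    r_pred_dc <- predictPhantomReflectance(phantom, lut, wl, 0)
    r_pred_ac <- predictPhantomReflectance(phantom, lut, wl, fx_ac)
    R_dc <- calibrateReflectance(m_s_dc, m_p_dc, r_pred_dc, noise_floor_frac)
    R_ac <- calibrateReflectance(m_s_ac, m_p_ac, r_pred_ac, noise_floor_frac)
    pm <- invertMap(R_dc, R_ac, lut)
    wkey <- as.character(wl)
    props[[wkey]] <- pm
    refl[[wkey]] <- list(dc = R_dc, ac = R_ac)
    log[[wkey]] <- list(invalid_fraction = mean(!pm@valid_mask),
                        clamped_dc = m_s_dc@n_clamped)
  }
  chromo <- unmixChromophores(props, table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (wl in names(props)) {
      write.csv(props[[wl]]@mu_a, file.path(out_dir, paste0("mu_a_", wl, "nm.csv")), row.names = FALSE)
      write.csv(props[[wl]]@mu_s_prime, file.path(out_dir, paste0("mu_s_prime_", wl, "nm.csv")), row.names = FALSE)
    }
    write.csv(chromo@C_water, file.path(out_dir, "C_water.csv"), row.names = FALSE)
    write.csv(chromo@C_lipid, file.path(out_dir, "C_lipid.csv"), row.names = FALSE)
  }
  list(props = props, chromo = chromo, reflectance = refl, log = log)
}

#' Mean and standard deviation over an ROI, valid pixels only
#'
#' @param values matrix of per-pixel values
#' @param mask logical validity matrix (same shape); NULL means all valid
#' @param roi half-open 0-based rectangle c(row0, row1, col0, col1)
#' @return list(mean, sd, n_valid, n_excluded, ok); \code{ok = FALSE} with NA
#'   statistics when the ROI holds no valid pixel
#' @export
roiStats <- function(values, mask = NULL, roi) {
  d <- dim(values)
  rm_ <- roiMask(d, roi)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  sel <- rm_ & mask & is.finite(values)
  n_roi <- sum(rm_)
  v <- values[sel]
  if (length(v) == 0)
    return(list(mean = NA_real_, sd = NA_real_, n_valid = 0L,
                n_excluded = n_roi, ok = FALSE))
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n_valid = length(v), n_excluded = n_roi - length(v), ok = TRUE)
}

#' Percent change of ROI statistics against a baseline
#'
#' Builds a trend table with one row per (timepoint, quantity):
#' 100 (x_t - x_base)/x_base, optionally as absolute values ("absolute
#' percent change").  The baseline is either the first timepoint or the mean
#' of the pre-event timepoints.
#'
#' @param stats data.frame with columns \code{timepoint}, \code{mean},
#'   \code{sd} and any identifying columns (wavelength, quantity, roi_id)
#' @param baseline "first" or "pre_event_mean"
#' @param n_pre number of pre-event timepoints when baseline = "pre_event_mean"
#' @param absolute return |percent change|
#' @return the input data.frame with a \code{percent_change} column; baseline
#'   rows read 0.  Zero-baseline groups are flagged with NA and a warning.
#' @export
percentChangeSeries <- function(stats, baseline = c("first", "pre_event_mean"),
                                n_pre = 1, absolute = FALSE) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("timepoint", "mean") %in% names(stats)))
  if (length(unique(stats$timepoint)) < 2) stop("need at least 2 timepoints")
  idcols <- setdiff(names(stats), c("timepoint", "mean", "sd", "n_valid",
                                    "n_excluded", "ok", "percent_change"))
  key <- if (length(idcols)) interaction(stats[idcols], drop = TRUE)
         else factor(rep(1, nrow(stats)))
  out <- stats
  out$percent_change <- NA_real_
  for (g in levels(key)) {
    i <- which(key == g)
    ord <- i[order(stats$timepoint[i])]
    base_val <- if (baseline == "first") stats$mean[ord[1]]
                else mean(stats$mean[ord[seq_len(min(n_pre, length(ord)))]])
    if (!is.finite(base_val) || base_val == 0) {
      warning("zero or non-finite baseline in group ", g, "; rows flagged NA")
      next
    }
    pc <- 100 * (stats$mean[ord] - base_val) / base_val
    out$percent_change[ord] <- if (absolute) abs(pc) else pc
  }
  out
}

#' Serialize / read back a trend table
#'
#' Plain-CSV round trip for \code{\link{percentChangeSeries}} output.
#'
#' @param trend data.frame
#' @param path CSV path
#' @return \code{readTrendTable} returns the data.frame
#' @export
writeTrendTable <- function(trend, path) {
  write.csv(trend, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrendTable
#' @export
readTrendTable <- function(path) read.csv(path, stringsAsFactors = FALSE)
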