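#' Kinetic plate-reader data for one MPO assay well series
#'
#' Raw material for the myeloperoxidase (MPO) activity computation: triplicate
#' absorbance readings at 450 nm taken at fixed times after the
#' O-dianisidine/H2O2 reaction is started (0, 30 and 60 s by default),
#' together with the dilution bookkeeping needed to express activity per gram
#' of wet tissue. Tissue is homogenized at `homogenate_concentration` grams
#' per mL of HTAB buffer and `supernatant_volume` mL of the cleared
#' supernatant goes into the assayed well, so the well contains
#' `homogenate_concentration * supernatant_volume` grams of tissue.
#'
#' @param absorbance Numeric matrix, replicates in rows and timepoints in
#'   columns (default shape 3 x 3); all values >= 0.
#' @param time_s Timepoints in seconds, strictly increasing; default
#'   `c(0, 30, 60)`.
#' @param tissue_mass Wet mass of the homogenized colon segment (g).
#' @param homogenate_concentration Grams of tissue per mL of buffer
#'   (default 0.030, i.e. approx. 30 mg/mL).
#' @param supernatant_volume Supernatant volume pipetted into the well, in mL
#'   (default 0.007, i.e. 7 uL).
#' @return An `mpo_kinetics` object.
#' @export
mpo_kinetics <- function(absorbance, time_s = c(0, 30, 60),
                         tissue_mass = 0.03,
                         homogenate_concentration = 0.030,
                         supernatant_volume = 0.007) {
  absorbance <- as.matrix(absorbance)
  if (!is.numeric(absorbance) || any(!is.finite(absorbance)) ||
      any(absorbance < 0)) {
    stop("`absorbance` must be a numeric matrix with finite values >= 0",
         call. = FALSE)
  }
  if (length(time_s) < 2 || any(diff(time_s) <= 0)) {
    stop("`time_s` must contain at least 2 strictly increasing timepoints",
         call. = FALSE)
  }
  if (ncol(absorbance) != length(time_s)) {
    stop("`absorbance` must have one column per timepoint", call. = FALSE)
  }
  stop_if_not_scalar_number(tissue_mass, "tissue_mass")
  if (tissue_mass <= 0) stop("`tissue_mass` must be > 0", call. = FALSE)
  stop_if_not_scalar_number(homogenate_concentration,
                            "homogenate_concentration")
  stop_if_not_scalar_number(supernatant_volume, "supernatant_volume")
  structure(
    list(absorbance = absorbance, time_s = as.numeric(time_s),
         tissue_mass = tissue_mass,
         homogenate_concentration = homogenate_concentration,
         supernatant_volume = supernatant_volume),
    class = "mpo_kinetics"
  )
}

#' Kinetic reaction rate in absorbance units per minute
#'
#' Per replicate, the least-squares slope of absorbance against time (per
#' second) is computed in closed form and converted to per-minute; replicate
#' rates are then aggregated (mean by default, median available). Enzyme
#' activity cannot be negative, so a negative aggregated slope is clamped to
#' 0 with a warning.
#'
#' @param k An [mpo_kinetics()] object.
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @return Reaction rate in absorbance/min, >= 0.
#' @examples
#' k <- mpo_kinetics(matrix(rep(c(0, 0.3, 0.6), each = 3), nrow = 3))
#' reaction_rate(k) # 0.6 abs/min
#' @export
reaction_rate <- function(k, aggregate = c("mean", "median")) {
  stopifnot(inherits(k, "mpo_kinetics"))
  aggregate <- match.arg(aggregate)
  t <- k$time_s
  tc <- t - mean(t)
  # OLS slope per replicate: sum((t - tbar) * y) / sum((t - tbar)^2)
  slopes_per_s <- as.numeric(k$absorbance %*% tc) / sum(tc^2)
  rate <- switch(aggregate,
                 mean = mean(slopes_per_s),
                 median = stats::median(slopes_per_s)) * 60
  if (rate < 0) {
    warning(sprintf("negative fitted rate %.4g abs/min clamped to 0", rate),
            call. = FALSE)
    rate <- 0
  }
  rate
}

#' Construct a peroxidase standard curve from known slope and intercept
#'
#' @param slope Absorbance/min per mU of enzyme activity; must be > 0.
#' @param intercept Absorbance/min at zero activity (default 0).
#' @return A `standard_curve` object.
#' @seealso [fit_standard_curve()] to estimate the line from calibration
#'   points.
#' @export
standard_curve <- function(slope, intercept = 0) {
  stop_if_not_scalar_number(slope, "slope")
  stop_if_not_scalar_number(intercept, "intercept")
  if (slope <= 0) stop("standard curve `slope` must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 calibration_points = NULL, residuals = NULL),
            class = "standard_curve")
}

#' Fit a peroxidase standard curve by ordinary least squares
#'
#' Fits `rate = slope * activity + intercept` to calibration points measured
#' with purified peroxidase of known activity, keeping residual diagnostics.
#'
#' @param activity_mU Known activities (mU); at least 2 distinct values.
#' @param rate Measured reaction rates (absorbance/min), same length.
#' @return A `standard_curve` with `calibration_points` and `residuals`.
#' @examples
#' fit_standard_curve(c(0, 100), c(0, 1)) # slope 0.01, intercept 0
#' @export
fit_standard_curve <- function(activity_mU, rate) {
  if (length(activity_mU) < 2 || length(rate) != length(activity_mU)) {
    stop("need >= 2 calibration points with matching lengths", call. = FALSE)
  }
  if (any(!is.finite(activity_mU)) || any(!is.finite(rate))) {
    stop("calibration points must be finite", call. = FALSE)
  }
  if (length(unique(activity_mU)) < 2) {
    stop("degenerate calibration: all activities identical", call. = FALSE)
  }
  xc <- activity_mU - mean(activity_mU)
  slope <- sum(xc * rate) / sum(xc^2)
  intercept <- mean(rate) - slope * mean(activity_mU)
  if (slope <= 0) {
    stop("fitted standard-curve slope is not positive; check calibration data",
         call. = FALSE)
  }
  curve <- standard_curve(slope, intercept)
  curve$calibration_points <- data.frame(activity_mU = activity_mU,
                                         rate = rate)
  curve$residuals <- rate - (slope * activity_mU + intercept)
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Peroxidase standard curve: rate = %.5g * activity + %.5g\n",
              x$slope, x$intercept))
  if (!is.null(x$residuals)) {
    cat(sprintf("  %d calibration points, residual SD %.3g abs/min\n",
                length(x$residuals), stats::sd(x$residuals)))
  }
  invisible(x)
}

#' MPO activity in milliunits per gram of wet tissue
#'
#' Converts a kinetic trace into MPO activity: the aggregated reaction rate
#' ([reaction_rate()]) is mapped through the inverted standard curve to the
#' enzyme activity present in the well, `(rate - intercept) / slope` mU
#' (clamped at 0), and then normalized by the grams of tissue the assayed
#' supernatant aliquot represents, `homogenate_concentration *
#' supernatant_volume`. One unit is the quantity of enzyme converting 1 umol
#' of hydrogen peroxide to water per minute at room temperature.
#'
#' @inheritParams reaction_rate
#' @param curve A [standard_curve()] or [fit_standard_curve()] result.
#' @return Activity in mU per gram of wet tissue, >= 0.
#' @examples
#' k <- mpo_kinetics(matrix(rep(c(0, 0.3, 0.6), each = 3), nrow = 3))
#' mpo_activity(k, standard_curve(slope = 0.01)) # 60 mU in well -> per gram
#' @export
mpo_activity <- function(k, curve, aggregate = c("mean", "median")) {
  stopifnot(inherits(k, "mpo_kinetics"), inherits(curve, "standard_curve"))
  if (curve$slope <= 0) stop("standard curve slope must be > 0", call. = FALSE)
  rate <- reaction_rate(k, aggregate = match.arg(aggregate))
  activity_in_well <- max(0, (rate - curve$intercept) / curve$slope)
  grams_in_well <- k$homogenate_concentration * k$supernatant_volume
  activity_in_well / grams_in_well
}
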