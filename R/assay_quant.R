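# Assay arithmetic: calibration curves, dual-culture inhibition, CAS
# siderophore percentage, seed germination, chlorophyll a/b.

#' Fit a linear standard curve
#'
#' Ordinary least squares fit of `absorbance = slope * concentration +
#' intercept` to a standard series, as used to quantify IAA (vs a commercial
#' IAA series), solubilized phosphate (vs KH2PO4) and ammonia (vs ammonium
#' sulfate). The intercept is left free: blank correction of the readouts is
#' not assumed.
#'
#' @param standards data.frame with columns `concentration` and `absorbance`
#'   (one row per standard), or a 2-column matrix in that order.
#' @param r2_warn warn when the fit quality drops below this R-squared
#'   (default 0.98, a conventional acceptance bar for colorimetric curves).
#' @return object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r2` and the `standards` used.
#' @export
fit_standard_curve <- function(standards, r2_warn = 0.98) {
  standards <- as.data.frame(standards)
  if (ncol(standards) >= 2 &&
      !all(c("concentration", "absorbance") %in% names(standards))) {
    names(standards)[1:2] <- c("concentration", "absorbance")
  }
  if (nrow(standards) < 3) {
    stop("degenerate design: need at least 3 standards", call. = FALSE)
  }
  if (length(unique(standards$concentration)) < 2) {
    stop("degenerate design: all standard concentrations identical",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration, data = standards)
  # summary.lm warns on an exactly collinear (noiseless) series; that case
  # is legitimate here and simply means r2 = 1
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.na(r2)) r2 <- 1  # exact fit with zero residual variance
  if (r2 < r2_warn) {
    warning(sprintf("standard curve r2 = %.4f is below %.2f", r2, r2_warn),
            call. = FALSE)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, standards = standards),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: absorbance = %.6g * conc + %.6g (r2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r2, nrow(x$standards)))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Maps sample absorbances to concentrations via `(A - intercept) / slope`.
#' Negative concentrations (absorbance below the blank) are not clamped --
#' they carry QC information -- but are flagged, and a censored-at-zero
#' companion is attached.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param absorbance numeric vector of sample readouts.
#' @return numeric vector of concentrations in the standards' unit, with
#'   attributes `flagged_negative` (logical) and `censored` (values with
#'   negatives set to 0).
#' @export
concentration_from_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("unusable curve: slope is zero", call. = FALSE)
  conc <- (absorbance - curve$intercept) / curve$slope
  structure(conc,
            flagged_negative = !is.na(conc) & conc < 0,
            censored = pmax(conc, 0))
}

#' Dual-culture percent inhibition
#'
#' `100 * (C - T) / C` where `C` and `T` are the fungal mycelium diameters on
#' the control and test plates. A test diameter exceeding the control gives a
#' negative value, which is allowed but flagged with a warning.
#'
#' @param control_diameter C, mm, must be > 0.
#' @param test_diameter T, mm, >= 0.
#' @return percent inhibition (vectorized).
#' @export
percent_inhibition <- function(control_diameter, test_diameter) {
  if (any(control_diameter <= 0)) {
    stop("domain error: control diameter must be positive", call. = FALSE)
  }
  if (any(test_diameter < 0)) {
    stop("domain error: test diameter must be non-negative", call. = FALSE)
  }
  out <- 100 * (control_diameter - test_diameter) / control_diameter
  if (any(out < 0)) {
    warning("negative inhibition: test mycelium grew beyond the control",
            call. = FALSE)
  }
  out
}

#' CAS-shuttle siderophore percentage
#'
#' `100 * (Ar - As) / Ar` with `Ar` the absorbance of the CAS reference
#' (medium plus dye) and `As` the sample absorbance, both at 630 nm. Iron
#' chelation by siderophores decolorizes the dye, so lower `As` means more
#' siderophore.
#'
#' @param ar reference absorbance, must be > 0.
#' @param as_sample sample absorbance, >= 0.
#' @return siderophore units in percent (vectorized).
#' @export
siderophore_percent <- function(ar, as_sample) {
  if (any(ar <= 0)) stop("domain error: reference absorbance must be positive",
                         call. = FALSE)
  100 * (ar - as_sample) / ar
}

#' Seed germination percentage
#'
#' @param germinated number of seeds that germinated (integer >= 0).
#' @param total total seeds plated (integer > 0).
#' @return percent germination (vectorized).
#' @export
germination_percent <- function(germinated, total) {
  if (any(total <= 0)) stop("domain error: total seeds must be positive",
                            call. = FALSE)
  if (any(germinated < 0 | germinated > total)) {
    stop("domain error: germinated count outside [0, total]", call. = FALSE)
  }
  100 * germinated / total
}

#' Chlorophyll a and b from DMSO-extract absorbances
#'
#' The two-wavelength equations for DMSO extracts:
#' `Chla = 11.75 * A663 - 2.35 * A645` and
#' `Chlb = 18.61 * A645 - 3.96 * A663`, in mg per g fresh weight for the
#' extraction protocol's volumes. Negative outputs (possible for extreme
#' absorbance ratios) are flagged, not clamped.
#'
#' @param a663,a645 absorbances at 663 and 645 nm (>= 0).
#' @return data.frame with columns `chl_a`, `chl_b`, `flagged` (TRUE where
#'   either pigment came out negative).
#' @export
chlorophyll_ab <- function(a663, a645) {
  if (any(a663 < 0 | a645 < 0)) {
    stop("domain error: absorbances must be non-negative", call. = FALSE)
  }
  chl_a <- 11.75 * a663 - 2.35 * a645
  chl_b <- 18.61 * a645 - 3.96 * a663
  data.frame(chl_a = chl_a, chl_b = chl_b, flagged = chl_a < 0 | chl_b < 0)
}

#' Mean and standard error of replicate measurements
#'
#' Replicate assay values are summarised as mean +/- SE with SE = sd /
#' sqrt(n) (sample sd, n - 1 denominator).
#'
#' @param values numeric vector of replicate values (n >= 2).
#' @return list with `mean`, `se`, `n`.
#' @export
measurement_with_error <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("insufficient replication: need at least 2 values",
                  call. = FALSE)
  list(mean = mean(values), se = stats::sd(values) / sqrt(n), n = n)
}
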