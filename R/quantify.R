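# DER estimation, ROI statistics, size-specific concentration calibration
# (the "manual method") and bias / total-error metrics.

#' Estimate a dual-energy ratio from insert CT numbers
#'
#' The DER is the slope of the ordinary-least-squares fit of low-energy HU
#' as a function of high-energy HU across insert means, fitted with an
#' intercept (raw insert HU include the base-material offset, which the
#' intercept absorbs).
#'
#' @param data Data frame of per-insert mean CT numbers.
#' @param high,low Column names (strings) holding the high- and low-energy
#'   HU means; defaults `"hu_high"`, `"hu_low"`.
#' @return An object of class `der_fit` with fields `der` (the slope),
#'   `intercept`, `r_squared` and `n_points`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' pts <- tibble::tibble(hu_high = c(0, 10, 20), hu_low = c(0, 19.7, 39.4))
#' estimate_der(pts)$der
#' @export
estimate_der <- function(data, high = "hu_high", low = "hu_low") {
  data <- as.data.frame(data)
  if (!all(c(high, low) %in% names(data))) {
    stop_validation(sprintf("`data` must have columns '%s' and '%s'", high, low))
  }
  x <- data[[high]]
  y <- data[[low]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L) {
    stop_fit("DER fit needs >= 2 points with distinct high-energy HU values")
  }
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(
    list(der = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = r2, n_points = length(x),
         data = tibble(hu_high = x, hu_low = y)),
    class = "der_fit"
  )
}

#' @export
print.der_fit <- function(x, ...) {
  cat(sprintf("<der_fit> DER = %.4f (intercept %.2f HU, r^2 = %.4f, n = %d)\n",
              x$der, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

# circular ROI mask indices for one insert at a given fraction of its
# diameter; errors when the ROI is clipped by the volume edge
roi_mask <- function(dim_rc, spacing_mm, x_cm, y_cm, radius_cm) {
  xs <- grid_coords(dim_rc[2], spacing_mm)
  ys <- grid_coords(dim_rc[1], spacing_mm)
  half_x <- dim_rc[2] * spacing_mm / 20  # cm
  half_y <- dim_rc[1] * spacing_mm / 20
  if (abs(x_cm) + radius_cm > half_x || abs(y_cm) + radius_cm > half_y) {
    stop_geometry("ROI extends beyond the volume edge")
  }
  dx2 <- outer(rep(1, dim_rc[1]), (xs - x_cm)^2)
  dy2 <- outer((ys - y_cm)^2, rep(1, dim_rc[2]))
  which(dx2 + dy2 <= radius_cm^2)
}

#' ROI statistics inside inserts
#'
#' Places a circular ROI of diameter `fraction` times the insert diameter
#' at each insert center on the central slice, copies it over `n_slices`
#' slices (central slice plus/minus `floor(n_slices / 2)`), and reports the
#' mean and SD over all included voxels.
#'
#' @param volume 3-D array in the phantom frame (origin at center).
#' @param inserts Insert table (see [default_inserts()]); any data frame
#'   with `insert`, `x_cm`, `y_cm`, `diameter_cm` columns works.
#' @param spacing_mm In-plane pixel spacing.
#' @param fraction ROI diameter as a fraction of the insert diameter,
#'   default 0.60.
#' @param n_slices Number of slices to include, default 5 (clipped demand
#'   beyond the volume errors).
#' @param center_slice Central slice index; defaults to the middle slice.
#' @return A tibble with one row per insert: `insert`, `mean`, `sd`,
#'   `n_voxels`, `n_slices`.
#' @export
roi_stats <- function(volume, inserts, spacing_mm, fraction = 0.60,
                      n_slices = 5, center_slice = NULL) {
  if (length(dim(volume)) == 2L) dim(volume) <- c(dim(volume), 1L)
  d <- dim(volume)
  check_number(spacing_mm, "spacing_mm", positive = TRUE)
  if (fraction <= 0 || fraction > 1) {
    stop_validation("`fraction` must lie in (0, 1]")
  }
  center_slice <- center_slice %||% ((d[3] + 1L) %/% 2L)
  half <- floor(n_slices / 2)
  slices <- (center_slice - half):(center_slice + half)
  if (any(slices < 1L) || any(slices > d[3])) {
    stop_geometry("requested slices extend beyond the volume")
  }
  inserts <- as.data.frame(inserts)
  rows <- lapply(seq_len(nrow(inserts)), function(i) {
    idx <- roi_mask(d[1:2], spacing_mm, inserts$x_cm[i], inserts$y_cm[i],
                    fraction * inserts$diameter_cm[i] / 2)
    vals <- unlist(lapply(slices, function(k) volume[, , k][idx]),
                   use.names = FALSE)
    tibble(insert = inserts$insert[i],
           mean = mean(vals),
           sd = if (length(vals) > 1L) sd(vals) else 0,
           n_voxels = length(vals),
           n_slices = length(slices))
  })
  dplyr::bind_rows(rows)
}

#' Per-insert mean HU in both beams
#'
#' ROI means of the low- and high-energy volumes for every insert — the
#' measurement that feeds [estimate_der()].
#'
#' @param pair A `dect_pair`.
#' @param inserts Insert table; defaults to the pair's own metadata.
#' @param ... Passed to [roi_stats()] (`fraction`, `n_slices`, ...).
#' @return A tibble with columns `insert`, `hu_low`, `hu_high`.
#' @export
insert_hu_means <- function(pair, inserts = pair$meta$inserts, ...) {
  lowt <- roi_stats(pair$low, inserts, pair$meta$pixel_spacing_mm, ...)
  hight <- roi_stats(pair$high, inserts, pair$meta$pixel_spacing_mm, ...)
  tibble(insert = lowt$insert, hu_low = lowt$mean, hu_high = hight$mean)
}

#' Fit a size-specific concentration calibration curve
#'
#' Ordinary least squares of concentration on enhancement HU (the
#' prediction direction), with intercept:
#' `conc = a * enhancement + b`.
#'
#' @param data Data frame pairing true concentrations with measured
#'   enhancement-image HU means.
#' @param conc,enh Column names, defaults `"conc_mg_ml"` and `"enh_hu"`.
#' @param size_label,material,modality,source_workflow Optional provenance
#'   recorded on the curve.
#' @return An object of class `calibration_curve` with `slope`
#'   ((mg/ml)/HU) and `intercept` (mg/ml). Supports [tidy()], [glance()]
#'   and [predict()].
#' @examples
#' cal <- fit_calibration(tibble::tibble(conc_mg_ml = c(0, 5, 10),
#'                                       enh_hu = c(0, 100, 200)))
#' predict(cal, enh = 200)
#' @export
fit_calibration <- function(data, conc = "conc_mg_ml", enh = "enh_hu",
                            size_label = NULL, material = NULL,
                            modality = NULL, source_workflow = NULL) {
  data <- as.data.frame(data)
  if (!all(c(conc, enh) %in% names(data))) {
    stop_validation(sprintf("`data` must have columns '%s' and '%s'", conc, enh))
  }
  y <- data[[conc]]; x <- data[[enh]]
  if (length(x) != length(y)) stop_fit("paired lists of equal length required")
  if (length(unique(x)) < 2L) {
    stop_fit("calibration needs >= 2 inserts with distinct enhancement values")
  }
  fit <- lm(y ~ x)
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         n_points = length(x),
         size_label = size_label, material = material, modality = modality,
         source_workflow = source_workflow,
         data = tibble(conc_mg_ml = y, enh_hu = x)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> conc = %.5f * enh + %.4f mg/ml (n = %d%s)\n",
    x$slope, x$intercept, x$n_points,
    if (!is.null(x$source_workflow)) {
      sprintf(", workflow %s %s", x$source_workflow, x$size_label %||% "")
    } else ""))
  invisible(x)
}

#' Concentration from an enhancement CT number
#'
#' @param curve A [fit_calibration()] result.
#' @param enh Enhancement HU value(s).
#' @return Concentration(s) in mg/ml.
#' @export
concentration_from_enhancement <- function(curve, enh) {
  if (!inherits(curve, "calibration_curve")) {
    stop_validation("`curve` must be a calibration_curve")
  }
  curve$slope * enh + curve$intercept
}

#' @export
predict.calibration_curve <- function(object, enh, ...) {
  concentration_from_enhancement(object, enh)
}

#' Bias and total-error metrics for quantified concentrations
#'
#' Following the convention of inter-scanner iodine-quantification
#' comparisons: `bias` is the mean signed error, `total_error_mean` the
#' mean absolute error and `total_error_sd` the SD of the absolute errors,
#' across inserts.
#'
#' @param data Data frame pairing measured and true concentrations.
#' @param measured,truth Column names, defaults `"measured"` and `"truth"`.
#' @return A one-row tibble: `bias`, `total_error_mean`, `total_error_sd`,
#'   `n`.
#' @export
error_metrics <- function(data, measured = "measured", truth = "truth") {
  data <- as.data.frame(data)
  if (!all(c(measured, truth) %in% names(data))) {
    stop_validation(sprintf("`data` must have columns '%s' and '%s'",
                            measured, truth))
  }
  m <- data[[measured]]; t_ <- data[[truth]]
  if (length(m) != length(t_) || length(m) == 0L) {
    stop_validation("`measured` and `truth` must be nonempty and paired")
  }
  err <- m - t_
  tibble(
    bias = mean(err),
    total_error_mean = mean(abs(err)),
    total_error_sd = if (length(err) > 1L) sd(abs(err)) else 0,
    n = length(err)
  )
}
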