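# broom-style tidiers for the fitted/result objects.

#' @exportS3Method generics::tidy
tidy.der_fit <- function(x, ...) {
  tibble(term = c("intercept", "der"),
         estimate = c(x$intercept, x$der))
}

#' @exportS3Method generics::glance
glance.der_fit <- function(x, ...) {
  tibble(der = x$der, intercept = x$intercept,
         r.squared = x$r_squared, n_points = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n_points = x$n_points,
         size_label = x$size_label %||% NA_character_,
         material = x$material %||% NA_character_,
         source_workflow = x$source_workflow %||% NA_integer_)
}

#' @exportS3Method generics::tidy
tidy.vnc_grid <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.vnc_grid <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.noise_study <- function(x, ...) x$insert_means

#' @exportS3Method generics::glance
glance.noise_study <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.dect_decomp <- function(x, ...) {
  conservation <- max(abs(x$vnc_mixed + x$enhancement_mixed - x$mixed))
  tibble(applied_der = x$applied_der,
         water_equiv_diameter_cm = x$water_equiv_diameter_cm,
         bhc_active = x$config$bhc_active,
         conservation_max_dev_hu = conservation)
}
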