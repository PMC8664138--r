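# Modality profiles and the per-material, per-beam, per-size HU model.
#
# Rendering is "effective-HU": each base material carries a (low, high) HU
# baseline per phantom size, each contrast material a (low, high) HU-per-
# (mg/ml) slope per size. The ratio slope_low/slope_high is the material's
# dual-energy ratio (DER) at that size; defaults are calibrated so the
# implied DERs equal the measured values for the TwinBeam (split-filter)
# and Dual Spiral (80/140 kVp) techniques.

# Measured DERs per modality, material and phantom size (head 20 cm disc,
# body 35 x 26 cm ellipse). These drive the default slope tables.
.der_reference <- function() {
  tibble(
    modality = rep(c("TwinBeam", "DualSpiral"), each = 4L),
    material = rep(rep(c("iodine", "calcium"), each = 2L), 2L),
    size     = rep(c("head", "body"), 4L),
    der      = c(1.40, 1.30, 1.19, 1.14,
                 1.97, 2.18, 1.52, 1.57)
  )
}

#' Modality profile for a dual-energy acquisition
#'
#' Describes which physical beams form the low- and high-energy channels and
#' how they are blended into the 120 kVp-equivalent mixed image.
#'
#' @param name `"DualSpiral"` (sequential 80/140 kVp spirals) or `"TwinBeam"`
#'   (gold/tin split-filter single 120 kVp beam).
#' @param mixed_weight Weight of the *low*-energy image in the mixed image,
#'   in `[0, 1]`. The mixed image is `w * low + (1 - w) * high`.
#' @return A list of class `dect_modality` with fields `name`, `low_label`,
#'   `high_label` and `mixed_weight`.
#' @examples
#' dect_modality("DualSpiral")
#' @export
dect_modality <- function(name = c("DualSpiral", "TwinBeam"),
                          mixed_weight = 0.5) {
  name <- match.arg(name)
  check_number(mixed_weight, "mixed_weight")
  if (mixed_weight < 0 || mixed_weight > 1) {
    stop_validation("`mixed_weight` must lie in [0, 1].")
  }
  labels <- switch(name,
    DualSpiral = c(low = "80 kVp", high = "140 kVp"),
    TwinBeam   = c(low = "AuBeam", high = "SnBeam")
  )
  structure(
    list(name = name, low_label = unname(labels["low"]),
         high_label = unname(labels["high"]), mixed_weight = mixed_weight),
    class = "dect_modality"
  )
}

#' @export
print.dect_modality <- function(x, ...) {
  cat(sprintf("<dect_modality> %s  low = %s, high = %s, mixed weight w = %g\n",
              x$name, x$low_label, x$high_label, x$mixed_weight))
  invisible(x)
}

#' Default material table for a modality
#'
#' One row per material, phantom size and role. Base materials carry
#' `(hu_low, hu_high)` baselines; contrast materials carry
#' `(slope_low, slope_high)` in HU per (mg/ml). Water is fixed at exactly
#' 0 HU in both beams and air renders at -1000 HU.
#'
#' Baselines are modality-specific because they encode the technique's
#' spectral separation. Dual Spiral (wide 80/140 kVp separation): water
#' (0, 0), fat (-110, -100), tissue (55, 50), CB2 (60, 50). TwinBeam
#' (narrow split-filter separation, HU pairs compressed toward equality):
#' water (0, 0), fat (-102, -100), tissue (51, 50), CB2 (57, 53). In both
#' tables water, tissue and fat are exactly collinear in (low, high) HU
#' space — so water sits on the tissue–fat basis line used for iodine —
#' and CB2's mixed value at w = 0.5 is the 55 HU calcium-free baseline.
#' Contrast slopes use a high-beam slope of 17 HU/(mg/ml) for iodine and
#' 2.6 HU/(mg/ml) for calcium; the low-beam slope is `DER * slope_high`
#' with the size- and modality-specific DER, so fitting low-vs-high
#' insert HU recovers the reference DERs exactly.
#'
#' @param modality A [dect_modality()] or a modality name.
#' @return A tibble with columns `material`, `role`, `size`, `hu_low`,
#'   `hu_high`, `slope_low`, `slope_high`.
#' @examples
#' default_material_table("DualSpiral")
#' @export
default_material_table <- function(modality = "DualSpiral") {
  if (inherits(modality, "dect_modality")) modality <- modality$name
  modality <- match.arg(modality, c("DualSpiral", "TwinBeam"))

  base <- tidyr::expand_grid(
    material = c("water", "fat", "tissue", "CB2"),
    size = c("head", "body")
  )
  base_hu <- switch(modality,
    DualSpiral = tibble(
      material = c("water", "fat", "tissue", "CB2"),
      hu_low   = c(0, -110, 55, 60),
      hu_high  = c(0, -100, 50, 50)
    ),
    TwinBeam = tibble(
      material = c("water", "fat", "tissue", "CB2"),
      hu_low   = c(0, -102, 51, 57),
      hu_high  = c(0, -100, 50, 53)
    )
  )
  base <- dplyr::left_join(base, base_hu, by = "material")
  base$role <- "base"
  base$slope_low <- NA_real_
  base$slope_high <- NA_real_

  ders <- dplyr::filter(.der_reference(), .data$modality == !!modality)
  contrast <- tibble(
    material = ders$material,
    size = ders$size,
    role = "contrast",
    hu_low = NA_real_,
    hu_high = NA_real_,
    slope_high = ifelse(ders$material == "iodine", 17, 2.6)
  )
  contrast$slope_low <- ders$der * contrast$slope_high

  dplyr::bind_rows(base, contrast)[
    , c("material", "role", "size", "hu_low", "hu_high",
        "slope_low", "slope_high")
  ]
}

# Lookup helpers -------------------------------------------------------------

material_row <- function(materials, material, size) {
  row <- dplyr::filter(materials, .data$material == !!material,
                       .data$size == !!size)
  if (nrow(row) != 1L) {
    stop_config(sprintf(
      "no unique material-table entry for material '%s' at size '%s'",
      material, size))
  }
  row
}

#' Implied dual-energy ratio of a contrast material
#'
#' The DER implied by a material table: `slope_low / slope_high` for the
#' given contrast material and phantom size.
#'
#' @param materials A material table, see [default_material_table()].
#' @param material Contrast material name (`"iodine"`, `"calcium"`).
#' @param size `"head"` or `"body"`.
#' @return A single number.
#' @export
implied_der <- function(materials, material, size) {
  row <- material_row(materials, material, size)
  if (!identical(row$role, "contrast")) {
    stop_config(sprintf("'%s' is not a contrast material", material))
  }
  d <- row$slope_low / row$slope_high
  if (!is.finite(d)) stop_config("implied DER is not finite")
  d
}

#' Basis-material HU pairs for decomposing a contrast material
#'
#' Returns the conventional basis pair: tissue/fat for iodine and fat/CB2
#' for calcium (the material makeup of the calcium inserts), as
#' `(low, high)` HU pairs read from the material table.
#'
#' @inheritParams implied_der
#' @return A list with elements `basis1`, `basis2` (numeric length-2,
#'   `(low, high)`) and `names`.
#' @export
basis_for_material <- function(materials, material, size = "head") {
  pair_names <- switch(material,
    iodine  = c("tissue", "fat"),
    calcium = c("fat", "CB2"),
    stop_config(sprintf("no default basis pair for material '%s'", material))
  )
  pairs <- lapply(pair_names, function(m) {
    row <- material_row(materials, m, size)
    c(row$hu_low, row$hu_high)
  })
  list(basis1 = pairs[[1L]], basis2 = pairs[[2L]], names = pair_names)
}
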