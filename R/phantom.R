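# Phantom geometry and anti-aliased rasterization.
#
# The phantom mimics a multi-energy CT phantom: a 20 cm circular "head"
# section or a 35 x 26 cm elliptical "body" section, with cylindrical
# inserts of concentration-graded contrast material placed on a ring in
# the inner (head-sized) portion. All user-facing positions are metric
# (cm in the phantom frame, origin at the phantom center); voxel indices
# never appear in specs.

#' Insert layout table
#'
#' Builds the default ring layout of cylindrical inserts: `length(conc)`
#' inserts of 2.8 cm diameter equally spaced on a 5 cm-radius ring.
#'
#' @param material Contrast material: `"iodine"` or `"calcium"`.
#' @param conc Concentrations in mg/ml. Defaults to the insert sets of the
#'   physical phantom: 2, 5, 10, 15 mg/ml iodine (on a water base) and 0,
#'   50, 100, 300 mg/ml calcium (on a CB2 epoxy base; the 0 mg/ml insert is
#'   the calcium-free CB2 reference).
#' @param ring_radius_cm,diameter_cm Ring radius and insert diameter (cm).
#' @return A tibble with columns `insert`, `x_cm`, `y_cm`, `diameter_cm`,
#'   `base_material`, `contrast_material`, `conc_mg_ml`.
#' @examples
#' default_inserts("iodine")
#' @export
default_inserts <- function(material = c("iodine", "calcium"),
                            conc = NULL,
                            ring_radius_cm = 5, diameter_cm = 2.8) {
  material <- match.arg(material)
  if (is.null(conc)) {
    conc <- switch(material,
      iodine = c(2, 5, 10, 15),
      calcium = c(0, 50, 100, 300)
    )
  }
  if (any(conc < 0)) stop_validation("concentrations must be >= 0")
  n <- length(conc)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  base <- switch(material, iodine = "water", calcium = "CB2")
  tibble(
    insert = sprintf("%s_%g", material, conc),
    x_cm = round(ring_radius_cm * cos(theta), 10),
    y_cm = round(ring_radius_cm * sin(theta), 10),
    diameter_cm = diameter_cm,
    base_material = base,
    contrast_material = ifelse(conc > 0, material, NA_character_),
    conc_mg_ml = as.numeric(conc)
  )
}

#' Phantom specification
#'
#' @param size `"head"` (circle) or `"body"` (ellipse).
#' @param inserts Insert table as produced by [default_inserts()]; may be
#'   empty (`NULL` gives an insert-free phantom).
#' @param diameter_cm Outer diameter: head default 20 cm; for the body this
#'   is the major axis, default 35 cm.
#' @param minor_axis_cm Body minor axis, default 26 cm (ignored for head).
#' @param pixel_spacing_mm In-plane voxel size, default 1 mm.
#' @param n_slices Number of axial slices, default 5.
#' @param slice_thickness_mm Slice thickness, default 3 mm (metadata).
#' @param margin_cm Air margin around the phantom in the rendered field of
#'   view, default 2 cm.
#' @return A list of class `phantom_spec`.
#' @examples
#' phantom_spec("head", default_inserts("iodine"))
#' @export
phantom_spec <- function(size = c("head", "body"), inserts = NULL,
                         diameter_cm = NULL, minor_axis_cm = 26,
                         pixel_spacing_mm = 1, n_slices = 5,
                         slice_thickness_mm = 3, margin_cm = 2) {
  size <- match.arg(size)
  diameter_cm <- diameter_cm %||% switch(size, head = 20, body = 35)
  check_number(diameter_cm, "diameter_cm", positive = TRUE)
  check_number(minor_axis_cm, "minor_axis_cm", positive = TRUE)
  check_number(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  check_number(slice_thickness_mm, "slice_thickness_mm", positive = TRUE)
  if (!is.numeric(n_slices) || n_slices < 1) {
    stop_validation("`n_slices` must be >= 1")
  }
  n_slices <- as.integer(n_slices)

  if (is.null(inserts)) {
    inserts <- default_inserts("iodine")[0, ]
  }
  inserts <- as_tibble(inserts)
  required <- c("insert", "x_cm", "y_cm", "diameter_cm",
                "base_material", "contrast_material", "conc_mg_ml")
  if (!all(required %in% names(inserts))) {
    stop_validation(paste0("insert table must have columns: ",
                           paste(required, collapse = ", ")))
  }
  if (nrow(inserts) > 0 && any(inserts$diameter_cm <= 0)) {
    stop_validation("insert diameters must be > 0")
  }
  if (nrow(inserts) > 0 && any(inserts$conc_mg_ml < 0)) {
    stop_validation("insert concentrations must be >= 0")
  }
  if (anyDuplicated(inserts$insert)) {
    stop_validation("insert ids must be unique")
  }

  # semi-axes of the outer shape (circle is the a == b case)
  a <- diameter_cm / 2
  b <- if (size == "head") a else minor_axis_cm / 2

  # inserts must lie strictly inside the outer shape
  for (i in seq_len(nrow(inserts))) {
    r <- inserts$diameter_cm[i] / 2
    th <- seq(0, 2 * pi, length.out = 73L)
    px <- inserts$x_cm[i] + r * cos(th)
    py <- inserts$y_cm[i] + r * sin(th)
    if (any((px / a)^2 + (py / b)^2 >= 1)) {
      stop_geometry(sprintf(
        "insert '%s' at (%g, %g) cm does not lie strictly inside the %s outline",
        inserts$insert[i], inserts$x_cm[i], inserts$y_cm[i], size))
    }
  }

  structure(
    list(size = size, semi_axis_x_cm = a, semi_axis_y_cm = b,
         inserts = inserts, pixel_spacing_mm = pixel_spacing_mm,
         n_slices = n_slices, slice_thickness_mm = slice_thickness_mm,
         margin_cm = margin_cm),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s: %g x %g cm, %d insert(s), %g mm px, %d slice(s)\n",
              x$size, 2 * x$semi_axis_x_cm, 2 * x$semi_axis_y_cm,
              nrow(x$inserts), x$pixel_spacing_mm, x$n_slices))
  invisible(x)
}

# in-plane voxel-center coordinates (cm), origin at phantom center
grid_coords <- function(n, spacing_mm) {
  (seq_len(n) - (n + 1) / 2) * spacing_mm / 10
}

phantom_grid <- function(spec) {
  dx <- spec$pixel_spacing_mm / 10  # cm
  half_x <- spec$semi_axis_x_cm + spec$margin_cm
  half_y <- spec$semi_axis_y_cm + spec$margin_cm
  nc <- 2L * ceiling(half_x / dx)
  nr <- 2L * ceiling(half_y / dx)
  list(nr = nr, nc = nc,
       x = grid_coords(nc, spec$pixel_spacing_mm),
       y = grid_coords(nr, spec$pixel_spacing_mm))
}

# mean over S x S sub-pixel blocks of a (nr*S) x (nc*S) matrix
block_mean <- function(m, s, nr, nc) {
  a <- array(m, dim = c(s, nr, s * nc))
  a <- colMeans(a)                      # nr x (s*nc)
  a <- array(a, dim = c(nr, s, nc))
  a <- colMeans(aperm(a, c(2L, 1L, 3L)))  # nr x nc
  a
}

#' Rasterize a phantom into per-region occupancy fractions
#'
#' Anti-aliased rasterization by area sampling: each pixel is divided into
#' `supersample^2` sub-pixels, each sub-pixel is assigned to exactly one
#' region (an insert where inserts overlap the body, otherwise the phantom
#' body, otherwise background air), and the per-region occupancy of a pixel
#' is the fraction of its sub-pixels in that region. Occupancies therefore
#' sum to exactly 1 in every pixel.
#'
#' @param spec A [phantom_spec()].
#' @param supersample Sub-pixel sampling factor per axis (>= 1), default 4.
#' @return A list of class `phantom_labels`: `occupancy` (array
#'   `nr x nc x n_regions`), `regions` (tibble describing each region),
#'   `spec`, and grid geometry.
#' @examples
#' labels <- build_phantom(phantom_spec("head", default_inserts("iodine")))
#' dim(labels$occupancy)
#' @export
build_phantom <- function(spec, supersample = 4) {
  if (!inherits(spec, "phantom_spec")) {
    stop_validation("`spec` must be a phantom_spec")
  }
  if (!is.numeric(supersample) || supersample < 1) {
    stop_validation("`supersample` must be >= 1")
  }
  s <- as.integer(supersample)
  g <- phantom_grid(spec)
  dx <- spec$pixel_spacing_mm / 10

  sub_off <- ((seq_len(s) - 0.5) / s - 0.5) * dx
  xs <- as.vector(outer(sub_off, g$x, `+`))  # length nc*s, col-major blocks
  ys <- as.vector(outer(sub_off, g$y, `+`))

  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))

  a <- spec$semi_axis_x_cm
  b <- spec$semi_axis_y_cm
  region <- matrix(0L, nrow = length(ys), ncol = length(xs))
  region[(X / a)^2 + (Y / b)^2 <= 1] <- 1L
  for (i in seq_len(nrow(spec$inserts))) {
    r <- spec$inserts$diameter_cm[i] / 2
    inside <- (X - spec$inserts$x_cm[i])^2 + (Y - spec$inserts$y_cm[i])^2 <= r^2
    region[inside] <- i + 1L
  }

  n_regions <- 2L + nrow(spec$inserts)
  occ <- array(0, dim = c(g$nr, g$nc, n_regions))
  for (k in seq_len(n_regions)) {
    occ[, , k] <- block_mean(region == (k - 1L), s, g$nr, g$nc)
  }

  regions <- dplyr::bind_rows(
    tibble(region = "background", kind = "background",
           base_material = NA_character_, contrast_material = NA_character_,
           conc_mg_ml = 0),
    tibble(region = "body", kind = "body", base_material = "water",
           contrast_material = NA_character_, conc_mg_ml = 0),
    tibble(region = spec$inserts$insert, kind = "insert",
           base_material = spec$inserts$base_material,
           contrast_material = spec$inserts$contrast_material,
           conc_mg_ml = spec$inserts$conc_mg_ml)
  )
  dimnames(occ)[[3]] <- regions$region

  structure(
    list(occupancy = occ, regions = regions, spec = spec,
         nr = g$nr, nc = g$nc, x_cm = g$x, y_cm = g$y,
         pixel_spacing_mm = spec$pixel_spacing_mm,
         n_slices = spec$n_slices, supersample = s),
    class = "phantom_labels"
  )
}

#' @export
print.phantom_labels <- function(x, ...) {
  cat(sprintf("<phantom_labels> %s phantom, %d x %d px (%g mm), %d region(s)\n",
              x$spec$size, x$nr, x$nc, x$pixel_spacing_mm,
              nrow(x$regions)))
  invisible(x)
}
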