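# The eight-workflow factorial: every combination of BHC active/inactive,
# head or body DER, and head or body phantom, for one modality and one
# contrast material. The DERs a workflow applies are re-estimated from the
# generated images themselves (generator -> estimator -> decomposition),
# so the factorial exercises the whole pipeline, and concentrations are
# calibrated with the size-matched BHC-off workflows (5 for head images,
# 8 for body images) — the "manual method".

#' Enumerate the workflow factorial
#'
#' @return A tibble with 8 rows: `workflow`, `bhc_active`, `der_source`,
#'   `phantom_size`. Workflows 1–4 have the BHC active and 5–8 inactive;
#'   within each block the (DER, phantom) pattern is (head, head),
#'   (head, body), (body, head), (body, body).
#' @examples
#' enumerate_workflows()
#' @export
enumerate_workflows <- function() {
  tibble(
    workflow = 1:8,
    bhc_active = rep(c(TRUE, FALSE), each = 4L),
    der_source = rep(c("head", "head", "body", "body"), 2L),
    phantom_size = rep(c("head", "body"), 4L)
  )
}

# VNC baseline on the mixed scale: what a perfect decomposition leaves
# inside the inserts (the insert base material's mixed HU)
vnc_baseline <- function(materials, material, w, size = "head") {
  base_name <- switch(material, iodine = "water", calcium = "CB2",
                      stop_config(sprintf("no baseline for '%s'", material)))
  row <- material_row(materials, base_name, size)
  w * row$hu_low + (1 - w) * row$hu_high
}

#' Run the eight-workflow factorial
#'
#' Generates head and body phantoms carrying the material's insert set,
#' renders the image pairs (noise-free by default), estimates the head and
#' body DERs from the rendered insert CT numbers, calibrates the emulated
#' BHC at the measured water-equivalent diameters of the two mixed images
#' (reference = head), decomposes each workflow, extracts ROI statistics,
#' converts enhancement means to concentrations with the workflow-5 (head
#' images) or workflow-8 (body images) calibration curve, and tabulates
#' VNC and concentration errors.
#'
#' @param modality Modality name or [dect_modality()].
#' @param material `"iodine"` or `"calcium"`.
#' @param tau Accuracy threshold in HU: a workflow is flagged accurate when
#'   its largest absolute VNC error across inserts is `<= tau`. Default 20.
#' @param noisy Add seeded acquisition noise? Default `FALSE`.
#' @param seed Seed for the noisy arms.
#' @param materials Material table.
#' @param inserts Insert table; defaults to [default_inserts()] for the
#'   material.
#' @param pixel_spacing_mm,n_slices,supersample Geometry settings.
#' @param roi_fraction,roi_slices ROI protocol (60% diameter, 5 slices).
#' @return An object of class `vnc_grid`. `tidy()` returns the per-insert
#'   table, `glance()` the per-workflow summary, [accurate_workflows()]
#'   the accurate set and `autoplot()` the concentration-error chart.
#' @export
run_grid <- function(modality = "DualSpiral",
                     material = c("iodine", "calcium"),
                     tau = 20, noisy = FALSE, seed = 1L,
                     materials = NULL, inserts = NULL,
                     pixel_spacing_mm = 1, n_slices = 5, supersample = 4,
                     roi_fraction = 0.60, roi_slices = n_slices) {
  if (!inherits(modality, "dect_modality")) modality <- dect_modality(modality)
  material <- match.arg(material)
  materials <- materials %||% default_material_table(modality$name)
  inserts <- inserts %||% default_inserts(material)
  w <- modality$mixed_weight

  sizes <- c("head", "body")
  pairs <- list()
  for (sz in sizes) {
    spec <- phantom_spec(sz, inserts, pixel_spacing_mm = pixel_spacing_mm,
                         n_slices = n_slices)
    acq <- acquisition_spec(modality, sz, seed = seed + match(sz, sizes))
    pair <- render_image_pair(build_phantom(spec, supersample), materials, acq)
    if (noisy) pair <- apply_noise(pair, acq)
    pairs[[sz]] <- pair
  }

  # measured DERs close the generator -> estimator loop
  der_fits <- lapply(pairs, function(p) {
    estimate_der(insert_hu_means(p, fraction = roi_fraction,
                                 n_slices = roi_slices))
  })
  ders <- c(head = der_fits$head$der, body = der_fits$body$der)

  # BHC anchored at the measured water-equivalent diameters of these images
  d_w <- vapply(pairs, function(p) {
    water_equivalent_diameter(make_mixed(p, w), p$meta$pixel_spacing_mm)
  }, numeric(1))
  bhc <- bhc_model(
    tibble(diameter_cm = unname(d_w[sizes]),
           der = c(implied_der(materials, "iodine", "head"),
                   implied_der(materials, "iodine", "body"))),
    reference_diameter_cm = unname(d_w["head"])
  )

  baseline <- vnc_baseline(materials, material, w)
  wfs <- enumerate_workflows()

  results <- list()
  decomps <- list()
  for (i in seq_len(nrow(wfs))) {
    wf <- wfs[i, ]
    cfg <- workflow_config(materials, material,
                           der = ders[[wf$der_source]],
                           bhc_active = wf$bhc_active, bhc = bhc,
                           mixed_weight = w)
    dec <- decompose(pairs[[wf$phantom_size]], cfg)
    decomps[[i]] <- dec
    vnc <- roi_stats(dec$vnc_mixed, inserts, pixel_spacing_mm,
                     fraction = roi_fraction, n_slices = roi_slices)
    enh <- roi_stats(dec$enhancement_mixed, inserts, pixel_spacing_mm,
                     fraction = roi_fraction, n_slices = roi_slices)
    results[[i]] <- tibble(
      workflow = wf$workflow, bhc_active = wf$bhc_active,
      der_source = wf$der_source, phantom_size = wf$phantom_size,
      applied_der = dec$applied_der,
      water_equiv_diameter_cm = dec$water_equiv_diameter_cm,
      insert = vnc$insert, conc_mg_ml = inserts$conc_mg_ml,
      vnc_mean = vnc$mean, vnc_sd = vnc$sd, enh_mean = enh$mean,
      vnc_error = vnc$mean - baseline
    )
  }
  results <- dplyr::bind_rows(results)

  # manual-method calibration: workflow 5 for head images, 8 for body
  curves <- lapply(c(head = 5L, body = 8L), function(src) {
    d <- dplyr::filter(results, .data$workflow == src)
    fit_calibration(tibble(conc_mg_ml = d$conc_mg_ml, enh_hu = d$enh_mean),
                    size_label = if (src == 5L) "head" else "body",
                    material = material, modality = modality$name,
                    source_workflow = src)
  })
  results$conc_est <- purrr::map2_dbl(
    results$phantom_size, results$enh_mean,
    function(sz, e) concentration_from_enhancement(curves[[sz]], e))
  results$conc_error <- results$conc_est - results$conc_mg_ml

  summary <- results |>
    dplyr::group_by(.data$workflow, .data$bhc_active, .data$der_source,
                    .data$phantom_size, .data$applied_der) |>
    dplyr::summarise(
      largest_error_hu = .data$vnc_error[which.max(abs(.data$vnc_error))],
      largest_conc_error = .data$conc_error[which.max(abs(.data$conc_error))],
      .groups = "drop") |>
    dplyr::mutate(accurate = abs(.data$largest_error_hu) <= tau)

  # central slices retained for montage rendering
  mid <- (dim(pairs$head$low)[3] + 1L) %/% 2L
  montage <- list(
    mixed = lapply(pairs, function(p) make_mixed(p, w)[, , mid]),
    vnc = lapply(decomps, function(d) d$vnc_mixed[, , mid]),
    enhancement = lapply(decomps, function(d) d$enhancement_mixed[, , mid])
  )

  structure(
    list(results = results, summary = summary, tau = tau,
         modality = modality$name, material = material,
         baseline_hu = baseline, ders = ders, der_fits = der_fits,
         calibrations = curves, bhc = bhc,
         water_equiv_diameters = d_w, noisy = noisy,
         inserts = inserts, montage = montage,
         pixel_spacing_mm = pixel_spacing_mm),
    class = "vnc_grid"
  )
}

#' @export
print.vnc_grid <- function(x, ...) {
  cat(sprintf(
    "<vnc_grid> %s %s, %s: baseline %.1f HU, tau = %g HU\n",
    x$modality, x$material, if (x$noisy) "noisy" else "noise-free",
    x$baseline_hu, x$tau))
  cat(sprintf("  measured DERs: head %.4f, body %.4f\n",
              x$ders[["head"]], x$ders[["body"]]))
  cat(sprintf("  accurate workflows: {%s}\n",
              paste(accurate_workflows(x), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Accurate workflows of a factorial run
#'
#' @param grid A [run_grid()] result.
#' @param tau Optional threshold overriding the grid's; accuracy means the
#'   largest absolute VNC error across inserts is `<= tau` HU.
#' @return Sorted integer vector of workflow ids.
#' @export
accurate_workflows <- function(grid, tau = grid$tau) {
  if (!inherits(grid, "vnc_grid")) stop_validation("`grid` must be a vnc_grid")
  sort(grid$summary$workflow[abs(grid$summary$largest_error_hu) <= tau])
}
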