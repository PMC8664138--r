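# Report bundle for a factorial run: CSV tables keyed like the published
# per-insert VNC tables, the concentration-error chart data, and a montage
# figure (mixed image plus VNC/enhancement with the BHC active vs
# inactive on the body phantom).

#' Write the report bundle for a factorial run
#'
#' Writes `workflow_table.csv` (one row per workflow x insert),
#' `workflow_summary.csv` (largest errors and accuracy flags),
#' `concentration_errors.csv` (the bar-chart data) and, optionally,
#' `montage.png`.
#'
#' @param grid A [run_grid()] result.
#' @param dir Output directory (created if missing).
#' @param montage Write the montage figure? Default `TRUE`.
#' @return Invisibly, a character vector of the files written.
#' @export
render_report <- function(grid, dir, montage = TRUE) {
  if (!inherits(grid, "vnc_grid")) stop_validation("`grid` must be a vnc_grid")
  if (nrow(grid$results) == 0L) stop_report("empty results: nothing to report")
  expected <- nrow(enumerate_workflows()) * nrow(grid$inserts)
  if (nrow(grid$results) < expected ||
      length(unique(grid$results$workflow)) < 8L) {
    stop_report(sprintf(
      "partial grid: %d of %d workflow x insert rows present",
      nrow(grid$results), expected))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "workflow_table.csv"),
    summary = file.path(dir, "workflow_summary.csv"),
    errors = file.path(dir, "concentration_errors.csv")
  )
  utils::write.csv(grid$results, paths["table"], row.names = FALSE)
  utils::write.csv(grid$summary, paths["summary"], row.names = FALSE)
  errors <- grid$results[, c("workflow", "insert", "conc_mg_ml",
                             "conc_est", "conc_error")]
  utils::write.csv(errors, paths["errors"], row.names = FALSE)

  if (montage) {
    p <- plot_montage(grid)
    path <- file.path(dir, "montage.png")
    ok <- tryCatch({
      grDevices::png(path, width = 1500, height = 1000, res = 150)
      print(p)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warn(paste0("montage rendering failed: ", conditionMessage(e)))
      FALSE
    })
    if (ok) paths <- c(paths, montage = path)
  }
  invisible(paths)
}

#' Montage figure: mixed, VNC and enhancement with and without the BHC
#'
#' Central-slice panels of the body phantom, mirroring the published
#' figure: the mixed 120 kVp-equivalent image, then the VNC and
#' enhancement images of the body-DER workflows with the BHC active
#' (workflow 4) and inactive (workflow 8).
#'
#' @param grid A [run_grid()] result.
#' @param workflows Two workflow ids to contrast, default `c(4, 8)`.
#' @return A ggplot object.
#' @export
plot_montage <- function(grid, workflows = c(4L, 8L)) {
  if (!inherits(grid, "vnc_grid")) stop_validation("`grid` must be a vnc_grid")
  wfs <- enumerate_workflows()
  panel_df <- function(mat, label) {
    tibble(
      row = rep(seq_len(nrow(mat)), times = ncol(mat)),
      col = rep(seq_len(ncol(mat)), each = nrow(mat)),
      hu = as.vector(mat), panel = label
    )
  }
  panels <- list(panel_df(grid$montage$mixed$body, "mixed"))
  for (id in workflows) {
    tag <- if (wfs$bhc_active[id]) "BHC active" else "BHC inactive"
    panels <- c(panels, list(
      panel_df(grid$montage$vnc[[id]], sprintf("VNC wf%d (%s)", id, tag)),
      panel_df(grid$montage$enhancement[[id]],
               sprintf("enhancement wf%d (%s)", id, tag))
    ))
  }
  df <- dplyr::bind_rows(panels)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-100, 750),
                                 oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(fill = "HU", x = NULL, y = NULL,
                  title = sprintf("%s %s: size correction on vs off",
                                  grid$modality, grid$material)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right",
                   plot.title = ggplot2::element_text(hjust = 0.5))
}

# window/level clamp without depending on the scales namespace directly
scales_squish <- function(x, range = c(0, 1), ...) {
  x[x < range[1]] <- range[1]
  x[x > range[2]] <- range[2]
  x
}

#' Read back a workflow table written by [render_report()]
#'
#' @param dir Report directory.
#' @return The per-insert results tibble.
#' @export
read_report_table <- function(dir) {
  path <- file.path(dir, "workflow_table.csv")
  if (!file.exists(path)) stop_format(sprintf("missing report table '%s'", path))
  as_tibble(utils::read.csv(path))
}
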