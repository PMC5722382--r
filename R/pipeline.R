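# End-to-end pipeline: segment -> trace -> classify -> junctions ->
# concatenate -> elliptic Fourier description.

#' Pipeline configuration
#'
#' @param close_radius Disk radius of the binary close applied to the
#'   inverted T1 mask (removes thin venation traces); 0 disables.
#' @param min_area Minimum traced region area (px^2).
#' @param d_adj Junction adjacency distance (px).
#' @param min_sep Minimum vertex separation between junctions of a pair.
#' @param efa_n Number of elliptic Fourier harmonics to export.
#' @param panel If TRUE, also build the 3 x 3 perturbed-threshold panel.
#' @param t1,t2 Optional threshold overrides; NULL = automatic.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(close_radius = 2, min_area = 16, d_adj = 2,
                            min_sep = 10L, efa_n = 20L, panel = FALSE,
                            t1 = NULL, t2 = NULL) {
  structure(list(close_radius = close_radius, min_area = min_area,
                 d_adj = d_adj, min_sep = min_sep, efa_n = as.integer(efa_n),
                 panel = isTRUE(panel), t1 = t1, t2 = t2),
            class = "pipeline_config")
}

#' Run the full leaf-contour pipeline
#'
#' Thresholds the image (maximum entropy for T1, intermeans for T2),
#' builds the XOR composite, traces and classifies all interior regions,
#' localizes cross and touch points, concatenates everything into one
#' closed self-intersecting contour and computes its elliptic Fourier
#' coefficients. When \code{out_dir} is given, writes the final contour as
#' an XY coordinate file, the coefficients as CSV and a JSON report.
#'
#' @param image A \code{gray_image}, a matrix, or a path to a PNG/TIFF.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list: \code{contour} (final ring), \code{efa},
#'   \code{report} (thresholds, per-stage contour counts, junction table,
#'   per-merge ledger), \code{set} (classified contours), \code{masks},
#'   \code{composite} and optionally \code{panel}.
#' @export
run_pipeline <- function(image, config = pipeline_config(), out_dir = NULL) {
  img <- if (is.character(image)) read_gray(image) else as_gray_image(image)
  t1 <- if (is.null(config$t1)) max_entropy_threshold(img) else config$t1
  t2 <- if (is.null(config$t2)) default_threshold(img) else config$t2
  # Leaves without overlapping lobes need only the single bimodal
  # threshold: there the maximum-entropy threshold has no small dark
  # doubled-tissue class to isolate (it lands on the blade/background
  # split too) and the XOR composite is degenerate. Overlaps are present
  # when the dark class is a small pixel fraction well below the bimodal
  # threshold.
  dark_frac <- mean(unclass(img) <= t1)
  dual <- t1 < t2 && (t2 - t1) >= 16 && dark_frac <= 0.2
  masks <- make_masks(img, t1, t2)
  if (config$close_radius > 0)
    masks$t1_inverted <- binary_close(masks$t1_inverted, config$close_radius)
  composite <- if (dual) {
    xor_compose(masks$t1_inverted, masks$t2)
  } else {
    masks$t2
  }
  panel <- if (config$panel) threshold_panel(img, t1, t2) else NULL

  set <- trace_contours(composite, config$min_area)
  set <- classify_regions(set, masks$t1_inverted)
  junctions <- find_junctions(set, config$d_adj, config$min_sep)
  final <- concatenate_all(set, junctions)
  coeffs <- efa_forward(final, config$efa_n)

  ledger <- attr(final, "merge_ledger")
  report <- list(
    thresholds = list(t1 = t1, t2 = t2),
    mode = if (dual) "dual" else "single",
    contour_count = length(set$contours),
    region_classes = vapply(set$contours, `[[`, character(1), "region_class"),
    junctions = junctions_df(junctions),
    merge_ledger = ledger,
    merges = nrow(ledger),
    final_vertices = nrow(final$xy),
    perimeter = coeffs$perimeter
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_xy(final, file.path(out_dir, "leaf.xy"))
    write_efa_csv(coeffs, file.path(out_dir, "efa.csv"))
    jsonlite::write_json(
      list(thresholds = report$thresholds,
           contour_count = report$contour_count,
           region_classes = unname(report$region_classes),
           junctions = report$junctions,
           merge_ledger = report$merge_ledger),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(panel)) {
      for (e in panel$entries)
        write_gray(e$composite,
                   file.path(out_dir, sprintf("xor_f1-%.2f_f2-%.2f.png", e$f1, e$f2)))
      jsonlite::write_json(list(t1 = t1, t2 = t2),
                           file.path(out_dir, "panel_thresholds.json"),
                           auto_unbox = TRUE)
    }
  }

  invisible(list(contour = final, efa = coeffs, report = report, set = set,
                 masks = masks, composite = composite, panel = panel))
}
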