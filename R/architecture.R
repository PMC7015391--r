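# Architecture parameters: pennation angle (sum of the fascicle and
# deep-aponeurosis inclinations), fascicle length (straight composite
# fascicle between the aponeuroses at the dominant orientation) and
# muscle thickness (mean inter-aponeurosis distance), plus the
# end-to-end single-image analysis that chains the four stages.

#' Pennation angle from the component inclinations
#'
#' Pennation is the angle between the composite fascicle and the deep
#' aponeurosis, computed as the sum `beta + alpha` of the fascicle
#' inclination (positive rising toward the left) and the deep
#' aponeurosis inclination (positive descending toward the left). The
#' sum is asserted against the dot-product angle between the two
#' direction vectors (they agree identically under these conventions).
#'
#' @param fascicle_angle_deg fascicle inclination beta.
#' @param deep_apo_angle_deg deep aponeurosis inclination alpha.
#' @return pennation angle in degrees.
#' @export
pennation_angle <- function(fascicle_angle_deg, deep_apo_angle_deg) {
  theta <- fascicle_angle_deg + deep_apo_angle_deg
  # cross-check against explicit direction vectors (y down)
  vf <- c(1, tan(fascicle_angle_deg * pi / 180))
  va <- c(1, -tan(deep_apo_angle_deg * pi / 180))
  geom <- abs(atan2(vf[2], vf[1]) - atan2(va[2], va[1])) * 180 / pi
  stopifnot(abs(abs(theta) - geom) < 1e-9)
  theta
}

#' Composite fascicle length between the aponeuroses
#'
#' Constructs a straight line through `anchor_x` on the deep aponeurosis
#' at the dominant fascicle inclination and intersects it with the
#' superficial aponeurosis: the detected edge where the intersection
#' falls inside its support, otherwise the extrapolated fitted line
#' (flagged). Length is the Euclidean distance between the two
#' insertion points.
#'
#' @param sup_path,deep_path [apo_path()]s with fitted lines.
#' @param fascicle_angle_deg dominant fascicle inclination beta.
#' @param anchor_x x of the anchor on the deep aponeurosis (default:
#'   midpoint of its detected extent).
#' @return list `length_px`, `extrapolated`, `anchor` (x, y),
#'   `insertion` (x, y).
#' @export
fascicle_length <- function(sup_path, deep_path, fascicle_angle_deg,
                            anchor_x = NULL) {
  stopifnot(inherits(sup_path, "apo_path"), inherits(deep_path, "apo_path"))
  if (is.null(anchor_x)) anchor_x <- mean(deep_path$x_extent)
  theta <- pennation_angle(fascicle_angle_deg, deep_path$line_angle_deg)
  assert_that(abs(theta) > 0.5, "validation",
              "fascicle_length: pennation below 0.5 degrees; intersection degenerate")
  mf <- tan(fascicle_angle_deg * pi / 180)
  ms <- line_slope(sup_path)
  if (abs(mf - ms) < 1e-9) {
    stop_sma("no_intersection",
             "composite fascicle is parallel to the superficial aponeurosis")
  }
  ya <- extrapolate(deep_path, anchor_x)
  s0 <- sup_path$line_intercept_px
  xi <- (ya - mf * anchor_x - s0) / (ms - mf)
  extrapolated <- xi < sup_path$x_extent[1] || xi > sup_path$x_extent[2]
  yi <- if (extrapolated) s0 + ms * xi else {
    # refine against the detected edge near the line intersection
    yi2 <- extrapolate(sup_path, xi)
    yi2
  }
  list(length_px = sqrt((xi - anchor_x)^2 + (yi - ya)^2),
       extrapolated = extrapolated,
       anchor = c(x = anchor_x, y = ya),
       insertion = c(x = xi, y = yi))
}

#' Muscle thickness as the mean inter-aponeurosis distance
#'
#' Mean per-column vertical distance between the detected superficial
#' and deep paths over their shared x-range.
#'
#' @param sup_path,deep_path [apo_path()]s.
#' @return thickness in pixels.
#' @export
muscle_thickness <- function(sup_path, deep_path) {
  x0 <- max(sup_path$x_extent[1], deep_path$x_extent[1])
  x1 <- min(sup_path$x_extent[2], deep_path$x_extent[2])
  assert_that(x1 > x0, "validation",
              "muscle_thickness: aponeurosis paths share no x support")
  xs <- seq(x0, x1)
  mean(extrapolate(deep_path, xs) - extrapolate(sup_path, xs))
}

#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline with the standard
#' defaults.
#'
#' @param flip flip the image horizontally before analysis (for scans
#'   acquired with the proximal side on the right).
#' @param crop `"auto"` (detect the field of view), `"manual"` (use
#'   `crop_rect`) or `"none"`.
#' @param crop_rect [fov_rect()] for manual cropping.
#' @param tubeness_sigma_apo tubeness scale for aponeurosis detection
#'   (default 10).
#' @param n_rois,roi_width_pct,roi_height_pct ROI layout, see
#'   [define_rois()].
#' @param spectrum_threshold `"auto"` or a fraction in (0, 1].
#' @param orientation_sigma structure-tensor window (default 4).
#' @param tubeness_sigma_fascicle fascicle-scale ridge enhancement.
#' @param aggregate `"greatest"`, `"mean"` or `"median"`.
#' @param coherency_floor ROIs below this coherency are dropped before
#'   aggregation.
#' @param mm_per_px optional calibration overriding the image's own.
#' @param anchor_x optional fascicle anchor override (field-of-view x).
#' @param print_params echo all parameters into the results row.
#' @return list of class `sma_config`.
#' @export
sma_config <- function(flip = FALSE, crop = c("auto", "manual", "none"),
                       crop_rect = NULL, tubeness_sigma_apo = 10,
                       n_rois = 3L, roi_width_pct = 60,
                       roi_height_pct = 90, spectrum_threshold = "auto",
                       orientation_sigma = 4,
                       tubeness_sigma_fascicle = 2,
                       aggregate = c("median", "greatest", "mean"),
                       coherency_floor = 0.05, mm_per_px = NULL,
                       anchor_x = NULL, print_params = FALSE) {
  crop <- match.arg(crop)
  aggregate <- match.arg(aggregate)
  if (crop == "manual") {
    assert_that(inherits(crop_rect, "fov_rect"), "validation",
                "sma_config: manual cropping requires crop_rect")
  }
  structure(list(flip = isTRUE(flip), crop = crop, crop_rect = crop_rect,
                 tubeness_sigma_apo = tubeness_sigma_apo,
                 n_rois = as.integer(n_rois),
                 roi_width_pct = roi_width_pct,
                 roi_height_pct = roi_height_pct,
                 spectrum_threshold = spectrum_threshold,
                 orientation_sigma = orientation_sigma,
                 tubeness_sigma_fascicle = tubeness_sigma_fascicle,
                 aggregate = aggregate,
                 coherency_floor = coherency_floor,
                 mm_per_px = mm_per_px, anchor_x = anchor_x,
                 print_params = isTRUE(print_params)),
            class = "sma_config")
}

#' Analyse a single ultrasound image
#'
#' Runs the four pipeline stages in order -- field-of-view detection,
#' aponeurosis segmentation, dominant fascicle orientation, architecture
#' computation -- and returns the architecture parameters. The analysis
#' contains no randomness, so repeated calls on the same input yield
#' identical results.
#'
#' @param image grayscale image ([us_image()] or matrix in \[0,1\]).
#' @param config an [sma_config()].
#' @return object of class `architecture_result` with fields
#'   `pennation_deg`, `fascicle_length_px`, `thickness_px` (and `_mm`
#'   variants when calibrated), `fascicle_angle_deg`,
#'   `deep_apo_angle_deg`, `extrapolated`, `per_roi` (data frame of
#'   per-ROI angles and coherencies), `fov`, `paths`, `rois`, `config`.
#' @export
analyse_image <- function(image, config = sma_config()) {
  stopifnot(inherits(config, "sma_config"))
  m <- clamp01(as_raster(image))
  if (config$flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]

  rect <- switch(config$crop,
    auto = tryCatch(detect_fov(m), sma_fov_not_found = function(e) {
      stop_sma("fov_not_found", paste0("[fov] ", conditionMessage(e)))
    }),
    manual = config$crop_rect,
    none = fov_rect(0, 0, ncol(m), nrow(m)))
  fov <- as_raster(crop(m, rect))

  paths <- withCallingHandlers(
    detect_aponeuroses(fov,
                       tubeness_sigma = config$tubeness_sigma_apo,
                       spectrum_threshold = config$spectrum_threshold),
    sma_apo_not_found = function(e) {
      stop_sma("apo_not_found", paste0("[aponeurosis] ", conditionMessage(e)))
    })

  rois <- define_rois(dim(fov), paths$superficial, paths$deep,
                      n_rois = config$n_rois,
                      roi_width_pct = config$roi_width_pct,
                      roi_height_pct = config$roi_height_pct)
  per_roi <- lapply(rois, function(r) {
    sub <- as_raster(crop(fov, r))
    dominant_orientation(sub, sigma = config$orientation_sigma,
                         spectrum_threshold = config$spectrum_threshold,
                         tubeness_sigma_fascicle = config$tubeness_sigma_fascicle,
                         roi_rect = r)
  })
  roi_tab <- data.frame(
    roi = seq_along(per_roi),
    dominant_angle_deg = vapply(per_roi, `[[`, numeric(1), "dominant_angle_deg"),
    coherency = vapply(per_roi, `[[`, numeric(1), "coherency"),
    valid = vapply(per_roi, `[[`, logical(1), "valid"))
  usable <- roi_tab$valid & roi_tab$coherency >= config$coherency_floor
  if (!any(usable)) {
    stop_sma("no_fascicle_orientation",
             "[orientation] no ROI produced a usable fascicle orientation")
  }
  beta <- aggregate_angles(roi_tab$dominant_angle_deg[usable],
                           config$aggregate)

  alpha <- paths$deep$line_angle_deg
  theta <- pennation_angle(beta, alpha)
  fl <- fascicle_length(paths$superficial, paths$deep, beta,
                        anchor_x = config$anchor_x)
  th <- muscle_thickness(paths$superficial, paths$deep)
  stopifnot(fl$length_px >= th - 1e-6)   # chord can never beat the gap

  cal <- if (!is.null(config$mm_per_px)) config$mm_per_px else
    mm_per_px_of(image)
  res <- list(pennation_deg = theta,
              fascicle_angle_deg = beta,
              deep_apo_angle_deg = alpha,
              sup_apo_angle_deg = paths$superficial$line_angle_deg,
              fascicle_length_px = fl$length_px,
              thickness_px = th,
              fascicle_length_mm = if (!is.null(cal)) fl$length_px * cal,
              thickness_mm = if (!is.null(cal)) th * cal,
              extrapolated = fl$extrapolated,
              aggregate_method = config$aggregate,
              per_roi = roi_tab,
              fov = rect, paths = paths, rois = rois,
              fascicle_line = fl, mm_per_px = cal,
              config = config)
  class(res) <- "architecture_result"
  res
}

#' @export
print.architecture_result <- function(x, ...) {
  cat("Muscle architecture analysis\n")
  cat(sprintf("  pennation angle : %.2f deg%s\n", x$pennation_deg,
              if (x$extrapolated) "  (aponeurosis extrapolated)" else ""))
  cat(sprintf("  fascicle length : %.1f px%s\n", x$fascicle_length_px,
              if (!is.null(x$fascicle_length_mm))
                sprintf(" (%.2f mm)", x$fascicle_length_mm) else ""))
  cat(sprintf("  muscle thickness: %.1f px%s\n", x$thickness_px,
              if (!is.null(x$thickness_mm))
                sprintf(" (%.2f mm)", x$thickness_mm) else ""))
  cat(sprintf("  fascicle angle %.2f deg, deep aponeurosis %.2f deg (%s of %d ROIs)\n",
              x$fascicle_angle_deg, x$deep_apo_angle_deg,
              x$aggregate_method, nrow(x$per_roi)))
  invisible(x)
}

# One flat results-table row for an architecture_result.
result_row <- function(res, file = NA_character_, print_params = FALSE) {
  row <- data.frame(
    file = file,
    pennation_deg = res$pennation_deg,
    fascicle_length_px = res$fascicle_length_px,
    fascicle_length_mm = if (is.null(res$fascicle_length_mm)) NA_real_ else
      res$fascicle_length_mm,
    thickness_px = res$thickness_px,
    thickness_mm = if (is.null(res$thickness_mm)) NA_real_ else
      res$thickness_mm,
    extrapolated = res$extrapolated,
    fascicle_angle_deg = res$fascicle_angle_deg,
    deep_apo_angle_deg = res$deep_apo_angle_deg,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res$per_roi))) {
    row[[paste0("coherency_roi", i)]] <- res$per_roi$coherency[i]
  }
  if (print_params) {
    cfg <- res$config
    row$tubeness_sigma_apo <- cfg$tubeness_sigma_apo
    row$orientation_sigma <- cfg$orientation_sigma
    row$n_rois <- cfg$n_rois
    row$roi_width_pct <- cfg$roi_width_pct
    row$roi_height_pct <- cfg$roi_height_pct
    row$spectrum_threshold <- as.character(cfg$spectrum_threshold)
    row$aggregate <- cfg$aggregate
    row$flip <- cfg$flip
  }
  row
}
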