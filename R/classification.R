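# The two-part decision algorithm for subchondral bone changes after
# microfracture, plus threshold sensitivity sweeps.
#
# Part one: if no slice of the defect deviates from the projected cement
# line beyond tolerance, the defect is completely reconstituted.
# Part two, per slice: bone protruding above the line is an intra-lesional
# osteophyte; a persistent bridge (Vd2 < 0.5 Vd1) splits the section into
# two holes; each hole is then classified from its horizontal diameters
# against multiples of the awl diameter, cyst rule first.

#' Decision thresholds
#'
#' The decision constants of the classification algorithm, made explicit
#' and sweepable.
#'
#' @param bridge_fraction Fraction of Vd1 below which a bridge top counts
#'   as persistent (two holes); default 0.5.
#' @param hd1_multiplier Awl-diameter multiple separating a residual hole
#'   from peri-hole resorption; default 2.
#' @param hd2_multiplier Awl-diameter multiple defining a subchondral
#'   cyst; default 3.
#' @param reconstitution_tolerance_mm Surface deviation (either side of
#'   the cement line) tolerated as complete reconstitution; also the
#'   defect-detection threshold.  Default 0.1 mm.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(bridge_fraction = 0.5,
                             hd1_multiplier = 2,
                             hd2_multiplier = 3,
                             reconstitution_tolerance_mm = 0.1) {
  check_pos(bridge_fraction, "bridge_fraction")
  check_pos(hd1_multiplier, "hd1_multiplier")
  check_pos(hd2_multiplier, "hd2_multiplier")
  check_pos(reconstitution_tolerance_mm, "reconstitution_tolerance_mm")
  structure(list(bridge_fraction = bridge_fraction,
                 hd1_multiplier = hd1_multiplier,
                 hd2_multiplier = hd2_multiplier,
                 reconstitution_tolerance_mm = reconstitution_tolerance_mm),
            class = "threshold_config")
}

#' The five outcome classes
#'
#' @return Character vector of the five possible outcomes, cavity classes
#'   ordered by severity (residual hole < resorption < cyst).
#' @export
lesion_classes <- function() {
  c("complete_reconstitution", "intra_lesional_osteophyte",
    "residual_hole", "peri_hole_resorption", "subchondral_cyst")
}

cavity_severity <- c(residual_hole = 1L, peri_hole_resorption = 2L,
                     subchondral_cyst = 3L)

#' Complete-reconstitution check
#'
#' A defect is completely reconstituted when on every slice no surface
#' deviation from the projected cement line exceeds the tolerance — i.e.
#' [detect_defect_region()] found nothing (no cavity below, no overgrowth
#' above).  A deviation exactly at tolerance still counts as
#' reconstituted (strictly greater triggers a defect).
#'
#' @param regions A single [detect_defect_region()] result or a list of
#'   them (one per slice); `NULL` entries mean no deviation.
#' @return `TRUE` iff every slice shows no defect region.
#' @export
check_reconstitution <- function(regions) {
  if (inherits(regions, "defect_region")) return(FALSE)
  if (is.null(regions)) return(TRUE)
  all(vapply(regions, is.null, logical(1)))
}

#' Osteophyte call
#'
#' An intra-lesional osteophyte is present iff bone within the defect
#' rises strictly above the projected cement line: a bridge apex above
#' the line, or any measured overgrowth component.  An apex exactly on
#' the line does not qualify (strict protrusion required).
#'
#' @param bridge A [detect_bridge()] result, or `NULL`.
#' @param osteophyte A [measure_osteophyte()] result, or `NULL`.
#' @return Logical.
#' @export
classify_osteophyte <- function(bridge = NULL, osteophyte = NULL) {
  if (!is.null(bridge) && isTRUE(bridge$present) && bridge$apex_depth_mm < 0)
    return(TRUE)
  !is.null(osteophyte) && NROW(osteophyte) > 0L
}

#' One hole or two: the relative bridge height rule
#'
#' A persistent bone bridge (top strictly below half the defect depth,
#' `Vd2 < bridge_fraction * Vd1`) separates two microfracture holes.  A
#' higher bridge top (`Vd2 >= bridge_fraction * Vd1`) is read as erosion
#' relief around a single hole.  No bridge at all is a single hole.
#' Equality falls to the single-hole reading and is logged.
#'
#' @param vd1_mm Vertical distance from the cement line to the base of
#'   the defect (mm), positive.
#' @param vd2_mm Vertical distance to the bridge top (mm), or `NULL` when
#'   there is no bridge.
#' @param cfg A [threshold_config()].
#' @return `1L` or `2L`.
#' @export
count_holes <- function(vd1_mm, vd2_mm = NULL, cfg = threshold_config()) {
  check_pos(vd1_mm, "vd1_mm")
  if (is.null(vd2_mm)) return(1L)
  if (!is_num1(vd2_mm) || vd2_mm < 0) stopf("`vd2_mm` must be a number >= 0")
  if (vd2_mm > vd1_mm)
    stopf("vd2_mm (%g) > vd1_mm (%g): a bridge top below the defect base is geometrically impossible",
          vd2_mm, vd1_mm)
  # strict inequality with a relative floating-point guard (see classify_lesion)
  if (vd2_mm < cfg$bridge_fraction * vd1_mm * (1 - 1e-9)) 2L else 1L
}

#' Classify one cavity from its horizontal diameters
#'
#' Cyst rule first: `Hd2 > hd2_multiplier * awl diameter` is a
#' subchondral bone cyst regardless of Hd1.  Otherwise
#' `Hd1 > hd1_multiplier * awl diameter` is peri-hole bone resorption,
#' and anything else a residual microfracture hole.  Pathology requires
#' the strict inequality; values exactly at a threshold fall to the
#' milder class.  Vectorized over `hd1_mm`/`hd2_mm`.
#'
#' @param hd1_mm Opening diameter(s) at cement-line level, mm.
#' @param hd2_mm Diameter(s) at half the awl penetration depth, mm.
#' @param awl An [awl_spec()].
#' @param cfg A [threshold_config()].
#' @return Character vector of cavity classes.
#' @export
classify_lesion <- function(hd1_mm, hd2_mm, awl = awl_spec(),
                            cfg = threshold_config()) {
  stopifnot(inherits(awl, "awl_spec"))
  if (!is.numeric(hd1_mm) || !is.numeric(hd2_mm) ||
      length(hd1_mm) != length(hd2_mm))
    stopf("`hd1_mm` and `hd2_mm` must be numeric vectors of equal length")
  if (any(hd1_mm < 0) || any(hd2_mm < 0) || anyNA(hd1_mm) || anyNA(hd2_mm))
    stopf("horizontal diameters must be non-negative and non-missing")
  d <- awl$diameter_mm
  # strict mathematical inequality: a value equal to the threshold up to
  # floating-point rounding (relative 1e-9, far below pixel resolution)
  # must not fire the rule, e.g. 3.6 vs 3 * 1.2
  ifelse(hd2_mm > cfg$hd2_multiplier * d * (1 + 1e-9), "subchondral_cyst",
         ifelse(hd1_mm > cfg$hd1_multiplier * d * (1 + 1e-9),
                "peri_hole_resorption", "residual_hole"))
}

# Construct a sub-region of a defect region (for recursive hole splitting).
subregion <- function(region, s, e) {
  r <- region
  r$col_range <- c(s, e)
  r$x_left_mm <- (s - 1L) * region$pixel_size_mm
  r$x_right_mm <- e * region$pixel_size_mm
  r
}

# Recursively locate persistent-bridge split points within a region.
# Returns the apex x positions (mm), sorted.
find_splits <- function(mask, line, region, cfg, min_relief_mm) {
  if (diff(region$col_range) < 10L) return(numeric(0))
  br <- detect_bridge(mask, line, region, min_relief_mm)
  if (!br$present) return(numeric(0))
  vert <- measure_vertical(mask, line, region, br,
                           x_range = c(region$x_left_mm, region$x_right_mm))
  if (vert$vd1_mm <= 0) return(numeric(0))
  if (count_holes(vert$vd1_mm, vert$vd2_mm, cfg) != 2L) return(numeric(0))
  # each candidate sub-hole must be a cavity in its own right: its floor
  # must lie at least twice the surface tolerance below the bridge apex.
  # Trabecular pores and gray noise sculpt saddles with relief up to the
  # pore scale (~0.1 mm) into the floor or walls of a single hole; a real
  # inter-hole bridge stands well clear of both floors.
  vl <- measure_vertical(mask, line, region, NULL,
                         x_range = c(region$x_left_mm, br$apex_x_mm))
  vr <- measure_vertical(mask, line, region, NULL,
                         x_range = c(br$apex_x_mm, region$x_right_mm))
  if (min(vl$vd1_mm, vr$vd1_mm) - br$apex_depth_mm < 2 * min_relief_mm)
    return(numeric(0))
  left <- subregion(region, region$col_range[1L], br$apex_col - 1L)
  right <- subregion(region, br$apex_col + 1L, region$col_range[2L])
  sort(c(find_splits(mask, line, left, cfg, min_relief_mm),
         br$apex_x_mm,
         find_splits(mask, line, right, cfg, min_relief_mm)))
}

#' Analyze a defect from a calibrated image stack
#'
#' Runs the full decision algorithm: segmentation, cement-line fit (with
#' a refit excluding the detected defect), defect detection, and — when
#' the defect is not completely reconstituted — per slice: bridge
#' detection, osteophyte call, hole counting by relative bridge height
#' (recursively, so sections with more than two holes split at every
#' persistent bridge), per-hole measurement, and Hd-threshold
#' classification.  Holes are tracked across slices by horizontal-centre
#' proximity (nearest centre within one awl diameter) and each tracked
#' hole receives its worst-case class (cyst > resorption > residual
#' hole).
#'
#' @param images A [calibrated_image()] or a list of them (consecutive
#'   slices of one defect).
#' @param annotations Optional [annotation_set()].
#' @param awl An [awl_spec()]; default from `annotations` if present.
#' @param cfg A [threshold_config()].
#' @param thr A [gray_threshold()] for segmentation.
#' @return An object of class `defect_report`; see
#'   [as.data.frame.defect_report()] for the per-lesion table.
#' @export
analyze_defect <- function(images, annotations = NULL, awl = NULL,
                           cfg = threshold_config(),
                           thr = gray_threshold()) {
  if (inherits(images, "calibrated_image")) images <- list(images)
  if (!length(images) || !all(vapply(images, inherits, logical(1), "calibrated_image")))
    stopf("`images` must be a calibrated_image or a list of them")
  if (is.null(awl) && !is.null(annotations)) awl <- annotations$awl
  if (is.null(awl)) stopf("an awl_spec is required (argument `awl` or annotations)")
  stopifnot(inherits(awl, "awl_spec"))
  ann_ep <- if (!is.null(annotations)) annotations$cement_line_endpoints
  ann_de <- if (!is.null(annotations)) annotations$defect_extent_mm

  slices <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    sid <- if (!is.null(img$slice_id)) img$slice_id else i
    mask <- segment_bone(img, thr)
    line <- fit_cement_line(mask, defect_extent_mm = ann_de, endpoints = ann_ep)
    region <- detect_defect_region(mask, line,
                                   min_deviation_mm = cfg$reconstitution_tolerance_mm)
    if (!is.null(region) && is.null(ann_ep)) {
      # refit excluding the detected defect, then re-detect
      line <- tryCatch(
        fit_cement_line(mask, defect_extent_mm = c(region$x_left_mm, region$x_right_mm)),
        error = function(e) line
      )
      region <- detect_defect_region(mask, line,
                                     min_deviation_mm = cfg$reconstitution_tolerance_mm)
    }
    if (!is.null(ann_de) && !is.null(region))
      region <- detect_defect_region(mask, line,
                                     min_deviation_mm = cfg$reconstitution_tolerance_mm,
                                     defect_extent_mm = ann_de)
    if (is.null(region)) {
      return(list(slice_id = sid, reconstituted = TRUE, hole_count = 0L,
                  lesions = NULL, osteophyte = NULL, line = line))
    }
    bridge <- detect_bridge(mask, line, region,
                            min_relief_mm = cfg$reconstitution_tolerance_mm)
    osteo <- measure_osteophyte(mask, line, region)
    splits <- find_splits(mask, line, region, cfg,
                          min_relief_mm = cfg$reconstitution_tolerance_mm)
    bounds <- c(-Inf, splits, Inf)
    lesions <- NULL
    for (h in seq_len(length(bounds) - 1L)) {
      xr <- bounds[h:(h + 1L)]
      hor <- withCallingHandlers(
        measure_horizontal(mask, line, region, awl, x_range = xr),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (is.null(hor$opening)) next  # no cavity in this span
      vert_h <- measure_vertical(mask, line, region, x_range = xr)
      area <- measure_area(mask, line, region, x_range = xr)
      lesions <- rbind(lesions, data.frame(
        slice_id = sid, lesion_id = h,
        center_x_mm = mean(hor$opening),
        vd1_mm = vert_h$vd1_mm,
        vd2_mm = if (bridge$present) max(bridge$apex_depth_mm, 0) else NA_real_,
        hd1_mm = hor$hd1_mm, hd2_mm = hor$hd2_mm,
        depth_mm = vert_h$vd1_mm, area_mm2 = area,
        class = classify_lesion(hor$hd1_mm, hor$hd2_mm, awl, cfg)
      ))
    }
    list(slice_id = sid, reconstituted = FALSE,
         hole_count = if (is.null(lesions)) 0L else nrow(lesions),
         lesions = lesions, osteophyte = osteo, bridge = bridge, line = line)
  })

  reconstituted <- all(vapply(slices, `[[`, logical(1), "reconstituted"))
  osteo_present <- any(vapply(slices, function(s)
    classify_osteophyte(s$bridge, s$osteophyte), logical(1)))

  # track holes across slices by centre proximity; a track can absorb at
  # most one hole per slice (two holes of one slice are never merged)
  tracks <- list()
  for (s in slices) {
    if (is.null(s$lesions)) next
    used <- integer(0)
    for (k in seq_len(nrow(s$lesions))) {
      les <- s$lesions[k, ]
      d <- vapply(tracks, function(t) abs(t$center_x_mm - les$center_x_mm),
                  numeric(1))
      if (length(used)) d[used] <- Inf
      j <- if (length(d) && min(d) < awl$diameter_mm) which.min(d) else 0L
      if (j == 0L) {
        tracks[[length(tracks) + 1L]] <- list(
          center_x_mm = les$center_x_mm, classes = les$class, n_slices = 1L)
        used <- c(used, length(tracks))
      } else {
        used <- c(used, j)
        tracks[[j]]$classes <- c(tracks[[j]]$classes, les$class)
        tracks[[j]]$n_slices <- tracks[[j]]$n_slices + 1L
        tracks[[j]]$center_x_mm <- les$center_x_mm
      }
    }
  }
  holes <- if (length(tracks)) {
    do.call(rbind, lapply(seq_along(tracks), function(i) {
      t <- tracks[[i]]
      worst <- t$classes[which.max(cavity_severity[t$classes])]
      data.frame(hole_id = i, center_x_mm = t$center_x_mm,
                 n_slices = t$n_slices, class = worst)
    }))
  } else NULL
  counts <- stats::setNames(integer(length(lesion_classes())), lesion_classes())
  if (!is.null(holes)) {
    tab <- table(holes$class)
    counts[names(tab)] <- as.integer(tab)
  }
  if (reconstituted) counts["complete_reconstitution"] <- 1L
  if (osteo_present) counts["intra_lesional_osteophyte"] <- 1L

  structure(list(
    schema_version = "1.0",
    reconstituted = reconstituted,
    osteophyte_present = osteo_present,
    holes = holes,
    class_counts = counts,
    slices = slices,
    awl = awl, config = cfg
  ), class = "defect_report")
}

#' @export
print.defect_report <- function(x, ...) {
  cat("<defect_report>\n")
  if (x$reconstituted) {
    cat("  complete reconstitution (no slice deviates from the cement line)\n")
  } else {
    cat(sprintf("  %d tracked hole(s) over %d slice(s); osteophyte: %s\n",
                if (is.null(x$holes)) 0L else nrow(x$holes), length(x$slices),
                if (x$osteophyte_present) "yes" else "no"))
    if (!is.null(x$holes)) {
      for (i in seq_len(nrow(x$holes)))
        cat(sprintf("  hole %d @ x = %.2f mm: %s\n", x$holes$hole_id[i],
                    x$holes$center_x_mm[i], x$holes$class[i]))
    }
  }
  invisible(x)
}

#' Per-lesion measurement table of a defect report
#'
#' One row per lesion per slice: slice_id, lesion_id, vd1_mm, vd2_mm,
#' hd1_mm, hd2_mm, depth_mm, area_mm2, class, plus the slice's maximal
#' osteophyte height and location (NA when none).
#'
#' @param x A `defect_report`.
#' @param ... Unused.
#' @return A data frame (zero rows for a reconstituted defect).
#' @export
as.data.frame.defect_report <- function(x, ...) {
  rows <- NULL
  for (s in x$slices) {
    if (is.null(s$lesions)) next
    les <- s$lesions
    if (!is.null(s$osteophyte) && nrow(s$osteophyte)) {
      i <- which.max(s$osteophyte$h0_mm)
      les$h0_mm <- s$osteophyte$h0_mm[i]
      les$osteophyte_location <- s$osteophyte$location[i]
    } else {
      les$h0_mm <- NA_real_
      les$osteophyte_location <- NA_character_
    }
    rows <- rbind(rows, les)
  }
  if (is.null(rows))
    rows <- data.frame(slice_id = integer(0), lesion_id = integer(0),
                       center_x_mm = numeric(0), vd1_mm = numeric(0),
                       vd2_mm = numeric(0), hd1_mm = numeric(0),
                       hd2_mm = numeric(0), depth_mm = numeric(0),
                       area_mm2 = numeric(0), class = character(0),
                       h0_mm = numeric(0), osteophyte_location = character(0))
  rows
}

#' Threshold sensitivity sweep
#'
#' Re-classifies a set of lesion measurements for every combination of
#' Hd1 and Hd2 multipliers and tabulates the class counts.  The count of
#' a pathology is non-increasing in its own multiplier.
#'
#' @param measurements Data frame with columns `hd1_mm` and `hd2_mm`
#'   (e.g. from [as.data.frame.defect_report()]).
#' @param awl An [awl_spec()].
#' @param hd1_multipliers Numeric vector of Hd1 multipliers (default
#'   1.5, 2, 3).
#' @param hd2_multipliers Numeric vector of Hd2 multipliers (default
#'   2, 3, 4).
#' @param cfg Base [threshold_config()] (bridge fraction etc.).
#' @return Data frame: one row per multiplier pair with columns
#'   `hd1_multiplier`, `hd2_multiplier`, `residual_hole`,
#'   `peri_hole_resorption`, `subchondral_cyst`.
#' @export
threshold_sweep <- function(measurements, awl = awl_spec(),
                            hd1_multipliers = c(1.5, 2, 3),
                            hd2_multipliers = c(2, 3, 4),
                            cfg = threshold_config()) {
  if (!is.data.frame(measurements) ||
      !all(c("hd1_mm", "hd2_mm") %in% names(measurements)) ||
      !nrow(measurements))
    stopf("`measurements` must be a non-empty data frame with hd1_mm and hd2_mm")
  grid <- expand.grid(hd1_multiplier = hd1_multipliers,
                      hd2_multiplier = hd2_multipliers,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- threshold_config(bridge_fraction = cfg$bridge_fraction,
                           hd1_multiplier = grid$hd1_multiplier[i],
                           hd2_multiplier = grid$hd2_multiplier[i],
                           reconstitution_tolerance_mm = cfg$reconstitution_tolerance_mm)
    cl <- classify_lesion(measurements$hd1_mm, measurements$hd2_mm, awl, ci)
    data.frame(hd1_multiplier = grid$hd1_multiplier[i],
               hd2_multiplier = grid$hd2_multiplier[i],
               residual_hole = sum(cl == "residual_hole"),
               peri_hole_resorption = sum(cl == "peri_hole_resorption"),
               subchondral_cyst = sum(cl == "subchondral_cyst"))
  })
  do.call(rbind, out)
}
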