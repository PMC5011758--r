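# Synthetic osteochondral cross-section phantoms with analytic ground truth.
#
# A phantom is defined by continuous geometry (cement line, cavity width
# profiles, bridge floor, osteophyte cap).  The rendered image and the
# ground truth are both derived from that geometry, but independently: the
# truth comes from interval arithmetic on the continuous profiles, never
# from the rendered pixels.

#' Microfracture awl geometry
#'
#' @param diameter_mm Diameter of the cylindrical awl body in mm
#'   (default 1.2, the standard instrument).
#' @param penetration_depth_mm Standardized penetration depth set by the
#'   awl's stop, in mm.  The Hd2 measuring level sits at half this depth
#'   below the projected cement line.
#' @return An object of class `awl_spec`.
#' @export
awl_spec <- function(diameter_mm = 1.2, penetration_depth_mm = 2.0) {
  check_pos(diameter_mm, "diameter_mm")
  check_pos(penetration_depth_mm, "penetration_depth_mm")
  structure(list(diameter_mm = diameter_mm,
                 penetration_depth_mm = penetration_depth_mm),
            class = "awl_spec")
}

#' Single cavity (microfracture hole) specification
#'
#' The cavity wall is a piecewise-linear width profile below the cement
#' line.  A `"trapezoid"` profile interpolates the width linearly from
#' `hd1_mm` at the opening to the base width that realizes `hd2_mm` at the
#' Hd2 level (half the awl penetration depth); it requires
#' `hd2_mm <= hd1_mm`.  A `"bulb"` profile places its maximum width
#' `hd2_mm` at the Hd2 level (narrow-neck cyst morphology); it requires
#' `hd2_mm > hd1_mm`.
#'
#' @param center_x_mm Horizontal centre of the cavity (mm).
#' @param hd1_mm Opening width at cement-line level (mm).
#' @param hd2_mm Width at half the awl penetration depth (mm).
#' @param depth_mm Vertical extent below the cement line (mm).
#' @param profile `"auto"` (bulb iff `hd2_mm > hd1_mm`), `"trapezoid"`,
#'   or `"bulb"`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_x_mm, hd1_mm, hd2_mm, depth_mm,
                        profile = c("auto", "trapezoid", "bulb")) {
  profile <- match.arg(profile)
  check_pos(hd1_mm, "hd1_mm"); check_pos(hd2_mm, "hd2_mm")
  check_pos(depth_mm, "depth_mm")
  if (!is_num1(center_x_mm)) stopf("`center_x_mm` must be a single number")
  if (profile == "auto") profile <- if (hd2_mm > hd1_mm) "bulb" else "trapezoid"
  if (profile == "bulb" && hd2_mm <= hd1_mm)
    stopf("bulb profile requires hd2_mm > hd1_mm")
  if (profile == "trapezoid" && hd2_mm > hd1_mm)
    stopf("trapezoid profile requires hd2_mm <= hd1_mm (use bulb)")
  structure(list(center_x_mm = center_x_mm, hd1_mm = hd1_mm, hd2_mm = hd2_mm,
                 depth_mm = depth_mm, profile = profile),
            class = "lesion_spec")
}

# Width-profile knots (depth, width) of a cavity, given the Hd2 level hm.
lesion_knots <- function(les, hm) {
  if (les$profile == "trapezoid") {
    w_base <- les$hd1_mm + (les$hd2_mm - les$hd1_mm) * les$depth_mm / hm
    if (w_base < 0)
      stopf("trapezoid cavity closes before its base (hd1 = %g, hd2 = %g, depth = %g, Hd2 level = %g): reduce depth or raise hd2",
            les$hd1_mm, les$hd2_mm, les$depth_mm, hm)
    list(d = c(0, les$depth_mm), w = c(les$hd1_mm, w_base))
  } else {
    w_end <- 0.4 * les$hd1_mm
    list(d = c(0, hm, les$depth_mm), w = c(les$hd1_mm, les$hd2_mm, w_end))
  }
}

# Cavity width at depth d (0 beyond the base).
lesion_width_at <- function(les, d, hm) {
  k <- lesion_knots(les, hm)
  ifelse(d < 0 | d > les$depth_mm, 0, stats::approx(k$d, k$w, xout = d, rule = 2)$y)
}

# Per-column void depth interval (d_lo, d_hi) of a cavity: the set
# {d : w(d) > 2 |x - c|}, a single interval since w is unimodal.
lesion_column_interval <- function(les, x, hm) {
  t <- 2 * abs(x - les$center_x_mm)
  k <- lesion_knots(les, hm)
  d_lo <- rep(Inf, length(x))
  d_hi <- rep(-Inf, length(x))
  if (les$profile == "trapezoid") {
    hd1 <- k$w[1L]; w_b <- k$w[2L]; depth <- les$depth_mm
    open <- t < hd1
    if (w_b == hd1) {
      d_lo[open] <- 0; d_hi[open] <- depth
    } else {
      d_lo[open] <- 0
      d_hi[open] <- ifelse(t[open] <= w_b, depth,
                           depth * (hd1 - t[open]) / (hd1 - w_b))
    }
  } else {
    hd1 <- k$w[1L]; hd2 <- k$w[2L]; w_end <- k$w[3L]; depth <- les$depth_mm
    inb <- t < hd2
    d_lo[inb] <- ifelse(t[inb] < hd1, 0, hm * (t[inb] - hd1) / (hd2 - hd1))
    d_hi[inb] <- ifelse(t[inb] < w_end, depth,
                        hm + (depth - hm) * (hd2 - t[inb]) / (hd2 - w_end))
  }
  list(d_lo = d_lo, d_hi = d_hi)
}

#' Full synthetic cross-section specification
#'
#' Describes one 2D osteochondral cross-section: a bone block whose upper
#' surface is the (projected) cement line `y = cement_line_depth_mm +
#' cement_line_slope * x`, with 1--2 microfracture cavities, an optional
#' inter-hole bone bridge of controlled height, an optional osteophytic
#' cap protruding above the line, plus trabecular texture and gray noise.
#'
#' Geometric constraints enforced here (so that the analytic ground truth
#' is exact):
#' \itemize{
#' \item Two-cavity sections use trapezoid profiles only; narrow-neck
#'   (bulb) cysts are generated as single-cavity sections.
#' \item With a sub-line bridge (`bridge_vd2_mm`), the two openings are
#'   adjacent: the inner opening edges meet at the bridge apex, and the
#'   bridge surface between the cavity walls is carved flat at exactly
#'   `bridge_vd2_mm` below the cement line.
#' \item A central osteophyte (cap between two separated openings)
#'   excludes `bridge_vd2_mm`: the bridge then reaches the line and the
#'   cap rises above it.
#' }
#'
#' @param lesions A [lesion_spec()] or list of 1--2 of them (sorted by
#'   centre internally).
#' @param width_mm,height_mm Canvas size in mm.
#' @param pixel_size_mm Pixel size in mm (default 0.015, i.e. 15 um).
#' @param cement_line_depth_mm,cement_line_slope Cement line
#'   `y = depth + slope * x`.
#' @param defect_extent_mm `NULL` (hull of lesions and cap) or
#'   `c(x_left, x_right)`.
#' @param bridge_vd2_mm Bridge-top depth below the cement line (Vd2), only
#'   with two lesions; `NULL` for none.
#' @param osteophyte `NULL` or `list(center_x_mm, h0_mm, width_mm)`: a
#'   parabolic bone cap protruding `h0_mm` above the cement line.
#' @param noise_sigma Gaussian gray-noise standard deviation.
#' @param trabecular_porosity Fraction of the bone deeper than 0.5 mm
#'   below the cement line carved into elliptical voids.
#' @param awl An [awl_spec()].
#' @param seed RNG seed for the render (noise, pores).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesions,
                         width_mm = 8, height_mm = 4.6,
                         pixel_size_mm = 0.015,
                         cement_line_depth_mm = 1.2,
                         cement_line_slope = 0,
                         defect_extent_mm = NULL,
                         bridge_vd2_mm = NULL,
                         osteophyte = NULL,
                         noise_sigma = 0,
                         trabecular_porosity = 0,
                         awl = awl_spec(),
                         seed = 1L) {
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (!is.list(lesions) || !length(lesions) %in% 1:2 ||
      !all(vapply(lesions, inherits, logical(1), "lesion_spec")))
    stopf("`lesions` must be a list of 1 or 2 lesion_spec objects")
  check_pos(width_mm, "width_mm"); check_pos(height_mm, "height_mm")
  check_pos(pixel_size_mm, "pixel_size_mm")
  check_pos(cement_line_depth_mm, "cement_line_depth_mm")
  if (!is_num1(cement_line_slope)) stopf("`cement_line_slope` must be a number")
  if (!inherits(awl, "awl_spec")) stopf("`awl` must be an awl_spec")
  if (!is_num1(noise_sigma) || noise_sigma < 0) stopf("`noise_sigma` must be >= 0")
  if (!is_num1(trabecular_porosity) || trabecular_porosity < 0 ||
      trabecular_porosity >= 1)
    stopf("`trabecular_porosity` must be in [0, 1)")

  hm <- awl$penetration_depth_mm / 2
  ord <- order(vapply(lesions, `[[`, numeric(1), "center_x_mm"))
  lesions <- lesions[ord]
  for (les in lesions) {
    if (les$depth_mm < hm)
      stopf("Hd2 level below cavity depth: cavity depth %g mm < half penetration depth %g mm",
            les$depth_mm, hm)
    lesion_knots(les, hm)  # validates trapezoid base width
  }
  n_les <- length(lesions)
  if (!is.null(bridge_vd2_mm)) {
    check_pos(bridge_vd2_mm, "bridge_vd2_mm")
    if (n_les != 2L) stopf("`bridge_vd2_mm` requires exactly two lesions")
    min_depth <- min(vapply(lesions, `[[`, numeric(1), "depth_mm"))
    if (bridge_vd2_mm >= min_depth)
      stopf("bridge top (%g mm) must lie above both cavity bases (min depth %g mm)",
            bridge_vd2_mm, min_depth)
  }
  if (n_les == 2L) {
    if (any(vapply(lesions, `[[`, character(1), "profile") == "bulb"))
      stopf("two-lesion sections support trapezoid profiles only")
    c1 <- lesions[[1L]]$center_x_mm; c2 <- lesions[[2L]]$center_x_mm
    inner_gap <- (c2 - lesions[[2L]]$hd1_mm / 2) - (c1 + lesions[[1L]]$hd1_mm / 2)
    if (!is.null(bridge_vd2_mm)) {
      if (abs(inner_gap) > pixel_size_mm)
        stopf("with a sub-line bridge the two openings must be adjacent (inner edge gap %g mm)",
              inner_gap)
    } else if (inner_gap < -pixel_size_mm) {
      stopf("two-lesion openings overlap by %g mm", -inner_gap)
    }
  }
  if (!is.null(osteophyte)) {
    if (!is.list(osteophyte) ||
        !all(c("center_x_mm", "h0_mm", "width_mm") %in% names(osteophyte)))
      stopf("`osteophyte` must be list(center_x_mm, h0_mm, width_mm)")
    check_pos(osteophyte$h0_mm, "osteophyte$h0_mm")
    check_pos(osteophyte$width_mm, "osteophyte$width_mm")
    cap_iv <- osteophyte$center_x_mm + c(-0.5, 0.5) * osteophyte$width_mm
    for (les in lesions) {
      op <- les$center_x_mm + c(-0.5, 0.5) * les$hd1_mm
      if (cap_iv[1L] < op[2L] - 2 * pixel_size_mm &&
          cap_iv[2L] > op[1L] + 2 * pixel_size_mm)
        stopf("osteophyte cap overlaps a cavity opening")
    }
    if (!is.null(bridge_vd2_mm) && n_les == 2L) {
      c1 <- lesions[[1L]]$center_x_mm; c2 <- lesions[[2L]]$center_x_mm
      if (osteophyte$center_x_mm > c1 && osteophyte$center_x_mm < c2)
        stopf("a central osteophyte excludes `bridge_vd2_mm` (the bridge reaches above the line)")
    }
  }

  # defect extent: hull of cavity extents (widest level) and the cap
  half_ext <- vapply(lesions, function(l) max(l$hd1_mm, l$hd2_mm) / 2, numeric(1))
  centers <- vapply(lesions, `[[`, numeric(1), "center_x_mm")
  hull <- c(min(centers - half_ext), max(centers + half_ext))
  if (!is.null(osteophyte)) {
    cap_iv <- osteophyte$center_x_mm + c(-0.5, 0.5) * osteophyte$width_mm
    hull <- range(hull, cap_iv)
  }
  if (is.null(defect_extent_mm)) {
    defect_extent_mm <- hull
  } else {
    defect_extent_mm <- as.numeric(defect_extent_mm)
    if (length(defect_extent_mm) != 2L || defect_extent_mm[1L] >= defect_extent_mm[2L])
      stopf("`defect_extent_mm` must be c(x_left, x_right) with x_left < x_right")
    if (hull[1L] < defect_extent_mm[1L] - 1e-9 || hull[2L] > defect_extent_mm[2L] + 1e-9)
      stopf("lesion wider than defect: cavities span [%.3g, %.3g] mm but defect extent is [%.3g, %.3g] mm",
            hull[1L], hull[2L], defect_extent_mm[1L], defect_extent_mm[2L])
  }
  flank <- 0.45
  if (defect_extent_mm[1L] < flank || defect_extent_mm[2L] > width_mm - flank)
    stopf("defect extent [%.3g, %.3g] mm leaves less than %g mm of intact plate on a side (canvas %g mm)",
          defect_extent_mm[1L], defect_extent_mm[2L], flank, width_mm)
  line_at_hull <- cement_line_depth_mm + cement_line_slope * hull
  max_depth <- max(vapply(lesions, `[[`, numeric(1), "depth_mm"))
  if (max(line_at_hull) + max_depth + 0.2 > height_mm)
    stopf("cavity base reaches below the canvas (need height_mm > %.3g)",
          max(line_at_hull) + max_depth + 0.2)
  if (!is.null(osteophyte) &&
      cement_line_depth_mm + cement_line_slope * osteophyte$center_x_mm -
        osteophyte$h0_mm < 0.05)
    stopf("osteophyte cap reaches above the canvas")

  structure(list(
    width_mm = width_mm, height_mm = height_mm, pixel_size_mm = pixel_size_mm,
    cement_line_depth_mm = cement_line_depth_mm,
    cement_line_slope = cement_line_slope,
    defect_extent_mm = defect_extent_mm,
    lesions = lesions, bridge_vd2_mm = bridge_vd2_mm,
    osteophyte = osteophyte,
    noise_sigma = noise_sigma, trabecular_porosity = trabecular_porosity,
    awl = awl, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Bridge-floor x-interval: between the points where the two cavity walls
# reach depth bridge_vd2_mm.  NULL when there is no sub-line bridge.
bridge_floor_interval <- function(spec) {
  if (is.null(spec$bridge_vd2_mm)) return(NULL)
  hm <- spec$awl$penetration_depth_mm / 2
  l1 <- spec$lesions[[1L]]; l2 <- spec$lesions[[2L]]
  c(l1$center_x_mm + lesion_width_at(l1, spec$bridge_vd2_mm, hm) / 2,
    l2$center_x_mm - lesion_width_at(l2, spec$bridge_vd2_mm, hm) / 2)
}

# Void x-intervals at depth d below the cement line (continuous geometry).
level_intervals <- function(spec, d) {
  hm <- spec$awl$penetration_depth_mm / 2
  iv <- matrix(numeric(0), ncol = 2L)
  for (les in spec$lesions) {
    if (d <= les$depth_mm) {
      w <- lesion_width_at(les, d, hm)
      if (w > 0) iv <- rbind(iv, les$center_x_mm + c(-0.5, 0.5) * w)
    }
  }
  bf <- bridge_floor_interval(spec)
  if (!is.null(bf) && d < spec$bridge_vd2_mm) iv <- rbind(iv, bf)
  merge_intervals(iv, tol = 1e-9)
}

# Analytic measurements and forced classes for a phantom specification.
# Applies the same decision rules as the classifier, but to exact
# continuous geometry.
#' Analytic ground truth of a phantom
#'
#' Computes the exact Vd1/Vd2/Hd1/Hd2, depths, areas, osteophyte metrics,
#' hole count and lesion classes that the decision rules force on a
#' [phantom_spec()], from its continuous geometry (never from rendered
#' pixels).  Classes use the default [threshold_config()].
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `ground_truth`: `hole_count`, per-lesion
#'   data frame `lesions` (class, hd1_mm, hd2_mm, vd1_mm, depth_mm,
#'   area_mm2, center_x_mm), defect-level `vd1_mm`/`vd2_mm`,
#'   `bridge_above_line`, and `osteophyte` metrics (or `NULL`).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cfg <- threshold_config()
  hm <- spec$awl$penetration_depth_mm / 2
  n_les <- length(spec$lesions)
  centers <- vapply(spec$lesions, `[[`, numeric(1), "center_x_mm")
  depths <- vapply(spec$lesions, `[[`, numeric(1), "depth_mm")
  vd1 <- max(depths)

  osteo <- NULL
  if (!is.null(spec$osteophyte)) {
    o <- spec$osteophyte
    loc <- if (n_les == 2L && o$center_x_mm > centers[1L] &&
               o$center_x_mm < centers[2L]) "central" else "peripheral"
    osteo <- list(h0_mm = o$h0_mm, width_mm = o$width_mm,
                  area_mm2 = (2 / 3) * o$h0_mm * o$width_mm,
                  location = loc, center_x_mm = o$center_x_mm)
  }
  central_cap <- !is.null(osteo) && osteo$location == "central"

  if (n_les == 1L) {
    vd2 <- NULL
    hole_count <- 1L
  } else if (!is.null(spec$bridge_vd2_mm)) {
    vd2 <- spec$bridge_vd2_mm
    hole_count <- count_holes(vd1, vd2, cfg)
  } else {
    vd2 <- 0  # bridge at/above the line: persistent by definition
    hole_count <- 2L
  }

  # split point between tracked holes
  split_x <- if (n_les == 2L) {
    if (!is.null(spec$bridge_vd2_mm)) {
      mean(bridge_floor_interval(spec))
    } else if (central_cap) {
      osteo$center_x_mm
    } else {
      mean(c(centers[1L] + spec$lesions[[1L]]$hd1_mm / 2,
             centers[2L] - spec$lesions[[2L]]$hd1_mm / 2))
    }
  } else NA_real_

  iv0 <- level_intervals(spec, 0)
  ivh <- level_intervals(spec, hm)
  run_len_in <- function(iv, lo, hi) {
    # lengths of runs clipped to [lo, hi]
    if (nrow(iv) == 0L) return(0)
    a <- pmax(iv[, 1L], lo); b <- pmin(iv[, 2L], hi)
    max(c(0, b - a))
  }
  run_len_touching <- function(iv, lo, hi) {
    # full lengths of runs whose interior intersects (lo, hi)
    if (nrow(iv) == 0L) return(0)
    sel <- iv[, 2L] > lo + 1e-12 & iv[, 1L] < hi - 1e-12
    if (!any(sel)) return(0)
    max(iv[sel, 2L] - iv[sel, 1L])
  }
  area_between <- function(lo, hi) {
    # numeric integration of clipped run length over depth; the
    # piecewise-linear widths are evaluated for the whole depth grid at
    # once (equivalent to level_intervals() per step, but vectorized)
    dd <- seq(0, max(depths), by = spec$pixel_size_mm / 5)
    W <- lapply(spec$lesions, function(les) {
      k <- lesion_knots(les, hm)
      w <- stats::approx(k$d, k$w, xout = dd, rule = 2)$y
      w[dd > les$depth_mm] <- 0
      w
    })
    bf <- bridge_floor_interval(spec)
    v <- vapply(seq_along(dd), function(i) {
      iv <- matrix(numeric(0), ncol = 2L)
      for (j in seq_along(W)) {
        if (W[[j]][i] > 0)
          iv <- rbind(iv, centers[j] + c(-0.5, 0.5) * W[[j]][i])
      }
      if (!is.null(bf) && dd[i] < spec$bridge_vd2_mm) iv <- rbind(iv, bf)
      run_len_in(merge_intervals(iv, tol = 1e-9), lo, hi)
    }, numeric(1))
    sum((v[-1L] + v[-length(v)]) / 2) * (dd[2L] - dd[1L])
  }

  if (hole_count == 2L) {
    sub <- rbind(c(-Inf, split_x), c(split_x, Inf))
    les_df <- do.call(rbind, lapply(1:2, function(i) {
      hd1 <- run_len_in(iv0, sub[i, 1L], sub[i, 2L])
      hd2 <- run_len_touching(ivh, sub[i, 1L], sub[i, 2L])
      data.frame(lesion_id = i, center_x_mm = centers[i],
                 hd1_mm = hd1, hd2_mm = hd2,
                 vd1_mm = depths[i], depth_mm = depths[i],
                 area_mm2 = area_between(sub[i, 1L], sub[i, 2L]))
    }))
  } else {
    # single hole (or two cavities read as one lesion with erosion relief)
    hd1 <- run_len_in(iv0, -Inf, Inf)
    hd2 <- run_len_touching(ivh, -Inf, Inf)
    les_df <- data.frame(lesion_id = 1L, center_x_mm = mean(centers),
                         hd1_mm = hd1, hd2_mm = hd2,
                         vd1_mm = vd1, depth_mm = vd1,
                         area_mm2 = area_between(-Inf, Inf))
  }
  les_df$class <- classify_lesion(les_df$hd1_mm, les_df$hd2_mm, spec$awl, cfg)

  structure(list(
    hole_count = hole_count,
    lesions = les_df,
    vd1_mm = vd1,
    vd2_mm = if (is.null(vd2)) NA_real_ else vd2,
    bridge_above_line = central_cap,
    osteophyte = osteo,
    osteophyte_present = !is.null(osteo)
  ), class = "ground_truth")
}

#' Render a synthetic cross-section
#'
#' Renders the continuous geometry of a [phantom_spec()] onto the pixel
#' grid (bone gray ~ N(180, sigma), background ~ N(40, sigma), clipped to
#' 0--255) and pairs it with the analytic [ground_truth()].  Identical
#' spec and seed give a bit-identical image.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `image` ([calibrated_image()]),
#'   `truth` ([ground_truth()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  px <- spec$pixel_size_mm
  hm <- spec$awl$penetration_depth_mm / 2
  nr <- round(spec$height_mm / px)
  nc <- round(spec$width_mm / px)
  x <- (seq_len(nc) - 0.5) * px
  y <- (seq_len(nr) - 0.5) * px
  line_y <- spec$cement_line_depth_mm + spec$cement_line_slope * x
  D <- outer(y, line_y, "-")  # depth below the cement line, per pixel
  bone <- D > 0

  for (les in spec$lesions) {
    iv <- lesion_column_interval(les, x, hm)
    lo <- matrix(iv$d_lo, nr, nc, byrow = TRUE)
    hi <- matrix(iv$d_hi, nr, nc, byrow = TRUE)
    bone[D > lo & D < hi] <- FALSE
  }
  bf <- bridge_floor_interval(spec)
  if (!is.null(bf)) {
    cols <- x > bf[1L] & x < bf[2L]
    if (any(cols)) {
      sel <- D > 0 & D < spec$bridge_vd2_mm
      sel[, !cols] <- FALSE
      bone[sel] <- FALSE
    }
  }
  if (!is.null(spec$osteophyte)) {
    o <- spec$osteophyte
    cap <- o$h0_mm * (1 - (2 * (x - o$center_x_mm) / o$width_mm)^2)
    cap[cap < 0] <- 0
    capM <- matrix(cap, nr, nc, byrow = TRUE)
    bone[D < 0 & D > -capM] <- TRUE
  }

  img <- with_seed(spec$seed, {
    if (spec$trabecular_porosity > 0) {
      eligible <- bone & D > 0.5
      target <- spec$trabecular_porosity * sum(eligible) * px^2
      mean_pore <- pi * 0.06 * 0.035
      n_pores <- round(target / mean_pore)
      max_line <- max(line_y)
      for (k in seq_len(n_pores)) {
        a <- stats::runif(1, 0.03, 0.09)   # semi-axes, mm
        b <- stats::runif(1, 0.02, 0.05)
        th <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, 0, spec$width_mm)
        cy <- stats::runif(1, max_line + 0.5 + b, spec$height_mm - 0.05)
        rad <- max(a, b)
        rows <- which(y > cy - rad & y < cy + rad)
        cols <- which(x > cx - rad & x < cx + rad)
        if (!length(rows) || !length(cols)) next
        dx <- outer(rep(1, length(rows)), x[cols] - cx)
        dy <- outer(y[rows] - cy, rep(1, length(cols)))
        e <- ((dx * cos(th) + dy * sin(th)) / a)^2 +
             ((-dx * sin(th) + dy * cos(th)) / b)^2
        sub <- bone[rows, cols, drop = FALSE]
        sub[e <= 1 & D[rows, cols, drop = FALSE] > 0.5] <- FALSE
        bone[rows, cols] <- sub
      }
    }
    g <- ifelse(bone, 180, 40)
    if (spec$noise_sigma > 0)
      g <- g + stats::rnorm(length(g), 0, spec$noise_sigma)
    matrix(as.integer(pmin(255, pmax(0, round(g)))), nr, nc)
  })

  structure(list(
    image = calibrated_image(img, px),
    truth = ground_truth(spec),
    spec = spec
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("<phantom> %d lesion(s), hole count %d, classes: %s%s\n",
              length(x$spec$lesions), tr$hole_count,
              paste(tr$lesions$class, collapse = ", "),
              if (tr$osteophyte_present) " + osteophyte" else ""))
  print(x$image)
  invisible(x)
}

#' Default parameter ranges for random phantoms
#'
#' The ranges span the morphologies the decision algorithm distinguishes:
#' openings straddling twice the awl diameter, Hd2 straddling three times
#' the awl diameter (narrow-neck cysts via bulb profiles in single-hole
#' sections), bridges both above and below half the defect depth, and
#' central/peripheral osteophyte caps.
#'
#' @param noise_sigma Gray-noise SD applied to sampled specs.
#' @param trabecular_porosity Trabecular void fraction applied to sampled
#'   specs.
#' @param awl The [awl_spec()] used for all sampled sections.
#' @param ... Named overrides of any default range element.
#' @return A list of ranges consumed by [sample_random_spec()].
#' @export
phantom_ranges <- function(noise_sigma = 0, trabecular_porosity = 0,
                           awl = awl_spec(), ...) {
  r <- list(
    width_mm = 8, height_mm = 4.6, pixel_size_mm = 0.015,
    cement_line_depth_mm = c(1.0, 1.4),
    cement_line_slope = c(-0.03, 0.03),
    center_jitter_mm = c(-0.25, 0.25),
    two_lesion_prob = 0.5,
    hd1_single_mm = c(0.8, 4.2),
    hd1_double_mm = c(0.8, 2.9),
    bulb_prob = 0.5,
    bulb_hd2_extra_mm = c(0.2, 2.2),
    depth_mm = c(1.3, 2.5),
    bridge_vd2_lo_mm = 0.15,
    bridge_vd2_margin_mm = 0.25,
    osteophyte_prob = 0.3,
    central_osteophyte_prob = 0.25,
    osteophyte_h0_mm = c(0.15, 0.5),
    osteophyte_width_mm = c(0.4, 0.9),
    osteophyte_gap_mm = 0.1,
    noise_sigma = noise_sigma,
    trabecular_porosity = trabecular_porosity,
    awl = awl
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(r))
  if (length(bad)) stopf("unknown range element(s): %s", paste(bad, collapse = ", "))
  r[names(dots)] <- dots
  r
}

runif1 <- function(rg) stats::runif(1, rg[1L], rg[2L])

# TRUE when any analytic ground-truth value of `spec` lies within
# `margin` of a decision boundary (see sample_random_spec).
near_boundary <- function(spec, margin) {
  cfg <- threshold_config()
  d <- spec$awl$diameter_mm
  hm <- spec$awl$penetration_depth_mm / 2
  tr <- ground_truth(spec)
  if (any(abs(tr$lesions$hd1_mm - cfg$hd1_multiplier * d) < margin)) return(TRUE)
  if (any(abs(tr$lesions$hd2_mm - cfg$hd2_multiplier * d) < margin)) return(TRUE)
  if (!is.na(tr$vd2_mm)) {
    if (abs(tr$vd2_mm - cfg$bridge_fraction * tr$vd1_mm) < margin) return(TRUE)
    if (abs(tr$vd2_mm - hm) < margin) return(TRUE)
  }
  FALSE
}

#' Draw a random phantom specification
#'
#' Samples uniformly from the given ranges, with rejection of (a)
#' geometrically infeasible draws and (b) draws whose analytic ground
#' truth lies within `boundary_margin_mm` of a decision boundary (Hd1 vs
#' 2x awl diameter, Hd2 vs 3x, Vd2 vs half Vd1, and the bridge top vs the
#' Hd2 level).  A validation phantom must have an unambiguous label: at
#' finite pixel resolution no measurement can resolve a class across a
#' boundary closer than the sampling error, so boundary behaviour is
#' exercised by explicit forced examples on [classify_lesion()] and
#' [count_holes()] rather than by rendered images.  Reproducible under
#' `seed`.
#'
#' @param ranges A [phantom_ranges()] list.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling bound per draw.
#' @param boundary_margin_mm Minimum distance of every analytic value
#'   from its decision threshold (default 0.09 mm = 6 pixels at the
#'   default calibration).
#' @return A [phantom_spec()].
#' @export
sample_random_spec <- function(ranges = phantom_ranges(), seed = 1L,
                               max_tries = 100L,
                               boundary_margin_mm = 0.09) {
  with_seed(seed, {
    hmv <- ranges$awl$penetration_depth_mm / 2
    draw_trap_hd2 <- function(hd1, depth) {
      # lower bound keeps the trapezoid base width >= 0.05 mm
      lb <- hd1 * (1 - hmv / depth) + 0.05 * hmv / depth
      stats::runif(1, min(lb + 0.02, hd1), hd1)
    }
    for (try in seq_len(max_tries)) {
      two <- stats::runif(1) < ranges$two_lesion_prob
      mid <- ranges$width_mm / 2 + runif1(ranges$center_jitter_mm)
      osteo <- NULL
      bridge <- NULL
      if (!two) {
        hd1 <- runif1(ranges$hd1_single_mm)
        depth <- runif1(ranges$depth_mm)
        if (stats::runif(1) < ranges$bulb_prob) {
          hd2 <- hd1 + runif1(ranges$bulb_hd2_extra_mm)
        } else {
          hd2 <- draw_trap_hd2(hd1, depth)
        }
        lesions <- list(lesion_spec(mid, hd1, hd2, depth))
        if (stats::runif(1) < ranges$osteophyte_prob) {
          ow <- runif1(ranges$osteophyte_width_mm)
          side <- sample(c(-1, 1), 1)
          osteo <- list(
            center_x_mm = mid + side * (hd1 / 2 + ranges$osteophyte_gap_mm + ow / 2),
            h0_mm = runif1(ranges$osteophyte_h0_mm),
            width_mm = ow
          )
        }
      } else {
        hd1a <- runif1(ranges$hd1_double_mm)
        hd1b <- runif1(ranges$hd1_double_mm)
        da <- runif1(ranges$depth_mm)
        db <- runif1(ranges$depth_mm)
        central <- stats::runif(1) < ranges$central_osteophyte_prob
        if (central) {
          ow <- runif1(ranges$osteophyte_width_mm)
          gap <- ow + 2 * ranges$osteophyte_gap_mm
          c1 <- mid - gap / 2 - hd1a / 2
          c2 <- mid + gap / 2 + hd1b / 2
          osteo <- list(center_x_mm = mid,
                        h0_mm = runif1(ranges$osteophyte_h0_mm),
                        width_mm = ow)
        } else {
          c1 <- mid - hd1a / 2
          c2 <- mid + hd1b / 2
          hi <- min(da, db) - ranges$bridge_vd2_margin_mm
          if (hi <= ranges$bridge_vd2_lo_mm) next
          bridge <- stats::runif(1, ranges$bridge_vd2_lo_mm, hi)
        }
        lesions <- list(
          lesion_spec(c1, hd1a, draw_trap_hd2(hd1a, da), da),
          lesion_spec(c2, hd1b, draw_trap_hd2(hd1b, db), db)
        )
      }
      spec <- tryCatch(
        phantom_spec(
          lesions,
          width_mm = ranges$width_mm, height_mm = ranges$height_mm,
          pixel_size_mm = ranges$pixel_size_mm,
          cement_line_depth_mm = runif1(ranges$cement_line_depth_mm),
          cement_line_slope = runif1(ranges$cement_line_slope),
          bridge_vd2_mm = bridge,
          osteophyte = osteo,
          noise_sigma = ranges$noise_sigma,
          trabecular_porosity = ranges$trabecular_porosity,
          awl = ranges$awl,
          seed = sample.int(.Machine$integer.max, 1L)
        ),
        error = function(e) NULL
      )
      if (!is.null(spec) && !near_boundary(spec, boundary_margin_mm))
        return(spec)
    }
    stopf("could not sample a feasible phantom spec in %d attempts: ranges infeasible",
          max_tries)
  })
}
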