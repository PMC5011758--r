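# Geometric measurement operators on binarized cross-sections.
#
# All vertical measurements are anchored to the projected cement line,
# positive downward (into the subarticular spongiosa).  Void components
# use 4-connectivity, bone components 8-connectivity; ties at equal relief
# are broken toward the middle column.

# Depth of every pixel centre below the cement line (negative = above).
depth_matrix <- function(mask, line) {
  px <- mask$pixel_size_mm
  x <- (seq_len(ncol(mask$pixels)) - 0.5) * px
  y <- (seq_len(nrow(mask$pixels)) - 0.5) * px
  outer(y, line_depth_at(line, x), "-")
}

# Topmost-bone depth (mm) per column; NA where a column has no bone.
# The surface runs somewhere between the last void-pixel centre and the
# first bone-pixel centre, so the boundary between the two pixels (the
# bone pixel's top edge) is the unbiased estimate; using the bone pixel's
# centre would bias every surface depth half a pixel too deep.
surface_tops <- function(mask) {
  idx <- vapply(seq_len(ncol(mask$pixels)),
                function(c) match(TRUE, mask$pixels[, c], nomatch = NA_integer_),
                integer(1))
  (idx - 1) * mask$pixel_size_mm
}

#' Projected cement line
#'
#' Straight apical reference line `y = intercept_mm + slope * x` marking
#' the original top of the subchondral bone plate; every vertical
#' measurement is taken relative to it.
#'
#' @param intercept_mm Depth of the line at `x = 0`, mm.
#' @param slope Dimensionless rise per mm of x.
#' @param x_range Validity interval in x (informational).
#' @param provenance `"fitted"` or `"annotated"`.
#' @return An object of class `cement_line`.
#' @export
cement_line <- function(intercept_mm, slope, x_range = c(-Inf, Inf),
                        provenance = "fitted") {
  if (!is_num1(intercept_mm) || !is_num1(slope))
    stopf("cement line parameters must be finite numbers")
  structure(list(intercept_mm = intercept_mm, slope = slope,
                 x_range = as.numeric(x_range), provenance = provenance),
            class = "cement_line")
}

#' Evaluate the cement line at horizontal positions
#'
#' @param line A [cement_line()].
#' @param x Numeric vector of x positions in mm.
#' @return Line depth(s) in mm.
#' @export
line_depth_at <- function(line, x) line$intercept_mm + line$slope * x

#' @export
print.cement_line <- function(x, ...) {
  cat(sprintf("<cement_line> y = %.4g + %.4g x mm (%s)\n",
              x$intercept_mm, x$slope, x$provenance))
  invisible(x)
}

# Least-absolute-deviations straight line via iteratively reweighted LS.
lad_fit <- function(x, y, iters = 60L) {
  X <- cbind(1, x)
  b <- stats::lm.fit(X, y)$coefficients
  for (i in seq_len(iters)) {
    r <- y - X %*% b
    w <- 1 / pmax(abs(r), 1e-6)
    b_new <- stats::lm.wfit(X, y, as.numeric(w))$coefficients
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  as.numeric(b)
}

#' Fit the projected cement line
#'
#' With annotated endpoints the line is taken verbatim.  Otherwise a
#' robust straight line is fitted to the topmost-bone profile of the
#' intact plate: if the defect extent is known its columns are excluded
#' and a least-absolute-deviations (LAD) fit is used on the flanking
#' columns; if not, a deterministic consensus search (all line candidates
#' through pairs of evenly spaced surface points, scored by 0.05 mm
#' inliers) localizes the plate surface before the LAD refit, so that the
#' defect columns cannot drag the line down.
#'
#' @param mask A [binary_mask()].
#' @param defect_extent_mm Optional `c(x_left, x_right)` to exclude.
#' @param endpoints Optional 2x2 matrix of annotated (x, y) points.
#' @return A [cement_line()].
#' @export
fit_cement_line <- function(mask, defect_extent_mm = NULL, endpoints = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(endpoints)) {
    ep <- endpoints
    if (is.data.frame(ep)) ep <- as.matrix(ep)
    if (!is.matrix(ep) || !identical(dim(ep), c(2L, 2L)) || ep[1, 1] == ep[2, 1])
      stopf("`endpoints` must be two (x, y) points with distinct x")
    slope <- (ep[2, 2] - ep[1, 2]) / (ep[2, 1] - ep[1, 1])
    return(cement_line(ep[1, 2] - slope * ep[1, 1], slope,
                       x_range = sort(ep[, 1]), provenance = "annotated"))
  }
  px <- mask$pixel_size_mm
  x <- (seq_len(ncol(mask$pixels)) - 0.5) * px
  tops <- surface_tops(mask)
  ok <- !is.na(tops)
  if (!is.null(defect_extent_mm)) {
    de <- as.numeric(defect_extent_mm)
    left <- ok & x < de[1L]
    right <- ok & x > de[2L]
    if (sum(left) < 5L || sum(right) < 5L)
      stopf("fewer than 5 intact plate columns flank the defect on a side; annotate the cement line manually")
    use <- left | right
    b <- lad_fit(x[use], tops[use])
    return(cement_line(b[1L], b[2L], x_range = range(x[use])))
  }
  if (sum(ok) < 10L)
    stopf("too few bone columns to estimate the cement line; annotate it manually")
  xs <- x[ok]; ys <- tops[ok]
  grid <- unique(round(seq(1L, length(xs), length.out = 40L)))
  cand <- t(utils::combn(grid, 2L))
  dx <- xs[cand[, 2L]] - xs[cand[, 1L]]
  keep <- abs(dx) > 0.5  # need horizontal leverage
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) {
    b <- lad_fit(xs, ys)
    return(cement_line(b[1L], b[2L], x_range = range(xs)))
  }
  slopes <- (ys[cand[, 2L]] - ys[cand[, 1L]]) / (xs[cand[, 2L]] - xs[cand[, 1L]])
  ints <- ys[cand[, 1L]] - slopes * xs[cand[, 1L]]
  resid_s <- sweep(outer(slopes, xs) + ints, 2L, ys, "-")  # >0: surface above line
  n_in <- rowSums(abs(resid_s) < 0.05)
  # the intact plate is the topmost surface: a wide defect can give a line
  # through the cavity floor more inliers, but such a line leaves the
  # whole plate far above it; only small osteophyte caps may rise above
  # the true cement line, so candidates with many columns above are out
  n_above <- rowSums(resid_s > 0.1)
  valid <- n_above <= 0.15 * length(xs)
  best <- if (any(valid)) which(valid)[which.max(n_in[valid])] else which.max(n_in)
  inl <- abs(ints[best] + slopes[best] * xs - ys) < 0.05
  b <- lad_fit(xs[inl], ys[inl])
  cement_line(b[1L], b[2L], x_range = range(xs[inl]))
}

#' Defect region
#'
#' Maximal contiguous horizontal interval whose surface profile deviates
#' from the projected cement line by more than `min_deviation_mm` in
#' either direction (cavity below or overgrowth above).  Gaps of up to
#' `close_gap_mm` of non-deviating columns inside the defect (e.g. the
#' sub-tolerance foot of an osteophyte cap, or an inter-hole bridge
#' reaching the line) are closed before taking the maximal run.  The
#' default 0.4 mm is one third of the standard awl diameter, below both
#' the narrowest plausible opening and the intact flank beside a defect,
#' so it keeps one surgical defect contiguous without merging it into
#' unrelated surface irregularities.  `NULL` when no column deviates: the section is
#' consistent with complete reconstitution.
#'
#' @param mask A [binary_mask()].
#' @param line A [cement_line()].
#' @param min_deviation_mm Deviation tolerance, mm (default 0.1).
#' @param defect_extent_mm Optional annotated extent: echoed with
#'   provenance `"annotated"`.
#' @param close_gap_mm Gap-closing width, mm.
#' @return An object of class `defect_region` (or `NULL`): `x_left_mm`,
#'   `x_right_mm`, `col_range`, per-column `deviation_mm` (full image
#'   width, NA-free), `provenance`.
#' @export
detect_defect_region <- function(mask, line, min_deviation_mm = 0.1,
                                 defect_extent_mm = NULL,
                                 close_gap_mm = 0.4) {
  stopifnot(inherits(mask, "binary_mask"), inherits(line, "cement_line"))
  px <- mask$pixel_size_mm
  x <- (seq_len(ncol(mask$pixels)) - 0.5) * px
  tops <- surface_tops(mask)
  dev <- tops - line_depth_at(line, x)
  dev[is.na(dev)] <- nrow(mask$pixels) * px  # no bone at all: fully void
  region <- function(s, e, prov) {
    structure(list(x_left_mm = (s - 1L) * px, x_right_mm = e * px,
                   col_range = c(s, e), deviation_mm = dev,
                   pixel_size_mm = px, provenance = prov),
              class = "defect_region")
  }
  if (!is.null(defect_extent_mm)) {
    de <- as.numeric(defect_extent_mm)
    cols <- which(x > de[1L] & x < de[2L])
    if (!length(cols)) stopf("annotated defect extent contains no columns")
    return(region(min(cols), max(cols), "annotated"))
  }
  deviating <- abs(dev) > min_deviation_mm
  deviating <- close_gaps(deviating, round(close_gap_mm / px))
  r <- true_runs(deviating)
  if (!nrow(r)) return(NULL)
  len <- r$end - r$start
  i <- which.max(len)
  region(r$start[i], r$end[i], "detected")
}

#' @export
print.defect_region <- function(x, ...) {
  cat(sprintf("<defect_region> x = [%.3g, %.3g] mm (%s)\n",
              x$x_left_mm, x$x_right_mm, x$provenance))
  invisible(x)
}

#' Detect an inter-hole bone bridge
#'
#' Scans the surface profile inside the defect region for a saddle: a
#' column whose topmost bone is shallower than the deepest surface on
#' both sides by more than `min_relief_mm`, with both flanks reaching
#' below the cement line (two cavity basins).  A single-basin cavity has
#' no bridge.  The apex may protrude above the cement line (negative
#' `apex_depth_mm`), which routes to osteophyte analysis.  Ties in relief
#' (a flat bridge top) resolve to the middle column of the plateau.
#'
#' @param mask A [binary_mask()].
#' @param line A [cement_line()].
#' @param region A defect region from [detect_defect_region()].
#' @param min_relief_mm Minimum relief, mm (default 0.1).
#' @return An object of class `bridge_measure`: `present`, and when
#'   present `apex_depth_mm` (signed; negative = above the line),
#'   `apex_x_mm`, `apex_col`.
#' @export
detect_bridge <- function(mask, line, region, min_relief_mm = 0.1) {
  stopifnot(inherits(region, "defect_region"))
  px <- region$pixel_size_mm
  cols <- seq(region$col_range[1L], region$col_range[2L])
  s <- region$deviation_mm[cols]
  n <- length(s)
  absent <- structure(list(present = FALSE, apex_depth_mm = NULL,
                           apex_x_mm = NULL, apex_col = NULL),
                      class = "bridge_measure")
  if (n < 5L) return(absent)
  L <- c(-Inf, cummax(s)[-n])                 # deepest surface left of c
  R <- rev(c(-Inf, cummax(rev(s))[-n]))       # deepest surface right of c
  score <- pmin(L, R) - s
  interior <- seq(2L, n - 1L)
  best <- max(score[interior])
  # one-pixel tolerance: a flat bridge top renders as a staircase when the
  # cement line is sloped, so the exact-max set is only part of the plateau
  cand <- interior[score[interior] > best - px - 1e-9]
  apex <- cand[ceiling(length(cand) / 2)]
  if (pmin(L, R)[apex] - max(s[apex], 0) <= min_relief_mm) return(absent)
  col <- cols[apex]
  structure(list(present = TRUE, apex_depth_mm = s[apex],
                 apex_x_mm = (col - 0.5) * px, apex_col = col),
            class = "bridge_measure")
}

#' @export
print.bridge_measure <- function(x, ...) {
  if (!x$present) cat("<bridge_measure> no bridge\n")
  else cat(sprintf("<bridge_measure> apex %.3g mm %s the cement line at x = %.3g mm\n",
                   abs(x$apex_depth_mm),
                   if (x$apex_depth_mm < 0) "above" else "below", x$apex_x_mm))
  invisible(x)
}

# Void components (4-connectivity) below the line that are connected to
# the defect opening; returns the label matrix and the opening labels.
cavity_components <- function(mask, line, region) {
  D <- depth_matrix(mask, line)
  void <- !mask$pixels & D > 0
  lab <- label_components(void, 4L)
  px <- mask$pixel_size_mm
  cols <- seq(region$col_range[1L], region$col_range[2L])
  x <- (cols - 0.5) * px
  r0 <- floor(line_depth_at(line, x) / px + 0.5) + 1L  # first row below line
  keep <- r0 >= 1L & r0 <= nrow(lab)
  ids <- unique(lab[cbind(r0[keep], cols[keep])])
  ids <- ids[ids > 0L]
  list(lab = lab, D = D, opening_labels = ids)
}

#' Vertical lesion measurements (Vd1, Vd2)
#'
#' `vd1_mm` is the vertical distance from the cement line to the deepest
#' void pixel connected to the defect opening (the base of the defect).
#' `vd2_mm` is the bridge-apex depth when a bridge lies below the line;
#' a bridge protruding above the line yields `vd2_mm = 0` and the
#' `above_line` flag (it routes to osteophyte analysis).
#'
#' @param mask A [binary_mask()].
#' @param line A [cement_line()].
#' @param region A defect region from [detect_defect_region()].
#' @param bridge Optional [detect_bridge()] result.
#' @param x_range Optional `c(lo, hi)`: restrict the depth search to one
#'   hole's columns (after a split).
#' @return List with `vd1_mm`, `vd2_mm` (`NULL` when no bridge),
#'   `above_line`.
#' @export
measure_vertical <- function(mask, line, region, bridge = NULL,
                             x_range = NULL) {
  cc <- cavity_components(mask, line, region)
  vd1 <- 0
  if (length(cc$opening_labels)) {
    sel <- matrix(cc$lab %in% cc$opening_labels, nrow(cc$lab))
    if (!is.null(x_range)) {
      x <- (seq_len(ncol(mask$pixels)) - 0.5) * mask$pixel_size_mm
      sel[, !(x > x_range[1L] & x < x_range[2L])] <- FALSE
    }
    # the cavity bottom lies between the deepest void-pixel centre and the
    # bone-pixel centre below it: half a pixel past the centre is unbiased
    if (any(sel)) vd1 <- max(cc$D[sel]) + mask$pixel_size_mm / 2
  }
  vd2 <- NULL; above <- FALSE
  if (!is.null(bridge) && isTRUE(bridge$present)) {
    if (bridge$apex_depth_mm <= 0) { vd2 <- 0; above <- TRUE }
    else vd2 <- bridge$apex_depth_mm
  }
  list(vd1_mm = vd1, vd2_mm = vd2, above_line = above)
}

# Subpixel cavity-wall localization.  A wall position read from a single
# pixel row is (a) quantized to the column grid and (b) taken at the row's
# depth rather than at the exact measurement level (up to one pixel off),
# which together can push a width error beyond 2 px for shallow-sloped
# walls.  Since cavity walls are locally straight, we track the wall over
# up to `k_rows` consecutive rows (moving away from the measurement level
# into the cavity), fit x(depth) by least squares, and evaluate at the
# exact level.  Tracking stops at a jump > 4 px (e.g. two cavities merging
# across a bridge floor).  Falls back to the single-row estimate when
# fewer than two rows are usable.
refine_wall <- function(voidM, px, line, col0, r_start, side, level_mm,
                        step, k_rows = 12L) {
  nr <- nrow(voidM); nc <- ncol(voidM)
  xs <- numeric(0); ds <- numeric(0)
  col <- col0
  for (k in seq_len(k_rows) - 1L) {
    r <- r_start + step * k
    if (r < 1L || r > nr) break
    v <- voidM[r, ]
    if (!v[col]) {
      # wall moved inward between rows: re-locate the void nearby
      win <- max(1L, col - 4L):min(nc, col + 4L)
      hit <- win[v[win]]
      if (!length(hit)) break
      col <- hit[which.min(abs(hit - col))]
    }
    if (side == "L") {
      while (col > 1L && v[col - 1L]) col <- col - 1L
      est_x <- (col - 1L) * px
    } else {
      while (col < nc && v[col + 1L]) col <- col + 1L
      est_x <- col * px
    }
    d <- (r - 0.5) * px - line_depth_at(line, est_x)
    # approaching from above a profile kink (bulb maximum at the Hd2
    # level): rows below the level lie on the other wall branch — skip
    # them (they would also trip the jump guard for the rows above)
    if (step < 0L && d > level_mm + 1e-12) next
    if (length(xs) && abs(est_x - xs[length(xs)]) > 4 * px) break
    xs <- c(xs, est_x)
    ds <- c(ds, d)
  }
  if (length(xs) >= 2L && diff(range(ds)) > 1e-12) {
    b <- stats::cov(ds, xs) / stats::var(ds)
    mean(xs) + b * (level_mm - mean(ds))
  } else if (length(xs)) {
    xs[1L]
  } else {
    if (side == "L") (col0 - 1L) * px else col0 * px
  }
}

#' Horizontal lesion diameters (Hd1, Hd2)
#'
#' `hd1_mm` is the void run length along the cement line across the
#' cavity opening.  `hd2_mm` is the maximal void run length along the
#' line parallel to the cement line at half the awl penetration depth,
#' restricted to the cavity's connected component.  When the section is
#' split at a bridge apex, pass the hole's x-interval as `x_range`:
#' the opening run is clipped at the split boundary, while the Hd2 run
#' keeps its full width (a cyst may undermine the bridge).
#'
#' @param mask A [binary_mask()].
#' @param line A [cement_line()].
#' @param region A defect region from [detect_defect_region()].
#' @param awl An [awl_spec()]; sets the Hd2 level.
#' @param x_range Optional `c(lo, hi)` x-interval of one hole, mm.
#' @return List with `hd1_mm` and `hd2_mm` (0, with a warning, when the
#'   cavity does not reach the Hd2 level).
#' @export
measure_horizontal <- function(mask, line, region, awl, x_range = NULL) {
  stopifnot(inherits(awl, "awl_spec"))
  px <- mask$pixel_size_mm
  nc <- ncol(mask$pixels)
  x <- (seq_len(nc) - 0.5) * px
  clip_range <- if (is.null(x_range)) c(-Inf, Inf) else as.numeric(x_range)
  select_range <- c(max(region$x_left_mm, clip_range[1L]),
                    min(region$x_right_mm, clip_range[2L]))
  hm <- awl$penetration_depth_mm / 2
  cc <- cavity_components(mask, line, region)
  line_y <- line_depth_at(line, x)
  voidM <- matrix(cc$lab %in% cc$opening_labels, nrow(cc$lab))

  # width at a level: pick the run of cavity void along the level's pixel
  # row (selected by region overlap, clipped at a split boundary), then
  # refine each unclipped wall to subpixel at the exact level
  width_at_level <- function(rows, level_mm, step, clip) {
    ok <- rows >= 1L & rows <= nrow(voidM)
    v <- rep(FALSE, nc)
    v[ok] <- voidM[cbind(rows[ok], which(ok))]
    r <- true_runs(v)
    if (!nrow(r)) return(NULL)
    lo_raw <- (r$start - 1L) * px
    hi_raw <- r$end * px
    lo <- pmax(lo_raw, clip[1L]); hi <- pmin(hi_raw, clip[2L])
    sel <- hi_raw > select_range[1L] + 1e-12 &
           lo_raw < select_range[2L] - 1e-12 & hi > lo
    if (!any(sel)) return(NULL)
    i <- which(sel)[which.max((hi - lo)[sel])]
    lo_sub <- if (lo_raw[i] < clip[1L]) clip[1L] else
      refine_wall(voidM, px, line, r$start[i], rows[r$start[i]], "L",
                  level_mm, step)
    hi_sub <- if (hi_raw[i] > clip[2L]) clip[2L] else
      refine_wall(voidM, px, line, r$end[i], rows[r$end[i]], "R",
                  level_mm, step)
    c(max(lo_sub, clip[1L]), min(hi_sub, clip[2L]))
  }

  # start one extra row down: the fitted line is unbiased with error up to
  # half a pixel, so the first nominal row below it can lie in the air above
  # the plate (where the whole row is void); refine_wall extrapolates the
  # tracked wall back to the exact line level, so the deeper start adds no bias
  r0 <- floor(line_y / px + 0.5) + 2L
  op <- width_at_level(r0, 0, step = 1L, clip = clip_range)
  hd1 <- if (is.null(op)) 0 else max(0, op[2L] - op[1L])
  opening <- op

  sel <- voidM
  if (!is.null(x_range)) sel[, !(x > clip_range[1L] & x < clip_range[2L])] <- FALSE
  max_depth <- if (any(sel)) max(cc$D[sel]) else 0
  if (max_depth < hm) {
    warnf("cavity (depth %.3g mm) does not reach the Hd2 level (%.3g mm below the cement line): hd2 reported as 0",
          max_depth, hm)
    return(list(hd1_mm = hd1, hd2_mm = 0, opening = opening))
  }
  rh <- round((line_y + hm) / px + 0.5)
  # Hd2 keeps the full run width (a cyst may undermine the bridge)
  iv2 <- width_at_level(rh, hm, step = -1L, clip = c(-Inf, Inf))
  hd2 <- if (is.null(iv2)) 0 else max(0, iv2[2L] - iv2[1L])
  list(hd1_mm = hd1, hd2_mm = hd2, opening = opening)
}

#' 2D lesion area below the cement line
#'
#' Pixel count of the void connected to the defect opening, below the
#' projected cement line, times the pixel area.  `x_range` restricts the
#' count to one hole's columns after a split.
#'
#' @inheritParams measure_horizontal
#' @return Area in mm^2.
#' @export
measure_area <- function(mask, line, region, x_range = NULL) {
  px <- mask$pixel_size_mm
  cc <- cavity_components(mask, line, region)
  if (!length(cc$opening_labels)) return(0)
  sel <- matrix(cc$lab %in% cc$opening_labels, nrow(cc$lab)) & cc$D > 0
  if (!is.null(x_range)) {
    x <- (seq_len(ncol(mask$pixels)) - 0.5) * px
    sel[, !(x > x_range[1L] & x < x_range[2L])] <- FALSE
  }
  sum(sel) * px^2
}

#' Measure intra-lesional osteophytes
#'
#' Finds connected bone components (8-connectivity) protruding above the
#' projected cement line within the defect region and reports, for each,
#' the maximal perpendicular height H0 above the line, the maximal
#' horizontal width, the 2D area, and the location (`"central"` when the
#' component lies strictly inside the defect region, `"peripheral"` when
#' it touches a region edge).  Components of at most one pixel above the
#' line are ignored.
#'
#' @param mask A [binary_mask()].
#' @param line A [cement_line()].
#' @param region A defect region from [detect_defect_region()].
#' @return A data frame (one row per component: `h0_mm`, `width_mm`,
#'   `area_mm2`, `location`, `center_x_mm`) or `NULL` when none.
#' @export
measure_osteophyte <- function(mask, line, region) {
  px <- mask$pixel_size_mm
  D <- depth_matrix(mask, line)
  above <- mask$pixels & D < 0
  cols_region <- seq(region$col_range[1L], region$col_range[2L])
  keep <- matrix(FALSE, nrow(above), ncol(above))
  keep[, cols_region] <- TRUE
  above <- above & keep
  if (!any(above)) return(NULL)
  lab <- label_components(above, 8L)
  out <- NULL
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < 2L) next
    h0 <- max(-D[idx])
    if (h0 <= px) next
    cr <- range(idx[, 2L])
    loc <- if (cr[1L] <= region$col_range[1L] + 2L ||
               cr[2L] >= region$col_range[2L] - 2L) "peripheral" else "central"
    out <- rbind(out, data.frame(
      h0_mm = h0,
      width_mm = (cr[2L] - cr[1L] + 1L) * px,
      area_mm2 = nrow(idx) * px^2,
      location = loc,
      center_x_mm = mean(cr) * px - px / 2
    ))
  }
  out
}
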