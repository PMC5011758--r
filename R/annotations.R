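# Manual annotations: cement-line endpoints, defect extent, awl geometry.

#' Manual annotation set
#'
#' Optional manual inputs for a defect analysis: two cement-line endpoints
#' (physical mm coordinates), the horizontal defect extent, and the awl
#' geometry.  Raters traditionally draw the projected cement line by hand;
#' when endpoints are absent the line is estimated from the flanking
#' intact plate by [fit_cement_line()].
#'
#' @param cement_line_endpoints `NULL`, or a 2x2 numeric matrix (rows =
#'   points, columns = x, y in mm) of two distinct points on the line.
#' @param defect_extent_mm `NULL`, or `c(x_left, x_right)` in mm with
#'   `x_left < x_right`.
#' @param awl `NULL`, or an [awl_spec()].
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(cement_line_endpoints = NULL,
                           defect_extent_mm = NULL,
                           awl = NULL) {
  bad <- character(0)
  if (!is.null(cement_line_endpoints)) {
    ep <- cement_line_endpoints
    if (is.data.frame(ep)) ep <- as.matrix(ep)
    if (!is.matrix(ep) || !identical(dim(ep), c(2L, 2L)) || !is.numeric(ep) ||
        anyNA(ep)) {
      bad <- c(bad, "cement_line: need two numeric (x, y) points")
    } else if (ep[1L, 1L] == ep[2L, 1L] && ep[1L, 2L] == ep[2L, 2L]) {
      bad <- c(bad, "cement_line: endpoints must be distinct")
    } else if (ep[1L, 1L] == ep[2L, 1L]) {
      bad <- c(bad, "cement_line: endpoints must differ in x (vertical line)")
    } else {
      cement_line_endpoints <- ep
    }
  }
  if (!is.null(defect_extent_mm)) {
    de <- as.numeric(defect_extent_mm)
    if (length(de) != 2L || anyNA(de) || de[1L] >= de[2L])
      bad <- c(bad, "defect_extent_mm: need c(x_left, x_right) with x_left < x_right")
    else defect_extent_mm <- de
  }
  if (!is.null(awl) && !inherits(awl, "awl_spec"))
    bad <- c(bad, "awl: must be an awl_spec")
  if (length(bad))
    stopf("invalid annotations:\n  - %s", paste(bad, collapse = "\n  - "))
  structure(list(cement_line_endpoints = cement_line_endpoints,
                 defect_extent_mm = defect_extent_mm,
                 awl = awl),
            class = "annotation_set")
}

#' Read annotations from JSON
#'
#' Schema (all keys optional):
#' \preformatted{
#' {
#'   "cement_line": [[x1, y1], [x2, y2]],
#'   "defect_extent_mm": [x_left, x_right],
#'   "awl": {"diameter_mm": 1.2, "penetration_depth_mm": 2.0}
#' }
#' }
#' All coordinates in mm.
#'
#' @param path Path to a JSON file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file does not exist: '%s'", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  known <- c("cement_line", "defect_extent_mm", "awl")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stopf("invalid annotations: unknown keys: %s", paste(extra, collapse = ", "))
  awl <- NULL
  if (!is.null(obj$awl)) {
    if (!all(c("diameter_mm", "penetration_depth_mm") %in% names(obj$awl)))
      stopf("invalid annotations: awl needs diameter_mm and penetration_depth_mm")
    awl <- awl_spec(obj$awl$diameter_mm, obj$awl$penetration_depth_mm)
  }
  ep <- obj$cement_line
  if (!is.null(ep) && !is.matrix(ep)) ep <- do.call(rbind, ep)
  annotation_set(cement_line_endpoints = ep,
                 defect_extent_mm = obj$defect_extent_mm,
                 awl = awl)
}

#' Write annotations to JSON
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  obj <- list()
  if (!is.null(ann$cement_line_endpoints))
    obj$cement_line <- unname(ann$cement_line_endpoints)
  if (!is.null(ann$defect_extent_mm))
    obj$defect_extent_mm <- ann$defect_extent_mm
  if (!is.null(ann$awl))
    obj$awl <- list(diameter_mm = ann$awl$diameter_mm,
                    penetration_depth_mm = ann$awl$penetration_depth_mm)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
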