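#' Anchor points
#'
#' The 12 manually marked body landmarks that drive ROI geometry, named
#' `Pur_1` ... `Pur_12`:
#'
#' | name    | landmark            | name     | landmark           |
#' |---------|---------------------|----------|--------------------|
#' | Pur_1   | right wrist         | Pur_7    | left armpit        |
#' | Pur_2   | medial right elbow  | Pur_8    | left shoulder      |
#' | Pur_3   | right armpit        | Pur_9    | forehead           |
#' | Pur_4   | right shoulder      | Pur_10   | chin               |
#' | Pur_5   | left wrist          | Pur_11   | belly-button       |
#' | Pur_6   | medial left elbow   | Pur_12   | crotch             |
#'
#' Coordinates are 1-based `(row, col)` pixel positions. "Right"/"left" are
#' the participant's sides, facing the camera.
#'
#' @param coords a 12 x 2 numeric matrix (columns row, col) with rownames
#'   `Pur_1` ... `Pur_12`, or a named list of length-2 vectors.
#' @return An object of class `anchor_set` (a 12 x 2 matrix).
#' @export
anchor_set <- function(coords) {
  if (is.list(coords))
    coords <- do.call(rbind, coords)
  coords <- as.matrix(coords)
  nm <- paste0("Pur_", 1:12)
  if (is.null(rownames(coords)) || !setequal(rownames(coords), nm) ||
      anyDuplicated(rownames(coords)) || ncol(coords) != 2L)
    ta_error("anchors must be a 12 x 2 (row, col) table named Pur_1 ... Pur_12",
             "validation_error")
  coords <- coords[nm, , drop = FALSE]
  colnames(coords) <- c("row", "col")
  storage.mode(coords) <- "double"
  structure(coords, class = c("anchor_set", class(coords)))
}

#' Read / write anchor files (JSON)
#'
#' The anchor file maps `"Pur_1"` ... `"Pur_12"` to `[row, col]` (1-based).
#'
#' @param path file path.
#' @return [read_anchors()] returns an [anchor_set()].
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) ta_error(sprintf("file not found: %s", path), "io_error")
  anchor_set(lapply(jsonlite::read_json(path), function(p) unlist(p)))
}

#' @rdname read_anchors
#' @param anchors an [anchor_set()].
#' @export
write_anchors <- function(anchors, path) {
  stopifnot(inherits(anchors, "anchor_set"))
  lst <- stats::setNames(lapply(seq_len(nrow(anchors)),
                                function(i) as.vector(anchors[i, ])),
                         rownames(anchors))
  jsonlite::write_json(lst, path, auto_unbox = FALSE)
  invisible(path)
}

#' Validate an anchor set against a field
#'
#' Checks presence, in-bounds coordinates, pairwise distinctness, and the
#' vertical ordering forehead < chin < belly-button < crotch. Anchors lying
#' on a background (zero) cell only raise a warning: the medial landmarks
#' sit close to the silhouette edge and may fall just outside it.
#'
#' @param anchors an [anchor_set()].
#' @param field a background-filtered [temperature_field()].
#' @return The validated anchors, invisibly.
#' @export
validate_anchors <- function(anchors, field) {
  anchors <- anchor_set(anchors)
  stopifnot(inherits(field, "temperature_field"))
  if (any(anchors[, "row"] < 1 | anchors[, "row"] > field$rows |
          anchors[, "col"] < 1 | anchors[, "col"] > field$cols))
    ta_error("anchor outside image bounds", "validation_error")
  if (anyDuplicated(anchors))
    ta_error("anchor coordinates must be pairwise distinct", "validation_error")
  mid_rows <- anchors[c("Pur_9", "Pur_10", "Pur_11", "Pur_12"), "row"]
  if (any(diff(mid_rows) <= 0))
    ta_error("midline anchors must satisfy forehead < chin < belly-button < crotch (rows)",
             "validation_error")
  on_bg <- field$values[cbind(round(anchors[, "row"]), round(anchors[, "col"]))] == 0
  if (any(on_bg))
    ta_warn(sprintf("anchors on background cells: %s",
                    paste(rownames(anchors)[on_bg], collapse = ", ")))
  invisible(anchors)
}

#' Silhouette boundary along one scanline
#'
#' First and last nonzero positions along a row or column of a
#' background-filtered field; `NULL` if the scanline is entirely zero.
#'
#' @param field a filtered [temperature_field()].
#' @param axis `"row"` (scan across columns) or `"col"` (scan across rows).
#' @param index 1-based row or column index.
#' @return `NULL`, or a list with `first` and `last`.
#' @export
body_boundary <- function(field, axis = c("row", "col"), index) {
  stopifnot(inherits(field, "temperature_field"))
  axis <- match.arg(axis)
  v <- if (axis == "row") field$values[index, ] else field$values[, index]
  nz <- which(v != 0)
  if (!length(nz)) return(NULL)
  list(first = min(nz), last = max(nz))
}

# nonzero run in `row` containing column `col`; a run starting within
# `tol_px` is accepted, so anchors marked a couple of pixels off the
# silhouette edge still resolve, but absent body parts error out
scanline_run <- function(field, row, col, label, tol_px = 3L) {
  v <- field$values[row, ] != 0
  if (!any(v))
    ta_error(sprintf("%s: silhouette scanline at row %d is empty", label, row),
             "segmentation_error")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  d <- pmax(runs[, 1] - col, col - runs[, 2], 0)
  j <- which.min(d)
  if (d[j] > tol_px)
    ta_error(sprintf("%s: no silhouette within %d px of column %d at row %d",
                     label, tol_px, col, row), "segmentation_error")
  c(lo = unname(runs[j, 1]), hi = unname(runs[j, 2]))
}

# last row >= r1 such that cols clo:chi still contain silhouette, scanning
# contiguously downward (stops at the first fully-background row)
extent_down <- function(field, r1, clo, chi, label) {
  rmax <- field$rows
  r <- r1
  while (r < rmax && any(field$values[r + 1L, clo:chi] != 0)) r <- r + 1L
  if (all(field$values[r1, clo:chi] == 0))
    ta_error(sprintf("%s: no silhouette below row %d", label, r1),
             "segmentation_error")
  r
}

rect_quad <- function(r1, r2, c1, c2) {
  cbind(row = c(r1, r1, r2, r2), col = c(c1, c2, c2, c1))
}

#' Default ROI geometry table
#'
#' One entry per ROI: the label, body-part name, governing anchors, and a
#' vertex rule mapping (anchors, field, layout helpers) to a 4-vertex quad.
#' The 18 regions are split left/right about the midline (the vertical
#' through the mean column of the forehead, chin, belly-button and crotch
#' anchors); arm regions follow the silhouette via scanline runs; the
#' anterior-elbow squares use the same-size scale (side = half the
#' wrist-elbow distance). The whole table is an explicit extension point:
#' pass a modified copy to [segment()] to change any rule.
#'
#' @return A named list of 18 rule entries (classes `roi_rule`).
#' @export
roi_geometry <- function() {
  side_rules <- function(wrist, elbow, armpit, shoulder) {
    list(
      palm = function(a, f, lay, label) {
        run <- scanline_run(f, a[wrist, "row"], a[wrist, "col"], label)
        r2 <- extent_down(f, a[wrist, "row"], run["lo"], run["hi"], label)
        rect_quad(a[wrist, "row"], r2, run["lo"], run["hi"])
      },
      forearm = function(a, f, lay, label) {
        r1 <- a[elbow, "row"]; r2 <- a[wrist, "row"]
        if (r2 <= r1) ta_error(sprintf("%s: wrist not below elbow", label),
                               "segmentation_error")
        run <- scanline_run(f, (r1 + r2) %/% 2L, a[elbow, "col"], label)
        rect_quad(r1, r2, run["lo"], run["hi"])
      },
      ant_elbow = function(a, f, lay, label) {
        d <- sqrt(sum((a[wrist, ] - a[elbow, ])^2))
        if (d == 0) ta_error(sprintf("%s: wrist and elbow anchors coincide", label),
                             "segmentation_error")
        h <- max(1, round(d / 4))  # half-side of the same-size-scale square
        rect_quad(a[elbow, "row"] - h, a[elbow, "row"] + h,
                  a[elbow, "col"] - h, a[elbow, "col"] + h)
      },
      upper_arm = function(a, f, lay, label) {
        r1 <- a[shoulder, "row"]; r2 <- a[elbow, "row"]
        if (r2 <= r1) ta_error(sprintf("%s: elbow not below shoulder", label),
                               "segmentation_error")
        run <- scanline_run(f, (r1 + r2) %/% 2L, a[elbow, "col"], label)
        rect_quad(r1, r2, run["lo"], run["hi"])
      })
  }
  right <- side_rules("Pur_1", "Pur_2", "Pur_3", "Pur_4")
  left <- side_rules("Pur_5", "Pur_6", "Pur_7", "Pur_8")

  face <- function(side) function(a, f, lay, label) {
    r1 <- a["Pur_9", "row"]; r2 <- a["Pur_10", "row"]
    run <- scanline_run(f, (r1 + r2) %/% 2L, lay$mid, label)
    if (side == "right") rect_quad(r1, r2, min(run["lo"], lay$mid), lay$mid)
    else rect_quad(r1, r2, lay$mid, max(run["hi"], lay$mid))
  }
  fossa <- function(side) function(a, f, lay, label) {
    r1 <- a["Pur_10", "row"]
    r2 <- round((a["Pur_4", "row"] + a["Pur_8", "row"]) / 2)
    if (r2 <= r1) ta_error(sprintf("%s: shoulders not below chin", label),
                           "segmentation_error")
    if (side == "right") rect_quad(r1, r2, a["Pur_4", "col"], lay$mid)
    else rect_quad(r1, r2, lay$mid, a["Pur_8", "col"])
  }
  chest <- function(side) function(a, f, lay, label) {
    r1 <- round((a["Pur_4", "row"] + a["Pur_8", "row"]) / 2)
    r2 <- lay$chest_bottom
    if (side == "right") rect_quad(r1, r2, a["Pur_3", "col"], lay$mid)
    else rect_quad(r1, r2, lay$mid, a["Pur_7", "col"])
  }
  upper_abd <- function(side) function(a, f, lay, label) {
    r1 <- lay$chest_bottom; r2 <- a["Pur_11", "row"]
    if (side == "right") rect_quad(r1, r2, a["Pur_4", "col"], lay$mid)
    else rect_quad(r1, r2, lay$mid, a["Pur_8", "col"])
  }
  lower_abd <- function(side) function(a, f, lay, label) {
    r1 <- a["Pur_11", "row"]; r2 <- a["Pur_12", "row"]
    run <- scanline_run(f, (r1 + r2) %/% 2L, lay$mid, label)
    if (side == "right") rect_quad(r1, r2, min(run["lo"], lay$mid), lay$mid)
    else rect_quad(r1, r2, lay$mid, max(run["hi"], lay$mid))
  }

  entry <- function(label, part, anchors, fn)
    structure(list(label = label, body_part = part, anchors = anchors, fn = fn),
              class = "roi_rule")
  rules <- list(
    entry("ROI1", "right palm", "Pur_1", right$palm),
    entry("ROI2", "right forearm", c("Pur_1", "Pur_2"), right$forearm),
    entry("ROI3", "right anterior elbow", "Pur_2", right$ant_elbow),
    entry("ROI4", "right upper arm", c("Pur_2", "Pur_3", "Pur_4"), right$upper_arm),
    entry("ROI5", "left palm", "Pur_5", left$palm),
    entry("ROI6", "left forearm", c("Pur_5", "Pur_6"), left$forearm),
    entry("ROI7", "left anterior elbow", "Pur_6", left$ant_elbow),
    entry("ROI8", "left upper arm", c("Pur_6", "Pur_7", "Pur_8"), left$upper_arm),
    entry("ROI9", "right face", c("Pur_9", "Pur_10"), face("right")),
    entry("ROI10", "left face", c("Pur_9", "Pur_10"), face("left")),
    entry("ROI11", "right clavicle fossa", c("Pur_4", "Pur_8", "Pur_10"), fossa("right")),
    entry("ROI12", "left clavicle fossa", c("Pur_4", "Pur_8", "Pur_10"), fossa("left")),
    entry("ROI13", "right chest", c("Pur_3", "Pur_4", "Pur_7", "Pur_8", "Pur_11"), chest("right")),
    entry("ROI14", "left chest", c("Pur_3", "Pur_4", "Pur_7", "Pur_8", "Pur_11"), chest("left")),
    entry("ROI15", "right upper abdomen", c("Pur_4", "Pur_8", "Pur_11"), upper_abd("right")),
    entry("ROI16", "left upper abdomen", c("Pur_4", "Pur_8", "Pur_11"), upper_abd("left")),
    entry("ROI17", "right lower abdomen", c("Pur_11", "Pur_12"), lower_abd("right")),
    entry("ROI18", "left lower abdomen", c("Pur_11", "Pur_12"), lower_abd("left")))
  stats::setNames(rules, vapply(rules, `[[`, "", "label"))
}

# shared layout quantities the rules consult
roi_layout <- function(anchors) {
  mid <- round(mean(anchors[c("Pur_9", "Pur_10", "Pur_11", "Pur_12"), "col"]))
  armpit_row <- round((anchors["Pur_3", "row"] + anchors["Pur_7", "row"]) / 2)
  list(mid = mid,
       chest_bottom = (armpit_row + anchors["Pur_11", "row"]) %/% 2L)
}

#' Compute the 18 ROI quadrilaterals
#'
#' Applies the geometry table to a validated anchor set and a
#' background-filtered field.
#'
#' @param anchors a validated [anchor_set()].
#' @param field a filtered [temperature_field()].
#' @param geometry a geometry table, by default [roi_geometry()].
#' @return A named list of 18 `roi_quad` objects (label, body part,
#'   governing anchors, 4 x 2 vertex matrix).
#' @export
compute_roi_quads <- function(anchors, field, geometry = roi_geometry()) {
  anchors <- validate_anchors(anchors, field)
  lay <- roi_layout(anchors)
  lapply(geometry, function(rule) {
    verts <- rule$fn(anchors, field, lay, rule$label)
    verts[, "row"] <- pmin(pmax(verts[, "row"], 1), field$rows)
    verts[, "col"] <- pmin(pmax(verts[, "col"], 1), field$cols)
    if (nrow(verts) != 4L)
      ta_error(sprintf("%s: rule did not produce 4 vertices", rule$label),
               "segmentation_error")
    if (anyDuplicated(verts))
      ta_error(sprintf("%s: degenerate quad (coincident vertices)", rule$label),
               "segmentation_error")
    structure(list(label = rule$label, body_part = rule$body_part,
                   anchors = rule$anchors, vertices = verts),
              class = "roi_quad")
  })
}

# Even-odd (ray casting) point-in-polygon on grid cell centers, boundary
# inclusive. points: 2-col matrix (row, col); verts: 4x2 (row, col).
point_in_polygon <- function(points, verts) {
  px <- points[, 2]; py <- points[, 1]
  n <- nrow(verts)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- verts[j, 2]; y1 <- verts[j, 1]
    x2 <- verts[i, 2]; y2 <- verts[i, 1]
    # boundary test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    onseg <- abs(cross) < 1e-9 &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    onedge <- onedge | onseg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Extract the temperature multiset of one ROI
#'
#' Collects the temperatures of every grid cell whose center lies inside or
#' on the quad (even-odd rule). Background zeros are retained at this stage;
#' the granulation step excludes them.
#'
#' @param field a [temperature_field()].
#' @param quad an `roi_quad` from [compute_roi_quads()].
#' @return Numeric vector of temperatures (degC).
#' @export
extract_roi <- function(field, quad) {
  stopifnot(inherits(quad, "roi_quad"))
  v <- quad$vertices
  r <- max(1L, floor(min(v[, "row"]))):min(field$rows, ceiling(max(v[, "row"])))
  cc <- max(1L, floor(min(v[, "col"]))):min(field$cols, ceiling(max(v[, "col"])))
  pts <- cbind(row = rep(r, times = length(cc)), col = rep(cc, each = length(r)))
  keep <- point_in_polygon(pts, v)
  if (!any(keep))
    ta_error(sprintf("%s: polygon encloses no grid cells", quad$label),
             "empty_roi_error")
  field$values[pts[keep, , drop = FALSE]]
}

#' Segment a filtered field into the 18 ROIs
#'
#' @inheritParams compute_roi_quads
#' @return An object of class `roi_set`: named list of 18 entries, each with
#'   `label`, `body_part`, `anchors`, `vertices` and `temps` (the raw
#'   temperature multiset, zeros included).
#' @examples
#' ph <- generate_phantom(seed = 1)
#' rs <- segment(filter_background(ph$field), ph$anchors)
#' summary(rs)
#' @export
segment <- function(field, anchors, geometry = roi_geometry()) {
  quads <- compute_roi_quads(anchors, field, geometry)
  out <- lapply(quads, function(q) {
    q$temps <- extract_roi(field, q)
    q
  })
  structure(out, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d regions\n", length(x)))
  invisible(x)
}

#' @export
summary.roi_set <- function(object, ...) {
  rows <- lapply(object, function(q) {
    nz <- q$temps[q$temps != 0]
    data.frame(label = q$label, body_part = q$body_part,
               pixels = length(q$temps), nonzero = length(nz),
               min = if (length(nz)) min(nz) else NA_real_,
               mean = if (length(nz)) mean(nz) else NA_real_,
               max = if (length(nz)) max(nz) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an ROI report as JSON
#'
#' Vertices, pixel counts and nonzero min/mean/max per ROI.
#'
#' @param roiset an [segment()] result.
#' @param path output path.
#' @export
write_roi_report <- function(roiset, path) {
  rep <- lapply(roiset, function(q) {
    nz <- q$temps[q$temps != 0]
    list(label = q$label, body_part = q$body_part, anchors = q$anchors,
         vertices = unname(apply(q$vertices, 1, as.vector, simplify = FALSE)),
         pixels = length(q$temps), nonzero = length(nz),
         min = if (length(nz)) min(nz) else NA,
         mean = if (length(nz)) mean(nz) else NA,
         max = if (length(nz)) max(nz) else NA)
  })
  jsonlite::write_json(unname(rep), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
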