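#' Plan the tiling of a slide region for two-model prediction
#'
#' Splits a region of interest (40x frame) into aligned patch pairs: a
#' 500 x 500 patch at 10x for the semantic model and the co-located
#' 2000 x 2000 rectangle at 40x for the instance model. Each 40x
#' rectangle is sub-tiled into partially overlapping 500 x 500 windows
#' stepping by `500 - 2 * margin`; a margin of `margin` pixels per side
#' is discarded from every sub-window prediction to suppress edge
#' effects, and the retained interiors tile the region with no gaps and
#' no double-assignment. Boundary windows clamp to the region edge and
#' keep their outer rim.
#'
#' @param roi numeric `c(x0, y0, width, height)` at 40x; width and
#'   height must be at least 2000.
#' @param margin discard margin in 40x pixels, `0 <= margin < 250`.
#' @return object of class `"tile_plan"`: list with `roi`, `margin`,
#'   `tiles` (data.frame of 40x tile rectangles and their ownership
#'   rectangles) and `windows` (data.frame of sub-windows with tile id,
#'   window rectangle and effective ownership rectangle, all in global
#'   40x coordinates).
#' @export
plan_tiles <- function(roi, margin = 50) {
  stopifnot(length(roi) == 4)
  if (margin < 0 || margin >= 250)
    stop("margin must lie in [0, 250)", call. = FALSE)
  if (roi[3] < 2000 || roi[4] < 2000)
    stop("region of interest is smaller than one 2000 x 2000 tile at 40x; ",
         "pad the region (e.g. with background) to at least 2000 x 2000",
         call. = FALSE)

  tx <- cover_1d(roi[3], 2000, 0)
  ty <- cover_1d(roi[4], 2000, 0)
  tiles <- expand.grid(ix = seq_len(nrow(tx)), iy = seq_len(nrow(ty)))
  tiles <- data.frame(
    tile = sprintf("t%02d_%02d", tiles$ix, tiles$iy),
    x0 = roi[1] + tx$start[tiles$ix], y0 = roi[2] + ty$start[tiles$iy],
    w = 2000, h = 2000,
    own_x0 = roi[1] + tx$own0[tiles$ix], own_x1 = roi[1] + tx$own1[tiles$ix],
    own_y0 = roi[2] + ty$own0[tiles$iy], own_y1 = roi[2] + ty$own1[tiles$iy],
    stringsAsFactors = FALSE)

  win_list <- lapply(seq_len(nrow(tiles)), function(t) {
    wx <- cover_1d(2000, 500, margin)
    wy <- cover_1d(2000, 500, margin)
    g <- expand.grid(ix = seq_len(nrow(wx)), iy = seq_len(nrow(wy)))
    data.frame(
      tile = tiles$tile[t],
      window = sprintf("%s_w%02d_%02d", tiles$tile[t], g$ix, g$iy),
      x0 = tiles$x0[t] + wx$start[g$ix], y0 = tiles$y0[t] + wy$start[g$iy],
      w = 500, h = 500,
      # effective ownership: within-tile partition clipped by the tile's
      # own ownership rectangle, so the partition holds slide-wide
      own_x0 = pmax(tiles$x0[t] + wx$own0[g$ix], tiles$own_x0[t]),
      own_x1 = pmin(tiles$x0[t] + wx$own1[g$ix], tiles$own_x1[t]),
      own_y0 = pmax(tiles$y0[t] + wy$own0[g$iy], tiles$own_y0[t]),
      own_y1 = pmin(tiles$y0[t] + wy$own1[g$iy], tiles$own_y1[t]),
      stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  structure(list(roi = roi, margin = margin, tiles = tiles,
                 windows = windows),
            class = "tile_plan")
}

# 1-D cover of [0, L) by windows of width w stepping by w - 2m, last
# window clamped to L - w; ownership intervals [own0, own1) partition
# [0, L): interior boundaries sit at the margin line of the next window
cover_1d <- function(L, w, m) {
  step <- w - 2 * m
  starts <- seq(0, L - w, by = step)
  if (max(starts) < L - w) starts <- c(starts, L - w)
  k <- length(starts)
  own0 <- c(0, starts[-1] + m)
  own1 <- c(starts[-1] + m, L)
  data.frame(start = starts, own0 = own0, own1 = own1)
}

#' @export
print.tile_plan <- function(x, ...) {
  cat("tile_plan:", nrow(x$tiles), "tile(s),", nrow(x$windows),
      "sub-window(s), margin", x$margin, "px\n")
  invisible(x)
}

#' Reclassify instance detections by the semantic class under their
#' centroid
#'
#' Combines the two segmentation models: each instance detection keeps
#' its geometry (centroid, area) but takes its final cell class from the
#' semantic label map at its centroid, through the fixed mapping
#' [SEMANTIC_TO_CELL]. The instance model's own class label is ignored.
#' Instances whose centroid falls off the map are dropped and reported.
#'
#' @param instances data.frame with columns `x`, `y` and optionally
#'   `area`, `source_class`.
#' @param map a [semantic_map()].
#' @param slide_id slide identifier for the resulting records.
#' @return a [cell_table()]; dropped instances are reported via a
#'   warning and the `"dropped"` attribute (row indices).
#' @export
reclassify_by_center <- function(instances, map, slide_id = "slide") {
  stopifnot(all(c("x", "y") %in% names(instances)))
  sem <- semantic_class_at(map, instances$x, instances$y)
  off <- which(is.na(sem))
  if (length(off))
    warning(length(off), " instance(s) fell outside the semantic map ",
            "footprint and were dropped", call. = FALSE)
  keep <- !is.na(sem)
  out <- data.frame(x = instances$x[keep], y = instances$y[keep],
                    cell_class = unname(SEMANTIC_TO_CELL[sem[keep]]),
                    area = if ("area" %in% names(instances))
                      instances$area[keep] else NA_real_,
                    is_pseudo = FALSE,
                    slide_id = slide_id)
  out <- cell_table(out)
  attr(out, "dropped") <- off
  out
}

#' Synthesize pseudo-points in background and corneum regions
#'
#' Background and stratum corneum contain no segmentable nuclei, yet the
#' edge-point rules need background/corneum *points* among a nucleus's
#' Delaunay neighbors. This places a hexagonal grid of pseudo-points
#' (marked `is_pseudo = TRUE`) inside the map's BACKGROUND and CORNEUM
#' regions at the given spacing, each carrying its region's class.
#'
#' @param map a [semantic_map()].
#' @param spacing grid spacing in 40x pixels.
#' @param slide_id slide identifier.
#' @param bbox optional `c(x0, y0, x1, y1)` clip rectangle (40x); points
#'   outside it are dropped (used to avoid duplicates across tiles).
#' @return a [cell_table()] of pseudo-points (possibly empty).
#' @export
generate_pseudo_points <- function(map, spacing = 60, slide_id = "slide",
                                   bbox = NULL) {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  W <- ncol(map$labels) * map$scale
  H <- nrow(map$labels) * map$scale
  dy <- spacing * sqrt(3) / 2
  ys <- seq(map$y0 + dy / 2, map$y0 + H - 1e-9, by = dy)
  pts <- lapply(seq_along(ys), function(r) {
    off <- ((r - 1) %% 2) * spacing / 2
    xs <- seq(map$x0 + spacing / 2 + off, map$x0 + W - 1e-9, by = spacing)
    data.frame(x = xs, y = ys[r])
  })
  pts <- do.call(rbind, pts)
  sem <- semantic_class_at(map, pts$x, pts$y)
  keep <- !is.na(sem) & sem %in% c("BACKGROUND", "CORNEUM")
  pts <- pts[keep, , drop = FALSE]
  sem <- sem[keep]
  if (!is.null(bbox) && nrow(pts)) {
    inside <- pts$x >= bbox[1] & pts$x < bbox[3] &
              pts$y >= bbox[2] & pts$y < bbox[4]
    pts <- pts[inside, , drop = FALSE]
    sem <- sem[inside]
  }
  if (!nrow(pts))
    return(cell_table(data.frame(x = numeric(), y = numeric(),
                                 cell_class = character())))
  cell_table(data.frame(x = pts$x, y = pts$y,
                        cell_class = sem,  # BACKGROUND or CORNEUM
                        area = NA_real_, is_pseudo = TRUE,
                        slide_id = slide_id))
}

#' Fuse per-window instance detections and per-tile semantic maps into
#' one slide cell table
#'
#' Applies the overlap bookkeeping of whole-slide prediction: detections
#' from a sub-window's discarded margin are removed, a nucleus detected
#' in several overlapping sub-windows is kept exactly once (owned by the
#' window whose retained interior contains its centroid), surviving
#' detections are reclassified by their tile's semantic map, and
#' pseudo-points are appended for background/corneum regions. Output ids
#' are sequential in (y, x) order.
#'
#' @param plan a [plan_tiles()] result.
#' @param maps named list of [semantic_map()]s, one per plan tile id.
#' @param instances named list of data.frames (columns `x`, `y`,
#'   optional `area`), one per plan window id; windows without
#'   detections may be omitted or `NULL`.
#' @param spacing pseudo-point spacing (40x pixels).
#' @param slide_id slide identifier.
#' @return a [cell_table()] for the slide.
#' @export
fuse_slide <- function(plan, maps, instances, spacing = 60,
                       slide_id = "slide") {
  stopifnot(inherits(plan, "tile_plan"))
  missing_tiles <- setdiff(plan$tiles$tile, names(maps))
  if (length(missing_tiles))
    stop("missing semantic map for tile(s): ",
         paste(missing_tiles, collapse = ", "), call. = FALSE)

  w <- plan$windows
  owned <- lapply(seq_len(nrow(w)), function(k) {
    det <- instances[[w$window[k]]]
    if (is.null(det) || !nrow(det)) return(NULL)
    keep <- det$x >= w$own_x0[k] & det$x < w$own_x1[k] &
            det$y >= w$own_y0[k] & det$y < w$own_y1[k]
    if (!any(keep)) return(NULL)
    cbind(det[keep, c("x", "y", intersect("area", names(det))),
              drop = FALSE],
          tile = w$tile[k])
  })
  owned <- do.call(rbind, owned)

  parts <- list()
  for (t in seq_len(nrow(plan$tiles))) {
    tid <- plan$tiles$tile[t]
    map <- maps[[tid]]
    det_t <- if (!is.null(owned)) owned[owned$tile == tid, , drop = FALSE]
             else NULL
    if (!is.null(det_t) && nrow(det_t))
      parts[[length(parts) + 1L]] <-
        as.data.frame(reclassify_by_center(det_t, map, slide_id = slide_id))
    pseudo <- generate_pseudo_points(
      map, spacing = spacing, slide_id = slide_id,
      bbox = c(plan$tiles$own_x0[t], plan$tiles$own_y0[t],
               plan$tiles$own_x1[t], plan$tiles$own_y1[t]))
    if (nrow(pseudo))
      parts[[length(parts) + 1L]] <- as.data.frame(pseudo)
  }
  if (!length(parts))
    return(cell_table(data.frame(x = numeric(), y = numeric(),
                                 cell_class = character())))
  out <- do.call(rbind, lapply(parts, function(p) p[names(parts[[1]])]))
  out <- out[order(out$y, out$x), , drop = FALSE]
  out$id <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  cell_table(out)
}
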