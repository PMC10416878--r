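#' Cell and tissue-region class vocabularies
#'
#' `CELL_CLASSES` enumerates the six nucleus/point classes used throughout
#' the package. `EPITHELIAL_CLASSES` is the subset that makes up the
#' epithelium proper (basal nuclei, other epithelial nuclei, and
#' intraepithelial lymphocytes). `SEMANTIC_CLASSES` enumerates the five
#' region classes of a semantic label map, and `SEMANTIC_TO_CELL` is the
#' fixed mapping applied when an instance centroid is reclassified by the
#' semantic map under it.
#'
#' @format Character vectors; `SEMANTIC_TO_CELL` is named by semantic class.
#' @export
CELL_CLASSES <- c("BASAL", "EPITHELIAL_OTHER", "LYMPHOCYTE",
                  "STROMA", "CORNEUM", "BACKGROUND")

#' @rdname CELL_CLASSES
#' @export
EPITHELIAL_CLASSES <- c("BASAL", "EPITHELIAL_OTHER", "LYMPHOCYTE")

#' @rdname CELL_CLASSES
#' @export
SEMANTIC_CLASSES <- c("EPI_BASAL", "EPI_OTHER", "CORNEUM",
                      "NON_EPI", "BACKGROUND")

#' @rdname CELL_CLASSES
#' @export
SEMANTIC_TO_CELL <- c(EPI_BASAL  = "BASAL",
                      EPI_OTHER  = "EPITHELIAL_OTHER",
                      CORNEUM    = "CORNEUM",
                      NON_EPI    = "STROMA",
                      BACKGROUND = "BACKGROUND")

# classes that may be carried by synthesized grid points
PSEUDO_CLASSES <- c("BACKGROUND", "CORNEUM")

#' Test whether a cell class is epithelial
#'
#' @param cell_class character vector of cell classes.
#' @return logical vector.
#' @export
is_epithelial <- function(cell_class) cell_class %in% EPITHELIAL_CLASSES

#' Construct and validate a cell table
#'
#' A cell table is a `data.frame` with one row per nucleus (or pseudo-point)
#' and columns `id` (integer, unique), `x`, `y` (pixels at 40x
#' magnification, raster convention: x = column, y = row, 0-based,
#' increasing downward), `cell_class` (one of [CELL_CLASSES]), `area`
#' (pixels^2 at 40x, `NA` when unknown), `is_pseudo` (logical; `TRUE` only
#' for grid points synthesized in background/corneum regions) and
#' `slide_id`.
#'
#' @param df data.frame with at least `x`, `y`, `cell_class`. Missing
#'   `id` is assigned sequentially from 0; missing `area`, `is_pseudo`,
#'   `slide_id` get `NA`, `FALSE`, `"slide"`.
#' @return the validated data.frame with class `"cell_table"`.
#' @export
cell_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("x", "y", "cell_class")) {
    if (!col %in% names(df))
      stop("cell table is missing mandatory column '", col, "'", call. = FALSE)
  }
  n <- nrow(df)
  if (!"id" %in% names(df)) df$id <- seq_len(n) - 1L
  if (!"area" %in% names(df)) df$area <- rep(NA_real_, n)
  if (!"is_pseudo" %in% names(df)) df$is_pseudo <- rep(FALSE, n)
  if (!"slide_id" %in% names(df)) df$slide_id <- rep("slide", n)
  df <- df[, c("id", "x", "y", "cell_class", "area", "is_pseudo", "slide_id")]
  df$id <- as.integer(df$id)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$area <- as.numeric(df$area)
  df$is_pseudo <- as.logical(df$is_pseudo)
  df$slide_id <- as.character(df$slide_id)
  validate_cell_table(df)
  class(df) <- c("cell_table", "data.frame")
  df
}

validate_cell_table <- function(df) {
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("unparseable coordinate in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$x < 0) || any(df$y < 0))
    stop("coordinates must be non-negative", call. = FALSE)
  unknown <- setdiff(unique(df$cell_class), CELL_CLASSES)
  if (length(unknown))
    stop("unknown cell class label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("cell ids must be unique within a slide", call. = FALSE)
  if (any(!is.na(df$area) & df$area <= 0))
    stop("area must be positive when present", call. = FALSE)
  if (any(df$is_pseudo & !df$cell_class %in% PSEUDO_CLASSES))
    stop("is_pseudo = TRUE is only allowed for BACKGROUND/CORNEUM points",
         call. = FALSE)
  invisible(df)
}

#' Read a cell table from CSV
#'
#' Reads one-nucleus-per-row CSV output of a segmentation pipeline. A
#' `dialect` adapts foreign column names and class labels so external
#' spreadsheets can be ingested without rewriting them. Invalid class
#' labels and unparseable coordinates are rejected, never coerced.
#'
#' @param path CSV file with a header.
#' @param dialect optional list with elements `columns` (named character;
#'   canonical name -> file column name) and `classes` (named character;
#'   file class label -> canonical [CELL_CLASSES] value).
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- dialect$columns
  if (!is.null(cols)) {
    for (canon in names(cols)) {
      src <- cols[[canon]]
      if (!src %in% names(raw))
        stop("cell table '", path, "' is missing mandatory column '",
             src, "'", call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  for (col in c("x", "y", "cell_class")) {
    if (!col %in% names(raw))
      stop("cell table '", path, "' is missing mandatory column '",
           col, "'", call. = FALSE)
  }
  suppressWarnings({
    xs <- as.numeric(raw$x)
    ys <- as.numeric(raw$y)
  })
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop("unparseable coordinate in row(s) ",
         paste(bad, collapse = ", "), " of '", path, "'", call. = FALSE)
  raw$x <- xs
  raw$y <- ys
  if (!is.null(dialect$classes)) {
    cls <- as.character(raw$cell_class)
    known <- cls %in% names(dialect$classes)
    if (any(!known))
      stop("unknown cell class label(s): ",
           paste(unique(cls[!known]), collapse = ", "), call. = FALSE)
    raw$cell_class <- unname(dialect$classes[cls])
  }
  cell_table(raw)
}

#' Write a cell table to CSV
#'
#' @param cells a [cell_table()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a semantic label map
#'
#' A semantic map is a label grid at 10x magnification, anchored in the
#' 40x coordinate frame: 40x point (x, y) falls in grid cell
#' `(floor((y - y0)/scale) + 1, floor((x - x0)/scale) + 1)` (row, col,
#' 1-based R indexing of the underlying matrix).
#'
#' @param labels character matrix with values from [SEMANTIC_CLASSES].
#' @param x0,y0 origin offset of the grid in 40x pixels.
#' @param scale linear scale factor between 40x and grid pixels (4).
#' @return an object of class `"semantic_map"`.
#' @export
semantic_map <- function(labels, x0 = 0, y0 = 0, scale = 4) {
  if (!is.matrix(labels))
    stop("labels must be a matrix", call. = FALSE)
  labels <- matrix(as.character(labels), nrow(labels), ncol(labels))
  unknown <- setdiff(unique(as.vector(labels)), SEMANTIC_CLASSES)
  if (length(unknown))
    stop("unknown semantic class label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, x0 = x0, y0 = y0, scale = scale),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  cat("semantic_map: ", nrow(x$labels), " x ", ncol(x$labels),
      " at scale ", x$scale, ", origin (", x$x0, ", ", x$y0, ")\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Look up semantic classes at 40x coordinates
#'
#' @param map a [semantic_map()].
#' @param x,y numeric vectors of 40x coordinates.
#' @return character vector of semantic classes; `NA` for points outside
#'   the map footprint.
#' @export
semantic_class_at <- function(map, x, y) {
  row <- floor((y - map$y0) / map$scale) + 1
  col <- floor((x - map$x0) / map$scale) + 1
  inside <- row >= 1 & row <= nrow(map$labels) &
            col >= 1 & col <= ncol(map$labels)
  out <- rep(NA_character_, length(x))
  out[inside] <- map$labels[cbind(row[inside], col[inside])]
  out
}

#' Read/write a semantic label map (single-channel PNG + JSON sidecar)
#'
#' The PNG stores integer palette codes; the sidecar
#' (`<path>.json`) records `{x0, y0, scale, palette}` where `palette`
#' maps code -> semantic class. Any pixel value outside the palette is an
#' error, never silently defaulted.
#'
#' @param path PNG file path (sidecar at `paste0(path, ".json")`).
#' @param palette named character vector (names = integer codes as
#'   strings, values = semantic classes); read from the sidecar when
#'   omitted.
#' @param x0,y0,scale override the sidecar geometry if given.
#' @return a [semantic_map()].
#' @export
read_semantic_map <- function(path, palette = NULL,
                              x0 = NULL, y0 = NULL, scale = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(palette)) {
    if (is.null(meta$palette))
      stop("no palette given and no sidecar found for '", path, "'",
           call. = FALSE)
    palette <- unlist(meta$palette)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  codes <- round(img * 255)
  seen <- sort(unique(as.vector(codes)))
  missing <- setdiff(as.character(seen), names(palette))
  if (length(missing))
    stop("label image '", path, "' contains pixel value(s) ",
         paste(missing, collapse = ", "), " outside the palette",
         call. = FALSE)
  labels <- matrix(unname(palette[as.character(codes)]),
                   nrow(codes), ncol(codes))
  semantic_map(labels,
               x0 = x0 %||% meta$x0 %||% 0,
               y0 = y0 %||% meta$y0 %||% 0,
               scale = scale %||% meta$scale %||% 4)
}

#' @param map a [semantic_map()] to write.
#' @param palette for writing: named character vector code -> class
#'   covering every class present in the map.
#' @rdname read_semantic_map
#' @export
write_semantic_map <- function(map, path, palette = NULL) {
  if (is.null(palette)) {
    classes <- sort(unique(as.vector(map$labels)))
    palette <- stats::setNames(classes, as.character(seq_along(classes) - 1L))
  }
  inv <- stats::setNames(as.integer(names(palette)), unname(palette))
  missing <- setdiff(unique(as.vector(map$labels)), names(inv))
  if (length(missing))
    stop("palette does not cover class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  codes <- matrix(inv[as.vector(map$labels)],
                  nrow(map$labels), ncol(map$labels))
  png::writePNG(codes / 255, path)
  jsonlite::write_json(
    list(x0 = map$x0, y0 = map$y0, scale = map$scale,
         palette = as.list(palette)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-slide layer-count result
#'
#' Holds the per-node layer counts recorded at inner-edge nuclei, the ids
#' of inner-edge nuclei the peeling wave never reached, and the slide
#' summary (median, population SD, number of counted nuclei).
#'
#' @param counts data.frame with columns `id`, `layer_count`.
#' @param unreachable_ids integer vector of unreached inner-edge node ids.
#' @param quantile quantile used for the slide summary (0.5 = median).
#' @return object of class `"layer_result"` with fields `counts`,
#'   `unreachable_ids`, `median_layers`, `sd_layers`, `n_inner`.
#' @export
layer_result <- function(counts, unreachable_ids = integer(),
                         quantile = 0.5) {
  stopifnot(is.data.frame(counts),
            all(c("id", "layer_count") %in% names(counts)))
  if (nrow(counts) && (any(counts$layer_count < 1) ||
                       any(counts$layer_count != round(counts$layer_count))))
    stop("layer counts must be positive integers", call. = FALSE)
  counts$id <- as.integer(counts$id)
  counts$layer_count <- as.integer(counts$layer_count)
  s <- summarize_counts(counts$layer_count, quantile)
  structure(list(counts = counts,
                 unreachable_ids = as.integer(unreachable_ids),
                 median_layers = s$center,
                 sd_layers = s$sd,
                 n_inner = nrow(counts)),
            class = "layer_result")
}

# quantile (type 7, linear interpolation) + population SD
summarize_counts <- function(x, quantile = 0.5) {
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  if (!length(x)) return(list(center = NA_real_, sd = NA_real_))
  center <- unname(stats::quantile(x, probs = quantile, type = 7))
  list(center = center, sd = sqrt(mean((x - mean(x))^2)))
}

#' @export
print.layer_result <- function(x, ...) {
  cat("layer_result: n_inner =", x$n_inner,
      " median =", x$median_layers,
      " sd =", round(x$sd_layers, 3),
      " unreachable =", length(x$unreachable_ids), "\n")
  invisible(x)
}

#' Write/read a layer-count result (CSV + JSON sidecar)
#'
#' The CSV holds the per-node counts (`id,layer_count`); the sidecar
#' (`<path>.json`) holds `{median_layers, sd_layers, n_inner,
#' n_unreachable, unreachable_ids}`. Integer counts round-trip exactly.
#'
#' @param result a [layer_result()].
#' @param path output CSV path.
#' @export
write_layer_result <- function(result, path) {
  utils::write.csv(result$counts, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(median_layers = result$median_layers,
         sd_layers = result$sd_layers,
         n_inner = result$n_inner,
         n_unreachable = length(result$unreachable_ids),
         unreachable_ids = as.list(result$unreachable_ids)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(path)
}

#' @rdname write_layer_result
#' @export
read_layer_result <- function(path) {
  counts <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  res <- layer_result(counts,
                      unreachable_ids = unlist(meta$unreachable_ids) %||%
                        integer())
  res
}
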