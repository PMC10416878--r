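#' Specification of a synthetic epithelium point pattern
#'
#' Describes a layered epithelial point pattern with known ground-truth
#' layer number, used as the package's test and demonstration substrate.
#' Two geometries are supported: a horizontal `strip` (background and
#' stratum corneum above, K epithelial cell rows, stroma beneath, stroma
#' "caps" flanking the cut ends) and an `annulus` (stroma core, K
#' epithelial rings, corneum and background outside).
#'
#' @param geometry `"strip"` or `"annulus"`.
#' @param n_layers K, the true number of epithelial cell layers (>= 1).
#' @param cell_spacing lattice spacing in 40x pixels (nucleus scale).
#' @param jitter_sd Gaussian positional noise SD in 40x pixels.
#' @param length strip geometry: number of cells along the strip.
#' @param cracks strip geometry: list of cracks, each
#'   `list(x = <offset px from strip start>, width = <px>,
#'   depth = <fraction of layers removed, from the outer side>)`.
#'   Cells inside the crack rectangle are deleted.
#' @param stroma_rows,corneum_rows,background_rows zonation band depths
#'   (rows of points) below/above the epithelium.
#' @param cap_cols strip geometry: columns of flanking stroma at each
#'   cut end (lateral connective tissue; keeps the section boundary from
#'   touching the epithelium).
#' @param lymphocyte_fraction fraction of epithelial cells replaced by
#'   intraepithelial lymphocytes, in `[0, 1)`.
#' @param slide_id slide identifier stamped on the cells.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return validated list of class `"epithelium_spec"`.
#' @export
epithelium_spec <- function(geometry = c("strip", "annulus"),
                            n_layers = 5,
                            cell_spacing = 60,
                            jitter_sd = 0,
                            length = 40,
                            cracks = list(),
                            stroma_rows = 3,
                            corneum_rows = 2,
                            background_rows = 2,
                            cap_cols = 2,
                            lymphocyte_fraction = 0,
                            slide_id = "synthetic",
                            seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_layers < 1 || n_layers != round(n_layers))
    stop("n_layers must be a positive integer", call. = FALSE)
  if (cell_spacing <= 0) stop("cell_spacing must be positive", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be non-negative", call. = FALSE)
  if (length < 2) stop("length must be at least 2 cells", call. = FALSE)
  if (lymphocyte_fraction < 0 || lymphocyte_fraction >= 1)
    stop("lymphocyte_fraction must lie in [0, 1)", call. = FALSE)
  if (stroma_rows < 2 || corneum_rows < 2 || background_rows < 1)
    stop("need >= 2 stroma rows, >= 2 corneum rows, >= 1 background row",
         call. = FALSE)
  for (cr in cracks) {
    if (is.null(cr$x) || is.null(cr$width) ||
        cr$width < 0 || (cr$depth %||% 1) <= 0 || (cr$depth %||% 1) > 1)
      stop("each crack needs x, width >= 0 and depth in (0, 1]",
           call. = FALSE)
  }
  structure(list(geometry = geometry, n_layers = as.integer(n_layers),
                 cell_spacing = cell_spacing, jitter_sd = jitter_sd,
                 length = as.integer(length), cracks = cracks,
                 stroma_rows = as.integer(stroma_rows),
                 corneum_rows = as.integer(corneum_rows),
                 background_rows = as.integer(background_rows),
                 cap_cols = as.integer(cap_cols),
                 lymphocyte_fraction = lymphocyte_fraction,
                 slide_id = slide_id, seed = as.integer(seed)),
            class = "epithelium_spec")
}

# strip row layout: classes from top (y smallest) to bottom and the
# per-row y positions; row pitch is the hex value spacing * sqrt(3)/2
strip_layout <- function(spec) {
  a <- spec$cell_spacing
  dy <- a * sqrt(3) / 2
  classes <- c(rep("BACKGROUND", spec$background_rows),
               rep("CORNEUM", spec$corneum_rows),
               rep("EPITHELIAL_OTHER", spec$n_layers - 1L),
               "BASAL",
               rep("STROMA", spec$stroma_rows))
  n_rows <- length(classes)
  x_margin <- (spec$cap_cols + 1) * a
  y_margin <- a
  list(a = a, dy = dy, classes = classes, n_rows = n_rows,
       x_margin = x_margin, y_margin = y_margin,
       row_y = y_margin + (seq_len(n_rows) - 1) * dy,
       epi_top_row = spec$background_rows + spec$corneum_rows + 1L,
       epi_bottom_row = spec$background_rows + spec$corneum_rows +
         spec$n_layers)
}

#' Generate a synthetic epithelium cell table with known layer number
#'
#' Builds the point pattern described by an [epithelium_spec()]:
#' a hexagonal-offset lattice for strips (row pitch `spacing * sqrt(3)/2`)
#' or concentric rings for annuli (ring pitch equal to the azimuthal
#' spacing). Epithelial rows/rings carry `EPITHELIAL_OTHER` with the
#' stroma-facing row/ring replaced by `BASAL`; corneum and background
#' points are emitted as pseudo-points. Positions receive Gaussian
#' jitter, cracks delete epithelial cells in rectangular bands, and a
#' fraction of epithelial cells may be relabeled `LYMPHOCYTE`.
#' Deterministic for a fixed spec (byte-identical tables).
#'
#' @param spec an [epithelium_spec()].
#' @return list with `cells` (a [cell_table()]) and `k` (true layer
#'   number).
#' @export
generate_epithelium <- function(spec) {
  stopifnot(inherits(spec, "epithelium_spec"))
  with_seed(spec$seed, {
    df <- if (spec$geometry == "strip") strip_points(spec)
          else annulus_points(spec)
    epi <- is_epithelial(df$cell_class)
    if (spec$lymphocyte_fraction > 0) {
      idx <- which(epi)
      k <- floor(spec$lymphocyte_fraction * length(idx))
      if (k > 0)
        df$cell_class[sample(idx, k)] <- "LYMPHOCYTE"
    }
    if (spec$jitter_sd > 0) {
      df$x <- df$x + stats::rnorm(nrow(df), 0, spec$jitter_sd)
      df$y <- df$y + stats::rnorm(nrow(df), 0, spec$jitter_sd)
    }
    df$x <- pmax(df$x, 0)
    df$y <- pmax(df$y, 0)
    df$id <- seq_len(nrow(df)) - 1L
    df$slide_id <- spec$slide_id
    list(cells = cell_table(df), k = spec$n_layers)
  })
}

strip_points <- function(spec) {
  lay <- strip_layout(spec)
  a <- lay$a
  rows <- list()
  for (r in seq_len(lay$n_rows)) {
    offset <- ((r - 1) %% 2) * a / 2
    cls <- lay$classes[r]
    cols <- 0:(spec$length - 1)
    # stroma caps flank the epithelial and stroma rows at both cut ends
    if (cls %in% c("BASAL", "EPITHELIAL_OTHER", "STROMA") &&
        spec$cap_cols > 0) {
      capL <- data.frame(x = lay$x_margin + (-(spec$cap_cols:1)) * a + offset,
                         y = lay$row_y[r], cell_class = "STROMA",
                         is_pseudo = FALSE)
      capR <- data.frame(x = lay$x_margin +
                           (spec$length:(spec$length + spec$cap_cols - 1)) *
                           a + offset,
                         y = lay$row_y[r], cell_class = "STROMA",
                         is_pseudo = FALSE)
    } else capL <- capR <- NULL
    body <- data.frame(x = lay$x_margin + cols * a + offset,
                       y = lay$row_y[r], cell_class = cls,
                       is_pseudo = cls %in% PSEUDO_CLASSES)
    rows[[r]] <- rbind(capL, body, capR)
  }
  df <- do.call(rbind, rows)
  # cracks: axis-aligned deletions of epithelial cells, entering from the
  # outer (corneum-facing) side down to depth * K layers
  for (cr in spec$cracks) {
    depth_rows <- ceiling((cr$depth %||% 1) * spec$n_layers)
    y_lo <- lay$row_y[lay$epi_top_row] - lay$dy / 2
    y_hi <- lay$row_y[lay$epi_top_row + depth_rows - 1L] + lay$dy / 2
    x_lo <- lay$x_margin + cr$x
    hit <- is_epithelial(df$cell_class) &
      df$x >= x_lo & df$x < x_lo + cr$width &
      df$y >= y_lo & df$y < y_hi
    df <- df[!hit, , drop = FALSE]
  }
  df$area <- NA_real_
  df
}

annulus_points <- function(spec) {
  a <- spec$cell_spacing
  # radial pitch equals the azimuthal spacing: with this square-ish local
  # lattice a Delaunay edge can never skip a ring, so ring adjacency (and
  # hence hop counts) is exact
  n_in <- spec$stroma_rows
  classes <- c(rep("STROMA", n_in),
               "BASAL",
               rep("EPITHELIAL_OTHER", spec$n_layers - 1L),
               rep("CORNEUM", spec$corneum_rows),
               rep("BACKGROUND", spec$background_rows))
  r0 <- 2 * a  # hollow center keeps innermost ring populated
  center <- r0 + (n_in + spec$n_layers + spec$corneum_rows +
                    spec$background_rows) * a + a
  rings <- lapply(seq_along(classes), function(k) {
    r <- r0 + (k - 1) * a
    m <- max(6L, round(2 * pi * r / a))
    theta <- 2 * pi * (seq_len(m) - 1) / m + (k - 1) * 0.35
    data.frame(x = center + r * cos(theta),
               y = center + r * sin(theta),
               cell_class = classes[k],
               is_pseudo = classes[k] %in% PSEUDO_CLASSES)
  })
  df <- do.call(rbind, rings)
  df$area <- NA_real_
  df
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of slides with group-dependent epithelial
#' thickness and thickness-dependent progression-free interval (PFI).
#' PFI times are exponential with log-hazard
#' `intercept + beta * median_layers`; censoring is independent uniform,
#' calibrated per subject so the marginal censoring probability equals
#' `censor_rate`.
#'
#' @param groups list of groups, each
#'   `list(label =, n =, mean_k =, sd_k =)`; the default mirrors a
#'   three-stage dysplasia cohort of 45/82/8 slides.
#' @param beta log-hazard increment per epithelial layer.
#' @param intercept baseline log-hazard (per day).
#' @param censor_rate target probability of censoring, in `[0, 1)`.
#' @param seed RNG seed.
#' @return validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups = list(
                          list(label = "hyperkeratosis_hyperplasia",
                               n = 45, mean_k = 8,  sd_k = 2),
                          list(label = "mild_moderate",
                               n = 82, mean_k = 11, sd_k = 2),
                          list(label = "severe_carcinoma",
                               n = 8,  mean_k = 15, sd_k = 2)),
                        beta = 0.15,
                        intercept = -7.5,
                        censor_rate = 0.3,
                        seed = 1L) {
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1 ||
        is.null(g$mean_k) || is.null(g$sd_k) || g$sd_k < 0)
      stop("each group needs label, n >= 1, mean_k, sd_k >= 0",
           call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  structure(list(groups = groups, beta = beta, intercept = intercept,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws per-slide summary statistics from the group thickness
#' distributions (medians rounded to the half-integer grid that medians
#' of integer layer counts live on) and simulates exponential PFI with
#' the spec's log-hazard. Deterministic per seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `slide_id`, `median_layers`,
#'   `sd_layers`, `diagnosis_group`, `pfi_time` (days), `pfi_event`
#'   (0/1).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(spec$groups, function(g) {
      med <- pmax(1, round(stats::rnorm(g$n, g$mean_k, g$sd_k) * 2) / 2)
      data.frame(median_layers = med,
                 sd_layers = abs(stats::rnorm(g$n, 0.12 * med + 0.5, 0.3)),
                 diagnosis_group = g$label)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df <- data.frame(slide_id = sprintf("S%03d", seq_len(n)), df)
    lambda <- exp(spec$intercept + spec$beta * df$median_layers)
    t_event <- stats::rexp(n, rate = lambda)
    if (spec$censor_rate > 0) {
      umax <- vapply(lambda, censor_upper, numeric(1),
                     target = spec$censor_rate)
      t_cens <- stats::runif(n, 0, umax)
      df$pfi_time <- pmin(t_event, t_cens)
      df$pfi_event <- as.integer(t_event <= t_cens)
    } else {
      df$pfi_time <- t_event
      df$pfi_event <- 1L
    }
    df$pfi_time <- pmax(df$pfi_time, 1e-6)
    rownames(df) <- NULL
    df
  })
}

# upper bound u of Uniform(0, u) censoring such that
# P(C < T) = (1 - exp(-lambda u)) / (lambda u) equals `target`
censor_upper <- function(lambda, target) {
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - target
  lo <- 1e-8 / lambda
  hi <- 1e6 / lambda
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a semantic-map + instance fixture for the fusion stage
#'
#' Rasterizes the zonation of a strip [epithelium_spec()] into a 10x
#' semantic label map covering a 2000 x 2000 region at 40x (one canonical
#' tile) and emits the real nuclei (epithelial, stroma and cap cells) as
#' instance detections. Running [plan_tiles()] + [fuse_slide()] on this
#' fixture, then [count_layers()], recovers the spec's layer number.
#'
#' @param spec a strip [epithelium_spec()]; `length` is clamped so the
#'   strip fits the 2000 px tile.
#' @param empty_epithelium if `TRUE`, the epithelial band and instances
#'   are removed (degenerate no-epithelium scene).
#' @return list with `map` (a [semantic_map()]), `instances`
#'   (data.frame `x`, `y`, `area`, `source_class`), `cells` (the
#'   underlying generated [cell_table()]) and `k`.
#' @export
generate_semantic_fixture <- function(spec, empty_epithelium = FALSE) {
  stopifnot(inherits(spec, "epithelium_spec"))
  if (spec$geometry != "strip")
    stop("semantic fixtures are only defined for strip geometry",
         call. = FALSE)
  a <- spec$cell_spacing
  max_len <- floor((2000 - (2 * spec$cap_cols + 2) * a) / a)
  if (spec$length > max_len) {
    spec$length <- as.integer(max_len)
  }
  gen <- generate_epithelium(spec)
  lay <- strip_layout(spec)

  scale <- 4
  n10 <- 2000 / scale
  grid_y <- (seq_len(n10) - 0.5) * scale   # 40x center of each 10x row
  grid_x <- (seq_len(n10) - 0.5) * scale
  corneum_top <- lay$row_y[spec$background_rows + 1L] - lay$dy / 2
  epi_top <- lay$row_y[lay$epi_top_row] - lay$dy / 2
  basal_top <- lay$row_y[lay$epi_bottom_row] - lay$dy / 2
  stroma_top <- lay$row_y[lay$epi_bottom_row] + lay$dy / 2

  band <- cut(grid_y,
              breaks = c(-Inf, corneum_top, epi_top, basal_top,
                         stroma_top, Inf),
              labels = c("BACKGROUND", "CORNEUM", "EPI_OTHER",
                         "EPI_BASAL", "NON_EPI"),
              right = FALSE)
  labels <- matrix(as.character(band), nrow = n10, ncol = n10)
  # flanking caps: epithelial bands give way to connective tissue at the
  # cut ends, so cap nuclei reclassify as stroma
  x_cut_lo <- lay$x_margin - a / 4
  x_cut_hi <- lay$x_margin + (spec$length - 1) * a + 3 * a / 4
  epi_rows10 <- which(grid_y >= epi_top & grid_y < stroma_top)
  cap_cols10 <- which(grid_x < x_cut_lo | grid_x >= x_cut_hi)
  labels[epi_rows10, cap_cols10] <- "NON_EPI"
  if (empty_epithelium)
    labels[epi_rows10, ] <- "NON_EPI"
  map <- semantic_map(labels, x0 = 0, y0 = 0, scale = scale)

  cells <- gen$cells
  real <- cells[!cells$is_pseudo, , drop = FALSE]
  if (empty_epithelium)
    real <- real[!is_epithelial(real$cell_class), , drop = FALSE]
  instances <- data.frame(x = real$x, y = real$y,
                          area = pi * (a / 4)^2,
                          source_class = "nucleus")
  list(map = map, instances = instances, cells = cells, k = gen$k)
}

#' Split a flat instance table into per-window detection lists
#'
#' Emulates per-window instance-model output: every detection whose
#' centroid falls inside a sub-window's full rectangle is reported by
#' that window, so nuclei in overlap zones are detected multiple times
#' (the duplicates [fuse_slide()] must resolve).
#'
#' @param instances data.frame with `x`, `y` (plus extra columns).
#' @param plan a [plan_tiles()] result.
#' @return named list of data.frames keyed by plan window id.
#' @export
split_instances_by_window <- function(instances, plan) {
  w <- plan$windows
  out <- lapply(seq_len(nrow(w)), function(k) {
    hit <- instances$x >= w$x0[k] & instances$x < w$x0[k] + w$w[k] &
           instances$y >= w$y0[k] & instances$y < w$y0[k] + w$h[k]
    instances[hit, , drop = FALSE]
  })
  names(out) <- w$window
  out
}
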