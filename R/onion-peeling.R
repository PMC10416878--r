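#' Node roles assigned by edge-point classification
#'
#' @format character vector of the six roles.
#' @export
EDGE_ROLES <- c("OUTER_EDGE", "INNER_EDGE", "BOTH", "INTERIOR",
                "NON_EDGE", "NON_EPITHELIAL")

#' Classify inner and outer epithelial edge points
#'
#' An epithelial nucleus with a background or corneum point among its
#' graph neighbors is an outside edge point; one with a stroma nucleus
#' among its neighbors is an inside edge point; one satisfying both
#' conditions is `BOTH`; one satisfying neither is `INTERIOR`.
#' Stroma, corneum and background nodes themselves are `NON_EPITHELIAL`
#' and only ever serve as classification context.
#'
#' @param graph a pruned `cell_graph` (see [prune_long_edges()]).
#' @return character vector of roles (one of [EDGE_ROLES]) per node, in
#'   node-table order.
#' @export
classify_edge_points <- function(graph) {
  cls <- graph$cells$cell_class
  n <- length(cls)
  epi <- is_epithelial(cls)
  outer_ctx <- cls %in% c("BACKGROUND", "CORNEUM")
  inner_ctx <- cls == "STROMA"
  has_outer <- has_inner <- rep(FALSE, n)
  e <- graph$edges
  if (nrow(e)) {
    ends <- c(e$i, e$j)
    nbrs <- c(e$j, e$i)
    touch <- function(ctx) {
      hit <- ctx[nbrs]
      as.logical(tapply(hit, factor(ends, levels = seq_len(n)), any,
                        default = FALSE))
    }
    has_outer <- touch(outer_ctx)
    has_inner <- touch(inner_ctx)
  }
  roles <- rep("NON_EPITHELIAL", n)
  roles[epi] <- "INTERIOR"
  roles[epi & has_outer & !has_inner] <- "OUTER_EDGE"
  roles[epi & !has_outer & has_inner] <- "INNER_EDGE"
  roles[epi & has_outer & has_inner] <- "BOTH"
  roles
}

#' Re-label small epithelial fragments as non-edge
#'
#' Connected components of the epithelial induced subgraph with fewer
#' than `min_component_size` cells (small connective cell areas, crack
#' debris) have all their nodes re-categorized as `NON_EDGE`, so they
#' contribute neither seeds nor layer counts. A component of exactly
#' `min_component_size` cells is retained.
#'
#' @param graph a pruned `cell_graph`.
#' @param labeling roles from [classify_edge_points()].
#' @param min_component_size minimum epithelial component size (cells).
#' @return the updated role vector.
#' @export
filter_small_components <- function(graph, labeling,
                                    min_component_size = 20) {
  if (!is.numeric(min_component_size) || min_component_size < 1)
    stop("min_component_size must be a positive integer", call. = FALSE)
  comps <- graph_components(graph, is_epithelial(graph$cells$cell_class))
  for (comp in comps) {
    if (length(comp) < min_component_size)
      labeling[comp] <- "NON_EDGE"
  }
  labeling
}

#' Peel the epithelium layer by layer and count layers
#'
#' Runs the wave-front peeling over the epithelial subgraph: all outside
#' edge points form layer 1; each breadth-synchronous expansion step
#' visits the not-yet-visited epithelial neighbors of the whole current
#' layer and increments the layer index; when an inside edge point is
#' first reached, the current layer index is recorded as its layer
#' count. Nodes that are simultaneously outside and inside edge points
#' (`BOTH`; a one-cell-thick epithelium) count as layer 1. The recorded
#' count equals 1 + the minimum hop distance from the outer seed set
#' within the epithelial subgraph. Inside edge points in components
#' without any outer seed are never reached and are reported in
#' `unreachable_ids`, excluded from the summary.
#'
#' @param graph a pruned `cell_graph`.
#' @param labeling roles, after [filter_small_components()].
#' @param quantile quantile used for the slide summary (default median).
#' @return a [layer_result()].
#' @export
peel_layers <- function(graph, labeling, quantile = 0.5) {
  stopifnot(length(labeling) == nrow(graph$cells))
  seeds <- which(labeling %in% c("OUTER_EDGE", "BOTH"))
  targets <- which(labeling %in% c("INNER_EDGE", "BOTH"))
  if (!length(targets)) stop("no inner boundary found", call. = FALSE)
  if (!length(seeds)) stop("no outer boundary found", call. = FALSE)
  traversable <- is_epithelial(graph$cells$cell_class)
  adj <- adjacency_list(graph)
  n <- nrow(graph$cells)
  visited <- rep(FALSE, n)
  layer_of <- rep(NA_integer_, n)
  wave <- seeds
  layer <- 1L
  while (length(wave)) {
    visited[wave] <- TRUE
    layer_of[wave] <- layer
    nxt <- unique(unlist(adj[wave], use.names = FALSE))
    nxt <- nxt[traversable[nxt] & !visited[nxt]]
    wave <- nxt
    layer <- layer + 1L
  }
  reached <- targets[visited[targets]]
  unreachable <- targets[!visited[targets]]
  counts <- data.frame(id = graph$cells$id[reached],
                       layer_count = layer_of[reached])
  counts <- counts[order(counts$id), , drop = FALSE]
  rownames(counts) <- NULL
  layer_result(counts,
               unreachable_ids = graph$cells$id[unreachable],
               quantile = quantile)
}

#' Summarize a layer-count result at a given quantile
#'
#' Recomputes the slide summary of an existing result: the layer-count
#' quantile (type-7 linear interpolation; 0.5 gives the median used as
#' the slide's epithelial thickness) and the population standard
#' deviation over reached inner-edge counts.
#'
#' @param result a [layer_result()].
#' @param quantile summary quantile in (0, 1).
#' @return list with `median_layers`, `sd_layers`, `n_inner`.
#' @export
summarize_slide <- function(result, quantile = 0.5) {
  s <- summarize_counts(result$counts$layer_count, quantile)
  if (!nrow(result$counts))
    warning("no reached inner-edge nuclei; summary is NA", call. = FALSE)
  list(median_layers = s$center, sd_layers = s$sd,
       n_inner = nrow(result$counts))
}

#' Count epithelium layers from a cell table (full per-slide pipeline)
#'
#' Convenience wrapper running the whole per-slide chain: Delaunay
#' neighbor graph, long-edge pruning, inner/outer edge-point
#' classification, small-fragment filtering, and wave-front peeling.
#'
#' @param cells a [cell_table()] (or data.frame coercible to one).
#' @param max_edge_len neighbor-edge length threshold (40x pixels).
#' @param min_component_size minimum epithelial fragment size (cells).
#' @param quantile slide-summary quantile.
#' @return a [layer_result()].
#' @examples
#' spec <- epithelium_spec(n_layers = 5, length = 20, seed = 1)
#' res <- count_layers(generate_epithelium(spec)$cells)
#' res$median_layers
#' @export
count_layers <- function(cells, max_edge_len = 500,
                         min_component_size = 20, quantile = 0.5) {
  graph <- build_delaunay_graph(cells)
  graph <- prune_long_edges(graph, max_edge_len)
  roles <- classify_edge_points(graph)
  roles <- filter_small_components(graph, roles, min_component_size)
  peel_layers(graph, roles, quantile = quantile)
}
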