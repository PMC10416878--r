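#' Build the Delaunay neighbor graph over a cell table
#'
#' Nuclei become graph nodes and every unique edge of the Delaunay
#' triangulation of their centroids becomes an undirected neighbor edge,
#' so that all line-connected points are neighboring cells. Exactly
#' co-located centroids (which make the triangulation degenerate) are
#' perturbed by a deterministic, seeded jitter of `eps` pixels before
#' triangulating; the original coordinates are retained on the nodes.
#'
#' @param cells a [cell_table()] with at least 3 non-collinear points.
#' @param eps jitter magnitude (40x pixels) applied to duplicated
#'   coordinates only.
#' @param jitter_seed seed for the degeneracy jitter; fixed so graph
#'   construction is reproducible.
#' @return object of class `"cell_graph"`: list with `cells` (the node
#'   table) and `edges` (data.frame `i`, `j`, `length`; `i`/`j` are
#'   1-based row indices into `cells`, `i < j`, lengths in 40x pixels).
#' @export
build_delaunay_graph <- function(cells, eps = 1e-6, jitter_seed = 8191L) {
  cells <- if (inherits(cells, "cell_table")) cells else cell_table(cells)
  n <- nrow(cells)
  if (n < 3) stop("triangulation undefined: fewer than 3 points",
                  call. = FALSE)
  x <- cells$x
  y <- cells$y
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    jit <- with_seed(jitter_seed, {
      k <- sum(dup)
      cbind(stats::runif(k, -eps, eps), stats::runif(k, -eps, eps))
    })
    x[dup] <- x[dup] + jit[, 1]
    y[dup] <- y[dup] + jit[, 2]
  }
  if (all_collinear(x, y))
    stop("triangulation undefined: all points are collinear", call. = FALSE)
  tri <- deldir::deldir(x, y, round = FALSE)
  i <- pmin(tri$delsgs$ind1, tri$delsgs$ind2)
  j <- pmax(tri$delsgs$ind1, tri$delsgs$ind2)
  keep <- !duplicated(cbind(i, j)) & i != j
  i <- i[keep]; j <- j[keep]
  len <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
  structure(list(cells = cells,
                 edges = data.frame(i = i, j = j, length = len)),
            class = "cell_graph")
}

all_collinear <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  max(abs(dx * dy[2] - dy * dx[2])) < 1e-9 * max(1, max(abs(dx)), max(abs(dy)))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("cell_graph:", nrow(x$cells), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Remove neighbor edges longer than a threshold
#'
#' Drops graph edges whose Euclidean length strictly exceeds
#' `max_edge_len` (default 500 pixels at 40x), so that points more than
#' 500 pixels apart are not treated as neighboring cells. An edge of
#' exactly `max_edge_len` is retained. Idempotent; nodes untouched.
#'
#' @param graph a `cell_graph`.
#' @param max_edge_len length threshold in 40x pixels.
#' @return the pruned `cell_graph`.
#' @export
prune_long_edges <- function(graph, max_edge_len = 500) {
  if (!is.numeric(max_edge_len) || max_edge_len <= 0)
    stop("max_edge_len must be positive", call. = FALSE)
  graph$edges <- graph$edges[graph$edges$length <= max_edge_len, ,
                             drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Connected components of (a filtered subgraph of) the cell graph
#'
#' Partitions the nodes selected by `node_filter` into maximal connected
#' sets of the induced subgraph.
#'
#' @param graph a `cell_graph`.
#' @param node_filter logical vector over nodes, or a predicate taking
#'   the node table and returning one; `NULL` keeps all nodes.
#' @return list of integer vectors of node *indices* (rows of
#'   `graph$cells`), one per component.
#' @export
graph_components <- function(graph, node_filter = NULL) {
  n <- nrow(graph$cells)
  keep <- if (is.null(node_filter)) rep(TRUE, n)
          else if (is.function(node_filter)) node_filter(graph$cells)
          else node_filter
  stopifnot(is.logical(keep), length(keep) == n)
  idx <- which(keep)
  if (!length(idx)) return(list())
  e <- graph$edges[keep[graph$edges$i] & keep[graph$edges$j], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  if (nrow(e))
    g <- igraph::add_edges(g, rbind(remap[e$i], remap[e$j]))
  comp <- igraph::components(g)
  unname(split(idx, comp$membership))
}

# adjacency list (1-based node index -> integer vector of neighbors)
adjacency_list <- function(graph) {
  n <- nrow(graph$cells)
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    ends <- c(graph$edges$i, graph$edges$j)
    nbrs <- c(graph$edges$j, graph$edges$i)
    adj_split <- split(nbrs, factor(ends, levels = seq_len(n)))
    adj <- lapply(adj_split, as.integer)
  } else {
    adj <- replicate(n, integer(), simplify = FALSE)
  }
  adj
}

#' Export a cell graph to GraphML for external inspection
#'
#' @param graph a `cell_graph`.
#' @param path output `.graphml` file.
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$cells$id[graph$edges$i],
               to = graph$cells$id[graph$edges$j],
               length = graph$edges$length),
    directed = FALSE,
    vertices = data.frame(name = graph$cells$id,
                          x = graph$cells$x, y = graph$cells$y,
                          cell_class = graph$cells$cell_class))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
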