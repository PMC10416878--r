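# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive, brute-force formulations.

# Brute-force Delaunay edge set: a triangle (i, j, k) belongs to the
# triangulation iff its circumcircle contains no other point; the edge
# set is the union over such triangles. O(n^4); fine for n <= 60.
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(), ncol = 2)
  combs <- utils::combn(n, 3)
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]; k <- combs[3, c_i]
    cc <- circumcircle(x[i], y[i], x[j], y[j], x[k], y[k])
    if (is.null(cc)) next  # collinear triple
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - cc$cx)^2 + (y[others] - cc$cy)^2
    if (all(d2 > cc$r2 * (1 + 1e-12)))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  edges <- unique(as.data.frame(t(apply(edges, 1, sort))))
  edges <- edges[order(edges[[1]], edges[[2]]), ]
  rownames(edges) <- NULL
  edges
}

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

# Union-find partition of nodes 1..n under an edge list (two-column
# matrix/data.frame), restricted to `keep` nodes.
oracle_components <- function(n, edges, keep = rep(TRUE, n)) {
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (keep[i] && keep[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(which(keep), find, integer(1))
  unname(split(which(keep), roots))
}

# Minimum hop distance from a seed set within an allowed node set, by
# exhaustive enumeration of simple paths (tiny n only).
oracle_minhop_exhaustive <- function(adj, seeds, target, allowed) {
  best <- Inf
  walk <- function(v, depth, seen) {
    if (depth >= best) return()
    if (v %in% seeds) {
      best <<- depth
      return()
    }
    for (w in adj[[v]]) {
      if (!allowed[w] || seen[w]) next
      seen[w] <- TRUE
      walk(w, depth + 1, seen)
      seen[w] <- FALSE
    }
  }
  seen <- rep(FALSE, length(adj))
  seen[target] <- TRUE
  walk(target, 0, seen)
  best
}

# Minimum hop distances from a seed set via igraph (independent of the
# package's wave-front implementation); returns per-node distances.
oracle_minhop_igraph <- function(graph, seeds, allowed) {
  n <- nrow(graph$cells)
  e <- graph$edges[allowed[graph$edges$i] & allowed[graph$edges$j], ,
                   drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$i, e$j))
  d <- igraph::distances(g, v = seeds, mode = "all")
  apply(d, 2, min)
}

# hex-lattice patch of epithelial cells (for fragment-size fixtures)
make_patch <- function(n_cells, x0, y0, spacing = 60,
                       cell_class = "EPITHELIAL_OTHER") {
  cols <- ceiling(sqrt(n_cells))
  pts <- list()
  r <- 0
  while (length(pts) * cols < n_cells) {
    off <- (r %% 2) * spacing / 2
    pts[[r + 1]] <- data.frame(
      x = x0 + (0:(cols - 1)) * spacing + off,
      y = y0 + r * spacing * sqrt(3) / 2)
    r <- r + 1
  }
  df <- do.call(rbind, pts)[seq_len(n_cells), ]
  df$cell_class <- cell_class
  df
}

# random scattered cell table with an epithelial blob flanked by stroma
# (below) and background (above); returns a cell_table
random_epithelium_cloud <- function(n_epi, seed, width = 1200) {
  set.seed(seed)
  band <- function(n, ymin, ymax, cls) {
    data.frame(x = runif(n, 0, width), y = runif(n, ymin, ymax),
               cell_class = cls)
  }
  h <- runif(1, 150, 400)
  df <- rbind(
    band(max(12, n_epi %/% 3), 0, 120, "BACKGROUND"),
    band(max(12, n_epi %/% 3), 120, 200, "CORNEUM"),
    band(n_epi, 200, 200 + h,
         sample(c("EPITHELIAL_OTHER", "BASAL", "LYMPHOCYTE"), n_epi,
                replace = TRUE, prob = c(0.7, 0.2, 0.1))),
    band(max(12, n_epi %/% 3), 200 + h, 320 + h, "STROMA"))
  df$is_pseudo <- df$cell_class %in% c("BACKGROUND", "CORNEUM")
  cell_table(df)
}
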