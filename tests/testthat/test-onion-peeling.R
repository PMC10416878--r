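# small hand-built neighborhood: one focal epithelial cell surrounded by
# chosen neighbor classes, far enough apart that Delaunay connects the
# focal cell to all of them
star_graph <- function(neighbor_classes) {
  k <- length(neighbor_classes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  cells <- cell_table(data.frame(
    x = c(200, 200 + 60 * cos(theta)),
    y = c(200, 200 + 60 * sin(theta)),
    cell_class = c("EPITHELIAL_OTHER", neighbor_classes)))
  prune_long_edges(build_delaunay_graph(cells), 500)
}

test_that("edge-point classification follows the neighbor rules", {
  g <- star_graph(c("BACKGROUND", "EPITHELIAL_OTHER", "EPITHELIAL_OTHER"))
  expect_equal(classify_edge_points(g)[1], "OUTER_EDGE")

  g <- star_graph(c("STROMA", "EPITHELIAL_OTHER", "EPITHELIAL_OTHER"))
  expect_equal(classify_edge_points(g)[1], "INNER_EDGE")

  g <- star_graph(c("STROMA", "CORNEUM", "EPITHELIAL_OTHER"))
  expect_equal(classify_edge_points(g)[1], "BOTH")

  g <- star_graph(rep("EPITHELIAL_OTHER", 6))
  roles <- classify_edge_points(g)
  expect_equal(roles[1], "INTERIOR")

  g <- star_graph(c("STROMA", "STROMA", "STROMA"))
  roles <- classify_edge_points(g)
  expect_true(all(roles[2:4] == "NON_EPITHELIAL"))
})

test_that("small epithelial fragments are re-labeled NON_EDGE at the
           strict 20-cell boundary", {
  main <- generate_epithelium(epithelium_spec(n_layers = 4, length = 30,
                                              seed = 1))$cells
  run_with_fragment <- function(n_frag) {
    frag <- make_patch(n_frag, x0 = 4000, y0 = 300)
    frag$is_pseudo <- FALSE
    all <- rbind(as.data.frame(main)[c("x", "y", "cell_class", "is_pseudo")],
                 frag[c("x", "y", "cell_class", "is_pseudo")])
    g <- prune_long_edges(build_delaunay_graph(cell_table(all)), 500)
    roles <- classify_edge_points(g)
    roles <- filter_small_components(g, roles)
    roles[g$cells$x >= 3900]
  }
  expect_true(all(run_with_fragment(19) == "NON_EDGE"))
  expect_false(any(run_with_fragment(20) == "NON_EDGE"))
})

test_that("the component filter leaves a single giant component alone
           and is monotone in the size threshold", {
  gen <- generate_epithelium(epithelium_spec(n_layers = 5, length = 25,
                                             seed = 2))
  g <- prune_long_edges(build_delaunay_graph(gen$cells), 500)
  roles <- classify_edge_points(g)
  expect_equal(filter_small_components(g, roles, 20), roles)

  # raising the threshold only ever converts roles *to* NON_EDGE
  r20 <- filter_small_components(g, roles, 20)
  r1000 <- filter_small_components(g, roles, 1000)
  converted <- r20 != r1000
  expect_true(all(r1000[converted] == "NON_EDGE"))
  expect_error(filter_small_components(g, roles, 0), "positive")
})

test_that("strip lattices peel to exactly K layers", {
  for (K in c(1, 3, 8)) {
    gen <- generate_epithelium(epithelium_spec(n_layers = K, length = 30,
                                               seed = K))
    res <- count_layers(gen$cells)
    expect_equal(res$median_layers, K)
    # basal-row nuclei (the anatomical inner edge) count exactly K
    basal_ids <- gen$cells$id[gen$cells$cell_class == "BASAL"]
    basal_counts <- res$counts$layer_count[res$counts$id %in% basal_ids]
    expect_true(all(basal_counts == K))
  }
})

test_that("one-cell-thick epithelium reports layer 1 everywhere", {
  gen <- generate_epithelium(epithelium_spec(n_layers = 1, length = 20,
                                             seed = 5))
  g <- prune_long_edges(build_delaunay_graph(gen$cells), 500)
  roles <- classify_edge_points(g)
  epi_roles <- roles[is_epithelial(g$cells$cell_class) &
                       g$cells$cell_class != "STROMA"]
  expect_true(all(epi_roles %in% c("BOTH", "INNER_EDGE")))
  res <- peel_layers(g, filter_small_components(g, roles))
  expect_true(all(res$counts$layer_count == 1))
  expect_equal(res$median_layers, 1)
})

test_that("layer counts equal 1 + min hop distance from the outer seeds
           (independent shortest-path oracle)", {
  for (seed in 1:10) {
    cells <- random_epithelium_cloud(n_epi = 120, seed = seed)
    g <- prune_long_edges(build_delaunay_graph(cells), 150)
    roles <- classify_edge_points(g)
    roles <- filter_small_components(g, roles)
    seeds <- which(roles %in% c("OUTER_EDGE", "BOTH"))
    if (!length(seeds) ||
        !length(which(roles %in% c("INNER_EDGE", "BOTH")))) next
    res <- peel_layers(g, roles)
    dist <- oracle_minhop_igraph(g, seeds,
                                 is_epithelial(g$cells$cell_class))
    for (r in seq_len(nrow(res$counts))) {
      idx <- match(res$counts$id[r], g$cells$id)
      expect_equal(res$counts$layer_count[r], 1 + dist[idx],
                   info = paste("seed", seed, "node", idx))
    }
  }
})

test_that("wave-front counts agree with exhaustive path enumeration on
           tiny graphs", {
  for (seed in 1:5) {
    cells <- random_epithelium_cloud(n_epi = 8, seed = 100 + seed)
    g <- prune_long_edges(build_delaunay_graph(cells), 200)
    roles <- classify_edge_points(g)
    seeds <- which(roles %in% c("OUTER_EDGE", "BOTH"))
    targets <- which(roles %in% c("INNER_EDGE", "BOTH"))
    if (!length(seeds) || !length(targets)) next
    res <- peel_layers(g, roles)
    adj <- onionpeel:::adjacency_list(g)
    allowed <- is_epithelial(g$cells$cell_class)
    for (t in targets) {
      want <- oracle_minhop_exhaustive(adj, seeds, t, allowed)
      got <- res$counts$layer_count[res$counts$id == g$cells$id[t]]
      if (is.infinite(want)) expect_length(got, 0)
      else expect_equal(got, 1 + want)
    }
  }
})

test_that("appending an epithelial row increments every basal count", {
  for (K in c(2, 5, 9)) {
    c1 <- count_layers(generate_epithelium(
      epithelium_spec(n_layers = K, length = 25, seed = 3))$cells)
    c2 <- count_layers(generate_epithelium(
      epithelium_spec(n_layers = K + 1, length = 25, seed = 3))$cells)
    expect_equal(c2$median_layers, c1$median_layers + 1)
  }
})

test_that("layer counts are invariant under rigid motion", {
  gen <- generate_epithelium(epithelium_spec(n_layers = 6, length = 25,
                                             seed = 7))
  res <- count_layers(gen$cells)
  th <- 0.7
  cells2 <- gen$cells
  x <- cells2$x; y <- cells2$y
  cells2$x <- x * cos(th) - y * sin(th) + 4000
  cells2$y <- x * sin(th) + y * cos(th) + 3000
  res2 <- count_layers(cells2)
  expect_equal(res2$median_layers, res$median_layers)
  expect_equal(sort(res2$counts$layer_count),
               sort(res$counts$layer_count))
})

test_that("detached full-thickness fragments are filtered and
           epithelial islands are reported unreachable", {
  # crack wider than the 500 px prune threshold splits off 2 columns x
  # 4 rows = 8 epithelial cells
  spec <- epithelium_spec(n_layers = 4, length = 30, seed = 4,
                          cracks = list(list(x = 100, width = 660,
                                             depth = 1)))
  gen <- generate_epithelium(spec)
  res <- count_layers(gen$cells)
  expect_equal(res$median_layers, 4)
  # fragment cells (x below the crack) contribute no counts
  frag_ids <- gen$cells$id[is_epithelial(gen$cells$cell_class) &
                             gen$cells$x < 100 + 180]
  expect_length(frag_ids, 8)
  expect_false(any(res$counts$id %in% frag_ids))
  expect_false(any(res$unreachable_ids %in% frag_ids))  # NON_EDGE, not unreachable

  # an epithelial island inside stroma: large enough to survive the
  # filter, but with no outer boundary, so its inner-edge nuclei are
  # unreachable and excluded from the median
  main <- generate_epithelium(epithelium_spec(n_layers = 3, length = 30,
                                              seed = 6))$cells
  island <- make_patch(25, x0 = 4000, y0 = 300)
  ring <- make_patch(40, x0 = 3880, y0 = 560, cell_class = "STROMA")
  extra <- rbind(island, ring)
  extra$is_pseudo <- FALSE
  all <- rbind(as.data.frame(main)[c("x", "y", "cell_class", "is_pseudo")],
               extra)
  res2 <- count_layers(cell_table(all))
  expect_gt(length(res2$unreachable_ids), 0)
  expect_equal(res2$median_layers, 3)
})

test_that("peeling demands both boundaries", {
  # epithelium with stroma on both sides: no outer boundary
  df <- rbind(make_patch(40, 400, 400),
              make_patch(30, 380, 140, cell_class = "STROMA"),
              make_patch(30, 380, 712, cell_class = "STROMA"))
  df$is_pseudo <- FALSE
  g <- prune_long_edges(build_delaunay_graph(cell_table(df)), 500)
  roles <- classify_edge_points(g)
  expect_error(peel_layers(g, roles), "no outer boundary")

  # epithelium with background on both sides: no inner boundary
  df2 <- rbind(make_patch(40, 400, 400),
               make_patch(30, 380, 140, cell_class = "BACKGROUND"),
               make_patch(30, 380, 712, cell_class = "BACKGROUND"))
  df2$is_pseudo <- df2$cell_class == "BACKGROUND"
  g2 <- prune_long_edges(build_delaunay_graph(cell_table(df2)), 500)
  expect_error(peel_layers(g2, classify_edge_points(g2)),
               "no inner boundary")
})

test_that("slide summaries use interpolated quantiles and population SD", {
  res <- layer_result(data.frame(id = 1:4, layer_count = c(2, 3, 3, 4)))
  s <- summarize_slide(res)
  expect_equal(s$median_layers, 3)
  expect_equal(s$sd_layers, sqrt(0.5), tolerance = 1e-12)

  one <- layer_result(data.frame(id = 1, layer_count = 5))
  s1 <- summarize_slide(one)
  expect_equal(s1$median_layers, 5)
  expect_equal(s1$sd_layers, 0)

  q <- layer_result(data.frame(id = 1:4, layer_count = 1:4))
  expect_equal(summarize_slide(q, quantile = 0.25)$median_layers,
               unname(quantile(1:4, 0.25)))
  expect_equal(summarize_slide(q, quantile = 0.25)$median_layers, 1.75)
  expect_error(summarize_slide(q, quantile = 0), "quantile")
  expect_error(summarize_slide(q, quantile = 1.2), "quantile")
})
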