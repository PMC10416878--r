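test_that("tile plans step by 500 - 2*margin with exact-cover ownership", {
  plan <- plan_tiles(c(0, 0, 2000, 2000), margin = 50)
  w <- plan$windows
  expect_equal(nrow(w), 25)                       # 5 x 5 sub-windows
  expect_setequal(unique(w$x0), c(0, 400, 800, 1200, 1500))
  # enumerate a pixel grid: every pixel owned exactly once
  px <- expand.grid(x = seq(0.5, 1999.5, by = 7),
                    y = seq(0.5, 1999.5, by = 7))
  claims <- rowSums(sapply(seq_len(nrow(w)), function(k) {
    px$x >= w$own_x0[k] & px$x < w$own_x1[k] &
      px$y >= w$own_y0[k] & px$y < w$own_y1[k]
  }))
  expect_true(all(claims == 1))

  plan0 <- plan_tiles(c(0, 0, 2000, 2000), margin = 0)
  expect_equal(nrow(plan0$windows), 16)           # 4 x 4, step 500
  expect_setequal(unique(plan0$windows$x0), c(0, 500, 1000, 1500))

  expect_error(plan_tiles(c(0, 0, 2000, 2000), margin = 250), "margin")
  expect_error(plan_tiles(c(0, 0, 1500, 2000)), "pad")
})

test_that("ownership partition holds slide-wide under random centroids", {
  # multi-tile region with a clamped (overlapping) last tile in x
  plan <- plan_tiles(c(100, 50, 4600, 2300), margin = 50)
  w <- plan$windows
  set.seed(42)
  pts <- data.frame(x = runif(2000, 100, 100 + 4600),
                    y = runif(2000, 50, 50 + 2300))
  claims <- rowSums(sapply(seq_len(nrow(w)), function(k) {
    pts$x >= w$own_x0[k] & pts$x < w$own_x1[k] &
      pts$y >= w$own_y0[k] & pts$y < w$own_y1[k]
  }))
  expect_true(all(claims == 1))
})

test_that("instances take their class from the semantic map at the
           centroid", {
  lab <- matrix("NON_EPI", 125, 125)   # 500x500 at 40x
  lab[1:50, ] <- "EPI_BASAL"
  lab[51:80, ] <- "EPI_OTHER"
  map <- semantic_map(lab, x0 = 0, y0 = 0, scale = 4)
  inst <- data.frame(x = c(100, 100, 100), y = c(100, 250, 450),
                     source_class = c("stroma nuclei", "stroma nuclei",
                                      "basal"),
                     area = c(90, 100, 110))
  out <- reclassify_by_center(inst, map)
  # the semantic map wins over the instance model's own labels
  expect_equal(out$cell_class,
               c("BASAL", "EPITHELIAL_OTHER", "STROMA"))
  expect_equal(out$area, inst$area)      # geometry untouched
  expect_equal(out$x, inst$x)

  # off-map centroid: dropped and reported
  inst_off <- rbind(inst, data.frame(x = 9999, y = 9999,
                                     source_class = "x", area = 1))
  expect_warning(out2 <- reclassify_by_center(inst_off, map), "dropped")
  expect_equal(nrow(out2), 3)
  expect_equal(attr(out2, "dropped"), 4L)
})

test_that("pseudo-points fill background/corneum at hex spacing", {
  lab <- matrix("BACKGROUND", 125, 125)
  map <- semantic_map(lab, 0, 0, 4)
  pts <- generate_pseudo_points(map, spacing = 60)
  expect_true(all(pts$cell_class == "BACKGROUND"))
  expect_true(all(pts$is_pseudo))
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  expect_gte(min(d), 60 * sqrt(3) / 2 - 1e-9)

  # no background/corneum -> empty
  expect_equal(nrow(generate_pseudo_points(
    semantic_map(matrix("NON_EPI", 50, 50), 0, 0, 4))), 0)

  # corneum stripe: points confined to the stripe footprint
  lab2 <- matrix("NON_EPI", 125, 125)
  lab2[40:60, ] <- "CORNEUM"
  pts2 <- generate_pseudo_points(semantic_map(lab2, 0, 0, 4), spacing = 60)
  expect_true(all(pts2$cell_class == "CORNEUM"))
  expect_true(all(pts2$y >= 39 * 4 & pts2$y < 60 * 4))
})

test_that("fusion keeps each nucleus exactly once across overlaps and
           discards margin-only detections", {
  plan <- plan_tiles(c(0, 0, 2000, 2000), margin = 50)
  lab <- matrix("NON_EPI", 500, 500)
  maps <- setNames(list(semantic_map(lab, 0, 0, 4)), plan$tiles$tile)

  # a nucleus in the overlap zone of windows (1,1) and (2,1): x = 420
  # lies in window 1 [0,500) and window 2 [400,900)
  dup <- data.frame(x = 420, y = 100, area = 80)
  inst <- list()
  inst[[plan$windows$window[plan$windows$x0 == 0 &
                              plan$windows$y0 == 0]]] <- dup
  inst[[plan$windows$window[plan$windows$x0 == 400 &
                              plan$windows$y0 == 0]]] <- dup
  fused <- fuse_slide(plan, maps, inst, spacing = 60)
  expect_equal(sum(!fused$is_pseudo), 1)

  # a detection reported only inside a window's discarded margin:
  # x = 460 falls in window 1's rectangle [0, 500) but is owned by
  # window 2's retained interior [450, 850); the owner saw nothing,
  # so the detection must vanish
  lone <- data.frame(x = 460, y = 100, area = 80)
  inst2 <- list()
  inst2[[plan$windows$window[plan$windows$x0 == 0 &
                               plan$windows$y0 == 0]]] <- lone
  w <- plan$windows
  owner <- which(lone$x >= w$own_x0 & lone$x < w$own_x1 &
                   lone$y >= w$own_y0 & lone$y < w$own_y1)
  expect_equal(w$x0[owner], 400)
  fused2 <- fuse_slide(plan, maps, inst2, spacing = 60)
  expect_equal(sum(!fused2$is_pseudo), 0)

  # disjoint nuclei across two tiles concatenate
  plan2 <- plan_tiles(c(0, 0, 4000, 2000), margin = 0)
  maps2 <- setNames(rep(list(semantic_map(lab, 0, 0, 4)),
                        nrow(plan2$tiles)), plan2$tiles$tile)
  maps2[[2]]$x0 <- 2000   # second tile anchored at its origin
  a <- data.frame(x = 100, y = 100, area = 50)
  b <- data.frame(x = 3900, y = 100, area = 50)
  inst3 <- list()
  inst3[[plan2$windows$window[1]]] <- a
  win_b <- with(plan2$windows, window[x0 <= 3900 & 3900 < x0 + 500 &
                                        y0 <= 100 & 100 < y0 + 500])
  inst3[[win_b[1]]] <- b
  fused3 <- fuse_slide(plan2, maps2, inst3, spacing = 60)
  expect_equal(sum(!fused3$is_pseudo), 2)

  # a missing semantic map is an error naming the tile
  expect_error(fuse_slide(plan2, maps2[1], inst3), plan2$tiles$tile[2])
})

test_that("fuse -> count on the semantic fixture recovers K end-to-end", {
  fx <- generate_semantic_fixture(epithelium_spec(n_layers = 4,
                                                  length = 40, seed = 2))
  plan <- plan_tiles(c(0, 0, 2000, 2000), margin = 50)
  inst <- split_instances_by_window(fx$instances, plan)
  fused <- fuse_slide(plan, setNames(list(fx$map), plan$tiles$tile), inst)
  # every real nucleus appears exactly once
  expect_equal(sum(!fused$is_pseudo), nrow(fx$instances))
  res <- count_layers(fused)
  expect_equal(res$median_layers, 4)
})
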