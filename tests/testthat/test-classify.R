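classify_all <- function(mask, params) {
  cmap <- dbscan_serial(mask, params)
  list(cmap = cmap, cls = classify_nodes(cmap, mask, params))
}

test_that("hand-derived block classifications are reproduced", {
  # isolated node, min_pts 2: cluster of one => noise
  m <- node_mask(matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 4)), 3, 3))
  r <- classify_all(m, db_params(1, 2))
  expect_equal(c(r$cls$n_core, r$cls$n_border, r$cls$n_noise), c(0, 0, 1))

  # solid 5x5, eps 1, min_pts 4: corners have |N| = 3 but sit next to core
  # edge pixels => 21 core + 4 border
  r5 <- classify_all(node_mask(matrix(TRUE, 5, 5)), db_params(1, 4))
  expect_equal(c(r5$cls$n_core, r5$cls$n_border, r5$cls$n_noise), c(21, 4, 0))

  # solid 7x7, eps 1, min_pts 5: the 5x5 interior is core (|N| = 5); edge
  # pixels (|N| = 4) border it; the 4 corners have no core pixel within
  # distance 1 (nearest is diagonal, distance 2), are unreachable, and are
  # noise by the cluster-size rule
  r7 <- classify_all(node_mask(matrix(TRUE, 7, 7)), db_params(1, 5))
  expect_equal(c(r7$cls$n_core, r7$cls$n_border, r7$cls$n_noise), c(25, 20, 4))
  corner_cells <- rbind(c(1, 1), c(1, 7), c(7, 1), c(7, 7))
  expect_true(all(r7$cls$class[corner_cells] == 3L))
})

test_that("classification matches the first-principles definitions", {
  for (i in 1:10) {
    w <- sample(10:26, 1); h <- sample(10:26, 1)
    eps <- sample(1:3, 1); mp <- sample(2:5, 1)
    m <- make_random_mask(w, h, runif(1, 0.25, 0.65), seed = 900 + i)
    if (n_nodes(m) == 0) next
    p <- db_params(eps, mp)
    r <- classify_all(m, p)
    want <- brute_classify(r$cmap, m, eps, mp)
    got <- as.data.frame(r$cls)
    expect_identical(stats::setNames(got$class, got$pid), want)
    # tri-partition is exact
    expect_equal(r$cls$n_core + r$cls$n_border + r$cls$n_noise, n_nodes(m))
    # every border node has a core node within eps; no noise node does
    core_pids <- as.integer(got$pid[got$class == "core"])
    for (cl in c("border", "noise")) {
      for (pid in as.integer(got$pid[got$class == cl])) {
        xy <- xy_from_pid(pid, w)
        has_core <- length(core_pids) > 0 &&
          any(abs(xy_from_pid(core_pids, w)$x - xy$x) +
                abs(xy_from_pid(core_pids, w)$y - xy$y) <= eps)
        if (cl == "border") expect_true(has_core) else expect_false(has_core)
      }
    }
  }
})

test_that("the border of a solid rectangle is a thin connected ring", {
  m <- node_mask(matrix(TRUE, 9, 13))
  p <- db_params(1, 5)
  r <- classify_all(m, p)
  border_cells <- which(r$cls$class == 2L)
  xy <- data.frame(x = (border_cells - 1) %/% 9, y = (border_cells - 1) %% 9)
  # ring: all border pixels on the rectangle perimeter, and the ring closes
  expect_true(all(xy$x %in% c(0, 12) | xy$y %in% c(0, 8)))
  g <- igraph::graph_from_adjacency_matrix(
    (abs(outer(xy$x, xy$x, "-")) + abs(outer(xy$y, xy$y, "-"))) <= 2,
    mode = "undirected")
  expect_equal(igraph::components(g)$no, 1)
})

test_that("overlay painting touches exactly the requested pixels", {
  img <- array(100L, c(6, 6, 3))
  m <- unclass(node_mask(matrix(FALSE, 6, 6)))
  m[5, 4] <- TRUE                        # single node at (x = 3, y = 4)
  m <- node_mask(m)
  p <- db_params(1, 1)                   # min_pts 1: the node is core
  r <- classify_all(m, p)
  # empty border: overlay equals input when core_color is unset
  expect_identical(render_overlay(img, r$cls), img)
  # painting the core touches exactly (3, 4)
  out <- render_overlay(img, r$cls, border_color = NULL,
                        core_color = c(255L, 0L, 0L))
  diff <- which(out != img, arr.ind = TRUE)
  expect_identical(unique(diff[, 1]), 5L)
  expect_identical(unique(diff[, 2]), 4L)
  expect_error(render_overlay(array(0L, c(3, 3, 3)), r$cls), "dimensions")
})

test_that("lesion_region_mask selects the requested clusters", {
  p <- db_params(1, 3)
  empty <- classify_all(node_mask(matrix(FALSE, 5, 5)), p)
  expect_equal(n_nodes(lesion_region_mask(empty$cls, empty$cmap)), 0)

  m <- unclass(node_mask(matrix(FALSE, 12, 24)))
  m[2:7, 2:6] <- TRUE        # 30-node cluster
  m[9:11, 15:17] <- TRUE     # 9-node cluster (clear of the first)
  m <- node_mask(m)
  r <- classify_all(m, p)
  largest <- lesion_region_mask(r$cls, r$cmap, "largest_cluster")
  expect_equal(n_nodes(largest), 30)
  expect_true(all(unclass(largest)[2:7, 2:6]))
  both <- lesion_region_mask(r$cls, r$cmap, "all_clusters")
  expect_equal(n_nodes(both), 39)
})
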