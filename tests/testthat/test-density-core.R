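test_that("manhattan_distance matches |dx| + |dy|", {
  expect_equal(manhattan_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(manhattan_distance(c(1, 2), c(4, 6)), 7)
  # the radius-4 ring: straight, diagonal, and mixed offsets all measure 4
  ring <- rbind(c(4, 0), c(-4, 0), c(0, 4), c(0, -4), c(2, 2), c(1, 3))
  center <- matrix(rep(c(10, 10), nrow(ring)), ncol = 2, byrow = TRUE)
  expect_equal(manhattan_distance(center, center + ring), rep(4, nrow(ring)))
  # symmetry
  expect_equal(manhattan_distance(c(0, 9), c(5, 2)),
               manhattan_distance(c(5, 2), c(0, 9)))
})

test_that("region_query equals the exhaustive scan on random masks", {
  set.seed(21)
  for (i in 1:40) {
    w <- sample(3:24, 1); h <- sample(3:24, 1)
    m <- make_random_mask(w, h, runif(1, 0.1, 0.9), seed = 1000 + i)
    x <- sample(0:(w - 1), 1); y <- sample(0:(h - 1), 1)
    eps <- sample(1:5, 1)
    expect_identical(region_query(m, x, y, eps)$members$pid,
                     brute_region_query(m, x, y, eps))
  }
})

test_that("interior Manhattan disc has eps^2 + (eps+1)^2 pixels", {
  m <- node_mask(matrix(TRUE, 15, 15))
  for (eps in 1:6)
    expect_equal(nrow(region_query(m, 7, 7, eps)$members), eps^2 + (eps + 1)^2)
  # radius 1 diamond and self-only masks
  expect_equal(nrow(region_query(m, 7, 7, 1)$members), 5)
  solo <- node_mask(matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 4)), 3, 3))
  expect_equal(region_query(solo, 1, 1, 2)$members$pid, 4L)
  expect_error(region_query(m, 20, 2, 1), "outside")
})

test_that("neighbor_counts agrees with pairwise-distance counting", {
  for (i in 1:8) {
    m <- make_random_mask(14, 11, 0.5, seed = 60 + i)
    eps <- 1 + i %% 3
    sizes <- brute_neighbor_sizes(m, eps)
    cnt <- neighbor_counts(m, eps)
    cells <- which(unclass(m))
    got <- cnt[cells]
    names(got) <- pid_from_xy((cells - 1) %/% nrow(m), (cells - 1) %% nrow(m),
                              ncol(m))
    expect_identical(got[names(sizes)], stats::setNames(as.integer(sizes),
                                                        names(sizes)))
  }
})

test_that("serial clustering handles the canonical hand-checked cases", {
  p14 <- db_params(1, 4)
  # empty mask: no clusters, no noise
  empty <- dbscan_serial(node_mask(matrix(FALSE, 6, 6)), p14)
  expect_length(empty$cluster_sizes, 0)
  expect_true(all(is.na(empty$labels)))
  # isolated node with min_pts 4 is noise
  m1 <- node_mask(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)), 5, 5))
  s1 <- dbscan_serial(m1, p14)
  expect_equal(sum(s1$labels == NOISE_LABEL, na.rm = TRUE), 1)
  expect_length(s1$cluster_sizes, 0)
  # solid 5x5: one cluster of all 25 nodes (corners have |N| = 3 < 4 but are
  # density-reachable), labeled with the minimum pid 0
  s2 <- dbscan_serial(node_mask(matrix(TRUE, 5, 5)), p14)
  expect_identical(s2$cluster_sizes, stats::setNames(25L, "0"))
  expect_true(all(s2$labels == 0L))
})

test_that("serial clusters are the components of the dense-node graph", {
  for (i in 1:12) {
    w <- sample(8:28, 1); h <- sample(8:28, 1)
    eps <- sample(1:3, 1); mp <- sample(2:5, 1)
    m <- make_random_mask(w, h, runif(1, 0.2, 0.7), seed = 400 + i)
    cmap <- dbscan_serial(m, db_params(eps, mp))
    lab <- labels_by_pid(cmap)
    comps <- oracle_core_components(m, eps, mp)
    # every oracle component lies in exactly one cluster; distinct
    # surviving components lie in distinct clusters; a dense component may
    # only end up as noise when it is itself below the min_pts size
    # threshold (the cluster-size demotion rule)
    comp_labels <- integer(0)
    for (cp in comps) {
      ls <- unique(lab[as.character(cp)])
      expect_length(ls, 1)
      if (ls[1] == NOISE_LABEL) expect_lt(length(cp), mp)
      else comp_labels <- c(comp_labels, ls[1])
    }
    expect_false(any(duplicated(comp_labels)))
    # every clustered node is dense or within eps of a dense node
    sizes <- brute_neighbor_sizes(m, eps)
    dense <- as.integer(names(sizes))[sizes >= mp]
    clustered <- as.integer(names(lab))[lab >= 0]
    w_ <- ncol(m)
    dxy <- xy_from_pid(dense, w_)
    for (pid in clustered) {
      xy <- xy_from_pid(pid, w_)
      expect_true(any(abs(dxy$x - xy$x) + abs(dxy$y - xy$y) <= eps))
    }
  }
})

test_that("every node gets exactly one label and clusters contain a core", {
  m <- make_random_mask(30, 30, 0.45, seed = 77)
  p <- db_params(2, 4)
  cmap <- dbscan_serial(m, p)
  df <- as.data.frame(cmap)
  expect_equal(nrow(df), n_nodes(m))                 # all nodes labeled
  expect_false(anyNA(df$cluster_id))
  expect_false(any(duplicated(df$pid)))
  cnt <- neighbor_counts(m, p$eps)
  for (id in as.integer(names(cmap$cluster_sizes))) {
    cells <- which(cmap$labels == id)
    expect_gte(max(cnt[cells]), p$min_pts)           # at least one core node
    expect_gte(length(cells), p$min_pts)             # demotion rule held
  }
})

test_that("spanning eps with min_pts 1 gives one cluster at the global min pid", {
  m <- make_random_mask(9, 9, 0.4, seed = 13)
  cmap <- dbscan_serial(m, db_params(20, 1))
  df <- as.data.frame(cmap)
  expect_identical(unique(df$cluster_id), min(df$pid))
})

test_that("canonicalization maps clusters to their minimum member pid", {
  # one cluster {7, 8, 9} on a 1-D strip
  m <- node_mask(matrix(c(rep(FALSE, 7), TRUE, TRUE, TRUE), 1, 10))
  cmap <- dbscan_serial(m, db_params(1, 2))
  expect_true(all(cmap$labels[8:10] == 7L))
  # two clusters {3, 4} and {10, 11} in a 12-wide strip
  m2 <- unclass(node_mask(matrix(FALSE, 1, 13)))
  m2[1, c(4, 5, 11, 12)] <- TRUE
  cmap2 <- dbscan_serial(node_mask(m2), db_params(1, 2))
  expect_identical(sort(as.integer(names(cmap2$cluster_sizes))), c(3L, 10L))
  # idempotence
  expect_identical(canonicalize_labels(cmap2)$labels, cmap2$labels)
})
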