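test_that("random masks are seed-reproducible with exact density extremes", {
  expect_equal(n_nodes(make_random_mask(12, 12, 0, seed = 1)), 0)
  expect_equal(n_nodes(make_random_mask(12, 12, 1, seed = 1)), 144)
  a <- make_random_mask(32, 20, 0.4, seed = 7)
  b <- make_random_mask(32, 20, 0.4, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(make_random_mask(32, 20, 0.4, seed = 8))))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_random_mask(8, 8, 0.5, seed = 99))
  invisible(make_lesion_image(32, 32, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("the serpentine is a 1-px path with the stated geometry", {
  for (L in c(1, 5, 23, 44)) {
    sp <- make_serpentine(L)
    expect_equal(n_nodes(sp), L)
    path <- attr(sp, "path")
    expect_equal(nrow(path), L)
    expect_equal(path$x[1] + path$y[1], 0)          # starts at (0, 0)
    if (L > 1) {
      step <- abs(diff(path$x)) + abs(diff(path$y))
      expect_true(all(step == 1))                   # consecutive pixels touch
      D <- abs(outer(path$x, path$x, "-")) + abs(outer(path$y, path$y, "-"))
      near <- which(D == 1, arr.ind = TRUE)
      expect_true(all(abs(near[, 1] - near[, 2]) == 1))  # no shortcuts
      # longest path in the eps = 1 adjacency graph equals L (it is a chain)
      g <- igraph::graph_from_adjacency_matrix(D == 1, mode = "undirected")
      expect_equal(igraph::diameter(g) + 1, L)
    }
  }
  expect_error(make_serpentine(50, width = 4, height = 3), "does not fit")
})

test_that("serpentine scan needs one pass per pixel at eps 1", {
  sp <- make_serpentine(44)
  part <- create_partitions(sp, ncol(sp), nrow(sp), 1)[[1]]
  st <- process_partition(part, db_params(1, 2))
  expect_equal(st$iterations, 44)
})

test_that("the lesion generator produces a recoverable connected blob", {
  fx <- make_lesion_image(64, 64, seed = 11, irregularity = 0, noise_rate = 0)
  # no salt, no irregularity: thresholding the blue channel recovers the
  # ground truth exactly, and the blob is a fat disc-like region
  got <- extract_nodes(fx$image, "B", 128)
  expect_identical(unclass(got), unclass(fx$mask))
  expect_gt(n_nodes(fx$mask), 0.5 * pi * (0.32 * 64)^2)
  expect_equal(nrow(fx$salt), 0)
  # reproducibility of image bytes and mask
  fx2 <- make_lesion_image(64, 64, seed = 11, irregularity = 0, noise_rate = 0)
  expect_identical(fx$image, fx2$image)
  expect_identical(unclass(fx$mask), unclass(fx2$mask))
})

test_that("salt pixels are isolated and clear of the blob", {
  fx <- make_lesion_image(96, 96, seed = 4, noise_rate = 0.02)
  expect_gt(nrow(fx$salt), 0)
  blob_xy <- which(unclass(fx$mask), arr.ind = TRUE)
  for (i in seq_len(nrow(fx$salt))) {
    d_blob <- min(abs(blob_xy[, 2] - 1 - fx$salt$x[i]) +
                    abs(blob_xy[, 1] - 1 - fx$salt$y[i]))
    expect_gt(d_blob, 4)
    if (nrow(fx$salt) > 1) {
      others <- setdiff(seq_len(nrow(fx$salt)), i)
      d_salt <- min(abs(fx$salt$x[others] - fx$salt$x[i]) +
                      abs(fx$salt$y[others] - fx$salt$y[i]))
      expect_gt(d_salt, 4)
    }
  }
})

test_that("split-cluster fixture crosses every partition boundary once merged", {
  m <- make_split_cluster(24, 16, 8, 8)
  # nodes on both sides of every internal vertical and horizontal boundary
  for (bx in c(8, 16))
    expect_true(any(unclass(m)[, bx]) && any(unclass(m)[, bx + 1]))
  expect_true(any(unclass(m)[8, ]) && any(unclass(m)[9, ]))
  p <- db_params(1, 2)
  expect_same_clustering(run_pipeline(m, p, 8, 8), dbscan_serial(m, p))
  expect_length(run_pipeline(m, p, 8, 8)$cluster_sizes, 1)
  expect_identical(unclass(make_split_cluster(24, 16, 8, 8)), unclass(m))
  expect_error(make_split_cluster(8, 8, 8, 8), "larger than one partition")
})

test_that("fixture_spec validates and make_fixture dispatches", {
  expect_error(fixture_spec(density = 2), "density")
  expect_error(fixture_spec(path_length = 0), "path_length")
  expect_error(fixture_spec(kind = "nope"), "arg")
  sp <- fixture_spec("serpentine_path", path_length = 9)
  expect_equal(n_nodes(make_fixture(sp)), 9)
  rm1 <- make_fixture(fixture_spec("random_mask", width = 10, height = 10,
                                   seed = 2, density = 0.5))
  expect_identical(unclass(rm1),
                   unclass(make_random_mask(10, 10, 0.5, seed = 2)))
})
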