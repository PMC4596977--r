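# Test-side oracles, kept deliberately naive and independent of the
# package's shift-kernel internals.

# build a node_mask from string art ("X" = node, "." = background)
mask_from_strings <- function(rows) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "X"))
  node_mask(m)
}

# exhaustive region query: scan every pixel of the raster
brute_region_query <- function(mask, x, y, eps) {
  w <- ncol(mask); h <- nrow(mask)
  hits <- integer(0)
  for (yy in 0:(h - 1)) for (xx in 0:(w - 1)) {
    if (unclass(mask)[yy + 1, xx + 1] && abs(xx - x) + abs(yy - y) <= eps)
      hits <- c(hits, yy * w + xx)
  }
  sort(hits)
}

# per-node neighborhood sizes from the pairwise distance matrix of node
# coordinates (no convolution involved)
brute_neighbor_sizes <- function(mask, eps) {
  cells <- which(unclass(mask))
  h <- nrow(mask)
  x <- (cells - 1) %/% h
  y <- (cells - 1) %% h
  D <- abs(outer(x, x, "-")) + abs(outer(y, y, "-"))
  out <- stats::setNames(rowSums(D <= eps), y * ncol(mask) + x)
  out[order(as.integer(names(out)))]
}

# independent clustering oracle: dense nodes from brute-force neighborhood
# sizes, components of the dense-node graph via igraph
oracle_core_components <- function(mask, eps, min_pts) {
  sizes <- brute_neighbor_sizes(mask, eps)
  pids <- as.integer(names(sizes))
  core <- pids[sizes >= min_pts]
  if (!length(core)) return(list())
  w <- ncol(mask)
  x <- core %% w; y <- core %/% w
  D <- abs(outer(x, x, "-")) + abs(outer(y, y, "-"))
  g <- igraph::graph_from_adjacency_matrix(D <= eps, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(core, comp))
}

# the canonical label of the cluster containing each node, read off a
# cluster_map as a named vector pid -> label
labels_by_pid <- function(cmap) {
  df <- as.data.frame(cmap)
  stats::setNames(df$cluster_id, df$pid)
}

# first-principles core/border/noise classifier straight from the textual
# definitions, on top of a given cluster map
brute_classify <- function(cmap, mask, eps, min_pts) {
  sizes <- brute_neighbor_sizes(mask, eps)
  pids <- as.integer(names(sizes))
  lab <- labels_by_pid(cmap)[as.character(pids)]
  member_count <- vapply(pids, function(p) {
    l <- lab[[as.character(p)]]
    if (is.na(l) || l < 0) 1L else sum(lab == l)
  }, integer(1))
  out <- ifelse(member_count < min_pts, "noise",
                ifelse(sizes < min_pts, "border", "core"))
  stats::setNames(out, pids)
}

expect_same_clustering <- function(a, b) {
  expect_identical(a$labels, b$labels)
  expect_identical(a$cluster_sizes, b$cluster_sizes)
}
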