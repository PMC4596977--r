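## Manhattan-distance density primitives and the serial clusterer that the
## partitioned pipeline is proven against.

#' Manhattan distance between pixels
#'
#' `|dx| + |dy|`; the metric used for all neighborhoods in this package. Its
#' radius-`eps` ball is a diamond of `eps^2 + (eps+1)^2` pixels.
#'
#' @param p,q pixels as length-2 vectors `c(x, y)` or 2-column matrices
#'   (vectorized row-wise).
#' @return integer distance(s).
#' @examples
#' manhattan_distance(c(1, 2), c(4, 6))  # 7
#' @export
manhattan_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  as.integer(abs(p[, 1] - q[, 1]) + abs(p[, 2] - q[, 2]))
}

# all (dx, dy) with |dx| + |dy| <= eps, as a 2-column integer matrix
manhattan_offsets <- function(eps) {
  g <- expand.grid(dx = -eps:eps, dy = -eps:eps)
  g <- g[abs(g$dx) + abs(g$dy) <= eps, , drop = FALSE]
  cbind(dx = as.integer(g$dx), dy = as.integer(g$dy))
}

## shifted-neighborhood reductions -------------------------------------------
## out[y, x] = f over M[y + dy, x + dx] for all in-bounds offsets. These two
## kernels carry the whole package: density counts are a shift-sum of the
## binary mask, and the label negotiation is a shift-min of the label grid.

shift_sum <- function(M, offsets) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(0, h, w)
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets[k, 1]; dy <- offsets[k, 2]
    y0 <- max(1L, 1L - dy); y1 <- min(h, h - dy)
    x0 <- max(1L, 1L - dx); x1 <- min(w, w - dx)
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    out[ys, xs] <- out[ys, xs] + M[ys + dy, xs + dx]
  }
  out
}

shift_min <- function(M, offsets) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(Inf, h, w)
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets[k, 1]; dy <- offsets[k, 2]
    y0 <- max(1L, 1L - dy); y1 <- min(h, h - dy)
    x0 <- max(1L, 1L - dx); x1 <- min(w, w - dx)
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    out[ys, xs] <- pmin(out[ys, xs], M[ys + dy, xs + dx])
  }
  out
}

#' Neighborhood population of every pixel
#'
#' Counts, for each pixel, the node pixels within Manhattan distance `eps`
#' (the pixel itself included when it is a node). A node is *dense* (core
#' candidate) when its count is `>= min_pts`.
#'
#' @param mask a [node_mask()].
#' @param eps Manhattan radius.
#' @return integer matrix of counts, same shape as the mask.
#' @export
neighbor_counts <- function(mask, eps) {
  out <- shift_sum(unclass(mask) * 1, manhattan_offsets(eps))
  storage.mode(out) <- "integer"
  out
}

#' Query the epsilon-neighborhood of a pixel
#'
#' Returns every node pixel at Manhattan distance `<= eps` from the center
#' (the center included when it is itself a node), clipped at the raster
#' boundary.
#'
#' @param mask a [node_mask()].
#' @param x,y 0-based center coordinates.
#' @param eps Manhattan radius.
#' @return object of class `neighbor_list`: a list with `center` (x, y, pid)
#'   and `members`, a data frame with columns `x`, `y`, `pid` sorted by pid.
#' @examples
#' m <- node_mask(matrix(TRUE, 5, 5))
#' nrow(region_query(m, 2, 2, 1)$members)  # 5
#' @export
region_query <- function(mask, x, y, eps) {
  h <- mask_height(mask); w <- mask_width(mask)
  if (x < 0 || x >= w || y < 0 || y >= h)
    stop(sprintf("center (%d, %d) outside %dx%d raster", x, y, w, h))
  off <- manhattan_offsets(eps)
  nx <- x + off[, 1]; ny <- y + off[, 2]
  ok <- nx >= 0 & nx < w & ny >= 0 & ny < h
  nx <- nx[ok]; ny <- ny[ok]
  isn <- unclass(mask)[cbind(ny + 1L, nx + 1L)]
  nx <- nx[isn]; ny <- ny[isn]
  pid <- pid_from_xy(nx, ny, w)
  o <- order(pid)
  structure(list(
    center  = list(x = x, y = y, pid = pid_from_xy(x, y, w)),
    members = data.frame(x = nx[o], y = ny[o], pid = pid[o])
  ), class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat(sprintf("<neighbor_list> center (%d, %d) pid %d: %d member(s)\n",
              x$center$x, x$center$y, x$center$pid, nrow(x$members)))
  invisible(x)
}

## ---- cluster map -----------------------------------------------------------

new_cluster_map <- function(labels, eps, min_pts, extra = list()) {
  storage.mode(labels) <- "integer"
  sizes <- cluster_sizes_from_labels(labels)
  structure(c(list(labels = labels, width = ncol(labels),
                   height = nrow(labels), eps = as.integer(eps),
                   min_pts = as.integer(min_pts), cluster_sizes = sizes),
              extra),
            class = "cluster_map")
}

cluster_sizes_from_labels <- function(labels) {
  v <- labels[!is.na(labels) & labels >= 0L]
  if (!length(v)) return(integer(0))
  tab <- table(v)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  sizes
}

#' @export
print.cluster_map <- function(x, ...) {
  nn <- sum(!is.na(x$labels))
  cat(sprintf("<cluster_map> %d x %d px, %d nodes, %d cluster(s), %d noise\n",
              x$width, x$height, nn, length(x$cluster_sizes),
              sum(x$labels == NOISE_LABEL, na.rm = TRUE)))
  invisible(x)
}

#' Convert a cluster map to a per-node data frame
#'
#' @param x a `cluster_map`.
#' @param ... unused.
#' @return data frame with columns `x`, `y`, `pid`, `cluster_id`
#'   (`-1` = noise), sorted by pid.
#' @export
as.data.frame.cluster_map <- function(x, ...) {
  cells <- which(!is.na(x$labels))
  xy <- cell_xy(cells, x$height)
  df <- data.frame(x = xy$x, y = xy$y,
                   pid = pid_from_xy(xy$x, xy$y, x$width),
                   cluster_id = x$labels[cells])
  df[order(df$pid), , drop = FALSE]
}

## ---- serial DBSCAN (the oracle) --------------------------------------------

#' Serial density-based clustering (the correctness oracle)
#'
#' Classic DBSCAN on the node grid: nodes are visited in ascending pid
#' order; a node whose `eps`-neighborhood holds at least `min_pts` nodes
#' (itself included) is dense and seeds/extends a cluster, which is expanded
#' over all density-reachable nodes. Non-dense nodes within `eps` of a dense
#' node join a cluster as border members; border attribution — which is the
#' only order-dependent part of classic DBSCAN — is made deterministic by
#' assigning each border node to the candidate cluster with the smallest
#' label. Clusters left with fewer than `min_pts` members are demoted to
#' noise, and labels are canonicalized to the minimum member pid, so the
#' output is directly comparable with [run_pipeline()].
#'
#' @param mask a [node_mask()].
#' @param params a [db_params()].
#' @return a `cluster_map`: integer label matrix (`NA` = not a node,
#'   `-1` = noise, otherwise the minimum member pid of the cluster) plus
#'   `cluster_sizes`.
#' @examples
#' m <- node_mask(matrix(TRUE, 5, 5))
#' dbscan_serial(m, db_params(eps = 1, min_pts = 4))
#' @export
dbscan_serial <- function(mask, params) {
  params <- as_db_params(params)
  h <- mask_height(mask); w <- mask_width(mask)
  eps <- params$eps; min_pts <- params$min_pts
  off <- manhattan_offsets(eps)
  pidm <- pid_matrix(h, w)
  m <- unclass(mask)

  counts <- neighbor_counts(mask, eps)
  core <- m & counts >= min_pts
  lab <- matrix(NA_integer_, h, w)

  # visit dense nodes in pid order; each unlabeled one seeds a cluster that
  # is expanded breadth-first over dense neighbors. Because seeds are taken
  # in ascending pid order, a component's label is its minimum dense pid.
  core_cells <- which(core)
  core_cells <- core_cells[order(pidm[core_cells])]
  for (cell in core_cells) {
    if (!is.na(lab[cell])) next
    cl <- pidm[cell]
    lab[cell] <- cl
    frontier <- cell
    while (length(frontier)) {
      fxy <- cell_xy(frontier, h)
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        nx <- fxy$x + off[k, 1]; ny <- fxy$y + off[k, 2]
        ok <- nx >= 0L & nx < w & ny >= 0L & ny < h
        if (!any(ok)) next
        idx <- nx[ok] * h + ny[ok] + 1L       # column-major cell index
        idx <- idx[core[idx] & is.na(lab[idx])]
        if (length(idx)) {
          lab[idx] <- cl
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }

  # border attribution: each non-dense node joins the smallest-labeled
  # cluster among its dense eps-neighbors; unreachable nodes keep their own
  # pid (singleton, demoted below)
  lab_d <- matrix(Inf, h, w)
  lab_d[core] <- as.double(lab[core])
  near <- shift_min(lab_d, off)
  border_cells <- which(m & !core & is.finite(near))
  lab[border_cells] <- as.integer(near[border_cells])
  solo_cells <- which(m & !core & !is.finite(near))
  lab[solo_cells] <- pidm[solo_cells]

  lab <- demote_small_clusters(lab, min_pts)
  lab <- canonicalize_label_matrix(lab, pidm)
  new_cluster_map(lab, eps, min_pts)
}

# Algorithm step shared by both routes: cluster groups smaller than min_pts
# are noise
demote_small_clusters <- function(lab, min_pts) {
  cells <- which(!is.na(lab) & lab >= 0L)
  if (!length(cells)) return(lab)
  v <- lab[cells]
  tab <- table(v)
  small <- as.integer(names(tab)[tab < min_pts])
  if (length(small)) lab[cells[v %in% small]] <- NOISE_LABEL
  lab
}

canonicalize_label_matrix <- function(lab, pidm) {
  cells <- which(!is.na(lab) & lab >= 0L)
  if (!length(cells)) return(lab)
  v <- lab[cells]; p <- pidm[cells]
  minp <- tapply(p, v, min)
  lab[cells] <- as.integer(minp[match(v, as.integer(names(minp)))])
  lab
}

#' Canonicalize cluster labels to minimum member pids
#'
#' Relabels every cluster with the smallest pid among its members (noise and
#' non-node pixels unchanged). Idempotent; both clustering routes already
#' return canonical maps, so this is mainly useful after manual label
#' surgery.
#'
#' @param cmap a `cluster_map`.
#' @return a `cluster_map` with canonical labels.
#' @export
canonicalize_labels <- function(cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  pidm <- pid_matrix(cmap$height, cmap$width)
  lab <- canonicalize_label_matrix(cmap$labels, pidm)
  new_cluster_map(lab, cmap$eps, cmap$min_pts)
}
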