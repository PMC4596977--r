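## Merging per-partition labelings into one global labeling. Pixels inside a
## lap region are observed by several partitions; when such a pixel is dense
## (in at least one view — which, with a full lap, is equivalent to globally
## dense), every cluster id it carries names the same global cluster, so the
## ids are unified transitively with a union-find. Non-dense pixels are then
## re-attributed to the candidate cluster with the smallest resolved id,
## mirroring the serial border-attribution rule.

#' Merge converged partition labelings into a global one
#'
#' @param locals list of converged `local_node_list`s (one per partition,
#'   same order as `parts`).
#' @param parts the `partition_set` the locals were produced from.
#' @param eps Manhattan radius used for the scans.
#' @return object of class `global_node_list`: a data frame (`pid`, `x`,
#'   `y`, `cluster`, `dense`, `n_views`) sorted by pid, where `cluster` is
#'   the unified pre-canonical id (own pid for unreachable nodes) and
#'   `n_views` records how many partitions observed the node.
#' @export
merge_partitions <- function(locals, parts, eps) {
  stopifnot(length(locals) == length(parts))
  dfs <- lapply(locals, as.data.frame)

  # internal sanity: each partition must have observed exactly the node set
  # of its view; anything else indicates a partitioning bug
  for (i in seq_along(parts)) {
    expect <- sort(partition_pid_matrix(parts[[i]])[parts[[i]]$view])
    if (!identical(sort(dfs[[i]]$pid), as.integer(expect)))
      stop("internal error: inconsistent node observations in partition ", i)
  }

  obs <- do.call(rbind, dfs)
  if (is.null(obs) || nrow(obs) == 0L) {
    out <- data.frame(pid = integer(0), x = integer(0), y = integer(0),
                      cluster = integer(0), dense = logical(0),
                      n_views = integer(0))
    return(structure(out, class = c("global_node_list", "data.frame")))
  }

  dense_pids <- unique(obs$pid[obs$dense])
  obs_dense <- obs[obs$pid %in% dense_pids, , drop = FALSE]

  # union-find over cluster ids: for every dense pixel, its own pid and all
  # ids it carries across views belong to one cluster
  elems <- sort(unique(c(obs_dense$pid, obs_dense$C)))
  parent <- seq_along(elems)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  a <- match(obs_dense$pid, elems)
  b <- match(obs_dense$C, elems)
  for (k in seq_len(nrow(obs_dense))) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(elems), find, integer(1))
  # resolved id of a component = its minimum element (a pid)
  comp_min <- tapply(elems, roots, min)
  resolved <- as.integer(comp_min[match(roots, as.integer(names(comp_min)))])
  resolve_id <- function(ids) resolved[match(ids, elems)]

  # one row per pid
  first <- obs[!duplicated(obs$pid), c("pid", "x", "y")]
  up <- sort(unique(obs$pid))
  nv <- as.integer(table(factor(obs$pid, levels = up)))
  out <- data.frame(first, cluster = NA_integer_,
                    dense = first$pid %in% dense_pids,
                    n_views = nv[match(first$pid, up)])

  out$cluster[out$dense] <- resolve_id(out$pid[out$dense])

  # attribution of non-dense nodes: candidates are the converged labels of
  # all their in-view dense neighbors, pooled over every observing view and
  # resolved through the union-find before taking the minimum (resolution is
  # not monotone in the raw label value, so the minimum must be taken after
  # resolving)
  cand <- do.call(rbind, lapply(locals, `[[`, "border_cands"))
  cand <- cand[!(cand$pid %in% dense_pids), , drop = FALSE]
  if (nrow(cand)) {
    cand$res <- resolve_id(cand$C)
    o <- order(cand$pid, cand$res)
    best <- cand[o, ][!duplicated(cand$pid[o]), c("pid", "res")]
    hit <- match(out$pid, best$pid)
    take <- !is.na(hit) & !out$dense
    out$cluster[take] <- best$res[hit[take]]
  }
  out$cluster[is.na(out$cluster)] <- out$pid[is.na(out$cluster)]  # unreachable

  out <- out[order(out$pid), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("global_node_list", "data.frame"))
}

#' @export
print.global_node_list <- function(x, ...) {
  cat(sprintf("<global_node_list> %d nodes, %d cluster id(s), %d lap node(s)\n",
              nrow(x), length(unique(x$cluster)), sum(x$n_views > 1L)))
  invisible(x)
}

#' Partitioned clustering pipeline
#'
#' Runs the full partitioned route: [create_partitions()], then
#' [process_partition()] on every shingle (independently; with
#' `workers > 1` they are processed in parallel via forked workers, with
#' bitwise-identical results), then [merge_partitions()]. Cluster groups
#' with fewer than `min_pts` members are demoted to noise and labels are
#' canonicalized to the minimum member pid, so for every input the result is
#' identical to [dbscan_serial()].
#'
#' @param mask a [node_mask()].
#' @param params a [db_params()].
#' @param core_width,core_height core partition size in pixels (default
#'   256 x 256).
#' @param workers number of parallel workers for partition processing
#'   (1 = sequential).
#' @param lap lap width; leave at the default `2 * eps + 1` (see
#'   [create_partitions()]).
#' @return a `cluster_map` (as [dbscan_serial()]); attribute `"iterations"`
#'   holds the per-partition scan counts and `"grid"` the partition grid.
#' @examples
#' m <- node_mask(matrix(TRUE, 8, 8))
#' p <- db_params(eps = 1, min_pts = 4)
#' identical(run_pipeline(m, p, 4, 4)$labels, dbscan_serial(m, p)$labels)
#' @export
run_pipeline <- function(mask, params, core_width = 256L, core_height = 256L,
                         workers = 1L, lap = NULL) {
  params <- as_db_params(params)
  if (is.null(lap)) lap <- 2L * params$eps + 1L
  parts <- create_partitions(mask, core_width, core_height, params$eps,
                             lap = lap)
  locals <- if (workers > 1L) {
    parallel::mclapply(parts, process_partition, params = params,
                       mc.cores = workers)
  } else {
    lapply(parts, process_partition, params = params)
  }
  gnl <- merge_partitions(locals, parts, params$eps)

  h <- mask_height(mask); w <- mask_width(mask)
  lab <- matrix(NA_integer_, h, w)
  if (nrow(gnl)) lab[cbind(gnl$y + 1L, gnl$x + 1L)] <- gnl$cluster
  lab <- demote_small_clusters(lab, params$min_pts)
  lab <- canonicalize_label_matrix(lab, pid_matrix(h, w))
  cmap <- new_cluster_map(lab, params$eps, params$min_pts)
  attr(cmap, "iterations") <- vapply(locals, `[[`, integer(1), "iterations")
  attr(cmap, "grid") <- attr(parts, "grid")
  cmap
}
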