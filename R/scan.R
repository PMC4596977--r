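## Per-partition iterative minimum-id label negotiation. Every node starts
## with its own global pid as cluster id C; repeated synchronous scans
## replace each dense node's C with the minimum C among its dense
## eps-neighbors, and each non-dense node's C with the minimum C among its
## dense eps-neighbors when it has any. At the fixed point every
## density-connected group shares C = its minimum dense pid.

#' Initialize the negotiation state of a partition
#'
#' @param part a `partition` from [create_partitions()].
#' @param params a [db_params()].
#' @return object of class `local_node_list`: label grid `C` (double matrix,
#'   `Inf` at non-nodes), the static in-view density flags `dense`, the
#'   global pid grid, and bookkeeping fields (`iterations`, `checksums`).
#' @export
local_state <- function(part, params) {
  params <- as_db_params(params)
  pid <- partition_pid_matrix(part)
  counts <- shift_sum(part$view * 1, manhattan_offsets(params$eps))
  C <- matrix(Inf, part$height, part$width)
  C[part$view] <- as.double(pid[part$view])
  structure(list(
    C = C, dense = part$view & counts >= params$min_pts, pid = pid,
    offsets = manhattan_offsets(params$eps),
    node = part$view, part_index = part$index,
    x_off = part$x_off, y_off = part$y_off, img_width = part$img_width,
    iterations = 0L, moves = 0L, checksums = numeric(0)
  ), class = "local_node_list")
}

#' One synchronous negotiation scan over a partition
#'
#' All reads are against the previous iteration's labels (Jacobi semantics),
#' so one scan is deterministic and independent of any pixel ordering. Dense
#' nodes take the minimum C over their dense `eps`-neighbors (themselves
#' included); non-dense nodes within `eps` of a dense node take the minimum
#' C over those dense neighbors; other nodes keep their C. The minimum is
#' taken over *dense* neighbors so that non-dense (border) nodes — whose
#' cluster membership is attribution, not identity — cannot bridge two
#' clusters or inject their pids into cluster labels; this is what makes the
#' fixed point agree exactly with [dbscan_serial()].
#'
#' @param part a `partition`.
#' @param state a `local_node_list` (from [local_state()] or a previous
#'   scan).
#' @param params a [db_params()].
#' @return the updated `local_node_list`.
#' @export
scan_once <- function(part, state, params) {
  params <- as_db_params(params)
  off <- manhattan_offsets(params$eps)
  Cd <- state$C
  Cd[!state$dense] <- Inf
  m <- shift_min(Cd, off)                 # min over dense neighbors (+ self)
  newC <- state$C
  newC[state$dense] <- m[state$dense]
  reach <- state$node & !state$dense & is.finite(m)
  newC[reach] <- m[reach]
  state$C <- newC
  state
}

#' Iterate the negotiation to convergence
#'
#' Repeats [scan_once()] until a pass changes nothing. After convergence each
#' density-connected group inside the partition carries C = the minimum pid
#' among its in-view dense members, and each reachable non-dense node the
#' minimum C among its dense neighbors. The per-pass checksum (sum of all
#' finite C) is recorded for observability, but convergence is declared on
#' elementwise equality of the label grid, which a checksum alone cannot
#' guarantee.
#'
#' @inheritParams local_state
#' @return converged `local_node_list`; `iterations` counts every scan pass
#'   including the final no-change pass, `moves = iterations - 1` the passes
#'   that changed labels.
#' @examples
#' m <- node_mask(matrix(rep(c(TRUE, TRUE, TRUE, TRUE, TRUE), 1), 1, 5))
#' p <- create_partitions(m, 5, 1, eps = 1)[[1]]
#' st <- process_partition(p, db_params(1, 2))
#' unique(st$C[st$node])   # all 0 (leftmost pid)
#' @export
process_partition <- function(part, params) {
  params <- as_db_params(params)
  state <- local_state(part, params)
  sums <- numeric(0)
  repeat {
    prev <- state$C
    state <- scan_once(part, state, params)
    state$iterations <- state$iterations + 1L
    sums <- c(sums, sum(state$C[state$node]))
    if (identical(state$C, prev)) break
    state$moves <- state$moves + 1L
  }
  state$checksums <- sums
  state$border_cands <- border_candidates(state)
  state
}

# candidate cluster ids of every non-dense node: the converged labels of all
# its dense eps-neighbors in this view. One in-view label value is not
# enough for global attribution — after merging, a numerically larger label
# can resolve to a smaller global cluster — so the full candidate set is
# recorded per partition and resolved at merge time.
border_candidates <- function(state) {
  h <- nrow(state$node); w <- ncol(state$node)
  nd_cells <- which(state$node & !state$dense)
  out_pid <- integer(0); out_C <- integer(0)
  if (length(nd_cells)) {
    off <- state$offsets
    xy <- cell_xy(nd_cells, h)
    for (k in seq_len(nrow(off))) {
      nx <- xy$x + off[k, 1]; ny <- xy$y + off[k, 2]
      ok <- nx >= 0L & nx < w & ny >= 0L & ny < h
      if (!any(ok)) next
      nidx <- nx[ok] * h + ny[ok] + 1L
      sel <- state$dense[nidx]
      if (!any(sel)) next
      out_pid <- c(out_pid, state$pid[nd_cells[ok][sel]])
      out_C <- c(out_C, as.integer(state$C[nidx[sel]]))
    }
  }
  df <- unique(data.frame(pid = out_pid, C = out_C))
  rownames(df) <- NULL
  df
}

#' @export
print.local_node_list <- function(x, ...) {
  cat(sprintf(
    "<local_node_list> partition #%d: %d nodes, %d iteration(s)\n",
    x$part_index, sum(x$node), x$iterations))
  invisible(x)
}

#' Per-node records of a converged partition
#'
#' @param x a `local_node_list`.
#' @param ... unused.
#' @return data frame with global `pid`, global coordinates `x`/`y`, the
#'   negotiated cluster id `C`, and the in-view density flag `dense`.
#' @export
as.data.frame.local_node_list <- function(x, ...) {
  cells <- which(x$node)
  data.frame(
    pid = x$pid[cells],
    x = x$x_off + (cells - 1L) %/% nrow(x$node),
    y = x$y_off + (cells - 1L) %% nrow(x$node),
    C = as.integer(x$C[cells]),
    dense = x$dense[cells]
  )
}
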