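## Core / border / noise classification and border rendering.

CLASS_NONE   <- 0L
CLASS_CORE   <- 1L
CLASS_BORDER <- 2L
CLASS_NOISE  <- 3L

class_names <- c("core", "border", "noise")

#' Classify nodes as core, border, or noise
#'
#' For each node, the tests are applied in this fixed order: if the node's
#' cluster has fewer than `min_pts` members (an unclustered node counts as a
#' cluster of one), it is *noise*; otherwise, if its `eps`-neighborhood
#' holds fewer than `min_pts` nodes, it is *border*; otherwise it is *core*.
#' The cluster-size test comes first, so members of sub-threshold groups are
#' noise even when locally dense.
#'
#' @param cmap a `cluster_map` from [dbscan_serial()] or [run_pipeline()].
#' @param mask the [node_mask()] the map was computed from.
#' @param params the [db_params()] used.
#' @return object of class `node_classification`: integer matrix `class`
#'   (0 = not a node, 1 = core, 2 = border, 3 = noise) plus the counts.
#' @examples
#' m <- node_mask(matrix(TRUE, 5, 5))
#' p <- db_params(1, 4)
#' cls <- classify_nodes(dbscan_serial(m, p), m, p)
#' cls$n_core; cls$n_border    # 21; 4 (the corners)
#' @export
classify_nodes <- function(cmap, mask, params) {
  stopifnot(inherits(cmap, "cluster_map"), is_node_mask(mask))
  params <- as_db_params(params)
  if (cmap$width != mask_width(mask) || cmap$height != mask_height(mask))
    stop("cluster map and mask dimensions disagree")
  m <- unclass(mask)
  lab <- cmap$labels
  counts <- neighbor_counts(mask, params$eps)

  # cluster population per node (noise / unclustered = 1)
  sizes <- cmap$cluster_sizes
  pop <- matrix(0L, cmap$height, cmap$width)
  clustered <- !is.na(lab) & lab >= 0L
  pop[clustered] <- sizes[match(lab[clustered], as.integer(names(sizes)))]
  pop[m & !clustered] <- 1L

  cls <- matrix(CLASS_NONE, cmap$height, cmap$width)
  cls[m] <- CLASS_CORE
  cls[m & counts < params$min_pts] <- CLASS_BORDER
  cls[m & pop < params$min_pts] <- CLASS_NOISE
  structure(list(
    class = cls, width = cmap$width, height = cmap$height,
    n_core = sum(cls == CLASS_CORE), n_border = sum(cls == CLASS_BORDER),
    n_noise = sum(cls == CLASS_NOISE)
  ), class = "node_classification")
}

#' @export
print.node_classification <- function(x, ...) {
  cat(sprintf("<node_classification> %d core, %d border, %d noise\n",
              x$n_core, x$n_border, x$n_noise))
  invisible(x)
}

#' Per-node classification records
#'
#' @param x a `node_classification`.
#' @param cmap optional `cluster_map` to include cluster ids.
#' @param ... unused.
#' @return data frame `x`, `y`, `pid`, `class` (`"core"`, `"border"`,
#'   `"noise"`), and `cluster_id` when `cmap` is given; sorted by pid.
#' @export
as.data.frame.node_classification <- function(x, cmap = NULL, ...) {
  cells <- which(x$class != CLASS_NONE)
  xy <- cell_xy(cells, x$height)
  df <- data.frame(x = xy$x, y = xy$y,
                   pid = pid_from_xy(xy$x, xy$y, x$width),
                   class = class_names[x$class[cells]])
  if (!is.null(cmap)) df$cluster_id <- cmap$labels[cells]
  df[order(df$pid), , drop = FALSE]
}

#' Paint the detected border onto an image
#'
#' Returns a copy of the image with border pixels painted `border_color`
#' (default pure green, a color with high contrast against skin) and,
#' optionally, core pixels painted `core_color`. Noise pixels are never
#' touched.
#'
#' @param image integer array `h x w x 3` (0..255).
#' @param cls a `node_classification`.
#' @param border_color,core_color RGB triplets in 0..255; `NULL` leaves the
#'   class unpainted.
#' @return integer array `h x w x 3`.
#' @export
render_overlay <- function(image, cls, border_color = c(0L, 255L, 0L),
                           core_color = NULL) {
  stopifnot(inherits(cls, "node_classification"),
            length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (dim(image)[1] != cls$height || dim(image)[2] != cls$width)
    stop("image and classification dimensions disagree")
  out <- image
  paint <- function(out, which_cls, col) {
    cells <- which(cls$class == which_cls)
    if (!length(cells)) return(out)
    xy <- cell_xy(cells, cls$height)
    for (k in 1:3)
      out[cbind(xy$y + 1L, xy$x + 1L, k)] <- as.integer(col[k])
    out
  }
  if (!is.null(core_color)) out <- paint(out, CLASS_CORE, core_color)
  if (!is.null(border_color)) out <- paint(out, CLASS_BORDER, border_color)
  out
}

#' Binary mask of the detected lesion region
#'
#' The filled region (core plus border pixels; noise excluded) of either the
#' largest cluster — the dermoscopy default, since an image holds one
#' dominant lesion — or of all clusters. Largest is by member count, ties
#' broken by the smaller cluster id.
#'
#' @param cls a `node_classification`.
#' @param cmap the matching `cluster_map`.
#' @param mode `"largest_cluster"` or `"all_clusters"`.
#' @return a [node_mask()].
#' @export
lesion_region_mask <- function(cls, cmap,
                               mode = c("largest_cluster", "all_clusters")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cls, "node_classification"), inherits(cmap, "cluster_map"))
  member <- cls$class %in% c(CLASS_CORE, CLASS_BORDER)
  lab <- cmap$labels
  keep <- member & !is.na(lab) & lab >= 0L
  if (mode == "largest_cluster" && any(keep)) {
    sizes <- table(lab[keep])
    ids <- as.integer(names(sizes))
    best <- ids[order(-as.integer(sizes), ids)][1]
    keep <- keep & lab == best
  }
  node_mask(matrix(keep, cmap$height, cmap$width))
}
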