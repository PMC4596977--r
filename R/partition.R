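## Shingled partitioning: the image is tiled by non-overlapping core
## rectangles, and each partition's working view extends a lap region past
## the core to the right and bottom so that edge pixels still see full
## neighborhoods in *some* partition.

#' Split a mask into shingled partitions
#'
#' Tiles the image with `ceiling(width / core_width) x
#' ceiling(height / core_height)` core rectangles (row-major; the last row /
#' column of cores is clipped at the image edge). Each partition's view is
#' its core plus a lap region of `2 * eps + 1` pixels extending right and
#' bottom (clipped at the image), so a shingle overlaps the shingles to its
#' immediate right, below, and bottom-right. The lap width guarantees that
#' every pixel has its complete `eps`-neighborhood inside at least one view,
#' which is what makes per-partition density judgements globally valid.
#'
#' @param mask a [node_mask()].
#' @param core_width,core_height core tile size in pixels, >= 1.
#' @param eps Manhattan radius the partitions will be scanned with.
#' @param lap lap width in pixels; the default `2 * eps + 1` is required for
#'   correctness and overriding it exists only to demonstrate (e.g. in tests)
#'   that narrower laps break the serial/partitioned equivalence.
#' @return list of `partition` objects, row-major. Each has 0-based global
#'   offsets `x_off`, `y_off`, the clipped `core_width`/`core_height`, view
#'   dimensions `width`/`height`, the global image size, and `view`, the mask
#'   restricted to core + lap.
#' @examples
#' m <- node_mask(matrix(FALSE, 100, 100))
#' p <- create_partitions(m, 50, 50, eps = 3)
#' length(p)             # 4
#' p[[1]]$width          # 57 = 50 + 2*3 + 1
#' @export
create_partitions <- function(mask, core_width, core_height, eps,
                              lap = 2L * eps + 1L) {
  stopifnot(is_node_mask(mask))
  core_width <- as.integer(core_width); core_height <- as.integer(core_height)
  if (core_width < 1L || core_height < 1L)
    stop("core partition size must be >= 1 pixel")
  lap <- as.integer(lap)
  h <- mask_height(mask); w <- mask_width(mask)
  n_cols <- ceiling(w / core_width)
  n_rows <- ceiling(h / core_height)
  parts <- vector("list", n_rows * n_cols)
  i <- 0L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      x_off <- (c - 1L) * core_width
      y_off <- (r - 1L) * core_height
      cw <- min(core_width, w - x_off)
      ch <- min(core_height, h - y_off)
      vw <- min(cw + lap, w - x_off)
      vh <- min(ch + lap, h - y_off)
      i <- i + 1L
      parts[[i]] <- structure(list(
        index = i, x_off = x_off, y_off = y_off,
        core_width = cw, core_height = ch,
        width = vw, height = vh,
        img_width = w, img_height = h, lap = lap,
        view = unclass(mask)[y_off + seq_len(vh), x_off + seq_len(vw),
                             drop = FALSE]
      ), class = "partition")
    }
  }
  structure(parts, class = "partition_set",
            grid = c(rows = n_rows, cols = n_cols))
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf(
    "<partition #%d> core %dx%d at (%d, %d), view %dx%d (lap %d), %d nodes\n",
    x$index, x$core_width, x$core_height, x$x_off, x$y_off,
    x$width, x$height, x$lap, sum(x$view)))
  invisible(x)
}

#' @export
print.partition_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<partition_set> %d partitions (%d x %d grid)\n",
              length(x), g["rows"], g["cols"]))
  invisible(x)
}

# global pid of every view cell, same shape as part$view
partition_pid_matrix <- function(part) {
  x <- part$x_off + seq_len(part$width) - 1L
  y <- part$y_off + seq_len(part$height) - 1L
  matrix(rep(y, times = part$width) * part$img_width +
           rep(x, each = part$height),
         nrow = part$height, ncol = part$width)
}
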