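#' shinglescan: density-based lesion border detection on pixel grids
#'
#' Clusters dark pixels of a dermoscopy image with a grid-adapted DBSCAN
#' (Manhattan-distance neighborhoods), either serially or through shingled
#' image partitions whose per-partition labelings are merged into a global
#' one. See `vignette("lesion-border-detection", package = "shinglescan")`
#' for the method.
#'
#' @section Conventions:
#' Rasters are stored as R matrices indexed `[row, col]` with the origin at
#' the top-left; pixel coordinates are 0-based with `x` the column and `y`
#' the row. Every pixel has a unique id `pid = y * width + x` (row-major),
#' which provides the total order used for cluster naming.
#'
#' @name shinglescan-package
#' @keywords internal
"_PACKAGE"

#' Sentinel label for noise pixels
#'
#' Cluster labels are pixel ids (non-negative integers); `NOISE_LABEL` is a
#' reserved value distinct from every pid. Pixels that are not nodes carry
#' `NA` instead.
#' @export
NOISE_LABEL <- -1L

## ---- node mask -------------------------------------------------------------

#' Binary node mask
#'
#' A `node_mask` is a logical matrix (`[row, col]`, top-left origin) marking
#' which pixels belong to the point set the clustering operates on.
#'
#' @param is_node logical matrix, `TRUE` = pixel is a node.
#' @return An object of class `node_mask`.
#' @examples
#' m <- node_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' n_nodes(m)
#' @export
node_mask <- function(is_node) {
  if (is.null(dim(is_node)) || length(dim(is_node)) != 2L)
    stop("`is_node` must be a 2-D matrix")
  storage.mode(is_node) <- "logical"
  if (anyNA(is_node)) stop("`is_node` must not contain NA")
  if (nrow(is_node) < 1L || ncol(is_node) < 1L)
    stop("mask must be at least 1x1")
  structure(is_node, class = c("node_mask", "matrix"))
}

#' @rdname node_mask
#' @param x object to test or count.
#' @export
is_node_mask <- function(x) inherits(x, "node_mask")

#' @rdname node_mask
#' @export
n_nodes <- function(x) sum(unclass(x))

#' @export
print.node_mask <- function(x, ...) {
  cat(sprintf("<node_mask> %d x %d pixels, %d nodes (%.1f%%)\n",
              mask_width(x), mask_height(x), n_nodes(x),
              100 * n_nodes(x) / length(x)))
  invisible(x)
}

mask_width  <- function(mask) ncol(mask)
mask_height <- function(mask) nrow(mask)

## ---- pixel ids -------------------------------------------------------------

#' Pixel id conventions
#'
#' Pixels are identified by `pid = y * width + x` with 0-based `x` (column)
#' and `y` (row); pids are a bijection with coordinates and strictly
#' increasing in raster-scan order.
#'
#' @param x,y 0-based column and row indices (vectorized).
#' @param width image width in pixels.
#' @return `pid_from_xy()` returns integer pids; `xy_from_pid()` a data frame
#'   with columns `x` and `y`.
#' @examples
#' pid_from_xy(2, 1, width = 10)  # 12
#' xy_from_pid(12L, width = 10)
#' @export
pid_from_xy <- function(x, y, width) {
  as.integer(y) * as.integer(width) + as.integer(x)
}

#' @rdname pid_from_xy
#' @param pid integer pixel ids.
#' @export
xy_from_pid <- function(pid, width) {
  pid <- as.integer(pid)
  data.frame(x = pid %% as.integer(width), y = pid %/% as.integer(width))
}

# matrix of pids for an H x W raster (same shape as the mask)
pid_matrix <- function(h, w) {
  matrix(rep(seq_len(h) - 1L, times = w) * w + rep(seq_len(w) - 1L, each = h),
         nrow = h, ncol = w)
}

# convert R linear (column-major) cell indices to 0-based x/y
cell_xy <- function(cells, h) {
  list(x = (cells - 1L) %/% h, y = (cells - 1L) %% h)
}

## ---- clustering parameters -------------------------------------------------

#' Clustering parameters
#'
#' `eps` is the Manhattan neighborhood radius in pixels and `min_pts` the
#' minimum neighborhood population (the query pixel counts itself) for a node
#' to be dense. Defaults are the values used for the dermoscopy experiments
#' this method was developed on.
#'
#' @param eps integer Manhattan radius, >= 1.
#' @param min_pts integer minimum neighborhood density, >= 1.
#' @return An object of class `db_params`.
#' @examples
#' db_params()          # eps 3, min_pts 4
#' db_params(1, 2)
#' @export
db_params <- function(eps = 3L, min_pts = 4L) {
  eps <- as.integer(eps); min_pts <- as.integer(min_pts)
  if (length(eps) != 1L || is.na(eps) || eps < 1L)
    stop("`eps` must be a single integer >= 1")
  if (length(min_pts) != 1L || is.na(min_pts) || min_pts < 1L)
    stop("`min_pts` must be a single integer >= 1")
  structure(list(eps = eps, min_pts = min_pts), class = "db_params")
}

#' @export
print.db_params <- function(x, ...) {
  cat(sprintf("<db_params> eps = %d (Manhattan), min_pts = %d\n",
              x$eps, x$min_pts))
  invisible(x)
}

as_db_params <- function(params) {
  if (inherits(params, "db_params")) return(params)
  if (is.list(params) && all(c("eps", "min_pts") %in% names(params)))
    return(db_params(params$eps, params$min_pts))
  stop("`params` must be created with db_params()")
}

## ---- raster I/O ------------------------------------------------------------

#' Read an RGB image (PNG or binary PPM)
#'
#' Returns an integer array `[height, width, 3]` with 8-bit channel values.
#' Grayscale images are promoted to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path path to a PNG or binary (P6) PPM file.
#' @return integer array `h x w x 3`, values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  magic <- tryCatch(readBin(path, "raw", n = 8L), error = function(e) raw(0))
  if (length(magic) >= 8 &&
      identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot read PNG file ", path,
                                             ": ", conditionMessage(e)))
    return(png_to_rgb255(img))
  }
  if (length(magic) >= 2 && rawToChar(magic[1:2]) == "P6")
    return(read_ppm(path))
  stop("unsupported or corrupt image file (need PNG or binary PPM): ", path)
}

png_to_rgb255 <- function(img) {
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  out <- array(0L, c(h, w, 3L))
  if (nc == 1L || nc == 2L) {          # gray (+alpha): replicate
    g <- as.integer(round(img[, , 1] * 255))
    for (k in 1:3) out[, , k] <- g
  } else {
    for (k in 1:3) out[, , k] <- as.integer(round(img[, , k] * 255))
  }
  out
}

# binary PPM (P6), maxval <= 255
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- ppm_tokenizer(con)
  if (!identical(tok(), "P6")) stop("not a binary PPM (P6) file: ", path)
  w <- suppressWarnings(as.integer(tok()))
  h <- suppressWarnings(as.integer(tok()))
  maxval <- suppressWarnings(as.integer(tok()))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L)
    stop("corrupt PPM header in ", path)
  if (maxval > 255L) stop("16-bit PPM not supported: ", path)
  px <- readBin(con, "integer", n = 3L * w * h, size = 1L, signed = FALSE)
  if (length(px) < 3L * w * h) stop("truncated PPM pixel data in ", path)
  # pixel data is row-major, channel-interleaved
  arr <- array(0L, c(h, w, 3L))
  px <- matrix(px, nrow = 3L)                 # [channel, pixel] pixel row-major
  for (k in 1:3)
    arr[, , k] <- matrix(px[k, ], nrow = h, ncol = w, byrow = TRUE)
  arr
}

# whitespace/comment-aware single-token reader for PPM headers; stops after
# the maxval token so the following single whitespace byte separates the
# binary pixel block
ppm_tokenizer <- function(con) {
  function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (length(tok)) break else stop("unexpected end of PPM header")
      } else if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
      } else if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break
      } else {
        tok <- c(tok, ch)
      }
    }
    paste(tok, collapse = "")
  }
}

#' Write an RGB image as PNG
#'
#' @param path output path.
#' @param image integer array `h x w x 3`, values 0..255.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Write a binary PPM (P6) image
#'
#' @inheritParams write_image
#' @export
write_ppm <- function(path, image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  # interleave channels pixel-by-pixel in row-major order
  px <- aperm(image, c(3L, 2L, 1L))   # [channel, col, row]; vectorizes to RGBRGB...
  writeBin(as.integer(as.vector(px)), con, size = 1L)
  invisible(path)
}

## ---- node extraction -------------------------------------------------------

#' Extract the node set from an RGB image
#'
#' Thresholds one color channel: a pixel is a node when its channel value is
#' `<= threshold`. Lesions are darker than the surrounding skin, so low
#' intensities mark lesion candidates; the blue channel is the conventional
#' choice for dermoscopy.
#'
#' @param image integer array `h x w x 3` (0..255), e.g. from [read_image()].
#' @param channel one of `"R"`, `"G"`, `"B"`.
#' @param threshold inclusive upper intensity bound, in 0..255.
#' @return a [node_mask()].
#' @examples
#' img <- array(200L, c(4, 4, 3))
#' img[2, 2, ] <- 30L
#' extract_nodes(img, "B", 128)
#' @export
extract_nodes <- function(image, channel = c("B", "R", "G"), threshold = 128) {
  channel <- match.arg(channel)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("`threshold` must be in [0, 255]")
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  k <- match(channel, c("R", "G", "B"))
  ch <- image[, , k, drop = FALSE]
  dim(ch) <- dim(image)[1:2]
  node_mask(ch <= threshold)
}

## ---- mask I/O --------------------------------------------------------------

#' Read / write a node mask as a single-channel PNG
#'
#' Nonzero pixels are nodes. `write_mask()` stores nodes as 255 and
#' background as 0; `read_mask(write_mask(...))` is the identity.
#'
#' @param path PNG path.
#' @param mask a [node_mask()].
#' @param expect_dim optional `c(height, width)`; mismatch is an error.
#' @return `read_mask()` returns a [node_mask()]; `write_mask()` its path,
#'   invisibly.
#' @export
read_mask <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read PNG mask ", path, ": ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!is.null(expect_dim) && !identical(dim(img), as.integer(expect_dim)))
    stop(sprintf("mask %s is %dx%d, expected %dx%d", path,
                 nrow(img), ncol(img), expect_dim[1], expect_dim[2]))
  node_mask(img > 0)
}

#' @rdname read_mask
#' @export
write_mask <- function(path, mask) {
  stopifnot(is_node_mask(mask))
  png::writePNG(unclass(mask) * 1, target = path)
  invisible(path)
}
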