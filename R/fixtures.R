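## Seeded generators for every input the pipeline and its equivalence proofs
## need: Bernoulli random masks, dermoscopy-like lesion images (one dark
## irregular connected blob on lighter skin, plus isolated salt noise),
## worst-case serpentine paths, and partition-spanning lattice clusters.
## All generators are pure functions of their spec: same seed, same bytes.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Fixture specification
#'
#' Validated container for the generator parameters; [make_fixture()]
#' dispatches on `kind`. Field relevance by kind: `density` for
#' `random_mask`; `irregularity`, `noise_rate` for `lesion_blob`;
#' `path_length` for `serpentine_path`; `core_width`, `core_height`, `eps`
#' for `split_cluster`.
#'
#' @param kind one of `"random_mask"`, `"lesion_blob"`, `"serpentine_path"`,
#'   `"split_cluster"`.
#' @param width,height raster size in pixels.
#' @param seed RNG seed (integer).
#' @param density node probability in `[0, 1]` (random_mask).
#' @param irregularity boundary roughness, >= 0; 0 gives a near-circular
#'   blob (lesion_blob).
#' @param noise_rate fraction of background pixels turned into isolated
#'   dark salt pixels (lesion_blob).
#' @param path_length number of path pixels (serpentine_path).
#' @param core_width,core_height,eps partition geometry the split cluster
#'   must span (split_cluster).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("random_mask", "lesion_blob",
                                  "serpentine_path", "split_cluster"),
                         width = 64L, height = 64L, seed = 1L,
                         density = 0.5, irregularity = 0.3,
                         noise_rate = 0.01, path_length = 44L,
                         core_width = 16L, core_height = 16L, eps = 3L) {
  kind <- match.arg(kind)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("fixture raster must be at least 1x1")
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]")
  if (irregularity < 0) stop("`irregularity` must be >= 0")
  if (noise_rate < 0 || noise_rate > 1) stop("`noise_rate` must be in [0, 1]")
  if (path_length < 1L) stop("`path_length` must be >= 1")
  structure(list(kind = kind, width = width, height = height,
                 seed = as.integer(seed), density = density,
                 irregularity = irregularity, noise_rate = noise_rate,
                 path_length = as.integer(path_length),
                 core_width = as.integer(core_width),
                 core_height = as.integer(core_height),
                 eps = as.integer(eps)),
            class = "fixture_spec")
}

#' Generate the fixture described by a spec
#'
#' @param spec a [fixture_spec()].
#' @return a [node_mask()] for mask kinds; for `"lesion_blob"` the full list
#'   from [make_lesion_image()].
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  switch(spec$kind,
    random_mask     = make_random_mask(spec$width, spec$height, spec$density,
                                       spec$seed),
    lesion_blob     = make_lesion_image(spec$width, spec$height,
                                        seed = spec$seed,
                                        irregularity = spec$irregularity,
                                        noise_rate = spec$noise_rate),
    serpentine_path = make_serpentine(spec$path_length, spec$width,
                                      spec$height),
    split_cluster   = make_split_cluster(spec$width, spec$height,
                                         spec$core_width, spec$core_height,
                                         spec$eps)
  )
}

#' Bernoulli random node mask
#'
#' Each pixel is independently a node with probability `density`.
#'
#' @param width,height raster size.
#' @param density node probability in `[0, 1]`.
#' @param seed RNG seed; identical arguments give identical masks.
#' @return a [node_mask()].
#' @export
make_random_mask <- function(width, height, density, seed = 1L) {
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]")
  with_seed(seed, {
    node_mask(matrix(stats::runif(width * height) < density,
                     nrow = height, ncol = width))
  })
}

# bilinear upsample of a coarse g x g field to h x w
upsample_bilinear <- function(coarse, h, w) {
  g <- nrow(coarse)
  ry <- seq(1, g, length.out = h)
  rx <- seq(1, g, length.out = w)
  y0 <- pmin(floor(ry), g - 1L); x0 <- pmin(floor(rx), g - 1L)
  fy <- ry - y0; fx <- rx - x0
  a <- coarse[cbind(rep(y0, times = w), rep(x0, each = h))]
  b <- coarse[cbind(rep(y0, times = w), rep(x0 + 1L, each = h))]
  c_ <- coarse[cbind(rep(y0 + 1L, times = w), rep(x0, each = h))]
  d <- coarse[cbind(rep(y0 + 1L, times = w), rep(x0 + 1L, each = h))]
  FY <- rep(fy, times = w); FX <- rep(fx, each = h)
  matrix(a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX +
           c_ * FY * (1 - FX) + d * FY * FX, nrow = h, ncol = w)
}

# largest 4-connected component of a logical matrix (Manhattan radius 1)
largest_component <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  off <- manhattan_offsets(1L)
  for (cell in which(m)) {
    if (lab[cell] != 0L) next
    cur <- cur + 1L
    lab[cell] <- cur
    frontier <- cell
    while (length(frontier)) {
      fxy <- cell_xy(frontier, h)
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        nx <- fxy$x + off[k, 1]; ny <- fxy$y + off[k, 2]
        ok <- nx >= 0L & nx < w & ny >= 0L & ny < h
        if (!any(ok)) next
        idx <- nx[ok] * h + ny[ok] + 1L
        idx <- idx[m[idx] & lab[idx] == 0L]
        if (length(idx)) { lab[idx] <- cur; nxt <- c(nxt, idx) }
      }
      frontier <- unique(nxt)
    }
  }
  if (cur == 0L) return(m)   # empty
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  lab == which.max(sizes)
}

#' Synthetic dermoscopy-like lesion image
#'
#' Emulates only what the detector consumes: one dark, connected,
#' irregularly-bounded blob (the lesion) on a lighter background, plus
#' isolated dark salt pixels. The blob is the largest connected component
#' of a thresholded field `d/r - 1 + irregularity * S`, where `d` is the
#' distance to the image center, `r` a base radius of `0.32 * min(w, h)`,
#' and `S` seeded smooth (bilinearly upsampled coarse Gaussian) noise; with
#' `irregularity = 0` the blob is a disc. Blob and salt pixels get blue
#' value 40 and the background 180, so thresholding the blue channel at the
#' default 128 recovers blob + salt exactly. Salt pixels keep a Manhattan
#' distance greater than `salt_margin` from the blob and from each other, so
#' for any `eps <= salt_margin` they are isolated single-pixel groups.
#'
#' @param width,height image size in pixels.
#' @param seed RNG seed.
#' @param irregularity boundary roughness (>= 0).
#' @param noise_rate fraction of background pixels to salt.
#' @param salt_margin minimum Manhattan separation of salt pixels from the
#'   blob and from one another (default 4, isolating salt for `eps <= 3`).
#' @return list with `image` (integer `h x w x 3`), `mask` (the clean blob
#'   as ground truth, a [node_mask()]), and `salt` (data frame of salt pixel
#'   coordinates).
#' @export
make_lesion_image <- function(width, height, seed = 1L, irregularity = 0.3,
                              noise_rate = 0.01, salt_margin = 4L) {
  w <- as.integer(width); h <- as.integer(height)
  with_seed(seed, {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    r0 <- 0.32 * min(w, h)
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    S <- upsample_bilinear(matrix(stats::rnorm(36), 6, 6), h, w)
    blob <- largest_component(d / r0 - 1 + irregularity * S <= 0)

    img <- array(0L, c(h, w, 3L))
    img[, , 1] <- ifelse(blob, 70L, 205L)
    img[, , 2] <- ifelse(blob, 45L, 160L)
    img[, , 3] <- ifelse(blob, 40L, 180L)

    # salt: dark isolated pixels well clear of the blob and of each other
    away <- shift_sum(blob * 1, manhattan_offsets(salt_margin)) == 0
    cand <- which(!blob & away)
    n_salt <- floor(noise_rate * sum(!blob))
    salt_cells <- integer(0)
    if (n_salt > 0 && length(cand)) {
      for (cell in cand[sample.int(length(cand))]) {
        if (length(salt_cells) >= n_salt) break
        xy <- cell_xy(cell, h)
        if (length(salt_cells)) {
          kept <- cell_xy(salt_cells, h)
          if (min(abs(kept$x - xy$x) + abs(kept$y - xy$y)) <= salt_margin)
            next
        }
        salt_cells <- c(salt_cells, cell)
      }
      for (k in 1:3)
        img[salt_cells + (k - 1L) * h * w] <- c(70L, 45L, 40L)[k]
    }
    sxy <- cell_xy(salt_cells, h)
    list(image = img, mask = node_mask(blob),
         salt = data.frame(x = sxy$x, y = sxy$y,
                           pid = pid_from_xy(sxy$x, sxy$y, w)))
  })
}

#' Worst-case serpentine path mask
#'
#' A 1-pixel-wide boustrophedon path of exactly `path_length` node pixels:
#' horizontal runs on every second row, joined by single connector pixels,
#' so consecutive path pixels are 4-adjacent while non-consecutive pixels
#' are always at Manhattan distance >= 2. The path starts at (0, 0), which
#' is also the smallest pid, so with `eps = 1` the minimum label must crawl
#' the full path: [process_partition()] needs exactly `path_length` scan
#' passes (including the final no-change pass).
#'
#' @param path_length number of path pixels, >= 1.
#' @param width,height optional raster size; auto-sized when `NULL`. The
#'   path must fit, else an error.
#' @return a [node_mask()] with attribute `"path"`, the path pixels in order
#'   (data frame `x`, `y`).
#' @export
make_serpentine <- function(path_length, width = NULL, height = NULL) {
  L <- as.integer(path_length)
  if (L < 1L) stop("`path_length` must be >= 1")
  if (is.null(width)) width <- max(2L, as.integer(ceiling(sqrt(2 * L))))
  width <- as.integer(width)
  if (width < 1L) stop("`width` must be >= 1")
  run <- min(width, L)

  px <- integer(0); py <- integer(0)
  y <- 0L; leftward <- FALSE
  while (length(px) < L) {
    xs <- if (leftward) (run - 1L):0L else 0L:(run - 1L)
    px <- c(px, xs); py <- c(py, rep(y, length(xs)))
    if (length(px) >= L) break
    px <- c(px, xs[length(xs)])   # connector below the run's end
    py <- c(py, y + 1L)
    y <- y + 2L
    leftward <- !leftward
  }
  px <- px[seq_len(L)]; py <- py[seq_len(L)]

  need_h <- max(py) + 1L
  if (is.null(height)) height <- need_h
  height <- as.integer(height)
  if (need_h > height || max(px) + 1L > width)
    stop(sprintf("path of length %d does not fit a %dx%d raster",
                 L, width, height))
  m <- matrix(FALSE, height, width)
  m[cbind(py + 1L, px + 1L)] <- TRUE
  out <- node_mask(m)
  attr(out, "path") <- data.frame(x = px, y = py)
  out
}

#' Partition-spanning lattice cluster
#'
#' One connected cluster crossing every internal partition boundary of a
#' `core_width x core_height` tiling: a 2-pixel-thick horizontal line
#' through the middle of every partition row band and a vertical one through
#' every column band. Adversarial input for the merge stage — every
#' partition sees fragments that only the transitive merge can unify.
#'
#' @param width,height raster size.
#' @param core_width,core_height the partition geometry to span.
#' @param eps unused in construction (accepted for spec symmetry with the
#'   partition grid the fixture targets).
#' @return a [node_mask()].
#' @export
make_split_cluster <- function(width, height, core_width, core_height,
                               eps = 3L) {
  w <- as.integer(width); h <- as.integer(height)
  cw <- as.integer(core_width); ch <- as.integer(core_height)
  if (w <= cw && h <= ch)
    stop("raster must be larger than one partition")
  m <- matrix(FALSE, h, w)
  n_cols <- ceiling(w / cw); n_rows <- ceiling(h / ch)
  for (j in seq_len(n_cols)) {                 # vertical line per column band
    x0 <- min((j - 1L) * cw + max(cw %/% 2L, 1L), w - 1L)
    xs <- unique(pmin(pmax(c(x0, x0 + 1L), 0L), w - 1L))
    m[, xs + 1L] <- TRUE
  }
  for (i in seq_len(n_rows)) {                 # horizontal line per row band
    y0 <- min((i - 1L) * ch + max(ch %/% 2L, 1L), h - 1L)
    ys <- unique(pmin(pmax(c(y0, y0 + 1L), 0L), h - 1L))
    m[ys + 1L, ] <- TRUE
  }
  node_mask(m)
}
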