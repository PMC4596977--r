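## Segmentation accuracy: pixelwise confusion counts of an automatic lesion
## region mask against a manual (ground-truth) mask, the XOR border error,
## and precision/recall.

#' Compare an automatic lesion mask against a manual one
#'
#' Pixelwise confusion counts with the manual mask as truth, and from them:
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and the XOR
#' border error `100 * |A xor M| / |M| = 100 * (fp + fn) / (tp + fn)` — the
#' symmetric-difference area normalized by the manual lesion area, expressed
#' in percent. Over-segmentation can push the border error past 100%.
#'
#' @param auto,manual [node_mask()]s of identical dimensions; `manual` must
#'   be non-empty (the border error is undefined otherwise).
#' @return object of class `eval_report`: `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `border_error_pct`.
#' @examples
#' a <- node_mask(matrix(c(rep(TRUE, 50), rep(FALSE, 50)), 10, 10))
#' m <- node_mask(matrix(TRUE, 10, 10))
#' evaluate_masks(a, m)   # precision 1, recall 0.5, border error 50%
#' @export
evaluate_masks <- function(auto, manual) {
  stopifnot(is_node_mask(auto), is_node_mask(manual))
  if (!identical(dim(auto), dim(manual)))
    stop(sprintf("mask dimensions disagree: %dx%d vs %dx%d",
                 nrow(auto), ncol(auto), nrow(manual), ncol(manual)))
  a <- unclass(auto); m <- unclass(manual)
  if (!any(m)) stop("manual mask is empty: border error undefined")
  tp <- sum(a & m); fp <- sum(a & !m); fn <- sum(!a & m); tn <- sum(!a & !m)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = tp / (tp + fn),
    border_error_pct = 100 * (fp + fn) / (tp + fn)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> border error %.2f%%, precision %.4f, recall %.4f (tp %d, fp %d, fn %d)\n",
    x$border_error_pct, x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Batch evaluation table
#'
#' One row per (automatic, manual) pair plus an unweighted means row, in the
#' layout `image_id`, `border_error_pct`, `precision`, `recall`.
#'
#' @param pairs list of `list(auto = , manual = )` mask pairs.
#' @param ids optional character labels (default `"img_1"`, ...).
#' @return data frame; the final row has `image_id = "mean"`.
#' @export
batch_report <- function(pairs, ids = NULL) {
  stopifnot(length(pairs) >= 1L)
  if (is.null(ids)) ids <- paste0("img_", seq_along(pairs))
  stopifnot(length(ids) == length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    r <- evaluate_masks(pairs[[i]]$auto, pairs[[i]]$manual)
    data.frame(image_id = ids[i], border_error_pct = r$border_error_pct,
               precision = r$precision, recall = r$recall)
  })
  out <- do.call(rbind, rows)
  means <- data.frame(image_id = "mean",
                      border_error_pct = mean(out$border_error_pct),
                      precision = mean(out$precision),
                      recall = mean(out$recall))
  rbind(out, means)
}
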