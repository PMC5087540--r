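# Overlap metrics for binary segmentation masks: precision |M∩G|/|M|,
# recall |M∩G|/|G|, and their harmonic mean F1.

#' @noRd
check_masks <- function(m, g) {
  if (!all(dim(m) == dim(g)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(m), ncol(m), nrow(g), ncol(g)), call. = FALSE)
  if (!all(m %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("masks must contain only 0/1 values", call. = FALSE)
  invisible(NULL)
}

#' Precision of a segmentation mask
#'
#' `|M intersect G| / |M|`: the fraction of segmented pixels that are truly
#' foreground. An empty segmentation yields 0 with a warning rather than an
#' error, so batch pipelines keep running.
#'
#' @param m Segmentation result mask (0/1 matrix).
#' @param g Ground-truth mask, same shape.
#' @return A scalar in \[0, 1\].
#' @export
mask_precision <- function(m, g) {
  check_masks(m, g)
  denom <- sum(m == 1)
  if (denom == 0) {
    warning("empty segmentation mask: precision defined as 0")
    return(0)
  }
  sum(m == 1 & g == 1) / denom
}

#' Recall of a segmentation mask
#'
#' `|M intersect G| / |G|`: the fraction of true foreground recovered.
#'
#' @inheritParams mask_precision
#' @return A scalar in \[0, 1\].
#' @export
mask_recall <- function(m, g) {
  check_masks(m, g)
  denom <- sum(g == 1)
  if (denom == 0) {
    warning("empty ground-truth mask: recall defined as 0")
    return(0)
  }
  sum(m == 1 & g == 1) / denom
}

#' F1 measure from precision and recall
#'
#' `F = 2 P R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param p,r Precision and recall, each in \[0, 1\].
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' f1_measure(0.9475, 0.9246)  # 0.9359 to 4 decimals
f1_measure <- function(p, r) {
  if (any(p < 0 | p > 1) || any(r < 0 | r > 1))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(p))
  pos <- (p + r) > 0
  out[pos] <- 2 * p[pos] * r[pos] / (p[pos] + r[pos])
  out
}

#' Score a segmentation mask against ground truth
#'
#' @inheritParams mask_precision
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
#' @examples
#' g <- matrix(c(1, 1, 0, 0), 2, 2)
#' evaluate_mask(g, g)
evaluate_mask <- function(m, g) {
  p <- mask_precision(m, g)
  r <- mask_recall(m, g)
  tibble::tibble(precision = p, recall = r, f1 = f1_measure(p, r))
}
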