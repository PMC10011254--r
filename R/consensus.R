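#' Majority-vote consensus contour
#'
#' Fuses several binary segmentations of the same grid into a consensus
#' contour: a voxel belongs to the consensus iff it belongs to at least
#' `k` of the input masks. With `k = 1` the result is the union, with
#' `k = length(masks)` the intersection; the default is the strict
#' majority of four methods (`k = 3`).
#'
#' @param masks list of logical 3-D masks (or `segmentation_result`
#'   objects) on one common grid; at least 2.
#' @param k minimum number of agreeing masks, `1 <= k <= length(masks)`.
#' @return Logical consensus mask.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 2))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(1, 2, 2))
#' majority_vote(list(a, b), k = 2)  # intersection
#' @export
majority_vote <- function(masks, k = 3L) {
  masks <- lapply(masks, function(m)
    if (inherits(m, "segmentation_result")) m$mask else m)
  if (length(masks) < 2L) stop("need at least 2 masks")
  if (k < 1L || k > length(masks))
    stop("'k' must be between 1 and the number of masks")
  d <- dim(masks[[1]])
  for (m in masks[-1]) check_same_grid(masks[[1]], m, "vote masks")
  votes <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), d)))
  array(votes >= k, d)
}

#' Per-case average of per-method metric values (AveSeg)
#'
#' The "average segmentation" summary: the arithmetic mean of the
#' individual methods' metric values (MATV, RE, or DSC) for one case and
#' mask condition. This averages metrics, not contours. Missing values
#' are dropped; if all are missing the result is `NA`.
#'
#' @param values numeric vector of per-method metric values.
#' @return The mean, or `NA_real_` when no finite value is available.
#' @examples
#' aveseg(c(20.15, 10.78, 14.51, 14.43))  # 14.97
#' @export
aveseg <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}
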