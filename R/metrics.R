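#' Metabolically active tumor volume
#'
#' Volume of a binary contour: voxel count times the physical volume of
#' one voxel.
#'
#' @param mask logical 3-D mask (or a `segmentation_result`).
#' @param spacing voxel spacing `(dz, dy, dx)` in cm; taken from the mask
#'   attributes if present.
#' @return Volume in cm^3.
#' @examples
#' matv(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))  # 1000
#' @export
matv <- function(mask, spacing = attr(mask, "spacing")) {
  if (inherits(mask, "segmentation_result")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("'spacing' is required")
  sum(mask) * prod(spacing)
}

#' Relative volume error
#'
#' `RE = (MATV(SM) - MATV(GT)) / MATV(GT) * 100`, in percent, of a
#' segmentation `sm` against a non-empty ground truth `gt`. Bounded below
#' by -100% (empty segmentation); negative values mean underestimation.
#'
#' @param sm segmentation mask (logical array or `segmentation_result`).
#' @param gt non-empty ground-truth mask on the same grid.
#' @param spacing voxel spacing in cm (any common spacing cancels; kept
#'   for interface symmetry with [matv()]). Default unit spacing.
#' @return Signed percentage.
#' @export
rel_vol_error <- function(sm, gt, spacing = c(1, 1, 1)) {
  if (inherits(sm, "segmentation_result")) { spacing <- sm$spacing; sm <- sm$mask }
  check_same_grid(sm, gt, "SM and GT")
  vgt <- sum(gt) * prod(spacing)
  if (vgt == 0) stop("ground truth is empty; RE undefined")
  (sum(sm) * prod(spacing) - vgt) / vgt * 100
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |SM intersect GT| / (|SM| + |GT|)`, in `[0, 1]`; symmetric in
#' its arguments. Undefined (error) when both masks are empty.
#'
#' @param sm,gt logical masks on one grid (`sm` may be a
#'   `segmentation_result`).
#' @return Overlap coefficient in `[0, 1]`.
#' @export
dsc <- function(sm, gt) {
  if (inherits(sm, "segmentation_result")) sm <- sm$mask
  check_same_grid(sm, gt, "SM and GT")
  denom <- sum(sm) + sum(gt)
  if (denom == 0) stop("both masks are empty; DSC undefined")
  2 * sum(sm & gt) / denom
}

#' Test-retest value between two mask conditions
#'
#' Symmetric-denominator relative difference of a metric computed under
#' the rectangle and the irregular initial mask,
#' `TRT = (m_rect - m_irr) / ((m_rect + m_irr) / 2)`.
#' Zero means perfect reproducibility; for non-negative metrics the value
#' is bounded in `[-2, 2]`. When the denominator is numerically zero
#' (possible for signed metrics such as RE) the value is undefined and
#' returned as `NA`.
#'
#' @param m_rect,m_irr metric values from the rectangle and irregular
#'   mask conditions (vectorized).
#' @return TRT value(s); `NA` where undefined.
#' @examples
#' trt(3, 1)  # 1
#' trt(0, 2)  # -2, the boundary for non-negative metrics
#' @export
trt <- function(m_rect, m_irr) {
  denom <- (m_rect + m_irr) / 2
  out <- (m_rect - m_irr) / denom
  out[abs(denom) < 1e-9] <- NA_real_
  out
}
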