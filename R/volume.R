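#' Construct a voxel volume
#'
#' A `voxel_volume` is the universal image carrier of the package: a 3-D
#' numeric array together with its physical voxel spacing. Axis order is
#' `(z, y, x)`, i.e. the first array dimension is the axial (cranio-caudal)
#' direction, matching the `(dz, dy, dx)` order of `spacing`.
#'
#' @param data 3-D numeric array of voxel values (finite).
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in cm;
#'   all entries must be positive. Default is the simulated-scanner grid
#'   spacing `c(0.50, 0.41, 0.41)`.
#' @return An object of class `voxel_volume`: the array with a `spacing`
#'   attribute.
#' @examples
#' v <- voxel_volume(array(1, c(4, 4, 4)))
#' voxel_size(v)  # cm^3 per voxel
#' @export
voxel_volume <- function(data, spacing = c(0.50, 0.41, 0.41)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (!all(is.finite(data)))
    stop("'data' must contain only finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (dz, dy, dx) in cm")
  structure(data, spacing = spacing, class = c("voxel_volume", "array"))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel spacing and voxel size
#'
#' @param x a `voxel_volume` (or any array with a `spacing` attribute).
#' @return `vox_spacing()`: the `(dz, dy, dx)` spacing in cm;
#'   `voxel_size()`: the volume of one voxel in cm^3.
#' @export
vox_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object has no 'spacing' attribute")
  sp
}

#' @rdname vox_spacing
#' @export
voxel_size <- function(x) prod(vox_spacing(x))

# carry a voxel_volume's class/spacing onto a plain array result
as_volume_like <- function(data, template) {
  voxel_volume(data, vox_spacing(template))
}

## ---- internal 3-D array utilities -------------------------------------

# Separable Gaussian blur with sigma given per axis in *voxels*.
# Edge handling: replicate padding, so a constant array stays constant.
gauss_blur3 <- function(x, sigma_vox) {
  d <- dim(x)
  out <- x
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    out <- .conv_axis(out, k, ax, d)
  }
  out
}

# convolve along axis `ax` with kernel k (odd length), replicate padding
.conv_axis <- function(x, k, ax, d) {
  r <- (length(k) - 1L) %/% 2L
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  # replicate-pad rows
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
  res <- stats::filter(mp, k, method = "convolution", sides = 2)
  res <- res[(r + 1L):(r + dp[1]), , drop = FALSE]
  out <- array(as.numeric(res), dp)
  aperm(out, order(perm))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Shift a 3-D array by whole voxels, filling exposed voxels with `fill`.
shift3 <- function(x, shift, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else        { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# 26-connectivity components; returns integer label array (0 = background)
label_components <- function(mask) {
  d <- dim(mask)
  lab <- cc_label26(as.logical(mask), as.integer(d))
  array(lab, d)
}

# keep only the largest 26-connected component of a logical array
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  tab <- tabulate(lab[lab > 0L])
  array(lab == which.max(tab), dim(mask))
}

# fill interior holes: background components not touching the array border
fill_holes <- function(mask) {
  d <- dim(mask)
  lab <- label_components(!mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  holes <- lab > 0L & !(lab %in% border)
  array(mask | holes, d)
}

# one 26-neighbourhood binary dilation step
dilate1 <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out | shift3(mask, c(dz, dy, dx), fill = FALSE)
  }
  out
}

# dilation depth map: 0 on the mask, k on voxels first reached at step k,
# Inf beyond `steps`
dilate_depth <- function(mask, steps) {
  depth <- array(Inf, dim(mask))
  depth[mask] <- 0
  cur <- mask
  for (k in seq_len(steps)) {
    nxt <- dilate1(cur)
    depth[nxt & !cur] <- k
    cur <- nxt
  }
  depth
}

# one 6-neighbourhood binary erosion step
erode1 <- function(mask) {
  out <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift3(mask, s, fill = FALSE)
  out
}

# erosion-depth (layer peeling) map: 1 on the boundary layer, increasing inward
peel_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    nxt <- erode1(cur)
    depth[cur & !nxt] <- k
    cur <- nxt
    if (k > max(dim(mask))) break
  }
  depth
}

# binary median (majority) filter over the 3x3x3 neighbourhood
binary_median3 <- function(mask) {
  cnt <- array(0L, dim(mask))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    cnt <- cnt + shift3(mask, c(dz, dy, dx), fill = FALSE)
  cnt >= 14L  # majority of the 27-voxel neighbourhood
}

# bounding box of a non-empty logical array, as a list of index ranges
bbox_ranges <- function(mask, margin = 0L) {
  stopifnot(any(mask))
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - margin)
    hi <- min(d[ax], max(idx[, ax]) + margin)
    lo:hi
  })
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
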