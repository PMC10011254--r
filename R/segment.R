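#' Segmentation configuration
#'
#' Tunable parameters of the four delineation methods.
#'
#' @param lambda active-contour data-fidelity (contrast) weight for the
#'   MASAC method; larger values weaken the boundary-smoothing penalty.
#'   Default 3.
#' @param st_a,st_b contrast-oriented thresholding coefficients: the
#'   threshold is `st_a * mSUV70 + st_b * BG`, where `mSUV70` is the mean
#'   of the region above 70% of the maximum and `BG` the mean background.
#'   The coefficients are scanner-specific calibration constants; defaults
#'   0.5 / 0.5.
#' @param ap_preference affinity-propagation exemplar preference:
#'   `"median"` (the median pairwise similarity, the method's customary
#'   default) or a number.
#' @param ap_damping message damping factor in (0, 1); default 0.9.
#'   One-dimensional intensity similarities carry many near-ties, for
#'   which lightly damped message passing is known to oscillate into
#'   degenerate all-exemplar states; 0.9 is stable across the package's
#'   phantom regime.
#' @param ap_rule which affinity-propagation cluster is the tumor:
#'   `"hottest"` (cluster whose exemplar has the highest intensity;
#'   default) or `"largest"` (largest-cardinality cluster).
#' @param ap_voxel_cap clustering is O(n^2) in voxels; initial masks with
#'   more voxels than this are intensity-stratified subsampled and the
#'   remaining voxels assigned to the nearest exemplar. Default 3000.
#' @param max_iter iteration cap for the iterative methods (default 200).
#' @param tol convergence tolerance (unused by the discrete methods,
#'   reserved; default 1e-4).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(lambda = 3, st_a = 0.5, st_b = 0.5,
                       ap_preference = "median", ap_damping = 0.9,
                       ap_rule = c("hottest", "largest"),
                       ap_voxel_cap = 3000L, max_iter = 200L, tol = 1e-4) {
  if (lambda <= 0) stop("'lambda' must be positive")
  if (ap_damping <= 0 || ap_damping >= 1) stop("'ap_damping' must be in (0, 1)")
  ap_rule <- match.arg(ap_rule)
  structure(list(lambda = lambda, st_a = st_a, st_b = st_b,
                 ap_preference = ap_preference, ap_damping = ap_damping,
                 ap_rule = ap_rule, ap_voxel_cap = as.integer(ap_voxel_cap),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "seg_config")
}

# common wrapper: package a mask as a segmentation_result
seg_result <- function(mask, method, image, failed = FALSE,
                       converged = TRUE, mask_condition = NA_character_,
                       case_id = NA_character_) {
  structure(list(mask = mask, method = method,
                 mask_condition = mask_condition, case_id = case_id,
                 failed = failed, converged = converged,
                 spacing = vox_spacing(image)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d voxels (%.2f cm^3)%s%s\n",
              x$method, sum(x$mask), sum(x$mask) * prod(x$spacing),
              if (x$failed) " [FAILED]" else "",
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

.check_seg_input <- function(image, init) {
  stopifnot(inherits(image, "voxel_volume"))
  check_same_grid(image, init, "image and initial mask")
  if (!any(init)) stop("initial mask is empty")
  invisible(TRUE)
}

# the methods only ever look inside the initial mask, so work on a cropped
# box around it (margin accommodates background shells / smoothing support)
.crop_to_init <- function(image, init, margin = 2L) {
  rng <- bbox_ranges(init, margin = margin)
  list(img = unclass(image)[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       init = init[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       rng = rng, dims = dim(image))
}

.embed_mask <- function(mask, dims, rng) {
  full <- array(FALSE, dims)
  full[rng[[1]], rng[[2]], rng[[3]]] <- mask
  full
}

#' Fixed-threshold segmentation at 41% of the maximum
#'
#' Keeps the voxels of the initial mask with intensity at or above 41% of
#' the maximum intensity inside the mask, then retains the largest
#' 26-connected component. Scale-invariant by construction.
#'
#' @param image a [voxel_volume()].
#' @param init logical initial (cropping) mask, same grid, non-empty.
#' @return A `segmentation_result`.
#' @export
seg_41max <- function(image, init) {
  .check_seg_input(image, init)
  mx <- max(image[init])
  if (mx <= 0)
    return(seg_result(array(FALSE, dim(image)), "41MAX", image, failed = TRUE))
  mask <- array(init & (unclass(image) >= 0.41 * mx), dim(image))
  seg_result(largest_component(mask), "41MAX", image)
}

#' Contrast-oriented (adaptive) threshold segmentation
#'
#' Iterative contrast-oriented thresholding: the threshold is a linear
#' combination `st_a * mSUV70 + st_b * BG` of the mean intensity of the
#' region above 70% of the maximum (recomputed on the current estimate
#' each iteration) and the mean background intensity. Iterates until the
#' mask is stable or `max_iter` is reached; the largest connected
#' component is retained.
#'
#' @param image a [voxel_volume()].
#' @param init logical initial mask, non-empty.
#' @param bg logical background mask, disjoint from `init`; if `NULL`
#'   (default) an automatic background shell is used (`init` dilated by 3
#'   voxels minus `init`).
#' @param cfg a [seg_config()].
#' @return A `segmentation_result`.
#' @export
seg_st <- function(image, init, bg = NULL, cfg = seg_config()) {
  .check_seg_input(image, init)
  if (!is.null(bg)) {
    check_same_grid(image, bg, "image and background mask")
    if (!any(bg)) stop("background mask is empty")
    if (any(bg & init)) stop("background mask overlaps the initial mask")
    bgv <- mean(unclass(image)[bg])
  }
  cr <- .crop_to_init(image, init, margin = 4L)
  img <- cr$img; init_c <- cr$init
  if (is.null(bg)) {
    shell <- dilate1(dilate1(dilate1(init_c))) & !init_c
    bgv <- mean(img[shell])
  }
  est <- init_c
  converged <- FALSE
  for (i in seq_len(cfg$max_iter)) {
    mx <- max(img[est])
    if (mx <= 0)
      return(seg_result(array(FALSE, cr$dims), "ST", image, failed = TRUE))
    m70 <- mean(img[est & img >= 0.7 * mx])
    thr <- cfg$st_a * m70 + cfg$st_b * bgv
    new_est <- init_c & (img >= thr)
    if (!any(new_est))
      return(seg_result(array(FALSE, cr$dims), "ST", image, failed = TRUE))
    if (identical(new_est, est)) { converged <- TRUE; break }
    est <- new_est
  }
  mask <- largest_component(array(est, dim(img)))
  seg_result(.embed_mask(mask, cr$dims, cr$rng), "ST", image,
             converged = converged)
}

#' Affinity-propagation segmentation
#'
#' Clusters the voxels of the initial mask by affinity propagation
#' (responsibility/availability message passing) on intensity, with
#' similarity `-(I_i - I_k)^2` and, by default, the median pairwise
#' similarity as the exemplar preference. The tumor is taken as the
#' cluster selected by `cfg$ap_rule` (default: the cluster whose exemplar
#' has the highest intensity), reduced to its largest connected
#' component. Masks above `cfg$ap_voxel_cap` voxels are
#' intensity-stratified subsampled before clustering and the remaining
#' voxels are assigned to the nearest exemplar by intensity.
#'
#' @inheritParams seg_st
#' @return A `segmentation_result`; `converged = FALSE` flags message
#'   passing that hit the iteration cap (the best iterate is returned).
#' @export
seg_ap <- function(image, init, cfg = seg_config()) {
  .check_seg_input(image, init)
  cr <- .crop_to_init(image, init, margin = 1L)
  img <- cr$img; init_c <- cr$init
  idx <- which(init_c)
  vals <- img[idx]
  n <- length(idx)

  sub <- seq_len(n)
  if (n > cfg$ap_voxel_cap) {
    # stratified by intensity decile, proportional allocation
    strata <- cut(rank(vals, ties.method = "first"),
                  breaks = 10, labels = FALSE)
    keep <- unlist(lapply(split(seq_len(n), strata), function(ii) {
      k <- max(1L, round(length(ii) / n * cfg$ap_voxel_cap))
      ii[round(seq(1, length(ii), length.out = min(k, length(ii))))]
    }), use.names = FALSE)
    sub <- sort(unique(keep))
  }
  x <- vals[sub]

  if (stats::sd(x) == 0) {
    # constant image: zero dissimilarity, a single cluster covering init
    return(seg_result(.embed_mask(init_c, cr$dims, cr$rng), "AP", image))
  }

  # collapse exact intensity duplicates into weighted points (exact for
  # the net-similarity objective: a group of w identical voxels pays
  # w * s(v, exemplar), and an exemplar serves its twins at zero cost);
  # plain per-point message passing is degenerate on duplicate plateaus
  uv <- sort(unique(x))
  grp <- match(x, uv)
  w <- tabulate(grp, nbins = length(uv))
  m <- length(uv)
  D2 <- outer(uv, uv, `-`)^2
  pref <- if (identical(cfg$ap_preference, "median")) {
    # weighted median of the informative (distinct-value) pair similarities
    sims <- -D2[upper.tri(D2)]
    wts <- outer(w, w)[upper.tri(D2)]
    o <- order(sims)
    cw <- cumsum(wts[o])
    sims[o][which(cw >= cw[length(cw)] / 2)[1]]
  } else as.numeric(cfg$ap_preference)
  S <- -w * D2                 # row j scaled by group weight w_j
  diag(S) <- pref
  # tiny seeded jitter breaks exact-tie degeneracies of message passing
  # (the customary remedy in reference implementations); magnitude is at
  # machine precision and cannot change real structure
  S <- S + withr::with_seed(1L,
    (.Machine$double.eps * abs(S) + .Machine$double.xmin * 100) *
      matrix(stats::runif(m * m), m, m))
  # message passing on plateau-structured similarities can settle in a
  # degenerate all-singleton state; escalate damping deterministically
  # when (and only when) that happens
  damps <- unique(c(cfg$ap_damping,
                    pmax(cfg$ap_damping, c(0.95, 0.975, 0.99))))
  for (dmp in damps) {
    res <- ap_messages(S, maxit = max(cfg$max_iter, 500L), convits = 50L,
                       damping = dmp)
    n_ex <- length(unique(res$exemplar))
    if (n_ex <= max(5, m / 2)) break
  }
  exem_grp <- res$exemplar       # exemplar group per unique value
  ex_ids <- sort(unique(exem_grp))
  ex_vals <- uv[ex_ids]

  # assign every init voxel (incl. non-subsampled) to the nearest
  # exemplar by intensity; subsampled voxels keep their cluster
  assign_all <- ex_ids[max.col(-outer(vals, ex_vals, `-`)^2,
                               ties.method = "first")]
  assign_all[sub] <- exem_grp[grp]

  chosen <- if (cfg$ap_rule == "hottest") {
    ex_ids[which.max(ex_vals)]
  } else {
    as.integer(names(which.max(table(assign_all))))
  }
  mask <- array(FALSE, dim(img))
  mask[idx[assign_all == chosen]] <- TRUE
  mask <- largest_component(mask)
  seg_result(.embed_mask(mask, cr$dims, cr$rng), "AP", image,
             converged = isTRUE(res$converged))
}

#' Region-based active-contour segmentation (MASAC)
#'
#' Two-phase region-based active contour of Chan–Vese type, evolved
#' inside the initial mask with a morphological (discrete) scheme: each
#' iteration re-estimates the inside/outside mean intensities `c1`, `c2`,
#' reassigns voxels by the two-region data term, and applies binary
#' median smoothing as the curvature (contour-length) regularizer. The
#' contrast weight `lambda` balances data fidelity against smoothing:
#' curvature smoothing may only overrule the data term for voxels whose
#' normalized data margin `|(I-c1)^2 - (I-c2)^2| / (c1-c2)^2` is below
#' `1/lambda`, so sharp two-level boundaries (margin 1 everywhere) are
#' recovered exactly and large `lambda` degenerates to the pure
#' two-region data partition. Evolution starts from the 41%-of-maximum
#' mask and stops when the contour is stable. The result is
#' deterministic; the largest connected component is retained.
#'
#' @inheritParams seg_st
#' @return A `segmentation_result`.
#' @export
seg_masac <- function(image, init, cfg = seg_config()) {
  .check_seg_input(image, init)
  cr <- .crop_to_init(image, init, margin = 2L)
  img <- cr$img; init_c <- cr$init
  mx <- max(img[init_c])
  if (mx <= 0)
    return(seg_result(array(FALSE, cr$dims), "MASAC", image, failed = TRUE))
  u <- array(init_c & (img >= 0.41 * mx), dim(img))   # 41%-threshold init
  converged <- FALSE
  for (i in seq_len(cfg$max_iter)) {
    inside <- u & init_c
    outside <- init_c & !u
    if (!any(inside) || !any(outside)) break
    c1 <- mean(img[inside])
    c2 <- mean(img[outside])
    d1 <- (img - c1)^2
    d2 <- (img - c2)^2
    u_att <- init_c & (d1 < d2)
    # curvature smoothing overrules the data term only inside the
    # low-margin band of width 1/lambda around the decision boundary
    u_med <- binary_median3(u_att) & init_c
    band <- abs(d1 - d2) / max((c1 - c2)^2, .Machine$double.eps) < 1 / cfg$lambda
    u_new <- array(ifelse(band, u_med, u_att), dim(img))
    if (identical(u_new, u)) { converged <- TRUE; break }
    u <- u_new
  }
  if (!any(u))
    return(seg_result(array(FALSE, cr$dims), "MASAC", image, failed = TRUE))
  mask <- largest_component(u)
  seg_result(.embed_mask(mask, cr$dims, cr$rng), "MASAC", image,
             converged = converged)
}

#' Run one delineation method by name
#'
#' Dispatcher over the four individual methods.
#'
#' @param image a [voxel_volume()].
#' @param init logical initial mask.
#' @param method one of `"masac"`, `"ap"`, `"st"`, `"41max"`
#'   (case-insensitive).
#' @param cfg a [seg_config()].
#' @param bg optional background mask for `"st"`.
#' @return A `segmentation_result`.
#' @export
segment_pet <- function(image, init, method, cfg = seg_config(), bg = NULL) {
  switch(tolower(method),
         masac   = seg_masac(image, init, cfg),
         ap      = seg_ap(image, init, cfg),
         st      = seg_st(image, init, bg, cfg),
         `41max` = seg_41max(image, init),
         stop("unknown method: ", method))
}
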