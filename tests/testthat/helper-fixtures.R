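# shared in-code fixtures: no binary data, everything generated at test time

# solid sphere mask of radius r (voxels) centered in a cubic grid
sphere_mask <- function(n = 24, r = 6, center = rep((n + 1) / 2, 3)) {
  g <- seq_len(n)
  d2 <- outer(outer((g - center[1])^2, (g - center[2])^2, `+`),
              (g - center[3])^2, `+`)
  d2 <= r^2
}

# sharp two-level image: object at `hot`, background at `cold`
two_level_volume <- function(mask, hot = 10, cold = 1,
                             spacing = c(1, 1, 1)) {
  arr <- array(cold, dim(mask))
  arr[mask] <- hot
  voxel_volume(arr, spacing)
}

# seeded random blob mask (union of a few random boxes, largest component)
random_mask <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    m <- array(FALSE, c(n, n, n))
    for (i in 1:3) {
      lo <- sample(2:(n - 4), 3, replace = TRUE)
      hi <- pmin(n - 1, lo + sample(2:4, 3, replace = TRUE))
      m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    }
    m
  })
}

# independent Feng-curve evaluation (closed form, written out separately
# from the package implementation)
feng_reference <- function(t, A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
                           l1 = -4.133859, l2 = -0.1190996,
                           l3 = -0.0104233) {
  (A1 * t - A2 - A3) * exp(l1 * t) + A2 * exp(l2 * t) + A3 * exp(l3 * t)
}

# independent numeric 2TC oracle: stiff ODE integration with deSolve
tac_ode_oracle <- function(params, times) {
  rhs <- function(t, y, parms) {
    cp <- max(feng_reference(t), 0)
    list(c(params$K1 * cp - (params$k2 + params$k3) * y[1] + params$k4 * y[2],
           params$k3 * y[1] - params$k4 * y[2]))
  }
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(c(0, 0), tt, rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  keep <- if (times[1] > 0) -1L else seq_len(nrow(sol))
  tissue <- rowSums(sol[keep, 2:3, drop = FALSE])
  (1 - params$vB) * tissue + params$vB * pmax(feng_reference(times), 0)
}

# brute-force affinity-propagation oracle: maximize net similarity over
# all non-empty exemplar subsets (feasible for <= 12 points)
ap_brute_force <- function(x, pref) {
  n <- length(x)
  S <- -outer(x, x, `-`)^2
  best <- -Inf
  best_assign <- NULL
  for (code in 1:(2^n - 1)) {
    ex <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    sim <- S[, ex, drop = FALSE]
    assign_to <- ex[max.col(sim, ties.method = "first")]
    assign_to[ex] <- ex
    non_ex <- setdiff(seq_len(n), ex)
    net <- length(ex) * pref +
      sum(S[cbind(non_ex, assign_to[non_ex])])
    if (net > best) { best <- net; best_assign <- assign_to }
  }
  list(assign = best_assign, net = best)
}
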