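#' Two-tissue compartment kinetic parameters
#'
#' Rate constants of the irreversible/reversible two-tissue compartment
#' (2TC) model of FDG kinetics: plasma-to-tissue transfer `K1`, efflux
#' `k2`, phosphorylation `k3`, dephosphorylation `k4`, and the fractional
#' blood volume `vB`. Published parameter tables often leave `k4` and `vB`
#' blank for tissues where they are negligible; pass 0 in that case (the
#' defaults).
#'
#' @param K1 plasma-to-tissue transfer constant, ml/(min*g).
#' @param k2 tissue-to-plasma efflux rate, 1/min.
#' @param k3 phosphorylation rate, 1/min.
#' @param k4 dephosphorylation rate, 1/min (default 0).
#' @param vB fractional blood volume, ml/ml in `[0, 1)` (default 0).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(K1 = 0.108, k2 = 0.735, k3 = 0.016, k4 = 0.013, vB = 0.017)
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, vB = 0) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all kinetic parameters must be finite and non-negative")
  if (vB >= 1) stop("'vB' must be < 1")
  structure(as.list(p), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> K1=%.3f ml/(min*g), k2=%.3f, k3=%.3f, k4=%.3f 1/min, vB=%.3f\n",
    x$K1, x$k2, x$k3, x$k4, x$vB))
  invisible(x)
}

#' Reference FDG kinetic parameter sets for the lung-lesion simulation
#'
#' Literature-derived 2TC parameter sets for the three intratumoral uptake
#' levels of a heterogeneous lung lesion and for normal thoracic tissues.
#' Level I is the hottest (core) lesion tissue and Level III the coldest;
#' normal lung is the background/normalizing tissue of the phantom.
#'
#' @return Named list of [kinetic_params()]: `level1`, `level2`, `level3`,
#'   `lung`, `liver`, `myocardium`, `marrow`.
#' @examples
#' fdg_tissue_params()$lung
#' @export
fdg_tissue_params <- function() {
  list(
    level1     = kinetic_params(0.180, 0.990, 0.190, 0,     0.036),
    level2     = kinetic_params(0.150, 0.550, 0.120, 0,     0.071),
    level3     = kinetic_params(0.110, 0.400, 0.073, 0,     0.095),
    lung       = kinetic_params(0.108, 0.735, 0.016, 0.013, 0.017),
    liver      = kinetic_params(0.864, 0.981, 0.005, 0.016, 0),
    myocardium = kinetic_params(0.600, 1.200, 0.100, 0.001, 0),
    marrow     = kinetic_params(0.200, 0.680, 0.050, 0.020, 0.010)
  )
}

#' Feng population arterial input function
#'
#' The 4-exponential population model of the arterial plasma FDG
#' concentration (Feng model 4),
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{\lambda_1 t} + A_2 e^{\lambda_2 t}
#'   + A_3 e^{\lambda_3 t},}
#' with the published population coefficients as defaults. The curve is 0
#' at `t = 0`, peaks within the first minute and decays thereafter. Units
#' of the amplitudes are arbitrary activity-concentration units; ratios of
#' tissue activities are independent of the overall scale.
#'
#' @param A1 amplitude of the ramp term, activity/min (default 851.1225).
#' @param A2,A3 amplitudes of the slow exponentials (defaults 21.8798,
#'   20.8113).
#' @param l1,l2,l3 decay exponents, 1/min, all negative (defaults
#'   -4.133859, -0.1190996, -0.0104233).
#' @param delay appearance delay in minutes (default 0).
#' @return An object of class `feng_input`.
#' @examples
#' f <- feng_input()
#' plasma_activity(f, c(0, 1, 35, 70))
#' @export
feng_input <- function(A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
                       l1 = -4.133859, l2 = -0.1190996, l3 = -0.0104233,
                       delay = 0) {
  if (any(c(l1, l2, l3) >= 0)) stop("decay exponents must be negative")
  if (delay < 0) stop("'delay' must be non-negative")
  structure(list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3,
                 delay = delay),
            class = "feng_input")
}

#' @export
print.feng_input <- function(x, ...) {
  cat(sprintf(
    "<feng_input> A = (%.4g, %.4g, %.4g), lambda = (%.4g, %.4g, %.4g) 1/min, delay = %g min\n",
    x$A1, x$A2, x$A3, x$l1, x$l2, x$l3, x$delay))
  invisible(x)
}

#' Evaluate an arterial input function
#'
#' @param input a [feng_input()] object (or a plain function of time).
#' @param t times in minutes, all `>= 0`.
#' @return Plasma activity concentration at `t` (non-negative).
#' @export
plasma_activity <- function(input, t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative (minutes)")
  if (is.function(input)) return(pmax(input(t), 0))
  if (!inherits(input, "feng_input"))
    stop("'input' must be a 'feng_input' or a function of time")
  u <- t - input$delay
  v <- ifelse(u <= 0, 0,
              (input$A1 * u - input$A2 - input$A3) * exp(input$l1 * u) +
                input$A2 * exp(input$l2 * u) + input$A3 * exp(input$l3 * u))
  pmax(v, 0)
}

# exponential-polynomial representation of the Feng curve:
# Cp(t) = sum_j coef_j * t^pow_j * exp(-rate_j * t)  (rates > 0)
.feng_terms <- function(input) {
  list(coef = c(input$A1, -(input$A2 + input$A3), input$A2, input$A3),
       pow  = c(1L, 0L, 0L, 0L),
       rate = -c(input$l1, input$l1, input$l2, input$l3))
}

# closed-form convolution  (e^{-a t}) * (t^p e^{-r t})  for p in {0, 1}
.conv_exp_term <- function(a, coefv, p, r, t) {
  mu <- a - r
  if (p == 0L) {
    if (abs(mu) < 1e-12) return(coefv * t * exp(-a * t))
    coefv * (exp(-r * t) - exp(-a * t)) / mu
  } else {
    if (abs(mu) < 1e-12) return(coefv * t^2 / 2 * exp(-a * t))
    coefv * (exp(-r * t) * (t / mu - 1 / mu^2) + exp(-a * t) / mu^2)
  }
}

#' Solve the two-tissue compartment model
#'
#' Computes the total tissue time-activity curve
#' \deqn{C_T(t) = (1 - v_B)\,(C_f(t) + C_b(t)) + v_B\, C_p(t)}
#' for the linear 2TC system
#' \deqn{\dot C_f = K_1 C_p - (k_2 + k_3) C_f + k_4 C_b, \qquad
#'       \dot C_b = k_3 C_f - k_4 C_b,}
#' with whole-blood activity taken equal to plasma activity. For a
#' [feng_input()] the solution is evaluated in closed form (analytic
#' convolution of the bi-exponential tissue impulse response with the
#' exponential-polynomial input); for a plain function input, or in the
#' degenerate double-eigenvalue case, the system is integrated numerically
#' with `deSolve::lsoda`.
#'
#' @param params a [kinetic_params()] object.
#' @param input a [feng_input()] or a function of time (minutes).
#' @param times strictly increasing, non-negative times in minutes.
#' @return A `tac` object: data frame with columns `time` (min) and
#'   `activity` (same units as the input amplitudes).
#' @examples
#' p <- fdg_tissue_params()
#' tac <- solve_2tc(p$lung, feng_input(), seq(0, 70, by = 0.5))
#' tail(tac, 2)
#' @export
solve_2tc <- function(params, input, times) {
  stopifnot(inherits(params, "kinetic_params"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite, non-negative minutes")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")

  k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4

  analytic <- inherits(input, "feng_input") && input$delay == 0 &&
    (s == 0 || (disc > 0 && sqrt(disc) > 1e-8 * max(s, 1)))

  if (analytic) {
    tissue <- .solve_2tc_analytic(params, input, times)
  } else {
    tissue <- .solve_2tc_ode(params, input, times)
  }
  cp <- plasma_activity(input, times)
  activity <- (1 - params$vB) * tissue + params$vB * cp
  structure(data.frame(time = times, activity = pmax(activity, 0)),
            class = c("tac", "data.frame"))
}

# C_f + C_b via analytic convolution with the Feng input
.solve_2tc_analytic <- function(params, input, times) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  tm <- .feng_terms(input)
  s <- k2 + k3 + k4
  if (s == 0) {
    # no efflux at all: C_f = K1 * integral of Cp, C_b = 0
    tot <- numeric(length(times))
    for (j in seq_along(tm$coef))
      tot <- tot + .conv_exp_term(0, tm$coef[j], tm$pow[j], tm$rate[j], times)
    return(K1 * tot)
  }
  rt <- sqrt(s^2 - 4 * k2 * k4)
  a1 <- (s - rt) / 2
  a2 <- (s + rt) / 2
  # impulse response of C_f + C_b: K1/(a2-a1) * [(k3+k4-a1) e^{-a1 t} + (a2-k3-k4) e^{-a2 t}]
  w1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  w2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  tot <- numeric(length(times))
  for (j in seq_along(tm$coef)) {
    tot <- tot + w1 * .conv_exp_term(a1, tm$coef[j], tm$pow[j], tm$rate[j], times)
    tot <- tot + w2 * .conv_exp_term(a2, tm$coef[j], tm$pow[j], tm$rate[j], times)
  }
  tot
}

.solve_2tc_ode <- function(params, input, times) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  tt <- if (times[1] > 0) c(0, times) else times
  rhs <- function(t, y, parms) {
    cp <- plasma_activity(input, t)
    list(c(K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), tt, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  keep <- if (times[1] > 0) -1L else seq_len(nrow(sol))
  rowSums(sol[keep, 2:3, drop = FALSE])
}

#' Lesion-to-background uptake ratios at a fixed time
#'
#' Solves the 2TC model for each lesion tissue and for the background
#' tissue under a common arterial input, and returns the ratio of lesion
#' to background total activity at time `t`. With the default thoracic
#' parameter sets and the Feng population input at `t = 70` min, the three
#' intratumoral levels come out close to 11.0 : 10.1 : 6.6 relative to
#' normal lung.
#'
#' @param lesion_params list of [kinetic_params()], one per lesion level
#'   (ordered hottest first by convention).
#' @param background_params [kinetic_params()] of the normalizing tissue.
#' @param input arterial input function (default [feng_input()]).
#' @param t time in minutes, `> 0` (default 70, a late static acquisition).
#' @return Numeric vector of ratios, one per lesion parameter set.
#' @examples
#' p <- fdg_tissue_params()
#' uptake_ratios(p[c("level1", "level2", "level3")], p$lung)
#' @export
uptake_ratios <- function(lesion_params, background_params,
                          input = feng_input(), t = 70) {
  if (inherits(lesion_params, "kinetic_params"))
    lesion_params <- list(lesion_params)
  if (length(t) != 1L || t <= 0) stop("'t' must be a single positive time")
  bg <- solve_2tc(background_params, input, t)$activity
  if (bg <= 0) stop("background activity is zero at t; ratios undefined")
  vapply(lesion_params,
         function(p) solve_2tc(p, input, t)$activity / bg,
         numeric(1))
}
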