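#' Fractional Adams-Bashforth-Moulton solver with a discrete delay
#'
#' Independent verification solver: the Diethelm-Ford-Freed
#' predictor-corrector for Caputo fractional systems, extended with a single
#' discrete delay. The predictor uses fractional rectangle (Adams-Bashforth)
#' convolution weights and the corrector the fractional trapezoidal
#' (Adams-Moulton) weights; delayed infected values are read from the
#' history for `t - tau < 0` and otherwise interpolated from the already
#' computed steps.
#'
#' @param params a [sir_params()] object.
#' @param histories a [history_set()] object.
#' @param h step size; must satisfy `h <= tau` so that delayed lookups only
#'   touch already computed values.
#' @param corrector_iters number of corrector sweeps (PECE with 1 sweep by
#'   default).
#' @param interpolation `"linear"` or `"cubic_hermite"` (Catmull-Rom slopes
#'   estimated from the computed series) for delayed lookups.
#' @param forcing optional list of three functions added to the respective
#'   right-hand sides (manufactured problems).
#' @return an object of class `sir_trajectory`: data.frame with columns
#'   `t`, `S`, `I`, `R`, with attributes `solver` and `h`.
#' @export
abm_fdde <- function(params, histories, h = 1e-3, corrector_iters = 1,
                     interpolation = c("linear", "cubic_hermite"),
                     forcing = NULL) {
  stopifnot(inherits(params, "sir_params"), inherits(histories, "history_set"))
  interpolation <- match.arg(interpolation)
  if (h <= 0) stop("`h` must be positive")
  if (h > params$tau)
    stop("step size h = ", h, " exceeds the delay tau = ", params$tau,
         ": delayed lookups would precede the available data")
  if (corrector_iters < 1) stop("`corrector_iters` must be >= 1")
  alpha <- params$alpha
  n <- ceiling(params$horizon / h - 1e-9)
  tgrid <- (0:n) * h

  Y <- matrix(0, n + 1, 3)
  Fv <- matrix(0, n + 1, 3)
  Y[1, ] <- c(histories$phi1(0), histories$phi2(0), histories$phi3(0))

  force_at <- function(t) {
    if (is.null(forcing)) c(0, 0, 0)
    else c(forcing$S(t), forcing$I(t), forcing$R(t))
  }
  lookup_I <- function(s, upto) {
    ## delayed infected value at time s, using Y rows 1..upto
    if (s <= 0) return(histories$phi2(s))
    idx <- round(s / h)
    if (abs(s - idx * h) < 1e-9 * h && idx + 1L <= upto)
      return(Y[idx + 1L, 2])
    j <- min(floor(s / h + 1e-12), upto - 2L)
    j <- max(j, 0L)
    t0 <- j * h
    w <- (s - t0) / h
    if (interpolation == "linear" || j < 1L || j + 3L > upto) {
      (1 - w) * Y[j + 1L, 2] + w * Y[j + 2L, 2]
    } else {
      y0 <- Y[j + 1L, 2]; y1 <- Y[j + 2L, 2]
      m0 <- (Y[j + 2L, 2] - Y[j, 2]) / 2
      m1 <- (Y[j + 3L, 2] - Y[j + 1L, 2]) / 2
      h00 <- (1 + 2 * w) * (1 - w)^2; h10 <- w * (1 - w)^2
      h01 <- w^2 * (3 - 2 * w); h11 <- w^2 * (w - 1)
      h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1
    }
  }
  rhs_at <- function(t, y, Idel) {
    r <- sir_rhs(y[1], y[2], y[3], Idel, params)
    c(r$dS, r$dI, r$dR) + force_at(t)
  }

  Fv[1, ] <- rhs_at(0, Y[1, ], lookup_I(-params$tau, 1L))

  ## convolution kernels (index m = distance to the target step)
  m <- 0:(n + 1)
  Bk <- (m + 1)^alpha - m^alpha              # predictor, m = n - j
  Ka <- c(1, (m[-1] + 1)^(alpha + 1) + (m[-1] - 1)^(alpha + 1) -
            2 * m[-1]^(alpha + 1))           # corrector, m = n + 1 - j >= 1
  c_pred <- h^alpha / gamma(alpha + 1)
  c_corr <- h^alpha / gamma(alpha + 2)

  for (k in 1:n) {                            # compute Y at t_k
    jj <- 1:k                                 # rows of F used (steps 0..k-1)
    wb <- Bk[k:1]                             # (k - j)^... for j = 0..k-1
    pred <- Y[1, ] + c_pred * as.vector(crossprod(Fv[jj, , drop = FALSE], wb))
    ## corrector weights a_{j,k}: j = 0 edge + interior kernel + j = k
    wa <- c((k - 1)^(alpha + 1) - (k - 1 - alpha) * k^alpha,
            if (k >= 2) Ka[k:2] else NULL)
    hist_part <- Y[1, ] + c_corr *
      as.vector(crossprod(Fv[jj, , drop = FALSE], wa))
    tk <- tgrid[k + 1]
    Idel <- lookup_I(tk - params$tau, k)
    ynew <- pred
    for (it in seq_len(corrector_iters)) {
      fnew <- rhs_at(tk, ynew, Idel)
      ynew <- hist_part + c_corr * fnew
    }
    Y[k + 1, ] <- ynew
    Fv[k + 1, ] <- rhs_at(tk, ynew, Idel)
  }

  structure(data.frame(t = tgrid, S = Y[, 1], I = Y[, 2], R = Y[, 3]),
            solver = "abm", h = h, class = c("sir_trajectory", "data.frame"))
}

#' Classical RK4 by the method of steps (alpha = 1 only)
#'
#' Solves the delayed SIR system at integer order with the classical
#' fourth-order Runge-Kutta scheme; delayed values come from the history on
#' `[-tau, 0]` and from cubic Hermite interpolation of the already computed
#' solution afterwards (slopes are the stored right-hand sides, which equal
#' the true derivatives at integer order).
#'
#' @inheritParams abm_fdde
#' @return an object of class `sir_trajectory`.
#' @export
rk4_dde <- function(params, histories, h = 1e-3, forcing = NULL) {
  stopifnot(inherits(params, "sir_params"), inherits(histories, "history_set"))
  if (params$alpha != 1)
    stop("rk4_dde requires alpha = 1; use abm_fdde for fractional orders")
  if (h <= 0) stop("`h` must be positive")
  if (h > params$tau) stop("step size must not exceed the delay")
  n <- ceiling(params$horizon / h - 1e-9)
  tgrid <- (0:n) * h

  Y <- matrix(0, n + 1, 3)
  D <- matrix(0, n + 1, 3)                   # derivatives at the grid
  Y[1, ] <- c(histories$phi1(0), histories$phi2(0), histories$phi3(0))

  force_at <- function(t) {
    if (is.null(forcing)) c(0, 0, 0)
    else c(forcing$S(t), forcing$I(t), forcing$R(t))
  }
  lookup_I <- function(s, upto) {
    if (s <= 0) return(histories$phi2(s))
    idx <- round(s / h)
    if (abs(s - idx * h) < 1e-9 * h && idx <= upto)
      return(Y[idx + 1L, 2])
    j <- min(floor(s / h + 1e-12), upto - 1L)
    t0 <- j * h
    w <- (s - t0) / h
    y0 <- Y[j + 1L, 2]; y1 <- Y[j + 2L, 2]
    m0 <- h * D[j + 1L, 2]; m1 <- h * D[j + 2L, 2]
    (1 + 2 * w) * (1 - w)^2 * y0 + w * (1 - w)^2 * m0 +
      w^2 * (3 - 2 * w) * y1 + w^2 * (w - 1) * m1
  }
  f <- function(t, y, upto) {
    Idel <- lookup_I(t - params$tau, upto)
    r <- sir_rhs(y[1], y[2], y[3], Idel, params)
    c(r$dS, r$dI, r$dR) + force_at(t)
  }

  D[1, ] <- f(0, Y[1, ], 0L)
  for (k in 1:n) {
    t0 <- tgrid[k]
    y0 <- Y[k, ]
    k1 <- D[k, ]                             # f(t0, y0) already stored
    k2 <- f(t0 + h / 2, y0 + h / 2 * k1, k - 1L)
    k3 <- f(t0 + h / 2, y0 + h / 2 * k2, k - 1L)
    k4 <- f(t0 + h, y0 + h * k3, k - 1L)
    Y[k + 1, ] <- y0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    D[k + 1, ] <- f(tgrid[k + 1], Y[k + 1, ], k)
  }

  structure(data.frame(t = tgrid, S = Y[, 1], I = Y[, 2], R = Y[, 3]),
            solver = "rk4", h = h, class = c("sir_trajectory", "data.frame"))
}
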