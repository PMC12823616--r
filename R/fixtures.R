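#' Caputo derivative of a polynomial, in closed form
#'
#' Applies the power-function law
#' `D^alpha t^p = Gamma(p+1)/Gamma(p+1-alpha) t^(p-alpha)` termwise
#' (constants are annihilated). Valid for `0 < alpha <= 1`; at `alpha = 1` it
#' reduces to the ordinary derivative.
#'
#' @param coefs polynomial coefficients, constant first.
#' @param alpha order in `(0, 1]`.
#' @return a vectorized function of `t >= 0`.
#' @export
caputo_poly <- function(coefs, alpha) {
  force(coefs); force(alpha)
  function(t) {
    out <- numeric(length(t))
    for (p in seq_len(length(coefs) - 1)) {
      ## p - alpha >= 0 on the supported range, and R takes 0^0 = 1,
      ## so the formula is valid down to t = 0 (including alpha = 1, p = 1)
      out <- out + coefs[p + 1] * gamma(p + 1) / gamma(p + 1 - alpha) *
        t^(p - alpha)
    }
    out
  }
}

#' Manufactured polynomial test problem
#'
#' Chooses a polynomial solution triple of degree at most 3, computes the
#' forcing terms that make the triple solve the forced delayed SIR system
#' exactly (Caputo derivatives in closed form via the Gamma-ratio law,
#' delayed values evaluated analytically), and returns the problem together
#' with the exact solution. Histories are the polynomials restricted to
#' `[-tau, 0]`, so they are consistent with the solution by construction.
#'
#' @param params a [sir_params()] object.
#' @param coef_S,coef_I,coef_R polynomial coefficients (constant first),
#'   degree at most 3.
#' @return list with `params`, `histories`, `forcing` (list of three
#'   functions added to the respective equations), and `exact` (list of
#'   three solution functions).
#' @export
manufactured_problem <- function(params,
                                 coef_S = c(600, -4, 0.2),
                                 coef_I = c(30, 2, -0.1),
                                 coef_R = c(70, 2, -0.1)) {
  stopifnot(inherits(params, "sir_params"))
  for (cf in list(coef_S, coef_I, coef_R))
    if (length(cf) > 4) stop("manufactured degree is capped at 3")
  Sx <- poly_fn(coef_S); Ix <- poly_fn(coef_I); Rx <- poly_fn(coef_R)
  DS <- caputo_poly(coef_S, params$alpha)
  DI <- caputo_poly(coef_I, params$alpha)
  DR <- caputo_poly(coef_R, params$alpha)
  tau <- params$tau
  forcing <- list(
    S = function(t) {
      r <- sir_rhs(Sx(t), Ix(t), Rx(t), Ix(t - tau), params)
      DS(t) - r$dS
    },
    I = function(t) {
      r <- sir_rhs(Sx(t), Ix(t), Rx(t), Ix(t - tau), params)
      DI(t) - r$dI
    },
    R = function(t) {
      r <- sir_rhs(Sx(t), Ix(t), Rx(t), Ix(t - tau), params)
      DR(t) - r$dR
    })
  list(params = params,
       histories = history_set(coef_S, coef_I, coef_R, tau),
       forcing = forcing,
       exact = list(S = Sx, I = Ix, R = Rx))
}

#' Mittag-Leffler relaxation fixture
#'
#' With `beta = delta = 0` the infected compartment decouples and relaxes as
#' `I(t) = I0 E_alpha(-gamma t^alpha)`; the susceptible compartment stays
#' constant and the recovered one follows from the fractional integral
#' identity `R(t) = R0 + gamma I0 t^alpha E_{alpha, alpha+1}(-gamma t^alpha)`.
#' This gives a closed-form benchmark for the collocation solver at genuinely
#' fractional orders.
#'
#' @param alpha fractional order in `(0, 1]`.
#' @param gamma recovery rate, `> 0`.
#' @param I0 initial infected population.
#' @param S0,R0 initial susceptible / recovered populations.
#' @param horizon simulation horizon.
#' @param tau nominal delay (inert, since `beta = 0`).
#' @return list with `params`, `histories` (constant), and `exact` solution
#'   functions.
#' @export
ml_decay_problem <- function(alpha, gamma, I0 = 70, S0 = 630, R0 = 0,
                             horizon = 10, tau = 2) {
  if (gamma <= 0) stop("`gamma` must be positive")
  params <- sir_params(beta = 0, gamma = gamma, delta = 0, alpha = alpha,
                       tau = tau, N = S0 + I0 + R0, horizon = horizon)
  histories <- history_set(S0, I0, R0, tau)
  exact <- list(
    S = function(t) rep(S0, length(t)),
    I = function(t) I0 * mittag_leffler(alpha, -gamma * t^alpha),
    R = function(t) R0 + gamma * I0 * t^alpha *
      mittag_leffler(alpha, -gamma * t^alpha, beta = alpha + 1))
  list(params = params, histories = histories, exact = exact)
}
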