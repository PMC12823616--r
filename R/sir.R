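#' Parameters of the fractional delayed SIR model
#'
#' The model tracks susceptible `S`, infected `I` and recovered `R`
#' individuals in a closed population of size `N`, with Caputo fractional
#' derivatives of order `alpha` and a discrete delay `tau` (the incubation
#' period) in the transmission term:
#'
#' \deqn{^C D^\alpha S = -\beta S(t) I(t-\tau) + \delta I(t)}
#' \deqn{^C D^\alpha I = \beta S(t) I(t-\tau) - (\delta + \gamma) I(t)}
#' \deqn{^C D^\alpha R = \gamma I(t)}
#'
#' `beta` is the transmission rate (per individual per unit time), `gamma`
#' the recovery rate, and `delta` the reinfection rate returning recovered
#' individuals to the susceptible pool (waning immunity, as seen in
#' influenza). The three right-hand sides sum to zero, so `S + I + R = N` is
#' conserved by the exact dynamics. Rates are taken at face value (units
#' `time^-alpha` under Caputo dynamics); no dimensional rescaling is applied.
#'
#' @param beta,gamma,delta non-negative rates.
#' @param alpha fractional order in `(0, 1]`.
#' @param tau delay (incubation period), `0 < tau < horizon`.
#' @param N total population, `> 0`.
#' @param horizon simulation horizon `T`.
#' @return an object of class `sir_params`.
#' @export
sir_params <- function(beta, gamma, delta, alpha, tau, N, horizon) {
  if (any(c(beta, gamma, delta) < 0)) stop("rates must be non-negative")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  if (N <= 0) stop("`N` must be positive")
  if (tau <= 0 || tau >= horizon) stop("need 0 < tau < horizon")
  structure(list(beta = beta, gamma = gamma, delta = delta, alpha = alpha,
                 tau = tau, N = N, horizon = horizon),
            class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf(
    "Fractional delayed SIR: beta = %g, gamma = %g, delta = %g, alpha = %g, tau = %g, N = %g, horizon = %g\n",
    x$beta, x$gamma, x$delta, x$alpha, x$tau, x$N, x$horizon))
  invisible(x)
}

#' Right-hand side of the delayed SIR system
#'
#' Pure arithmetic (vectorized): the Caputo-derivative targets of each
#' compartment. The components sum to zero identically, which underpins
#' conservation of the total population.
#'
#' @param S,I,R compartment values.
#' @param I_delayed delayed infected value `I(t - tau)`.
#' @param params a [sir_params()] object.
#' @return list with components `dS`, `dI`, `dR`.
#' @export
sir_rhs <- function(S, I, R, I_delayed, params) {
  infection <- params$beta * S * I_delayed
  list(dS = -infection + params$delta * I,
       dI = infection - (params$delta + params$gamma) * I,
       dR = params$gamma * I)
}

#' Built-in influenza scenario
#'
#' The reference scenario: linear compartment histories on `[-2, 0]`
#' (`S = 620 - 5t`, `I = 10 + 2t`, `R = 70 + 3t`), delay `tau = 2`, total
#' population `N = 700`, horizon 10. Two variants are shipped because the
#' stated histories and the tabulated `t = 0` values of reference solutions
#' disagree on which compartment starts at 10 and which at 70:
#' `"as_text"` takes `I(0) = 10, R(0) = 70`; `"as_tables"` swaps the infected
#' and recovered histories (`I(0) = 70, R(0) = 10`). The choice is explicit;
#' no default side is picked silently at the command line.
#'
#' The rate and order defaults (`beta = 5e-4`, `gamma = 0.1`, `delta = 0.05`,
#' `alpha = 0.9`) are illustrative placeholders chosen by this package: they
#' are not part of the scenario definition, which only fixes the histories,
#' the delay and the population size.
#'
#' @param variant `"as_text"` or `"as_tables"`.
#' @param beta,gamma,delta,alpha model rates and fractional order
#'   (placeholder defaults, see Details).
#' @param tau,N,horizon scenario constants.
#' @return list with elements `params` ([sir_params()]) and `histories`
#'   ([history_set()]).
#' @export
sir_scenario <- function(variant = c("as_text", "as_tables"),
                         beta = 5e-4, gamma = 0.1, delta = 0.05,
                         alpha = 0.9, tau = 2, N = 700, horizon = 10) {
  variant <- match.arg(variant)
  params <- sir_params(beta, gamma, delta, alpha, tau, N, horizon)
  hS <- c(620, -5)
  hI <- c(10, 2)
  hR <- c(70, 3)
  if (variant == "as_tables") { tmp <- hI; hI <- hR; hR <- tmp }
  list(params = params,
       histories = history_set(hS, hI, hR, tau),
       variant = variant)
}

#' Conservation residual of a trajectory
#'
#' Maximum relative deviation of `S + I + R` from the total population.
#'
#' @param trajectory data.frame with columns `S`, `I`, `R` (e.g. a solver
#'   output), or a `sir_solution`.
#' @param N total population; taken from the object if absent.
#' @return scalar `max |S + I + R - N| / N`.
#' @export
conservation_residual <- function(trajectory, N = NULL) {
  if (inherits(trajectory, "sir_solution")) {
    if (is.null(N)) N <- trajectory$params$N
    trajectory <- trajectory$trajectory
  }
  if (nrow(trajectory) == 0) stop("empty trajectory")
  if (is.null(N)) stop("`N` must be supplied")
  max(abs(trajectory$S + trajectory$I + trajectory$R - N)) / N
}
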