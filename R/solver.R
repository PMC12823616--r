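#' Solver configuration
#'
#' Numerical settings for the wavelet collocation solver.
#'
#' @param J resolution level; the collocation system has `3 * n_b` unknowns
#'   with `n_b = 2^J + augment`.
#' @param order Daubechies order (vanishing moments), default 4.
#' @param augment number of polynomial trend columns appended to the
#'   periodized basis (default 1). The expanded quantity (the Caputo
#'   derivative of each compartment) is generally non-periodic on `[0, T]`;
#'   one analytic linear column removes the dominant periodization seam.
#' @param method `"newton"` (damped, analytic Jacobian) or `"fixed_point"`.
#' @param residual_tol convergence tolerance on the infinity norm of the
#'   collocation residual.
#' @param max_iter maximum iterations.
#' @param interp_order delay interpolation order (1 or 3).
#' @param n_quad fine-grid panels for operator assembly (default
#'   `max(1024, 32 * n_b)`).
#' @param refinement cascade table refinement level.
#' @param output_points number of equally spaced reporting times on
#'   `[0, T]` (always including both endpoints).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(J = 6, order = 4, augment = 1,
                          method = c("newton", "fixed_point"),
                          residual_tol = 1e-10, max_iter = 50,
                          interp_order = 3, n_quad = NULL,
                          refinement = 12, output_points = 201) {
  method <- match.arg(method)
  if (residual_tol <= 0) stop("`residual_tol` must be positive")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  structure(list(J = J, order = order, augment = augment, method = method,
                 residual_tol = residual_tol, max_iter = max_iter,
                 interp_order = interp_order, n_quad = n_quad,
                 refinement = refinement, output_points = output_points),
            class = "solver_config")
}

#' Assemble the wavelet collocation system for the delayed SIR model
#'
#' Builds the square nonlinear collocation system. Each compartment's
#' *Caputo derivative* is expanded in the wavelet basis; the compartment
#' itself is reconstructed through the fractional-integration matrix,
#' `X(t_l) = X(0) + [P_alpha a^(X)]_l` with `X(0)` taken from the history at
#' 0. This enforces the initial conditions exactly and keeps the singular
#' behaviour of `D^alpha` at `t = 0` out of the residual; on the basis span
#' it is algebraically equivalent to expanding the compartments and applying
#' the differentiation matrix. Collocation nodes are the midpoints
#' `t_l = (l - 1/2) T / n_c` (the Caputo kernel is singular at `t = 0`).
#' The delayed term is evaluated by the shift matrix on the reconstructed
#' grid values (augmented with the exact value at `t = 0`), with pre-history
#' rows served by the history function.
#'
#' @param params a [sir_params()] object.
#' @param histories a [history_set()] object.
#' @param config a [solver_config()].
#' @param forcing optional list of functions `S`, `I`, `R` added to the
#'   right-hand sides (manufactured problems).
#' @return an object of class `collocation_problem`.
#' @export
sir_collocation <- function(params, histories, config = solver_config(),
                            forcing = NULL) {
  stopifnot(inherits(params, "sir_params"), inherits(histories, "history_set"))
  if (params$tau >= params$horizon) stop("need tau < horizon")
  basis <- wavelet_basis(order = config$order, T = params$horizon,
                         J = config$J, mode = "scaling_only",
                         refinement = config$refinement,
                         augment = config$augment)
  n_b <- basis$n_b
  if (n_b < 8) stop("basis too small: need n_b >= 8 (level J >= 3)")
  n_c <- n_b
  nodes <- (seq_len(n_c) - 0.5) * params$horizon / n_c

  op <- caputo_operator(basis, params$alpha, nodes, n_quad = config$n_quad)
  Psi <- unclass(evaluate_basis(basis, nodes))
  P <- op$P_alpha

  ## shift machinery on the node grid augmented with t = 0, so that shifted
  ## abscissae falling in (0, first node) are still interpolated, not sent
  ## to the history
  ga <- c(0, nodes)
  shift <- shift_matrix(ga, params$tau, interp_order = config$interp_order,
                        policy = "history")
  Wfull <- as.matrix(shift$weights)[-1, , drop = FALSE]
  pre <- shift$prehistory_rows
  pre <- pre[pre > 1L] - 1L               # row indices within the node set
  s_nodes <- nodes - params$tau
  hist_I <- numeric(n_c)
  if (length(pre) > 0) hist_I[pre] <- histories$phi2(s_nodes[pre])
  MP <- Wfull[, -1, drop = FALSE] %*% P   # d(I delayed)/d(a_I)

  X0 <- c(S = histories$phi1(0), I = histories$phi2(0), R = histories$phi3(0))
  f_nodes <- if (is.null(forcing)) NULL else
    list(S = forcing$S(nodes), I = forcing$I(nodes), R = forcing$R(nodes))

  structure(list(params = params, histories = histories, config = config,
                 basis = basis, nodes = nodes, operator = op,
                 Psi = Psi, P = P, Wfull = Wfull, MP = MP,
                 prehistory_rows = pre, hist_I = hist_I, X0 = X0,
                 forcing = forcing, f_nodes = f_nodes,
                 n_b = n_b, n_c = n_c),
            class = "collocation_problem")
}

#' @export
print.collocation_problem <- function(x, ...) {
  cat(sprintf(
    "Wavelet collocation problem: db%d, J = %d, n_b = %d (3x%d unknowns), alpha = %g, tau = %g\n",
    x$basis$filter$order, x$basis$J, x$n_b, x$n_b, x$params$alpha,
    x$params$tau))
  invisible(x)
}

## states and delayed infected values implied by a coefficient vector
.colloc_states <- function(pr, x) {
  n_b <- pr$n_b
  aS <- x[1:n_b]; aI <- x[n_b + 1:n_b]; aR <- x[2 * n_b + 1:n_b]
  S <- pr$X0[["S"]] + as.vector(pr$P %*% aS)
  I <- pr$X0[["I"]] + as.vector(pr$P %*% aI)
  R <- pr$X0[["R"]] + as.vector(pr$P %*% aR)
  Idel <- as.vector(pr$Wfull %*% c(pr$X0[["I"]], I))
  if (length(pr$prehistory_rows) > 0)
    Idel[pr$prehistory_rows] <- pr$hist_I[pr$prehistory_rows]
  list(aS = aS, aI = aI, aR = aR, S = S, I = I, R = R, Idel = Idel)
}

#' Collocation residual at a coefficient vector
#'
#' The residual of the assembled system (length `3 * n_b`): the basis
#' expansion of each Caputo derivative at the nodes minus the (possibly
#' forced) right-hand side evaluated at the reconstructed states.
#'
#' @param problem a [sir_collocation()] object.
#' @param x coefficient vector of length `3 * n_b` (blocks `a_S, a_I, a_R`).
#' @return numeric residual vector of length `3 * n_c`.
#' @export
collocation_residual <- function(problem, x) {
  st <- .colloc_states(problem, x)
  r <- sir_rhs(st$S, st$I, st$R, st$Idel, problem$params)
  if (!is.null(problem$f_nodes)) {
    r$dS <- r$dS + problem$f_nodes$S
    r$dI <- r$dI + problem$f_nodes$I
    r$dR <- r$dR + problem$f_nodes$R
  }
  c(as.vector(problem$Psi %*% st$aS) - r$dS,
    as.vector(problem$Psi %*% st$aI) - r$dI,
    as.vector(problem$Psi %*% st$aR) - r$dR)
}

## analytic Jacobian exploiting the bilinear Hadamard structure of the
## transmission term: d/da of (S o I_delayed) gives diagonal-times-matrix
## blocks
.colloc_jacobian <- function(pr, st) {
  n_b <- pr$n_b; n_c <- pr$n_c
  p <- pr$params
  Z <- matrix(0, n_c, n_b)
  bSI <- p$beta * st$Idel
  bS <- p$beta * st$S
  J11 <- pr$Psi + bSI * pr$P
  J12 <- bS * pr$MP - p$delta * pr$P
  J21 <- -bSI * pr$P
  J22 <- pr$Psi - bS * pr$MP + (p$delta + p$gamma) * pr$P
  J32 <- -p$gamma * pr$P
  rbind(cbind(J11, J12, Z),
        cbind(J21, J22, Z),
        cbind(Z, J32, pr$Psi))
}

## finite-difference Jacobian (debug / verification path)
.colloc_jacobian_fd <- function(pr, x, eps = 1e-6) {
  n <- length(x)
  F0 <- collocation_residual(pr, x)
  J <- matrix(0, length(F0), n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + eps
    J[, j] <- (collocation_residual(pr, xp) - F0) / eps
  }
  J
}

#' Solve the assembled collocation system
#'
#' Damped Newton iteration with the analytic Jacobian (halving line search
#' down to 1/64), starting from zero derivative coefficients (constant
#' compartments at their initial values); falls back to fixed-point
#' iteration if the Jacobian becomes singular. Fixed-point iteration
#' re-expands the right-hand side at the current states through the basis
#' interpolation at the nodes.
#'
#' @param problem a [sir_collocation()] object.
#' @param config optional [solver_config()] override (defaults to the one
#'   used at assembly).
#' @return an object of class `sir_solution`: list with `trajectory`
#'   (data.frame `t`, `S`, `I`, `R` on the output grid), `coefficients`,
#'   `iterations`, `residual_norm`, `converged`, `conservation`, `params`,
#'   `config`, and the node-level states.
#' @export
solve_collocation <- function(problem, config = NULL) {
  stopifnot(inherits(problem, "collocation_problem"))
  if (is.null(config)) config <- problem$config
  n <- 3 * problem$n_b
  x <- numeric(n)
  tol <- config$residual_tol
  iterations <- 0L
  converged <- FALSE
  method <- config$method
  history_norms <- numeric(0)

  F0 <- collocation_residual(problem, x)
  nrm <- max(abs(F0))
  for (it in seq_len(config$max_iter)) {
    if (nrm <= tol) { converged <- TRUE; break }
    iterations <- it
    if (method == "newton") {
      st <- .colloc_states(problem, x)
      J <- .colloc_jacobian(problem, st)
      dx <- tryCatch(solve(J, -F0), error = function(e) NULL)
      if (is.null(dx)) { method <- "fixed_point"; next }
      accepted <- FALSE
      lambda <- 1
      while (lambda >= 1 / 64) {
        xt <- x + lambda * dx
        Ft <- collocation_residual(problem, xt)
        if (max(abs(Ft)) < nrm) {
          x <- xt; F0 <- Ft; nrm <- max(abs(Ft)); accepted <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!accepted) { method <- "fixed_point"; next }
    } else {
      st <- .colloc_states(problem, x)
      r <- sir_rhs(st$S, st$I, st$R, st$Idel, problem$params)
      if (!is.null(problem$f_nodes)) {
        r$dS <- r$dS + problem$f_nodes$S
        r$dI <- r$dI + problem$f_nodes$I
        r$dR <- r$dR + problem$f_nodes$R
      }
      xn <- c(solve(problem$Psi, r$dS),
              solve(problem$Psi, r$dI),
              solve(problem$Psi, r$dR))
      x <- 0.5 * x + 0.5 * xn              # relaxed fixed point
      F0 <- collocation_residual(problem, x)
      nrm <- max(abs(F0))
    }
    history_norms <- c(history_norms, nrm)
  }
  if (!converged && nrm <= tol) converged <- TRUE
  if (!converged && max(abs(F0)) > sqrt(tol))
    stop("collocation solver failed to converge: residual ", signif(nrm, 4),
         " after ", iterations, " iterations (norm history: ",
         paste(signif(utils::tail(history_norms, 8), 3), collapse = ", "),
         ")")

  times <- seq(0, problem$params$horizon, length.out = config$output_points)
  P_out <- integration_rows(problem$operator, times)
  n_b <- problem$n_b
  S <- problem$X0[["S"]] + as.vector(P_out %*% x[1:n_b])
  I <- problem$X0[["I"]] + as.vector(P_out %*% x[n_b + 1:n_b])
  R <- problem$X0[["R"]] + as.vector(P_out %*% x[2 * n_b + 1:n_b])
  traj <- data.frame(t = times, S = S, I = I, R = R)
  sol <- structure(list(trajectory = traj,
                        coefficients = matrix(x, ncol = 3,
                                              dimnames = list(NULL, c("S", "I", "R"))),
                        iterations = iterations,
                        residual_norm = nrm,
                        converged = converged,
                        conservation = NA_real_,
                        params = problem$params,
                        config = config,
                        problem = problem),
                   class = "sir_solution")
  sol$conservation <- conservation_residual(traj, problem$params$N)
  sol
}

#' One-call interface: assemble and solve
#'
#' @inheritParams sir_collocation
#' @return an object of class `sir_solution`.
#' @examples
#' \donttest{
#' sc <- sir_scenario("as_text")
#' sol <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
#' head(sol$trajectory)
#' }
#' @export
solve_sir <- function(params, histories, config = solver_config(),
                      forcing = NULL) {
  pr <- sir_collocation(params, histories, config, forcing = forcing)
  solve_collocation(pr, config)
}

#' @export
print.sir_solution <- function(x, ...) {
  cat(sprintf(
    "Fractional delayed SIR solution (alpha = %g): %d output times on [0, %g]\n",
    x$params$alpha, nrow(x$trajectory), x$params$horizon))
  cat(sprintf(
    "  %d iterations, residual %.3g, conservation %.3g, converged: %s\n",
    x$iterations, x$residual_norm, x$conservation, x$converged))
  invisible(x)
}

#' Evaluate a solution at arbitrary times
#' @param sol a `sir_solution`.
#' @param times evaluation times in `[0, T]`.
#' @return data.frame with columns `t`, `S`, `I`, `R`.
#' @export
evaluate_solution <- function(sol, times) {
  pr <- sol$problem
  P_out <- integration_rows(pr$operator, times)
  x <- as.vector(sol$coefficients)
  n_b <- pr$n_b
  data.frame(t = times,
             S = pr$X0[["S"]] + as.vector(P_out %*% x[1:n_b]),
             I = pr$X0[["I"]] + as.vector(P_out %*% x[n_b + 1:n_b]),
             R = pr$X0[["R"]] + as.vector(P_out %*% x[2 * n_b + 1:n_b]))
}

#' Function-space residual of an exact solution at the collocation nodes
#'
#' Substitutes a known solution triple (with closed-form Caputo derivatives)
#' into the assembled system: delayed values are produced by the problem's
#' shift machinery applied to exact grid values, and the residual is the
#' closed-form derivative minus the (forced) right-hand side. For
#' manufactured problems this is analytically zero; the returned norm
#' measures the end-to-end consistency of the fractional, delay and assembly
#' machinery.
#'
#' @param problem a [sir_collocation()] object.
#' @param exact list of exact solution functions `S`, `I`, `R` (defined on
#'   `[-tau, T]`).
#' @param exact_caputo list of their Caputo derivatives `S`, `I`, `R` as
#'   functions on `[0, T]`.
#' @return infinity norm of the residual over all nodes and equations.
#' @export
exact_triple_residual <- function(problem, exact, exact_caputo) {
  nodes <- problem$nodes
  S <- exact$S(nodes); I <- exact$I(nodes); R <- exact$R(nodes)
  Idel <- as.vector(problem$Wfull %*% c(exact$I(0), I))
  pre <- problem$prehistory_rows
  if (length(pre) > 0) Idel[pre] <- exact$I(nodes[pre] - problem$params$tau)
  r <- sir_rhs(S, I, R, Idel, problem$params)
  if (!is.null(problem$f_nodes)) {
    r$dS <- r$dS + problem$f_nodes$S
    r$dI <- r$dI + problem$f_nodes$I
    r$dR <- r$dR + problem$f_nodes$R
  }
  max(abs(c(exact_caputo$S(nodes) - r$dS,
            exact_caputo$I(nodes) - r$dI,
            exact_caputo$R(nodes) - r$dR)))
}

#' Refinement (convergence) study against a known solution
#'
#' Solves the same problem at several resolution levels and reports L2
#' errors on a fine uniform grid, together with the empirical order from a
#' log-log fit of error against basis size.
#'
#' @param problem_family list with `params`, `histories`, `exact` (list of
#'   `S`, `I`, `R` functions) and optionally `forcing`.
#' @param J_list resolution levels to run.
#' @param config base [solver_config()]; `J` is overridden per run.
#' @param n_eval number of evaluation points for the error norm.
#' @return data.frame with columns `J`, `n_b`, `l2_error`; attribute
#'   `order` holds the fitted empirical convergence order.
#' @export
convergence_study <- function(problem_family, J_list,
                              config = solver_config(), n_eval = 401) {
  stopifnot(!is.null(problem_family$exact))
  tgrid <- seq(0, problem_family$params$horizon, length.out = n_eval)
  exS <- problem_family$exact$S(tgrid)
  exI <- problem_family$exact$I(tgrid)
  exR <- problem_family$exact$R(tgrid)
  hgrid <- tgrid[2] - tgrid[1]
  rows <- lapply(J_list, function(J) {
    cfg <- config
    cfg$J <- J
    sol <- solve_sir(problem_family$params, problem_family$histories, cfg,
                     forcing = problem_family$forcing)
    tr <- evaluate_solution(sol, tgrid)
    err2 <- (tr$S - exS)^2 + (tr$I - exI)^2 + (tr$R - exR)^2
    data.frame(J = J, n_b = sol$problem$n_b,
               l2_error = sqrt(sum(err2) * hgrid))
  })
  out <- do.call(rbind, rows)
  fit <- stats::lm(log(l2_error) ~ log(n_b), data = out)
  attr(out, "order") <- -unname(stats::coef(fit)[2])
  out
}

#' Parameter sweep
#'
#' Independent solves across a list of values of one model parameter.
#'
#' @param params base [sir_params()].
#' @param histories a [history_set()].
#' @param parameter one of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`,
#'   `"tau"`.
#' @param values numeric vector of parameter values.
#' @param config a [solver_config()].
#' @return an object of class `sir_sweep`: named list of `sir_solution`
#'   objects (or `try-error` for failed values), with attributes
#'   `parameter` and `values`.
#' @export
sweep_parameter <- function(params, histories, parameter, values,
                            config = solver_config()) {
  parameter <- match.arg(parameter,
                         c("alpha", "beta", "gamma", "delta", "tau"))
  sols <- lapply(values, function(v) {
    p <- params
    p[[parameter]] <- v
    tryCatch(solve_sir(p, histories, config),
             error = function(e) structure(list(message = conditionMessage(e),
                                                value = v),
                                           class = "sir_sweep_failure"))
  })
  names(sols) <- paste0(parameter, "=", values)
  structure(sols, parameter = parameter, values = values,
            class = "sir_sweep")
}

#' @export
print.sir_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s: %d runs (%d failed)\n",
              attr(x, "parameter"), length(x),
              sum(vapply(x, inherits, logical(1), "sir_sweep_failure"))))
  invisible(x)
}
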