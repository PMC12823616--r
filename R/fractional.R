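#' @title Riemann-Liouville integration and Caputo differentiation
#' @description Product-trapezoidal quadrature for the weakly singular
#'   Riemann-Liouville kernel, Caputo derivatives of callables, and
#'   collocation operators mapping wavelet-basis coefficients to fractional
#'   derivative / integral values at nodes.
#' @name fractional
NULL

## Product-trapezoidal weights for I^alpha f(t) on the grid u (strictly
## increasing, u[1] = 0): f is treated as piecewise linear on u and the
## kernel (t - s)^(alpha - 1) is integrated exactly on each panel. Panels are
## clipped at t, so t need not be a grid point. Returns weights w with
## I^alpha f(t) ~= sum(w * f(u)).
.pt_weights <- function(alpha, t, u) {
  n <- length(u)
  w <- numeric(n)
  if (t <= u[1]) return(w)
  ## panels [u[i], min(u[i+1], t)] for i with u[i] < t
  last <- findInterval(t, u, left.open = FALSE)   # u[last] <= t
  i <- seq_len(min(last, n - 1))
  a <- u[i]
  b <- pmin(u[i + 1], t)
  keep <- b > a
  i <- i[keep]; a <- a[keep]; b <- b[keep]
  A <- t - a
  B <- t - b
  h <- u[i + 1] - u[i]                 # full panel width (f is linear on it)
  M0 <- (A^alpha - B^alpha) / alpha
  G1 <- A * M0 - (A^(alpha + 1) - B^(alpha + 1)) / (alpha + 1)
  ## f(s) = f_a + (f_b - f_a)(s - a)/h on the (possibly clipped) panel;
  ## M0 and G1 are the exact kernel moments against 1 and (s - a)
  wa <- M0 - G1 / h
  wb <- G1 / h
  w[i] <- w[i] + wa
  w[i + 1] <- w[i + 1] + wb
  w / gamma(alpha)
}

## matrix of product-trapezoidal weights: rows = targets, cols = grid points
.frac_weight_matrix <- function(alpha, targets, u) {
  W <- matrix(0, length(targets), length(u))
  for (l in seq_along(targets)) W[l, ] <- .pt_weights(alpha, targets[l], u)
  W
}

#' Riemann-Liouville fractional integral
#'
#' Computes `(I^alpha f)(t)` with base point 0 by product-trapezoidal
#' quadrature: `f` is interpolated piecewise-linearly on a uniform grid and
#' the weakly singular kernel `(t - s)^(alpha - 1)` is integrated exactly on
#' each panel.
#'
#' @param f a function of one argument, or a list/data.frame with components
#'   `x`, `y` giving samples (linearly interpolated).
#' @param alpha integration order, `alpha > 0`.
#' @param t_eval numeric vector of evaluation times, `t_eval >= 0`.
#' @param n number of quadrature panels per evaluation time.
#' @return numeric vector of the same length as `t_eval`.
#' @examples
#' rl_integral(function(s) rep(1, length(s)), 0.5, 1)  # 1/gamma(1.5)
#' @export
rl_integral <- function(f, alpha, t_eval, n = 1024) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a positive scalar")
  if (any(t_eval < 0)) stop("`t_eval` must be non-negative")
  fn <- .as_callable(f)
  vapply(t_eval, function(t) {
    if (t == 0) return(0)
    u <- seq(0, t, length.out = n + 1)
    sum(.pt_weights(alpha, t, u) * fn(u))
  }, numeric(1))
}

.as_callable <- function(f) {
  if (is.function(f)) return(f)
  if (is.list(f) && !is.null(f$x) && !is.null(f$y)) {
    x <- f$x; y <- f$y
    return(function(s) stats::approx(x, y, xout = s, rule = 2)$y)
  }
  stop("`f` must be a function or a list with components x and y")
}

#' Caputo fractional derivative
#'
#' Computes `(^C D^alpha f)(t)` for `0 < alpha <= 1` as the
#' Riemann-Liouville integral of order `1 - alpha` of `f'`. The derivative is
#' taken from `deriv` when supplied, otherwise by central differences.
#'
#' @param f function of one argument (or samples, see [rl_integral()]).
#' @param alpha derivative order in `(0, 1]`.
#' @param t_eval evaluation times, `>= 0`.
#' @param deriv optional function returning `f'`.
#' @param n quadrature panels per evaluation time.
#' @return numeric vector of Caputo derivative values.
#' @export
caputo_derivative <- function(f, alpha, t_eval, deriv = NULL, n = 1024) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  fn <- .as_callable(f)
  dfn <- if (!is.null(deriv)) deriv else {
    eps <- max(1e-6, max(t_eval) * 1e-7)
    function(s) {
      lo <- pmax(s - eps, 0)
      hi <- s + eps
      (fn(hi) - fn(lo)) / (hi - lo)
    }
  }
  if (alpha == 1) return(dfn(t_eval))
  rl_integral(dfn, 1 - alpha, t_eval, n = n)
}

#' Collocation operator for the Caputo derivative and RL integral of a basis
#'
#' Assembles the matrices that represent fractional differentiation and
#' integration of a wavelet basis at collocation nodes:
#' `D_alpha[l, j] = (^C D^alpha psi_j)(t_l)` and
#' `P_alpha[l, j] = (I^alpha psi_j)(t_l)`. Columns are computed by
#' product-trapezoidal quadrature of the (differenced) cascade-table basis on
#' a fine uniform grid. Optionally the Galerkin matrix
#' `gram_D[i, j] = <D^alpha psi_j, psi_i>` is also assembled.
#'
#' @param basis a [wavelet_basis()] object.
#' @param alpha fractional order in `(0, 1]`.
#' @param nodes collocation nodes; must avoid `t = 0` when `alpha < 1`
#'   (the Caputo kernel is singular at the left endpoint).
#' @param n_quad number of fine-grid panels (default `32 * n_b`, at least
#'   1024).
#' @param gram if `TRUE` also compute the Galerkin matrix.
#' @return an object of class `caputo_operator` with elements `D_alpha`,
#'   `P_alpha`, `gram_D_alpha` (or `NULL`), `nodes`, `alpha`, `basis`,
#'   `fine_grid`, plus the fine-grid basis matrices used in the assembly.
#' @export
caputo_operator <- function(basis, alpha, nodes, n_quad = NULL, gram = FALSE) {
  stopifnot(inherits(basis, "wavelet_basis"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (any(nodes < 0 | nodes > basis$T)) stop("nodes outside [0, T]")
  if (alpha < 1 && any(nodes == 0))
    stop("collocation node at t = 0 with alpha < 1: the Caputo kernel is ",
         "singular at the left endpoint; use midpoint nodes")
  if (is.null(n_quad)) n_quad <- max(1024, 32 * basis$n_b)
  u <- seq(0, basis$T, length.out = n_quad + 1)
  Psi_fine <- evaluate_basis(basis, u)
  dPsi_fine <- evaluate_basis(basis, u, deriv = TRUE)

  Wp <- .frac_weight_matrix(alpha, nodes, u)
  P_alpha <- Wp %*% Psi_fine
  if (alpha == 1) {
    D_alpha <- evaluate_basis(basis, nodes, deriv = TRUE)
  } else {
    Wd <- .frac_weight_matrix(1 - alpha, nodes, u)
    D_alpha <- Wd %*% dPsi_fine
  }

  gram_D <- NULL
  if (gram) {
    if (alpha == 1) {
      D_fine <- dPsi_fine
    } else {
      Wf <- .frac_weight_matrix(1 - alpha, u, u)
      D_fine <- Wf %*% dPsi_fine
    }
    wq <- rep(basis$T / n_quad, n_quad + 1)
    wq[c(1, n_quad + 1)] <- wq[c(1, n_quad + 1)] / 2
    gram_D <- crossprod(Psi_fine, D_fine * wq)
  }

  structure(list(basis = basis, alpha = alpha, nodes = nodes,
                 D_alpha = D_alpha, P_alpha = P_alpha,
                 gram_D_alpha = gram_D,
                 fine_grid = u, Psi_fine = Psi_fine, dPsi_fine = dPsi_fine),
            class = "caputo_operator")
}

#' @export
print.caputo_operator <- function(x, ...) {
  cat(sprintf(
    "Caputo collocation operator: alpha = %g, %d nodes, n_b = %d%s\n",
    x$alpha, length(x$nodes), x$basis$n_b,
    if (is.null(x$gram_D_alpha)) "" else " (+ Galerkin matrix)"))
  invisible(x)
}

#' Fractional integration matrix at arbitrary targets
#'
#' Rows map fine-grid samples of a function to `I^alpha` values at `targets`
#' via the same product-trapezoidal rule used in [caputo_operator()];
#' multiplied with the fine-grid basis matrix it yields `P_alpha` rows at
#' any output times.
#'
#' @param op a `caputo_operator`.
#' @param targets evaluation times in `[0, T]`.
#' @return `length(targets) x n_b` matrix.
#' @export
integration_rows <- function(op, targets) {
  W <- .frac_weight_matrix(op$alpha, targets, op$fine_grid)
  W %*% op$Psi_fine
}
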