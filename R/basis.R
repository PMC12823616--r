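#' Periodized Daubechies wavelet basis on an interval
#'
#' Builds a finite orthonormal basis of `2^J` periodized Daubechies scaling
#' functions (or an equivalent multiresolution mix of scaling and wavelet
#' functions) on `[0, T]`, rescaled from the unit interval. Functions are
#' evaluated by linear interpolation in a cascade table of refinement level
#' `refinement` (default 12, i.e. spacing 2^-12 on the native support).
#'
#' Periodization preserves exact orthonormality and reproduction of
#' constants. Non-periodic functions are only approximated up to a seam
#' (wrap-around) error at the interval boundary; for collocation solves the
#' basis can be augmented with `augment` low-degree polynomial trend
#' functions (shifted Legendre, degree 1..augment), which removes the
#' dominant seam term at the cost of exact Gram orthonormality.
#'
#' @param order Daubechies order (vanishing moments), 2..10. Default 4.
#' @param T right endpoint of the domain `[0, T]`.
#' @param J resolution level; the wavelet part of the basis has `2^J`
#'   functions. Requires `2^J >= 2 * order - 1`.
#' @param mode `"scaling_only"` (default) uses scaling functions at level J;
#'   `"full_mra"` uses scaling functions at a coarse level plus wavelet
#'   functions on the intermediate levels (same span).
#' @param boundary interval handling; only `"periodized"` is implemented.
#' @param refinement cascade refinement level for function evaluation.
#' @param augment number of polynomial trend functions to append (0, 1 or 2).
#' @return an object of class `wavelet_basis`.
#' @export
wavelet_basis <- function(order = 4, T = 1, J = 6,
                          mode = c("scaling_only", "full_mra"),
                          boundary = "periodized",
                          refinement = 12, augment = 0) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary, "periodized")
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("`T` must be > 0")
  if (J < 1 || J != round(J)) stop("`J` must be a positive integer")
  J <- as.integer(J)
  filt <- daub_filter(order)
  N <- filt$order
  Lsupp <- 2L * N - 1L
  if (augment < 0 || augment > 2 || augment != round(augment))
    stop("`augment` must be 0, 1 or 2")

  tab <- daub_cascade(filt, refinement)
  dphi <- .table_derivative(tab$values, refinement)

  ## coarsest usable periodization level: one wrap at most
  Jmin <- ceiling(log2(Lsupp))
  if (2^J < Lsupp)
    stop("level J = ", J, " too coarse for db", N,
         " periodization; need 2^J >= ", Lsupp)

  funs <- NULL
  psi_tab <- NULL
  dpsi_tab <- NULL
  if (mode == "scaling_only") {
    funs <- data.frame(type = "phi", level = J, k = 0:(2^J - 1))
  } else {
    J0 <- as.integer(Jmin)
    if (J < J0) stop("full_mra requires J >= ", J0, " for db", N)
    funs <- data.frame(type = "phi", level = J0, k = 0:(2^J0 - 1))
    if (J > J0) {
      for (j in J0:(J - 1L)) {
        funs <- rbind(funs,
                      data.frame(type = "psi", level = j, k = 0:(2^j - 1)))
      }
    }
    ## wavelet table psi(y) = sqrt(2) sum_k g_k phi(2y - k)
    g <- rev(filt$coefficients) * (-1)^(0:(2 * N - 1))
    nt <- length(tab$values)
    psi_tab <- numeric(nt)
    p <- 0:(nt - 1)
    for (k in 0:(2 * N - 1)) {
      idx <- 2L * p - k * 2^refinement
      ok <- idx >= 0L & idx <= (nt - 1L)
      psi_tab[ok] <- psi_tab[ok] +
        sqrt(2) * g[k + 1L] * tab$values[idx[ok] + 1L]
    }
    dpsi_tab <- .table_derivative(psi_tab, refinement)
  }

  n_w <- nrow(funs)
  structure(list(filter = filt, T = T, J = J, mode = mode,
                 boundary = boundary, refinement = refinement,
                 augment = as.integer(augment),
                 n_b = n_w + as.integer(augment), n_wavelet = n_w,
                 functions = funs,
                 phi_tab = tab$values, dphi_tab = dphi,
                 psi_tab = psi_tab, dpsi_tab = dpsi_tab),
            class = "wavelet_basis")
}

#' @export
print.wavelet_basis <- function(x, ...) {
  cat(sprintf(
    "Periodized db%d wavelet basis on [0, %g]: J = %d, mode = %s, n_b = %d%s\n",
    x$filter$order, x$T, x$J, x$mode, x$n_b,
    if (x$augment > 0) sprintf(" (incl. %d polynomial trend column%s)",
                               x$augment, if (x$augment > 1) "s" else "")
    else ""))
  invisible(x)
}

#' Summarize a basis as a plain list (JSON-exportable)
#' @param basis a [wavelet_basis()] object.
#' @return a named list of scalar descriptors.
#' @export
basis_summary <- function(basis) {
  list(order = basis$filter$order, J = basis$J, n_b = basis$n_b,
       mode = basis$mode, boundary = basis$boundary,
       domain = c(0, basis$T), refinement = basis$refinement,
       augment = basis$augment)
}

## evaluate one periodized table function (level j, shift k) at x in [0, 1]
.periodized_eval <- function(values, refinement, Lsupp, j, k, x) {
  y <- (2^j * x - k) %% 2^j
  out <- 2^(j / 2) * .table_eval(values, refinement, y)
  ## a second wrapped copy can only contribute when y + 2^j <= Lsupp,
  ## impossible for 2^j >= Lsupp except at the exact endpoint (phi = 0 there)
  out
}

#' Evaluate all basis functions at given nodes
#'
#' @param basis a [wavelet_basis()] object.
#' @param nodes numeric vector of evaluation points in `[0, T]`.
#' @param deriv if `TRUE`, evaluate first derivatives (from the differenced
#'   cascade table) instead of function values.
#' @return a `length(nodes) x n_b` matrix with entry `(l, j)` equal to
#'   `psi_j(nodes[l])`; class `basis_matrix` with attributes `nodes`.
#' @export
evaluate_basis <- function(basis, nodes, deriv = FALSE) {
  stopifnot(inherits(basis, "wavelet_basis"))
  if (any(!is.finite(nodes))) stop("nodes must be finite")
  if (any(nodes < 0 | nodes > basis$T))
    stop("nodes outside the basis domain [0, ", basis$T, "]")
  Tlen <- basis$T
  x <- nodes / Tlen
  Lsupp <- 2L * basis$filter$order - 1L
  out <- matrix(0, length(nodes), basis$n_b)
  scale <- if (deriv) Tlen^(-1 / 2) / Tlen else Tlen^(-1 / 2)
  for (m in seq_len(basis$n_wavelet)) {
    fn <- basis$functions[m, ]
    vals <- if (fn$type == "phi") {
      if (deriv) basis$dphi_tab else basis$phi_tab
    } else {
      if (deriv) basis$dpsi_tab else basis$psi_tab
    }
    v <- .periodized_eval(vals, basis$refinement, Lsupp, fn$level, fn$k, x)
    if (deriv) v <- v * 2^fn$level      # chain rule for the dilation
    out[, m] <- scale * v
  }
  if (basis$augment >= 1) {
    j <- basis$n_wavelet + 1L
    if (deriv) out[, j] <- sqrt(3 / Tlen) * 2 / Tlen
    else out[, j] <- sqrt(3 / Tlen) * (2 * x - 1)
  }
  if (basis$augment >= 2) {
    j <- basis$n_wavelet + 2L
    if (deriv) out[, j] <- sqrt(5 / Tlen) * (12 * x - 6) / Tlen
    else out[, j] <- sqrt(5 / Tlen) * (6 * x^2 - 6 * x + 1)
  }
  structure(out, nodes = nodes, class = c("basis_matrix", "matrix", "array"))
}

#' Least-squares projection onto the basis
#'
#' Projects a function (or sampled values) onto the basis by least squares on
#' a fine uniform quadrature grid, and reports the discrete reconstruction
#' error.
#'
#' @param basis a [wavelet_basis()] object.
#' @param f a function of one argument defined on `[0, T]`, or a numeric
#'   vector of samples on the quadrature grid.
#' @param quadrature_points number of uniform quadrature points (default
#'   `8 * n_b`).
#' @return numeric coefficient vector of length `n_b`, with attributes
#'   `l2_error` (discrete L2 reconstruction error) and `max_error`.
#' @export
basis_project <- function(basis, f, quadrature_points = 8 * basis$n_b) {
  grid <- seq(0, basis$T, length.out = quadrature_points)
  fx <- if (is.function(f)) f(grid) else {
    if (length(f) != quadrature_points)
      stop("sample vector must have length `quadrature_points`")
    as.numeric(f)
  }
  if (any(!is.finite(fx))) stop("function values must be finite on [0, T]")
  Psi <- evaluate_basis(basis, grid)
  qr_Psi <- qr(Psi)
  if (qr_Psi$rank < basis$n_b)
    stop("rank-deficient projection: degenerate basis or quadrature grid")
  coef <- qr.coef(qr_Psi, fx)
  resid <- fx - as.vector(Psi %*% coef)
  hq <- basis$T / (quadrature_points - 1)
  structure(coef,
            l2_error = sqrt(sum(resid^2) * hq),
            max_error = max(abs(resid)))
}

#' Reconstruct a projected function at arbitrary points
#' @param basis a [wavelet_basis()] object.
#' @param coef coefficient vector of length `n_b`.
#' @param t evaluation points in `[0, T]`.
#' @return numeric vector of reconstructed values.
#' @export
basis_reconstruct <- function(basis, coef, t) {
  as.vector(evaluate_basis(basis, t) %*% coef)
}

#' Gram matrix of the basis by trapezoidal quadrature
#' @param basis a [wavelet_basis()] object.
#' @param n number of quadrature points.
#' @return `n_b x n_b` numeric matrix.
#' @export
basis_gram <- function(basis, n = 4096) {
  grid <- seq(0, basis$T, length.out = n + 1)
  Psi <- evaluate_basis(basis, grid)
  w <- rep(basis$T / n, n + 1)
  w[c(1, n + 1)] <- w[c(1, n + 1)] / 2
  crossprod(Psi, Psi * w)
}
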