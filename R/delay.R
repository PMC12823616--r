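#' Shift matrix for delayed evaluation on a grid
#'
#' Builds the sparse interpolation matrix `T_tau` whose row `l` carries the
#' Lagrange weights that map grid values `f(t_m)` to the delayed value
#' `f(t_l - tau)`. Two conventions are supported for shifted abscissae that
#' fall before the grid:
#'
#' * `policy = "history"` (solver default): such rows are left identically
#'   zero and recorded in `prehistory_rows`; the history function supplies
#'   those values separately in [delayed_values()].
#' * `policy = "cyclic"`: shifted abscissae are wrapped around the grid. On a
#'   uniform grid with `tau` an integer multiple `q` of the spacing this
#'   reduces exactly to the permutation matrix that cyclically shifts entries
#'   by `q` (a reproduction mode for the textbook illustration; wrapping
#'   pre-history onto future times has no epidemiological meaning).
#'
#' @param nodes strictly increasing grid abscissae.
#' @param tau delay, `tau > 0` (a zero delay yields the identity).
#' @param interp_order Lagrange interpolation order, 1 (linear) or 3 (cubic;
#'   the 4-point stencil is shifted one-sided next to the grid edges).
#' @param policy `"history"` or `"cyclic"`.
#' @return an object of class `delay_shift`: list with the sparse `weights`
#'   matrix (`Matrix::dgCMatrix`), `nodes`, `tau`, `shifted` abscissae,
#'   `prehistory_rows`, `policy`, `interp_order`.
#' @examples
#' sh <- shift_matrix(seq(0, 1, 0.25), 0.5, interp_order = 1,
#'                    policy = "cyclic")
#' as.matrix(sh$weights)  # cyclic permutation shifting entries by two
#' @export
shift_matrix <- function(nodes, tau, interp_order = 3,
                         policy = c("history", "cyclic")) {
  policy <- match.arg(policy)
  n <- length(nodes)
  if (n == 0L) stop("`nodes` must be non-empty")
  if (any(diff(nodes) <= 0)) stop("`nodes` must be strictly increasing")
  if (tau < 0) stop("`tau` must be non-negative")
  if (!interp_order %in% c(1, 3)) stop("`interp_order` must be 1 or 3")
  span <- nodes[n] - nodes[1]
  if (policy == "cyclic" && tau >= span)
    stop("cyclic policy requires tau < span of the nodes")

  s <- nodes - tau
  tol <- 1e-9 * max(1, span)
  prehistory <- integer(0)

  hdiff <- diff(nodes)
  uniform <- n > 1 && max(hdiff) - min(hdiff) < tol
  h <- if (uniform) mean(hdiff) else NA_real_

  if (policy == "cyclic") {
    if (!uniform) stop("cyclic policy requires a uniform grid")
    q <- tau / h
    if (abs(q - round(q)) < 1e-9) {
      ## exact grid multiple: permutation cyclically shifting entries by q
      q <- as.integer(round(q))
      ii <- seq_len(n)
      jj <- ((ii - 1L + q) %% n) + 1L
      W <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, n), dims = c(n, n))
      return(structure(list(weights = W, nodes = nodes, tau = tau,
                            shifted = s, prehistory_rows = integer(0),
                            policy = policy, interp_order = interp_order),
                       class = "delay_shift"))
    }
    ## non-integer shift: wrap below the grid by the index period n * h
    s[s < nodes[1] - tol] <- s[s < nodes[1] - tol] + n * h
  } else {
    prehistory <- which(s < nodes[1] - tol)
  }

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (l in seq_len(n)) {
    if (l %in% prehistory) next
    sl <- s[l]
    hit <- which(abs(nodes - sl) <= tol)
    if (length(hit) > 0) {
      ii <- c(ii, l); jj <- c(jj, hit[1]); xx <- c(xx, 1)
      next
    }
    i0 <- findInterval(sl, nodes)
    if (i0 < 1L || i0 >= n)
      stop("shifted node ", sl, " outside the interpolation range")
    stencil <- if (interp_order == 3 && n >= 4L) {
      ## centered 4-point stencil, shifted one-sided at the grid edges so
      ## cubic accuracy (and exactness on cubics) holds everywhere
      lo <- min(max(i0 - 1L, 1L), n - 3L)
      lo:(lo + 3L)
    } else {
      i0:(i0 + 1L)
    }
    xs <- nodes[stencil]
    w <- vapply(seq_along(xs), function(j) {
      prod((sl - xs[-j]) / (xs[j] - xs[-j]))
    }, numeric(1))
    ii <- c(ii, rep(l, length(stencil))); jj <- c(jj, stencil); xx <- c(xx, w)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(list(weights = W, nodes = nodes, tau = tau, shifted = s,
                 prehistory_rows = prehistory, policy = policy,
                 interp_order = interp_order),
            class = "delay_shift")
}

#' @export
print.delay_shift <- function(x, ...) {
  cat(sprintf(
    "Delay shift matrix: %d nodes, tau = %g, order-%d interpolation, %s policy (%d pre-history rows)\n",
    length(x$nodes), x$tau, x$interp_order, x$policy,
    length(x$prehistory_rows)))
  invisible(x)
}

#' Delayed values on a grid
#'
#' Applies the shift matrix to grid values and fills pre-history rows (where
#' `t_l - tau` precedes the grid) from the history function.
#'
#' @param shift a [shift_matrix()] object.
#' @param grid_values numeric vector of values at `shift$nodes`.
#' @param history function defined on `[-tau, 0]`; required when
#'   `prehistory_rows` is non-empty.
#' @return numeric vector of `f(t_l - tau)` values.
#' @export
delayed_values <- function(shift, grid_values, history = NULL) {
  stopifnot(inherits(shift, "delay_shift"))
  if (length(grid_values) != length(shift$nodes))
    stop("`grid_values` must match the number of nodes")
  out <- as.vector(shift$weights %*% grid_values)
  pre <- shift$prehistory_rows
  if (length(pre) > 0) {
    if (is.null(history))
      stop("history function required: ", length(pre),
           " shifted nodes precede the grid")
    sp <- shift$shifted[pre]
    if (any(sp > 1e-12))
      stop("history undefined at requested point(s) ",
           paste(signif(sp[sp > 1e-12], 4), collapse = ", "),
           " (history covers [-tau, 0])")
    hv <- history(pmin(sp, 0))
    if (any(!is.finite(hv))) stop("history returned non-finite values")
    out[pre] <- hv
  }
  out
}

#' Export a shift matrix as coordinate-format text
#' @param shift a [shift_matrix()] object.
#' @param path output file; three whitespace-separated columns
#'   (row, col, weight), 1-based.
#' @return the path, invisibly.
#' @export
write_shift_matrix <- function(shift, path) {
  trip <- Matrix::summary(shift$weights)
  utils::write.table(data.frame(row = trip$i, col = trip$j,
                                weight = trip$x),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' History set for a three-compartment delay system
#'
#' Bundles the three history functions defined on `[-tau, 0]` that serve as
#' generalized initial conditions. Each component may be given as a function,
#' a numeric vector of polynomial coefficients (constant first), or a
#' data.frame/list with `x`, `y` samples (linearly interpolated).
#'
#' @param phi1,phi2,phi3 history specifications for the three components
#'   (susceptible, infected, recovered in the SIR application).
#' @param tau delay; the common history domain is `[-tau, 0]`.
#' @return an object of class `history_set`: list of three functions plus
#'   `tau`.
#' @export
history_set <- function(phi1, phi2, phi3, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a positive scalar")
  fns <- lapply(list(phi1, phi2, phi3), .as_history)
  for (f in fns) {
    probe <- f(seq(-tau, 0, length.out = 11))
    if (any(!is.finite(probe)))
      stop("history function is not finite on [-tau, 0]")
  }
  structure(list(phi1 = fns[[1]], phi2 = fns[[2]], phi3 = fns[[3]],
                 tau = tau),
            class = "history_set")
}

.as_history <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.numeric(spec)) return(poly_fn(spec))
  if ((is.list(spec) || is.data.frame(spec)) &&
      !is.null(spec$x) && !is.null(spec$y)) {
    x <- spec$x; y <- spec$y
    return(function(t) stats::approx(x, y, xout = t, rule = 2)$y)
  }
  stop("history must be a function, polynomial coefficients, or x/y samples")
}

#' Polynomial as a function (coefficients constant-first)
#' @param coefs numeric coefficients `c0, c1, ...` of `c0 + c1 t + ...`.
#' @return a vectorized function of `t`.
#' @export
poly_fn <- function(coefs) {
  force(coefs)
  function(t) {
    out <- rep(coefs[length(coefs)], length(t))
    for (k in rev(seq_len(length(coefs) - 1))) out <- out * t + coefs[k]
    out
  }
}
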