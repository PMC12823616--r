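#' Daubechies low-pass filter coefficients
#'
#' Computes the 2N low-pass (scaling) filter coefficients of the Daubechies
#' orthonormal wavelet family with `order` vanishing moments by spectral
#' factorization: the Daubechies half-band polynomial is factored with
#' `polyroot()`, the roots are polished by complex Newton iteration, and the
#' minimal-phase factor is assembled and normalized so that the coefficients
#' sum to sqrt(2).
#'
#' The returned filter satisfies, to near machine precision,
#' * sum(h) = sqrt(2),
#' * the double-shift orthonormality relations sum_k h_k h_{k+2m} = delta_m0,
#' * N vanishing moments of the derived wavelet: sum_k (-1)^k k^p h_k = 0 for
#'   p = 0, ..., N-1.
#'
#' @param order integer number of vanishing moments N, between 2 and 10.
#' @return an object of class `daub_filter`: a list with elements `order` and
#'   `coefficients` (numeric vector of length `2 * order`).
#' @examples
#' f <- daub_filter(2)
#' sum(f$coefficients)  # sqrt(2)
#' @export
daub_filter <- function(order) {
  if (length(order) != 1L || !is.finite(order) || order != round(order))
    stop("`order` must be a single integer")
  order <- as.integer(order)
  if (order < 2L || order > 10L)
    stop("unsupported Daubechies order ", order,
         ": supported range is 2..10 vanishing moments")
  N <- order

  ## Daubechies polynomial P(y) = sum_{k<N} C(N-1+k, k) y^k with
  ## y = (2 - z - 1/z)/4, accumulated as a Laurent polynomial in z.
  base <- c(-0.25, 0.5, -0.25)            # powers -1, 0, 1
  q <- 0
  pw <- 1                                  # base^k, powers -k..k
  for (k in 0:(N - 1)) {
    coef <- choose(N - 1 + k, k)
    ## align pw (powers -k..k) into accumulator of powers -(N-1)..(N-1)
    pad <- N - 1 - k
    q <- q + coef * c(rep(0, pad), pw, rep(0, pad))
    if (k < N - 1) pw <- .poly_mult(pw, base)
  }
  ## q now holds Q(z) for powers -(N-1)..(N-1); as ordinary polynomial of
  ## degree 2N-2 (ascending coefficients) it is the same vector.
  if (N == 2) {
    ## degree-2 polynomial; polyroot handles it but keep the generic path
  }
  r <- polyroot(q)
  r <- .polish_roots(q, r)
  inside <- Mod(r) < 1
  ri <- r[inside]
  if (length(ri) != N - 1)
    stop("spectral factorization failed: expected ", N - 1,
         " roots inside the unit circle, found ", length(ri))

  ## L(z) = prod (z - r_i) with real coefficients (roots close under conj)
  L <- 1 + 0i
  for (root in ri) L <- .poly_mult(L, c(-root, 1))
  if (max(abs(Im(L))) > 1e-8)
    stop("spectral factorization produced a non-real factor")
  L <- Re(L)

  ## h(z) proportional to ((1+z)/2)^N L(z)
  h <- L
  for (i in seq_len(N)) h <- .poly_mult(h, c(0.5, 0.5))
  h <- h * sqrt(2) / sum(h)

  ## orient with energy front-loaded (extremal/minimal-phase convention)
  front <- sum(h[seq_len(N)]^2)
  back <- sum(h[(N + 1):(2 * N)]^2)
  if (back > front) h <- rev(h)

  h <- .refine_filter(h, N)
  structure(list(order = N, coefficients = h), class = "daub_filter")
}

## plain polynomial product, ascending coefficients
.poly_mult <- function(a, b) {
  na <- length(a); nb <- length(b)
  out <- vector(if (is.complex(a) || is.complex(b)) "complex" else "numeric",
                na + nb - 1)
  for (i in seq_len(na)) out[i:(i + nb - 1)] <- out[i:(i + nb - 1)] + a[i] * b
  out
}

## Gauss-Newton projection of the assembled coefficients onto the defining
## constraints (normalization, double-shift orthonormality, vanishing
## moments); removes the residual convolution roundoff at high orders
.refine_filter <- function(h, N, iter = 3L) {
  k <- 0:(2 * N - 1)
  sgn <- (-1)^k
  mom_rows <- t(vapply(0:(N - 1), function(p) sgn * k^p,
                       numeric(2 * N)))
  mom_scale <- pmax(rowSums(abs(mom_rows)), 1)
  for (i in seq_len(iter)) {
    r_sum <- sum(h) - sqrt(2)
    r_orth <- vapply(0:(N - 1), function(m) {
      sum(h[1:(2 * N - 2 * m)] * h[(2 * m + 1):(2 * N)]) -
        (m == 0)
    }, numeric(1))
    r_mom <- as.vector(mom_rows %*% h) / mom_scale
    r <- c(r_sum, r_orth, r_mom)
    J_orth <- t(vapply(0:(N - 1), function(m) {
      row <- numeric(2 * N)
      idx <- seq_len(2 * N - 2 * m)
      row[idx] <- row[idx] + h[idx + 2 * m]
      row[idx + 2 * m] <- row[idx + 2 * m] + h[idx]
      row
    }, numeric(2 * N)))
    J <- rbind(rep(1, 2 * N), J_orth, mom_rows / mom_scale)
    h <- h - qr.coef(qr(J), r)
  }
  h
}

## polish polyroot output by Newton iteration on the exact coefficients
.polish_roots <- function(coefs, roots, iter = 8L) {
  dcoefs <- coefs[-1] * seq_along(coefs[-1])
  for (i in seq_len(iter)) {
    p <- .horner(coefs, roots)
    dp <- .horner(dcoefs, roots)
    step <- p / dp
    step[!is.finite(step)] <- 0
    roots <- roots - step
  }
  roots
}

.horner <- function(coefs, x) {
  out <- rep(coefs[length(coefs)], length(x))
  for (k in rev(seq_len(length(coefs) - 1))) out <- out * x + coefs[k]
  out
}

#' @export
print.daub_filter <- function(x, ...) {
  cat("Daubechies filter: N =", x$order, "vanishing moments,",
      length(x$coefficients), "coefficients\n")
  print(x$coefficients)
  invisible(x)
}

#' Scaling function by the cascade algorithm
#'
#' Tabulates the Daubechies scaling function phi on the dyadic grid of
#' spacing `2^-refinement_level` over its support `[0, 2N-1]`. Values at the
#' integers are the (suitably normalized) eigenvector of the two-scale
#' transition operator for eigenvalue 1; finer dyadic values follow exactly
#' from the two-scale relation phi(x) = sqrt(2) sum_k h_k phi(2x - k).
#'
#' @param filter a [daub_filter()] object.
#' @param refinement_level non-negative integer r; the table spacing is 2^-r.
#' @return an object of class `scaling_table`: list with `order`,
#'   `refinement_level`, `abscissae`, `values`.
#' @export
daub_cascade <- function(filter, refinement_level) {
  stopifnot(inherits(filter, "daub_filter"))
  if (length(refinement_level) != 1L || refinement_level < 0 ||
      refinement_level != round(refinement_level))
    stop("`refinement_level` must be a non-negative integer")
  r <- as.integer(refinement_level)
  h <- filter$coefficients
  N <- filter$order
  L <- 2L * N - 1L                       # support [0, L]

  ## values at interior integers: eigenvector of M[i, j] = sqrt(2) h[2i - j]
  n <- L - 1L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k <- 2L * i - j                    # filter index (0-based)
      if (k >= 0L && k <= 2L * N - 1L) M[i, j] <- sqrt(2) * h[k + 1L]
    }
  }
  ev <- eigen(M)
  sel <- which(abs(ev$values - 1) < 1e-8)
  if (length(sel) != 1L)
    stop("two-scale transition operator has no simple eigenvalue 1; ",
         "the filter is not a valid orthonormal scaling filter")
  v <- Re(ev$vectors[, sel])
  v <- v / sum(v)                        # partition of unity at the integers
  vals <- c(0, v, 0)                     # phi at integers 0..L

  ## dyadic refinement: at step s the grid spacing halves to 2^-s
  for (s in seq_len(r)) {
    n_old <- length(vals)                # indices 0..(n_old-1), spacing 2^-(s-1)
    n_new <- 2L * (n_old - 1L) + 1L
    new_vals <- numeric(n_new)
    new_vals[seq(1L, n_new, by = 2L)] <- vals
    odd <- seq(2L, n_new - 1L, by = 2L)  # 1-based positions of odd indices
    p <- odd - 1L                        # 0-based new index, odd
    acc <- numeric(length(p))
    shift <- 2^(s - 1L)
    for (k in 0:(2L * N - 1L)) {
      idx <- p - k * shift               # 0-based old index of phi(2y - k)
      ok <- idx >= 0L & idx <= (n_old - 1L)
      if (any(ok)) acc[ok] <- acc[ok] + sqrt(2) * h[k + 1L] * vals[idx[ok] + 1L]
    }
    new_vals[odd] <- acc
    vals <- new_vals
  }

  structure(list(order = N,
                 refinement_level = r,
                 abscissae = seq(0, L, by = 2^-r),
                 values = vals),
            class = "scaling_table")
}

## linear interpolation into a dyadic table over [0, L]; zero outside support
.table_eval <- function(values, r, y) {
  n <- length(values)
  pos <- y * 2^r
  out <- numeric(length(y))
  ok <- pos >= 0 & pos < (n - 1)
  if (any(ok)) {
    p <- pos[ok]
    i0 <- floor(p)
    w <- p - i0
    out[ok] <- (1 - w) * values[i0 + 1] + w * values[i0 + 2]
  }
  out[pos == (n - 1)] <- values[n]
  out
}

## centered-difference derivative table with zero extension beyond the
## support; the uniform stencil preserves telescoping identities such as
## sum_k phi'(x - k) = 0 exactly at every table point
.table_derivative <- function(values, r) {
  n <- length(values)
  hstep <- 2^-r
  ext <- c(0, values, 0)
  (ext[3:(n + 2)] - ext[1:n]) / (2 * hstep)
}
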