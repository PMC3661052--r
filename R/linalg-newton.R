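# Dense LU decomposition with partial pivoting, triangular solves,
# finite-difference Jacobians and damped-free k-dimensional Newton
# iteration. Written from scratch: these primitives back every implicit
# integrator step, algebraic-rule solve and fast-reaction equilibration.

#' Newton solver settings
#'
#' @param tolerance residual max-norm threshold declaring convergence.
#' @param max_iterations iteration cap before a non-convergence error.
#' @param jacobian_epsilon base finite-difference step; the step used for
#'   component j is `jacobian_epsilon * max(|x_j|, 1)`.
#' @return a list of validated settings.
#' @export
newton_settings <- function(tolerance = 1e-10, max_iterations = 100L,
                            jacobian_epsilon = sqrt(.Machine$double.eps)) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
       jacobian_epsilon = jacobian_epsilon)
}

#' LU decomposition with partial pivoting
#'
#' Factorizes `P A = L U` (Doolittle, unit-diagonal L) with row pivoting
#' on the largest column magnitude. The factors are stored compactly in
#' one matrix: U on and above the diagonal, the multipliers of L below.
#'
#' @param A square numeric matrix.
#' @return `list(lu = <matrix>, perm = <integer row permutation>)`.
#' @export
lu_decompose <- function(A) {
  A <- as.matrix(A)
  k <- nrow(A)
  if (ncol(A) != k) stop_sbml("numeric", "LU requires a square matrix")
  if (!all(is.finite(A))) stop_sbml("numeric", "non-finite matrix entry")
  perm <- seq_len(k)
  for (col in seq_len(k)) {
    p <- which.max(abs(A[col:k, col])) + col - 1L
    if (abs(A[p, col]) < 1e-14)
      stop_sbml("numeric", "singular matrix in LU decomposition (pivot ",
                col, ")")
    if (p != col) {
      A[c(col, p), ] <- A[c(p, col), ]
      perm[c(col, p)] <- perm[c(p, col)]
    }
    if (col < k) {
      rows <- (col + 1L):k
      A[rows, col] <- A[rows, col] / A[col, col]
      A[rows, (col + 1L):k] <- A[rows, (col + 1L):k] -
        outer(A[rows, col], A[col, (col + 1L):k])
    }
  }
  list(lu = A, perm = perm)
}

#' Solve a factorized linear system
#'
#' Forward elimination with the unit-lower factor followed by backward
#' substitution with the upper factor.
#'
#' @param factors result of [lu_decompose()].
#' @param b right-hand-side vector.
#' @return the solution vector `x` with `A x = b`.
#' @export
lu_solve <- function(factors, b) {
  lu <- factors$lu
  k <- nrow(lu)
  if (length(b) != k) stop_sbml("numeric", "rhs length mismatch")
  y <- b[factors$perm]
  for (i in seq_len(k)[-1])                 # forward elimination
    y[i] <- y[i] - sum(lu[i, 1:(i - 1L)] * y[1:(i - 1L)])
  x <- numeric(k)
  for (i in rev(seq_len(k))) {              # backward substitution
    s <- if (i < k) sum(lu[i, (i + 1L):k] * x[(i + 1L):k]) else 0
    x[i] <- (y[i] - s) / lu[i, i]
  }
  x
}

#' Forward-difference Jacobian
#'
#' `J[i,j] = (F_i(x + e_j h_j) - F_i(x)) / h_j` with a componentwise step
#' `h_j = jacobian_epsilon * max(|x_j|, 1)`.
#'
#' @param F function mapping a numeric vector to a numeric vector.
#' @param x evaluation point.
#' @param settings from [newton_settings()].
#' @return the Jacobian matrix (rows: outputs, columns: inputs).
#' @export
numerical_jacobian <- function(F, x, settings = newton_settings()) {
  f0 <- F(x)
  if (!all(is.finite(f0)))
    stop_sbml("numeric", "non-finite function value at component ",
              which(!is.finite(f0))[1])
  m <- length(f0); n <- length(x)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- settings$jacobian_epsilon * max(abs(x[j]), 1)
    xj <- x
    xj[j] <- xj[j] + h
    fj <- F(xj)
    if (!all(is.finite(fj)))
      stop_sbml("numeric", "non-finite function value at component ",
                which(!is.finite(fj))[1], " (perturbing x[", j, "])")
    J[, j] <- (fj - f0) / h
  }
  J
}

#' k-dimensional Newton iteration
#'
#' Plain (undamped) Newton: `x <- x - J(x)^{-1} F(x)` with the numerical
#' Jacobian and the LU solve above, until the residual max-norm drops
#' below the tolerance. Non-convergence is surfaced as an error carrying
#' the last residual so callers (implicit integrators) can retry with a
#' smaller step.
#'
#' @param F square vector function (output length == input length).
#' @param x0 starting point.
#' @param settings from [newton_settings()].
#' @return the root, with attributes `iterations` and `residual`.
#' @export
newton_solve <- function(F, x0, settings = newton_settings()) {
  x <- as.numeric(x0)
  fx <- F(x)
  if (length(fx) != length(x))
    stop_sbml("numeric", "Newton requires a square system (F: ",
              length(x), " -> ", length(fx), ")")
  for (it in seq_len(settings$max_iterations)) {
    res <- max(abs(fx))
    if (is.finite(res) && res < settings$tolerance) {
      attr(x, "iterations") <- it - 1L
      attr(x, "residual") <- res
      return(x)
    }
    if (!all(is.finite(fx)))
      stop_sbml("numeric", "non-finite residual in Newton iteration ", it)
    J <- numerical_jacobian(F, x, settings)
    step <- lu_solve(lu_decompose(J), fx)
    x <- x - step
    fx <- F(x)
  }
  res <- max(abs(fx))
  if (is.finite(res) && res < settings$tolerance) {
    attr(x, "iterations") <- settings$max_iterations
    attr(x, "residual") <- res
    return(x)
  }
  stop_sbml("numeric", "Newton did not converge in ",
            settings$max_iterations, " iterations (last residual ",
            format(res), ")")
}
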