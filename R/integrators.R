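# Steppers: explicit Euler, classical RK4, Adams-Bashforth (orders 1-4);
# implicit backward Euler, Adams-Moulton (1-4), Gear/BDF (1-4); adaptive
# embedded Runge-Kutta-Fehlberg 4(5) and Cash-Karp 4(5). All advance one
# step; the simulation loop in runner.R owns step-size policy, event
# clamping and multistep history management.

METHOD_FAMILIES <- c("euler", "rk4", "adams_bashforth", "backward_euler",
                     "adams_moulton", "gear", "rkf45", "cash_karp")

#' Integration method specification
#'
#' @param family one of `"euler"`, `"rk4"`, `"adams_bashforth"`,
#'   `"backward_euler"`, `"adams_moulton"`, `"gear"`, `"rkf45"`,
#'   `"cash_karp"`.
#' @param order multistep/Gear order, 1-4 (ignored for single-step
#'   families).
#' @param atol,rtol absolute and relative local-error tolerances
#'   (adaptive families only).
#' @return a validated `method_spec` list.
#' @export
method_spec <- function(family = "rk4", order = 2L,
                        atol = 1e-8, rtol = 1e-8) {
  family <- match.arg(family, METHOD_FAMILIES)
  order <- as.integer(order)
  if (family %in% c("adams_bashforth", "adams_moulton", "gear") &&
      (order < 1L || order > 4L))
    stop_sbml("semantic", "order ", order, " unsupported for ", family,
              " (supported: 1-4)")
  structure(list(family = family, order = order, atol = atol, rtol = rtol),
            class = "method_spec")
}

step_result <- function(y, accepted = TRUE, error = NULL, h_next = NULL) {
  list(y = y, accepted = accepted, error = error, h_next = h_next)
}

check_finite_deriv <- function(dy) {
  if (!all(is.finite(dy)))
    stop_sbml("numeric", "non-finite derivative at component ",
              which(!is.finite(dy))[1])
  dy
}

#' One explicit Euler step
#'
#' `y_{n+1} = y_n + h f(t_n, y_n)`.
#'
#' @param f derivative function `f(t, y) -> dy`.
#' @param t,y current time and state.
#' @param h step size (> 0).
#' @return a step result list with the new state in `$y`.
#' @export
step_explicit_euler <- function(f, t, y, h) {
  stopifnot(h > 0)
  step_result(y + h * check_finite_deriv(f(t, y)))
}

#' One classical fourth-order Runge-Kutta step
#' @inheritParams step_explicit_euler
#' @return a step result list.
#' @export
step_rk4 <- function(f, t, y, h) {
  stopifnot(h > 0)
  k1 <- check_finite_deriv(f(t, y))
  k2 <- check_finite_deriv(f(t + h / 2, y + h / 2 * k1))
  k3 <- check_finite_deriv(f(t + h / 2, y + h / 2 * k2))
  k4 <- check_finite_deriv(f(t + h, y + h * k3))
  step_result(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' One backward (implicit) Euler step
#'
#' Solves `y_{n+1} - y_n - h f(t_{n+1}, y_{n+1}) = 0` with
#' [newton_solve()] seeded at `y_n`.
#'
#' @inheritParams step_explicit_euler
#' @param newton settings from [newton_settings()].
#' @return a step result list; `accepted = FALSE` if Newton failed to
#'   converge (caller may halve `h` and retry).
#' @export
step_backward_euler <- function(f, t, y, h, newton = newton_settings()) {
  stopifnot(h > 0)
  G <- function(z) z - y - h * f(t + h, z)
  z <- tryCatch(newton_solve(G, y, newton), sbml_numeric_error = function(e) e)
  if (inherits(z, "error")) return(step_result(y, accepted = FALSE))
  step_result(as.numeric(z))
}

# ---- adaptive embedded pairs --------------------------------------------

# Fehlberg 4(5) tableau
RKF45_TABLEAU <- list(
  c = c(0, 1/4, 3/8, 12/13, 1, 1/2),
  a = list(NULL,
           1/4,
           c(3/32, 9/32),
           c(1932/2197, -7200/2197, 7296/2197),
           c(439/216, -8, 3680/513, -845/4104),
           c(-8/27, 2, -3544/2565, 1859/4104, -11/40)),
  b_high = c(16/135, 0, 6656/12825, 28561/56430, -9/50, 2/55),
  b_low  = c(25/216, 0, 1408/2565, 2197/4104, -1/5, 0))

# Cash-Karp 4(5) tableau
CASH_KARP_TABLEAU <- list(
  c = c(0, 1/5, 3/10, 3/5, 1, 7/8),
  a = list(NULL,
           1/5,
           c(3/40, 9/40),
           c(3/10, -9/10, 6/5),
           c(-11/54, 5/2, -70/27, 35/27),
           c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)),
  b_high = c(37/378, 0, 250/621, 125/594, 0, 512/1771),
  b_low  = c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4))

#' One adaptive embedded Runge-Kutta step
#'
#' Takes a trial step with the published Fehlberg or Cash-Karp 4(5)
#' tableau. The local error is
#' `max_i |y5_i - y4_i| / (atol + rtol |y5_i|)`; the step is accepted iff
#' the error is at most 1, and the suggested next step is
#' `h * min(5, max(0.1, 0.9 * error^(-1/5)))`. The fifth-order solution
#' is the one advanced (local extrapolation).
#'
#' @inheritParams step_explicit_euler
#' @param method `"rkf45"` or `"cash_karp"`.
#' @param atol,rtol error tolerances.
#' @return a step result list with `$error` (scaled local error) and
#'   `$h_next` (suggested next step size).
#' @export
step_adaptive <- function(f, t, y, h, method = c("rkf45", "cash_karp"),
                          atol = 1e-8, rtol = 1e-8) {
  stopifnot(h > 0)
  method <- match.arg(method)
  tab <- if (method == "rkf45") RKF45_TABLEAU else CASH_KARP_TABLEAU
  k <- vector("list", 6L)
  k[[1]] <- check_finite_deriv(f(t, y))
  for (s in 2:6) {
    ys <- y
    aw <- tab$a[[s]]
    for (j in seq_along(aw)) ys <- ys + h * aw[j] * k[[j]]
    k[[s]] <- check_finite_deriv(f(t + tab$c[s] * h, ys))
  }
  y5 <- y; y4 <- y
  for (s in 1:6) {
    y5 <- y5 + h * tab$b_high[s] * k[[s]]
    y4 <- y4 + h * tab$b_low[s] * k[[s]]
  }
  scale <- atol + rtol * abs(y5)
  err <- max(abs(y5 - y4) / scale, 0)
  fac <- if (err > 0) 0.9 * err^(-1 / 5) else 5
  h_next <- h * min(5, max(0.1, fac))
  step_result(y5, accepted = err <= 1, error = err, h_next = h_next)
}

# ---- fixed-step multistep ------------------------------------------------

# Adams-Bashforth coefficients on (f_n, f_{n-1}, ...)
AB_COEF <- list(1, c(3/2, -1/2), c(23, -16, 5) / 12, c(55, -59, 37, -9) / 24)
# Adams-Moulton coefficients on (f_{n+1}, f_n, f_{n-1}, ...);
# order 1 is the implicit Euler member, order 2 the trapezoid
AM_COEF <- list(1, c(1/2, 1/2), c(5, 8, -1) / 12, c(9, 19, -5, 1) / 24)
# BDF (Gear): y_{n+1} = sum alpha_i y_{n-i} + h beta f_{n+1}
BDF_ALPHA <- list(1, c(4, -1) / 3, c(18, -9, 2) / 11, c(48, -36, 16, -3) / 25)
BDF_BETA <- c(1, 2/3, 6/11, 12/25)

#' One fixed-coefficient multistep step
#'
#' Adams-Bashforth (explicit), Adams-Moulton (implicit) or Gear/BDF
#' (implicit) at orders 1-4. `history` must hold at least the required
#' previous points at uniform spacing `h`, most recent last; each entry
#' is `list(t = , y = , f = )`. The caller is responsible for startup
#' (RK4 until the history is full) and for invalidating the history at
#' state discontinuities.
#'
#' @param f derivative function.
#' @param history list of `list(t, y, f)` records, most recent last.
#' @param h step size.
#' @param method `"adams_bashforth"`, `"adams_moulton"` or `"gear"`.
#' @param order 1-4.
#' @param newton settings for the implicit corrector solve.
#' @return a step result list.
#' @export
step_multistep <- function(f, history, h,
                           method = c("adams_bashforth", "adams_moulton",
                                      "gear"),
                           order = 2L, newton = newton_settings()) {
  stopifnot(h > 0)
  method <- match.arg(method)
  order <- as.integer(order)
  if (order < 1L || order > 4L)
    stop_sbml("semantic", "multistep order must be 1-4")
  need <- multistep_history_needed(method, order)
  if (length(history) < need)
    stop("internal error: multistep called with ", length(history),
         " history points, needs ", need)
  last <- history[[length(history)]]
  t <- last$t; y <- last$y

  if (method == "adams_bashforth") {
    co <- AB_COEF[[order]]
    acc <- 0
    for (i in seq_len(order))
      acc <- acc + co[i] * history[[length(history) - i + 1L]]$f
    return(step_result(y + h * acc))
  }

  if (method == "adams_moulton") {
    co <- AM_COEF[[order]]
    expl <- 0
    for (i in seq_len(order - 1L))
      expl <- expl + co[i + 1L] * history[[length(history) - i + 1L]]$f
    G <- function(z) z - y - h * (co[1] * f(t + h, z) + expl)
  } else {                                   # gear / BDF
    al <- BDF_ALPHA[[order]]
    past <- 0
    for (i in seq_len(order))
      past <- past + al[i] * history[[length(history) - i + 1L]]$y
    G <- function(z) z - past - h * BDF_BETA[order] * f(t + h, z)
  }
  z <- tryCatch(newton_solve(G, y, newton), sbml_numeric_error = function(e) e)
  if (inherits(z, "error")) return(step_result(y, accepted = FALSE))
  step_result(as.numeric(z))
}

# previous points required before step_multistep may be used
multistep_history_needed <- function(method, order) {
  switch(method,
         adams_bashforth = order,
         adams_moulton = max(order - 1L, 1L),
         gear = order)
}
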