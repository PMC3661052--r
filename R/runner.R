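# Simulation main loop binding all modules: step-size policy with
# clamping onto output and event-fire times, assignment closure, fast
# equilibration, algebraic solves, history recording, trigger detection
# and cascades, delayed firings, CSV output and the CLI entry point.

#' Simulation configuration
#'
#' @param duration simulated time span (> 0); output runs 0..duration.
#' @param steps number of output intervals (>= 1); the table has
#'   `steps + 1` rows at `i * duration / steps`.
#' @param method a [method_spec()], or a family name string.
#' @param refinement fixed-step methods take `refinement` internal steps
#'   per output interval (`h = duration / (steps * refinement)`).
#' @param newton Newton settings for implicit steps, algebraic rules and
#'   fast equilibration.
#' @param seed integer seed for the (rare) random tie-breaks among equal
#'   or absent event priorities; `NULL` leaves the RNG state alone.
#' @param print_targets ids to report; default: every species.
#' @param print_amounts named logical: report that species as an amount
#'   rather than a concentration. Default: amounts for species declared
#'   by `initialAmount` or with `hasOnlySubstanceUnits`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration, steps, method = "rk4", refinement = 10L,
                       newton = newton_settings(), seed = NULL,
                       print_targets = NULL, print_amounts = NULL) {
  stopifnot(duration > 0, steps >= 1)
  if (is.character(method)) method <- method_spec(method)
  structure(list(duration = duration, steps = as.integer(steps),
                 method = method, refinement = as.integer(refinement),
                 newton = newton, seed = seed,
                 print_targets = print_targets,
                 print_amounts = print_amounts),
            class = "sim_config")
}

IMPLICIT_FAMILIES <- c("backward_euler", "adams_moulton", "gear")

#' Simulate a model time course
#'
#' Integrates the model from 0 to `config$duration`, honouring the full
#' event/delay/fast/algebraic semantics, and returns the output table.
#' Internal steps are clamped to the next output time and the next
#' pending delayed-assignment fire time. After every accepted step the
#' assignment closure is applied, the fast subsystem equilibrated, the
#' algebraic constraints solved, the state recorded in the history
#' buffer, triggers checked (at accepted-step boundaries; no root
#' refinement of the crossing time) and due delayed assignments fired.
#'
#' @param model an `sbml_model` from [load_model()], or a path/XML text.
#' @param config a [sim_config()].
#' @return a data.frame of class `sbml_timecourse`: column `time` plus
#'   one column per print target.
#' @export
simulate_model <- function(model, config) {
  if (!inherits(model, "sbml_model")) model <- load_model(model)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(config$seed)
  }

  sys <- build_ode_system(model)
  fastp <- partition_fast_reactions(model)
  newton <- config$newton
  duration <- config$duration
  eps <- time_eps(duration)
  out_times <- (0:config$steps) * duration / config$steps

  buf <- history_buffer(sys$ids)
  uses_delay <- model_uses_delay(model)
  delay_for <- function(t) {
    if (uses_delay) make_delay_fn(model, buf, t) else NULL
  }
  f <- function(t, y) {
    dy <- ode_rhs(sys, t, stats::setNames(y, sys$ids), delay_for(t))
    if (!all(is.finite(dy)))
      stop_sbml("numeric", "numeric blow-up: derivative of '",
                sys$ids[which(!is.finite(dy))[1]], "' is non-finite at t = ",
                format(t))
    as.numeric(dy)
  }

  # ---- t = 0 -------------------------------------------------------------
  state <- resolve_initial_state(model)
  state <- apply_assignment_closure(sys, state, 0, delay_for(0))
  state <- solve_algebraic(sys, state, 0, newton)
  state <- equilibrate_fast(sys, fastp, state, 0, newton)
  history_append(buf, 0, state)

  memory <- trigger_memory_init(model)
  pending <- list()
  ev0 <- process_events(model, sys, state, 0, memory, pending,
                        delay_for(0), newton)
  state <- ev0$state; memory <- ev0$memory; pending <- ev0$pending
  if (ev0$changed) history_append(buf, 0, state)
  check_constraints(model, state, 0)

  targets <- config$print_targets %||% names(model$species)
  as_amount <- print_amount_flags(model, targets, config$print_amounts)
  tc <- matrix(NA_real_, length(out_times), length(targets),
               dimnames = list(NULL, targets))
  tc[1, ] <- report_values(model, state, targets, as_amount)

  # ---- stepping ----------------------------------------------------------
  family <- config$method$family
  order <- config$method$order
  h_fixed <- duration / (config$steps * config$refinement)
  h_adapt <- duration / config$steps / 10
  mshist <- list(list(t = 0, y = as.numeric(state),
                      f = tryCatch(f(0, as.numeric(state)),
                                   error = function(e) NULL)))
  if (is.null(mshist[[1]]$f)) mshist <- list()

  t <- 0
  for (row in seq_along(out_times)[-1]) {
    t_out <- out_times[row]
    while (t < t_out - eps) {
      h_clamp <- t_out - t
      nf <- next_fire_time(pending)
      if (!is.null(nf) && nf > t + eps) h_clamp <- min(h_clamp, nf - t)

      if (family %in% c("rkf45", "cash_karp")) {
        h <- min(h_adapt, h_clamp)
        repeat {
          res <- step_adaptive(f, t, as.numeric(state), h, family,
                               config$method$atol, config$method$rtol)
          if (res$accepted) { h_adapt <- res$h_next; break }
          h <- res$h_next
          if (h < duration * 1e-12)
            stop_sbml("numeric", "adaptive step size underflow at t = ",
                      format(t), "; the system appears stiff - use an ",
                      "implicit method")
        }
      } else {
        h <- min(h_fixed, h_clamp)
        res <- take_fixed_step(f, t, state, h, family, order, mshist, newton,
                               duration)
        h <- res$h_used
      }

      t <- t + h
      if (abs(t - t_out) <= eps) t <- t_out
      if (!is.null(nf) && abs(t - nf) <= eps) t <- nf
      y <- res$y
      if (!all(is.finite(y)))
        stop_sbml("numeric", "numeric blow-up: variable '",
                  sys$ids[which(!is.finite(y))[1]], "' at t = ", format(t))
      state[] <- y
      state <- apply_assignment_closure(sys, state, t, delay_for(t))
      pre_fast <- state
      state <- equilibrate_fast(sys, fastp, state, t, newton)
      fast_jump <- !fastp$empty &&
        max(abs(state - pre_fast)) > 1e-9 * max(1, max(abs(state)))
      state <- solve_algebraic(sys, state, t, newton)
      history_append(buf, t, state)

      evs <- process_events(model, sys, state, t, memory, pending,
                            delay_for(t), newton)
      state <- evs$state; memory <- evs$memory; pending <- evs$pending
      if (evs$changed) history_append(buf, t, state)
      check_constraints(model, state, t)

      if (evs$changed || fast_jump) {
        mshist <- list()            # discontinuity: restart multistep
      }
      if (!family %in% c("rkf45", "cash_karp")) {
        fdot <- f(t, as.numeric(state))
        if (length(mshist) && abs(mshist[[length(mshist)]]$t + h - t) > eps)
          mshist <- list()          # non-uniform spacing: restart
        mshist <- c(mshist, list(list(t = t, y = as.numeric(state),
                                      f = fdot)))
        if (length(mshist) > 5L) mshist <- mshist[-1]
      }
    }
    tc[row, ] <- report_values(model, state, targets, as_amount)
  }

  out <- data.frame(time = out_times, tc, check.names = FALSE)
  class(out) <- c("sbml_timecourse", "data.frame")
  out
}

# one fixed-step advance; handles implicit retries (up to 10 halvings)
# and multistep order ramp-up from the history actually available
take_fixed_step <- function(f, t, state, h, family, order, mshist, newton,
                            duration) {
  y <- as.numeric(state)
  if (family == "euler")
    return(list(y = step_explicit_euler(f, t, y, h)$y, h_used = h))
  if (family == "rk4")
    return(list(y = step_rk4(f, t, y, h)$y, h_used = h))
  if (family == "backward_euler")
    return(implicit_with_halving(function(hh)
      step_backward_euler(f, t, y, hh, newton), h, t))
  # multistep families: effective order limited by the usable history
  # (points at uniform spacing h ending at the current state)
  len <- length(mshist)
  if (len >= 2L) {
    spacing <- mshist[[len]]$t - mshist[[len - 1L]]$t
    if (abs(spacing - h) > 1e-9 * max(h, 1)) len <- 1L
  }
  eff <- switch(family,
                adams_bashforth = min(order, max(len, 1L)),
                adams_moulton = min(order, len + 1L),
                gear = min(order, max(len, 1L)))
  if (len == 0L) {  # no usable history (should not happen): implicit Euler
    return(implicit_with_halving(function(hh)
      step_backward_euler(f, t, y, hh, newton), h, t))
  }
  hist_use <- mshist[(length(mshist) - min(len, 4L) + 1L):length(mshist)]
  res <- step_multistep(f, hist_use, h, family, eff, newton)
  if (res$accepted) return(list(y = res$y, h_used = h))
  implicit_with_halving(function(hh)
    step_backward_euler(f, t, y, hh, newton), h, t)
}

implicit_with_halving <- function(stepper, h, t) {
  for (i in 0:10) {
    res <- stepper(h)
    if (res$accepted) return(list(y = res$y, h_used = h))
    h <- h / 2
  }
  stop_sbml("numeric", "implicit step failed after 10 halvings at t = ",
            format(t))
}

# detect triggers, run cascades, fire due delayed assignments; loop
# until the state settles at this time point
process_events <- function(model, sys, state, t, memory, pending,
                           delay_fn, newton) {
  changed <- FALSE
  if (!length(model$events))
    return(list(state = state, memory = memory, pending = pending,
                changed = FALSE))
  for (round in 1:100) {
    round_changed <- FALSE
    det <- detect_triggers(model, state, t, memory, delay_fn)
    memory <- det$memory
    if (length(det$fired)) {
      cas <- run_event_cascade(model, det$fired, state, t, memory, delay_fn)
      if (length(cas$executed)) round_changed <- TRUE
      state <- cas$state; memory <- cas$memory
      pending <- c(pending, cas$pending_new)
    }
    pending <- prune_pending(model, pending, state, t, delay_fn)
    due <- fire_due_assignments(model, pending, state, t)
    state <- due$state; pending <- due$pending
    if (due$fired_any) round_changed <- TRUE
    if (!round_changed) break
    # event assignments must leave assignment rules satisfied
    state <- apply_assignment_closure(sys, state, t, delay_fn)
    state <- solve_algebraic(sys, state, t, newton)
    changed <- TRUE
  }
  list(state = state, memory = memory, pending = pending, changed = changed)
}

# persistence between trigger and execution: a non-persistent event's
# pending delayed assignment is cancelled when its trigger lapses
prune_pending <- function(model, pending, state, t, delay_fn = NULL) {
  if (!length(pending)) return(pending)
  keep <- vapply(pending, function(p) {
    ev <- model$events[[p$event_id]]
    ev$persistent || eval_trigger(model, ev, state, t, delay_fn)
  }, NA)
  pending[keep]
}

next_fire_time <- function(pending) {
  if (!length(pending)) return(NULL)
  min(vapply(pending, `[[`, 0, "fire_time"))
}

model_uses_delay <- function(model) {
  progs <- c(lapply(model$reactions, `[[`, "kinetic_prog"),
             lapply(model$assignment_rules, `[[`, "prog"),
             lapply(model$rate_rules, `[[`, "prog"),
             lapply(model$algebraic_rules, `[[`, "prog"),
             lapply(model$events, `[[`, "trigger_prog"))
  any(vapply(progs, `[[`, NA, "uses_delay"))
}

check_constraints <- function(model, state, t) {
  for (i in seq_along(model$constraints)) {
    ok <- rpn_eval(model$constraints[[i]]$prog,
                   eval_context(time = t,
                                values = state_values(model, state)))
    if (ok == 0)
      sbml_log("constraint ", i, " violated at t = ", format(t),
               level = "warn")
  }
  invisible(NULL)
}

print_amount_flags <- function(model, targets, overrides) {
  flags <- vapply(targets, function(id) {
    sp <- model$species[[id]]
    if (is.null(sp)) TRUE                 # parameters/compartments: as-is
    else sp$initial_is_amount || sp$has_only_substance_units
  }, NA)
  names(flags) <- targets
  if (!is.null(overrides)) flags[names(overrides)] <- overrides
  flags
}

report_values <- function(model, state, targets, as_amount) {
  vapply(targets, function(id) {
    sp <- model$species[[id]]
    if (!is.null(sp) && !as_amount[[id]])
      state[[id]] / state[[sp$compartment]]
    else state[[id]]
  }, 0)
}

# ---- CSV I/O -------------------------------------------------------------

#' Write a time course as SBML-test-suite CSV
#'
#' Header `time,<id1>,...`, one row per output time, full double
#' precision (values survive a read round-trip bit for bit), comma
#' separator, `.` decimal mark, LF line endings.
#'
#' @param tc an `sbml_timecourse` (or any data.frame with a time column).
#' @param path output file path.
#' @export
write_timecourse_csv <- function(tc, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_sbml("parse",
                    "cannot open '", path, "' for writing"))
  on.exit(close(con))
  writeLines(paste(names(tc), collapse = ","), con, sep = "\n")
  for (i in seq_len(nrow(tc))) {
    row <- vapply(tc[i, ], function(v) sprintf("%.17g", as.numeric(v)), "")
    writeLines(paste(row, collapse = ","), con, sep = "\n")
  }
  invisible(path)
}

#' Read a time-course CSV written by [write_timecourse_csv()]
#' @param path file path.
#' @return a data.frame of class `sbml_timecourse`.
#' @export
read_timecourse_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  class(out) <- c("sbml_timecourse", "data.frame")
  out
}

# ---- CLI -----------------------------------------------------------------

CLI_USAGE <- paste(
  "usage: sbmlsim MODEL.xml --duration T --steps N",
  "  [--method euler|rk4|adams-bashforth|backward-euler|adams-moulton|",
  "            gear|rkf45|cash-karp] [--order K] [--atol A] [--rtol R]",
  "  [--refinement M] [--seed S] [--out FILE.csv] [-v]",
  sep = "\n")

#' Command-line entry point
#'
#' Parses arguments, simulates and writes CSV. Exit codes: 0 success,
#' 1 model/file error, 2 numeric failure, 64 usage error. Diagnostics go
#' to standard error.
#'
#' @param argv character vector of arguments (default: the process's).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- tryCatch(parse_cli_args(argv), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    message(CLI_USAGE)
    return(invisible(64L))
  }
  if (opts$verbose) options(sbmlsim.verbose = TRUE)
  code <- tryCatch({
    if (!file.exists(opts$model))
      stop_sbml("parse", "model file not found: ", opts$model)
    model <- load_model(opts$model)
    method <- method_spec(opts$method, order = opts$order,
                          atol = opts$atol, rtol = opts$rtol)
    config <- sim_config(opts$duration, opts$steps, method,
                         refinement = opts$refinement, seed = opts$seed)
    tc <- simulate_model(model, config)
    write_timecourse_csv(tc, opts$out)
    sbml_log("wrote ", opts$out)
    0L
  },
  sbml_numeric_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  sbml_error = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}

parse_cli_args <- function(argv) {
  opts <- list(model = NULL, duration = NULL, steps = NULL, method = "rk4",
               order = 2L, atol = 1e-8, rtol = 1e-8, refinement = 10L,
               seed = NULL, out = NULL, verbose = FALSE)
  i <- 1L
  need <- function(flag) {
    if (i + 1L > length(argv)) stop("missing value for ", flag, call. = FALSE)
    i <<- i + 1L
    argv[i]
  }
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--duration") opts$duration <- as.numeric(need(a))
    else if (a == "--steps") opts$steps <- as.integer(need(a))
    else if (a == "--method") opts$method <- gsub("-", "_", need(a))
    else if (a == "--order") opts$order <- as.integer(need(a))
    else if (a == "--atol") opts$atol <- as.numeric(need(a))
    else if (a == "--rtol") opts$rtol <- as.numeric(need(a))
    else if (a == "--refinement") opts$refinement <- as.integer(need(a))
    else if (a == "--seed") opts$seed <- as.integer(need(a))
    else if (a == "--out") opts$out <- need(a)
    else if (a == "-v" || a == "--verbose") opts$verbose <- TRUE
    else if (startsWith(a, "-")) stop("unknown flag ", a, call. = FALSE)
    else if (is.null(opts$model)) opts$model <- a
    else stop("unexpected argument ", a, call. = FALSE)
    i <- i + 1L
  }
  if (is.null(opts$model)) stop("no model file given", call. = FALSE)
  if (is.null(opts$duration) || is.na(opts$duration) || opts$duration <= 0)
    stop("--duration must be a positive number", call. = FALSE)
  if (is.null(opts$steps) || is.na(opts$steps) || opts$steps < 1)
    stop("--steps must be a positive integer", call. = FALSE)
  if (!opts$method %in% METHOD_FAMILIES)
    stop("unknown method ", opts$method, call. = FALSE)
  if (opts$method %in% c("adams_bashforth", "adams_moulton", "gear") &&
      (is.na(opts$order) || opts$order < 1L || opts$order > 4L))
    stop("--order must be 1-4 for ", opts$method, call. = FALSE)
  if (is.null(opts$out))
    opts$out <- paste0(tools::file_path_sans_ext(basename(opts$model)), ".csv")
  opts
}
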