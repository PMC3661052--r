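# SBML event semantics: false->true trigger edge detection, the
# six-step priority cascade, persistence re-checking, delayed
# assignments with optional value capture, and the history buffer that
# serves delay-expression lookups.

# ---- history buffer ------------------------------------------------------

#' Create a history buffer
#'
#' Time-indexed record of the full state vector, appended at every
#' accepted step; retained for the whole run so delay expressions can
#' look arbitrarily far back.
#'
#' @param ids state variable names.
#' @return an environment of class `history_buffer`.
#' @export
history_buffer <- function(ids) {
  buf <- new.env(parent = emptyenv())
  buf$ids <- ids
  buf$times <- numeric(64)
  buf$values <- matrix(NA_real_, 64, length(ids),
                       dimnames = list(NULL, ids))
  buf$n <- 0L
  class(buf) <- "history_buffer"
  buf
}

#' Append (or overwrite) a sample
#'
#' Times must be non-decreasing; appending at exactly the last recorded
#' time replaces that sample (the post-event state at a discontinuity).
#'
#' @param buf a [history_buffer()].
#' @param t sample time.
#' @param state named state vector.
#' @export
history_append <- function(buf, t, state) {
  n <- buf$n
  if (n > 0L) {
    last <- buf$times[n]
    if (t < last)
      stop_sbml("semantic", "history times must be non-decreasing")
    if (t == last) {
      buf$values[n, ] <- state[buf$ids]
      return(invisible(buf))
    }
  }
  if (n + 1L > length(buf$times)) {         # grow by doubling
    buf$times <- c(buf$times, numeric(length(buf$times)))
    buf$values <- rbind(buf$values,
                        matrix(NA_real_, nrow(buf$values), ncol(buf$values)))
  }
  buf$n <- n + 1L
  buf$times[n + 1L] <- t
  buf$values[n + 1L, ] <- state[buf$ids]
  invisible(buf)
}

# full historical state at t_query (linear interpolation; clamped to the
# first sample for t_query < 0 and to the last beyond the end)
history_state_at <- function(buf, t_query) {
  n <- buf$n
  if (n == 0L) stop_sbml("semantic", "history buffer is empty")
  times <- buf$times[seq_len(n)]
  if (t_query <= times[1]) return(stats::setNames(buf$values[1, ], buf$ids))
  if (t_query >= times[n]) return(stats::setNames(buf$values[n, ], buf$ids))
  i <- findInterval(t_query, times)
  w <- (t_query - times[i]) / (times[i + 1L] - times[i])
  stats::setNames((1 - w) * buf$values[i, ] + w * buf$values[i + 1L, ],
                  buf$ids)
}

#' Look up one variable in the history buffer
#'
#' Linear interpolation between the bracketing samples; queries before
#' t = 0 return the initial value, queries beyond the last sample return
#' the last value (only reachable transiently inside a step).
#'
#' @param buf a [history_buffer()].
#' @param variable state variable name.
#' @param t_query query time.
#' @return the interpolated value.
#' @export
history_lookup <- function(buf, variable, t_query) {
  if (!variable %in% buf$ids)
    stop_sbml("semantic", "unknown variable '", variable, "' in history")
  history_state_at(buf, t_query)[[variable]]
}

# delay_fn closure for one evaluation time: evaluates the delayed
# sub-expression in the historical context at t - lag
make_delay_fn <- function(model, buf, t) {
  force(t)
  function(sub_program, lag) {
    if (lag < 0)
      stop_sbml("semantic", "negative delay lag ", lag)
    tq <- t - lag
    st <- history_state_at(buf, tq)
    rpn_eval(sub_program,
             eval_context(time = max(tq, 0),
                          values = state_values(model, st)))
  }
}

# ---- triggers ------------------------------------------------------------

eval_trigger <- function(model, ev, state, t, delay_fn = NULL) {
  v <- rpn_eval(ev$trigger_prog,
                eval_context(time = t, values = state_values(model, state),
                             delay_fn = delay_fn))
  if (is.na(v)) stop_sbml("semantic", "trigger of event '", ev$id,
                          "' is not boolean-valued")
  v != 0
}

#' Initialize trigger memory
#'
#' Level 2 triggers count as true at t = 0 (no initial firing); Level 3
#' uses the trigger's `initialValue` attribute.
#'
#' @param model an `sbml_model`.
#' @return named logical vector of previous trigger values.
#' @export
trigger_memory_init <- function(model) {
  vapply(model$events, function(ev) isTRUE(ev$initial_trigger_value), NA)
}

#' Detect false-to-true trigger edges
#'
#' @param model an `sbml_model`.
#' @param state current state.
#' @param t current time.
#' @param memory previous trigger values from [trigger_memory_init()].
#' @param delay_fn optional delay lookup for triggers using delay().
#' @return `list(fired = <event ids>, memory = <updated memory>)`;
#'   memory is updated for every event, fired holds those whose trigger
#'   is true now and was false at the last check.
#' @export
detect_triggers <- function(model, state, t, memory, delay_fn = NULL) {
  fired <- character(0)
  for (ev in model$events) {
    now <- eval_trigger(model, ev, state, t, delay_fn)
    if (now && !memory[[ev$id]]) fired <- c(fired, ev$id)
    memory[[ev$id]] <- now
  }
  list(fired = fired, memory = memory)
}

# ---- delayed assignments -------------------------------------------------

#' Schedule the delayed assignments of a triggered event
#'
#' The fire time is the trigger time plus the delay expression evaluated
#' at trigger time. With `useValuesFromTriggerTime` the assignment
#' right-hand sides are evaluated now and frozen.
#'
#' @param model an `sbml_model`.
#' @param event_id the triggered event's id.
#' @param t_trigger trigger time.
#' @param state state at trigger time.
#' @param delay_fn optional delay lookup.
#' @return a pending-assignment record.
#' @export
schedule_delayed <- function(model, event_id, t_trigger, state,
                             delay_fn = NULL) {
  ev <- model$events[[event_id]]
  vals <- state_values(model, state)
  dly <- rpn_eval(ev$delay$prog,
                  eval_context(time = t_trigger, values = vals,
                               delay_fn = delay_fn))
  if (is.na(dly) || dly < 0)
    stop_sbml("semantic", "event '", event_id, "' evaluated a negative ",
              "delay (", dly, ")")
  captured <- NULL
  if (ev$use_values_from_trigger_time) {
    captured <- vapply(ev$assignments, function(a)
      rpn_eval(a$prog, eval_context(time = t_trigger, values = vals,
                                    delay_fn = delay_fn)), 0)
    names(captured) <- vapply(ev$assignments, `[[`, "", "target")
  }
  list(event_id = event_id, fire_time = t_trigger + dly,
       captured = captured)
}

# execute one event's assignments: all right-hand sides evaluated in the
# entry state before any target is written (simultaneous semantics)
execute_assignments <- function(model, ev, state, t, captured = NULL,
                                delay_fn = NULL) {
  vals <- state_values(model, state)
  rhs <- if (!is.null(captured)) captured else {
    v <- vapply(ev$assignments, function(a)
      rpn_eval(a$prog, eval_context(time = t, values = vals,
                                    delay_fn = delay_fn)), 0)
    names(v) <- vapply(ev$assignments, `[[`, "", "target")
    v
  }
  for (target in names(rhs))
    state[[target]] <- assigned_to_internal(model, state, target, rhs[[target]])
  state
}

#' Apply all pending delayed assignments that are due
#'
#' Assignments with fire time at or before `t` are applied in fire-time
#' order (ties broken by priority evaluated in the current state, then
#' randomly). A pending record whose originating event is
#' non-persistent is cancelled beforehand, at trigger lapse, by the
#' runner — records present here always fire.
#'
#' @param model an `sbml_model`.
#' @param pending list of records from [schedule_delayed()].
#' @param state current state.
#' @param t current time.
#' @return `list(state = , pending = <still-pending records>, fired_any = )`.
#' @export
fire_due_assignments <- function(model, pending, state, t) {
  fired_any <- FALSE
  repeat {
    if (!length(pending)) break
    due <- which(vapply(pending, function(p) p$fire_time <= t, NA))
    if (!length(due)) break
    ft <- vapply(pending[due], `[[`, 0, "fire_time")
    due <- due[ft == min(ft)]
    if (length(due) > 1L) {
      pr <- vapply(due, function(i)
        event_priority(model, pending[[i]]$event_id, state, t), 0)
      due <- pick_max_priority(due, pr)
    } else due <- due[1]
    p <- pending[[due]]
    state <- execute_assignments(model, model$events[[p$event_id]], state,
                                 t, captured = p$captured)
    pending[[due]] <- NULL
    fired_any <- TRUE
  }
  list(state = state, pending = pending, fired_any = fired_any)
}

# ---- the cascade ---------------------------------------------------------

# numeric priority, or -Inf for an absent Priority element (absent ranks
# below any numeric priority; ties are broken randomly by the caller)
event_priority <- function(model, event_id, state, t) {
  ev <- model$events[[event_id]]
  if (is.null(ev$priority)) return(-Inf)
  rpn_eval(ev$priority$prog,
           eval_context(time = t, values = state_values(model, state)))
}

# indices tied at maximum priority -> one winner, random among ties
pick_max_priority <- function(idx, priorities) {
  top <- idx[priorities == max(priorities)]
  if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
}

#' Run the event cascade
#'
#' Implements the queue procedure for simultaneously triggered events:
#' (i) enqueue the fired events; (ii) evaluate every queued event's
#' priority in the current state; (iii) execute the maximum-priority
#' event's assignments (all right-hand sides read the state at the start
#' of that event's execution); (iv) drop queued non-persistent events
#' whose triggers have gone false; (v) enqueue any event whose trigger
#' flipped false-to-true under the assignment (scheduling it instead if
#' it has a delay); (vi) repeat while the queue is nonempty. Events with
#' a Delay element are never executed in-cascade: they are scheduled.
#'
#' @param model an `sbml_model`.
#' @param fired event ids whose triggers just edged false-to-true.
#' @param state current state.
#' @param t current time.
#' @param memory trigger memory (already updated for the edge).
#' @param delay_fn optional delay lookup.
#' @return `list(state, memory, pending_new, executed)` where `executed`
#'   is the execution log (event ids in order) and `pending_new` the
#'   delayed assignments scheduled during the cascade.
#' @export
run_event_cascade <- function(model, fired, state, t, memory,
                              delay_fn = NULL) {
  queue <- character(0)
  pending_new <- list()
  executed <- character(0)

  admit <- function(ids) {
    for (id in ids) {
      ev <- model$events[[id]]
      if (!is.null(ev$delay)) {
        pending_new[[length(pending_new) + 1L]] <<-
          schedule_delayed(model, id, t, state, delay_fn)
      } else if (!id %in% queue) {
        queue <<- c(queue, id)
      }
    }
  }
  admit(fired)

  guard <- 0L
  while (length(queue)) {
    guard <- guard + 1L
    if (guard > 10000L)
      stop_sbml("semantic", "event cascade exceeded 10000 executions ",
                "(livelock)")
    pr <- vapply(queue, function(id) event_priority(model, id, state, t), 0)
    win <- pick_max_priority(seq_along(queue), pr)
    id <- queue[win]
    queue <- queue[-win]
    state <- execute_assignments(model, model$events[[id]], state, t,
                                 delay_fn = delay_fn)
    executed <- c(executed, id)

    # (iv) + (v): re-examine every trigger against memory
    newly <- character(0)
    for (ev in model$events) {
      now <- eval_trigger(model, ev, state, t, delay_fn)
      was <- memory[[ev$id]]
      if (!now && was && !ev$persistent && ev$id %in% queue)
        queue <- setdiff(queue, ev$id)
      if (now && !was) newly <- c(newly, ev$id)
      memory[[ev$id]] <- now
    }
    admit(newly)
  }
  list(state = state, memory = memory, pending_new = pending_new,
       executed = executed)
}
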