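# Assembles the time-derivative function, the algebraic-constraint
# system and the dependency-ordered assignment closure from reactions,
# stoichiometry and rules; partitions `fast` reactions and equilibrates
# their quasi-steady state after each accepted step.

#' Build the ODE/DAE system of a compiled model
#'
#' For each non-boundary, non-constant species that is not determined by
#' an assignment rule, the amount derivative is the stoichiometry-
#' weighted sum of kinetic-law rates (kinetic laws are extensive,
#' amount/time). Rate-ruled variables take their rule as derivative (a
#' concentration-based species' rule is scaled by its compartment size).
#' Each AlgebraicRule contributes one constraint; its solved-for
#' variable is the unique referenced variable not otherwise determined
#' (leftmost in state order if ambiguous, logged).
#'
#' @param model an `sbml_model` from [load_model()].
#' @return an object of class `sbml_ode_system`.
#' @export
build_ode_system <- function(model) {
  ids <- names(model$variable_index)
  n <- length(ids)
  ar_targets <- vapply(model$assignment_rules, `[[`, "", "target")
  rr_targets <- vapply(model$rate_rules, `[[`, "", "target")

  determined <- stats::setNames(rep("free", n), ids)
  for (id in ids) if (is_constant_id(model, id)) determined[[id]] <- "constant"
  determined[ar_targets] <- "assignment"
  conflict <- intersect(rr_targets, ar_targets)
  if (length(conflict))
    stop_sbml("semantic", "variable '", conflict[1], "' determined twice")
  determined[rr_targets] <- "rate_rule"

  # stoichiometry matrix in amount units; rows zeroed for variables
  # reactions may not determine
  stoich <- matrix(0, n, length(model$reactions),
                   dimnames = list(ids, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (ref in r$reactants)
      stoich[ref$species, j] <- stoich[ref$species, j] - ref$stoichiometry
    for (ref in r$products)
      stoich[ref$species, j] <- stoich[ref$species, j] + ref$stoichiometry
  }
  for (sp in model$species) {
    if (sp$boundary_condition || sp$constant ||
        determined[[sp$id]] %in% c("assignment", "rate_rule"))
      stoich[sp$id, ] <- 0
    else if (any(stoich[sp$id, ] != 0))
      determined[[sp$id]] <- "reactions"
  }

  # algebraic-variable selection, one per AlgebraicRule
  algebraic_ids <- character(0)
  for (ru in model$algebraic_rules) {
    cand <- intersect(ru$prog$referenced_ids, ids[determined == "free"])
    cand <- setdiff(cand, algebraic_ids)
    if (!length(cand))
      stop_sbml("semantic", "over-determined model: no free variable for ",
                "an algebraicRule")
    cand <- cand[order(model$variable_index[cand])]
    if (length(cand) > 1L)
      sbml_log("algebraicRule matches several free variables (",
               paste(cand, collapse = ", "), "); using '", cand[1], "'")
    algebraic_ids <- c(algebraic_ids, cand[1])
  }
  determined[algebraic_ids] <- "algebraic"

  closure <- lapply(model$assignment_rules, function(ru)
    list(target = ru$target, prog = ru$prog))
  closure <- order_closure(closure)

  rate_rules <- lapply(model$rate_rules, function(ru) {
    sp <- model$species[[ru$target]]
    list(target = ru$target, prog = ru$prog,
         scale_by = if (!is.null(sp) && !sp$has_only_substance_units)
           sp$compartment else NULL)
  })

  structure(list(
    model = model, ids = ids, n = n,
    stoich = stoich,
    reaction_progs = lapply(model$reactions, `[[`, "kinetic_prog"),
    rate_rules = rate_rules,
    closure = closure,
    algebraic_progs = lapply(model$algebraic_rules, `[[`, "prog"),
    algebraic_ids = algebraic_ids,
    determined = determined,
    n_differential = sum(determined %in% c("reactions", "rate_rule"))),
    class = "sbml_ode_system")
}

# dependency-order the assignment closure (target of one rule referenced
# by another must be computed first)
order_closure <- function(closure) {
  if (!length(closure)) return(closure)
  targets <- vapply(closure, `[[`, "", "target")
  deps <- lapply(closure, function(cl)
    intersect(cl$prog$referenced_ids, targets))
  closure[topological_order(targets, deps)]
}

#' @export
print.sbml_ode_system <- function(x, ...) {
  cat("<sbml_ode_system> ", x$n_differential, " differential, ",
      length(x$algebraic_ids), " algebraic, ",
      length(x$closure), " assigned of ", x$n, " variables\n", sep = "")
  invisible(x)
}

#' Apply the assignment-rule closure
#'
#' Recomputes every assignment-rule target from the current state, in
#' dependency order; called before each derivative evaluation and before
#' output. Species targets are assigned in concentration units (unless
#' `hasOnlySubstanceUnits`) and converted to internal amounts.
#'
#' @param system an `sbml_ode_system`.
#' @param state named state vector (internal amounts).
#' @param t current time.
#' @param delay_fn optional delay lookup passed through to evaluation.
#' @return the updated state vector.
#' @export
apply_assignment_closure <- function(system, state, t, delay_fn = NULL) {
  for (cl in system$closure) {
    ctx <- eval_context(time = t, values = state_values(system$model, state),
                        delay_fn = delay_fn)
    v <- rpn_eval(cl$prog, ctx)
    state[[cl$target]] <- assigned_to_internal(system$model, state,
                                               cl$target, v)
  }
  state
}

# all reaction rates at the given (closure-applied) state; evaluated in
# document order, earlier rates visible to later kinetic laws by id
reaction_rates <- function(system, state, t, delay_fn = NULL) {
  vals <- state_values(system$model, state)
  rates <- numeric(length(system$reaction_progs))
  names(rates) <- names(system$reaction_progs)
  for (j in seq_along(rates)) {
    ctx <- eval_context(time = t, values = c(vals, rates[seq_len(j - 1L)]),
                        delay_fn = delay_fn)
    rates[j] <- rpn_eval(system$reaction_progs[[j]], ctx)
  }
  rates
}

#' Evaluate the amount-space time derivative
#'
#' Applies the assignment closure, evaluates every kinetic law and
#' returns `d(state)/dt`: stoichiometric sums for reaction-determined
#' species, rule values for rate-ruled variables, zero for constants,
#' boundary species without rules, assigned and algebraic variables.
#'
#' @inheritParams apply_assignment_closure
#' @return named derivative vector.
#' @export
ode_rhs <- function(system, t, state, delay_fn = NULL) {
  state <- apply_assignment_closure(system, state, t, delay_fn)
  dy <- stats::setNames(numeric(system$n), system$ids)
  if (length(system$reaction_progs)) {
    rates <- reaction_rates(system, state, t, delay_fn)
    dy <- dy + as.numeric(system$stoich %*% rates)
    names(dy) <- system$ids
  }
  if (length(system$rate_rules)) {
    vals <- state_values(system$model, state)
    for (rr in system$rate_rules) {
      v <- rpn_eval(rr$prog, eval_context(time = t, values = vals,
                                          delay_fn = delay_fn))
      if (!is.null(rr$scale_by)) v <- v * state[[rr$scale_by]]
      dy[[rr$target]] <- v
    }
  }
  dy
}

#' Solve the algebraic constraints at the current state
#'
#' Newton-solves the square system formed by the AlgebraicRule
#' expressions over the algebraic variables, seeded at their current
#' values; called at t = 0 and after every accepted step.
#'
#' @inheritParams apply_assignment_closure
#' @param newton settings from [newton_settings()].
#' @return the state with algebraic variables replaced by the root.
#' @export
solve_algebraic <- function(system, state, t, newton = newton_settings()) {
  if (!length(system$algebraic_ids)) return(state)
  alg <- system$algebraic_ids
  G <- function(z) {
    st <- state
    st[alg] <- z
    st <- apply_assignment_closure(system, st, t)
    vals <- state_values(system$model, st)
    vapply(system$algebraic_progs, function(p)
      rpn_eval(p, eval_context(time = t, values = vals)), 0)
  }
  root <- newton_solve(G, state[alg], newton)
  state[alg] <- as.numeric(root)
  state
}

# ---- fast reactions ------------------------------------------------------

#' Partition `fast` reactions and derive their conservation relations
#'
#' Fast variables are the dynamic (non-boundary, non-constant) species
#' touched by fast reactions; slow reactions may also touch them, in
#' which case the quasi-equilibrium is re-imposed after each slow step
#' while the conserved totals drift with the slow fluxes. The
#' quasi-steady-state system couples the independent fast reaction rates
#' (set to zero) with the conserved totals spanned by the left null
#' space of the fast stoichiometry submatrix, giving a square system for
#' [equilibrate_fast()].
#'
#' @param model an `sbml_model`.
#' @return an object of class `fast_partition`; `$empty` is `TRUE` when
#'   the model has no fast reactions.
#' @export
partition_fast_reactions <- function(model) {
  fast_rxn <- names(model$reactions)[vapply(model$reactions, `[[`, NA, "fast")]
  if (!length(fast_rxn))
    return(structure(list(empty = TRUE), class = "fast_partition"))

  touched_by <- function(r) unique(c(
    vapply(r$reactants, `[[`, "", "species"),
    vapply(r$products, `[[`, "", "species")))
  fast_touch <- unique(unlist(lapply(model$reactions[fast_rxn], touched_by)))
  dynamic <- vapply(fast_touch, function(id) {
    sp <- model$species[[id]]
    !sp$boundary_condition && !sp$constant
  }, NA)
  fast_ids <- fast_touch[dynamic]
  if (!length(fast_ids))
    stop_sbml("semantic", "fast reactions present but affect no ",
              "dynamic species")

  N <- matrix(0, length(fast_ids), length(fast_rxn),
              dimnames = list(fast_ids, fast_rxn))
  for (j in seq_along(fast_rxn)) {
    r <- model$reactions[[fast_rxn[j]]]
    for (ref in r$reactants)
      if (ref$species %in% fast_ids)
        N[ref$species, j] <- N[ref$species, j] - ref$stoichiometry
    for (ref in r$products)
      if (ref$species %in% fast_ids)
        N[ref$species, j] <- N[ref$species, j] + ref$stoichiometry
  }
  qrN <- qr(N)
  r <- qrN$rank
  indep_rxn <- fast_rxn[sort(qrN$pivot[seq_len(r)])]
  # conserved totals: left null space of N
  sv <- svd(N, nu = nrow(N))
  L <- if (r < nrow(N)) t(sv$u[, (r + 1L):nrow(N), drop = FALSE])
       else matrix(0, 0, nrow(N))
  if (length(indep_rxn) + nrow(L) != length(fast_ids))
    stop_sbml("semantic", "fast subsystem is not square (",
              length(indep_rxn), " independent rates + ", nrow(L),
              " conservation relations for ", length(fast_ids),
              " species)")
  structure(list(empty = FALSE, fast_reactions = fast_rxn,
                 independent_reactions = indep_rxn,
                 fast_ids = fast_ids, stoich = N, conservation = L),
            class = "fast_partition")
}

#' Equilibrate the fast subsystem
#'
#' Replaces the fast species amounts by the root of the quasi-steady-
#' state system (independent fast rates zero, conserved totals fixed at
#' their current values); applied after every accepted integration step.
#'
#' @param system an `sbml_ode_system`.
#' @param partition a `fast_partition`.
#' @param state named state vector.
#' @param t current time.
#' @param newton settings from [newton_settings()].
#' @return the equilibrated state.
#' @export
equilibrate_fast <- function(system, partition, state, t,
                             newton = newton_settings()) {
  if (partition$empty) return(state)
  ids <- partition$fast_ids
  L <- partition$conservation
  totals <- as.numeric(L %*% state[ids])
  G <- function(z) {
    st <- state
    st[ids] <- z
    st <- apply_assignment_closure(system, st, t)
    vals <- state_values(system$model, st)
    rates <- vapply(partition$independent_reactions, function(rid)
      rpn_eval(system$reaction_progs[[rid]],
               eval_context(time = t, values = vals)), 0)
    c(rates, as.numeric(L %*% z) - totals)
  }
  root <- tryCatch(newton_solve(G, state[ids], newton),
                   sbml_numeric_error = function(e)
                     stop_sbml("numeric", "fast-reaction equilibration ",
                               "failed: ", conditionMessage(e)))
  state[ids] <- as.numeric(root)
  state
}
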