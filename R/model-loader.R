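# SBML reader: parses an SBML Level 2 / Level 3 document with xml2 and
# produces a compiled model: every MathML expression captured as an AST,
# FunctionDefinitions inlined, piecewise rewritten, and each expression
# compiled to a reverse Polish program ready for stack evaluation.

#' Load an SBML model
#'
#' Reads SBML Level 2 Version 1-4 or Level 3 Version 1 from a file path
#' or an XML string and returns the compiled in-memory model. All
#' function calls are inlined and piecewise expressions rewritten at
#' load time, so every stored program is directly evaluable. Kinetic-law
#' local parameters are substituted by value (they are constants). Level
#' 2 events get `persistent = TRUE` and are treated as already-true at
#' t = 0 (no firing from the initial condition); Level 3 honours the
#' trigger's `initialValue` and `persistent` attributes.
#'
#' @param path file path, or a character scalar starting with `<`
#'   containing the document itself.
#' @return an object of class `sbml_model` with fields `sbml_level`,
#'   `sbml_version`, `compartments`, `species`, `parameters`,
#'   `reactions`, `assignment_rules`, `rate_rules`, `algebraic_rules`,
#'   `initial_assignments`, `events`, `constraints`, `function_defs` and
#'   `variable_index` (named positions in the state vector).
#' @export
load_model <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop_sbml("parse", "cannot parse SBML XML: ",
                                  conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  if (!identical(xml2::xml_name(doc), "sbml"))
    stop_sbml("parse", "root element is <", xml2::xml_name(doc),
              ">, expected <sbml>")
  level <- as.integer(xml2::xml_attr(doc, "level"))
  version <- as.integer(xml2::xml_attr(doc, "version"))
  if (is.na(level) || !(level %in% c(2L, 3L)))
    stop_sbml("unsupported", "SBML Level ", level,
              " is not supported (Levels 2 and 3 only)")
  mod <- xml2::xml_find_first(doc, "./model")
  if (inherits(mod, "xml_missing"))
    stop_sbml("parse", "document has no <model> element")

  model <- list(sbml_level = level, sbml_version = version)
  class(model) <- "sbml_model"

  model$function_defs <- parse_function_defs(mod)
  model$compartments <- parse_compartments(mod, level)
  model$species <- parse_species(mod)
  model$parameters <- parse_parameters(mod, level)
  model$reactions <- parse_reactions(mod, model$function_defs)

  rules <- parse_rules(mod, model$function_defs)
  model$assignment_rules <- rules$assignment
  model$rate_rules <- rules$rate
  model$algebraic_rules <- rules$algebraic
  model$initial_assignments <- parse_initial_assignments(mod, model$function_defs)
  model$events <- parse_events(mod, level, model$function_defs)
  model$constraints <- parse_constraints(mod, model$function_defs)

  state_ids <- c(names(model$species), names(model$compartments),
                 names(model$parameters))
  if (anyDuplicated(state_ids))
    stop_sbml("semantic", "duplicate identifier '",
              state_ids[duplicated(state_ids)][1], "'")
  model$variable_index <- stats::setNames(seq_along(state_ids), state_ids)

  validate_model(model)
  model
}

#' @export
print.sbml_model <- function(x, ...) {
  cat("SBML L", x$sbml_level, "V", x$sbml_version, " model: ",
      length(x$species), " species, ", length(x$reactions), " reactions, ",
      length(x$assignment_rules) + length(x$rate_rules) +
        length(x$algebraic_rules), " rules, ",
      length(x$events), " events\n", sep = "")
  invisible(x)
}

# parse, transform and compile one <math> child of `nd`; NULL if absent
node_math <- function(nd, defs) {
  m <- xml2::xml_find_first(nd, "./math")
  if (inherits(m, "xml_missing")) return(NULL)
  ast <- parse_mathml(m)
  ast <- rewrite_piecewise(inline_function_calls(ast, defs))
  list(ast = ast, prog = compile_to_rpn(ast))
}

attr_flag <- function(nd, name, default) {
  v <- xml2::xml_attr(nd, name)
  if (is.na(v)) default else identical(v, "true")
}

attr_num <- function(nd, name, default = NA_real_) {
  v <- xml2::xml_attr(nd, name)
  if (is.na(v)) default else as.numeric(v)
}

req_id <- function(nd, what) {
  id <- xml2::xml_attr(nd, "id")
  if (is.na(id)) stop_sbml("parse", what, " without an id")
  id
}

parse_function_defs <- function(mod) {
  defs <- list()
  for (nd in xml2::xml_find_all(mod, ".//listOfFunctionDefinitions/functionDefinition")) {
    id <- req_id(nd, "functionDefinition")
    m <- xml2::xml_find_first(nd, "./math")
    lam <- parse_mathml(m)
    if (!is.list(lam) || is.null(lam$args))
      stop_sbml("parse", "functionDefinition '", id, "' math is not a lambda")
    defs[[id]] <- lam
  }
  defs
}

parse_compartments <- function(mod, level) {
  out <- list()
  for (nd in xml2::xml_find_all(mod, ".//listOfCompartments/compartment")) {
    id <- req_id(nd, "compartment")
    size <- attr_num(nd, "size")
    if (is.na(size) && level == 2L) size <- attr_num(nd, "volume")
    if (is.na(size) && level == 2L) size <- 1      # L2 default volume
    out[[id]] <- list(id = id, size = size,
                      constant = attr_flag(nd, "constant", TRUE),
                      spatial_dimensions = attr_num(nd, "spatialDimensions", 3))
  }
  out
}

parse_species <- function(mod) {
  out <- list()
  for (nd in xml2::xml_find_all(mod, ".//listOfSpecies/species")) {
    id <- req_id(nd, "species")
    amt <- attr_num(nd, "initialAmount")
    conc <- attr_num(nd, "initialConcentration")
    comp <- xml2::xml_attr(nd, "compartment")
    if (is.na(comp)) stop_sbml("parse", "species '", id, "' has no compartment")
    out[[id]] <- list(
      id = id,
      initial_value = if (!is.na(amt)) amt else conc,
      initial_is_amount = !is.na(amt),
      compartment = comp,
      boundary_condition = attr_flag(nd, "boundaryCondition", FALSE),
      constant = attr_flag(nd, "constant", FALSE),
      has_only_substance_units = attr_flag(nd, "hasOnlySubstanceUnits", FALSE))
  }
  out
}

parse_parameters <- function(mod, level) {
  out <- list()
  for (nd in xml2::xml_find_all(mod, "./listOfParameters/parameter")) {
    id <- req_id(nd, "parameter")
    out[[id]] <- list(id = id, value = attr_num(nd, "value"),
                      constant = attr_flag(nd, "constant", TRUE))
  }
  out
}

parse_reactions <- function(mod, defs) {
  out <- list()
  refs <- function(nd, xpath) {
    lapply(xml2::xml_find_all(nd, xpath), function(r)
      list(species = xml2::xml_attr(r, "species"),
           stoichiometry = attr_num(r, "stoichiometry", 1)))
  }
  for (nd in xml2::xml_find_all(mod, ".//listOfReactions/reaction")) {
    id <- req_id(nd, "reaction")
    kl <- xml2::xml_find_first(nd, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop_sbml("unsupported", "reaction '", id, "' has no kineticLaw")
    locals <- list()
    for (p in xml2::xml_find_all(
           kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")) {
      locals[[req_id(p, "local parameter")]] <- math_num(attr_num(p, "value"))
    }
    math <- node_math(kl, defs)
    if (is.null(math))
      stop_sbml("parse", "kineticLaw of '", id, "' has no <math>")
    if (length(locals)) {
      ast <- substitute_names(math$ast, locals)
      math <- list(ast = ast, prog = compile_to_rpn(ast))
    }
    out[[id]] <- list(
      id = id,
      reactants = refs(nd, "./listOfReactants/speciesReference"),
      products = refs(nd, "./listOfProducts/speciesReference"),
      modifiers = vapply(
        xml2::xml_find_all(nd, "./listOfModifiers/modifierSpeciesReference"),
        function(m) xml2::xml_attr(m, "species"), ""),
      fast = attr_flag(nd, "fast", FALSE),
      kinetic_ast = math$ast, kinetic_prog = math$prog)
  }
  out
}

parse_rules <- function(mod, defs) {
  assignment <- list(); rate <- list(); algebraic <- list()
  for (nd in xml2::xml_find_all(
         mod, ".//listOfRules/assignmentRule | .//listOfRules/rateRule | .//listOfRules/algebraicRule")) {
    math <- node_math(nd, defs)
    if (is.null(math)) stop_sbml("parse", "rule without <math>")
    kind <- xml2::xml_name(nd)
    if (kind == "algebraicRule") {
      algebraic[[length(algebraic) + 1L]] <- math
    } else {
      target <- xml2::xml_attr(nd, "variable")
      if (is.na(target)) stop_sbml("parse", kind, " without variable")
      rec <- c(list(target = target), math)
      if (kind == "assignmentRule") assignment[[length(assignment) + 1L]] <- rec
      else rate[[length(rate) + 1L]] <- rec
    }
  }
  list(assignment = assignment, rate = rate, algebraic = algebraic)
}

parse_initial_assignments <- function(mod, defs) {
  out <- list()
  for (nd in xml2::xml_find_all(mod, ".//listOfInitialAssignments/initialAssignment")) {
    target <- xml2::xml_attr(nd, "symbol")
    if (is.na(target)) stop_sbml("parse", "initialAssignment without symbol")
    math <- node_math(nd, defs)
    if (is.null(math)) stop_sbml("parse", "initialAssignment without <math>")
    out[[length(out) + 1L]] <- c(list(target = target), math)
  }
  out
}

parse_constraints <- function(mod, defs) {
  out <- list()
  for (nd in xml2::xml_find_all(mod, ".//listOfConstraints/constraint")) {
    math <- node_math(nd, defs)
    if (!is.null(math)) out[[length(out) + 1L]] <- math
  }
  out
}

parse_events <- function(mod, level, defs) {
  out <- list()
  idx <- 0L
  for (nd in xml2::xml_find_all(mod, ".//listOfEvents/event")) {
    idx <- idx + 1L
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) id <- paste0("_event_", idx)
    trig <- xml2::xml_find_first(nd, "./trigger")
    if (inherits(trig, "xml_missing"))
      stop_sbml("parse", "event '", id, "' has no trigger")
    trig_math <- node_math(trig, defs)
    if (is.null(trig_math)) stop_sbml("parse", "trigger of '", id,
                                      "' has no <math>")
    if (level >= 3L) {
      persistent <- attr_flag(trig, "persistent", TRUE)
      initial_value <- attr_flag(trig, "initialValue", TRUE)
    } else {
      # L2: no attributes; triggers persist and count as true at t=0
      persistent <- TRUE
      initial_value <- TRUE
    }
    pr <- xml2::xml_find_first(nd, "./priority")
    priority <- if (inherits(pr, "xml_missing")) NULL else node_math(pr, defs)
    dl <- xml2::xml_find_first(nd, "./delay")
    delay <- if (inherits(dl, "xml_missing")) NULL else node_math(dl, defs)
    assignments <- lapply(
      xml2::xml_find_all(nd, "./listOfEventAssignments/eventAssignment"),
      function(ea) {
        target <- xml2::xml_attr(ea, "variable")
        if (is.na(target)) stop_sbml("parse", "eventAssignment without variable")
        math <- node_math(ea, defs)
        if (is.null(math)) stop_sbml("parse", "eventAssignment of '", id,
                                     "' without <math>")
        c(list(target = target), math)
      })
    out[[id]] <- list(
      id = id, trigger_ast = trig_math$ast, trigger_prog = trig_math$prog,
      persistent = persistent, initial_trigger_value = initial_value,
      priority = priority, delay = delay,
      use_values_from_trigger_time =
        attr_flag(nd, "useValuesFromTriggerTime", TRUE),
      assignments = assignments)
  }
  out
}

# ---- semantic validation -------------------------------------------------

model_entity_ids <- function(model) {
  c(names(model$species), names(model$compartments), names(model$parameters))
}

is_constant_id <- function(model, id) {
  if (!is.null(model$species[[id]])) return(isTRUE(model$species[[id]]$constant))
  if (!is.null(model$compartments[[id]])) return(isTRUE(model$compartments[[id]]$constant))
  if (!is.null(model$parameters[[id]])) return(isTRUE(model$parameters[[id]]$constant))
  FALSE
}

validate_model <- function(model) {
  known <- c(model_entity_ids(model), names(model$reactions))
  check_ids <- function(ast, container) {
    bad <- setdiff(ast_identifiers(ast), known)
    if (length(bad))
      stop_sbml("semantic", "unresolvable identifier '", bad[1],
                "' in ", container)
  }
  for (r in model$reactions) {
    check_ids(r$kinetic_ast, paste0("kineticLaw of reaction '", r$id, "'"))
    for (ref in c(r$reactants, r$products))
      if (is.null(model$species[[ref$species]]))
        stop_sbml("semantic", "unknown species '", ref$species,
                  "' in reaction '", r$id, "'")
  }
  for (ru in model$assignment_rules) check_ids(ru$ast, "assignmentRule")
  for (ru in model$rate_rules) check_ids(ru$ast, "rateRule")
  for (ru in model$algebraic_rules) check_ids(ru$ast, "algebraicRule")
  for (ia in model$initial_assignments) check_ids(ia$ast, "initialAssignment")
  for (ev in model$events) {
    check_ids(ev$trigger_ast, paste0("trigger of event '", ev$id, "'"))
    if (!is.null(ev$priority)) check_ids(ev$priority$ast, "priority")
    if (!is.null(ev$delay)) check_ids(ev$delay$ast, "delay")
    for (a in ev$assignments) {
      check_ids(a$ast, paste0("eventAssignment of '", ev$id, "'"))
      if (!a$target %in% model_entity_ids(model))
        stop_sbml("semantic", "eventAssignment targets unknown id '",
                  a$target, "'")
      if (is_constant_id(model, a$target))
        stop_sbml("semantic", "eventAssignment targets constant '",
                  a$target, "'")
    }
  }

  # one determination per variable; constants are never rule targets
  ar_targets <- vapply(model$assignment_rules, `[[`, "", "target")
  rr_targets <- vapply(model$rate_rules, `[[`, "", "target")
  dup <- c(ar_targets, rr_targets)
  if (anyDuplicated(dup))
    stop_sbml("semantic", "variable '", dup[duplicated(dup)][1],
              "' is the target of more than one rule")
  for (tg in dup) {
    if (!tg %in% model_entity_ids(model))
      stop_sbml("semantic", "rule targets unknown id '", tg, "'")
    if (is_constant_id(model, tg))
      stop_sbml("semantic", "rule targets constant '", tg, "'")
  }
  ia_targets <- vapply(model$initial_assignments, `[[`, "", "target")
  if (anyDuplicated(ia_targets))
    stop_sbml("semantic", "duplicate initialAssignment for '",
              ia_targets[duplicated(ia_targets)][1], "'")

  # initial values must be determined somewhere
  for (sp in model$species) {
    if (is.na(sp$initial_value) &&
        !sp$id %in% c(ia_targets, ar_targets))
      stop_sbml("semantic", "species '", sp$id,
                "' has no initial value and no initialAssignment")
    if (is.null(model$compartments[[sp$compartment]]))
      stop_sbml("semantic", "species '", sp$id,
                "' references unknown compartment '", sp$compartment, "'")
  }
  invisible(model)
}

# ---- state view / initial state ------------------------------------------

# named value vector over all entity ids as seen by math expressions:
# species as concentrations (amount / compartment size) unless
# hasOnlySubstanceUnits; compartments as sizes; parameters as values
state_values <- function(model, state) {
  vals <- state
  for (sp in model$species) {
    if (!sp$has_only_substance_units) {
      size <- state[[sp$compartment]]
      vals[[sp$id]] <- state[[sp$id]] / size
    }
  }
  vals
}

# convert a value assigned to `id` (rule/event semantics) into the
# internal state representation (species stored as amounts)
assigned_to_internal <- function(model, state, id, value) {
  sp <- model$species[[id]]
  if (!is.null(sp) && !sp$has_only_substance_units)
    value * state[[sp$compartment]]
  else value
}

#' Resolve the state vector at t = 0
#'
#' Applies SBML initial semantics: attribute-derived values first
#' (species concentrations converted to amounts using their
#' compartment's size), then InitialAssignments and AssignmentRules
#' evaluated in dependency order. Species are stored internally as
#' amounts throughout the simulator; concentrations are materialized on
#' demand as amount divided by current compartment size.
#'
#' @param model an `sbml_model`.
#' @return named numeric state vector (order of `model$variable_index`).
#' @export
resolve_initial_state <- function(model) {
  n <- length(model$variable_index)
  state <- stats::setNames(numeric(n), names(model$variable_index))
  for (cp in model$compartments)
    state[[cp$id]] <- if (is.na(cp$size)) NA_real_ else cp$size
  for (p in model$parameters) state[[p$id]] <- p$value
  for (sp in model$species) {
    v <- sp$initial_value
    state[[sp$id]] <-
      if (is.na(v)) NA_real_
      else if (sp$initial_is_amount || sp$has_only_substance_units) v
      else v * state[[sp$compartment]]
  }

  jobs <- c(lapply(model$initial_assignments, function(x)
              c(x, list(kind = "initial"))),
            lapply(model$assignment_rules, function(x)
              c(x, list(kind = "rule"))))
  if (length(jobs)) {
    targets <- vapply(jobs, `[[`, "", "target")
    deps <- lapply(jobs, function(j)
      intersect(j$prog$referenced_ids, targets))
    order <- topological_order(targets, deps)
    for (i in order) {
      j <- jobs[[i]]
      ctx <- eval_context(time = 0, values = state_values(model, state))
      v <- rpn_eval(j$prog, ctx)
      state[[j$target]] <- assigned_to_internal(model, state, j$target, v)
    }
  }
  if (anyNA(state))
    stop_sbml("semantic", "initial value of '",
              names(state)[is.na(state)][1], "' is undetermined")
  state
}

# Kahn topological sort; returns evaluation order (indices into targets)
topological_order <- function(targets, deps) {
  n <- length(targets)
  remaining <- seq_len(n)
  done <- character(0)
  order <- integer(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      all(setdiff(deps[[i]], targets[i]) %in% done), NA)]
    if (!length(ready)) {
      cyc <- paste(targets[remaining], collapse = " -> ")
      stop_sbml("cycle", "circular dependency among assignments: ", cyc)
    }
    order <- c(order, ready)
    done <- c(done, targets[ready])
    remaining <- setdiff(remaining, ready)
  }
  order
}
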