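# Programmatic generator of small, valid SBML documents covering every
# supported feature (both L2V4 and L3V1 dialects where the feature
# exists in both), plus a harness for SBML-test-suite-layout case
# directories.

FIXTURE_TAGS <- c("decay", "chain", "stiff", "function_def", "piecewise",
                  "assignment_rule", "rate_rule", "algebraic_rule",
                  "event_basic", "event_priority", "event_persistent",
                  "event_delay", "delay_expression", "fast_reaction",
                  "boundary_species")

sbml_header <- function(level) {
  if (level == 2L)
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">'
  else
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">'
}

# attribute string differences between the dialects
x_comp <- function(level, id, size) {
  if (level == 2L)
    sprintf('<compartment id="%s" size="%s"/>', id, size)
  else
    sprintf('<compartment id="%s" size="%s" constant="true"/>', id, size)
}

# all fixture species are declared in amounts (hasOnlySubstanceUnits)
x_species <- function(level, id, amount, comp = "c", boundary = FALSE,
                      constant = FALSE) {
  sprintf(paste0('<species id="%s" compartment="%s" initialAmount="%s"',
                 ' boundaryCondition="%s" constant="%s"',
                 ' hasOnlySubstanceUnits="true"/>'),
          id, comp, amount, tolower(boundary), tolower(constant))
}

x_param <- function(level, id, value, constant = TRUE) {
  sprintf('<parameter id="%s" value="%s" constant="%s"/>',
          id, value, tolower(constant))
}

x_math <- function(body) {
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, '</math>')
}

m_times <- function(...) paste0('<apply><times/>', paste0(...), '</apply>')
m_minus <- function(a, b) paste0('<apply><minus/>', a, b, '</apply>')
m_ci <- function(id) paste0('<ci>', id, '</ci>')
m_cn <- function(x) paste0('<cn>', x, '</cn>')
m_time <- '<csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>'

x_reaction <- function(level, id, reactants, products, math,
                       fast = FALSE) {
  sref <- function(sp) {
    extra <- if (level == 3L) ' stoichiometry="1" constant="true"' else ''
    sprintf('<speciesReference species="%s"%s/>', sp, extra)
  }
  paste0(
    sprintf('<reaction id="%s" reversible="false" fast="%s">',
            id, tolower(fast)),
    if (length(reactants))
      paste0('<listOfReactants>',
             paste(vapply(reactants, sref, ""), collapse = ""),
             '</listOfReactants>'),
    if (length(products))
      paste0('<listOfProducts>',
             paste(vapply(products, sref, ""), collapse = ""),
             '</listOfProducts>'),
    '<kineticLaw>', x_math(math), '</kineticLaw>',
    '</reaction>')
}

assemble_sbml <- function(level, compartments = "", species = "",
                          parameters = "", rules = "", reactions = "",
                          events = "", function_defs = "",
                          initial_assignments = "") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n', sbml_header(level),
    '<model id="fixture">',
    if (nzchar(function_defs))
      paste0('<listOfFunctionDefinitions>', function_defs,
             '</listOfFunctionDefinitions>'),
    if (nzchar(compartments))
      paste0('<listOfCompartments>', compartments, '</listOfCompartments>'),
    if (nzchar(species))
      paste0('<listOfSpecies>', species, '</listOfSpecies>'),
    if (nzchar(parameters))
      paste0('<listOfParameters>', parameters, '</listOfParameters>'),
    if (nzchar(initial_assignments))
      paste0('<listOfInitialAssignments>', initial_assignments,
             '</listOfInitialAssignments>'),
    if (nzchar(rules))
      paste0('<listOfRules>', rules, '</listOfRules>'),
    if (nzchar(reactions))
      paste0('<listOfReactions>', reactions, '</listOfReactions>'),
    if (nzchar(events))
      paste0('<listOfEvents>', events, '</listOfEvents>'),
    '</model></sbml>')
}

#' Generate a small SBML document exercising one feature
#'
#' Deterministic given its arguments; every tag yields a minimal valid
#' model. Default rate constants and initial values are chosen so each
#' fixture has a hand-checkable closed-form or trace (see the package
#' vignette).
#'
#' @param tag one of `decay`, `chain`, `stiff`, `function_def`,
#'   `piecewise`, `assignment_rule`, `rate_rule`, `algebraic_rule`,
#'   `event_basic`, `event_priority`, `event_persistent`, `event_delay`,
#'   `delay_expression`, `fast_reaction`, `boundary_species`.
#' @param level SBML level, 2 or 3 (tags using Priority/persistent are
#'   Level 3 only).
#' @param params named list overriding the tag's default rate constants
#'   and initial values.
#' @return SBML XML as a character scalar.
#' @export
make_fixture <- function(tag, level = 3L, params = list()) {
  tag <- match.arg(tag, FIXTURE_TAGS)
  level <- as.integer(level)
  stopifnot(level %in% c(2L, 3L))
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default

  switch(tag,
    decay = {
      # dS1/dt = -k S1; S1(t) = S1_0 exp(-k t)
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 10)),
        parameters = x_param(level, "k", p("k", 0.5)),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_ci("k"), m_ci("S1"))))
    },
    chain = {
      # closed chain S1 -> S2 -> S3; total amount conserved
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = paste0(x_species(level, "S1", p("S1", 8)),
                         x_species(level, "S2", p("S2", 0)),
                         x_species(level, "S3", p("S3", 0))),
        parameters = paste0(x_param(level, "k1", p("k1", 0.3)),
                            x_param(level, "k2", p("k2", 0.2))),
        reactions = paste0(
          x_reaction(level, "J1", "S1", "S2",
                     m_times(m_ci("k1"), m_ci("S1"))),
          x_reaction(level, "J2", "S2", "S3",
                     m_times(m_ci("k2"), m_ci("S2")))))
    },
    stiff = {
      # dS1/dt = -k S1 with a large k: stresses explicit methods
      make_fixture("decay", level, list(k = p("k", 1000), S1 = p("S1", 1)))
    },
    function_def = {
      # kinetic law calls f(x) = 2 x; effective rate k * 2 * S1
      fd <- paste0('<functionDefinition id="f">',
        x_math(paste0('<lambda><bvar><ci>x</ci></bvar>',
                      m_times(m_cn(2), m_ci("x")), '</lambda>')),
        '</functionDefinition>')
      assemble_sbml(level,
        function_defs = fd,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 10)),
        parameters = x_param(level, "k", p("k", 0.25)),
        reactions = x_reaction(level, "J1", "S1", character(0),
          m_times(m_ci("k"),
                  paste0('<apply><ci>f</ci>', m_ci("S1"), '</apply>'))))
    },
    piecewise = {
      # p := piecewise(5, time > 2, 1): steps from 1 to 5 at t = 2
      pw <- paste0('<piecewise><piece>', m_cn(5),
        '<apply><gt/>', m_time, m_cn(2), '</apply></piece>',
        '<otherwise>', m_cn(1), '</otherwise></piecewise>')
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 10)),
        parameters = paste0(x_param(level, "k", p("k", 0.5)),
                            x_param(level, "p", 0, constant = FALSE)),
        rules = paste0('<assignmentRule variable="p">', x_math(pw),
                       '</assignmentRule>'),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_ci("k"), m_ci("S1"))))
    },
    assignment_rule = {
      # chained rules a := b + 1, b := 2 (a = 3 after closure)
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 1)),
        parameters = paste0(x_param(level, "a", 0, constant = FALSE),
                            x_param(level, "b", 0, constant = FALSE),
                            x_param(level, "k", p("k", 0.1))),
        rules = paste0(
          '<assignmentRule variable="a">',
          x_math(paste0('<apply><plus/>', m_ci("b"), m_cn(1), '</apply>')),
          '</assignmentRule>',
          '<assignmentRule variable="b">', x_math(m_cn(2)),
          '</assignmentRule>'),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_ci("k"), m_ci("S1"))))
    },
    rate_rule = {
      # dX/dt = -k X via a rate rule on a parameter
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 1)),
        parameters = paste0(x_param(level, "X", p("X", 10), constant = FALSE),
                            x_param(level, "k", p("k", 0.5))),
        rules = paste0('<rateRule variable="X">',
          x_math(paste0('<apply><minus/>',
                        m_times(m_ci("k"), m_ci("X")), '</apply>')),
          '</rateRule>'),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_cn(0.1), m_ci("S1"))))
    },
    algebraic_rule = {
      # 0 = S1 + S2 - T with S1 differential and T constant: S2 solved
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = paste0(x_species(level, "S1", p("S1", 1)),
                         x_species(level, "S2", p("S2", 2))),
        parameters = paste0(x_param(level, "T", p("T", 3)),
                            x_param(level, "k", p("k", 0.5))),
        rules = paste0('<algebraicRule>',
          x_math(m_minus(paste0('<apply><plus/>', m_ci("S1"), m_ci("S2"),
                                '</apply>'), m_ci("T"))),
          '</algebraicRule>'),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_ci("k"), m_ci("S1"))))
    },
    event_basic = {
      # decaying S1 reset to 10 whenever it crosses below 5 (sawtooth)
      ev <- paste0('<event id="E1"',
        if (level == 3L) ' useValuesFromTriggerTime="true"', '>',
        '<trigger', if (level == 3L)
          ' initialValue="true" persistent="true"', '>',
        x_math(paste0('<apply><lt/>', m_ci("S1"), m_cn(5), '</apply>')),
        '</trigger><listOfEventAssignments>',
        '<eventAssignment variable="S1">', x_math(m_cn(10)),
        '</eventAssignment></listOfEventAssignments></event>')
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 10)),
        parameters = x_param(level, "k", p("k", 0.5)),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_ci("k"), m_ci("S1"))),
        events = ev)
    },
    event_priority = ,
    event_persistent = {
      # two events fire together when S1 rises past 0.5:
      #   E1 (priority 2): S1 := 0   -- runs first
      #   E2 (priority 1): S2 := 9, persistent varies by tag
      # with persistent="false", E1's assignment withdraws E2
      if (level != 3L)
        stop_sbml("unsupported", "tag '", tag, "' needs Level 3 ",
                  "(Priority/persistent)")
      persistent2 <- if (tag == "event_priority") "false" else "true"
      ev <- function(id, priority, target, value, persistent, trig) paste0(
        '<event id="', id, '" useValuesFromTriggerTime="false">',
        '<trigger initialValue="true" persistent="', persistent, '">',
        x_math(trig), '</trigger>',
        '<priority>', x_math(m_cn(priority)), '</priority>',
        '<listOfEventAssignments><eventAssignment variable="', target, '">',
        x_math(m_cn(value)),
        '</eventAssignment></listOfEventAssignments></event>')
      trig <- paste0('<apply><gt/>', m_ci("S1"), m_cn(0.5), '</apply>')
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = paste0(x_species(level, "S1", 0),
                         x_species(level, "S2", 0)),
        parameters = x_param(level, "r", p("r", 1)),
        rules = paste0('<rateRule variable="S1">', x_math(m_ci("r")),
                       '</rateRule>'),
        events = paste0(ev("E1", 2, "S1", 0, "true", trig),
                        ev("E2", 1, "S2", 9, persistent2, trig)))
    },
    event_delay = {
      # triggered at t = 1 with delay 2; assigns S1 := pp where pp
      # drifts (pp = 4 + t): captures 5 at trigger time vs 7 at firing
      uv <- if (isTRUE(p("use_trigger_values", TRUE))) "true" else "false"
      ev <- paste0('<event id="E1" useValuesFromTriggerTime="', uv, '">',
        '<trigger', if (level == 3L)
          ' initialValue="true" persistent="true"', '>',
        x_math(paste0('<apply><geq/>', m_time, m_cn(1), '</apply>')),
        '</trigger>',
        '<delay>', x_math(m_cn(p("delay", 2))), '</delay>',
        '<listOfEventAssignments><eventAssignment variable="S1">',
        x_math(m_ci("pp")),
        '</eventAssignment></listOfEventAssignments></event>')
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", p("S1", 0)),
        parameters = x_param(level, "pp", 4, constant = FALSE),
        rules = paste0('<assignmentRule variable="pp">',
          x_math(paste0('<apply><plus/>', m_cn(4), m_time, '</apply>')),
          '</assignmentRule>'),
        events = ev)
    },
    delay_expression = {
      # dy/dt = -y(t - 1) with y = 1 for t <= 0: y(t) = 1 - t on [0, 1]
      dexpr <- paste0(
        '<apply><minus/>',
        '<apply><csymbol encoding="text" definitionURL=',
        '"http://www.sbml.org/sbml/symbols/delay">delay</csymbol>',
        m_ci("y"), m_cn(p("lag", 1)), '</apply></apply>')
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = x_species(level, "S1", 1),
        parameters = x_param(level, "y", p("y", 1), constant = FALSE),
        rules = paste0('<rateRule variable="y">', x_math(dexpr),
                       '</rateRule>'),
        reactions = x_reaction(level, "J1", "S1", character(0),
                               m_times(m_cn(0.1), m_ci("S1"))))
    },
    fast_reaction = {
      # fast A <-> B with v = kf A - kr B (defaults 2A - B) embedded in
      # nothing slow: equilibrium A:B = kr:kf with A + B conserved
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = paste0(x_species(level, "A", p("A", 3)),
                         x_species(level, "B", p("B", 0))),
        parameters = paste0(x_param(level, "kf", p("kf", 2)),
                            x_param(level, "kr", p("kr", 1))),
        reactions = x_reaction(level, "Jfast", "A", "B",
          m_minus(m_times(m_ci("kf"), m_ci("A")),
                  m_times(m_ci("kr"), m_ci("B"))),
          fast = TRUE))
    },
    boundary_species = {
      # boundary B feeds S at rate k B; B itself never changes
      assemble_sbml(level,
        compartments = x_comp(level, "c", 1),
        species = paste0(x_species(level, "B", p("B", 2), boundary = TRUE),
                         x_species(level, "S", p("S", 0))),
        parameters = x_param(level, "k", p("k", 0.5)),
        reactions = x_reaction(level, "J1", "B", "S",
                               m_times(m_ci("k"), m_ci("B"))))
    })
}

# ---- SBML test suite harness --------------------------------------------

#' Parse an SBML-test-suite settings file
#'
#' Reads the `NNNNN-settings.txt` grammar: `key: value` lines with
#' comma-separated lists for `variables`, `amount` and `concentration`.
#'
#' @param path path to the settings file.
#' @return a list with `start`, `duration`, `steps`, `variables`,
#'   `absolute`, `relative`, `amount`, `concentration`.
#' @export
parse_suite_settings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([a-zA-Z]+):(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  split_ids <- function(x) {
    if (is.null(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, ",")[[1]])
  }
  list(start = as.numeric(kv$start %||% 0),
       duration = as.numeric(kv$duration),
       steps = as.integer(kv$steps),
       variables = split_ids(kv$variables),
       absolute = as.numeric(kv$absolute %||% 1e-7),
       relative = as.numeric(kv$relative %||% 1e-4),
       amount = split_ids(kv$amount),
       concentration = split_ids(kv$concentration))
}

#' Run one SBML-test-suite-layout case
#'
#' Expects the suite's layout inside `case_dir`: a model file
#' (`*-sbml-l3v1.xml` preferred, `*-sbml-l2v4.xml` fallback),
#' `*-settings.txt`, and `*-results.csv` with the expected trajectory.
#' The case passes iff every required point satisfies
#' `|computed - expected| <= absolute + relative * |expected|`.
#'
#' @param case_dir directory of one case.
#' @param method a [method_spec()] (default RK4).
#' @param refinement internal steps per output interval.
#' @return a list with `pass`, `max_deviation`, `deviations` (matrix over
#'   time x variable of `|computed - expected| - (atol + rtol |expected|)`),
#'   and the simulated `timecourse`.
#' @export
run_suite_case <- function(case_dir, method = method_spec("rk4"),
                           refinement = 50L) {
  pick <- function(pattern) {
    fs <- list.files(case_dir, pattern = pattern, full.names = TRUE)
    if (length(fs)) fs[1] else NULL
  }
  model_file <- pick("sbml-l3v1\\.xml$") %||% pick("sbml-l2v4\\.xml$")
  settings_file <- pick("settings\\.txt$")
  results_file <- pick("results\\.csv$")
  if (is.null(model_file) || is.null(settings_file) || is.null(results_file))
    stop_sbml("parse", "case directory '", case_dir,
              "' is missing model, settings or results")
  st <- parse_suite_settings(settings_file)
  if (!identical(st$start, 0))
    stop_sbml("unsupported", "nonzero start time not supported")
  model <- load_model(model_file)
  amounts <- stats::setNames(
    c(rep(TRUE, length(st$amount)), rep(FALSE, length(st$concentration))),
    c(st$amount, st$concentration))
  config <- sim_config(st$duration, st$steps, method,
                       refinement = refinement,
                       print_targets = st$variables,
                       print_amounts = amounts[intersect(names(amounts),
                                                         st$variables)])
  tc <- simulate_model(model, config)
  expected <- utils::read.csv(results_file, check.names = FALSE)
  names(expected) <- trimws(names(expected))
  dev <- matrix(NA_real_, nrow(tc), length(st$variables),
                dimnames = list(NULL, st$variables))
  for (v in st$variables) {
    e <- expected[[v]]
    dev[, v] <- abs(tc[[v]] - e) - (st$absolute + st$relative * abs(e))
  }
  list(pass = all(dev <= 0), max_deviation = max(dev),
       deviations = dev, timecourse = tc)
}
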