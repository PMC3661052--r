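# Event semantics: trigger edges, the priority cascade, persistence,
# delayed assignments with value capture, and the history buffer.

test_that("triggers fire on false-to-true edges only", {
  m <- load_model(make_fixture("event_basic"))  # trigger S1 < 5
  st <- resolve_initial_state(m)
  memory <- trigger_memory_init(m)
  # S1 = 10: trigger false
  d1 <- detect_triggers(m, st, 0, memory)
  expect_length(d1$fired, 0)
  # crossing 5.1 -> 4.9 fires
  st["S1"] <- 4.9
  d2 <- detect_triggers(m, st, 1, d1$memory)
  expect_equal(d2$fired, "E1")
  # still true at the next check: no level-triggering
  st["S1"] <- 4.0
  d3 <- detect_triggers(m, st, 2, d2$memory)
  expect_length(d3$fired, 0)
})

test_that("a trigger true at t = 0 does not fire under L2 semantics", {
  m <- load_model(make_fixture("event_basic", 2L, params = list(S1 = 1)))
  expect_true(trigger_memory_init(m)[["E1"]])  # counts as already true
  st <- resolve_initial_state(m)
  d <- detect_triggers(m, st, 0, trigger_memory_init(m))
  expect_length(d$fired, 0)
  # under L3 with initialValue="false" the same situation fires at t = 0
  xml3 <- sub('initialValue="true"', 'initialValue="false"',
              make_fixture("event_basic", 3L, params = list(S1 = 1)))
  m3 <- load_model(xml3)
  expect_false(trigger_memory_init(m3)[["E1"]])
  d3 <- detect_triggers(m3, resolve_initial_state(m3), 0,
                        trigger_memory_init(m3))
  expect_equal(d3$fired, "E1")
})

test_that("the cascade executes by priority and re-checks persistence", {
  # E1 (priority 2): S1 := 0; E2 (priority 1, persistent=false,
  # trigger S1 > 0.5): S2 := 9. Firing both at S1 = 1: E1 runs first,
  # E2's trigger is rechecked, found false, and E2 is withdrawn.
  m <- load_model(make_fixture("event_priority"))
  st <- resolve_initial_state(m)
  st["S1"] <- 1
  memory <- c(E1 = FALSE, E2 = FALSE)
  det <- detect_triggers(m, st, 1, memory)
  expect_setequal(det$fired, c("E1", "E2"))
  cas <- run_event_cascade(m, det$fired, st, 1, det$memory)
  expect_identical(cas$executed, "E1")
  expect_equal(cas$state[["S1"]], 0)
  expect_equal(cas$state[["S2"]], 0)               # E2 never ran
  # persistent variant: E2 still executes after E1
  mp <- load_model(make_fixture("event_persistent"))
  stp <- resolve_initial_state(mp); stp["S1"] <- 1
  detp <- detect_triggers(mp, stp, 1, c(E1 = FALSE, E2 = FALSE))
  casp <- run_event_cascade(mp, detp$fired, stp, 1, detp$memory)
  expect_identical(casp$executed, c("E1", "E2"))
  expect_equal(casp$state[["S2"]], 9)
})

test_that("an assignment can chain-trigger another event (cascade step v)", {
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S1" compartment="c" initialAmount="0" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="true"/>',
    '<species id="S2" compartment="c" initialAmount="0" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="true"/>',
    '</listOfSpecies><listOfEvents>',
    '<event id="E1" useValuesFromTriggerTime="false">',
    '<trigger initialValue="true" persistent="true">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><geq/>',
    '<csymbol definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>',
    '<cn>1</cn></apply></math></trigger>',
    '<listOfEventAssignments><eventAssignment variable="S1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>9</cn></math>',
    '</eventAssignment></listOfEventAssignments></event>',
    '<event id="E2" useValuesFromTriggerTime="false">',
    '<trigger initialValue="true" persistent="true">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><gt/><ci>S1</ci><cn>5</cn></apply></math></trigger>',
    '<listOfEventAssignments><eventAssignment variable="S2">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>1</cn></math>',
    '</eventAssignment></listOfEventAssignments></event>',
    '</listOfEvents></model></sbml>')
  m <- load_model(xml)
  st <- resolve_initial_state(m)
  # memory reflects the just-detected edge on E1; E2 still false
  memory <- c(E1 = TRUE, E2 = FALSE)
  cas <- run_event_cascade(m, "E1", st, 1, memory)
  expect_identical(cas$executed, c("E1", "E2"))
  expect_equal(cas$state[["S1"]], 9)
  expect_equal(cas$state[["S2"]], 1)
})

test_that("three simultaneous events execute in descending priority", {
  ev <- function(id, pr) paste0(
    '<event id="', id, '" useValuesFromTriggerTime="false">',
    '<trigger initialValue="true" persistent="true">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><geq/>',
    '<csymbol definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>',
    '<cn>1</cn></apply></math></trigger>',
    '<priority><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>',
    pr, '</cn></math></priority>',
    '<listOfEventAssignments><eventAssignment variable="x">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>', pr,
    '</cn></math></eventAssignment></listOfEventAssignments></event>')
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfParameters><parameter id="x" value="0" constant="false"/>',
    '</listOfParameters><listOfEvents>',
    ev("Elow", 1), ev("Ehigh", 3), ev("Emid", 2),
    '</listOfEvents></model></sbml>')
  m <- load_model(xml)
  st <- resolve_initial_state(m)
  cas <- run_event_cascade(m, c("Elow", "Ehigh", "Emid"), st, 1,
                           c(Elow = TRUE, Ehigh = TRUE, Emid = TRUE))
  expect_identical(cas$executed, c("Ehigh", "Emid", "Elow"))
  expect_equal(cas$state[["x"]], 1)      # last (lowest-priority) write
})

test_that("delayed assignments capture trigger-time values when asked", {
  # trigger at t = 1, delay 2, assigns S1 := pp with pp = 4 + t
  m <- load_model(make_fixture("event_delay"))
  tc <- simulate_model(m, sim_config(4, 8))
  expect_equal(tc$S1[tc$time < 3], rep(0, 6))
  expect_equal(tc$S1[tc$time >= 3], rep(5, 3))     # captured at t = 1
  m2 <- load_model(make_fixture("event_delay",
                                params = list(use_trigger_values = FALSE)))
  tc2 <- simulate_model(m2, sim_config(4, 8))
  expect_equal(tc2$S1[tc2$time >= 3], rep(7, 3))   # evaluated at t = 3
})

test_that("schedule_delayed validates and zero delay fires immediately", {
  m <- load_model(make_fixture("event_delay"))
  st <- resolve_initial_state(m)
  st <- apply_assignment_closure(build_ode_system(m), st, 1)
  p <- schedule_delayed(m, "E1", 1, st)
  expect_equal(p$fire_time, 3)
  expect_equal(unname(p$captured["S1"]), 5)        # pp at t = 1
  # delay 0 fires in the same round as undelayed events
  m0 <- load_model(make_fixture("event_delay", params = list(delay = 0)))
  tc0 <- simulate_model(m0, sim_config(2, 4))
  expect_equal(tc0$S1[tc0$time >= 1], rep(5, 3))
  # negative evaluated delay is a semantic error
  mneg <- load_model(make_fixture("event_delay", params = list(delay = -1)))
  expect_error(simulate_model(mneg, sim_config(2, 4)),
               class = "sbml_semantic_error")
})

test_that("pending assignments fire in order; empty pending is identity", {
  m <- load_model(make_fixture("event_delay"))
  st <- resolve_initial_state(m)
  out <- fire_due_assignments(m, list(), st, 10)
  expect_identical(out$state, st)
  expect_false(out$fired_any)
  p1 <- list(event_id = "E1", fire_time = 2, captured = c(S1 = 111))
  p2 <- list(event_id = "E1", fire_time = 1, captured = c(S1 = 222))
  out2 <- fire_due_assignments(m, list(p1, p2), st, 5)
  expect_equal(out2$state[["S1"]], 111)  # later fire time applied last
  expect_length(out2$pending, 0)
})

test_that("the history buffer interpolates and clamps", {
  buf <- history_buffer(c("S"))
  history_append(buf, 0, c(S = 1))
  history_append(buf, 1, c(S = 3))
  expect_equal(history_lookup(buf, "S", 0.5), 2)
  expect_equal(history_lookup(buf, "S", -5), 1)    # pre-history: initial
  expect_equal(history_lookup(buf, "S", 99), 3)    # beyond end: last
  expect_error(history_lookup(buf, "nope", 0), class = "sbml_semantic_error")
  # same-time append replaces (post-event state)
  history_append(buf, 1, c(S = 7))
  expect_equal(history_lookup(buf, "S", 1), 7)
  expect_error(history_append(buf, 0.5, c(S = 0)),
               class = "sbml_semantic_error")
})

test_that("delay expressions integrate by the method of steps", {
  # y'(t) = -y(t-1), y == 1 for t <= 0: exact y(t) = 1 - t on [0, 1]
  m <- load_model(make_fixture("delay_expression"))
  tc <- simulate_model(m, sim_config(1, 10, refinement = 100,
                                     print_targets = "y"))
  expect_equal(tc$y, 1 - tc$time, tolerance = 1e-9)
  expect_lt(abs(tc$y[11] - 0), 1e-6)
  # second interval [1, 2]: y(t) = 1 - t + (t-1)^2/2... check t = 2
  tc2 <- simulate_model(m, sim_config(2, 20, refinement = 100,
                                      print_targets = "y"))
  expect_equal(tc2$y[21], 1 - 2 + 0.5, tolerance = 1e-4)
})

test_that("event-bearing runs are reproducible with a fixed seed", {
  m <- load_model(make_fixture("event_priority"))
  cfg <- sim_config(2, 8, seed = 17, print_targets = c("S1", "S2"))
  t1 <- simulate_model(m, cfg)
  t2 <- simulate_model(m, cfg)
  expect_identical(t1, t2)
})
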