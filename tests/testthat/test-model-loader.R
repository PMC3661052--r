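# SBML reading, compiled-model invariants and initial-state resolution.

test_that("the minimal decay model loads with expected structure", {
  for (lv in c(2L, 3L)) {
    m <- load_model(make_fixture("decay", lv))
    expect_s3_class(m, "sbml_model")
    expect_equal(m$sbml_level, lv)
    expect_length(m$species, 1L)
    expect_length(m$reactions, 1L)
    expect_named(m$species, "S1")
    expect_equal(m$species$S1$initial_value, 10)
    # variable_index is a bijection onto 1..N
    expect_setequal(m$variable_index, seq_along(m$variable_index))
    expect_equal(unname(m$variable_index[["S1"]]), 1L)
  }
})

test_that("function calls are inlined away at load time", {
  m <- load_model(make_fixture("function_def"))
  has_call <- function(nd) {
    if (identical(nd$kind, "call")) return(TRUE)
    any(vapply(nd$children, has_call, NA))
  }
  expect_false(has_call(m$reactions$J1$kinetic_ast))
  # f(x) = 2x at rate k = 0.25 behaves as decay with k = 0.5
  tc <- simulate_model(m, sim_config(2, 4))
  expect_equal(tc$S1, 10 * exp(-0.5 * tc$time), tolerance = 1e-6)
})

test_that("unresolvable identifiers are reported by name", {
  bad <- gsub("<ci>k</ci>", "<ci>Sx</ci>", make_fixture("decay"))
  err <- tryCatch(load_model(bad), condition = function(c) c)
  expect_s3_class(err, "sbml_semantic_error")
  expect_match(conditionMessage(err), "Sx")
  expect_match(conditionMessage(err), "kineticLaw")
})

test_that("malformed XML raises a parse error", {
  expect_error(load_model("<sbml><model>"), class = "sbml_parse_error")
  expect_error(load_model("<notsbml/>"), class = "sbml_parse_error")
})

test_that("level 1 documents are rejected as unsupported", {
  l1 <- sub('level="2"', 'level="1"', make_fixture("decay", 2L))
  expect_error(load_model(l1), class = "sbml_unsupported_error")
})

test_that("initial concentrations convert to amounts by compartment size", {
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c" size="3"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="2"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="J1"><listOfReactants>',
    '<speciesReference species="S1"/></listOfReactants><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>S1</ci></math>',
    '</kineticLaw></reaction></listOfReactions></model></sbml>')
  m <- load_model(xml)
  st <- resolve_initial_state(m)
  expect_equal(st[["S1"]], 6)            # amount = 2 * 3
  # math sees the concentration (species not hasOnlySubstanceUnits)
  expect_equal(sbmlsim:::state_values(m, st)[["S1"]], 2)
})

test_that("initial assignments and assignment rules resolve in order", {
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="0"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="true" constant="false"/>',
    '</listOfSpecies><listOfParameters>',
    '<parameter id="p" value="5" constant="true"/>',
    '<parameter id="a" value="0" constant="false"/>',
    '<parameter id="b" value="0" constant="false"/>',
    '</listOfParameters><listOfInitialAssignments>',
    '<initialAssignment symbol="S1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><cn>2</cn><ci>p</ci></apply></math>',
    '</initialAssignment></listOfInitialAssignments><listOfRules>',
    '<assignmentRule variable="a">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><plus/><ci>b</ci><cn>1</cn></apply></math></assignmentRule>',
    '<assignmentRule variable="b">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>2</cn></math>',
    '</assignmentRule></listOfRules></model></sbml>')
  m <- load_model(xml)
  st <- resolve_initial_state(m)
  expect_equal(st[["S1"]], 10)           # 2 * p
  expect_equal(st[["b"]], 2)             # evaluated before a
  expect_equal(st[["a"]], 3)
})

test_that("dependency order agrees with exhaustive order enumeration", {
  # rules a := b+1, b := c*2, c := 2; only the topological order gives a
  # fixed point. Enumerate all 3! evaluation orders of the closure on a
  # fresh state; exactly the orders ending in the dependency order reach
  # the values our loader computes.
  mk_rule <- function(var, mathml) paste0(
    '<assignmentRule variable="', var, '">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">', mathml,
    '</math></assignmentRule>')
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="cc" size="1" constant="true"/></listOfCompartments>',
    '<listOfParameters>',
    '<parameter id="a" value="0" constant="false"/>',
    '<parameter id="b" value="0" constant="false"/>',
    '<parameter id="c" value="0" constant="false"/>',
    '</listOfParameters><listOfRules>',
    mk_rule("a", '<apply><plus/><ci>b</ci><cn>1</cn></apply>'),
    mk_rule("b", '<apply><times/><ci>c</ci><cn>2</cn></apply>'),
    mk_rule("c", '<cn>2</cn>'),
    '</listOfRules></model></sbml>')
  m <- load_model(xml)
  st <- resolve_initial_state(m)
  expect_equal(st[["c"]], 2); expect_equal(st[["b"]], 4)
  expect_equal(st[["a"]], 5)
  # brute-force oracle: apply the three raw updates in every order
  upd <- list(a = function(s) { s["a"] <- s["b"] + 1; s },
              b = function(s) { s["b"] <- s["c"] * 2; s },
              c = function(s) { s["c"] <- 2; s })
  perms <- list(c("a","b","c"), c("a","c","b"), c("b","a","c"),
                c("b","c","a"), c("c","a","b"), c("c","b","a"))
  good <- vapply(perms, function(p) {
    s <- c(a = 0, b = 0, c = 0)
    for (nm in p) s <- upd[[nm]](s)
    all(s == c(a = 5, b = 4, c = 2))
  }, NA)
  # only orders consistent with the dependencies (c before b before a)
  expect_identical(good, vapply(perms, function(p)
    match("c", p) < match("b", p) && match("b", p) < match("a", p), NA))
})

test_that("circular assignment dependencies raise a cycle error", {
  xml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="cc" size="1" constant="true"/></listOfCompartments>',
    '<listOfParameters>',
    '<parameter id="a" value="0" constant="false"/>',
    '<parameter id="b" value="0" constant="false"/>',
    '</listOfParameters><listOfRules>',
    '<assignmentRule variable="a">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><plus/><ci>b</ci><cn>1</cn></apply></math></assignmentRule>',
    '<assignmentRule variable="b">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><plus/><ci>a</ci><cn>1</cn></apply></math></assignmentRule>',
    '</listOfRules></model></sbml>')
  m <- load_model(xml)
  err <- tryCatch(resolve_initial_state(m), condition = function(c) c)
  expect_s3_class(err, "sbml_cycle_error")
  expect_match(conditionMessage(err), "a")
  expect_match(conditionMessage(err), "b")
})

test_that("rule-target and event-target invariants are enforced", {
  base <- make_fixture("rate_rule")
  # rule targeting a constant parameter
  bad <- sub('<parameter id="X" value="10" constant="false"/>',
             '<parameter id="X" value="10" constant="true"/>', base)
  expect_error(load_model(bad), class = "sbml_semantic_error")
  # duplicate determination
  dup <- sub('</listOfRules>', paste0(
    '<assignmentRule variable="X">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>1</cn></math>',
    '</assignmentRule></listOfRules>'), base)
  expect_error(load_model(dup), class = "sbml_semantic_error")
  # event assigning to a constant
  evbad <- sub('<eventAssignment variable="S1">',
               '<eventAssignment variable="k">',
               make_fixture("event_basic"))
  expect_error(load_model(evbad), class = "sbml_semantic_error")
})

test_that("loading is reproducible and round-trips through xml2", {
  tags_l3 <- c("decay", "chain", "stiff", "function_def", "piecewise",
               "assignment_rule", "rate_rule", "algebraic_rule",
               "event_basic", "event_priority", "event_persistent",
               "event_delay", "delay_expression", "fast_reaction",
               "boundary_species")
  for (tag in tags_l3) {
    xml <- make_fixture(tag, 3L)
    m1 <- load_model(xml)
    # serialize through xml2 and reload: all fields identical
    rt <- as.character(xml2::read_xml(xml))
    m2 <- load_model(rt)
    expect_identical(m1, m2)
  }
})

test_that("the inlining pass is idempotent on loaded models", {
  m <- load_model(make_fixture("function_def"))
  ast <- m$reactions$J1$kinetic_ast
  expect_identical(inline_function_calls(ast, m$function_defs), ast)
  expect_identical(rewrite_piecewise(ast), ast)
})
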