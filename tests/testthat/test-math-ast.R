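# MathML parsing, AST transforms, RPN compilation and stack evaluation.

mml <- function(body)
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, '</math>')

test_that("MathML constants, identifiers and csymbols parse", {
  expect_equal(parse_mathml(mml('<cn>2.5</cn>'))$payload, 2.5)
  expect_equal(parse_mathml(mml(
    '<cn type="e-notation">2<sep/>3</cn>'))$payload, 2000)
  expect_equal(parse_mathml(mml(
    '<cn type="rational">3<sep/>4</cn>'))$payload, 0.75)
  expect_equal(parse_mathml(mml('<ci> S1 </ci>'))$payload, "S1")
  tm <- parse_mathml(mml(
    '<csymbol definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>'))
  expect_equal(tm$kind, "time")
  expect_error(parse_mathml(mml(
    '<csymbol definitionURL="http://example.org/other">x</csymbol>')),
    class = "sbml_unsupported_error")
})

test_that("n-ary operators fold and log/root honour qualifiers", {
  ctx <- eval_context(values = c(a = 2, b = 3, c = 4))
  val <- function(body) rpn_eval(compile_to_rpn(
    rewrite_piecewise(parse_mathml(mml(body)))), ctx)
  expect_equal(val('<apply><plus/><ci>a</ci><ci>b</ci><ci>c</ci></apply>'), 9)
  expect_equal(val('<apply><times/><ci>a</ci><ci>b</ci><ci>c</ci></apply>'), 24)
  expect_equal(val('<apply><minus/><ci>a</ci></apply>'), -2)
  expect_equal(val('<apply><root/><degree><cn>3</cn></degree><cn>8</cn></apply>'),
               2, tolerance = 1e-12)
  expect_equal(val('<apply><log/><cn>100</cn></apply>'), 2, tolerance = 1e-12)
  expect_equal(val('<apply><log/><logbase><cn>2</cn></logbase><cn>8</cn></apply>'),
               3, tolerance = 1e-12)
  # n-ary relational chains: 1 < b < c is true, 1 < b < 1 is not
  expect_equal(val('<apply><lt/><cn>1</cn><ci>b</ci><ci>c</ci></apply>'), 1)
  expect_equal(val('<apply><lt/><cn>1</cn><ci>b</ci><cn>1</cn></apply>'), 0)
})

test_that("function-definition inlining substitutes structurally", {
  defs <- list(
    f = list(args = "x",
             body = math_op("+", math_name("x"), math_num(1))),
    g = list(args = "y",
             body = math_op("*", math_call("f", math_name("y")), math_num(2))))
  # f(3*a) -> (3*a) + 1
  call <- math_call("f", math_op("*", math_num(3), math_name("a")))
  res <- inline_function_calls(call, defs)
  expect_equal(res$kind, "op")
  expect_equal(res$payload, "+")
  expect_equal(res$children[[1]]$payload, "*")
  expect_equal(res$children[[2]]$payload, 1)
  # nested: g(a) -> (a+1)*2, checked by evaluation on random a
  nested <- inline_function_calls(math_call("g", math_name("a")), defs)
  for (a in runif(5, -10, 10)) {
    got <- rpn_eval(compile_to_rpn(nested), eval_context(values = c(a = a)))
    expect_identical(got, (a + 1) * 2)
  }
  # expression without calls is returned structurally identical
  plain <- math_op("+", math_name("a"), math_num(2))
  expect_identical(inline_function_calls(plain, defs), plain)
})

test_that("inlining rejects arity mismatch and recursion", {
  defs <- list(f = list(args = c("x", "y"),
                        body = math_op("+", math_name("x"), math_name("y"))))
  expect_error(inline_function_calls(math_call("f", math_num(1)), defs),
               class = "sbml_semantic_error")
  rec <- list(h = list(args = "x", body = math_call("h", math_name("x"))))
  expect_error(inline_function_calls(math_call("h", math_num(1)), rec),
               class = "sbml_semantic_error")
  expect_error(inline_function_calls(math_call("nope", math_num(1)), list()),
               class = "sbml_semantic_error")
})

test_that("piecewise rewriting matches first-true-wins semantics", {
  # single branch with otherwise
  pw1 <- math_piecewise(math_num(5),
                        math_rel("gt", math_name("x"), math_num(2)),
                        math_num(1))
  # overlapping conditions, no otherwise
  pw2 <- math_piecewise(math_num(10),
                        math_rel("gt", math_name("x"), math_num(0)),
                        math_num(20),
                        math_rel("gt", math_name("x"), math_num(1)))
  for (pw in list(pw1, pw2)) {
    rw <- rewrite_piecewise(pw)
    expect_false(identical(rw$kind, "piecewise"))
    prog <- compile_to_rpn(rw)
    for (x in seq(-2, 4, by = 0.25)) {
      got <- rpn_eval(prog, eval_context(values = c(x = x)))
      want <- eval_ast_recursive(pw, values = c(x = x))
      expect_identical(got, want)
    }
  }
  # x = 3: first branch wins; x = 0: otherwise
  rw1 <- compile_to_rpn(rewrite_piecewise(pw1))
  expect_equal(rpn_eval(rw1, eval_context(values = c(x = 3))), 5)
  expect_equal(rpn_eval(rw1, eval_context(values = c(x = 0))), 1)
  # x = 2 with overlap: first true branch (10), not 20 or 30
  rw2 <- compile_to_rpn(rewrite_piecewise(pw2))
  expect_equal(rpn_eval(rw2, eval_context(values = c(x = 2))), 10)
  # no condition true, no otherwise -> 0
  expect_equal(rpn_eval(rw2, eval_context(values = c(x = -1))), 0)
})

test_that("RPN compilation is post-order and stack-balanced", {
  # (a+b)*c -> push a, push b, add, push c, mul
  prog <- compile_to_rpn(math_op("*",
                                 math_op("+", math_name("a"), math_name("b")),
                                 math_name("c")))
  expect_equal(prog$ops, c(2L, 2L, 4L, 2L, 6L))
  expect_setequal(prog$referenced_ids, c("a", "b", "c"))
  # single literal
  lit <- compile_to_rpn(math_num(7))
  expect_equal(length(lit$ops), 1L)
  expect_equal(rpn_eval(lit, eval_context()), 7)
  # compilation refuses non-transformed nodes
  expect_error(compile_to_rpn(math_call("f", math_num(1))),
               class = "sbml_semantic_error")
  expect_error(compile_to_rpn(math_piecewise(math_num(1), math_bool(TRUE))),
               class = "sbml_semantic_error")
})

test_that("stack evaluation equals recursive evaluation on random ASTs", {
  set.seed(4711)
  ids <- c("a", "b", "c", "d")
  for (i in 1:300) {
    ast <- random_ast(sample(2:8, 1), ids)
    prog <- compile_to_rpn(ast)
    expect_true(rpn_check_balance(prog))
    ctx <- random_context(ids)
    got <- rpn_eval(prog, ctx)
    want <- eval_ast_recursive(ast, ctx$values, ctx$time)
    expect_identical(got, want)
  }
})

test_that("transforms preserve value where the original is defined", {
  set.seed(99)
  defs <- list(sq = list(args = "u",
                         body = math_op("*", math_name("u"), math_name("u"))))
  for (i in 1:50) {
    base <- random_ast(4, c("a", "b"))
    ast <- math_op("+", math_call("sq", base),
                   math_piecewise(math_num(1),
                                  math_rel("gt", math_name("a"), math_num(0)),
                                  math_num(-1)))
    ctx <- random_context(c("a", "b"))
    transformed <- rewrite_piecewise(inline_function_calls(ast, defs))
    got <- rpn_eval(compile_to_rpn(transformed), ctx)
    want <- eval_ast_recursive(transformed, ctx$values, ctx$time)
    expect_identical(got, want)
  }
})

test_that("evaluation semantics: precedence, booleans, delay, errors", {
  # a + b*c
  prog <- compile_to_rpn(math_op("+", math_name("a"),
                                 math_op("*", math_name("b"), math_name("c"))))
  expect_equal(rpn_eval(prog, eval_context(values = c(a = 2, b = 3, c = 4))),
               14)
  # (x>2) and (x<5)
  band <- compile_to_rpn(math_logic("and",
    math_rel("gt", math_name("x"), math_num(2)),
    math_rel("lt", math_name("x"), math_num(5))))
  expect_identical(rpn_eval(band, eval_context(values = c(x = 3))), 1)
  expect_identical(rpn_eval(band, eval_context(values = c(x = 7))), 0)
  # delay routes through the context lookup
  dly <- compile_to_rpn(math_delay(math_name("S1"), math_num(1.5)))
  expect_true(dly$uses_delay)
  seen <- NULL
  ctx <- eval_context(values = c(S1 = 9),
                      delay_fn = function(sub, lag) { seen <<- lag; 42 })
  expect_equal(rpn_eval(dly, ctx), 42)
  expect_equal(seen, 1.5)
  # division by zero yields Inf, not an error
  div <- compile_to_rpn(math_op("/", math_num(1), math_name("z")))
  expect_identical(rpn_eval(div, eval_context(values = c(z = 0))), Inf)
  # missing identifier is a lookup error
  expect_error(rpn_eval(div, eval_context(values = c(w = 1))),
               class = "sbml_semantic_error")
  # delay without a lookup in the context
  expect_error(rpn_eval(dly, eval_context(values = c(S1 = 1))),
               class = "sbml_semantic_error")
})
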