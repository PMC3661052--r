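# Independent oracles used across the suite.
#
# eval_ast_recursive is a plain tree-walking evaluator, written without
# reference to the package's RPN compiler/stack machine, so the two
# paths can be compared bit for bit.

eval_ast_recursive <- function(node, values = numeric(0), time = 0,
                               delay_fn = NULL) {
  ev <- function(n) eval_ast_recursive(n, values, time, delay_fn)
  truthy <- function(x) x != 0
  switch(node$kind,
    number = node$payload,
    bool = as.numeric(node$payload),
    name = {
      if (!node$payload %in% names(values))
        stop("unresolved id ", node$payload)
      values[[node$payload]]
    },
    time = time,
    op = {
      if (identical(node$payload, "u-")) -ev(node$children[[1]])
      else {
        a <- ev(node$children[[1]]); b <- ev(node$children[[2]])
        switch(node$payload, "+" = a + b, "-" = a - b, "*" = a * b,
               "/" = a / b, "^" = a^b)
      }
    },
    fun = {
      a <- ev(node$children[[1]])
      suppressWarnings(switch(node$payload,
        exp = exp(a), ln = log(a), abs = abs(a), floor = floor(a),
        ceiling = ceiling(a), factorial = gamma(a + 1),
        sin = sin(a), cos = cos(a), tan = tan(a),
        sinh = sinh(a), cosh = cosh(a), tanh = tanh(a),
        arcsin = asin(a), arccos = acos(a), arctan = atan(a),
        sec = 1 / cos(a), csc = 1 / sin(a), cot = 1 / tan(a),
        stop("oracle: unsupported fun ", node$payload)))
    },
    rel = {
      a <- ev(node$children[[1]]); b <- ev(node$children[[2]])
      as.numeric(switch(node$payload, lt = a < b, leq = a <= b,
                        gt = a > b, geq = a >= b, eq = a == b,
                        neq = a != b))
    },
    logic = {
      if (identical(node$payload, "not"))
        as.numeric(!truthy(ev(node$children[[1]])))
      else {
        a <- truthy(ev(node$children[[1]]))
        b <- truthy(ev(node$children[[2]]))
        as.numeric(switch(node$payload, and = a && b, or = a || b,
                          xor = xor(a, b)))
      }
    },
    piecewise = {
      # direct first-true-wins semantics (the pre-rewrite meaning)
      ch <- node$children
      k <- length(ch) %/% 2L
      for (i in seq_len(k))
        if (truthy(ev(ch[[2L * i]]))) return(ev(ch[[2L * i - 1L]]))
      if (length(ch) %% 2L == 1L) ev(ch[[length(ch)]]) else 0
    },
    delay = {
      lag <- ev(node$children[[2]])
      delay_fn(node$children[[1]], lag)
    },
    stop("oracle: unknown kind ", node$kind))
}

# random arithmetic/logical AST over the given identifiers; leans on
# smooth functions so values stay finite most of the time (non-finite
# results are still compared exactly)
random_ast <- function(depth, ids) {
  if (depth <= 0L || runif(1) < 0.25) {
    return(if (runif(1) < 0.5) sbmlsim::math_node("number",
                                                  round(runif(1, -5, 5), 3))
           else sbmlsim::math_node("name", sample(ids, 1)))
  }
  pick <- sample(c("op", "fun", "rel", "logic", "time"), 1,
                 prob = c(0.45, 0.2, 0.15, 0.15, 0.05))
  sub <- function() random_ast(depth - 1L, ids)
  switch(pick,
    time = sbmlsim::math_node("time"),
    op = {
      o <- sample(c("+", "-", "*", "/", "^", "u-"), 1,
                  prob = c(0.3, 0.25, 0.25, 0.1, 0.05, 0.05))
      if (identical(o, "u-")) sbmlsim::math_node("op", "u-", list(sub()))
      else sbmlsim::math_node("op", o, list(sub(), sub()))
    },
    fun = sbmlsim::math_node("fun",
           sample(c("exp", "sin", "cos", "tanh", "abs", "floor"), 1),
           list(sub())),
    rel = sbmlsim::math_node("rel",
           sample(c("lt", "leq", "gt", "geq", "eq", "neq"), 1),
           list(sub(), sub())),
    logic = {
      o <- sample(c("and", "or", "xor", "not"), 1)
      if (identical(o, "not")) sbmlsim::math_node("logic", "not", list(sub()))
      else sbmlsim::math_node("logic", o, list(sub(), sub()))
    })
}

random_context <- function(ids) {
  sbmlsim::eval_context(time = runif(1, 0, 10),
                        values = stats::setNames(runif(length(ids), -3, 3),
                                                 ids))
}
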