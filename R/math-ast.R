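# Math AST: representation, MathML parsing, transformation (function
# inlining, piecewise rewriting), compilation to reverse Polish programs
# and their stack-machine evaluation.

# ---- AST node constructors ----------------------------------------------

#' Construct a math AST node
#'
#' Nodes form the in-memory representation of one SBML MathML expression.
#' `kind` is one of `"number"`, `"name"`, `"time"`, `"avogadro"`, `"bool"`,
#' `"op"` (arithmetic, payload `+ - * / ^` or unary `u-`), `"fun"`
#' (built-in unary function, payload its name), `"rel"` (relational,
#' payload `lt/leq/gt/geq/eq/neq`), `"logic"` (payload `and/or/xor/not`),
#' `"call"` (user FunctionDefinition call, payload the function id),
#' `"piecewise"` (children alternate value, condition, with an optional
#' trailing otherwise) or `"delay"` (children: expression, lag).
#'
#' @param kind node kind (see Details).
#' @param payload literal value, identifier or operator tag.
#' @param children list of child nodes.
#' @return an object of class `sbml_math`.
#' @export
math_node <- function(kind, payload = NULL, children = list()) {
  structure(list(kind = kind, payload = payload, children = children),
            class = "sbml_math")
}

math_num  <- function(x)  math_node("number", as.numeric(x))
math_name <- function(id) math_node("name", as.character(id))
math_time <- function()   math_node("time")
math_bool <- function(x)  math_node("bool", isTRUE(x))
math_op   <- function(op, ...)   math_node("op", op, list(...))
math_fun  <- function(fn, ...)   math_node("fun", fn, list(...))
math_rel  <- function(op, a, b)  math_node("rel", op, list(a, b))
math_logic <- function(op, ...)  math_node("logic", op, list(...))
math_call <- function(id, ...)   math_node("call", id, list(...))
math_delay <- function(expr, lag) math_node("delay", NULL, list(expr, lag))
math_piecewise <- function(...)  math_node("piecewise", NULL, list(...))

#' @export
print.sbml_math <- function(x, ...) {
  cat("<sbml_math> ", ast_deparse(x), "\n", sep = "")
  invisible(x)
}

#' Deparse an AST to an infix string (diagnostics only)
#' @param node an `sbml_math` node.
#' @return a character scalar.
#' @export
ast_deparse <- function(node) {
  ch <- function(i) ast_deparse(node$children[[i]])
  switch(node$kind,
    number = format(node$payload),
    name = node$payload,
    time = "time",
    avogadro = "avogadro",
    bool = if (isTRUE(node$payload)) "true" else "false",
    op = if (identical(node$payload, "u-")) paste0("(-", ch(1), ")")
         else paste0("(", ch(1), " ", node$payload, " ", ch(2), ")"),
    fun = paste0(node$payload, "(", ch(1), ")"),
    rel = paste0("(", ch(1), " ", node$payload, " ", ch(2), ")"),
    logic = if (identical(node$payload, "not")) paste0("not(", ch(1), ")")
            else paste0("(", paste(vapply(node$children, ast_deparse, ""),
                                   collapse = paste0(" ", node$payload, " ")), ")"),
    call = paste0(node$payload, "(", paste(vapply(node$children, ast_deparse, ""),
                                           collapse = ", "), ")"),
    piecewise = paste0("piecewise(", paste(vapply(node$children, ast_deparse, ""),
                                           collapse = ", "), ")"),
    delay = paste0("delay(", ch(1), ", ", ch(2), ")"),
    stop("unknown node kind: ", node$kind))
}

# ---- MathML parsing ------------------------------------------------------

DELAY_URL    <- "http://www.sbml.org/sbml/symbols/delay"
TIME_URL     <- "http://www.sbml.org/sbml/symbols/time"
AVOGADRO_URL <- "http://www.sbml.org/sbml/symbols/avogadro"
AVOGADRO_VALUE <- 6.02214179e23

#' Parse a MathML `<math>` element to an AST
#'
#' Accepts an xml2 node (namespaces may be present or stripped) or a
#' character scalar of MathML. A `<lambda>` body (FunctionDefinition)
#' is returned as `list(args = <character>, body = <sbml_math>)`.
#'
#' @param x xml2 node for `<math>`, or MathML text.
#' @return an `sbml_math` node, or a lambda list for `<lambda>`.
#' @export
parse_mathml <- function(x) {
  if (is.character(x)) x <- xml2::read_xml(x)
  xml2::xml_ns_strip(x)
  kids <- xml2::xml_children(x)
  if (identical(xml2::xml_name(x), "math")) {
    if (length(kids) != 1L)
      stop_sbml("parse", "<math> must contain exactly one expression")
    x <- kids[[1]]
  }
  mathml_to_ast(x)
}

mathml_to_ast <- function(nd) {
  name <- xml2::xml_name(nd)
  switch(name,
    cn = mathml_cn(nd),
    ci = math_name(trimws(xml2::xml_text(nd))),
    csymbol = mathml_csymbol(nd),
    apply = mathml_apply(nd),
    piecewise = mathml_piecewise(nd),
    lambda = mathml_lambda(nd),
    "true" = math_bool(TRUE),
    "false" = math_bool(FALSE),
    pi = math_num(pi),
    exponentiale = math_num(exp(1)),
    infinity = math_num(Inf),
    notanumber = math_num(NaN),
    stop_sbml("unsupported", "unsupported MathML element <", name, ">"))
}

mathml_cn <- function(nd) {
  type <- xml2::xml_attr(nd, "type")
  txt <- xml2::xml_text(nd)
  if (is.na(type) || type %in% c("real", "integer", "double"))
    return(math_num(as.numeric(trimws(txt))))
  # <sep/>-separated forms: mantissa/exponent or numerator/denominator
  parts <- vapply(xml2::xml_find_all(nd, "./text()"),
                  function(x) trimws(xml2::xml_text(x)), "")
  parts <- as.numeric(parts[nzchar(parts)])
  if (type == "e-notation") return(math_num(parts[1] * 10^parts[2]))
  if (type == "rational")   return(math_num(parts[1] / parts[2]))
  stop_sbml("unsupported", "unsupported <cn> type '", type, "'")
}

mathml_csymbol <- function(nd) {
  url <- xml2::xml_attr(nd, "definitionURL")
  if (identical(url, TIME_URL)) return(math_time())
  if (identical(url, AVOGADRO_URL)) return(math_num(AVOGADRO_VALUE))
  stop_sbml("unsupported", "unsupported csymbol '", url, "'")
}

mathml_lambda <- function(nd) {
  kids <- xml2::xml_children(nd)
  names <- xml2::xml_name(kids)
  bvars <- vapply(kids[names == "bvar"],
                  function(b) trimws(xml2::xml_text(b)), "")
  body <- kids[names != "bvar"]
  if (length(body) != 1L)
    stop_sbml("parse", "<lambda> must have exactly one body expression")
  list(args = as.character(bvars), body = mathml_to_ast(body[[1]]))
}

mathml_piecewise <- function(nd) {
  children <- list()
  for (piece in xml2::xml_children(nd)) {
    pn <- xml2::xml_name(piece)
    sub <- xml2::xml_children(piece)
    if (pn == "piece") {
      if (length(sub) != 2L)
        stop_sbml("parse", "<piece> needs value and condition")
      children <- c(children, list(mathml_to_ast(sub[[1]]),
                                   mathml_to_ast(sub[[2]])))
    } else if (pn == "otherwise") {
      if (length(sub) != 1L)
        stop_sbml("parse", "<otherwise> needs one value")
      children <- c(children, list(mathml_to_ast(sub[[1]])))
    } else stop_sbml("parse", "unexpected <", pn, "> inside piecewise")
  }
  math_node("piecewise", NULL, children)
}

# left-fold an n-ary operator into binary nodes
fold_binary <- function(op, args, empty = NULL) {
  if (length(args) == 0L) return(math_num(empty))
  out <- args[[1]]
  for (a in args[-1]) out <- math_op(op, out, a)
  out
}

REL_OPS <- c(lt = "lt", leq = "leq", gt = "gt", geq = "geq",
             eq = "eq", neq = "neq")
UNARY_FUNS <- c("exp", "ln", "abs", "floor", "ceiling", "factorial",
                "sin", "cos", "tan", "sec", "csc", "cot",
                "sinh", "cosh", "tanh", "sech", "csch", "coth",
                "arcsin", "arccos", "arctan", "arcsec", "arccsc", "arccot",
                "arcsinh", "arccosh", "arctanh", "arcsech", "arccsch",
                "arccoth")

mathml_apply <- function(nd) {
  kids <- xml2::xml_children(nd)
  if (length(kids) == 0L) stop_sbml("parse", "empty <apply>")
  head <- kids[[1]]
  hname <- xml2::xml_name(head)
  arg_nodes <- kids[-1]
  qualifier <- xml2::xml_name(arg_nodes) %in% c("degree", "logbase")
  args <- lapply(arg_nodes[!qualifier], mathml_to_ast)
  n <- length(args)

  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    if (identical(url, DELAY_URL)) {
      if (n != 2L) stop_sbml("parse", "delay takes 2 arguments")
      return(math_delay(args[[1]], args[[2]]))
    }
    stop_sbml("unsupported", "unsupported csymbol operator '", url, "'")
  }
  if (hname == "ci")
    return(math_node("call", trimws(xml2::xml_text(head)), args))

  switch(hname,
    plus  = fold_binary("+", args, empty = 0),
    times = fold_binary("*", args, empty = 1),
    minus = {
      if (n == 1L) math_node("op", "u-", args)
      else if (n == 2L) math_op("-", args[[1]], args[[2]])
      else stop_sbml("parse", "minus takes 1 or 2 arguments")
    },
    divide = { stopifnot(n == 2L); math_op("/", args[[1]], args[[2]]) },
    power  = { stopifnot(n == 2L); math_op("^", args[[1]], args[[2]]) },
    root = {
      degree <- xml2::xml_find_first(nd, "./degree")
      if (inherits(degree, "xml_missing")) {
        math_op("^", args[[1]], math_num(0.5))
      } else {
        deg <- mathml_to_ast(xml2::xml_children(degree)[[1]])
        math_op("^", args[[1]], math_op("/", math_num(1), deg))
      }
    },
    log = {
      logbase <- xml2::xml_find_first(nd, "./logbase")
      if (inherits(logbase, "xml_missing")) {
        math_op("/", math_fun("ln", args[[1]]), math_num(log(10)))
      } else {
        base <- mathml_to_ast(xml2::xml_children(logbase)[[1]])
        math_op("/", math_fun("ln", args[[1]]), math_fun("ln", base))
      }
    },
    and = fold_logic("and", args, TRUE),
    or  = fold_logic("or", args, FALSE),
    xor = fold_logic("xor", args, FALSE),
    not = { stopifnot(n == 1L); math_logic("not", args[[1]]) },
    {
      if (hname %in% names(REL_OPS)) {
        if (n < 2L) stop_sbml("parse", hname, " takes >= 2 arguments")
        # n-ary relational chains: a<b<c == (a<b) and (b<c)
        pairs <- lapply(seq_len(n - 1L), function(i)
          math_rel(hname, args[[i]], args[[i + 1L]]))
        fold_logic("and", pairs, TRUE)
      } else if (hname %in% UNARY_FUNS) {
        if (n != 1L) stop_sbml("parse", hname, " takes 1 argument")
        math_fun(hname, args[[1]])
      } else {
        stop_sbml("unsupported", "unsupported MathML operator <", hname, ">")
      }
    })
}

fold_logic <- function(op, args, empty) {
  if (length(args) == 0L) return(math_bool(empty))
  if (length(args) == 1L) return(args[[1]])
  out <- args[[1]]
  for (a in args[-1]) out <- math_logic(op, out, a)
  out
}

# ---- transforms ----------------------------------------------------------

map_children <- function(node, f) {
  node$children <- lapply(node$children, f)
  node
}

#' Inline FunctionDefinition calls
#'
#' Replaces every user-function-call node by the definition body with the
#' actual arguments structurally substituted for the formal parameters
#' (capture-free: a definition body may only reference its own formals
#' and global identifiers, per SBML).
#'
#' @param node an `sbml_math` node.
#' @param defs named list of `list(args = <character>, body = <sbml_math>)`.
#' @return an `sbml_math` node without `call` nodes.
#' @export
inline_function_calls <- function(node, defs) {
  inline_rec(node, defs, character(0))
}

inline_rec <- function(node, defs, expanding) {
  node <- map_children(node, function(ch) inline_rec(ch, defs, expanding))
  if (!identical(node$kind, "call")) return(node)
  fid <- node$payload
  if (fid %in% expanding)
    stop_sbml("semantic", "recursive FunctionDefinition '", fid, "'")
  def <- defs[[fid]]
  if (is.null(def))
    stop_sbml("semantic", "call to undefined function '", fid, "'")
  if (length(def$args) != length(node$children))
    stop_sbml("semantic", "function '", fid, "' called with ",
              length(node$children), " arguments, expects ",
              length(def$args))
  body <- substitute_names(def$body, stats::setNames(node$children, def$args))
  # body may itself contain calls (nested definitions)
  inline_rec(body, defs, c(expanding, fid))
}

substitute_names <- function(node, mapping) {
  if (identical(node$kind, "name") && node$payload %in% names(mapping))
    return(mapping[[node$payload]])
  map_children(node, function(ch) substitute_names(ch, mapping))
}

#' Rewrite piecewise nodes to arithmetic/logical form
#'
#' A k-branch `piecewise(v1,c1,...,vk,ck[,otherwise])` becomes the sum of
#' each value multiplied by its guard, where branch i's guard is
#' `ci AND NOT c1 AND ... AND NOT c(i-1)` (first true branch wins) and the
#' otherwise guard negates every condition. With no otherwise and no true
#' condition the rewritten expression evaluates to 0 (SBML leaves this
#' undefined); a warning is logged at rewrite time.
#'
#' @param node an `sbml_math` node.
#' @return an `sbml_math` node without `piecewise` nodes.
#' @export
rewrite_piecewise <- function(node) {
  node <- map_children(node, rewrite_piecewise)
  if (!identical(node$kind, "piecewise")) return(node)
  ch <- node$children
  has_otherwise <- length(ch) %% 2L == 1L
  k <- length(ch) %/% 2L
  values <- ch[seq_len(k) * 2L - 1L]
  conds  <- ch[seq_len(k) * 2L]
  if (!has_otherwise)
    sbml_log("piecewise without <otherwise>: value is 0 when no condition holds")
  terms <- vector("list", k + has_otherwise)
  for (i in seq_len(k)) {
    guard <- conds[[i]]
    for (j in seq_len(i - 1L))
      guard <- math_logic("and", guard, math_logic("not", conds[[j]]))
    terms[[i]] <- math_op("*", values[[i]], guard)
  }
  if (has_otherwise) {
    guard <- math_logic("not", conds[[1]])
    for (j in seq_len(k)[-1])
      guard <- math_logic("and", guard, math_logic("not", conds[[j]]))
    if (k == 0L) guard <- math_bool(TRUE)
    terms[[k + 1L]] <- math_op("*", ch[[length(ch)]], guard)
  }
  fold_binary("+", terms, empty = 0)
}

# ---- RPN compilation -----------------------------------------------------

# opcodes
OP_PUSH_NUM <- 1L; OP_PUSH_VAR <- 2L; OP_PUSH_TIME <- 3L
OP_ADD <- 4L; OP_SUB <- 5L; OP_MUL <- 6L; OP_DIV <- 7L; OP_POW <- 8L
OP_NEG <- 9L; OP_FUN1 <- 10L; OP_REL <- 11L
OP_AND <- 12L; OP_OR <- 13L; OP_XOR <- 14L; OP_NOT <- 15L
OP_DELAY <- 16L

#' Compile an AST to a reverse Polish program
#'
#' Post-order linearization of the (transformed) AST into a flat
#' instruction list evaluated by [rpn_eval()] on an explicit stack, so
#' expression evaluation never recurses. The compiled program is checked
#' statically for stack balance (net effect +1, no underflow). A delay
#' node compiles its lag inline and carries the delayed expression as an
#' embedded sub-program operand.
#'
#' @param node an `sbml_math` node free of `call` and `piecewise` nodes.
#' @return an object of class `rpn_program` with fields `ops` (integer
#'   opcode vector), `args` (operand list), `referenced_ids` (character),
#'   `uses_delay` (flag).
#' @export
compile_to_rpn <- function(node) {
  ops <- integer(0); args <- list()
  ids <- character(0); uses_delay <- FALSE
  emit <- function(op, arg = NULL) {
    k <- length(ops) + 1L
    ops[k] <<- op
    args[k] <<- list(arg)       # keeps NULL operands as elements
  }
  walk <- function(nd) {
    switch(nd$kind,
      number = emit(OP_PUSH_NUM, nd$payload),
      bool = emit(OP_PUSH_NUM, as.numeric(nd$payload)),
      name = { ids <<- union(ids, nd$payload); emit(OP_PUSH_VAR, nd$payload) },
      time = emit(OP_PUSH_TIME),
      op = {
        if (identical(nd$payload, "u-")) { walk(nd$children[[1]]); emit(OP_NEG) }
        else {
          walk(nd$children[[1]]); walk(nd$children[[2]])
          emit(switch(nd$payload, "+" = OP_ADD, "-" = OP_SUB, "*" = OP_MUL,
                      "/" = OP_DIV, "^" = OP_POW))
        }
      },
      fun = { walk(nd$children[[1]]); emit(OP_FUN1, nd$payload) },
      rel = { walk(nd$children[[1]]); walk(nd$children[[2]])
              emit(OP_REL, nd$payload) },
      logic = {
        if (identical(nd$payload, "not")) { walk(nd$children[[1]]); emit(OP_NOT) }
        else {
          walk(nd$children[[1]]); walk(nd$children[[2]])
          emit(switch(nd$payload, and = OP_AND, or = OP_OR, xor = OP_XOR))
        }
      },
      delay = {
        sub <- compile_to_rpn(nd$children[[1]])
        ids <<- union(ids, sub$referenced_ids)
        uses_delay <<- TRUE
        walk(nd$children[[2]])          # lag on the stack
        emit(OP_DELAY, sub)
      },
      call = stop_sbml("semantic",
        "cannot compile: function call '", nd$payload, "' not inlined"),
      piecewise = stop_sbml("semantic",
        "cannot compile: piecewise not rewritten"),
      stop_sbml("semantic", "unknown AST node kind '", nd$kind, "'"))
  }
  walk(node)
  prog <- structure(list(ops = ops, args = args, referenced_ids = ids,
                         uses_delay = uses_delay),
                    class = "rpn_program")
  if (!rpn_check_balance(prog))
    stop("internal error: compiled program is not stack-balanced")
  prog
}

#' Verify static stack balance of a compiled program
#'
#' @param program an `rpn_program`.
#' @return `TRUE` iff no instruction underflows the stack and the net
#'   stack effect of the whole program is exactly +1.
#' @export
rpn_check_balance <- function(program) {
  depth <- 0L
  for (op in program$ops) {
    need <- if (op %in% c(OP_PUSH_NUM, OP_PUSH_VAR, OP_PUSH_TIME)) 0L
            else if (op %in% c(OP_NEG, OP_FUN1, OP_NOT, OP_DELAY)) 1L
            else 2L
    if (depth < need) return(FALSE)
    depth <- depth - need + 1L
  }
  depth == 1L
}

#' @export
print.rpn_program <- function(x, ...) {
  cat("<rpn_program> ", length(x$ops), " instructions; ids: ",
      paste(x$referenced_ids, collapse = ", "),
      if (x$uses_delay) "; uses delay", "\n", sep = "")
  invisible(x)
}

#' Build an evaluation context
#'
#' @param time current simulation time.
#' @param values named numeric vector of identifier values.
#' @param delay_fn function `(sub_program, lag) -> number` serving delay
#'   lookups, or `NULL` when the expression uses none.
#' @return a list usable as the `ctx` of [rpn_eval()].
#' @export
eval_context <- function(time = 0, values = numeric(0), delay_fn = NULL) {
  list(time = time, values = values, delay_fn = delay_fn)
}

apply_fun1 <- function(fn, a) {
  switch(fn,
    exp = exp(a), ln = log(a), abs = abs(a), floor = floor(a),
    ceiling = ceiling(a), factorial = gamma(a + 1),
    sin = sin(a), cos = cos(a), tan = tan(a),
    sec = 1 / cos(a), csc = 1 / sin(a), cot = 1 / tan(a),
    sinh = sinh(a), cosh = cosh(a), tanh = tanh(a),
    sech = 1 / cosh(a), csch = 1 / sinh(a), coth = 1 / tanh(a),
    arcsin = asin(a), arccos = acos(a), arctan = atan(a),
    arcsec = acos(1 / a), arccsc = asin(1 / a), arccot = atan(1 / a),
    arcsinh = asinh(a), arccosh = acosh(a), arctanh = atanh(a),
    arcsech = acosh(1 / a), arccsch = asinh(1 / a), arccoth = atanh(1 / a),
    stop_sbml("unsupported", "unknown builtin function '", fn, "'"))
}

#' Evaluate a reverse Polish program
#'
#' Runs the stack machine over the instruction list. Relational and
#' logical opcodes produce 1.0/0.0; any nonzero operand counts as true.
#' Division by zero and out-of-domain function arguments propagate as
#' IEEE infinities/NaN without raising an error.
#'
#' @param program an `rpn_program` from [compile_to_rpn()].
#' @param ctx context from [eval_context()]; must resolve every id in
#'   `program$referenced_ids`, and supply `delay_fn` if the program uses
#'   delay.
#' @return a double scalar.
#' @export
rpn_eval <- function(program, ctx) {
  ops <- program$ops; args <- program$args
  st <- numeric(16L + length(ops)); sp <- 0L
  vals <- ctx$values; vnames <- names(vals)
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == OP_PUSH_NUM) {
      sp <- sp + 1L; st[sp] <- args[[k]]
    } else if (op == OP_PUSH_VAR) {
      i <- match(args[[k]], vnames)
      if (is.na(i))
        stop_sbml("semantic", "identifier '", args[[k]],
                  "' not resolvable in evaluation context")
      sp <- sp + 1L; st[sp] <- vals[[i]]
    } else if (op == OP_PUSH_TIME) {
      sp <- sp + 1L; st[sp] <- ctx$time
    } else if (op == OP_ADD) {
      st[sp - 1L] <- st[sp - 1L] + st[sp]; sp <- sp - 1L
    } else if (op == OP_SUB) {
      st[sp - 1L] <- st[sp - 1L] - st[sp]; sp <- sp - 1L
    } else if (op == OP_MUL) {
      st[sp - 1L] <- st[sp - 1L] * st[sp]; sp <- sp - 1L
    } else if (op == OP_DIV) {
      st[sp - 1L] <- st[sp - 1L] / st[sp]; sp <- sp - 1L
    } else if (op == OP_POW) {
      st[sp - 1L] <- st[sp - 1L]^st[sp]; sp <- sp - 1L
    } else if (op == OP_NEG) {
      st[sp] <- -st[sp]
    } else if (op == OP_FUN1) {
      st[sp] <- suppressWarnings(apply_fun1(args[[k]], st[sp]))
    } else if (op == OP_REL) {
      a <- st[sp - 1L]; b <- st[sp]; sp <- sp - 1L
      st[sp] <- as.numeric(switch(args[[k]],
        lt = a < b, leq = a <= b, gt = a > b, geq = a >= b,
        eq = a == b, neq = a != b))
    } else if (op == OP_AND) {
      st[sp - 1L] <- as.numeric(st[sp - 1L] != 0 && st[sp] != 0); sp <- sp - 1L
    } else if (op == OP_OR) {
      st[sp - 1L] <- as.numeric(st[sp - 1L] != 0 || st[sp] != 0); sp <- sp - 1L
    } else if (op == OP_XOR) {
      st[sp - 1L] <- as.numeric(xor(st[sp - 1L] != 0, st[sp] != 0)); sp <- sp - 1L
    } else if (op == OP_NOT) {
      st[sp] <- as.numeric(st[sp] == 0)
    } else if (op == OP_DELAY) {
      if (is.null(ctx$delay_fn))
        stop_sbml("semantic", "expression uses delay() but the context ",
                  "provides no delay lookup")
      st[sp] <- ctx$delay_fn(args[[k]], st[sp])
    }
  }
  st[sp]
}

# collect every identifier referenced in an AST (excluding bound names)
ast_identifiers <- function(node) {
  if (identical(node$kind, "name")) return(node$payload)
  if (identical(node$kind, "call"))
    return(unique(c(node$payload,
                    unlist(lapply(node$children, ast_identifiers)))))
  unique(unlist(lapply(node$children, ast_identifiers)))
}
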