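# Boolean expression parsing: a small recursive-descent parser so that
# syntax errors can name the offending token and position (R's own
# parser would accept too much and report too little).
#
# Grammar (OR binds loosest):
#   expr   := term  (OR  term)*
#   term   := factor (AND factor)*
#   factor := NOT factor | '(' expr ')' | variable | '0' | '1'
# Operators: & / AND / ∧, | / OR / ∨, ! / NOT (case-insensitive
# keywords); variables are [A-Za-z_][A-Za-z0-9_.]*.

.bf_tokenize <- function(expr) {
  tokens <- list()
  i <- 1L
  n <- nchar(expr)
  push <- function(type, text, pos)
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = text, pos = pos)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "∧")) { push("AND", ch, i); i <- i + 1L; next }
    if (ch %in% c("|", "∨")) { push("OR", ch, i); i <- i + 1L; next }
    if (ch == "!") { push("NOT", ch, i); i <- i + 1L; next }
    if (ch == "(") { push("LP", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("RP", ch, i); i <- i + 1L; next }
    if (ch %in% c("0", "1")) { push("CONST", ch, i); i <- i + 1L; next }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j < n && grepl("^[A-Za-z0-9_.]$", substr(expr, j + 1L, j + 1L)))
        j <- j + 1L
      word <- substr(expr, i, j)
      upper <- toupper(word)
      if (upper == "AND") push("AND", word, i)
      else if (upper == "OR") push("OR", word, i)
      else if (upper == "NOT") push("NOT", word, i)
      else push("VAR", word, i)
      i <- j + 1L
      next
    }
    stop(sprintf("parse error: unexpected character '%s' at position %d",
                 ch, i))
  }
  tokens
}

# parse to a nested list AST: list(op = "var"/"const"/"not"/"and"/"or", ...)
.bf_parse <- function(expr) {
  tokens <- .bf_tokenize(expr)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect_fail <- function(what) {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("parse error: expected %s but expression ended", what))
    stop(sprintf("parse error: expected %s but found '%s' at position %d",
                 what, tok$text, tok$pos))
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) expect_fail("a variable, constant, NOT or '('")
    if (tok$type == "NOT") {
      advance()
      return(list(op = "not", arg = parse_factor()))
    }
    if (tok$type == "LP") {
      advance()
      node <- parse_expr()
      if (is.null(peek()) || peek()$type != "RP") expect_fail("')'")
      advance()
      return(node)
    }
    if (tok$type == "VAR") {
      advance()
      return(list(op = "var", name = tok$text, pos = tok$pos))
    }
    if (tok$type == "CONST") {
      advance()
      return(list(op = "const", value = as.integer(tok$text)))
    }
    expect_fail("a variable, constant, NOT or '('")
  }
  ast <- parse_expr()
  if (!is.null(peek())) {
    tok <- peek()
    stop(sprintf("parse error: unexpected '%s' at position %d",
                 tok$text, tok$pos))
  }
  ast
}

.bf_ast_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = .bf_ast_vars(ast$arg),
         unique(c(.bf_ast_vars(ast$lhs), .bf_ast_vars(ast$rhs))))
}

# evaluate AST over all rows; env maps variable name -> 0/1 column vector
.bf_ast_eval <- function(ast, env) {
  switch(ast$op,
         var = env[[ast$name]],
         const = rep(ast$value, length(env[[1L]])),
         not = 1L - .bf_ast_eval(ast$arg, env),
         and = .bf_ast_eval(ast$lhs, env) * .bf_ast_eval(ast$rhs, env),
         or = {
           a <- .bf_ast_eval(ast$lhs, env)
           b <- .bf_ast_eval(ast$rhs, env)
           pmax(a, b)
         })
}

#' Truth table from a Boolean expression
#'
#' Builds the output vector of a Boolean expression over an ordered list of
#' input names.  Every name in \code{var_order} contributes one input slot
#' even if it does not occur in the expression (such inputs become dummies).
#'
#' @param expr expression text using \code{&}/\code{AND}, \code{|}/\code{OR},
#'   \code{!}/\code{NOT} and parentheses; keywords are case-insensitive.
#' @param var_order character vector of input names, \code{x_1} first.
#' @return a \code{\link{boolfn}} with \code{k = length(var_order)} inputs and
#'   attribute \code{"var_order"}.
#' @examples
#' bf_from_expression("x1 & x2", c("x1", "x2"))                  # "0001"
#' bf_from_expression("x1 & (!x2 | x3)", c("x1", "x2", "x3"))    # "00001101"
#' @export
bf_from_expression <- function(expr, var_order) {
  stopifnot(is.character(expr), length(expr) == 1L,
            is.character(var_order), length(var_order) >= 1L,
            !anyDuplicated(var_order))
  ast <- .bf_parse(expr)
  used <- .bf_ast_vars(ast)
  unknown <- setdiff(used, var_order)
  if (length(unknown) > 0L)
    stop("unknown variable(s) in expression: ",
         paste(unknown, collapse = ", "))
  k <- length(var_order)
  env <- stats::setNames(
    lapply(seq_len(k), function(i) .input_column(k, i)), var_order)
  if (length(used) == 0L)                       # constant expression
    env <- stats::setNames(list(rep(0L, 2^k)), "..dummy")
  out <- .bf_ast_eval(ast, env)
  f <- boolfn(as.integer(out), k)
  attr(f, "var_order") <- var_order
  f
}
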