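# AQL subset parser.
#
# Supported grammar (EBNF):
#   query    = SELECT selitem { "," selitem }
#              FROM EHR ident { CONTAINS rmtype ident [ "[" archetype_id "]" ] }
#              [ WHERE cond ] ;
#   selitem  = varpath [ AS ident ] ;
#   varpath  = ident { "/" step } ;            step = name [ "[at" digits "]" ]
#   cond     = or ;  or = and { OR and } ;  and = not { AND not } ;
#   not      = NOT not | "(" or ")" | predicate ;
#   predicate= EXISTS varpath
#            | varpath cmp literal
#            | varpath ( MATCHES | IN ) "{" literal { "," literal } "}" ;
#   cmp      = "=" | "!=" | ">" | ">=" | "<" | "<=" ;
# Keywords are case-insensitive; identifiers and archetype ids are
# case-sensitive.  ORDER BY and TIMEWINDOW are recognised and rejected as
# unsupported clauses.

AQL_KEYWORDS <- c("SELECT", "FROM", "CONTAINS", "WHERE", "AND", "OR", "NOT",
                  "AS", "EHR", "MATCHES", "IN", "EXISTS", "ORDER", "TIMEWINDOW")

aql_tokenize <- function(text) {
  patterns <- c(
    WS      = "[ \t\r\n]+",
    STRING  = "'[^']*'|\"[^\"]*\"",
    NUMBER  = "[0-9]+(\\.[0-9]+)?",
    BRACKET = "\\[[^]\n]*\\]",
    BRACE   = "[{}]",
    IDENT   = "[A-Za-z_][A-Za-z0-9_]*",
    OP      = ">=|<=|!=|=|>|<",
    PUNCT   = "[,/()]")
  tokens <- list()
  pos <- 1L; n <- nchar(text)
  line <- 1L; col <- 1L
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (ty in names(patterns)) {
      m <- regmatches(rest, regexpr(paste0("^(", patterns[[ty]], ")"), rest))
      if (length(m) && nchar(m)) {
        if (ty != "WS") {
          tokens[[length(tokens) + 1L]] <-
            list(type = ty, text = m, line = line, col = col)
        }
        nl <- gregexpr("\n", m, fixed = TRUE)[[1L]]
        if (nl[1L] != -1L) {
          line <- line + length(nl)
          col <- nchar(m) - nl[length(nl)] + 1L
        } else {
          col <- col + nchar(m)
        }
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("syntax error at line %d, column %d: unexpected character %s",
                   line, col, sQuote(substring(text, pos, pos))))
    }
  }
  tokens
}

# Cursor over the token stream.
aql_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens; env$i <- 1L
  env
}
tk_peek <- function(cur) {
  if (cur$i > length(cur$tokens)) NULL else cur$tokens[[cur$i]]
}
tk_next <- function(cur) {
  t <- tk_peek(cur); if (!is.null(t)) cur$i <- cur$i + 1L; t
}
tk_err <- function(tok, what) {
  if (is.null(tok)) stop("syntax error at end of input: expected ", what)
  stop(sprintf("syntax error at line %d, column %d: expected %s, found %s",
               tok$line, tok$col, what, sQuote(tok$text)))
}
is_kw <- function(tok, kw) {
  !is.null(tok) && tok$type == "IDENT" && toupper(tok$text) == kw
}
expect_kw <- function(cur, kw) {
  t <- tk_next(cur)
  if (!is_kw(t, kw)) tk_err(t, kw)
  t
}
is_punct <- function(tok, ch) !is.null(tok) && tok$text == ch

# varpath = ident { "/" step }; the leading ident is the variable.
parse_varpath <- function(cur) {
  t <- tk_next(cur)
  if (is.null(t) || t$type != "IDENT") tk_err(t, "variable")
  if (toupper(t$text) %in% AQL_KEYWORDS) tk_err(t, "variable")
  var <- t$text
  steps <- character(0)
  while (is_punct(tk_peek(cur), "/")) {
    tk_next(cur)
    s <- tk_next(cur)
    if (is.null(s) || s$type != "IDENT") tk_err(s, "path step")
    step <- s$text
    nxt <- tk_peek(cur)
    if (!is.null(nxt) && nxt$type == "BRACKET" &&
        grepl("^\\[at[0-9]+\\]$", nxt$text)) {
      step <- paste0(step, nxt$text)
      tk_next(cur)
    }
    steps <- c(steps, step)
  }
  list(variable = var, path = steps)
}

parse_literal <- function(cur) {
  t <- tk_next(cur)
  if (is.null(t)) tk_err(t, "literal")
  if (t$type == "NUMBER") return(as.double(t$text))
  if (t$type == "STRING") return(substr(t$text, 2L, nchar(t$text) - 1L))
  tk_err(t, "literal")
}

parse_predicate <- function(cur) {
  t <- tk_peek(cur)
  if (is_kw(t, "EXISTS")) {
    tk_next(cur)
    vp <- parse_varpath(cur)
    return(list(op = "pred", variable = vp$variable, path = vp$path,
                operator = "exists", value = NULL))
  }
  if (is_punct(t, "(")) {
    tk_next(cur)
    inner <- parse_or(cur)
    cl <- tk_next(cur)
    if (!is_punct(cl, ")")) tk_err(cl, "')'")
    return(inner)
  }
  if (is_kw(t, "NOT")) {
    tk_next(cur)
    return(list(op = "not", arg = parse_predicate(cur)))
  }
  vp <- parse_varpath(cur)
  t <- tk_next(cur)
  if (is.null(t)) tk_err(t, "comparison operator")
  if (t$type == "OP") {
    val <- parse_literal(cur)
    return(list(op = "pred", variable = vp$variable, path = vp$path,
                operator = t$text, value = val))
  }
  if (is_kw(t, "MATCHES") || is_kw(t, "IN")) {
    ob <- tk_next(cur)
    if (!is_punct(ob, "{")) tk_err(ob, "'{'")
    vals <- list(parse_literal(cur))
    while (is_punct(tk_peek(cur), ",")) {
      tk_next(cur)
      vals[[length(vals) + 1L]] <- parse_literal(cur)
    }
    cb <- tk_next(cur)
    if (!is_punct(cb, "}")) tk_err(cb, "'}'")
    return(list(op = "pred", variable = vp$variable, path = vp$path,
                operator = "matches", value = vals))
  }
  tk_err(t, "comparison operator")
}

parse_and <- function(cur) {
  args <- list(parse_predicate(cur))
  while (is_kw(tk_peek(cur), "AND")) {
    tk_next(cur)
    args[[length(args) + 1L]] <- parse_predicate(cur)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

parse_or <- function(cur) {
  args <- list(parse_and(cur))
  while (is_kw(tk_peek(cur), "OR")) {
    tk_next(cur)
    args[[length(args) + 1L]] <- parse_and(cur)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

#' Parse an AQL query into a query object model
#'
#' The location (containment) part, the selection and the optional condition
#' are kept separate so that the location part can be handed to the index
#' service on its own.
#'
#' @param text AQL query string (see the grammar in the package sources and
#'   the methods vignette).
#' @return An `aql_query` object with elements `selection`, `location`,
#'   `condition` (`NULL` when absent).
#' @export
parse_aql <- function(text) {
  cur <- aql_cursor(aql_tokenize(text))
  expect_kw(cur, "SELECT")
  items <- list()
  repeat {
    vp <- parse_varpath(cur)
    alias <- NA_character_
    if (is_kw(tk_peek(cur), "AS")) {
      tk_next(cur)
      a <- tk_next(cur)
      if (is.null(a) || a$type != "IDENT") tk_err(a, "alias")
      alias <- a$text
    }
    items[[length(items) + 1L]] <-
      list(variable = vp$variable, path = vp$path, alias = alias)
    if (is_punct(tk_peek(cur), ",")) tk_next(cur) else break
  }
  expect_kw(cur, "FROM")
  expect_kw(cur, "EHR")
  ev <- tk_next(cur)
  if (is.null(ev) || ev$type != "IDENT") tk_err(ev, "EHR variable")
  chain <- list()
  while (is_kw(tk_peek(cur), "CONTAINS")) {
    tk_next(cur)
    rm <- tk_next(cur)
    if (is.null(rm) || rm$type != "IDENT") tk_err(rm, "reference-model type")
    v <- tk_next(cur)
    if (is.null(v) || v$type != "IDENT") tk_err(v, "containment variable")
    pattern <- NA_character_
    nxt <- tk_peek(cur)
    if (!is.null(nxt) && nxt$type == "BRACKET") {
      pattern <- substr(nxt$text, 2L, nchar(nxt$text) - 1L)
      tk_next(cur)
    }
    chain[[length(chain) + 1L]] <-
      list(variable = v$text, rm_type = rm$text, pattern = pattern)
  }
  condition <- NULL
  t <- tk_peek(cur)
  if (is_kw(t, "WHERE")) {
    tk_next(cur)
    condition <- parse_or(cur)
    t <- tk_peek(cur)
  }
  if (is_kw(t, "ORDER") || is_kw(t, "TIMEWINDOW")) {
    stop("unsupported clause: ", toupper(t$text),
         " is not implemented in this AQL subset")
  }
  if (!is.null(t)) tk_err(t, "end of query")
  qom <- structure(
    list(selection = list(items = items),
         location = list(ehr_variable = ev$text, chain = chain),
         condition = condition),
    class = "aql_query")
  check_bindings(qom)
  qom
}

bound_variables <- function(qom) {
  c(qom$location$ehr_variable,
    vapply(qom$location$chain, `[[`, character(1), "variable"))
}

check_bindings <- function(qom) {
  bound <- bound_variables(qom)
  if (anyDuplicated(bound)) {
    stop("binding error: duplicate variable ",
         sQuote(bound[duplicated(bound)][1L]))
  }
  for (it in qom$selection$items) {
    if (!(it$variable %in% bound)) {
      stop("binding error: unbound variable ", sQuote(it$variable),
           " in SELECT")
    }
  }
  check_cond <- function(cond) {
    if (is.null(cond)) return(invisible())
    if (cond$op == "pred") {
      if (!(cond$variable %in% bound)) {
        stop("binding error: unbound variable ", sQuote(cond$variable),
             " in WHERE")
      }
    } else if (cond$op == "not") {
      check_cond(cond$arg)
    } else {
      for (a in cond$args) check_cond(a)
    }
  }
  check_cond(qom$condition)
  invisible(qom)
}

#' @export
print.aql_query <- function(x, ...) {
  cat(render_aql(x), "\n")
  invisible(x)
}

# -- rendering ----------------------------------------------------------------

aql_num_to_str <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

render_varpath <- function(variable, path) {
  paste0(variable, path_render(path))
}

render_literal <- function(v) {
  if (is.character(v)) paste0("'", v, "'") else aql_num_to_str(v)
}

render_cond <- function(cond, parent = "or") {
  if (cond$op == "pred") {
    vp <- render_varpath(cond$variable, cond$path)
    return(switch(cond$operator,
      exists = paste0("EXISTS ", vp),
      matches = paste0(vp, " MATCHES {",
                       paste(vapply(cond$value, render_literal, character(1)),
                             collapse = ", "), "}"),
      paste0(vp, " ", cond$operator, " ", render_literal(cond$value))))
  }
  if (cond$op == "not") {
    inner <- render_cond(cond$arg, parent = "not")
    if (cond$arg$op %in% c("and", "or")) inner <- paste0("(", inner, ")")
    return(paste0("NOT ", inner))
  }
  sep <- if (cond$op == "and") " AND " else " OR "
  parts <- vapply(cond$args, function(a) {
    s <- render_cond(a, parent = cond$op)
    if (cond$op == "and" && a$op == "or") s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Render a query object model to canonical AQL text
#'
#' `parse_aql(render_aql(q))` reproduces `q` exactly.
#'
#' @param qom An `aql_query`.
#' @return A one-line AQL string.
#' @export
render_aql <- function(qom) {
  stopifnot(inherits(qom, "aql_query"))
  sel <- vapply(qom$selection$items, function(it) {
    s <- render_varpath(it$variable, it$path)
    if (!is.na(it$alias)) s <- paste0(s, " AS ", it$alias)
    s
  }, character(1))
  from <- paste0("FROM EHR ", qom$location$ehr_variable)
  for (c in qom$location$chain) {
    from <- paste0(from, " CONTAINS ", c$rm_type, " ", c$variable,
                   if (!is.na(c$pattern)) paste0(" [", c$pattern, "]") else "")
  }
  out <- paste0("SELECT ", paste(sel, collapse = ", "), " ", from)
  if (!is.null(qom$condition)) {
    out <- paste0(out, " WHERE ", render_cond(qom$condition))
  }
  out
}

#' Containment chain of a query
#'
#' Extracts the location part handed to the index service: one class pattern
#' per CONTAINS, in FROM order.  A CONTAINS without a bracketed archetype id
#' contributes the wildcard pattern `"*"`.
#'
#' @param qom An `aql_query`.
#' @return A [containment_chain()]; empty chain for a query without
#'   CONTAINS (the engine then falls back to the full registry).
#' @export
location_of <- function(qom) {
  stopifnot(inherits(qom, "aql_query"))
  patterns <- vapply(qom$location$chain, function(c) {
    if (is.na(c$pattern)) "*" else c$pattern
  }, character(1))
  containment_chain(patterns)
}

#' Containment level of a query
#' @param qom An `aql_query`.
#' @return Number of CONTAINS clauses.
#' @export
containment_level <- function(qom) {
  length(qom$location$chain)
}
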