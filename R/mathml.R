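# Content-MathML <-> R expression translation for SBML kinetic laws.
# Only the constructs used by plain kinetic ODE models are supported;
# time-delay csymbols are rejected as unsupported.

.MATHML_BINOPS <- c(plus = "+", minus = "-", times = "*", divide = "/",
                    power = "^")
.MATHML_FUNS <- c(exp = "exp", abs = "abs", floor = "floor",
                  ceiling = "ceiling", sin = "sin", cos = "cos", tan = "tan",
                  arcsin = "asin", arccos = "acos", arctan = "atan",
                  sinh = "sinh", cosh = "cosh", tanh = "tanh",
                  factorial = "factorial")
.MATHML_RELOPS <- c(lt = "<", leq = "<=", gt = ">", geq = ">=",
                    eq = "==", neq = "!=")
.MATHML_LOGIC <- c(and = "&", or = "|", xor = "xor")

#' Parse a content-MathML node into an R expression
#'
#' @param node an `xml2` node: either `<math>` or the expression root.
#' @return an R language object (or numeric/logical scalar).
#' @noRd
mathml_to_expr <- function(node) {
  kids <- xml2::xml_find_all(node, "./*")
  if (xml2::xml_name(node) == "math") {
    if (length(kids) != 1L) stop("malformed MathML: <math> must wrap one expression",
                                 call. = FALSE)
    return(mathml_to_expr(kids[[1L]]))
  }
  nm <- xml2::xml_name(node)
  if (nm == "ci") {
    return(as.name(trimws(xml2::xml_text(node))))
  }
  if (nm == "cn") {
    return(.parse_cn(node))
  }
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (grepl("time$", url %||% "")) return(as.name("time"))
    if (grepl("delay$", url %||% "")) {
      stop("unsupported construct: delay csymbol", call. = FALSE)
    }
    stop(sprintf("unsupported construct: csymbol '%s'", url), call. = FALSE)
  }
  if (nm == "exponentiale") return(exp(1))
  if (nm == "pi") return(pi)
  if (nm == "true") return(TRUE)
  if (nm == "false") return(FALSE)
  if (nm == "notanumber") return(NaN)
  if (nm == "infinity") return(Inf)
  if (nm == "piecewise") return(.parse_piecewise(node))
  if (nm == "apply") return(.parse_apply(node))
  if (nm == "lambda") {
    bvars <- xml2::xml_find_all(node, "./bvar/ci")
    args <- vapply(bvars, function(b) trimws(xml2::xml_text(b)), character(1))
    body_nodes <- xml2::xml_find_all(node, "./*[not(self::bvar)]")
    if (length(body_nodes) != 1L) stop("malformed MathML lambda", call. = FALSE)
    return(list(args = args, body = mathml_to_expr(body_nodes[[1L]])))
  }
  stop(sprintf("unsupported MathML element <%s>", nm), call. = FALSE)
}

.parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type %in% c("e-notation", "rational")) {
    # the two numbers are the text nodes on either side of <sep/>
    parts <- trimws(vapply(xml2::xml_contents(node), as.character, character(1)))
    parts <- parts[nzchar(parts) & !grepl("^<", parts)]
    if (length(parts) != 2L) stop("malformed <cn> with <sep/>", call. = FALSE)
    a <- as.numeric(parts[1]); b <- as.numeric(parts[2])
    return(if (type == "e-notation") a * 10^b else a / b)
  }
  as.numeric(trimws(xml2::xml_text(node)))
}

.parse_piecewise <- function(node) {
  pieces <- xml2::xml_find_all(node, "./piece")
  other <- xml2::xml_find_all(node, "./otherwise")
  expr <- if (length(other) == 1L) {
    kids <- xml2::xml_find_all(other[[1L]], "./*")
    mathml_to_expr(kids[[1L]])
  } else {
    NaN
  }
  for (p in rev(pieces)) {
    kids <- xml2::xml_find_all(p, "./*")
    if (length(kids) != 2L) stop("malformed <piece>", call. = FALSE)
    val <- mathml_to_expr(kids[[1L]])
    cond <- mathml_to_expr(kids[[2L]])
    expr <- call("ifelse", cond, val, expr)
  }
  expr
}

.parse_apply <- function(node) {
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1L]])
  argn <- kids[-1L]

  if (op == "ci") {  # user-defined function call (functionDefinition)
    fname <- trimws(xml2::xml_text(kids[[1L]]))
    args <- lapply(argn, mathml_to_expr)
    return(as.call(c(as.name(fname), args)))
  }
  if (op %in% names(.MATHML_BINOPS)) {
    args <- lapply(argn, mathml_to_expr)
    if (op == "minus" && length(args) == 1L) return(call("-", args[[1L]]))
    if (length(args) == 0L) stop(sprintf("malformed <apply> %s", op), call. = FALSE)
    if (length(args) == 1L) return(args[[1L]])
    out <- args[[1L]]
    for (a in args[-1L]) out <- call(.MATHML_BINOPS[[op]], out, a)
    return(out)
  }
  if (op %in% names(.MATHML_RELOPS) || op %in% names(.MATHML_LOGIC)) {
    sym <- c(.MATHML_RELOPS, .MATHML_LOGIC)[[op]]
    args <- lapply(argn, mathml_to_expr)
    out <- call(sym, args[[1L]], args[[2L]])
    for (a in args[-(1:2)]) out <- call(sym, out, a)
    return(out)
  }
  if (op == "not") return(call("!", mathml_to_expr(argn[[1L]])))
  if (op %in% names(.MATHML_FUNS)) {
    return(call(.MATHML_FUNS[[op]], mathml_to_expr(argn[[1L]])))
  }
  if (op == "ln") return(call("log", mathml_to_expr(argn[[1L]])))
  if (op == "log") {
    base_node <- xml2::xml_find_all(node, "./logbase/*")
    arg <- mathml_to_expr(argn[[length(argn)]])
    base <- if (length(base_node) == 1L) mathml_to_expr(base_node[[1L]]) else 10
    return(call("log", arg, base))
  }
  if (op == "root") {
    deg_node <- xml2::xml_find_all(node, "./degree/*")
    arg <- mathml_to_expr(argn[[length(argn)]])
    if (length(deg_node) == 0L) return(call("sqrt", arg))
    deg <- mathml_to_expr(deg_node[[1L]])
    if (identical(deg, 2) || identical(deg, 2L)) return(call("sqrt", arg))
    return(call("^", arg, call("/", 1, deg)))
  }
  if (op %in% c("min", "max")) {
    args <- lapply(argn, mathml_to_expr)
    return(as.call(c(as.name(if (op == "min") "pmin" else "pmax"), args)))
  }
  stop(sprintf("unsupported MathML operator <%s>", op), call. = FALSE)
}

#' Inline user-defined function calls (SBML functionDefinitions)
#' @param e expression; @param funs named list of list(args, body)
#' @noRd
inline_function_calls <- function(e, funs) {
  if (length(funs) == 0L) return(e)
  walk <- function(x) {
    if (!is.call(x)) return(x)
    for (i in seq_along(x)[-1L]) x[[i]] <- walk(x[[i]])
    fn <- as.character(x[[1L]])
    if (fn %in% names(funs)) {
      def <- funs[[fn]]
      args <- as.list(x)[-1L]
      if (length(args) != length(def$args)) {
        stop(sprintf("function '%s' called with %d args, defined with %d",
                     fn, length(args), length(def$args)), call. = FALSE)
      }
      sub_env <- setNames(args, def$args)
      body <- def$body
      subst <- function(b) {
        if (is.name(b)) {
          nm <- as.character(b)
          if (nm %in% names(sub_env)) return(sub_env[[nm]])
          return(b)
        }
        if (is.call(b)) for (i in seq_along(b)[-1L]) b[[i]] <- subst(b[[i]])
        b
      }
      return(walk(subst(body)))
    }
    x
  }
  walk(e)
}

# ---- R expression -> MathML -------------------------------------------------

.R_TO_MATHML_OP <- c(`+` = "plus", `-` = "minus", `*` = "times",
                     `/` = "divide", `^` = "power")
.R_TO_MATHML_REL <- c(`<` = "lt", `<=` = "leq", `>` = "gt", `>=` = "geq",
                      `==` = "eq", `!=` = "neq", `&` = "and", `|` = "or")
.R_TO_MATHML_FUN <- c(exp = "exp", abs = "abs", floor = "floor",
                      ceiling = "ceiling", sin = "sin", cos = "cos",
                      tan = "tan", asin = "arcsin", acos = "arccos",
                      atan = "arctan", sinh = "sinh", cosh = "cosh",
                      tanh = "tanh", sqrt = "root", factorial = "factorial")

#' Serialize an R expression as content MathML (no <math> wrapper)
#' @noRd
expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (length(e) != 1L) stop("non-scalar constant in kinetic law", call. = FALSE)
    if (is.finite(e) && e == round(e) && abs(e) < 1e15) {
      return(sprintf("<cn type=\"integer\"> %d </cn>", as.integer(e)))
    }
    return(sprintf("<cn> %s </cn>", .fmt_num(e)))
  }
  if (is.logical(e)) return(if (e) "<true/>" else "<false/>")
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm == "time") {
      return(paste0("<csymbol encoding=\"text\" definitionURL=",
                    "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>"))
    }
    if (nm == "pi") return("<pi/>")
    return(sprintf("<ci> %s </ci>", .xml_escape(nm)))
  }
  if (!is.call(e)) stop("unsupported kinetic-law construct", call. = FALSE)
  fn <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  wrap <- function(op, parts) {
    paste0("<apply><", op, "/>", paste0(parts, collapse = ""), "</apply>")
  }
  if (fn %in% names(.R_TO_MATHML_OP)) {
    return(wrap(.R_TO_MATHML_OP[[fn]], vapply(args, expr_to_mathml, character(1))))
  }
  if (fn %in% names(.R_TO_MATHML_REL)) {
    return(wrap(.R_TO_MATHML_REL[[fn]], vapply(args, expr_to_mathml, character(1))))
  }
  if (fn == "!") return(wrap("not", expr_to_mathml(args[[1L]])))
  if (fn == "log") {
    if (length(args) == 1L) return(wrap("ln", expr_to_mathml(args[[1L]])))
    base <- args[[2L]]
    return(paste0("<apply><log/><logbase>", expr_to_mathml(base),
                  "</logbase>", expr_to_mathml(args[[1L]]), "</apply>"))
  }
  if (fn == "sqrt") return(wrap("root", expr_to_mathml(args[[1L]])))
  if (fn %in% names(.R_TO_MATHML_FUN)) {
    return(wrap(.R_TO_MATHML_FUN[[fn]], expr_to_mathml(args[[1L]])))
  }
  if (fn %in% c("pmin", "pmax")) {
    return(wrap(if (fn == "pmin") "min" else "max",
                vapply(args, expr_to_mathml, character(1))))
  }
  if (fn == "ifelse") {
    return(paste0("<piecewise><piece>", expr_to_mathml(args[[2L]]),
                  expr_to_mathml(args[[1L]]), "</piece><otherwise>",
                  expr_to_mathml(args[[3L]]), "</otherwise></piecewise>"))
  }
  if (fn == "(") return(expr_to_mathml(args[[1L]]))
  stop(sprintf("cannot serialize '%s' to MathML", fn), call. = FALSE)
}
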