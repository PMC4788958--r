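`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats setNames runif
#' @importFrom utils head tail modifyList
NULL

.fmt_num <- function(x) {
  # shortest representation that survives a text round trip
  vapply(x, function(v) {
    if (is.na(v)) return("NaN")
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# ---- expression helpers -----------------------------------------------------

#' Symbols referenced by an expression, in order of first appearance
#' @noRd
expr_symbols <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (is.name(x)) {
      out[[length(out) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      for (i in seq_along(x)[-1L]) walk(x[[i]])
    }
  }
  walk(e)
  unique(out)
}

#' Rename symbols in an expression according to a named character map
#' @noRd
substitute_symbols <- function(e, map) {
  if (length(map) == 0L) return(e)
  walk <- function(x) {
    if (is.name(x)) {
      nm <- as.character(x)
      if (nm %in% names(map)) return(as.name(map[[nm]]))
      return(x)
    }
    if (is.call(x)) {
      for (i in seq_along(x)[-1L]) x[[i]] <- walk(x[[i]])
    }
    x
  }
  walk(e)
}

#' Canonical form of an expression: n-ary flattening of + and * with
#' operands sorted lexicographically. Used for symbolic kinetic-law
#' equivalence; no numerical probing.
#' @noRd
canonical_expr <- function(e) {
  flatten <- function(x, op) {
    if (is.call(x) && identical(as.character(x[[1L]]), op) && length(x) == 3L) {
      c(flatten(x[[2L]], op), flatten(x[[3L]], op))
    } else {
      list(canonical_expr(x))
    }
  }
  rebuild <- function(parts, op) {
    parts <- parts[order(vapply(parts, function(p) paste(deparse(p), collapse = ""),
                                character(1)))]
    out <- parts[[1L]]
    for (p in parts[-1L]) out <- call(op, out, p)
    out
  }
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  if (op %in% c("+", "*") && length(e) == 3L) {
    return(rebuild(flatten(e, op), op))
  }
  for (i in seq_along(e)[-1L]) e[[i]] <- canonical_expr(e[[i]])
  e
}

expr_equivalent <- function(a, b) {
  identical(paste(deparse(canonical_expr(a)), collapse = ""),
            paste(deparse(canonical_expr(b)), collapse = ""))
}

#' Normalize a URI vector: names are MIRIAM qualifiers, default "is"
#' @noRd
.norm_uris <- function(uris) {
  if (length(uris) == 0) return(character(0))
  nm <- names(uris)
  if (is.null(nm)) nm <- rep("", length(uris))
  nm[!nzchar(nm)] <- "is"
  setNames(as.character(uris), nm)
}

.stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
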