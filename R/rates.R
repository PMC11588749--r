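# Rate-expression mini-language.
#
# Channel kinetics are declared as strings over the membrane voltage V and
# named parameters, so user-defined channels can be written in configuration
# files without executing arbitrary code. The whitelist is deliberately
# small: arithmetic, exp/log, and vtrap() for the removable singularity
# x/(exp(x/y) - 1) that the classic rate functions contain.

RATE_EXPR_FUNS <- c("+", "-", "*", "/", "^", "(", "exp", "log", "vtrap")

#' Guarded x/(exp(x/y) - 1)
#'
#' The form `x / (exp(x/y) - 1)` appears in classic voltage-dependent rate
#' functions and has a removable singularity at `x = 0`. Near zero it is
#' evaluated by its series `y * (1 - u/2 + u^2/12)` with `u = x/y`, which is
#' accurate to ~1e-28 for `|u| < 1e-7`.
#'
#' @param x,y Numeric vectors (recycled).
#' @return `x / (exp(x/y) - 1)` evaluated stably.
#' @export
vtrap <- function(x, y) {
  u <- x / y
  small <- abs(u) < 1e-7
  out <- numeric(length(u))
  if (any(!small)) out[!small] <- (x / (exp(u) - 1))[!small]
  if (any(small)) out[small] <- (y * (1 - u / 2 + u * u / 12))[small]
  out
}

#' Compile a rate-expression string into a function of voltage
#'
#' Parses `expr_string`, checks every symbol against the whitelist (`V`, the
#' names in `params`, numbers, arithmetic operators, `exp`, `log`,
#' [vtrap()]), and returns a vectorized function `f(V)` in ms^-1 (or ms for
#' time constants, dimensionless for steady states).
#'
#' @param expr_string A single character string, e.g.
#'   `"0.1 * vtrap(-(V + 40), 10)"`.
#' @param params Named list/vector of numeric parameters the expression may
#'   reference.
#' @return A function of one numeric vector argument `V` (mV).
#' @export
rate_expr <- function(expr_string, params = list()) {
  stopifnot(is.character(expr_string), length(expr_string) == 1L)
  e <- tryCatch(str2lang(expr_string),
                error = function(err) stop("cannot parse rate expression '",
                                           expr_string, "': ", conditionMessage(err)))
  allowed <- c("V", names(params))
  check <- function(x) {
    if (is.call(x)) {
      fn <- as.character(x[[1L]])
      if (!fn %in% RATE_EXPR_FUNS)
        stop("function '", fn, "' not allowed in rate expression '", expr_string, "'")
      for (a in as.list(x)[-1L]) check(a)
    } else if (is.symbol(x)) {
      if (!as.character(x) %in% allowed)
        stop("unknown symbol '", as.character(x), "' in rate expression '",
             expr_string, "' (allowed: V", if (length(params)) paste0(", ",
             paste(names(params), collapse = ", ")), ")")
    } else if (!is.numeric(x)) {
      stop("disallowed element in rate expression '", expr_string, "'")
    }
    invisible(TRUE)
  }
  check(e)
  env <- list2env(as.list(params), parent = baseenv())
  env$vtrap <- vtrap
  f <- function(V) {
    env2 <- new.env(parent = env)
    env2$V <- V
    eval(e, env2)
  }
  attr(f, "expr") <- expr_string
  attr(f, "params") <- params
  f
}
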