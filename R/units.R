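# Light-weight unit tagging. Every material-property result carries a unit
# string; adding, subtracting or comparing quantities with different units
# is an error (no silent unit coercion). Multiplication/division combine
# the tags textually.

#' Unit-tagged quantity
#'
#' @param value numeric value(s).
#' @param unit unit string, e.g. `"kPa"`, `"g (m2 h)-1"`.
#' @return object of class `qty`.
#' @examples
#' qty(19.65, "g (m2 h)-1")
#' @export
qty <- function(value, unit) {
  structure(as.numeric(value), unit = as.character(unit), class = "qty")
}

#' @export
print.qty <- function(x, ...) {
  cat(format(unclass(x)), attr(x, "unit"), "\n")
  invisible(x)
}

#' @export
format.qty <- function(x, ...) {
  paste(format(unclass(x), ...), attr(x, "unit"))
}

qty_unit <- function(x) attr(x, "unit") %||% ""

#' @export
Ops.qty <- function(e1, e2) {
  if (missing(e2)) return(qty(get(.Generic)(unclass(e1)), qty_unit(e1)))
  u1 <- if (inherits(e1, "qty")) qty_unit(e1) else NULL
  u2 <- if (inherits(e2, "qty")) qty_unit(e2) else NULL
  if (.Generic %in% c("+", "-", "==", "!=", "<", ">", "<=", ">=")) {
    if (!is.null(u1) && !is.null(u2) && !identical(u1, u2))
      mycomat_error("unit_mismatch", sprintf(
        "cannot combine '%s' and '%s' with `%s`", u1, u2, .Generic))
    r <- get(.Generic)(unclass(e1), unclass(e2))
    if (.Generic %in% c("+", "-")) qty(r, u1 %||% u2) else r
  } else if (.Generic == "*") {
    qty(unclass(e1) * unclass(e2), trimws(paste(u1 %||% "", u2 %||% "")))
  } else if (.Generic == "/") {
    u <- if (is.null(u2)) u1 %||% "" else paste0(u1 %||% "", " (", u2, ")-1")
    qty(unclass(e1) / unclass(e2), trimws(u))
  } else {
    get(.Generic)(unclass(e1), unclass(e2))
  }
}

#' Numeric value of a quantity
#' @param x a `qty` (or plain numeric).
#' @return bare numeric.
#' @export
qty_value <- function(x) as.numeric(unclass(x))
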