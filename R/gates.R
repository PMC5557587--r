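#' Truth tables for Boolean update functions
#'
#' A truth table stores the value of a Boolean function B(x_1, ..., x_N) at
#' each of the 2^N Boolean input tuples.  Tuples are ordered with the first
#' input as the fastest-cycling bit, i.e. row r (1-based) encodes the tuple
#' \code{(bit0(r-1), bit1(r-1), ...)}.
#'
#' @param arity number of inputs N (>= 1)
#' @param values vector of 2^N values in \{0,1\}, in tuple order
#' @return an object of class \code{truth_table}
#' @examples
#' or2  <- truth_table_or(2)
#' and2 <- truth_table_and(2)
#' boolcube_eval(or2, c(0.5, 0.5))   # 0.75
#' @export
truth_table <- function(arity, values) {
  arity <- as.integer(arity)
  if (arity < 1L) stop("truth table arity must be >= 1")
  values <- as.numeric(values)
  if (length(values) != 2L^arity)
    stop("truth table needs exactly 2^N = ", 2L^arity, " values, got ",
         length(values))
  if (!all(values %in% c(0, 1)))
    stop("truth table values must be 0 or 1")
  structure(list(arity = arity, values = values), class = "truth_table")
}

#' @rdname truth_table
#' @export
truth_table_or <- function(arity) {
  tup <- .bool_tuples(arity)
  truth_table(arity, as.numeric(rowSums(tup) > 0))
}

#' @rdname truth_table
#' @export
truth_table_and <- function(arity) {
  tup <- .bool_tuples(arity)
  truth_table(arity, as.numeric(rowSums(tup) == arity))
}

# all 2^N Boolean tuples as a matrix, first column fastest-cycling
.bool_tuples <- function(arity) {
  idx <- 0:(2L^arity - 1L)
  m <- vapply(seq_len(arity),
              function(b) bitwAnd(bitwShiftR(idx, b - 1L), 1L),
              integer(length(idx)))
  matrix(m, nrow = length(idx), ncol = arity)
}

#' Multilinear (BoolCube) interpolation of a Boolean function
#'
#' Evaluates the unique multilinear polynomial interpolating the truth table
#' on the vertices of the unit hypercube:
#' \deqn{\bar B(\bar x) = \sum_{x \in \{0,1\}^N} B(x) \prod_i
#'       \left[x_i \bar x_i + (1 - x_i)(1 - \bar x_i)\right].}
#' The interpolation is exact at every Boolean vertex and affine in each
#' coordinate.
#'
#' @param table a \code{truth_table}
#' @param xbar numeric vector of length N with entries in [0,1]
#' @param strict if \code{TRUE} (default) entries outside [0,1] are an error;
#'   if \code{FALSE} they are clamped into [0,1]
#' @return scalar in [0,1]
#' @export
boolcube_eval <- function(table, xbar, strict = TRUE) {
  stopifnot(inherits(table, "truth_table"))
  if (length(xbar) != table$arity)
    stop("xbar has length ", length(xbar), ", expected ", table$arity)
  if (any(xbar < 0 | xbar > 1)) {
    if (strict) stop("xbar entries must lie in [0,1] (use strict = FALSE to clamp)")
    xbar <- pmin(pmax(xbar, 0), 1)
  }
  tup <- .bool_tuples(table$arity)
  # weight of vertex x: prod_i [x_i xbar_i + (1-x_i)(1-xbar_i)]
  w <- apply(tup, 1L, function(x) prod(x * xbar + (1 - x) * (1 - xbar)))
  sum(table$values * w)
}

#' Hill and normalized Hill transfer functions
#'
#' \code{hill} is the standard Hill function \eqn{x^n / (x^n + k^n)};
#' \code{normalized_hill} rescales it by its value at 1 so that the unit
#' interval maps onto itself with fixed endpoints,
#' \eqn{f_{Hn}(x) = f_H(x) / f_H(1)}.
#'
#' @param x input in [0,1] (vectorised)
#' @param n Hill exponent, n > 0
#' @param k half-saturation constant, k > 0; \code{hill(k, n, k) == 0.5}
#' @return value(s) in [0,1)
#' @export
hill <- function(x, n, k) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("Hill exponent n must be > 0")
  if (any(!is.finite(k)) || any(k <= 0)) stop("half-saturation k must be > 0")
  xn <- x^n
  out <- xn / (xn + k^n)
  out[x == 0] <- 0  # avoid 0/0 when n is tiny
  out
}

#' @rdname hill
#' @export
normalized_hill <- function(x, n, k) {
  hill(x, n, k) / hill(1, n, k)
}

#' HillCube evaluation of a gate
#'
#' Substitutes a (normalized) Hill transform for each gate input before the
#' multilinear interpolation: activating inputs enter as \eqn{f(\bar x_i)},
#' inhibiting inputs as \eqn{1 - f(\bar x_i)}.  With \code{normalized = TRUE}
#' the result reproduces the truth-table value exactly at every Boolean
#' vertex.
#'
#' @param table a \code{truth_table}
#' @param xbar numeric vector of raw inputs in [0,1]
#' @param gate_params matrix (or data.frame) with one row per input and
#'   columns \code{n}, \code{k}
#' @param signs vector of +1 (activation) / -1 (inhibition), one per input
#' @param normalized use the normalized Hill function (default \code{TRUE})
#' @param strict passed to \code{\link{boolcube_eval}}
#' @return scalar in [0,1]
#' @export
hillcube_eval <- function(table, xbar, gate_params, signs = rep(1, length(xbar)),
                          normalized = TRUE, strict = TRUE) {
  stopifnot(inherits(table, "truth_table"))
  gate_params <- as.matrix(gate_params)
  if (nrow(gate_params) != table$arity || length(signs) != table$arity ||
      length(xbar) != table$arity)
    stop("need one input value, one (n,k) pair and one sign per gate input (arity ",
         table$arity, ")")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  f <- if (normalized) normalized_hill else hill
  z <- f(xbar, gate_params[, 1L], gate_params[, 2L])
  z <- ifelse(signs > 0, z, 1 - z)
  boolcube_eval(table, z, strict = strict)
}
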