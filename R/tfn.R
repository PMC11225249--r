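#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is defined by an ordered triple
#' \eqn{(a_1, a_2, a_3)} with \eqn{a_1 \le a_2 \le a_3}: membership rises
#' linearly from 0 at \eqn{a_1} to 1 at the vertex \eqn{a_2} and falls back
#' to 0 at \eqn{a_3}. `tfn()` builds a vector of TFNs from the three defining
#' points; all arithmetic and summaries in the package are vectorized over
#' such objects. Degenerate triples \eqn{a_1 = a_2 = a_3} are permitted so
#' that crisp numbers embed into fuzzy arithmetic.
#'
#' @param a1,a2,a3 Numeric vectors (recycled to common length) with
#'   `a1 <= a2 <= a3` elementwise; all values must be finite.
#' @return An object of class `"tfn"`: a numeric matrix with columns
#'   `a1`, `a2`, `a3`, one row per fuzzy number.
#' @examples
#' tfn(0, 0.5, 1)
#' tfn(c(0, 1), c(1, 2), c(2, 4))
#' @export
tfn <- function(a1, a2, a3) {
  n <- max(length(a1), length(a2), length(a3))
  a1 <- rep_len(as.double(a1), n)
  a2 <- rep_len(as.double(a2), n)
  a3 <- rep_len(as.double(a3), n)
  if (any(!is.finite(a1)) || any(!is.finite(a2)) || any(!is.finite(a3))) {
    stop("TFN defining points must all be finite", call. = FALSE)
  }
  bad12 <- which(a1 > a2)
  if (length(bad12)) {
    stop(sprintf("invalid TFN at position %d: a1 = %g > a2 = %g",
                 bad12[1L], a1[bad12[1L]], a2[bad12[1L]]), call. = FALSE)
  }
  bad23 <- which(a2 > a3)
  if (length(bad23)) {
    stop(sprintf("invalid TFN at position %d: a2 = %g > a3 = %g",
                 bad23[1L], a2[bad23[1L]], a3[bad23[1L]]), call. = FALSE)
  }
  structure(cbind(a1 = a1, a2 = a2, a3 = a3), class = "tfn")
}

#' @rdname tfn
#' @param x Object to test or coerce.
#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' @rdname tfn
#' @export
as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  if (is.numeric(x)) return(tfn(x, x, x))  # crisp embedding
  stop("cannot coerce to tfn", call. = FALSE)
}

tfn_n <- function(A) nrow(unclass(A))

#' @export
length.tfn <- function(x) nrow(unclass(x))

#' @export
`[.tfn` <- function(x, i, ...) {
  m <- unclass(x)[i, , drop = FALSE]
  structure(m, class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  m <- unclass(x)
  cat(sprintf("<tfn[%d]>\n", nrow(m)))
  show <- utils::head(m, 10L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  (%g, %g, %g)\n", show[i, 1L], show[i, 2L], show[i, 3L]))
  }
  if (nrow(m) > 10L) cat(sprintf("  ... %d more\n", nrow(m) - 10L))
  invisible(x)
}

#' @export
format.tfn <- function(x, digits = 4, ...) {
  m <- unclass(x)
  sprintf("(%s, %s, %s)",
          format(m[, 1L], digits = digits, trim = TRUE),
          format(m[, 2L], digits = digits, trim = TRUE),
          format(m[, 3L], digits = digits, trim = TRUE))
}

#' @export
as.matrix.tfn <- function(x, ...) unclass(x)

#' Alpha-cut of a triangular fuzzy number
#'
#' The \eqn{\alpha}-cut of a fuzzy set is the crisp interval of points with
#' membership at least \eqn{\alpha}. For a TFN \eqn{(a_1,a_2,a_3)} it is
#' \eqn{[a_1 + \alpha(a_2-a_1),\; a_3 - \alpha(a_3-a_2)]}; \eqn{\alpha = 0}
#' returns the support and \eqn{\alpha = 1} the vertex.
#'
#' @param A A [tfn] vector.
#' @param alpha Membership level in \[0, 1\].
#' @return A data frame with columns `lower`, `upper`, `alpha`, one row per
#'   fuzzy number.
#' @examples
#' alpha_cut(tfn(0, 1, 2), 0.5)
#' @export
alpha_cut <- function(A, alpha) {
  A <- as_tfn(A)
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  m <- unclass(A)
  data.frame(lower = unname(m[, 1L] + alpha * (m[, 2L] - m[, 1L])),
             upper = unname(m[, 3L] - alpha * (m[, 3L] - m[, 2L])),
             alpha = alpha, row.names = NULL)
}

#' TFN arithmetic
#'
#' Interval-based arithmetic on triangular fuzzy numbers. Addition and
#' subtraction are exact under the extension principle:
#' \eqn{A \oplus B = (a_1+b_1, a_2+b_2, a_3+b_3)} and
#' \eqn{A \ominus B = (a_1-b_3, a_2-b_2, a_3-b_1)}. The product of two TFNs
#' is generally not triangular; `*` re-triangularizes it by keeping the
#' vertex product \eqn{a_2 b_2} and the exact support (\eqn{\alpha = 0})
#' interval product, whose endpoints are the extrema of the four endpoint
#' products. Plain numerics are embedded as crisp (degenerate) TFNs, so
#' `2 * A` and `A + 1` work as expected.
#'
#' @param e1,e2 [tfn] vectors or numerics.
#' @return A [tfn] vector.
#' @examples
#' tfn(1, 2, 3) + tfn(0, 1, 2)
#' tfn(0.2, 0.3, 0.4) - tfn(0.4, 0.5, 0.6)
#' tfn(-1, 1, 2) * tfn(1, 2, 3)
#' @export
Ops.tfn <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*")) {
    stop(sprintf("operation `%s` is not defined for tfn objects", .Generic),
         call. = FALSE)
  }
  if (missing(e2)) {  # unary
    a <- unclass(as_tfn(e1))
    if (.Generic == "+") return(e1)
    return(tfn(-a[, 3L], -a[, 2L], -a[, 1L]))
  }
  a <- unclass(as_tfn(e1))
  b <- unclass(as_tfn(e2))
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  switch(.Generic,
    "+" = tfn(a[, 1L] + b[, 1L], a[, 2L] + b[, 2L], a[, 3L] + b[, 3L]),
    "-" = tfn(a[, 1L] - b[, 3L], a[, 2L] - b[, 2L], a[, 3L] - b[, 1L]),
    "*" = {
      p11 <- a[, 1L] * b[, 1L]; p13 <- a[, 1L] * b[, 3L]
      p31 <- a[, 3L] * b[, 1L]; p33 <- a[, 3L] * b[, 3L]
      tfn(pmin(p11, p13, p31, p33), a[, 2L] * b[, 2L],
          pmax(p11, p13, p31, p33))
    })
}

#' Expected value of a TFN
#'
#' Returns the Dubois–Prade mean value of a triangular fuzzy number. The
#' cited mean is interval-valued; this function returns its midpoint
#' \eqn{(a_1 + 2 a_2 + a_3) / 4}, which equals the membership-weighted mean
#' of the triangle and reduces to \eqn{c} for a crisp value \eqn{(c,c,c)}.
#'
#' @param A A [tfn] vector.
#' @return Numeric vector of expected values.
#' @examples
#' expected_value(tfn(0.4, 0.5, 0.6))  # 0.5
#' expected_value(tfn(0, 0, 1))        # 0.25
#' @export
expected_value <- function(A) {
  m <- unclass(as_tfn(A))
  (m[, 1L] + 2 * m[, 2L] + m[, 3L]) / 4
}

#' Center-of-gravity defuzzification
#'
#' Collapses a TFN to a crisp number by equal weighting of its three defining
#' points, \eqn{(a_1 + a_2 + a_3)/3} — the centroid abscissa of the
#' membership triangle. Used to turn fuzzy regression coefficients into crisp
#' estimates for interpretation.
#'
#' @param A A [tfn] vector.
#' @return Numeric vector of crisp values.
#' @examples
#' defuzzify_cog(tfn(-1.796, -1.308, -0.593))  # -1.232
#' @export
defuzzify_cog <- function(A) {
  m <- unclass(as_tfn(A))
  (m[, 1L] + m[, 2L] + m[, 3L]) / 3
}

#' Width (support length) of a TFN
#'
#' The degree of fuzziness of a TFN is the length of its support interval,
#' \eqn{a_3 - a_1}; a crisp value has width 0.
#'
#' @param A A [tfn] vector.
#' @return Nonnegative numeric vector.
#' @export
tfn_width <- function(A) {
  m <- unclass(as_tfn(A))
  m[, 3L] - m[, 1L]
}

#' Pointwise error between two TFN vectors
#'
#' Elementwise discrepancy between observed and predicted TFNs, averaged over
#' the defining points: with `points = "all"` the mean over the three
#' points of \eqn{|a_i - b_i|} (`kind = "absolute"`) or \eqn{(a_i - b_i)^2}
#' (`kind = "squared"`); with `points = "vertex"` only the vertices are
#' compared. This is the per-observation term of the MAE/MSE/RMSE
#' optimization measures used when fitting the fuzzy logistic regression.
#'
#' @param A,B [tfn] vectors of equal length.
#' @param kind `"absolute"` or `"squared"`.
#' @param points `"all"` (default) compares all three defining points,
#'   `"vertex"` only the vertices.
#' @return Numeric vector of nonnegative errors, one per pair.
#' @examples
#' tfn_error(tfn(0, 1, 2), tfn(1, 1, 3), kind = "squared")  # 2/3
#' @export
tfn_error <- function(A, B, kind = c("absolute", "squared"),
                      points = c("all", "vertex")) {
  kind <- match.arg(kind)
  points <- match.arg(points)
  a <- unclass(as_tfn(A))
  b <- unclass(as_tfn(B))
  if (nrow(a) != nrow(b)) {
    stop("`A` and `B` must have the same length", call. = FALSE)
  }
  d <- a - b
  if (points == "vertex") d <- d[, 2L, drop = FALSE]
  if (kind == "absolute") rowMeans(abs(d)) else rowMeans(d * d)
}
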