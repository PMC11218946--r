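## Alexander polynomial from a knot diagram, and knot classification.
##
## Polynomials in t are integer coefficient vectors, lowest power first.
## Determinants are computed with fraction-free (Bareiss) elimination over
## Z[t], which keeps every intermediate entry an exact integer polynomial.

poly_trim <- function(p) {
  nz <- which(abs(p) > 0.5)
  if (!length(nz)) return(numeric(0))
  p[seq_len(max(nz))]
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  poly_trim(a + b)
}

poly_sub <- function(a, b) poly_add(a, -b)

poly_mul <- function(a, b) {
  if (!length(a) || !length(b)) return(numeric(0))
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a)) {
    if (a[k] != 0) {
      idx <- k:(k + length(b) - 1L)
      out[idx] <- out[idx] + a[k] * b
    }
  }
  poly_trim(out)
}

## Exact division a / b in Z[t]; Bareiss guarantees divisibility.
poly_divexact <- function(a, b) {
  if (!length(b)) stop("polynomial division by zero")
  if (!length(a)) return(numeric(0))
  a <- rev(a)  # highest power first for long division
  b <- rev(b)
  if (length(a) < length(b)) stop("inexact polynomial division")
  q <- numeric(length(a) - length(b) + 1L)
  for (k in seq_along(q)) {
    q[k] <- a[k] / b[1]
    idx <- k:(k + length(b) - 1L)
    a[idx] <- a[idx] - q[k] * b
  }
  if (length(a) > length(q) &&
      any(abs(a[(length(q) + 1L):length(a)]) > 1e-6))
    stop("inexact polynomial division")
  q <- round(rev(q))
  poly_trim(q)
}

poly_is_zero <- function(p) !length(p)

## Determinant of a square matrix of polynomials (list-of-rows of coef
## vectors) via fraction-free Gaussian elimination with row pivoting.
poly_det <- function(M) {
  n <- length(M)
  if (n == 0L) return(c(1))
  sgn <- 1
  prev <- c(1)
  for (k in seq_len(n - 1L)) {
    if (poly_is_zero(M[[k]][[k]])) {
      piv <- NULL
      for (r in (k + 1L):n) if (!poly_is_zero(M[[r]][[k]])) { piv <- r; break }
      if (is.null(piv)) return(numeric(0))
      tmp <- M[[k]]; M[[k]] <- M[[piv]]; M[[piv]] <- tmp
      sgn <- -sgn
    }
    for (i in (k + 1L):n) {
      for (j in (k + 1L):n) {
        num <- poly_sub(poly_mul(M[[i]][[j]], M[[k]][[k]]),
                        poly_mul(M[[i]][[k]], M[[k]][[j]]))
        M[[i]][[j]] <- if (poly_is_zero(num)) num else poly_divexact(num, prev)
      }
      M[[i]][[k]] <- numeric(0)
    }
    prev <- M[[k]][[k]]
  }
  d <- M[[n]][[n]]
  if (sgn < 0) d <- -d
  d
}

## Normalize an Alexander determinant up to units +-t^k: strip powers of t
## and make the constant term positive.
alexander_normalize <- function(p) {
  p <- poly_trim(round(p))
  if (!length(p)) return(c(0))
  first <- which(p != 0)[1]
  p <- p[first:length(p)]
  if (p[1] < 0) p <- -p
  as.numeric(p)
}

#' Alexander polynomial of a knot diagram
#'
#' Builds the Alexander matrix from the diagram's crossing relations (one row
#' per crossing, one column per arc; entries `1-t`, `t`, `-1` placed according
#' to crossing sign), deletes one row and one column, and evaluates the
#' determinant exactly over the integer polynomial ring. The result is
#' normalized up to units \eqn{\pm t^k} so that the constant term is positive.
#'
#' @param diagram a knot diagram as returned by [project_to_diagram()].
#' @return integer coefficient vector, lowest power first; `1` for a
#'   crossing-free (unknot) diagram.
#' @seealso [classify_knot()], [project_to_diagram()]
#' @export
alexander_polynomial <- function(diagram) {
  n <- diagram$n_crossings
  if (n == 0L) return(c(1))
  cr <- diagram$crossings
  zero <- numeric(0)
  one_minus_t <- c(1, -1)
  tpoly <- c(0, 1)
  M <- vector("list", n)
  for (r in seq_len(n)) {
    row <- rep(list(zero), n)
    o <- cr$over_arc[r]; i <- cr$under_in[r]; j <- cr$under_out[r]
    add <- function(col, p) row[[col]] <<- poly_add(row[[col]], p)
    add(o, one_minus_t)
    if (cr$sign[r] > 0) {
      add(i, tpoly); add(j, c(-1))
    } else {
      add(i, c(-1)); add(j, tpoly)
    }
    M[[r]] <- row
  }
  ## delete last row and last column
  if (n == 1L) return(c(1))
  Msub <- lapply(M[-n], function(row) row[-n])
  d <- poly_det(Msub)
  alexander_normalize(d)
}

## Alexander polynomials of prime knots through 7 crossings (normalized,
## positive constant term, lowest power first).
.knot_table <- list(
  "3_1" = c(1, -1, 1),
  "4_1" = c(1, -3, 1),
  "5_1" = c(1, -1, 1, -1, 1),
  "5_2" = c(2, -3, 2),
  "6_1" = c(2, -5, 2),
  "6_2" = c(1, -3, 3, -3, 1),
  "6_3" = c(1, -3, 5, -3, 1),
  "7_1" = c(1, -1, 1, -1, 1, -1, 1),
  "7_2" = c(3, -5, 3),
  "7_3" = c(2, -3, 3, -3, 2),
  "7_4" = c(4, -7, 4),
  "7_5" = c(2, -4, 5, -4, 2),
  "7_6" = c(1, -5, 7, -5, 1),
  "7_7" = c(1, -5, 9, -5, 1)
)

#' Classify a knot from its Alexander polynomial
#'
#' Table lookup over the prime knots through 7 crossings; within this range
#' the Alexander polynomial separates all types, so each lookup yields a
#' single label. Polynomials not in the table (composites, knots with 8+
#' crossings) yield `"unknown"`.
#'
#' @param coeffs normalized Alexander coefficient vector.
#' @return a knot label: `"unknot"`, `"3_1"` ... `"7_7"`, or `"unknown"`.
#' @export
classify_knot <- function(coeffs) {
  coeffs <- alexander_normalize(coeffs)
  if (identical(as.numeric(coeffs), 1)) return("unknot")
  hits <- names(.knot_table)[vapply(.knot_table, function(p) {
    identical(as.numeric(p), as.numeric(coeffs)) ||
      identical(as.numeric(rev(p)), as.numeric(coeffs))
  }, logical(1))]
  if (!length(hits)) return("unknown")
  paste(hits, collapse = "|")
}

#' Knot determinant
#'
#' The Alexander polynomial evaluated at \eqn{t = -1}, in absolute value.
#' It is odd for every knot and equals 1 for the unknot.
#'
#' @param coeffs Alexander coefficient vector, lowest power first.
#' @return a non-negative integer.
#' @export
knot_determinant <- function(coeffs) {
  abs(sum(coeffs * (-1)^(seq_along(coeffs) - 1L)))
}
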