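## Independent oracles used by the tests. These deliberately do not call the
## package's own polynomial or decomposition code paths.

## Exact polynomial division with integer coefficients (lowest power first).
oracle_polydiv <- function(num, den) {
  num <- rev(num); den <- rev(den)
  q <- numeric(length(num) - length(den) + 1L)
  for (k in seq_along(q)) {
    q[k] <- num[k] / den[1]
    idx <- k:(k + length(den) - 1L)
    num[idx] <- num[idx] - q[k] * den
  }
  stopifnot(all(abs(num[-seq_along(q)]) < 1e-9))
  rev(q)
}

## t^n - 1 as a coefficient vector.
tn_minus_1 <- function(n) c(-1, rep(0, n - 1L), 1)

## Closed-form Alexander polynomial of the (p, q) torus knot:
## (t^{pq} - 1)(t - 1) / ((t^p - 1)(t^q - 1)), normalized to positive
## constant term with no t factor.
oracle_alexander_torus <- function(p, q) {
  mul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (k in seq_along(a)) out[k:(k + length(b) - 1L)] <-
        out[k:(k + length(b) - 1L)] + a[k] * b
    out
  }
  num <- mul(tn_minus_1(p * q), c(-1, 1))
  den <- mul(tn_minus_1(p), tn_minus_1(q))
  co <- round(oracle_polydiv(num, den))
  first <- which(co != 0)[1]
  co <- co[first:length(co)]
  if (co[1] < 0) co <- -co
  co
}

## Closed-form Alexander polynomials of the twist-knot family, indexed by
## the number of half-twists m (m = 1 trefoil, 2 figure-eight, ...):
## odd m: ((m+1)/2, -m, (m+1)/2); even m: (m/2, -(m+1), m/2).
oracle_alexander_twist <- function(m) {
  if (m %% 2 == 1) c((m + 1) / 2, -m, (m + 1) / 2)
  else c(m / 2, -(m + 1), m / 2)
}

## Independent stack-based bracket matcher (single- and multi-layer).
oracle_bracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  alphabets <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  out <- NULL
  for (ab in alphabets) {
    st <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == ab[1]) st <- c(st, k)
      if (chars[k] == ab[2]) {
        out <- rbind(out, c(st[length(st)], k))
        st <- st[-length(st)]
      }
    }
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  out[order(out[, 1]), , drop = FALSE]
}

## Parametric figure-eight knot (closed).
fig8_curve <- function(n = 240) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  P <- cbind((2 + cos(2 * t)) * cos(3 * t),
             (2 + cos(2 * t)) * sin(3 * t),
             sin(4 * t))
  rbind(P, P[1, ])
}

## Two exactly interlocked circles (Hopf link) with analytic linking +-1.
hopf_circles <- function(r = 5, n = 60) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  a <- cbind(r * cos(t), r * sin(t), 0)
  b <- cbind(r + r * cos(t), 0 * t, r * sin(t))
  list(a = a, b = b)
}
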