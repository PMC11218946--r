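## Low-level 3D geometry shared by the knot and entanglement code.
## All coordinates are plain numeric matrices (n x 3), units of Angstrom.

vec_len <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_len(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Row-wise cross product for n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

dot_rows <- function(A, B) rowSums(A * B)

#' Draw uniformly random unit vectors
#'
#' @param n number of vectors.
#' @return an `n x 3` matrix of unit vectors, sampled uniformly on the sphere.
#' @keywords internal
random_unit_vectors <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

## Orthonormal rotation taking `dir` to the +z axis (projection plane = xy).
rotation_to_z <- function(dir) {
  w <- vec_unit(dir)
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- vec_unit(cross3(ref, w))
  v <- cross3(w, u)
  rbind(u, v, w)
}

## Spherical linear interpolation between two points on a sphere centred at
## `center`; returns interior points only, spaced at most `step_deg` apart.
slerp_arc <- function(p1, p2, center, step_deg = 15) {
  a <- p1 - center
  b <- p2 - center
  ra <- vec_len(a)
  rb <- vec_len(b)
  ua <- a / ra
  ub <- b / rb
  cosang <- max(-1, min(1, sum(ua * ub)))
  ang <- acos(cosang)
  if (ang < 1e-9) return(NULL)
  k <- max(1L, ceiling(ang / (step_deg * pi / 180)))
  if (k == 1L) return(NULL)
  ts <- seq_len(k - 1L) / k
  sa <- sin(ang)
  pts <- t(vapply(ts, function(s) {
    w <- (sin((1 - s) * ang) * ua + sin(s * ang) * ub) / sa
    r <- (1 - s) * ra + s * rb
    center + r * w
  }, numeric(3)))
  pts
}

## Drop consecutive duplicate points (within tol) from a polyline.
dedupe_points <- function(P, tol = 1e-9) {
  if (nrow(P) < 2) return(P)
  keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2) > tol^2)
  P[keep, , drop = FALSE]
}

## Moller-Trumbore segment-vs-triangle test, vectorized over segments.
## O, D: n x 3 segment origins and (unnormalized) direction vectors;
## the segment is O + s*D, s in [0,1]. a, b, c: triangle vertices.
## Returns a list with logical `hit` plus barycentric (u,v) and line (t) params.
segments_hit_triangle <- function(O, D, a, b, c, tol = 1e-9) {
  E1 <- b - a
  E2 <- c - a
  n <- nrow(O)
  E1m <- matrix(E1, n, 3, byrow = TRUE)
  E2m <- matrix(E2, n, 3, byrow = TRUE)
  h <- cross3_rows(D, E2m)
  det <- dot_rows(E1m, h)
  ok <- abs(det) > tol
  s <- O - matrix(a, n, 3, byrow = TRUE)
  u <- ifelse(ok, dot_rows(s, h) / det, NA_real_)
  q <- cross3_rows(s, E1m)
  v <- ifelse(ok, dot_rows(D, q) / det, NA_real_)
  tt <- ifelse(ok, dot_rows(E2m, q) / det, NA_real_)
  hit <- ok & !is.na(u) & u >= -tol & v >= -tol & (u + v) <= 1 + tol &
    tt >= -tol & tt <= 1 + tol
  ## Segments lying in the triangle's plane (parallel, zero distance) are
  ## tested exactly in 2D: they hit when the clipped overlap with the
  ## triangle has positive length.
  par <- !ok
  if (any(par)) {
    nrm <- cross3(E1, E2)
    nl <- vec_len(nrm)
    if (nl > tol) {
      nrm <- nrm / nl
      segs <- which(par)
      for (k in segs) {
        s0 <- O[k, ]
        s1 <- O[k, ] + D[k, ]
        if (abs(sum((s0 - a) * nrm)) < 1e-7 &&
            abs(sum((s1 - a) * nrm)) < 1e-7 &&
            coplanar_segment_in_triangle(s0, s1, a, b, c, nrm))
          hit[k] <- TRUE
      }
    }
  }
  list(hit = hit, u = u, v = v, t = tt)
}

## All transversal crossings of a closed polyline's projection along +z.
## P: n x 3 (no duplicated closing point); segment i runs P[i] -> P[i+1]
## cyclically. Returns data.frame of crossings plus a general-position flag.
projection_crossings <- function(P, gp_tol = 1e-7) {
  m <- nrow(P)
  nxt <- c(2:m, 1L)
  A <- P[, 1:2, drop = FALSE]
  B <- P[nxt, 1:2, drop = FALSE]
  ZA <- P[, 3]
  ZB <- P[nxt, 3]
  ## candidate pairs i < j, non-adjacent (cyclically)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- (j - i) > 1L & !(i == 1L & j == m)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) {
    return(list(ok = TRUE, crossings = data.frame()))
  }
  ## quick bounding-box rejection
  lo1x <- pmin(A[i, 1], B[i, 1]); hi1x <- pmax(A[i, 1], B[i, 1])
  lo2x <- pmin(A[j, 1], B[j, 1]); hi2x <- pmax(A[j, 1], B[j, 1])
  lo1y <- pmin(A[i, 2], B[i, 2]); hi1y <- pmax(A[i, 2], B[i, 2])
  lo2y <- pmin(A[j, 2], B[j, 2]); hi2y <- pmax(A[j, 2], B[j, 2])
  bb <- lo1x <= hi2x & lo2x <= hi1x & lo1y <= hi2y & lo2y <= hi1y
  i <- i[bb]; j <- j[bb]
  if (!length(i)) {
    return(list(ok = TRUE, crossings = data.frame()))
  }
  d1x <- B[i, 1] - A[i, 1]; d1y <- B[i, 2] - A[i, 2]
  d2x <- B[j, 1] - A[j, 1]; d2y <- B[j, 2] - A[j, 2]
  ex <- A[j, 1] - A[i, 1]; ey <- A[j, 2] - A[i, 2]
  den <- d1x * d2y - d1y * d2x
  scl <- sqrt((d1x^2 + d1y^2) * (d2x^2 + d2y^2))
  degen <- abs(den) <= gp_tol * pmax(scl, 1e-12)
  u <- ifelse(degen, NA_real_, (ex * d2y - ey * d2x) / den)
  v <- ifelse(degen, NA_real_, (ex * d1y - ey * d1x) / den)
  inter <- !degen & u > 0 & u < 1 & v > 0 & v < 1
  ## general position: crossings must be transversal and away from vertices
  near_end <- !degen & u > -gp_tol & u < 1 + gp_tol & v > -gp_tol & v < 1 + gp_tol &
    (pmin(u, 1 - u) < gp_tol | pmin(v, 1 - v) < gp_tol)
  par_overlap <- degen & inter_parallel_overlap(A, B, i, j, gp_tol)
  if (any(near_end) || any(par_overlap)) {
    return(list(ok = FALSE, crossings = data.frame()))
  }
  if (!any(inter)) {
    return(list(ok = TRUE, crossings = data.frame()))
  }
  i <- i[inter]; j <- j[inter]; u <- u[inter]; v <- v[inter]
  zi <- ZA[i] + u * (ZB[i] - ZA[i])
  zj <- ZA[j] + v * (ZB[j] - ZA[j])
  if (any(abs(zi - zj) < 1e-7)) {
    return(list(ok = FALSE, crossings = data.frame()))
  }
  sgn <- sign((B[i, 1] - A[i, 1]) * (B[j, 2] - A[j, 2]) -
                (B[i, 2] - A[i, 2]) * (B[j, 1] - A[j, 1]))
  list(ok = TRUE,
       crossings = data.frame(seg_i = i, seg_j = j, u = u, v = v,
                              z_i = zi, z_j = zj, cross2 = sgn))
}

## Exact 2D clip of an in-plane segment against a triangle: TRUE when the
## overlap has positive length (touching a vertex or sliding exactly along
## an edge endpoint does not count).
coplanar_segment_in_triangle <- function(s0, s1, a, b, c, nrm,
                                         eps = 1e-7) {
  ## 2D frame in the triangle plane
  e1 <- b - a
  l1 <- vec_len(e1)
  if (l1 < 1e-12) return(FALSE)
  e1 <- e1 / l1
  e2 <- cross3(nrm, e1)
  to2d <- function(p) c(sum((p - a) * e1), sum((p - a) * e2))
  A <- c(0, 0); B <- to2d(b); C <- to2d(c)
  P0 <- to2d(s0); P1 <- to2d(s1)
  orient <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
  if (abs(orient) < 1e-12) return(FALSE)
  edges <- list(list(A, B), list(B, C), list(C, A))
  lo <- 0; hi <- 1
  d <- P1 - P0
  for (e in edges) {
    ## inward normal of the edge (w.r.t. triangle orientation)
    ev <- e[[2]] - e[[1]]
    n2 <- c(-ev[2], ev[1]) * sign(orient)
    f0 <- sum((P0 - e[[1]]) * n2)
    fd <- sum(d * n2)
    if (abs(fd) < 1e-12) {
      if (f0 < -eps) return(FALSE)  # entirely outside this half-plane
    } else {
      t_hit <- -f0 / fd
      if (fd > 0) lo <- max(lo, t_hit) else hi <- min(hi, t_hit)
    }
    if (lo >= hi) return(FALSE)
  }
  seg_len <- sqrt(sum(d^2)) * (hi - lo)
  seg_len > 1e-6
}

## Helper: do near-parallel projected segments actually overlap?
inter_parallel_overlap <- function(A, B, i, j, tol) {
  out <- logical(length(i))
  deg <- seq_along(i)
  for (k in deg) {
    a <- A[i[k], ]; b <- B[i[k], ]; c <- A[j[k], ]; d <- B[j[k], ]
    ab <- b - a
    l2 <- sum(ab^2)
    if (l2 < 1e-18) next
    dc <- abs((c[1] - a[1]) * ab[2] - (c[2] - a[2]) * ab[1]) / sqrt(l2)
    dd <- abs((d[1] - a[1]) * ab[2] - (d[2] - a[2]) * ab[1]) / sqrt(l2)
    if (dc > tol * 10 && dd > tol * 10) next
    tc <- sum((c - a) * ab) / l2
    td <- sum((d - a) * ab) / l2
    if (max(min(tc, td), 0) <= min(max(tc, td), 1)) out[k] <- TRUE
  }
  out
}
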