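## KMT chain reduction (Koniaris-Muthukumar-Taylor).

#' Simplify a polyline while preserving its topology
#'
#' Iteratively deletes an interior vertex `v` whenever the triangle spanned by
#' its neighbours `(prev, v, next)` is intersected by no other segment of the
#' chain, until no vertex can be removed. For a closed curve this preserves
#' the knot type; for an open chain with `fixed_endpoints = TRUE` the two
#' terminal vertices are never deleted and the reduction preserves the knot
#' type of any closure routed away from the chain.
#'
#' @param points `n x 3` matrix of chain vertices. A duplicated closing point
#'   (first == last) is detected and handled as a closed curve.
#' @param fixed_endpoints if `TRUE` (open chain), endpoints are kept;
#'   if `FALSE` the chain is treated as closed and all vertices are
#'   candidates (at least 3 are always retained).
#' @return the reduced polyline; for closed input the first point is
#'   re-appended so first == last.
#' @export
kmt_reduce <- function(points, fixed_endpoints = TRUE) {
  P <- as_curve_matrix(points)
  was_closed_dup <- FALSE
  if (nrow(P) >= 2 && sum((P[1, ] - P[nrow(P), ])^2) < 1e-18) {
    P <- P[-nrow(P), , drop = FALSE]
    was_closed_dup <- TRUE
  }
  closed <- was_closed_dup || !fixed_endpoints
  P <- dedupe_points(P)
  if (closed && nrow(P) >= 2 &&
      sum((P[1, ] - P[nrow(P), ])^2) < 1e-18)
    P <- P[-nrow(P), , drop = FALSE]
  n <- nrow(P)
  if (n < 4) return(finish_kmt(P, was_closed_dup))
  repeat {
    n <- nrow(P)
    min_n <- if (closed) 3L else 3L
    if (n <= min_n) break
    removed_any <- FALSE
    v <- if (closed) 1L else 2L
    while (TRUE) {
      n <- nrow(P)
      if (n <= min_n) break
      last_cand <- if (closed) n else n - 1L
      if (v > last_cand) break
      ip <- if (closed) ((v - 2L) %% n) + 1L else v - 1L
      inx <- if (closed) (v %% n) + 1L else v + 1L
      if (kmt_removable(P, ip, v, inx, closed)) {
        P <- P[-v, , drop = FALSE]
        removed_any <- TRUE
        ## do not advance: the next vertex slides into position v
      } else {
        v <- v + 1L
      }
    }
    if (!removed_any) break
  }
  finish_kmt(P, was_closed_dup)
}

finish_kmt <- function(P, reappend) {
  if (reappend && nrow(P) >= 1 &&
      sum((P[1, ] - P[nrow(P), ])^2) > 1e-18)
    P <- rbind(P, P[1, ])
  P
}

## Can vertex v (neighbours ip, inx) be deleted? True when no chain segment
## other than the two incident ones crosses the triangle (P[ip], P[v], P[inx]).
kmt_removable <- function(P, ip, v, inx, closed) {
  a <- P[ip, ]; b <- P[v, ]; c <- P[inx, ]
  ## degenerate (collinear) triangles are spikes; removal is always safe
  if (vec_len(cross3(b - a, c - a)) < 1e-12) return(TRUE)
  n <- nrow(P)
  starts <- seq_len(if (closed) n else n - 1L)
  ends <- if (closed) c(2:n, 1L) else 2:n
  ## exclude the two segments incident to v
  excl <- starts == v | ends == v
  starts <- starts[!excl]; ends <- ends[!excl]
  if (!length(starts)) return(TRUE)
  O <- P[starts, , drop = FALSE]
  D <- P[ends, , drop = FALSE] - O
  hit <- segments_hit_triangle(O, D, a, b, c, tol = 1e-9)
  if (!any(hit$hit)) return(TRUE)
  ## segments sharing the vertex a or c touch the triangle at that vertex;
  ## ignore hits that coincide with the shared endpoint
  bad <- which(hit$hit)
  for (k in bad) {
    s0 <- O[k, ]; s1 <- O[k, ] + D[k, ]
    shares_a <- sum((s0 - a)^2) < 1e-18 || sum((s1 - a)^2) < 1e-18
    shares_c <- sum((s0 - c)^2) < 1e-18 || sum((s1 - c)^2) < 1e-18
    if (!shares_a && !shares_c) return(FALSE)
    if (is.na(hit$t[k])) return(FALSE)  # parallel in-plane hit: keep vertex
    pt <- O[k, ] + hit$t[k] * D[k, ]
    near_shared <- (shares_a && sum((pt - a)^2) < 1e-12) ||
      (shares_c && sum((pt - c)^2) < 1e-12)
    if (!near_shared) return(FALSE)
  }
  TRUE
}
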