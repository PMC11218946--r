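## Projection of a closed 3D curve to a knot diagram.

#' Project a closed curve to a knot diagram
#'
#' Orthogonally projects the curve along a random direction and extracts the
#' crossing structure: for every transversal crossing, which arc passes over,
#' which arcs enter and leave underneath, and the orientation sign. Arcs are
#' the pieces of the curve between consecutive undercrossings. Directions
#' failing general position (tangencies, crossings at vertices, coincident
#' depths) are redrawn up to `max_tries` times.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param curve a closed curve: an `n x 3` matrix whose first and last points
#'   coincide, or a `closed_curve` object.
#' @param max_tries how many projection directions to attempt.
#' @return an object of class `knot_diagram`: list with `n_crossings`,
#'   `n_arcs`, and a `crossings` data frame (`over_arc`, `under_in`,
#'   `under_out`, `sign`).
#' @export
project_to_diagram <- function(curve, max_tries = 100) {
  P <- as_curve_matrix(curve)
  if (nrow(P) >= 2 && sum((P[1, ] - P[nrow(P), ])^2) < 1e-18)
    P <- P[-nrow(P), , drop = FALSE]
  P <- dedupe_points(P)
  if (nrow(P) < 3) return(new_knot_diagram(0L, data.frame()))
  for (try in seq_len(max_tries)) {
    dir <- as.numeric(random_unit_vectors(1))
    R <- rotation_to_z(dir)
    Q <- P %*% t(R)
    res <- projection_crossings(Q)
    if (!res$ok) next
    return(build_diagram(Q, res$crossings))
  }
  stop("no general-position projection found (structure too tangled)",
       call. = FALSE)
}

new_knot_diagram <- function(n_crossings, crossings, n_arcs = max(1L, n_crossings)) {
  structure(list(n_crossings = as.integer(n_crossings),
                 n_arcs = as.integer(n_arcs),
                 crossings = crossings),
            class = "knot_diagram")
}

## Assemble arcs and crossing relations from raw projected crossings.
build_diagram <- function(Q, cr) {
  if (!nrow(cr)) return(new_knot_diagram(0L, data.frame()))
  n <- nrow(cr)
  ## one over event and one under event per crossing, keyed by position
  ## along the curve: seg index + parameter in [0, 1)
  i_over_first <- cr$z_i > cr$z_j
  over_pos <- ifelse(i_over_first, cr$seg_i + cr$u, cr$seg_j + cr$v)
  under_pos <- ifelse(i_over_first, cr$seg_j + cr$v, cr$seg_i + cr$u)
  ## crossing sign: +1 when the frame (over direction, under direction) is
  ## positively oriented in the projection plane. cross2 is sign of
  ## cross(d_i, d_j); flip when segment j is the over strand.
  sgn <- ifelse(i_over_first, cr$cross2, -cr$cross2)
  ## arcs: pieces between consecutive under events (cyclic)
  ord <- order(under_pos)
  u_sorted <- under_pos[ord]
  ## arc k (k = 1..n) starts at u_sorted[k], ends at u_sorted[k+1] (cyclic)
  arc_of <- function(pos) {
    k <- findInterval(pos, u_sorted)
    if (k == 0L) k <- length(u_sorted)  # before the first under event
    k
  }
  over_arc <- vapply(over_pos, arc_of, integer(1))
  under_out <- integer(n)
  under_in <- integer(n)
  under_out[ord] <- seq_len(n)          # arc starting at this under event
  under_in[ord] <- c(n, seq_len(n - 1)) # arc ending at this under event
  new_knot_diagram(n, data.frame(over_arc = over_arc,
                                 under_in = under_in,
                                 under_out = under_out,
                                 sign = as.integer(sgn)))
}

as_curve_matrix <- function(curve) {
  if (inherits(curve, "closed_curve")) curve <- curve$points
  if (is.data.frame(curve)) curve <- as.matrix(curve)
  stopifnot(is.matrix(curve), ncol(curve) == 3)
  storage.mode(curve) <- "double"
  curve
}

#' Count crossings of a random projection
#'
#' Cheap complexity probe used by the too-tangled-to-check (TTC) pathway:
#' counts transversal crossings of one random general-position projection
#' without building the full diagram.
#'
#' @inheritParams project_to_diagram
#' @return integer crossing count.
#' @keywords internal
count_crossings <- function(curve, max_tries = 20) {
  P <- as_curve_matrix(curve)
  if (nrow(P) >= 2 && sum((P[1, ] - P[nrow(P), ])^2) < 1e-18)
    P <- P[-nrow(P), , drop = FALSE]
  P <- dedupe_points(P)
  if (nrow(P) < 3) return(0L)
  for (try in seq_len(max_tries)) {
    dir <- as.numeric(random_unit_vectors(1))
    Q <- P %*% t(rotation_to_z(dir))
    res <- projection_crossings(Q)
    if (res$ok) return(nrow(res$crossings))
  }
  stop("no general-position projection found (structure too tangled)",
       call. = FALSE)
}
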