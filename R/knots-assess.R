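## Chain closure and the per-chain knot assessment protocol.

#' Close an open chain through a random point on a large sphere
#'
#' Both endpoints are projected radially from the chain centroid onto a
#' sphere whose radius is `radius_factor` times the maximal centroid
#' distance, then connected through a random point on the hemisphere
#' opposite the endpoints, following great-circle arcs approximated with
#' straight segments. The closing path therefore stays far outside the
#' chain, so the (random) closure, not the connecting geometry, decides the
#' knot type. Uses the R random number generator.
#'
#' @param points open polyline (`n x 3`), endpoints distinct.
#' @param radius_factor sphere radius as a multiple of the chain extent.
#' @param step_deg arc discretization step in degrees.
#' @return object of class `closed_curve` (`points` with first == last).
#' @export
random_two_point_closure <- function(points, radius_factor = 10,
                                     step_deg = 15) {
  P <- as_curve_matrix(points)
  P <- dedupe_points(P)
  n <- nrow(P)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(P)
  rmax <- sqrt(max(rowSums((P - matrix(ctr, n, 3, byrow = TRUE))^2)))
  R <- radius_factor * max(rmax, 1e-6)
  e1 <- P[1, ]; e2 <- P[n, ]
  radial <- function(e) {
    d <- e - ctr
    if (vec_len(d) < 1e-9) d <- c(1, 0, 0)  # endpoint at centroid: pick axis
    ctr + R * vec_unit(d)
  }
  s1 <- radial(e1); s2 <- radial(e2)
  m <- (s1 - ctr) + (s2 - ctr)
  mhat <- if (vec_len(m) < 1e-9) vec_unit(s1 - ctr) else vec_unit(m)
  repeat {
    w <- as.numeric(random_unit_vectors(1))
    if (sum(w * mhat) < -0.05) break
  }
  fp <- ctr + R * w
  path <- rbind(s2, slerp_arc(s2, fp, ctr, step_deg), fp,
                slerp_arc(fp, s1, ctr, step_deg), s1)
  closed <- rbind(P, path, P[1, , drop = FALSE])
  structure(list(points = dedupe_points(closed)), class = "closed_curve")
}

#' Close an open chain with a straight segment
#'
#' @param points open polyline (`n x 3`).
#' @return a `closed_curve`; already-closed input is returned unchanged.
#' @export
direct_closure <- function(points) {
  P <- as_curve_matrix(points)
  if (sum((P[1, ] - P[nrow(P), ])^2) > 1e-18)
    P <- rbind(P, P[1, , drop = FALSE])
  structure(list(points = P), class = "closed_curve")
}

## Deterministic per-closure RNG stream from the master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

## Classify one closed curve; "unknown" when too complex for the budget.
classify_closure <- function(closed, crossing_budget) {
  d <- tryCatch(project_to_diagram(closed),
                error = function(e) NULL)
  if (is.null(d)) return(list(label = NA_character_, exceeded = TRUE))
  if (d$n_crossings > crossing_budget)
    return(list(label = NA_character_, exceeded = TRUE))
  co <- alexander_polynomial(d)
  list(label = classify_knot(co), exceeded = FALSE)
}

#' Assess whether a backbone chain is knotted
#'
#' Runs the closure-and-invariant protocol on an open chain: the chain is
#' simplified once by KMT reduction (endpoints fixed), then closed
#' `n_closures` times through random points on a large sphere; each closure
#' is classified by its Alexander polynomial. The chain is called knotted
#' when fewer than `unknot_threshold` of the completed closures are unknots
#' (strict inequality). Closures whose diagrams exceed `crossing_budget`
#' crossings, or that admit no general-position projection, count toward the
#' too-tangled-to-check (TTC) flag; TTC is raised when more than 20% of the
#' requested closures are in that state, and the remaining closures are then
#' skipped. A single direct closure (straight end-to-end segment) is also
#' classified; a chain that is probabilistically knotted but a direct-closure
#' unknot is flagged `ambiguous` rather than discarded.
#'
#' @param chain a `backbone_chain`, or an open polyline (`n x 3`).
#' @param n_closures number of random closures.
#' @param unknot_threshold unknot fraction below which the chain is knotted.
#' @param crossing_budget max diagram crossings after reduction before a
#'   closure counts as too tangled.
#' @param seed master seed; per-closure streams are derived from it by
#'   closure index, so histograms are reproducible bit for bit.
#' @return object of class `knot_assessment`: `chain_id`,
#'   `closure_histogram`, `dominant_label`, `knotted`, `ttc`,
#'   `direct_closure_label`, `ambiguous`, `n_closures`, `n_completed`,
#'   `n_exceeded`, `seed`.
#' @export
assess_knot <- function(chain, n_closures = 200, unknot_threshold = 0.5,
                        crossing_budget = 50, seed = 1) {
  chain_id <- if (inherits(chain, "backbone_chain")) chain$chain_id else ""
  P <- if (inherits(chain, "backbone_chain")) chain$points else
    as_curve_matrix(chain)
  dup <- duplicated(round(P, 6))
  if (any(dup))
    stop(structure(class = c("invalid_coordinates", "error", "condition"),
                   list(message = paste0("chain has ", sum(dup),
                                         " non-unique coordinate(s)"),
                        call = NULL)))
  P <- dedupe_points(P)
  if (nrow(P) < 3) stop("chain too short", call. = FALSE)
  red <- kmt_reduce(P, fixed_endpoints = TRUE)
  labels <- character(0)
  exceeded <- 0L
  ttc_cut <- 0.2 * n_closures
  for (k in seq_len(n_closures)) {
    set.seed(derive_seed(seed, k))
    closed <- random_two_point_closure(red)
    res <- classify_closure(closed, crossing_budget)
    if (res$exceeded) exceeded <- exceeded + 1L else
      labels <- c(labels, res$label)
    if (exceeded > ttc_cut) break
  }
  ttc <- exceeded > ttc_cut
  hist <- if (length(labels)) table(labels) else table(character(0))
  hist <- stats::setNames(as.integer(hist), names(hist))
  completed <- length(labels)
  unknot_frac <- if (completed) sum(labels == "unknot") / completed else NA
  knotted <- isTRUE(!is.na(unknot_frac) && unknot_frac < unknot_threshold)
  nontrivial <- hist[names(hist) != "unknot"]
  dominant <- if (knotted && length(nontrivial)) {
    names(nontrivial)[which.max(nontrivial)]
  } else if (length(hist)) {
    names(hist)[which.max(hist)]
  } else NA_character_
  set.seed(derive_seed(seed, 0L))
  direct <- classify_closure(direct_closure(red), crossing_budget)
  direct_label <- if (direct$exceeded) "unknown" else direct$label
  structure(list(chain_id = chain_id,
                 closure_histogram = hist,
                 dominant_label = dominant,
                 knotted = knotted,
                 ttc = ttc,
                 direct_closure_label = direct_label,
                 ambiguous = knotted && identical(direct_label, "unknot"),
                 unknot_fraction = unknot_frac,
                 n_closures = n_closures,
                 n_completed = completed,
                 n_exceeded = exceeded,
                 seed = seed),
            class = "knot_assessment")
}

#' @export
print.knot_assessment <- function(x, ...) {
  cat("<knot_assessment>", x$chain_id,
      if (x$ttc) "TTC" else if (x$knotted) paste0("knotted: ", x$dominant_label)
      else "unknotted", "\n")
  if (length(x$closure_histogram)) {
    h <- sort(x$closure_histogram, decreasing = TRUE)
    cat("  closures:", paste(names(h), h, sep = "=", collapse = ", "), "\n")
  }
  cat("  direct closure:", x$direct_closure_label,
      if (x$ambiguous) "(ambiguous)" else "", "\n")
  invisible(x)
}
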