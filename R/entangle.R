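## Entanglements of structure elements: spanning surfaces, punctures,
## linking numbers, the 9-subclass taxonomy, and lasso depth.

#' Span a surface over a closed element
#'
#' Builds a triangle fan from the boundary centroid, then applies
#' `subdivision_rounds` rounds of midpoint subdivision with Laplacian
#' relaxation of the interior vertices (boundary vertices stay fixed).
#' Deterministic for a given boundary. If the boundary self-intersects
#' within tolerance, the unrelaxed fan is used with a warning.
#'
#' @param element a closed `structural_element`, or an `n x 3` closed
#'   polyline (first point equals last).
#' @param subdivision_rounds rounds of 1-to-4 triangle subdivision.
#' @return object of class `spanning_surface`: `vertices` (`m x 3`),
#'   `triangles` (`k x 3` vertex indices, consistently oriented),
#'   `boundary` (the input boundary polyline).
#' @export
span_surface <- function(element, subdivision_rounds = 3) {
  B <- if (inherits(element, "structural_element")) element$curve else element
  B <- as_curve_matrix(B)
  if (nrow(B) >= 2 && sum((B[1, ] - B[nrow(B), ])^2) < 1e-18)
    B <- B[-nrow(B), , drop = FALSE]
  B <- dedupe_points(B)
  nb <- nrow(B)
  if (nb < 3) stop("boundary has fewer than 3 distinct points", call. = FALSE)
  centroid <- colMeans(B)
  V <- rbind(B, centroid)
  Tm <- cbind(seq_len(nb), c(2:nb, 1L), nb + 1L)
  fixed <- c(rep(TRUE, nb), FALSE)
  degenerate <- boundary_self_intersects(B)
  if (degenerate) {
    warning("degenerate (self-intersecting) boundary: unrelaxed fan used",
            call. = FALSE)
    subdivision_rounds <- 0
  }
  for (round in seq_len(subdivision_rounds)) {
    sub <- subdivide_mesh(V, Tm, fixed)
    V <- sub$V; Tm <- sub$T; fixed <- sub$fixed
    V <- relax_mesh(V, Tm, fixed, iters = 10)
  }
  structure(list(vertices = V, triangles = Tm,
                 boundary = rbind(B, B[1, , drop = FALSE])),
            class = "spanning_surface")
}

boundary_self_intersects <- function(B, tol = 1e-6) {
  nb <- nrow(B)
  if (nb > 400) return(FALSE)  # large smooth boundaries: skip O(n^2) check
  nxt <- c(2:nb, 1L)
  for (i in seq_len(nb - 2L)) {
    for (j in (i + 2L):nb) {
      if (i == 1L && j == nb) next
      d <- segment_segment_distance(B[i, ], B[nxt[i], ], B[j, ], B[nxt[j], ])
      if (d < tol) return(TRUE)
    }
  }
  FALSE
}

segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-18 && e < 1e-18) return(vec_len(r))
  if (a < 1e-18) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e < 1e-18) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-18) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  vec_len(p1 + s * d1 - (q1 + t * d2))
}

subdivide_mesh <- function(V, Tm, fixed) {
  edge_mid <- new.env(hash = TRUE)
  nv <- nrow(V)
  Vl <- lapply(seq_len(nv), function(i) V[i, ])
  fx <- as.list(fixed)
  mid_of <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- edge_mid[[key]]
    if (!is.null(hit)) return(hit)
    Vl[[length(Vl) + 1L]] <<- (Vl[[a]] + Vl[[b]]) / 2
    ## a midpoint is on the boundary iff both endpoints are boundary
    ## vertices of the same boundary edge (consecutive); conservatively,
    ## both fixed: fan construction only creates boundary-boundary edges
    ## along the boundary itself.
    fx[[length(fx) + 1L]] <<- isTRUE(fx[[a]]) && isTRUE(fx[[b]])
    edge_mid[[key]] <- length(Vl)
    length(Vl)
  }
  newT <- matrix(0L, nrow(Tm) * 4L, 3L)
  r <- 0L
  for (t in seq_len(nrow(Tm))) {
    a <- Tm[t, 1]; b <- Tm[t, 2]; c <- Tm[t, 3]
    ab <- mid_of(a, b); bc <- mid_of(b, c); ca <- mid_of(c, a)
    newT[r + 1L, ] <- c(a, ab, ca)
    newT[r + 2L, ] <- c(ab, b, bc)
    newT[r + 3L, ] <- c(ca, bc, c)
    newT[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(V = do.call(rbind, Vl), T = newT, fixed = unlist(fx))
}

relax_mesh <- function(V, Tm, fixed, iters = 10) {
  n <- nrow(V)
  ## adjacency from triangle edges
  e <- rbind(Tm[, 1:2], Tm[, 2:3], Tm[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  nb <- split(e[, 2], e[, 1])
  free <- which(!fixed)
  for (it in seq_len(iters)) {
    for (v in free) {
      ns <- unique(nb[[as.character(v)]])
      V[v, ] <- colMeans(V[ns, , drop = FALSE])
    }
  }
  V
}

#' Find punctures of a spanning surface by another element
#'
#' Tests every segment of `other` against every surface triangle and records
#' transversal interior intersections with a crossing sign taken from the
#' surface orientation. Intersections within `merge_tol` of each other along
#' the piercing element (as produced when a segment grazes a shared triangle
#' edge) are deduplicated.
#'
#' @param surface a `spanning_surface`.
#' @param other a `structural_element` whose segments may pierce it.
#' @param merge_tol merge distance in Angstrom.
#' @param tol absolute geometric tolerance for the segment-triangle test.
#' @return data frame of intersection points: `x`, `y`, `z`, `segment`
#'   (index in `other`'s curve), `residue_a`, `residue_b`, `provenance`,
#'   `sign`.
#' @export
find_punctures <- function(surface, other, merge_tol = 0.1, tol = 1e-6) {
  C <- other$curve
  ns <- nrow(C) - 1L
  O <- C[-nrow(C), , drop = FALSE]
  D <- C[-1, , drop = FALSE] - O
  hits <- list()
  V <- surface$vertices
  for (t in seq_len(nrow(surface$triangles))) {
    tri <- surface$triangles[t, ]
    a <- V[tri[1], ]; b <- V[tri[2], ]; c <- V[tri[3], ]
    nrm <- cross3(b - a, c - a)
    nl <- vec_len(nrm)
    if (nl < 1e-12) next
    nrm <- nrm / nl
    res <- segments_hit_triangle(O, D, a, b, c, tol = tol)
    hit <- which(res$hit & !is.na(res$t))
    for (k in hit) {
      pt <- O[k, ] + res$t[k] * D[k, ]
      sgn <- sign(sum(D[k, ] * nrm))
      if (sgn == 0) next
      hits[[length(hits) + 1L]] <- data.frame(
        x = pt[1], y = pt[2], z = pt[3], segment = k,
        arcpos = k + res$t[k], sign = sgn)
    }
  }
  if (!length(hits)) return(empty_punctures())
  H <- do.call(rbind, hits)
  H <- H[order(H$arcpos), , drop = FALSE]
  ## merge duplicates: same crossing found in adjacent triangles
  keep <- rep(TRUE, nrow(H))
  if (nrow(H) > 1) {
    for (k in 2:nrow(H)) {
      prev <- max(which(keep[1:(k - 1)]))
      d <- sqrt((H$x[k] - H$x[prev])^2 + (H$y[k] - H$y[prev])^2 +
                  (H$z[k] - H$z[prev])^2)
      if (d < merge_tol && H$sign[k] == H$sign[prev]) keep[k] <- FALSE
    }
  }
  H <- H[keep, , drop = FALSE]
  rp <- other$residue_of_point
  prov <- other$provenance
  data.frame(x = H$x, y = H$y, z = H$z, segment = H$segment,
             residue_a = rp[H$segment], residue_b = rp[H$segment + 1L],
             provenance = prov[H$segment], sign = H$sign,
             stringsAsFactors = FALSE)
}

empty_punctures <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             segment = integer(0), residue_a = integer(0),
             residue_b = integer(0), provenance = character(0),
             sign = numeric(0), stringsAsFactors = FALSE)
}

#' Gauss linking number of two closed curves
#'
#' Evaluates the Gauss linking integral exactly for polygonal curves as the
#' sum of signed solid angles over segment pairs. The result is an integer
#' for disjoint closed curves; `0` for unlinked, `+-1` for a Hopf link.
#'
#' @param a,b closed curves (`n x 3`, first equals last) or closed
#'   `structural_element`s.
#' @return integer linking number.
#' @export
linking_number <- function(a, b) {
  A <- if (inherits(a, "structural_element")) a$curve else as_curve_matrix(a)
  B <- if (inherits(b, "structural_element")) b$curve else as_curve_matrix(b)
  close_pl <- function(P) {
    if (sum((P[1, ] - P[nrow(P), ])^2) > 1e-18) P <- rbind(P, P[1, ])
    P
  }
  A <- close_pl(dedupe_points(A)); B <- close_pl(dedupe_points(B))
  total <- 0
  na <- nrow(A) - 1L; nb <- nrow(B) - 1L
  for (i in seq_len(na)) {
    a1 <- A[i, ]; a2 <- A[i + 1L, ]
    for (j in seq_len(nb)) {
      total <- total + solid_angle_quad(a1, a2, B[j, ], B[j + 1L, ])
    }
  }
  round(total / (4 * pi))
}

## Signed solid angle subtended by segment pair (Klenin & Langowski 2000).
solid_angle_quad <- function(a1, a2, b1, b2) {
  r13 <- b1 - a1; r14 <- b2 - a1; r23 <- b1 - a2; r24 <- b2 - a2
  n1 <- cross3(r13, r14); n2 <- cross3(r14, r24)
  n3 <- cross3(r24, r23); n4 <- cross3(r23, r13)
  ln <- c(vec_len(n1), vec_len(n2), vec_len(n3), vec_len(n4))
  if (any(ln < 1e-12)) return(0)
  n1 <- n1 / ln[1]; n2 <- n2 / ln[2]; n3 <- n3 / ln[3]; n4 <- n4 / ln[4]
  cl <- function(x) max(-1, min(1, x))
  ang <- asin(cl(sum(n1 * n2))) + asin(cl(sum(n2 * n3))) +
    asin(cl(sum(n3 * n4))) + asin(cl(sum(n4 * n1)))
  sgn <- sign(sum(cross3(a2 - a1, b2 - b1) * r13))
  if (sgn == 0) sgn <- 1
  ang * sgn
}

#' Classify an element pair as interlace, lasso, or unentangled
#'
#' Interlace when both elements are closed with non-zero linking number
#' (label from the element kinds, D before L). Lasso X(Y) when X's surface
#' is punctured by Y without linking. Interlaces, D(*) lassos, and deep
#' L(*) lassos are flagged as modeling artifacts; shallow L(*) lassos can
#' plausibly disentangle during folding and are not flagged.
#'
#' @param x the closed element whose surface was spanned.
#' @param y the potentially piercing element.
#' @param punctures output of [find_punctures()] for x's surface against y.
#' @param lk linking number of the two curves when y is closed, else `NA`.
#' @return an `entanglement` object, or `NULL` when the pair is clean.
#' @export
classify_pair <- function(x, y, punctures, lk = NA) {
  letter <- c(loop = "L", dinucleotide_step = "D", single_strand = "S")
  lx <- letter[[x$kind]]; ly <- letter[[y$kind]]
  if (y$closed && !is.na(lk) && lk != 0) {
    kinds <- sort(c(lx, ly))  # D before L
    sub <- paste0(kinds[1], "&", kinds[2])
    return(new_entanglement(sub, x, y, punctures, lk,
                            depth = NA_integer_,
                            depth_class = "not_applicable",
                            artifact = TRUE))
  }
  if (nrow(punctures) == 0) return(NULL)
  sub <- paste0(lx, "(", ly, ")")
  ent <- new_entanglement(sub, x, y, punctures, if (is.na(lk)) NA else lk,
                          depth = NA_integer_,
                          depth_class = "not_applicable",
                          artifact = lx == "D")
  if (lx == "L") {
    ent$depth <- lasso_depth(ent)
    ent$depth_class <- if (is.na(ent$depth)) "not_applicable"
    else if (ent$depth <= 5L) "shallow" else "deep"
    ent$artifact <- identical(ent$depth_class, "deep")
  }
  ent
}

new_entanglement <- function(subclass, x, y, punctures, lk, depth,
                             depth_class, artifact) {
  structure(list(subclass = subclass, element_x = x, element_y = y,
                 intersections = punctures, lk = lk, depth = depth,
                 depth_class = depth_class, artifact = artifact),
            class = "entanglement")
}

#' @export
print.entanglement <- function(x, ...) {
  cat("<entanglement>", x$subclass, ":", x$element_x$label, "/",
      x$element_y$label,
      if (!is.na(x$depth)) paste0("depth ", x$depth, " (", x$depth_class, ")")
      else "",
      if (x$artifact) "[artifact]" else "", "\n")
  invisible(x)
}

#' Depth of a lasso formed by a loop
#'
#' For a single puncture by a single strand, the depth is the number of the
#' strand's unpaired nucleotides beyond the crossing segment, counted toward
#' each chain end, taking the minimum of the two counts. For two punctures
#' (a lassoed closed element, or a strand puncturing the loop twice) the
#' depth is the number of nucleotides strictly between the two crossing
#' segments. Lassos with zero or more than two punctures have no depth.
#'
#' @param entanglement an L(*) lasso `entanglement`.
#' @return integer depth in nucleotides, or `NA` when not applicable.
#' @export
lasso_depth <- function(entanglement) {
  y <- entanglement$element_y
  P <- entanglement$intersections
  if (nrow(P) < 1 || nrow(P) > 2) return(NA_integer_)
  rs <- y$residues
  pos_of <- function(r) match(r, rs)
  if (nrow(P) == 2) {
    p1 <- min(pos_of(P$residue_a[1]), pos_of(P$residue_b[1]))
    p2 <- min(pos_of(P$residue_a[2]), pos_of(P$residue_b[2]))
    return(abs(p2 - p1))
  }
  if (y$kind != "single_strand") return(NA_integer_)
  unp <- y$unpaired
  if (is.null(unp)) unp <- rs
  pa <- min(P$residue_a[1], P$residue_b[1])
  pb <- max(P$residue_a[1], P$residue_b[1])
  n5 <- sum(unp < pa)
  n3 <- sum(unp > pb)
  as.integer(min(n5, n3))
}

#' Detect all entanglements of structure elements in a model
#'
#' Derives loops, dinucleotide steps and single strands for every chain,
#' then tests each ordered pair (closed element, other element) across all
#' chains. Elements sharing a residue on the same chain are never tested
#' against each other. Interlaces are reported once per unordered pair;
#' every L(*) lasso is annotated with its depth and shallow/deep class.
#'
#' @param model an `rna_model`.
#' @param ss a `secondary_structure`, or a named list of them (one per
#'   chain), or `NULL` to detect pairs geometrically.
#' @param subdivision_rounds surface subdivision rounds, see [span_surface()].
#' @return list of `entanglement` objects.
#' @export
detect_all <- function(model, ss = NULL, subdivision_rounds = 3) {
  elements <- list()
  for (cid in names(model$chains)) {
    chain <- model$chains[[cid]]
    ssc <- if (is.null(ss)) {
      annotate_base_pairs(model, source = "detect", chain_id = cid)
    } else if (inherits(ss, "secondary_structure")) {
      ss
    } else {
      ss[[cid]]
    }
    if (is.null(ssc)) next
    elements <- c(elements, find_elements(ssc, chain))
  }
  detect_entanglements(elements, subdivision_rounds)
}

## Core pair loop on a prepared element list.
detect_entanglements <- function(elements, subdivision_rounds = 3) {
  closed_idx <- which(vapply(elements, function(e) e$closed, logical(1)))
  out <- list()
  seen_interlace <- character(0)
  surfaces <- list()
  surf_of <- function(k) {
    key <- as.character(k)
    if (is.null(surfaces[[key]]))
      surfaces[[key]] <<- span_surface(elements[[k]], subdivision_rounds)
    surfaces[[key]]
  }
  for (xi in closed_idx) {
    x <- elements[[xi]]
    for (yi in seq_along(elements)) {
      if (yi == xi) next
      y <- elements[[yi]]
      if (identical(x$chain_id, y$chain_id) &&
          length(intersect(x$residues, y$residues)) > 0) next
      lk <- NA
      if (y$closed) lk <- linking_number(x$curve, y$curve)
      pun <- find_punctures(surf_of(xi), y)
      ent <- classify_pair(x, y, pun, lk)
      if (is.null(ent)) next
      if (grepl("&", ent$subclass, fixed = TRUE)) {
        key <- paste(sort(c(xi, yi)), collapse = "-")
        if (key %in% seen_interlace) next
        seen_interlace <- c(seen_interlace, key)
      }
      out[[length(out) + 1L]] <- ent
    }
  }
  out
}

#' Tabulate a list of entanglements
#'
#' @param entanglements list of `entanglement` objects.
#' @return data frame with one row per entanglement: subclass, elements,
#'   puncture count, linking number, depth, depth class, artifact flag.
#' @export
entanglement_table <- function(entanglements) {
  if (!length(entanglements))
    return(data.frame(subclass = character(0), element_x = character(0),
                      element_y = character(0), n_intersections = integer(0),
                      lk = numeric(0), depth = integer(0),
                      depth_class = character(0), artifact = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(entanglements, function(e) {
    data.frame(subclass = e$subclass, element_x = e$element_x$label,
               element_y = e$element_y$label,
               n_intersections = nrow(e$intersections),
               lk = if (is.na(e$lk)) NA_real_ else e$lk,
               depth = if (is.na(e$depth)) NA_integer_ else e$depth,
               depth_class = e$depth_class, artifact = e$artifact,
               stringsAsFactors = FALSE)
  }))
}
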