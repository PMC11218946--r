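## Synthetic ground-truth fixtures: knotted/unknotted chains and entangled
## RNA-like models with 6 backbone atoms per residue, written as PDB plus a
## dot-bracket sidecar. Every generator is deterministic given its seed and
## carries its expected labels in `$truth`.

RESIDUE_SPACING <- 5.9  # idealized P-P virtual spacing in Angstrom

## ---- knotted curves -----------------------------------------------------

#' Generate a parametric or template knot curve
#'
#' Torus knots T(2,3), T(2,5), T(2,7) use the standard torus parametrization;
#' twist knots (3_1, 4_1, 5_2, 6_1, 7_2) use a polygonal template - a twisted
#' double-helix loop whose top lobe threads the bottom lobe - whose knot
#' types were validated once against the closed-form Alexander polynomials
#' of the torus and twist families. `open_fraction` removes a terminal arc,
#' leaving the knot core intact.
#'
#' @param kind `"torus"`, `"twist"`, or `"unknot"` (a circle).
#' @param p,q torus knot parameters, coprime (`kind = "torus"`).
#' @param twists number of half-twists m = 1..5 for the twist template
#'   (1 = 3_1, 2 = 4_1, 3 = 5_2, 4 = 6_1, 5 = 7_2).
#' @param n_points approximate number of vertices (exact for torus/unknot).
#' @param open_fraction fraction of vertices removed from the end of the
#'   closed curve to produce an open chain; 0 keeps it closed.
#' @param scale coordinate scale factor (the unit figure is about 6 units
#'   wide; the default gives RNA-like dimensions in Angstrom).
#' @return list with `points` (`n x 3`; closed curves have first == last),
#'   `truth` (expected knot label), and `closed`.
#' @export
make_knot_curve <- function(kind = c("torus", "twist", "unknot"),
                            p = 2, q = 3, twists = 1, n_points = 200,
                            open_fraction = 0, scale = 10) {
  kind <- match.arg(kind)
  if (kind == "torus") {
    if (n_points < 50) stop("n_points must be >= 50", call. = FALSE)
    if (gcd_int(p, q) != 1L)
      stop("torus knot parameters must be coprime", call. = FALSE)
    tt <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    P <- cbind((2 + cos(q * tt)) * cos(p * tt),
               (2 + cos(q * tt)) * sin(p * tt),
               sin(q * tt))
    truth <- torus_knot_label(p, q)
  } else if (kind == "twist") {
    if (!twists %in% 1:5)
      stop("twist template supports 1..5 half-twists", call. = FALSE)
    P <- twist_template(twists,
                        pts_per_turn = max(8L, ceiling(n_points / (2 * twists))))
    truth <- c("3_1", "4_1", "5_2", "6_1", "7_2")[twists]
  } else {
    tt <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    P <- cbind(3 * cos(tt), 3 * sin(tt), 0 * tt)
    truth <- "unknot"
  }
  P <- P * scale
  closed <- open_fraction <= 0
  if (closed) {
    P <- rbind(P, P[1, , drop = FALSE])
  } else {
    drop <- max(1L, ceiling(open_fraction * nrow(P)))
    P <- P[seq_len(nrow(P) - drop), , drop = FALSE]
  }
  list(points = P, truth = truth, closed = closed)
}

gcd_int <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b) { t <- b; b <- a %% b; a <- t }
  a
}

torus_knot_label <- function(p, q) {
  key <- paste(sort(c(p, q)), collapse = ",")
  switch(key, "2,3" = "3_1", "2,5" = "5_1", "2,7" = "7_1", "unknown")
}

## Twisted double-helix loop with the top lobe threaded through the bottom
## lobe. The threading handedness that yields each twist knot was fixed once
## against the closed-form Alexander polynomials.
twist_template <- function(m, pts_per_turn = 16) {
  hand <- if (m %% 2 == 0) 1 else -1
  r <- 1; H <- 3 * m
  ns <- max(12, pts_per_turn * m)
  s <- seq(0, 1, length.out = ns)
  phi <- hand * m * pi * s
  A <- cbind(r * cos(phi), r * sin(phi), H * s)
  B <- cbind(-r * cos(phi), -r * sin(phi), H * s)
  a_top <- A[ns, ]; b_top <- B[ns, ]
  cap <- rbind(
    c(2 * a_top[1], 2 * a_top[2], H + 1),
    c(0, 3, H + 1),
    c(0, 3, -0.7),
    c(0, 1.8, -0.7),
    c(0, 0, -0.7),
    c(0, -1.8, -0.7),
    c(0, -3, -0.7),
    c(0, -3, H + 1),
    c(2 * b_top[1], 2 * b_top[2], H + 1))
  th <- seq(0, pi, length.out = 9)[2:8]
  lobe <- cbind(cos(th), 0, -1.4 * sin(th))
  rbind(A, cap, B[rev(seq_len(ns)), ], lobe[rev(seq_len(nrow(lobe))), ])
}

#' Generate a dense confined random walk
#'
#' A random walk confined to a small cubic box, emulating non-physically
#' dense predicted structures whose knot diagrams stay too complex to
#' classify (the TTC category).
#'
#' @param n_steps number of steps (at least 1000 for a genuinely dense walk).
#' @param box box edge length in Angstrom.
#' @param seed RNG seed; the walk is reproducible given the seed.
#' @param step step length in Angstrom.
#' @return `n x 3` matrix of walk vertices.
#' @export
make_dense_walk <- function(n_steps = 1500, box = 15, seed = 1, step = 2) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dirs <- random_unit_vectors(n_steps - 1L) * step
  P <- apply(rbind(c(0, 0, 0), dirs), 2, cumsum)
  ## reflect into [0, box]^3
  for (d in 1:3) {
    x <- P[, d] %% (2 * box)
    P[, d] <- ifelse(x > box, 2 * box - x, x)
  }
  dedupe_points(P)
}

## ---- RNA-like model assembly -------------------------------------------

## Expand a per-residue virtual trace into 6 backbone atoms per residue
## (placed along the segment to the next residue) plus a C1' proxy offset
## toward `inward` (per-residue n x 3, or NULL for a default offset).
trace_to_atoms <- function(trace, inward = NULL) {
  n <- nrow(trace)
  frac <- c(0, 0.12, 0.3, 0.5, 0.7, 0.88)
  atoms <- list()
  for (i in seq_len(n)) {
    d <- if (i < n) trace[i + 1L, ] - trace[i, ] else
      trace[i, ] - trace[i - 1L, ]
    base_pts <- matrix(trace[i, ], 6, 3, byrow = TRUE) +
      outer(frac, d)
    off <- if (!is.null(inward)) inward[i, ] else c(0.35, 0.35, 0.35)
    c1 <- trace[i, ] + off
    atoms[[i]] <- data.frame(
      residue = i,
      atom = c(BACKBONE_ATOMS, "C1'"),
      x = c(base_pts[, 1], c1[1]),
      y = c(base_pts[, 2], c1[2]),
      z = c(base_pts[, 3], c1[3]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, atoms)
}

assemble_model <- function(atoms, bases, model_id, chain_id = "A") {
  n <- max(atoms$residue)
  if (length(bases) == 1L) bases <- rep(bases, n)
  residues <- data.frame(number = seq_len(n), icode = "",
                         base = bases, stringsAsFactors = FALSE)
  ch <- structure(list(chain_id = chain_id, residues = residues,
                       atoms = atoms[, c("residue", "atom", "x", "y", "z")]),
                  class = "chain_record")
  structure(list(model_id = model_id,
                 chains = stats::setNames(list(ch), chain_id),
                 source_path = NA_character_),
            class = "rna_model")
}

#' Convert a bare polyline to an RNA-like model
#'
#' Each polyline segment becomes one residue whose six backbone atoms
#' subdivide the segment, so the backbone read back from the written file is
#' a subdivision of the input curve (topologically identical). Written as a
#' poly-U trace.
#'
#' @param points `n x 3` polyline.
#' @param model_id identifier for the resulting model.
#' @return an `rna_model` with `n - 1` residues.
#' @export
polyline_to_model <- function(points, model_id = "curve") {
  P <- dedupe_points(as_curve_matrix(points))
  n <- nrow(P)
  frac <- c(0, 1, 2, 3, 4, 5) / 6
  atoms <- list()
  for (i in seq_len(n - 1L)) {
    d <- P[i + 1L, ] - P[i, ]
    pts <- matrix(P[i, ], 6, 3, byrow = TRUE) + outer(frac, d)
    atoms[[i]] <- data.frame(residue = i, atom = BACKBONE_ATOMS,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             stringsAsFactors = FALSE)
  }
  assemble_model(do.call(rbind, atoms), "U", model_id)
}

## Hairpin trace in a local frame: loop circle of `loop_size` + 2 residues
## in the z = 0 plane centred at the origin, stem ladder extending in -x.
## Returns the per-residue trace, inward offsets, and index bookkeeping.
hairpin_trace <- function(loop_size, stem_bp, spacing = RESIDUE_SPACING) {
  ncyc <- loop_size + 2L
  r <- ncyc * spacing / (2 * pi)
  dth <- 2 * pi / ncyc
  th <- pi + (seq_len(ncyc) - 0.5) * dth
  circle <- cbind(r * cos(th), r * sin(th), 0)
  p_i <- circle[1, ]   # closing 5' residue (innermost stem pair, 5' side)
  p_j <- circle[ncyc, ]
  n <- 2L * stem_bp + loop_size
  trace <- matrix(0, n, 3)
  inward <- matrix(0, n, 3)
  for (k in seq_len(stem_bp)) {        # 5' strand, outermost first
    trace[k, ] <- p_i - c((stem_bp - k) * spacing, 0, 0)
    inward[k, ] <- c(0, -sign(p_i[2]) * 0.5, 0)
  }
  for (k in seq_len(loop_size)) {      # loop residues
    trace[stem_bp + k, ] <- circle[1L + k, ]
    inward[stem_bp + k, ] <- -0.5 * vec_unit(circle[1L + k, ])
  }
  for (k in seq_len(stem_bp)) {        # 3' strand, innermost first
    trace[stem_bp + loop_size + k, ] <- p_j - c((k - 1) * spacing, 0, 0)
    inward[stem_bp + loop_size + k, ] <- c(0, -sign(p_j[2]) * 0.5, 0)
  }
  pairs <- data.frame(i = seq_len(stem_bp),
                      j = n + 1L - seq_len(stem_bp))
  list(trace = trace, inward = inward, pairs = pairs, n = n, radius = r,
       loop_idx = stem_bp + seq_len(loop_size))
}

hairpin_dotbracket <- function(stem_bp, loop_size, tail = 0, lead = 0) {
  paste0(strrep(".", lead), strrep("(", stem_bp), strrep(".", loop_size),
         strrep(")", stem_bp), strrep(".", tail))
}

#' Generate an unentangled hairpin model
#'
#' Clean control: a planar stem-loop with no tails and no entanglements.
#'
#' @param loop_size unpaired loop residues.
#' @param stem_bp stem base pairs.
#' @return list with `model` (an `rna_model`), `dotbracket`, and `truth`.
#' @export
make_hairpin <- function(loop_size = 6, stem_bp = 4) {
  hp <- hairpin_trace(loop_size, stem_bp)
  atoms <- trace_to_atoms(hp$trace, hp$inward)
  model <- assemble_model(atoms, "U", "hairpin")
  list(model = model,
       dotbracket = hairpin_dotbracket(stem_bp, loop_size),
       truth = list(entanglements = character(0), knotted = FALSE))
}

#' Generate a hairpin lassoed by its own 3' tail
#'
#' Builds a stem-loop whose loop plane is threaded exactly once by the
#' single-stranded 3' tail, with the crossing placed so that the lasso depth
#' (minimum count of unpaired strand nucleotides beyond the crossing toward
#' either chain end) equals `depth` exactly. With `threaded = FALSE` the
#' tail is routed outside the loop (clean control).
#'
#' @param loop_size unpaired loop residues (>= 4).
#' @param depth requested lasso depth in nucleotides (>= 1).
#' @param stem_bp stem base pairs (>= 2).
#' @param tail_len tail length; defaults to `2 * depth + 4` and must exceed
#'   `depth + 2` so the free-end side is the minimum.
#' @param threaded route the tail through the loop (`TRUE`) or past it.
#' @return list with `model`, `dotbracket`, `truth` (subclass `L(S)`, the
#'   depth, and its shallow/deep class).
#' @export
make_hairpin_lasso <- function(loop_size = 6, depth = 6, stem_bp = 3,
                               tail_len = NULL, threaded = TRUE) {
  if (loop_size < 4) stop("loop_size must be >= 4", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (is.null(tail_len)) tail_len <- 2L * depth + 4L
  if (tail_len < depth + 2L)
    stop("tail too short for requested depth", call. = FALSE)
  hp <- hairpin_trace(loop_size, stem_bp)
  n0 <- hp$n
  N <- as.integer(tail_len)
  jc <- N - depth - 1L      # crossing between tail residues jc and jc + 1
  if (jc < 2L) stop("tail too short for requested depth", call. = FALSE)
  sp <- RESIDUE_SPACING
  out3 <- hp$trace[n0, ]     # outermost 3' stem residue
  cx <- if (threaded) 0 else 3.5 * hp$radius
  ## pre-crossing leg: descend below the loop plane and approach the centre
  pre_way <- rbind(out3 + c(-2, 0, -7),
                   c(cx, -hp$radius, -7),
                   c(cx, 0, -5.3))
  pre <- resample_polyline(pre_way, jc - 1L)
  t_jc <- c(cx, 0, -5)
  t_after <- c(cx, 0, 0.55)  # crossing falls between O3'(jc) and P(jc+1)
  post <- matrix(0, depth, 3)
  post[1, ] <- c(cx, 0, 6)
  if (depth > 1L)
    for (k in seq_len(depth - 1L))
      post[k + 1L, ] <- c(cx + k * sp * 0.8, 0, 6 + k * sp * 0.6)
  tail_trace <- rbind(pre, t_jc, t_after, post)
  stopifnot(nrow(tail_trace) == N)
  trace <- rbind(hp$trace, tail_trace)
  inward <- rbind(hp$inward, matrix(0.35, N, 3))
  atoms <- trace_to_atoms(trace, inward)
  model <- assemble_model(atoms, "U", if (threaded) "hairpin_lasso"
                          else "hairpin_tail_control")
  db <- hairpin_dotbracket(stem_bp, loop_size, tail = N)
  truth <- if (threaded) {
    list(entanglements = "L(S)", depth = as.integer(depth),
         depth_class = if (depth <= 5) "shallow" else "deep",
         knotted = FALSE)
  } else {
    list(entanglements = character(0), knotted = FALSE)
  }
  list(model = model, dotbracket = db, truth = truth)
}

## Evenly resample an open polyline to exactly n points (endpoints included).
resample_polyline <- function(way, n) {
  if (n == 1L) return(way[1, , drop = FALSE])
  seg <- sqrt(rowSums((way[-1, , drop = FALSE] -
                         way[-nrow(way), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  tt <- seq(0, cum[length(cum)], length.out = n)
  t(vapply(tt, function(s) {
    k <- max(1L, min(findInterval(s, cum), length(seg)))
    f <- if (seg[k] < 1e-12) 0 else (s - cum[k]) / seg[k]
    way[k, ] + f * (way[k + 1L, ] - way[k, ])
  }, numeric(3)))
}

#' Generate two hairpin loops forming an L&L interlace
#'
#' Two stem-loops on one chain whose loop cycles are interlocked with
#' linking number +-1 (the misfolded counterpart of kissing loops). With
#' `linked = FALSE` the second loop is translated away (clean control).
#'
#' @param loop_size unpaired residues per loop.
#' @param stem_bp stem base pairs per hairpin.
#' @param linker_len unpaired residues joining the two hairpins.
#' @param linked interlock the loops (`TRUE`) or separate them.
#' @return list with `model`, `dotbracket`, `truth`.
#' @export
make_hopf_loops <- function(loop_size = 8, stem_bp = 3, linker_len = 8,
                            linked = TRUE) {
  hp <- hairpin_trace(loop_size, stem_bp)
  n0 <- hp$n
  r <- hp$radius
  ## second hairpin: rotate pi about z (stem exits +x), then +90 deg about
  ## x (loop plane z=0 -> y=0), then translate along x
  Rz <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  M <- Rx %*% Rz
  shift <- c(if (linked) r else 3 * r + 15, 0, 0)
  tr2 <- t(M %*% t(hp$trace)) + matrix(shift, n0, 3, byrow = TRUE)
  in2 <- t(M %*% t(hp$inward))
  ## linker: from the outer 3' stem end of hairpin 1 to the outer 5' stem
  ## start of hairpin 2, routed far below both loop planes
  from <- hp$trace[n0, ]
  to <- tr2[1, ]
  deep <- -(3 * r + 15)
  ## approach hairpin 2 offset in +y so the linker stays out of its plane
  way <- rbind(from + c(-4, 0, -6),
               c(from[1] - 4, from[2], deep),
               c(to[1] + 4, 4, deep),
               to + c(4, 4, -6))
  link_trace <- resample_polyline(way, linker_len)
  trace <- rbind(hp$trace, link_trace, tr2)
  inward <- rbind(hp$inward, matrix(0.35, linker_len, 3), in2)
  atoms <- trace_to_atoms(trace, inward)
  model <- assemble_model(atoms, "U", if (linked) "hopf_loops"
                          else "hopf_loops_control")
  db <- paste0(hairpin_dotbracket(stem_bp, loop_size),
               strrep(".", linker_len),
               hairpin_dotbracket(stem_bp, loop_size))
  truth <- if (linked) list(entanglements = "L&L", knotted = FALSE)
  else list(entanglements = character(0), knotted = FALSE)
  list(model = model, dotbracket = db, truth = truth)
}

#' Generate a dinucleotide step pierced by a single strand
#'
#' A three-base-pair hairpin whose middle dinucleotide step is threaded by
#' the 3' tail, producing a D(S) lasso (always an artifact).
#'
#' @param tail_len tail residues (>= 5).
#' @return list with `model`, `dotbracket`, `truth`.
#' @export
make_dinucleotide_pierce <- function(tail_len = 6) {
  if (tail_len < 5) stop("tail_len must be >= 5", call. = FALSE)
  stem_bp <- 3L; loop_size <- 4L
  hp <- hairpin_trace(loop_size, stem_bp)
  n0 <- hp$n
  sp <- RESIDUE_SPACING
  ## middle step spans pairs (2, n0-1) and (3, n0-2); its quad centre:
  mid <- (hp$trace[2, ] + hp$trace[3, ] + hp$trace[n0 - 1L, ] +
            hp$trace[n0 - 2L, ]) / 4
  out3 <- hp$trace[n0, ]
  N <- as.integer(tail_len)
  pre <- resample_polyline(rbind(out3 + c(-2, 0, -7),
                                 c(mid[1], mid[2] - r_pad(hp), -7),
                                 mid + c(0, 0, -5.3)), N - 4L)
  t_c <- mid + c(0, 0, -5)
  t_a <- mid + c(0, 0, 0.55)
  post <- rbind(mid + c(0, 0, 6), mid + c(0, -8, 8))
  trace <- rbind(hp$trace, pre, t_c, t_a, post)
  inward <- rbind(hp$inward, matrix(0.35, N, 3))
  atoms <- trace_to_atoms(trace, inward)
  model <- assemble_model(atoms, "U", "step_pierce")
  db <- hairpin_dotbracket(stem_bp, loop_size, tail = N)
  list(model = model, dotbracket = db,
       truth = list(entanglements = "D(S)", knotted = FALSE))
}

r_pad <- function(hp) hp$radius + 6

#' Generate a model with duplicated atom coordinates
#'
#' A clean hairpin in which one residue's phosphate is copied onto another
#' residue, emulating the non-unique-coordinate defect that excludes a model
#' from knot analysis.
#'
#' @return list with `model`, `dotbracket`, `truth`.
#' @export
make_duplicate_coords <- function() {
  fx <- make_hairpin()
  at <- fx$model$chains[["A"]]$atoms
  src <- which(at$residue == 3 & at$atom == "P")
  dst <- which(at$residue == 7 & at$atom == "P")
  at[dst, c("x", "y", "z")] <- at[src, c("x", "y", "z")]
  fx$model$chains[["A"]]$atoms <- at
  fx$model$model_id <- "duplicate_coords"
  fx$truth <- list(entanglements = character(0), knotted = NA,
                   invalid_coordinates = TRUE)
  fx
}

#' Generate an idealized helix with known canonical pairs
#'
#' A ladder-like double helix carrying the base atoms of the canonical
#' hydrogen-bond patterns at pairing distance, so geometric pair detection
#' recovers exactly the designed pairs. Synthetic idealized geometry, not a
#' crystallographic A-form helix.
#'
#' @param sequence5 5' strand bases (paired to the reverse complement,
#'   closing a hairpin of 4 unpaired residues).
#' @return list with `model`, `dotbracket`, `truth` (`pairs` data frame).
#' @export
make_ideal_helix <- function(sequence5 = "GCAU") {
  b5 <- strsplit(sequence5, "")[[1]]
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  b3 <- rev(unname(comp[b5]))
  stem_bp <- length(b5); loop_size <- 4L
  hp <- hairpin_trace(loop_size, stem_bp)
  n <- hp$n
  bases <- c(b5, rep("U", loop_size), b3)
  atoms <- trace_to_atoms(hp$trace, hp$inward)
  ## add base atoms: C1' 10.5 A across the pair, donors/acceptors at 2.9 A
  extra <- list()
  for (k in seq_len(stem_bp)) {
    i <- k; j <- n + 1L - k
    pi_ <- hp$trace[i, ]; pj <- hp$trace[j, ]
    u <- vec_unit(pj - pi_)
    mid <- (pi_ + pj) / 2
    c1i <- mid - 5.25 * u
    c1j <- mid + 5.25 * u
    extra[[length(extra) + 1L]] <- base_pair_atoms(i, j, bases[i], bases[j],
                                                   c1i, c1j, u)
    ## overwrite trace C1' with the pairing-geometry C1'
    atoms[atoms$residue == i & atoms$atom == "C1'", c("x", "y", "z")] <-
      as.list(c1i)
    atoms[atoms$residue == j & atoms$atom == "C1'", c("x", "y", "z")] <-
      as.list(c1j)
  }
  atoms <- rbind(atoms, do.call(rbind, extra))
  model <- assemble_model(atoms, bases, "ideal_helix")
  list(model = model,
       dotbracket = hairpin_dotbracket(stem_bp, loop_size),
       truth = list(pairs = data.frame(i = seq_len(stem_bp),
                                       j = n + 1L - seq_len(stem_bp))))
}

## Place the canonical donor/acceptor heavy atoms of a pair along the pair
## axis u, 2.9 A apart, offset sideways per bond so distances are clean.
base_pair_atoms <- function(i, j, bi, bj, c1i, c1j, u) {
  pat <- NULL
  flip <- FALSE
  for (cls in names(.pair_patterns)) {
    pp <- .pair_patterns[[cls]]
    if (bi == pp$bases[1] && bj == pp$bases[2]) { pat <- pp; break }
    if (bj == pp$bases[1] && bi == pp$bases[2]) { pat <- pp; flip <- TRUE; break }
  }
  if (is.null(pat)) return(NULL)
  perp <- vec_unit(cross3(u, c(0, 0, 1)))
  mid <- (c1i + c1j) / 2
  out <- list()
  for (b in seq_along(pat$atoms)) {
    bond <- pat$atoms[[b]]
    side <- (b - (length(pat$atoms) + 1) / 2) * 1.1
    pa <- mid - 1.45 * u + side * perp
    pb <- mid + 1.45 * u + side * perp
    ra <- if (!flip) i else j
    rb <- if (!flip) j else i
    out[[b]] <- data.frame(residue = c(ra, rb), atom = bond,
                           x = c(pa[1], pb[1]), y = c(pa[2], pb[2]),
                           z = c(pa[3], pb[3]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- fixture output -----------------------------------------------------

#' Write a fixture to disk as PDB (plus dot-bracket sidecar)
#'
#' Models are written with residue numbering from 1 and chain "A"; bare
#' polylines are converted to a poly-U backbone trace first. When the
#' fixture carries a designed secondary structure, a `.dbn` sidecar (one
#' sequence line, one layered dot-bracket line) is written next to the PDB.
#'
#' @param x a fixture list (from a `make_*` generator), an `rna_model`, or
#'   an `n x 3` polyline.
#' @param path output PDB path.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(x, path) {
  db <- NULL
  truth <- NULL
  if (is.list(x) && !inherits(x, "rna_model") && !is.null(x$model)) {
    db <- x$dotbracket
    truth <- x$truth
    x <- x$model
  }
  if (is.matrix(x)) x <- polyline_to_model(x, tools::file_path_sans_ext(basename(path)))
  stopifnot(inherits(x, "rna_model"))
  at <- model_atoms(x)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  base_of <- unlist(lapply(x$chains, function(ch) ch$residues$base))
  resid_full <- unlist(lapply(x$chains, function(ch) ch$residues$base[ch$atoms$residue]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residue, chain = at$chain,
                   resid = ifelse(resid_full == "other", "N", resid_full),
                   elety = at$atom, eleno = seq_len(nrow(at)))
  paths <- path
  if (!is.null(db)) {
    dbn <- paste0(tools::file_path_sans_ext(path), ".dbn")
    seqline <- paste(ifelse(base_of == "other", "N", base_of), collapse = "")
    writeLines(c(seqline, db), dbn)
    paths <- c(paths, dbn)
  }
  if (!is.null(truth)) {
    tj <- paste0(tools::file_path_sans_ext(path), ".truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, tj)
  }
  invisible(paths)
}
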