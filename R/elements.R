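## Decomposition of a model into structural elements: loops (L),
## dinucleotide steps (D), and single-stranded fragments (S), each carried
## as a 3D polyline with per-segment provenance (backbone vs hydrogen bond).

#' Find loop elements
#'
#' One loop per cycle of the standard loop decomposition: a closing pair
#' (i, j) together with the maximal set of directly enclosed pairs, the cycle
#' alternating backbone paths with hydrogen-bond edges. Cycles consisting of
#' exactly two stacked pairs belong to helix interiors and are emitted by
#' [find_dinucleotide_steps()] instead. Pairs from deeper pseudoknot layers
#' close loops exactly like nested pairs.
#'
#' @param ss a `secondary_structure`.
#' @param chain the `chain_record` the pairs are defined on.
#' @return list of `structural_element` objects of kind `"loop"`.
#' @export
find_loops <- function(ss, chain) {
  p <- ss$pairs
  out <- list()
  for (k in seq_len(nrow(p))) {
    i <- p$i[k]; j <- p$j[k]
    kids <- direct_children(p, i, j)
    if (nrow(kids) == 1L && kids$i[1] == i + 1L && kids$j[1] == j - 1L)
      next  # helix interior: a dinucleotide step, not a loop
    el <- build_loop_element(chain, i, j, kids)
    if (!is.null(el)) out[[length(out) + 1L]] <- el
  }
  out
}

## Maximal pairs directly enclosed by (i, j): inside the interval, not nested
## within another inside pair, mutually non-crossing (greedy left to right).
direct_children <- function(p, i, j) {
  inside <- p[p$i > i & p$j < j, , drop = FALSE]
  if (!nrow(inside)) return(inside)
  ## keep only pairs not nested inside another inside pair
  top <- vapply(seq_len(nrow(inside)), function(k) {
    !any(inside$i < inside$i[k] & inside$j > inside$j[k])
  }, logical(1))
  inside <- inside[top, , drop = FALSE]
  inside <- inside[order(inside$i), , drop = FALSE]
  keep <- logical(nrow(inside))
  last_j <- i
  for (k in seq_len(nrow(inside))) {
    if (inside$i[k] > last_j) {
      keep[k] <- TRUE
      last_j <- inside$j[k]
    }
  }
  inside[keep, , drop = FALSE]
}

#' Find dinucleotide-step elements
#'
#' One element per pair of consecutive stacked pairs (i, j), (i+1, j-1):
#' the closed quadrilateral backbone i to i+1, hydrogen bond (i+1)-(j-1),
#' backbone (j-1) to j, hydrogen bond j-i.
#'
#' @inheritParams find_loops
#' @return list of `structural_element` objects of kind `"dinucleotide_step"`.
#' @export
find_dinucleotide_steps <- function(ss, chain) {
  p <- ss$pairs
  out <- list()
  if (!nrow(p)) return(out)
  key <- paste(p$i, p$j)
  for (k in seq_len(nrow(p))) {
    i <- p$i[k]; j <- p$j[k]
    if (paste(i + 1L, j - 1L) %in% key) {
      el <- build_step_element(chain, i, j)
      if (!is.null(el)) out[[length(out) + 1L]] <- el
    }
  }
  out
}

#' Find single-stranded fragments
#'
#' Maximal runs of unpaired residues that are not enclosed by any base pair
#' (dangling ends and inter-domain linkers; unpaired residues inside a loop
#' cycle already belong to that loop). Runs are extended by their flanking
#' paired residues (anchors) when those exist, so threading near a strand
#' end remains detectable; depth counting uses the unpaired residues only.
#'
#' @inheritParams find_loops
#' @return list of `structural_element` objects of kind `"single_strand"`.
#' @export
find_single_strands <- function(ss, chain) {
  n <- ss$n_residues
  paired <- logical(n)
  p <- ss$pairs
  paired[c(p$i, p$j)] <- TRUE
  out <- list()
  r <- 1L
  while (r <= n) {
    if (paired[r]) { r <- r + 1L; next }
    start <- r
    while (r <= n && !paired[r]) r <- r + 1L
    end <- r - 1L
    enclosed <- nrow(p) && any(p$i < start & p$j > end)
    if (!enclosed) {
      lo <- if (start > 1L) start - 1L else start
      hi <- if (end < n) end + 1L else end
      el <- build_strand_element(chain, lo:hi, start:end)
      if (!is.null(el)) out[[length(out) + 1L]] <- el
    }
  }
  out
}

#' All structural elements of a chain
#'
#' @inheritParams find_loops
#' @return list of `structural_element`s: loops, then dinucleotide steps,
#'   then single strands.
#' @export
find_elements <- function(ss, chain) {
  c(find_loops(ss, chain), find_dinucleotide_steps(ss, chain),
    find_single_strands(ss, chain))
}

## ---- curve construction -------------------------------------------------

## Proxy point anchoring hydrogen-bond edges at a residue: C1' when present,
## else C4' (pure-backbone fixtures).
residue_proxy <- function(chain, r) {
  sub <- chain$atoms[chain$atoms$residue == r, , drop = FALSE]
  for (nm in c("C1'", "C4'")) {
    hit <- which(sub$atom == nm)
    if (length(hit)) return(c(sub$x[hit[1]], sub$y[hit[1]], sub$z[hit[1]]))
  }
  NULL
}

## Backbone atoms of residues r1..r2 in order; NULL when a residue has no
## backbone atoms at all.
backbone_run <- function(chain, rs) {
  pts <- list(); rix <- integer(0)
  for (r in rs) {
    sub <- chain$atoms[chain$atoms$residue == r, , drop = FALSE]
    m <- match(BACKBONE_ATOMS, sub$atom)
    m <- m[!is.na(m)]
    if (!length(m)) return(NULL)
    pts[[length(pts) + 1L]] <- as.matrix(sub[m, c("x", "y", "z")])
    rix <- c(rix, rep(r, length(m)))
  }
  P <- do.call(rbind, pts)
  dimnames(P) <- NULL
  list(points = P, residues = rix)
}

new_element <- function(kind, closed, residues, curve, res_of_point,
                        provenance, chain_id, label) {
  structure(list(kind = kind, closed = closed, residues = residues,
                 curve = curve, residue_of_point = res_of_point,
                 provenance = provenance, chain_id = chain_id,
                 label = label),
            class = "structural_element")
}

#' @export
print.structural_element <- function(x, ...) {
  cat("<element>", x$label, if (x$closed) "(closed)" else "(open)",
      "-", length(x$residues), "residues,",
      nrow(x$curve) - 1L, "segments\n")
  invisible(x)
}

## Closed cycle alternating backbone arcs with hydrogen-bond edges.
## arcs: list of residue vectors; after each arc a hydrogen bond jumps to
## the start of the next arc (cyclically).
build_cycle_curve <- function(chain, arcs) {
  pts <- NULL; rix <- integer(0); prov <- character(0)
  add_seg <- function(p, r, tag) {
    if (is.null(pts)) {
      pts <<- matrix(p, ncol = 3)
      rix <<- r
    } else {
      prev <- nrow(pts)
      pts <<- rbind(pts, p)
      rix <<- c(rix, r)
      prov <<- c(prov, rep(tag, nrow(pts) - prev))
    }
  }
  for (a in seq_along(arcs)) {
    rs <- arcs[[a]]
    pr1 <- residue_proxy(chain, rs[1])
    bb <- backbone_run(chain, rs)
    pr2 <- residue_proxy(chain, rs[length(rs)])
    if (is.null(pr1) || is.null(pr2) || is.null(bb)) return(NULL)
    add_seg(pr1, rs[1], if (a == 1) "backbone" else "hydrogen_bond")
    for (k in seq_len(nrow(bb$points)))
      add_seg(bb$points[k, ], bb$residues[k], "backbone")
    add_seg(pr2, rs[length(rs)], "backbone")
  }
  ## close with the final hydrogen bond back to the first proxy point
  add_seg(pts[1, ], rix[1], "hydrogen_bond")
  pts <- dedupe_curve_keep_prov(pts, rix, prov)
  pts
}

dedupe_curve_keep_prov <- function(pts, rix, prov) {
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-18)
  ## segment k joins point k and k+1; provenance indexed by segment
  seg_keep <- keep[-1]
  list(points = pts[keep, , drop = FALSE], residues = rix[keep],
       provenance = prov[seg_keep])
}

build_loop_element <- function(chain, i, j, kids) {
  bounds <- rbind(data.frame(i = i, j = j), kids[, c("i", "j")])
  arcs <- list()
  ## first arc starts at the closing pair's 5' residue
  if (nrow(kids)) {
    ks <- kids[order(kids$i), , drop = FALSE]
    arcs[[1]] <- i:ks$i[1]
    for (t in seq_len(nrow(ks))) {
      nxt <- if (t < nrow(ks)) ks$i[t + 1L] else j
      arcs[[length(arcs) + 1L]] <- ks$j[t]:nxt
    }
  } else {
    arcs[[1]] <- i:j
  }
  cc <- build_cycle_curve(chain, arcs)
  if (is.null(cc)) {
    warning("loop (", i, ",", j, "): missing atoms, element dropped",
            call. = FALSE)
    return(NULL)
  }
  residues <- sort(unique(unlist(arcs)))
  new_element("loop", TRUE, residues, cc$points, cc$residues, cc$provenance,
              chain$chain_id, paste0("L[", i, "-", j, "]"))
}

build_step_element <- function(chain, i, j) {
  arcs <- list(i:(i + 1L), (j - 1L):j)
  cc <- build_cycle_curve(chain, arcs)
  if (is.null(cc)) {
    warning("step (", i, ",", j, "): missing atoms, element dropped",
            call. = FALSE)
    return(NULL)
  }
  new_element("dinucleotide_step", TRUE, c(i, i + 1L, j - 1L, j),
              cc$points, cc$residues, cc$provenance, chain$chain_id,
              paste0("D[", i, "+", i + 1L, "/", j - 1L, "+", j, "]"))
}

build_strand_element <- function(chain, residues, unpaired) {
  bb <- backbone_run(chain, residues)
  if (is.null(bb)) {
    warning("strand (", residues[1], "-", residues[length(residues)],
            "): missing atoms, element dropped", call. = FALSE)
    return(NULL)
  }
  P <- dedupe_points(bb$points)
  keep <- c(TRUE, rowSums((bb$points[-1, , drop = FALSE] -
                             bb$points[-nrow(bb$points), , drop = FALSE])^2) > 1e-18)
  el <- new_element("single_strand", FALSE, residues, P,
                    bb$residues[keep],
                    rep("backbone", nrow(P) - 1L), chain$chain_id,
                    paste0("S[", residues[1], "-",
                           residues[length(residues)], "]"))
  el$unpaired <- unpaired
  el
}
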