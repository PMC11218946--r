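square_loop <- function(side = 10) {
  rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0),
        c(0, 0, 0))
}

surface_area <- function(s) {
  V <- s$vertices
  sum(vapply(seq_len(nrow(s$triangles)), function(k) {
    tr <- s$triangles[k, ]
    0.5 * sqrt(sum(rnatangle:::cross3(V[tr[2], ] - V[tr[1], ],
                                      V[tr[3], ] - V[tr[1], ])^2))
  }, numeric(1)))
}

test_that("spanning surfaces stay in the boundary plane with the right area", {
  s <- span_surface(square_loop(10))
  expect_lt(abs(surface_area(s) - 100) / 100, 0.01)
  expect_true(all(abs(s$vertices[, 3]) < 1e-9))

  t <- seq(0, 2 * pi, length.out = 13)[-13]
  gon <- cbind(cos(t), sin(t), 0)
  s2 <- span_surface(rbind(gon, gon[1, ]))
  expect_true(all(abs(s2$vertices[, 3]) < 1e-9))

  ## dinucleotide-step quadrilateral: 4-triangle fan before subdivision
  s3 <- span_surface(square_loop(5), subdivision_rounds = 0)
  expect_equal(nrow(s3$triangles), 4)
})

test_that("punctures are found analytically for simple geometry", {
  surf <- span_surface(square_loop(10))
  strand <- list(curve = rbind(c(5, 5, -8), c(5, 5, 8)),
                 residue_of_point = c(1L, 2L),
                 provenance = "backbone", kind = "single_strand",
                 closed = FALSE, residues = 1:2,
                 chain_id = "A", label = "S")
  class(strand) <- "structural_element"
  p <- find_punctures(surf, strand)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$x, p$y, p$z), c(5, 5, 0), tolerance = 1e-6)

  outside <- strand
  outside$curve <- rbind(c(15, 5, -8), c(15, 5, 8))
  expect_equal(nrow(find_punctures(surf, outside)), 0)

  ## a loop threading in and out: 2 punctures with opposite signs
  thru <- strand
  thru$curve <- rbind(c(3, 5, -4), c(3, 5, 4), c(7, 5, 4), c(7, 5, -4),
                      c(3, 5, -4))
  thru$closed <- TRUE
  thru$residue_of_point <- c(1L, 2L, 3L, 4L, 1L)
  thru$provenance <- rep("backbone", 4)
  p2 <- find_punctures(surf, thru)
  expect_equal(nrow(p2), 2)
  expect_setequal(p2$sign, c(-1, 1))
})

test_that("linking numbers match analytic constructions", {
  hc <- hopf_circles()
  expect_equal(abs(linking_number(hc$a, hc$b)), 1)

  ## disjoint side-by-side circles
  t <- seq(0, 2 * pi, length.out = 41)
  a <- cbind(cos(t), sin(t), 0)
  b <- cbind(10 + cos(t), sin(t), 0)
  expect_equal(linking_number(a, b), 0)

  ## doubly wound link: a coil winding twice around the circle's tube,
  ## with a small y-drift separating the two turns
  r <- 5
  s <- seq(0, 4 * pi, length.out = 81)[-81]
  wind <- cbind(r + 1.5 * cos(s), 0.3 * sin(s / 2), 1.5 * sin(s))
  wind <- rbind(wind, wind[1, ])
  circ <- cbind(r * cos(t), r * sin(t), 0)
  expect_equal(abs(linking_number(circ, wind)), 2)
})

test_that("signed punctures equal the linking number on linked fixtures", {
  fx <- make_hopf_loops()
  ss <- annotate_base_pairs(fx$model, "dotbracket", dotbracket = fx$dotbracket)
  els <- find_elements(ss, fx$model$chains[[1]])
  loops <- Filter(function(e) e$kind == "loop", els)
  expect_length(loops, 2)
  lk <- linking_number(loops[[1]], loops[[2]])
  expect_equal(abs(lk), 1)
  p <- find_punctures(span_surface(loops[[1]]), loops[[2]])
  expect_equal(abs(sum(p$sign)), abs(lk))
  ## and for the unlinked control both vanish
  fx0 <- make_hopf_loops(linked = FALSE)
  ss0 <- annotate_base_pairs(fx0$model, "dotbracket", dotbracket = fx0$dotbracket)
  loops0 <- Filter(function(e) e$kind == "loop",
                   find_elements(ss0, fx0$model$chains[[1]]))
  expect_equal(linking_number(loops0[[1]], loops0[[2]]), 0)
  expect_equal(sum(find_punctures(span_surface(loops0[[1]]),
                                  loops0[[2]])$sign), 0)
})

test_that("the taxonomy assigns L&L, L(S), D(S) on the designed fixtures", {
  run <- function(fx) {
    ss <- annotate_base_pairs(fx$model, "dotbracket",
                              dotbracket = fx$dotbracket)
    entanglement_table(detect_all(fx$model, ss))
  }
  hopf <- run(make_hopf_loops())
  expect_equal(nrow(hopf), 1)
  expect_equal(hopf$subclass, "L&L")
  expect_true(hopf$artifact)

  lasso <- run(make_hairpin_lasso(depth = 7))
  expect_equal(nrow(lasso), 1)
  expect_equal(lasso$subclass, "L(S)")
  expect_equal(lasso$n_intersections, 1)

  ds <- run(make_dinucleotide_pierce())
  expect_equal(nrow(ds), 1)
  expect_equal(ds$subclass, "D(S)")
  expect_true(ds$artifact)

  expect_equal(nrow(run(make_hairpin())), 0)
  expect_equal(nrow(run(make_hopf_loops(linked = FALSE))), 0)
  expect_equal(nrow(run(make_hairpin_lasso(depth = 7, threaded = FALSE))), 0)
})

test_that("entanglement labels do not depend on surface refinement", {
  for (fx in list(make_hairpin_lasso(depth = 3), make_hopf_loops(),
                  make_dinucleotide_pierce())) {
    ss <- annotate_base_pairs(fx$model, "dotbracket",
                              dotbracket = fx$dotbracket)
    t1 <- entanglement_table(detect_all(fx$model, ss, subdivision_rounds = 1))
    t3 <- entanglement_table(detect_all(fx$model, ss, subdivision_rounds = 3))
    expect_equal(t1$subclass, t3$subclass)
    expect_equal(t1$depth, t3$depth)
  }
})

test_that("programmed lasso depths 1..10 are recovered exactly", {
  for (d in 1:10) {
    fx <- make_hairpin_lasso(depth = d)
    ss <- annotate_base_pairs(fx$model, "dotbracket",
                              dotbracket = fx$dotbracket)
    tab <- entanglement_table(detect_all(fx$model, ss))
    expect_equal(nrow(tab), 1, info = paste("depth", d))
    expect_equal(tab$depth, d, info = paste("depth", d))
    expect_equal(tab$depth_class, if (d <= 5) "shallow" else "deep")
    expect_equal(tab$artifact, d > 5)
  }
})

test_that("double-puncture depth counts residues between the crossings", {
  ## synthetic L(L)-style entanglement with two punctures 8 residues apart
  fx <- make_hairpin_lasso(depth = 3, tail_len = 20)
  ss <- annotate_base_pairs(fx$model, "dotbracket", dotbracket = fx$dotbracket)
  els <- find_elements(ss, fx$model$chains[[1]])
  loop <- Filter(function(e) e$kind == "loop", els)[[1]]
  strand <- Filter(function(e) e$kind == "single_strand", els)[[1]]
  p1 <- find_punctures(span_surface(loop), strand)
  ## fabricate the second crossing 8 residues upstream of the first
  p2 <- p1
  p2$residue_a <- p1$residue_a - 8L
  p2$residue_b <- p1$residue_b - 8L
  ent <- classify_pair(loop, strand, rbind(p1, p2), lk = NA)
  expect_equal(ent$depth, 8)
  expect_equal(ent$depth_class, "deep")
})
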