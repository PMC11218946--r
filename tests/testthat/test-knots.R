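closed_label <- function(P) {
  classify_knot(alexander_polynomial(project_to_diagram(kmt_reduce(P))))
}

test_that("Alexander polynomials of parametric knots match closed forms", {
  set.seed(101)
  for (pq in list(c(2, 3), c(2, 5), c(2, 7))) {
    cur <- make_knot_curve("torus", p = pq[1], q = pq[2], n_points = 180)
    co <- alexander_polynomial(project_to_diagram(kmt_reduce(cur$points)))
    expect_equal(as.numeric(co),
                 as.numeric(oracle_alexander_torus(pq[1], pq[2])),
                 info = paste("torus", pq[1], pq[2]))
  }
  for (m in 1:5) {
    cur <- make_knot_curve("twist", twists = m)
    co <- alexander_polynomial(project_to_diagram(kmt_reduce(cur$points)))
    expect_equal(as.numeric(co), as.numeric(oracle_alexander_twist(m)),
                 info = paste("twist", m))
  }
  ## figure-eight parametric curve agrees with the twist template family
  co8 <- alexander_polynomial(project_to_diagram(kmt_reduce(fig8_curve())))
  expect_equal(as.numeric(co8), c(1, -3, 1))
})

test_that("knot determinant |Delta(-1)| is odd, and 1 only for the unknot", {
  set.seed(3)
  dets <- c()
  for (m in 1:5) {
    co <- alexander_polynomial(project_to_diagram(
      kmt_reduce(make_knot_curve("twist", twists = m)$points)))
    dets <- c(dets, knot_determinant(co))
  }
  expect_true(all(dets %% 2 == 1))
  expect_true(all(dets > 1))
  circ <- make_knot_curve("unknot", n_points = 60)
  expect_equal(knot_determinant(alexander_polynomial(
    project_to_diagram(circ$points))), 1)
})

test_that("the Alexander polynomial is a projection, reduction, and
           orientation invariant", {
  set.seed(7)
  P <- make_knot_curve("torus", p = 2, q = 3, n_points = 200)$points
  ref <- alexander_polynomial(project_to_diagram(P))  # unreduced
  red <- kmt_reduce(P)
  for (k in 1:8)
    expect_equal(as.numeric(alexander_polynomial(project_to_diagram(red))),
                 as.numeric(ref))
  rev_cur <- P[rev(seq_len(nrow(P))), ]
  expect_equal(as.numeric(alexander_polynomial(project_to_diagram(rev_cur))),
               as.numeric(ref))
})

test_that("KMT reduction collapses unobstructed geometry and keeps topology", {
  ## planar convex 20-gon: nothing can obstruct, reduces to a triangle
  t <- seq(0, 2 * pi, length.out = 21)
  poly <- cbind(cos(t), sin(t), 0)
  red <- kmt_reduce(poly)
  expect_equal(nrow(unique(round(red, 9))), 3)

  ## 3-point chain returned unchanged
  three <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  expect_equal(kmt_reduce(three), three)

  ## open-chain endpoints are never removed
  set.seed(5)
  open_tref <- make_knot_curve("torus", 2, 3, n_points = 150,
                               open_fraction = 0.05)$points
  red2 <- kmt_reduce(open_tref, fixed_endpoints = TRUE)
  expect_equal(red2[1, ], open_tref[1, ])
  expect_equal(red2[nrow(red2), ], open_tref[nrow(open_tref), ])
  expect_lt(nrow(red2), nrow(open_tref))
})

test_that("projection produces minimal diagrams in general position", {
  set.seed(11)
  ## planar triangle: no crossings
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(project_to_diagram(tri)$n_crossings, 0)

  ## trefoil: some projection of the reduced curve achieves the minimal
  ## 3-crossing diagram with all signs equal
  red <- kmt_reduce(make_knot_curve("torus", 2, 3, n_points = 180)$points)
  found <- FALSE
  for (k in 1:40) {
    d <- project_to_diagram(red)
    if (d$n_crossings == 3 && length(unique(d$crossings$sign)) == 1) {
      found <- TRUE; break
    }
    expect_gte(d$n_crossings, 3)
  }
  expect_true(found)

  ## figure-eight minimal diagram, written down from its alternating Gauss
  ## code (O1+ U2+ O3- U4- O2+ U1+ O4- U3-): 4 crossings, writhe 0, and the
  ## Alexander matrix route reproduces 1 - 3t + t^2 (worked by hand from
  ## the crossing relations)
  d8 <- structure(list(
    n_crossings = 4L, n_arcs = 4L,
    crossings = data.frame(over_arc = c(4L, 2L, 1L, 3L),
                           under_in = c(2L, 4L, 3L, 1L),
                           under_out = c(3L, 1L, 4L, 2L),
                           sign = c(1L, 1L, -1L, -1L))),
    class = "knot_diagram")
  expect_equal(sum(d8$crossings$sign), 0)
  co <- alexander_polynomial(d8)
  expect_equal(as.numeric(co), c(1, -3, 1))
  expect_equal(knot_determinant(co), 5)
  expect_equal(classify_knot(co), "4_1")
})

test_that("knot classification covers the table through 7 crossings", {
  expect_equal(classify_knot(c(1)), "unknot")
  expect_equal(classify_knot(c(1, -1, 1)), "3_1")
  expect_equal(classify_knot(c(3, -5, 3)), "7_2")
  expect_equal(classify_knot(c(2, -4, 5, -4, 2)), "7_5")
  expect_equal(classify_knot(c(1, -2, 3, -2, 1)), "unknown")  # 3_1 # 3_1
})

test_that("random closures label an opened trefoil 3_1 and are reproducible", {
  cur <- make_knot_curve("torus", 2, 3, n_points = 200, open_fraction = 0.05)
  ka <- assess_knot(cur$points, n_closures = 200, seed = 42)
  expect_true(ka$knotted)
  expect_equal(ka$dominant_label, "3_1")
  expect_gte(ka$closure_histogram[["3_1"]] / ka$n_completed, 0.9)
  expect_false(ka$ambiguous)
  expect_equal(ka$direct_closure_label, "3_1")

  ## bit-for-bit reproducibility given (input, seed, n_closures)
  ka2 <- assess_knot(cur$points, n_closures = 200, seed = 42)
  expect_identical(ka$closure_histogram, ka2$closure_histogram)

  ## different seeds agree within 10 percentage points on the 3_1 bin
  ka3 <- assess_knot(cur$points, n_closures = 100, seed = 7)
  f1 <- ka$closure_histogram[["3_1"]] / ka$n_completed
  f3 <- ka3$closure_histogram[["3_1"]] / ka3$n_completed
  expect_lt(abs(f1 - f3), 0.1)
})

test_that("straight and planar chains are unknots under any closure", {
  straight <- cbind(seq(0, 60, length.out = 20), 0, 0)
  ka <- assess_knot(straight, n_closures = 50, seed = 7)
  expect_false(ka$knotted)
  expect_equal(ka$dominant_label, "unknot")
  u <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  lab <- classify_knot(alexander_polynomial(project_to_diagram(
    direct_closure(u)$points)))
  expect_equal(lab, "unknot")
})

test_that("direct closure appends one segment and keeps closed input as is", {
  u <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0))
  cl <- direct_closure(u)
  expect_equal(nrow(cl$points), 4)
  expect_equal(cl$points[4, ], cl$points[1, ])
  expect_equal(nrow(direct_closure(cl$points)$points), 4)
})

test_that("dense confined walks are too tangled to check; duplicates error", {
  dw <- make_dense_walk(n_steps = 1500, box = 15, seed = 5)
  ka <- assess_knot(dw, n_closures = 50, seed = 7)
  expect_true(ka$ttc)

  ## dilute walk is not TTC
  loose <- make_dense_walk(n_steps = 100, box = 1000, seed = 3, step = 12)
  ka2 <- assess_knot(loose, n_closures = 20, seed = 7)
  expect_false(ka2$ttc)

  ## duplicated coordinates abort the assessment (invalid-coordinates)
  bad <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(5, 0, 0), c(9, 2, 1))
  expect_error(assess_knot(bad, n_closures = 5, seed = 1),
               class = "invalid_coordinates")
})
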