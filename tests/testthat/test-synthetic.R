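test_that("knot-curve generators carry their own truth labels", {
  set.seed(9)
  panel <- list(
    make_knot_curve("torus", 2, 3, n_points = 160),
    make_knot_curve("torus", 2, 5, n_points = 160),
    make_knot_curve("torus", 2, 7, n_points = 160),
    make_knot_curve("twist", twists = 2),
    make_knot_curve("twist", twists = 3),
    make_knot_curve("twist", twists = 5),
    make_knot_curve("unknot", n_points = 80))
  for (cur in panel) {
    lab <- classify_knot(alexander_polynomial(project_to_diagram(
      kmt_reduce(cur$points))))
    expect_equal(lab, cur$truth)
  }
  expect_error(make_knot_curve("torus", p = 2, q = 4), "coprime")
})

test_that("opened knot curves keep their knot core", {
  cur <- make_knot_curve("torus", 2, 3, n_points = 200, open_fraction = 0.05)
  expect_false(cur$closed)
  ka <- assess_knot(cur$points, n_closures = 50, seed = 13)
  expect_true(ka$knotted)
  expect_equal(ka$dominant_label, "3_1")
})

test_that("generators are deterministic under a fixed seed", {
  w1 <- make_dense_walk(1200, box = 20, seed = 99)
  w2 <- make_dense_walk(1200, box = 20, seed = 99)
  expect_identical(w1, w2)
  w3 <- make_dense_walk(1200, box = 20, seed = 100)
  expect_false(identical(w1, w3))
  ## model generators are parameter-deterministic
  expect_identical(make_hairpin_lasso(depth = 4), make_hairpin_lasso(depth = 4))
})

test_that("fixture files round-trip: PDB, dot-bracket sidecar, truth JSON", {
  d <- withr::local_tempdir()
  fx <- make_hairpin_lasso(depth = 6)
  paths <- write_fixture(fx, file.path(d, "lasso.pdb"))
  expect_true(all(file.exists(paths)))
  m <- read_model(file.path(d, "lasso.pdb"))
  expect_equal(nrow(m$chains[[1]]$residues),
               nrow(fx$model$chains[[1]]$residues))
  dbn <- readLines(file.path(d, "lasso.dbn"))
  expect_equal(nchar(dbn[2]), nrow(m$chains[[1]]$residues))
  ss <- annotate_base_pairs(m, "dotbracket", dotbracket = dbn[2])
  expect_equal(nrow(ss$pairs), 3)
  truth <- jsonlite::read_json(file.path(d, "lasso.truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$depth, 6)

  ## bare polylines are written as a poly-U backbone trace
  cur <- make_knot_curve("torus", 2, 3, n_points = 120, open_fraction = 0.05)
  p2 <- file.path(d, "curve.pdb")
  write_fixture(cur$points, p2)
  m2 <- read_model(p2)
  expect_true(all(m2$chains[[1]]$residues$base == "U"))
  ka <- assess_knot(extract_backbone(m2), n_closures = 40, seed = 3)
  expect_true(ka$knotted)
  expect_equal(ka$dominant_label, "3_1")
})

test_that("the entanglement truth of every model generator is recovered", {
  fixtures <- list(make_hairpin(), make_hairpin_lasso(depth = 7),
                   make_hairpin_lasso(depth = 5),
                   make_hopf_loops(), make_dinucleotide_pierce())
  for (fx in fixtures) {
    ss <- annotate_base_pairs(fx$model, "dotbracket",
                              dotbracket = fx$dotbracket)
    tab <- entanglement_table(detect_all(fx$model, ss))
    expect_equal(sort(tab$subclass), sort(fx$truth$entanglements))
    if (!is.null(fx$truth$depth)) {
      expect_equal(tab$depth, fx$truth$depth)
      expect_equal(tab$depth_class, fx$truth$depth_class)
    }
  }
})
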