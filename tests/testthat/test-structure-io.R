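test_that("models written by the synthetic module round-trip through PDB", {
  d <- withr::local_tempdir()
  fx <- make_hairpin(loop_size = 6, stem_bp = 4)
  p <- file.path(d, "hairpin.pdb")
  write_fixture(fx, p)
  m <- read_model(p)
  expect_length(m$chains, 1)
  expect_equal(nrow(m$chains[[1]]$residues), 14)
  ## coordinates identical to PDB precision
  a0 <- fx$model$chains[[1]]$atoms
  a1 <- m$chains[[1]]$atoms
  expect_equal(nrow(a0), nrow(a1))
  ord0 <- order(a0$residue, a0$atom)
  ord1 <- order(a1$residue, a1$atom)
  expect_equal(a1$x[ord1], a0$x[ord0], tolerance = 1e-3)
  expect_equal(a1$z[ord1], a0$z[ord0], tolerance = 1e-3)
})

test_that("two-chain files keep chains in file order; non-RNA files error", {
  d <- withr::local_tempdir()
  fx <- make_hairpin()
  at <- model_atoms_for_test(fx$model)
  p <- file.path(d, "two.pdb")
  bio3d::write.pdb(file = p,
                   xyz = c(t(as.matrix(at[, c("x", "y", "z")])),
                           t(as.matrix(at[, c("x", "y", "z")]) + 100)),
                   resno = c(at$residue, at$residue),
                   chain = c(rep("A", nrow(at)), rep("B", nrow(at))),
                   resid = rep("U", 2 * nrow(at)),
                   elety = c(at$atom, at$atom),
                   eleno = seq_len(2 * nrow(at)))
  m <- read_model(p)
  expect_equal(names(m$chains), c("A", "B"))

  prot <- file.path(d, "prot.pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "END"), prot)
  expect_error(read_model(prot), "no RNA residues")
})

test_that("CASP TS headers are stripped before parsing", {
  d <- withr::local_tempdir()
  fx <- make_hairpin()
  p <- file.path(d, "R1107TS999_1.pdb")
  write_fixture(fx, p)
  lines <- readLines(p)
  withcasp <- c("PFRMAT TS", "TARGET R1107", "AUTHOR 1234-5678-9000",
                "METHOD some free text", lines)
  writeLines(withcasp, p)
  m <- read_model(p)
  expect_equal(nrow(m$chains[[1]]$residues), 14)
  expect_equal(parse_casp_model_id(m$model_id),
               list(target_id = "R1107", group_id = "TS999", index = 1L))
})

test_that("duplicate-coordinate detection respects the tolerance", {
  m <- make_hairpin()$model
  expect_equal(nrow(detect_duplicate_coordinates(m)), 0)

  dup <- make_duplicate_coords()$model
  hits <- detect_duplicate_coordinates(dup)
  expect_equal(nrow(hits), 1)
  expect_setequal(c(hits$residue_a, hits$residue_b), c(3, 7))

  ## atoms 0.005 A apart: invisible at tolerance 0, caught at 0.01
  near <- make_hairpin()$model
  at <- near$chains[[1]]$atoms
  src <- which(at$residue == 3 & at$atom == "P")
  dst <- which(at$residue == 7 & at$atom == "P")
  at[dst, c("x", "y", "z")] <- at[src, c("x", "y", "z")] + c(0.005, 0, 0)
  near$chains[[1]]$atoms <- at
  expect_equal(nrow(detect_duplicate_coordinates(near, tolerance = 0)), 0)
  expect_equal(nrow(detect_duplicate_coordinates(near, tolerance = 0.01)), 1)
})

test_that("backbone extraction follows the fixed atom order and skip rules", {
  fx <- make_hairpin(loop_size = 6, stem_bp = 2)  # 10 residues
  bb <- extract_backbone(fx$model)
  expect_equal(nrow(bb$points), 60)
  expect_equal(unname(bb$residue_of_point), rep(1:10, each = 6))

  ## missing P on residue 1 tolerated
  m <- fx$model
  at <- m$chains[[1]]$atoms
  m$chains[[1]]$atoms <- at[!(at$residue == 1 & at$atom == "P"), ]
  expect_equal(nrow(extract_backbone(m)$points), 59)

  ## residue 5 missing C4' -> skipped with a warning
  m2 <- fx$model
  at <- m2$chains[[1]]$atoms
  m2$chains[[1]]$atoms <- at[!(at$residue == 5 & at$atom == "C4'"), ]
  expect_warning(bb2 <- extract_backbone(m2), "skipped")
  expect_equal(nrow(bb2$points), 54)
  expect_false(5 %in% bb2$residue_of_point)

  expect_error(extract_backbone(fx$model, "Z"), "no chain")
})

test_that("dot-bracket parsing matches an independent bracket matcher", {
  fx <- make_hairpin(loop_size = 4, stem_bp = 4)  # 12 nt
  ss <- annotate_base_pairs(fx$model, "dotbracket",
                            dotbracket = "((((....))))")
  expect_equal(ss$pairs$i, 1:4)
  expect_equal(ss$pairs$j, 12:9)

  db <- "((..[[..))..]]"
  fx2 <- make_hairpin(loop_size = 6, stem_bp = 4)  # 14 nt
  ss2 <- annotate_base_pairs(fx2$model, "dotbracket", dotbracket = db)
  oracle <- oracle_bracket_pairs(db)
  expect_equal(cbind(ss2$pairs$i, ss2$pairs$j), unname(oracle))
  expect_equal(sort(unique(ss2$pairs$layer)), 1:2)
  ## round trip through the serializer
  expect_equal(write_dotbracket(ss2), db)

  expect_error(annotate_base_pairs(fx2$model, "dotbracket",
                                   dotbracket = "((((....))"),
               "length")
  expect_error(annotate_base_pairs(fx2$model, "dotbracket",
                                   dotbracket = "((((....))...."),
               "unbalanced")
})

test_that("geometric detection recovers the designed pairs of an idealized helix", {
  fx <- make_ideal_helix("GCAU")
  ss <- annotate_base_pairs(fx$model, "detect")
  expect_equal(ss$pairs$i, fx$truth$pairs$i)
  expect_equal(ss$pairs$j, fx$truth$pairs$j)
  expect_equal(ss$pairs$pair_class,
               c("WC-GC", "WC-GC", "WC-AU", "WC-AU"))
})
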