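ss_on <- function(fx, db = NULL) {
  annotate_base_pairs(fx$model, "dotbracket",
                      dotbracket = if (is.null(db)) fx$dotbracket else db)
}

test_that("loop decomposition emits hairpins and internal loops, not stacks", {
  fx <- make_hairpin(loop_size = 4, stem_bp = 4)  # "((((....))))"
  ss <- ss_on(fx)
  chain <- fx$model$chains[[1]]
  loops <- find_loops(ss, chain)
  expect_length(loops, 1)
  expect_equal(loops[[1]]$residues, 4:9)
  expect_true(loops[[1]]$closed)
  expect_equal(sum(loops[[1]]$provenance == "hydrogen_bond"), 1)

  ## "((..((...))..))" : internal loop + hairpin (enumerated by hand from
  ## the pair list {(1,15),(2,14),(5,11),(6,10)})
  fx2 <- make_hairpin(loop_size = 7, stem_bp = 4)  # 15 residues
  ss2 <- ss_on(fx2, "((..((...))..))")
  loops2 <- find_loops(ss2, fx2$model$chains[[1]])
  expect_length(loops2, 2)
  sets <- lapply(loops2, function(l) l$residues)
  expect_true(list(c(2:5, 11:14)) %in% sets || any(vapply(sets, identical,
                                                          logical(1), c(2:5, 11:14))))
  expect_true(any(vapply(sets, identical, logical(1), 6:10)))
  ## internal loop crosses two hydrogen bonds (two pairs on its cycle)
  il <- loops2[[which(vapply(sets, identical, logical(1), c(2:5, 11:14)))]]
  expect_equal(sum(il$provenance == "hydrogen_bond"), 2)

  ## empty pair set
  ss0 <- ss_on(fx, strrep(".", 12))
  expect_length(find_loops(ss0, chain), 0)
})

test_that("dinucleotide steps come from consecutive stacked pairs", {
  fx <- make_hairpin(loop_size = 4, stem_bp = 4)
  ss <- ss_on(fx)
  steps <- find_dinucleotide_steps(ss, fx$model$chains[[1]])
  expect_length(steps, 3)
  expect_equal(steps[[1]]$residues, c(1, 2, 11, 12))
  for (s in steps) {
    expect_true(s$closed)
    expect_equal(sum(s$provenance == "hydrogen_bond"), 2)
  }

  ## isolated single pair -> 0 steps
  fx1 <- make_hairpin(loop_size = 4, stem_bp = 2)  # 8 nt
  ss1 <- ss_on(fx1, "(......)")
  expect_length(find_dinucleotide_steps(ss1, fx1$model$chains[[1]]), 0)

  ## helices of length 4 and 3 -> 3 + 2 steps
  fx2 <- make_hairpin(loop_size = 12, stem_bp = 4)  # 20 nt
  ss2 <- ss_on(fx2, "((((...))))(((...)))")
  expect_length(find_dinucleotide_steps(ss2, fx2$model$chains[[1]]), 5)
})

test_that("single strands are dangling/linker runs extended by anchors", {
  fx <- make_hairpin(loop_size = 4, stem_bp = 4)
  ss <- ss_on(fx)
  chain <- fx$model$chains[[1]]
  expect_length(find_single_strands(ss, chain), 0)

  ## 16-nt chain with a 5' dangling end
  fx3 <- make_hairpin(loop_size = 8, stem_bp = 4)  # 16 nt
  ss3 <- ss_on(fx3, "....((((....))))")
  strands <- find_single_strands(ss3, fx3$model$chains[[1]])
  expect_length(strands, 1)
  expect_equal(strands[[1]]$residues, 1:5)  # run 1..4 plus anchor 5
  expect_equal(strands[[1]]$unpaired, 1:4)
  expect_false(strands[[1]]$closed)
  expect_true(all(strands[[1]]$provenance == "backbone"))

  ## fully unpaired chain -> one strand, no anchors
  ssu <- ss_on(fx3, strrep(".", 16))
  su <- find_single_strands(ssu, fx3$model$chains[[1]])
  expect_length(su, 1)
  expect_equal(su[[1]]$residues, 1:16)
})

test_that("decomposition covers all residues and ignores pair input order", {
  fx <- make_hairpin_lasso(depth = 4)
  ss <- ss_on(fx)
  chain <- fx$model$chains[[1]]
  els <- find_elements(ss, chain)
  covered <- sort(unique(unlist(lapply(els, function(e) e$residues))))
  expect_equal(covered, seq_len(ss$n_residues))
  ## permuting the pair rows changes nothing
  ss_perm <- ss
  ss_perm$pairs <- ss$pairs[rev(seq_len(nrow(ss$pairs))), ]
  els2 <- find_elements(ss_perm, chain)
  lab <- function(l) sort(vapply(l, function(e) e$label, character(1)))
  expect_equal(lab(els2), lab(els))
})

test_that("closed element curves are genuinely closed, open ones are not", {
  fx <- make_hopf_loops()
  ss <- ss_on(fx)
  els <- find_elements(ss, fx$model$chains[[1]])
  for (e in els) {
    gap <- sqrt(sum((e$curve[1, ] - e$curve[nrow(e$curve), ])^2))
    if (e$closed) expect_equal(gap, 0) else expect_gt(gap, 1)
  }
})
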