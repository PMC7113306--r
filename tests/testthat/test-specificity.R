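# family alignment consistent with the strand fixtures: the subfamily rows
# carry the inserted residue, the five other rows are gapped at that column
strand_family_alignment <- function(with_insertion = TRUE) {
  base <- strsplit(fx_template12()$truth$sequence_a, "")[[1]]
  if (with_insertion) {
    full <- fx_kink12()$truth$sequence_a
    gapped <- paste(append(base, "-", after = fx_kink12()$truth$insertion_at - 1),
                    collapse = "")
  } else {
    full <- paste(base, collapse = "")
    gapped <- full
  }
  bmpspec:::build_alignment(c(
    BMP9 = full, BMP10 = full, BMP14 = gapped, BMP2 = gapped,
    BMP4 = gapped, BMP6 = gapped, BMP7 = gapped))
}

test_that("a subfamily-specific insertion is located and its kink quantified", {
  aln <- strand_family_alignment()
  memb <- subset_chains(fx_kink12()$model, "A")
  ref <- subset_chains(fx_template12()$model, "A")
  call <- detect_insertion(aln, c("BMP9", "BMP10"), memb, "A", ref, "A",
                           "BMP9", "BMP2", strand_interval = c(3, 10))
  expect_equal(call$columns, fx_kink12()$truth$insertion_at)
  # gapped in all five non-subfamily rows, occupied in the subfamily
  col <- aln$mat[, call$columns]
  expect_true(all(col[c("BMP14", "BMP2", "BMP4", "BMP6", "BMP7")] == "-"))
  expect_true(all(col[c("BMP9", "BMP10")] != "-"))
  expect_equal(nrow(call$inserted_residues), 2)
  expect_equal(call$kink_metric, 3.0, tolerance = 0.1)
})

test_that("the kink metric is invariant under rigid motion of either structure", {
  aln <- strand_family_alignment()
  memb <- subset_chains(fx_kink12()$model, "A")
  ref <- subset_chains(fx_template12()$model, "A")
  base <- detect_insertion(aln, c("BMP9", "BMP10"), memb, "A", ref, "A",
                           "BMP9", "BMP2", strand_interval = c(3, 10))
  R <- bmpspec:::euler_rotation(0.7, 1.2, 0.4)
  moved <- transform_model(memb, R, c(12, -8, 5))
  m1 <- detect_insertion(aln, c("BMP9", "BMP10"), moved, "A", ref, "A",
                         "BMP9", "BMP2", strand_interval = c(3, 10))
  moved_ref <- transform_model(ref, t(R), c(-3, 9, 1))
  m2 <- detect_insertion(aln, c("BMP9", "BMP10"), memb, "A", moved_ref, "A",
                         "BMP9", "BMP2", strand_interval = c(3, 10))
  expect_equal(m1$kink_metric, base$kink_metric, tolerance = 1e-6)
  expect_equal(m2$kink_metric, base$kink_metric, tolerance = 1e-6)
})

test_that("an interval without subfamily-specific gaps gives an empty call", {
  aln <- strand_family_alignment(with_insertion = FALSE)
  ref <- subset_chains(fx_template12()$model, "A")
  call <- detect_insertion(aln, c("BMP9", "BMP10"), ref, "A", ref, "A",
                           "BMP9", "BMP2", strand_interval = c(3, 10))
  expect_length(call$columns, 0)
  expect_lt(call$kink_metric, 1e-6)   # still computed
})

test_that("beta-augmentation: the template is compatible with itself", {
  tmpl <- fx_template12()
  ladder <- group_sheet_ladders(find_hbonds(tmpl$model, "A", "B"))[[1]]
  v <- predict_beta_augmentation(tmpl$model, ladder, "A", tmpl$model, "A")
  expect_equal(v$verdict, "compatible")
  expect_equal(v$preserved_hbond_count, v$ladder_size)
  expect_lt(v$max_backbone_displacement, 1e-9)
})

test_that("a planted 3 A bulge at the ladder site breaks every bond", {
  tmpl <- fx_template12()
  ladder <- group_sheet_ladders(find_hbonds(tmpl$model, "A", "B"))[[1]]
  v <- predict_beta_augmentation(tmpl$model, ladder, "A",
                                 fx_kink12()$model, "A")
  expect_equal(v$verdict, "incompatible")
  expect_equal(v$preserved_hbond_count, 0)
  expect_lte(v$preserved_hbond_count, v$ladder_size)
  expect_gt(v$max_backbone_displacement, 2.0)
})

test_that("swap mutants cover exactly the differing variable interface positions", {
  kinds <- c("family", "variable", "subfamily", "variable", "family",
             "variable", "subfamily", "family")
  msa <- make_msa(kinds, seed = 13)
  prof <- classify_positions(msa$aln, msa$subfamily)
  seq9 <- paste(msa$aln$mat["BMP9", ], collapse = "")
  bb <- bmpspec:::build_strand_backbone(nchar(seq9))
  model <- bmpspec:::strand_to_model(bb, "A", strsplit(seq9, "")[[1]])
  tab <- map_profile_to_structure(prof, msa$aln, "BMP9", model, "A")
  part <- tripartite_partition(seq_len(8), tab)

  muts <- design_swap_mutants(part, msa$aln, "BMP9", "BMP10")
  vari <- part$orf[part$partition == "variable"]
  differing <- vari[msa$aln$mat["BMP9", vari] != msa$aln$mat["BMP10", vari]]
  expect_equal(muts$position, sort(differing))
  expect_true(all(muts$from != muts$to))
  expect_equal(muts$label, paste0(muts$from, muts$position, muts$to))

  # antisymmetry: reversing source and target swaps from/to
  rev <- design_swap_mutants(part, msa$aln, "BMP10", "BMP9")
  expect_equal(rev$position, muts$position)
  expect_equal(rev$from, muts$to)
  expect_equal(rev$to, muts$from)

  # identical source and target rows yield no mutants
  seqs <- stats::setNames(apply(msa$aln$mat, 1, paste, collapse = ""),
                          rownames(msa$aln$mat))
  seqs["BMP10"] <- seqs["BMP9"]
  aln_same <- bmpspec:::build_alignment(seqs)
  expect_equal(nrow(design_swap_mutants(part, aln_same, "BMP9", "BMP10")), 0)

  # structurally promoted residues are excluded from the panel
  ov <- stats::setNames("conserved interaction", differing[1])
  part_ov <- tripartite_partition(seq_len(8), tab, overrides = ov)
  muts_ov <- design_swap_mutants(part_ov, msa$aln, "BMP9", "BMP10")
  expect_false(differing[1] %in% muts_ov$position)
})
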