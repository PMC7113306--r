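kinds_all <- c("family", "subfamily", "variable", "insertion_same",
               "insertion_diff", "gap_sub", "family", "subfamily",
               "variable", "subfamily", "family", "variable")

test_that("planted column classes are recovered exactly", {
  msa <- make_msa(kinds_all, seed = 5)
  prof <- classify_positions(msa$aln, msa$subfamily)
  expect_equal(prof$class, msa$truth$expected_class)
  # classes partition the columns
  expect_equal(nrow(prof), msa$aln$n_cols)
  expect_false(anyNA(prof$class))
})

test_that("classification is invariant to row order and row names", {
  msa <- make_msa(kinds_all, seed = 8)
  seqs <- stats::setNames(apply(msa$aln$mat, 1, paste, collapse = ""),
                          rownames(msa$aln$mat))
  shuffled <- seqs[c(4, 1, 7, 2, 6, 3, 5)]
  aln2 <- bmpspec:::build_alignment(shuffled)
  p1 <- classify_positions(msa$aln, msa$subfamily)
  p2 <- classify_positions(aln2, msa$subfamily)
  expect_equal(p1$class, p2$class)
  renamed <- stats::setNames(seqs, paste0("row", seq_along(seqs)))
  aln3 <- bmpspec:::build_alignment(renamed)
  p3 <- classify_positions(aln3, paste0("row", 1:2))
  expect_equal(p1$class, p3$class)
})

test_that("raising family_min never promotes a column to family-conserved", {
  for (seed in c(2, 9)) {
    msa <- make_msa(kinds_all, seed = seed)
    p6 <- classify_positions(msa$aln, msa$subfamily, family_min = 6)
    p7 <- classify_positions(msa$aln, msa$subfamily, family_min = 7)
    fam6 <- p6$column[p6$class == "family_conserved"]
    fam7 <- p7$column[p7$class == "family_conserved"]
    expect_true(all(fam7 %in% fam6))
  }
  msa <- make_msa(kinds_all, seed = 2)
  expect_error(classify_positions(msa$aln, msa$subfamily, family_min = 8),
               "family_min")
})

test_that("alignment I/O validates input and honours declared ORF starts", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "--ACDEF", ">s2", "GHACDEF"), p)
  aln <- read_alignment(p, orf_starts = c(s1 = 10, s2 = 1))
  m1 <- dplyr::filter(aln$orf_map, row == "s1")
  expect_equal(m1$column[1], 3)   # first non-gap column
  expect_equal(m1$orf, 10:14)
  expect_equal(dplyr::filter(aln$orf_map, row == "s2")$orf, 1:7)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC", ">s2", "ACDE"), bad)
  expect_error(read_alignment(bad), "ragged")
  bad2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACJE", ">s2", "ACDE"), bad2)
  expect_error(read_alignment(bad2), "non-amino")
  expect_error(classify_positions(aln, c("s1", "zzz")), "subfamily")
})

test_that("profiles map onto structure residues through ORF numbering", {
  msa <- make_msa(rep(c("family", "subfamily", "variable"), 4), seed = 3)
  prof <- classify_positions(msa$aln, msa$subfamily)
  # structure for the first subfamily row: ungapped, orf = column index
  seq9 <- paste(msa$aln$mat["BMP9", ], collapse = "")
  bb <- bmpspec:::build_strand_backbone(nchar(seq9))
  model <- bmpspec:::strand_to_model(bb, "A", strsplit(seq9, "")[[1]])
  tab <- map_profile_to_structure(prof, msa$aln, "BMP9", model, "A")
  expect_equal(tab$class, prof$class)
  expect_true(all(tab$modelled))
  # drop two residues from the model: they come back flagged unmodelled
  model2 <- model
  model2$atoms <- dplyr::filter(model2$atoms, !resno %in% c(3, 7))
  tab2 <- map_profile_to_structure(prof, msa$aln, "BMP9", model2, "A")
  expect_equal(tab2$orf[!tab2$modelled], c(3, 7))
})

test_that("tripartite interface partition is complete and honours overrides", {
  msa <- make_msa(rep(c("family", "subfamily", "variable"), 4), seed = 3)
  prof <- classify_positions(msa$aln, msa$subfamily)
  seq9 <- paste(msa$aln$mat["BMP9", ], collapse = "")
  bb <- bmpspec:::build_strand_backbone(nchar(seq9))
  model <- bmpspec:::strand_to_model(bb, "A", strsplit(seq9, "")[[1]])
  tab <- map_profile_to_structure(prof, msa$aln, "BMP9", model, "A")

  interface <- 2:9
  part <- tripartite_partition(interface, tab)
  expect_equal(nrow(part), length(interface))
  expect_setequal(part$orf, interface)
  expect_equal(part$partition[part$class == "family_conserved"],
               rep("core_conserved", sum(part$class == "family_conserved")))

  # a variable residue making conserved interactions gets promoted, tagged
  var_orf <- part$orf[part$partition == "variable"][1]
  part2 <- tripartite_partition(interface, tab,
                                overrides = stats::setNames("conserved interaction",
                                                            var_orf))
  row <- part2[part2$orf == var_orf, ]
  expect_equal(row$partition, "subfamily_specific")
  expect_true(row$override)
  expect_equal(row$justification, "conserved interaction")
  expect_error(tripartite_partition(c(interface, 999), tab), "covered")
})
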