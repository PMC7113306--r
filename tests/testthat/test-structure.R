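test_that("minimal PDB parses with altloc, water and heteroatom policy", {
  p <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  a <- m$atoms
  expect_false(any(a$resid == "HOH"))
  expect_true(any(a$resid == "ZN" & !a$is_polymer))
  # altloc: single CA kept, the 0.6-occupancy conformer
  ca <- a[a$resno == 1 & a$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458, tolerance = 1e-6)
  expect_equal(sum(a$is_polymer & a$resno == 1), 5)  # Ala heavy atoms
  expect_setequal(unique(a$resid1[a$is_polymer]), c("A", "G"))
})

test_that("water-only files and missing files are rejected", {
  p <- write_water_only_pdb(withr::local_tempfile(fileext = ".pdb"))
  expect_error(read_structure(p), "water|polymer")
  expect_error(read_structure("does_not_exist.pdb"), "not found")
})

test_that("PDB round-trip preserves coordinates and residue identities", {
  m <- fx_pair6()$model
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  m2 <- read_structure(p)
  a1 <- dplyr::arrange(m$atoms, chain, resno, atom)
  a2 <- dplyr::arrange(m2$atoms, chain, resno, atom)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a1$resid, a2$resid)
  expect_lt(max(abs(a1$x - a2$x), abs(a1$y - a2$y), abs(a1$z - a2$z)), 1e-3)
})

test_that("ORF numbering maps observed residues through a global alignment", {
  m <- strand_model_from_seq <- local({
    bb <- bmpspec:::build_strand_backbone(5)
    bmpspec:::strand_to_model(bb, "A", strsplit("LLAAG", "")[[1]])
  })
  # identity: offset zero relative to reference start
  mp0 <- map_numbering(m, "A", "LLAAG")
  expect_equal(mp0$orf, 1:5)
  # observed is a C-terminal fragment of the ORF
  mp <- map_numbering(m, "A", "MKKLLAAG")
  expect_equal(mp$orf, 4:8)
  expect_true(all(diff(mp$orf) > 0))  # order-preserving
  # internal deletion in the observed chain skips the reference position
  m2 <- local({
    bb <- bmpspec:::build_strand_backbone(7)
    bmpspec:::strand_to_model(bb, "A", strsplit("MKLLAAG", "")[[1]])
  })
  mp2 <- map_numbering(m2, "A", "MKKLLAAG")
  expect_equal(mp2$orf, c(1, 2, 4, 5, 6, 7, 8))
  # idempotence: assigning twice gives the same orf column
  ma <- assign_orf(m, "A", "MKKLLAAG")
  mb <- assign_orf(ma, "A", "MKKLLAAG")
  expect_identical(ma$atoms$orf, mb$atoms$orf)
  # unrelated reference fails loudly
  expect_error(map_numbering(m, "A", "WWWWWWWWFFFF"), "mismatch|unaligned")
})

test_that("atom selection is stable-ordered and counts residue composition", {
  gly <- atoms_row("A", 1, "GLY", c("O", "C", "CA", "N"),
                   c(0, 1, 2, 3), c(0, 0, 0, 0), c(0, 0, 0, 0))
  val <- atoms_row("A", 2, "ALA", c("CB", "O", "C", "CA", "N", "CG1", "CG2"),
                   1:7, rep(0, 7), rep(0, 7))
  m <- bmpspec:::new_structure_model(dplyr::bind_rows(gly, val))
  sel_g <- select_atoms(m, "A", orf_range = c(1, 1))
  expect_equal(nrow(sel_g), 4)                     # Gly has 4 heavy atoms
  expect_equal(sel_g$atom, c("N", "CA", "C", "O"))  # canonical order first
  expect_equal(nrow(select_atoms(m, "A", orf_range = c(2, 2))), 7)
  expect_equal(nrow(select_atoms(m, "A", orf_range = c(2, 2),
                                 mainchain_only = TRUE)), 4)
  expect_error(select_atoms(m, "Z"), "chain")
  expect_error(select_atoms(m, "A", orf_range = c(50, 60)), "empty")
})
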