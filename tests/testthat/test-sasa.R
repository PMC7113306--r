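single_carbon <- function() {
  a <- atoms_row("A", 1, "UNK", "C1", 0, 0, 0, mainchain = FALSE)
  a$element <- "C"
  bmpspec:::new_structure_model(a)
}

test_that("an isolated sphere matches the analytic area", {
  analytic <- 4 * pi * (1.70 + 1.4)^2
  s <- compute_sasa(single_carbon())
  expect_lt(abs(s$per_atom$area - analytic) / analytic, 0.01)
  # coarsest allowed sampling still well-defined
  s92 <- compute_sasa(single_carbon(), n_points = 92)
  expect_lt(abs(s92$per_atom$area - analytic) / analytic, 0.05)
  expect_error(compute_sasa(single_carbon(), n_points = 50), "92")
})

test_that("distant atoms do not occlude each other and unknown elements fail", {
  a <- dplyr::bind_rows(
    atoms_row("A", 1, "UNK", "C1", 0, 0, 0, mainchain = FALSE),
    atoms_row("A", 2, "UNK", "C1", 100, 0, 0, mainchain = FALSE))
  a$element <- "C"
  s <- compute_sasa(bmpspec:::new_structure_model(a))
  analytic <- 4 * pi * 3.1^2
  expect_equal(s$per_atom$area, rep(analytic, 2), tolerance = 0.01)
  bad <- a; bad$element <- c("C", "QQ")
  expect_error(compute_sasa(bmpspec:::new_structure_model(bad)), "QQ")
})

test_that("per-residue areas are the sums of their atoms", {
  s <- compute_sasa(fx_pair6()$model)
  by_hand <- s$per_atom |>
    dplyr::group_by(chain, resno) |>
    dplyr::summarise(area = sum(area), .groups = "drop")
  expect_equal(dplyr::arrange(s$per_residue, chain, resno)$area,
               dplyr::arrange(by_hand, chain, resno)$area, tolerance = 1e-6)
})

test_that("golden-spiral SASA agrees with the Monte-Carlo oracle", {
  for (seed in c(1, 5)) {
    m <- random_carbon_cluster(5, seed)
    mine <- compute_sasa(m)$per_atom$area
    oracle <- bmpspec:::sasa_monte_carlo(m, n_points = 20000, seed = 99)$area
    expect_lt(max(abs(mine - oracle)), 1)            # per-atom, square A
    expect_lt(abs(sum(mine) - sum(oracle)) / sum(oracle), 0.02)
  }
})

test_that("SASA is monotone under added occluders and converges in n_points", {
  for (seed in 1:3) {
    m <- random_carbon_cluster(8, seed, spread = 5)
    extra <- random_carbon_cluster(4, seed + 100, spread = 5)
    extra$atoms$chain <- "B"
    both <- bmpspec:::new_structure_model(
      dplyr::bind_rows(m$atoms, extra$atoms))
    a1 <- compute_sasa(m)$per_atom$area
    a2 <- compute_sasa(both)$per_atom$area[seq_along(a1)]
    expect_true(all(a2 <= a1 + 1e-9))
  }
  m20 <- random_carbon_cluster(20, 11, spread = 8)
  a960 <- sum(compute_sasa(m20, n_points = 960)$per_atom$area)
  a4000 <- sum(compute_sasa(m20, n_points = 4000)$per_atom$area)
  expect_lt(abs(a960 - a4000) / a4000, 0.02)
})

test_that("separated chains report an empty interface with zero buried area", {
  far <- cluster_model("A", list(c(0, 0, 0), c(8, 0, 0)))
  far2 <- cluster_model("B", list(c(0, 50, 0), c(8, 50, 0)))
  m <- bmpspec:::new_structure_model(dplyr::bind_rows(far$atoms, far2$atoms))
  ir <- interface_report(m, "A", "B")
  expect_equal(ir$bsa_total, 0)
  expect_equal(nrow(interface_residues(ir, "a")), 0)
  expect_true(all(ir$residues$dsasa >= 0))
  expect_error(interface_report(m, c("A", "B"), "B"), "disjoint")
})

test_that("the toy complex's planted interface and oracle burial are recovered", {
  tc <- fx_toy()
  ir <- interface_report(tc$model, "A", "B")
  expect_equal(interface_residues(ir, "a")$resno, tc$truth$interface_a)
  expect_equal(interface_residues(ir, "b")$resno, tc$truth$interface_b)
  expect_lt(abs(ir$bsa_total - tc$truth$oracle_bsa) / tc$truth$oracle_bsa, 0.02)
  expect_true(all(ir$residues$area_complex <= ir$residues$area_isolated + 1e-9))
})

test_that("per-monomer burial shares partition correctly and symmetrically", {
  tc <- fx_toy()
  ir <- interface_report(tc$model, "A", "B")
  one <- per_monomer_breakdown(ir, list(mono = "A"))
  expect_equal(one$share, 1.0)
  expect_error(per_monomer_breakdown(ir, list("A", "B")), "partition")

  # receptor chain C flanked symmetrically by chains A and B: single-atom
  # residues so the construction is exactly symmetric under a 180-degree
  # rotation about the receptor midpoint
  one_atom_chain <- function(chain, centers) {
    a <- purrr::imap_dfr(centers, function(ctr, i)
      atoms_row(chain, i, "UNK", "C1", ctr[1], ctr[2], ctr[3],
                mainchain = FALSE))
    a$element <- "C"
    a
  }
  m <- bmpspec:::new_structure_model(dplyr::bind_rows(
    one_atom_chain("A", purrr::map(1:4, ~c(8 * .x, 5.5, 0))),
    one_atom_chain("B", purrr::map(1:4, ~c(72 - 8 * .x, -5.5, 0))),
    one_atom_chain("C", purrr::map(1:8, ~c(8 * .x, 0, 0)))))
  ir2 <- interface_report(m, c("A", "B"), "C")
  shares <- per_monomer_breakdown(ir2, list(A = "A", B = "B"))
  expect_equal(sum(shares$share), 1)
  expect_lt(abs(shares$share[1] - 0.5), 0.02)
})
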