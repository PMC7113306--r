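test_that("self-superposition is the identity with zero RMSD", {
  m <- fx_pair6()$model
  s <- superpose_models(m, m, c("A", "B"), c("A", "B"))
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$correspondence$coverage, 1.0)
  expect_equal(s$correspondence$source, "identical-sequence")
  expect_equal(s$rotation, diag(3), tolerance = 1e-6)
})

test_that("rigid motions are removed exactly and RMSD is symmetric", {
  m <- fx_pair6()$model
  for (seed in 1:5) {
    ang <- withr::with_seed(seed, stats::runif(3, 0, 2 * pi))
    tr <- withr::with_seed(seed + 50, stats::runif(3, -20, 20))
    moved <- perturb_copy(m, ang, tr)$model
    s <- superpose_models(moved, m, c("A", "B"), c("A", "B"))
    expect_lt(s$rmsd, 1e-6)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
  noisy <- perturb_copy(m, c(0.3, 0.9, 1.4), c(4, 5, 6), noise_sd = 0.4,
                        seed = 2)$model
  s_ab <- superpose_models(noisy, m, c("A", "B"), c("A", "B"))
  s_ba <- superpose_models(m, noisy, c("A", "B"), c("A", "B"))
  expect_equal(s_ab$rmsd, s_ba$rmsd, tolerance = 1e-9)
})

test_that("noisy-copy RMSD matches the Monte-Carlo expectation", {
  m <- fx_pair6()$model
  sigma <- 0.5
  rmsds <- purrr::map_dbl(1:20, function(seed) {
    moved <- perturb_copy(m, c(0.2, 0.5, 1.0), c(1, 2, 3), noise_sd = sigma,
                          seed = seed)$model
    superpose_models(moved, m, c("A", "B"), c("A", "B"))$rmsd
  })
  expect_lt(abs(mean(rmsds) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.10)
})

test_that("the SVD solution beats a brute-force rotation grid on 4-atom sets", {
  for (seed in 1:3) {
    X <- withr::with_seed(seed, matrix(stats::rnorm(12), 4))
    Y <- withr::with_seed(seed + 10, matrix(stats::rnorm(12), 4))
    k <- kabsch(list(xyz_moving = X, xyz_fixed = Y))
    g <- bmpspec:::rmsd_grid_oracle(X, Y, step = 15)
    expect_lte(k$rmsd, g + 1e-9)
  }
})

test_that("RMSD agrees with an independent least-squares fit implementation", {
  X <- withr::with_seed(3, matrix(stats::rnorm(30), 10))
  Y <- withr::with_seed(4, matrix(stats::rnorm(30), 10))
  k <- kabsch(list(xyz_moving = X, xyz_fixed = Y))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X))))
  expect_equal(k$rmsd, bio3d::rmsd(as.vector(t(Y)), fitted), tolerance = 1e-3)
})

test_that("degenerate collinear inputs are rejected", {
  X <- cbind(1:4, 0, 0); Y <- cbind(c(2, 4, 6, 8), 0, 0)
  expect_error(kabsch(list(xyz_moving = X, xyz_fixed = Y)), "degenerate|collinear")
  expect_error(kabsch(list(xyz_moving = X[1:2, ], xyz_fixed = Y[1:2, ])), "3")
})

test_that("alignment-derived correspondence leaves an inserted residue unpaired", {
  tmpl <- subset_chains(fx_template12()$model, "A")
  kink <- subset_chains(fx_kink12()$model, "A")
  co <- build_correspondence(kink, tmpl, "A", "A")
  expect_equal(co$source, "alignment")
  expect_equal(nrow(co$residue_pairs), 12)
  expect_equal(co$unpaired_moving$resno, fx_kink12()$truth$insertion_at)
  expect_equal(nrow(co$unpaired_fixed), 0)
  # CA-only mode pairs one atom per residue
  co_ca <- build_correspondence(kink, tmpl, "A", "A", ca_only = TRUE)
  expect_equal(nrow(co_ca$pairs), 12)
})

test_that("complex comparison runs per role and flags unmapped chains", {
  m <- fx_pair6()$model
  rm_ <- tibble::tibble(role = c("ligand", "partner"),
                        chains_a = c("A", "B"), chains_b = c("A", "B"))
  tab <- compare_complexes(m, m, rm_)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$rmsd < 1e-9))
  bad <- tibble::tibble(role = "x", chains_a = "Z", chains_b = "A")
  expect_error(compare_complexes(m, m, bad), "unmapped")
})
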