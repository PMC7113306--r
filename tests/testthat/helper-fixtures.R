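# Shared fixtures, memoised: strand docking is an optimisation, so each
# fixture is built once per test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_pair4 <- function() fixture("pair4", function() make_strand_pair(4, seed = 7))
fx_pair6 <- function() fixture("pair6", function() make_strand_pair(6, seed = 2))
fx_parallel6 <- function() fixture("parallel6", function()
  make_strand_pair(6, orientation = "parallel", seed = 9))
fx_template12 <- function() fixture("template12", function()
  make_strand_pair(12, seed = 7, n_res_b = 4, register_offset = 4))
fx_kink12 <- function() fixture("kink12", function()
  make_strand_pair(12, insertion_at = 6, bulge_displacement = 3, seed = 7,
                   n_res_b = 4, register_offset = 4))
fx_toy <- function() fixture("toy", function()
  make_toy_complex(8, 8, 0.5, seed = 3, oracle_points = 50000))

# atom-table constructor for hand-built geometries
atoms_row <- function(chain, resno, resid, atom, x, y, z,
                      mainchain = atom %in% c("N", "CA", "C", "O", "OXT")) {
  element <- substr(gsub("[0-9]", "", atom), 1, 1)
  tibble::tibble(chain = chain, resno = as.integer(resno), ins = "",
                 orf = as.integer(resno), resid = resid,
                 resid1 = unname(c(ALA = "A", GLY = "G", ASP = "D",
                                   ARG = "R", SER = "S", HIS = "H",
                                   LYS = "K", GLU = "E", UNK = "X")[resid]),
                 atom = atom, element = element, x = x, y = y, z = z,
                 occ = 1, is_mainchain = mainchain, is_polymer = TRUE)
}

# n_res single-carbon "residues" in a row: a minimal SASA testbed
cluster_model <- function(chain, centers, resid = "UNK") {
  cl <- rbind(N = c(0, 0, 0.8), CA = c(0.9, 0, -0.5),
              C = c(-0.8, 0.5, -0.5), O = c(-0.1, -1.0, 0))
  atoms <- purrr::imap_dfr(centers, function(ctr, i)
    atoms_row(chain, i, "GLY", rownames(cl),
              cl[, 1] + ctr[1], cl[, 2] + ctr[2], cl[, 3] + ctr[3]))
  bmpspec:::new_structure_model(atoms, id = paste0("cluster_", chain))
}

random_carbon_cluster <- function(n, seed, spread = 3) {
  xyz <- withr::with_seed(seed, matrix(stats::runif(3 * n, 0, spread), n, 3))
  atoms <- atoms_row("A", seq_len(n), "UNK", paste0("C", seq_len(n)),
                     xyz[, 1], xyz[, 2], xyz[, 3], mainchain = FALSE)
  atoms$element <- "C"
  bmpspec:::new_structure_model(atoms, id = paste0("cluster", seed))
}

# Asp--Arg pair with the closest carboxylate O to guanidinium N at `gap` A
saltbridge_model <- function(gap = 3.0, basic_resid = "ARG") {
  asp <- atoms_row("A", 1, "ASP", c("CB", "CG", "OD1", "OD2"),
                   c(0, 1.5, 2.2, 2.2), c(0, 0, 1.1, -1.1), c(0, 0, 0, 0))
  basic <- if (basic_resid == "ARG") {
    atoms_row("B", 1, "ARG", c("CD", "NE", "CZ", "NH1", "NH2"),
              2.2 + gap + c(2.9, 1.6, 0.8, 0, 0.8),
              c(0.8, 1.0, 2.2, 1.1, 3.4), c(0, 0, 0, 0, 0))
  } else {
    atoms_row("B", 1, "HIS", c("CG", "ND1", "CE1", "NE2", "CD2"),
              2.2 + gap + c(1.8, 0, 0.7, 1.9, 2.6),
              c(1.8, 1.1, 2.3, 2.9, 1.9), c(0, 0, 0, 0, 0))
  }
  bmpspec:::new_structure_model(dplyr::bind_rows(asp, basic), id = "sb")
}

# Ser hydroxyl donating to a backbone carbonyl across chains
ser_mainchain_hbond_model <- function(d_og_o = 2.87) {
  ser <- atoms_row("A", 1, "SER", c("CB", "OG"), c(0, 1.43), c(0, 0), c(0, 0))
  gly <- atoms_row("B", 1, "GLY", c("C", "O"),
                   c(1.43 + d_og_o + 1.23, 1.43 + d_og_o), c(0, 0), c(0, 0))
  bmpspec:::new_structure_model(dplyr::bind_rows(ser, gly), id = "ser_hb")
}

# hand-written PDB with altlocs, a water and a metal ion
write_mini_pdb <- function(path) {
  fmt <- function(rec, ser, name, alt, res, chain, resno, x, y, z, occ, elem)
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, ser, name, alt, res, chain, resno, x, y, z, occ, 10, elem)
  writeLines(c(
    fmt("ATOM", 1, " N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    fmt("ATOM", 2, " CA", "A", "ALA", "A", 1, 1.458, 0, 0, 0.6, "C"),
    fmt("ATOM", 3, " CA", "B", "ALA", "A", 1, 1.358, 0.1, 0, 0.4, "C"),
    fmt("ATOM", 4, " C", " ", "ALA", "A", 1, 2.009, 1.42, 0, 1, "C"),
    fmt("ATOM", 5, " O", " ", "ALA", "A", 1, 1.251, 2.39, 0, 1, "O"),
    fmt("ATOM", 6, " CB", " ", "ALA", "A", 1, 2.0, -0.8, -1.2, 1, "C"),
    fmt("ATOM", 7, " N", " ", "GLY", "A", 2, 3.332, 1.536, 0, 1, "N"),
    fmt("ATOM", 8, " CA", " ", "GLY", "A", 2, 4.0, 2.8, 0, 1, "C"),
    fmt("ATOM", 9, " C", " ", "GLY", "A", 2, 5.5, 2.7, 0, 1, "C"),
    fmt("ATOM", 10, " O", " ", "GLY", "A", 2, 6.1, 1.6, 0, 1, "O"),
    fmt("HETATM", 11, "ZN", " ", " ZN", "A", 101, 8, 8, 8, 1, "ZN"),
    fmt("HETATM", 12, " O", " ", "HOH", "A", 201, 10, 10, 10, 1, "O"),
    "END"), path)
  path
}

write_water_only_pdb <- function(path) {
  writeLines(c(sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       "HETATM", 1, " O", " ", "HOH", "A", 1, 0, 0, 0, 1, 10, "O"),
               "END"), path)
  path
}
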