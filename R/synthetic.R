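# Seeded generators for every input class the pipeline consumes. Fixtures
# test algorithms, not biology: strands use ideal beta geometry, toy
# complexes are docked short chains, alignments have planted column classes.

# Ideal backbone internal coordinates (angstrom / degrees)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, phi = -119, psi = 113, omega = 180
)

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
unit <- function(v) v / sqrt(sum(v^2))

# NeRF: place atom D given antecedents A-B-C, bond r (C-D), angle theta
# (B-C-D) and torsion tau (A-B-C-D), both in degrees
nerf_place <- function(a, b, c, r, theta, tau) {
  theta <- theta * pi / 180; tau <- tau * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(tau), r * sin(theta) * sin(tau))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Backbone coordinates of an ideal extended strand: one row per atom,
# residues numbered 1..n, atoms N, CA, C, O
build_strand_backbone <- function(n_res, phi = BB_GEOM$phi, psi = BB_GEOM$psi) {
  g <- BB_GEOM
  coords <- list()
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  C <- nerf_place(c(-1, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, 150)
  for (i in seq_len(n_res)) {
    Nn <- nerf_place(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
    O <- nerf_place(N, CA, C, g$c_o, g$ang_ca_c_o, psi - 180)
    coords[[i]] <- rbind(N = N, CA = CA, C = C, O = O)
    if (i < n_res) {
      CAn <- nerf_place(CA, C, Nn, g$n_ca, g$ang_c_n_ca, g$omega)
      Cn <- nerf_place(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  xyz <- do.call(rbind, coords)
  tibble(res = rep(seq_len(n_res), each = 4),
         atom = rep(c("N", "CA", "C", "O"), n_res),
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

strand_to_model <- function(bb, chain, resid1, id = "strand") {
  resid3 <- names(AA_3TO1)[match(resid1, AA_3TO1)]
  atoms <- tibble(
    chain = chain, resno = bb$res, ins = "", orf = bb$res,
    resid = resid3[bb$res], resid1 = resid1[bb$res], atom = bb$atom,
    element = substr(bb$atom, 1, 1), x = bb$x, y = bb$y, z = bb$z,
    occ = 1, is_mainchain = TRUE, is_polymer = TRUE
  )
  new_structure_model(atoms, id = id)
}

apply_rigid <- function(xyz, par, center) {
  R <- euler_rotation(par[4], par[5], par[6])
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + par[1:3], "+")
}

# Rigid-dock strand B against strand A so that the target donor/acceptor
# distances hit 2.9 A, non-target cross N/O pairs stay > ~3.9 A and no
# atoms clash. Deterministic: Nelder-Mead + BFGS polish from a geometric
# initial guess.
dock_strand <- function(bbA, bbB, targets, side_dir, init_offsets = c(4.8, -4.8),
                        flip_axis) {
  xyzA <- as.matrix(bbA[, c("x", "y", "z")])
  xyzB0 <- as.matrix(bbB[, c("x", "y", "z")])
  keyA <- paste(bbA$res, bbA$atom)
  keyB <- paste(bbB$res, bbB$atom)
  ia <- match(paste(targets$res_a, targets$atom_a), keyA)
  ib <- match(paste(targets$res_b, targets$atom_b), keyB)
  stopifnot(!anyNA(ia), !anyNA(ib))
  no_a <- which(bbA$atom %in% c("N", "O"))
  no_b <- which(bbB$atom %in% c("N", "O"))
  tkey <- paste(ia, ib)
  centerB <- colMeans(xyzB0)
  # antecedent CA indices for donor-angle terms (nitrogen targets only)
  ca_of <- function(bb, res) match(paste(res, "CA"), paste(bb$res, bb$atom))
  ant_a <- ifelse(targets$atom_a == "N", ca_of(bbA, targets$res_a), NA)
  ant_b <- ifelse(targets$atom_b == "N", ca_of(bbB, targets$res_b), NA)

  objective <- function(par, xyzBflip) {
    xyzB <- apply_rigid(xyzBflip, par, centerB)
    d_t <- sqrt(rowSums((xyzA[ia, , drop = FALSE] - xyzB[ib, , drop = FALSE])^2))
    obj <- 10 * sum((d_t - 2.9)^2)
    # donor angle (CA-N...O) must stay well above the detection cutoff
    for (k in seq_len(nrow(targets))) {
      if (!is.na(ant_a[k])) {
        ang <- vec_angle(xyzA[ant_a[k], , drop = FALSE],
                         xyzA[ia[k], , drop = FALSE],
                         xyzB[ib[k], , drop = FALSE])
        obj <- obj + 0.05 * max(0, 125 - ang)^2
      }
      if (!is.na(ant_b[k])) {
        ang <- vec_angle(xyzB[ant_b[k], , drop = FALSE],
                         xyzB[ib[k], , drop = FALSE],
                         xyzA[ia[k], , drop = FALSE])
        obj <- obj + 0.05 * max(0, 125 - ang)^2
      }
    }
    # non-target N/O cross pairs must stay out of H-bond range
    dno <- sqrt(outer(rowSums(xyzA[no_a, ]^2), rep(1, length(no_b))) -
                  2 * xyzA[no_a, ] %*% t(xyzB[no_b, ]) +
                  outer(rep(1, length(no_a)), rowSums(xyzB[no_b, ]^2)))
    pkey <- outer(no_a, no_b, paste)
    nt <- dno[!(pkey %in% tkey)]
    obj <- obj + sum(pmax(0, 3.9 - nt)^2)
    # clash penalty over all cross pairs
    dall <- sqrt(outer(rowSums(xyzA^2), rep(1, nrow(xyzB))) -
                   2 * xyzA %*% t(xyzB) +
                   outer(rep(1, nrow(xyzA)), rowSums(xyzB^2)))
    akey <- outer(seq_len(nrow(xyzA)), seq_len(nrow(xyzB)), paste)
    cl <- dall[!(akey %in% tkey)]
    obj + 5 * sum(pmax(0, 2.7 - cl)^2)
  }

  best <- NULL
  for (flip in list(NULL, flip_axis)) {
    xyzBflip <- xyzB0
    if (!is.null(flip)) {
      # rotate 180 degrees about flip axis through B's centroid
      K <- matrix(c(0, -flip[3], flip[2], flip[3], 0, -flip[1],
                    -flip[2], flip[1], 0), 3, byrow = TRUE)
      R180 <- diag(3) + 2 * K %*% K
      xyzBflip <- sweep(sweep(xyzB0, 2, centerB) %*% t(R180), 2, centerB, "+")
    }
    for (off in init_offsets) {
      init <- c(colMeans(xyzA) + off * side_dir - centerB, 0, 0, 0)
      o1 <- stats::optim(init, objective, xyzBflip = xyzBflip,
                         method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-12))
      o2 <- stats::optim(o1$par, objective, xyzBflip = xyzBflip,
                         method = "BFGS", control = list(maxit = 500))
      if (is.null(best) || o2$value < best$value)
        best <- list(value = o2$value, par = o2$par, xyzBflip = xyzBflip)
    }
  }
  xyzB <- apply_rigid(best$xyzBflip, best$par, centerB)
  d_t <- sqrt(rowSums((xyzA[ia, , drop = FALSE] - xyzB[ib, , drop = FALSE])^2))
  if (any(abs(d_t - 2.9) > 0.3))
    rlang::abort(sprintf("strand docking failed: bond distances %s",
                         paste(round(d_t, 2), collapse = ", ")))
  bbB$x <- xyzB[, 1]; bbB$y <- xyzB[, 2]; bbB$z <- xyzB[, 3]
  bbB
}

antiparallel_targets <- function(n_res) {
  i <- seq(1, n_res, by = 2)
  j <- n_res + 1 - i
  bind_rows(
    tibble(res_a = i, atom_a = "N", res_b = j, atom_b = "O"),
    tibble(res_a = i, atom_a = "O", res_b = j, atom_b = "N")
  ) |> arrange(.data$res_a)
}

parallel_targets <- function(n_res) {
  i <- seq(2, n_res, by = 2)
  bind_rows(
    tibble(res_a = i, atom_a = "N", res_b = i - 1, atom_b = "O"),
    tibble(res_a = i[i < n_res], atom_a = "O", res_b = i[i < n_res] + 1,
           atom_b = "N")
  ) |> arrange(.data$res_a)
}

sample_sequence <- function(n, seed) {
  withr::with_seed(seed, paste(sample(setdiff(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], "P"),
                                      n, replace = TRUE), collapse = ""))
}

#' Generate an ideal beta-strand pair with a planted hydrogen-bond ladder
#'
#' Two strands in ideal beta geometry (phi = -119, psi = 113, standard
#' bond lengths and angles), rigidly docked so that a known set of
#' backbone N...O pairs sits at hydrogen-bond distance (2.9 A) while all
#' other cross-strand N/O pairs stay out of range — the planted ladder.
#' Optionally one extra residue is inserted into strand A and the
#' inserted residue plus its flanking neighbours are displaced by
#' `bulge_displacement` away from strand B, emulating the register
#' disruption an insertion causes in a beta-augmentation site.
#'
#' @param n_res Residues in strand A (>= 4).
#' @param orientation `"antiparallel"` or `"parallel"`.
#' @param insertion_at Optional position in strand A (2..n_res) at which
#'   one extra residue is inserted as a bulge between its neighbours;
#'   the inserted residue and the flanking ones are displaced by
#'   `bulge_displacement` away from strand B, without shifting the rest
#'   of the strand out of register (how a one-residue beta-bulge distorts
#'   a sheet locally while the fold around it is unchanged).
#' @param bulge_displacement Displacement of the bulged segment (angstrom).
#' @param seed Integer seed (sequences are drawn from it; geometry is
#'   deterministic).
#' @param n_res_b Residues in strand B (default `n_res`); the ladder
#'   spans `min(n_res, n_res_b)` residues, so a short strand B against a
#'   long strand A gives a localised pairing site with flanking anchor.
#' @return List with `model` (two-chain `structure_model`, chains `A`,
#'   `B`), and `truth`: `ladder` (tibble of planted backbone bonds in the
#'   model's residue numbering; bonds whose strand-A residue was
#'   displaced are marked `broken`), `orientation`, `insertion_at`,
#'   `displaced_residues`, `bulge_vector`, `sequence_a`, `sequence_b`.
#' @export
make_strand_pair <- function(n_res, orientation = c("antiparallel", "parallel"),
                             insertion_at = NULL, bulge_displacement = 0,
                             seed = 1, n_res_b = n_res, register_offset = 0) {
  orientation <- match.arg(orientation)
  if (n_res < 4 || n_res_b < 4) rlang::abort("n_res must be >= 4")
  if (!is.null(insertion_at) && (insertion_at < 2 || insertion_at > n_res))
    rlang::abort("insertion_at must be in 2..n_res")
  m <- min(n_res, n_res_b)
  if (register_offset < 0 || register_offset + m > n_res)
    rlang::abort("register_offset out of range")
  bbA <- build_strand_backbone(n_res)
  bbB <- build_strand_backbone(n_res_b)

  xyzA <- as.matrix(bbA[, c("x", "y", "z")])
  ca <- xyzA[bbA$atom == "CA", , drop = FALSE]
  reg <- register_offset + seq_len(m)                    # A residues paired to B
  u <- unit(ca[reg[m], ] - ca[reg[1], ])                 # strand direction
  o1 <- xyzA[bbA$atom == "O", ][reg[1], ] - ca[reg[1], ]
  v <- unit(o1 - sum(o1 * u) * u)                        # pairing direction
  w <- unit(cross3(u, v))

  targets <- if (orientation == "antiparallel") antiparallel_targets(m)
    else parallel_targets(m)
  targets$res_a <- targets$res_a + register_offset
  bbB <- dock_strand(bbA, bbB, targets, side_dir = v,
                     flip_axis = if (orientation == "antiparallel") v else w)

  displaced_old <- integer(0)
  bulge_vec <- c(0, 0, 0)
  if (!is.null(insertion_at)) {
    p <- insertion_at
    # direction from A's pairing face towards B, perpendicular to the strand
    cb <- colMeans(as.matrix(bbB[, c("x", "y", "z")]))
    caR <- colMeans(ca[reg, , drop = FALSE])
    v_eff <- unit((cb - caR) - sum((cb - caR) * u) * u)
    bulge_vec <- -bulge_displacement * v_eff
    displaced_old <- intersect(seq_len(n_res), (p - 1):(p + 1))
    # inserted residue: copy of residue p parked between p-1 and p, bulged out
    ins <- filter(bbA, .data$res == p)
    cam <- (ca[p - 1, ] + ca[p, ]) / 2
    off <- cam - ca[p, ] - 2.0 * v_eff
    ins$x <- ins$x + off[1]; ins$y <- ins$y + off[2]; ins$z <- ins$z + off[3]
    for (r in displaced_old) {
      idx <- bbA$res == r
      bbA$x[idx] <- bbA$x[idx] + bulge_vec[1]
      bbA$y[idx] <- bbA$y[idx] + bulge_vec[2]
      bbA$z[idx] <- bbA$z[idx] + bulge_vec[3]
    }
    ins$x <- ins$x + bulge_vec[1]; ins$y <- ins$y + bulge_vec[2]
    ins$z <- ins$z + bulge_vec[3]
    bbA$res <- bbA$res + (bbA$res >= p)
    ins$res <- p
    bbA <- arrange(bind_rows(bbA, ins), .data$res)
  }
  renumber <- function(r) if (is.null(insertion_at)) r
    else r + as.integer(r >= insertion_at)
  displaced <- if (is.null(insertion_at)) integer(0)
    else sort(c(vapply(displaced_old, renumber, numeric(1)), insertion_at))

  # base sequence depends only on (n_res, seed) so the kinked variant of a
  # fixture shares its template's sequence apart from the inserted residue
  seq_base <- strsplit(sample_sequence(n_res, seed), "")[[1]]
  seq_a <- if (is.null(insertion_at)) paste(seq_base, collapse = "")
    else paste(append(seq_base, sample_sequence(1, seed + 500L),
                      after = insertion_at - 1L), collapse = "")
  seq_b <- sample_sequence(n_res_b, seed + 1000L)
  ma <- strand_to_model(bbA, "A", strsplit(seq_a, "")[[1]])
  mb <- strand_to_model(bbB, "B", strsplit(seq_b, "")[[1]])
  model <- new_structure_model(bind_rows(ma$atoms, mb$atoms),
                               id = sprintf("strand_pair_n%d_seed%d", n_res, seed))
  ladder <- targets |>
    mutate(res_a = vapply(.data$res_a, renumber, numeric(1)),
           broken = .data$res_a %in% displaced,
           distance = 2.9)
  list(model = model,
       truth = list(ladder = ladder, orientation = orientation,
                    insertion_at = insertion_at,
                    displaced_residues = displaced, bulge_vector = bulge_vec,
                    sequence_a = seq_a, sequence_b = seq_b))
}

#' Generate a toy two-chain complex with an oracle-computable interface
#'
#' Each residue is a compact four-atom backbone cluster; residues are
#' spaced 8 A apart along each chain so a residue's burial comes only
#' from the facing residue of the other chain. The leading
#' `ceiling(contact_fraction * n_res_b)` residues of chain B face their
#' chain A counterparts at contact range (5.5 A between cluster centres);
#' the rest sit 30 A away and bury nothing. The planted interface set is
#' certified by an independent Monte-Carlo SASA oracle at
#' `oracle_points` random directions; construction fails if any residue's
#' burial is ambiguous.
#'
#' @param n_res_a,n_res_b Residues per chain.
#' @param contact_fraction Fraction of chain B residues in contact (0, 1].
#' @param seed Integer seed.
#' @param oracle_points Monte-Carlo sample count for the oracle BSA.
#' @return List with `model`, `truth`: `interface_a`, `interface_b`
#'   (residue numbers), `oracle_bsa` (two-side average, square angstrom).
#' @export
make_toy_complex <- function(n_res_a = 8, n_res_b = 8, contact_fraction = 0.5,
                             seed = 1, oracle_points = 10000) {
  if (contact_fraction <= 0 || contact_fraction > 1)
    rlang::abort("contact_fraction must be in (0, 1]")
  k <- min(max(2L, ceiling(contact_fraction * n_res_b)), n_res_a)
  cluster <- rbind(N = c(0, 0, 0.8), CA = c(0.9, 0, -0.5),
                   C = c(-0.8, 0.5, -0.5), O = c(-0.1, -1.0, 0))
  residue_cluster <- function(res, center) {
    tibble(res = res, atom = rownames(cluster),
           x = cluster[, 1] + center[1], y = cluster[, 2] + center[2],
           z = cluster[, 3] + center[3])
  }
  bbA <- purrr::map_dfr(seq_len(n_res_a), function(i)
    residue_cluster(i, c(8 * i, 0, 0)))
  bbB <- purrr::map_dfr(seq_len(n_res_b), function(j)
    residue_cluster(j, c(8 * j, if (j <= k) 5.5 else 30, 0)))
  seq_a <- sample_sequence(n_res_a, seed + 1L)
  seq_b <- sample_sequence(n_res_b, seed + 2L)
  ma <- strand_to_model(bbA, "A", strsplit(seq_a, "")[[1]])
  mb <- strand_to_model(bbB, "B", strsplit(seq_b, "")[[1]])
  model <- new_structure_model(bind_rows(ma$atoms, mb$atoms),
                               id = sprintf("toy_complex_seed%d", seed))

  # planted truth from the independent Monte-Carlo oracle: a residue is
  # in the interface iff it buries area on complex formation; residues in
  # an ambiguous band would make the truth ill-defined, so construction
  # fails loudly rather than plant a fuzzy set
  oracle_iso_a <- sasa_monte_carlo(ma, n_points = oracle_points, seed = seed)
  oracle_iso_b <- sasa_monte_carlo(mb, n_points = oracle_points, seed = seed)
  oracle_cplx <- sasa_monte_carlo(model, n_points = oracle_points, seed = seed)
  akey <- function(a) paste(a$chain, a$resno, a$atom)
  rkey <- function(a) paste(a$chain, a$resno)
  d_at <- c(oracle_iso_a$area, oracle_iso_b$area) -
    oracle_cplx$area[match(c(akey(oracle_iso_a), akey(oracle_iso_b)),
                           akey(oracle_cplx))]
  d_res <- tapply(pmax(d_at, 0), c(rkey(oracle_iso_a), rkey(oracle_iso_b)), sum)
  if (any(d_res > 0.02 & d_res < 0.5))
    rlang::abort("toy complex construction failed: residue with ambiguous burial")
  buried <- names(d_res)[d_res >= 0.5]
  int_a <- sort(as.integer(sub("^A ", "", buried[grepl("^A ", buried)])))
  int_b <- sort(as.integer(sub("^B ", "", buried[grepl("^B ", buried)])))
  oracle_bsa <- (sum(oracle_iso_a$area) + sum(oracle_iso_b$area) -
                   sum(oracle_cplx$area)) / 2

  list(model = model,
       truth = list(interface_a = int_a, interface_b = int_b,
                    oracle_bsa = oracle_bsa, contact_residues_b = seq_len(k)))
}

#' Generate a family alignment with planted conservation classes
#'
#' Column classes are drawn to satisfy the request exactly: family
#' conserved (all rows identical), subfamily conserved (subfamily shares
#' one residue, every other row differs from it and from each other),
#' variable (subfamily rows differ), subfamily-specific insertion columns
#' (gapped in every non-subfamily row; `insertion_same` conserved within
#' the subfamily, `insertion_diff` not), and `gap_sub` (gap inside the
#' subfamily).
#'
#' @param class_vector Character vector over
#'   `c("family", "subfamily", "variable", "insertion_same",
#'   "insertion_diff", "gap_sub")`, one entry per column.
#' @param n_family Number of rows (default 7).
#' @param subfamily_size Leading rows forming the subfamily (default 2).
#' @param seed Integer seed.
#' @param row_names Row names; default `BMP9, BMP10, BMP14, BMP2, BMP4,
#'   BMP6, BMP7` layout for the default sizes.
#' @return List with `aln` (a `family_alignment`), `truth` (tibble
#'   `column`, `kind`, `expected_class`), `subfamily` (row names).
#' @export
make_msa <- function(class_vector, n_family = 7, subfamily_size = 2, seed = 1,
                     row_names = NULL) {
  kinds <- c("family", "subfamily", "variable", "insertion_same",
             "insertion_diff", "gap_sub")
  if (!all(class_vector %in% kinds))
    rlang::abort(paste0("unknown column kind(s): ",
                        paste(setdiff(class_vector, kinds), collapse = ", ")))
  if (subfamily_size < 2 || subfamily_size >= n_family)
    rlang::abort("need 2 <= subfamily_size < n_family")
  if (is.null(row_names)) {
    row_names <- if (n_family == 7 && subfamily_size == 2)
      c("BMP9", "BMP10", "BMP14", "BMP2", "BMP4", "BMP6", "BMP7")
    else paste0("SEQ", seq_len(n_family))
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sub_rows <- seq_len(subfamily_size)
  mat <- withr::with_seed(seed, {
    m <- matrix("-", n_family, length(class_vector))
    for (j in seq_along(class_vector)) {
      kind <- class_vector[j]
      col <- switch(kind,
        family = rep(sample(aa, 1), n_family),
        subfamily = {
          r <- sample(aa, 1)
          others <- sample(setdiff(aa, r), n_family - subfamily_size)
          c(rep(r, subfamily_size), others)
        },
        variable = {
          subs <- sample(aa, subfamily_size)
          while (length(unique(subs)) == 1) subs <- sample(aa, subfamily_size)
          c(subs, sample(aa, n_family - subfamily_size, replace = TRUE))
        },
        insertion_same = c(rep(sample(aa, 1), subfamily_size),
                           rep("-", n_family - subfamily_size)),
        insertion_diff = c(sample(aa, subfamily_size),
                           rep("-", n_family - subfamily_size)),
        gap_sub = {
          col <- sample(aa, n_family, replace = TRUE)
          col[sample(sub_rows, 1)] <- "-"
          col
        })
      m[, j] <- col
    }
    m
  })
  # insertion_diff with identical draws would misclassify; enforced distinct
  rownames(mat) <- row_names
  seqs <- stats::setNames(apply(mat, 1, paste, collapse = ""), row_names)
  aln <- build_alignment(seqs)
  expected <- dplyr::recode(class_vector,
    family = "family_conserved", subfamily = "subfamily_conserved",
    variable = "variable", insertion_same = "subfamily_conserved",
    insertion_diff = "variable", gap_sub = "gap_in_subfamily")
  list(aln = aln,
       truth = tibble(column = seq_along(class_vector), kind = class_vector,
                      expected_class = expected),
       subfamily = row_names[sub_rows])
}

#' Generate noisy sensorgrams from planted kinetic parameters
#'
#' @param params A [kinetic_params()] object (the planted truth).
#' @param concentrations Analyte concentrations (M); duplicates allowed.
#' @param noise_sd Additive Gaussian noise (RU).
#' @param seed Integer seed.
#' @param times Time grid (s).
#' @param t_assoc Association end time (s).
#' @return List with `data` (tibble `time`, `response`, `conc`, `curve`),
#'   `truth` (the params and `KD`).
#' @export
make_sensorgrams <- function(params, concentrations, noise_sd = 0, seed = 1,
                             times = seq(0, 600, by = 2), t_assoc = 300) {
  curves <- purrr::imap_dfr(concentrations, function(cc, i) {
    simulate_sensorgram(params, cc, times, t_assoc) |>
      mutate(curve = i)
  })
  if (noise_sd > 0)
    curves$response <- curves$response +
      withr::with_seed(seed, stats::rnorm(nrow(curves), 0, noise_sd))
  list(data = curves,
       truth = list(params = params, KD = equilibrium_kd(params$ka, params$kd),
                    noise_sd = noise_sd, t_assoc = t_assoc))
}

#' Rigidly transform and optionally perturb a copy of a model
#'
#' @param model A `structure_model`.
#' @param rotation_angles Euler angles (radians, z-y-z convention).
#' @param translation Length-3 translation (angstrom).
#' @param noise_sd Per-coordinate iid Gaussian noise (angstrom).
#' @param seed Integer seed.
#' @return List with `model` (the perturbed copy) and `truth` (`rotation`,
#'   `translation`, `noise_sd`).
#' @export
perturb_copy <- function(model, rotation_angles = c(0, 0, 0),
                         translation = c(0, 0, 0), noise_sd = 0, seed = 1) {
  R <- euler_rotation(rotation_angles[1], rotation_angles[2], rotation_angles[3])
  out <- transform_model(model, R, translation)
  if (noise_sd > 0) {
    n <- nrow(out$atoms)
    noise <- withr::with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3))
    out$atoms$x <- out$atoms$x + noise[, 1]
    out$atoms$y <- out$atoms$y + noise[, 2]
    out$atoms$z <- out$atoms$z + noise[, 3]
  }
  out$id <- paste0(model$id, "_perturbed")
  list(model = out,
       truth = list(rotation = R, translation = translation,
                    noise_sd = noise_sd))
}
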