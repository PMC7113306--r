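# Van der Waals radii (angstrom) for protein heavy atoms, standard
# interface-analysis values: C 1.70, N 1.55, O 1.52, S 1.80.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.40, ZN = 1.39, MG = 1.73, MN = 1.40, CA = 1.70,
               "NA" = 2.27, CU = 1.40, NI = 1.60, CO = 1.40)

atom_radii <- function(atoms) {
  r <- unname(VDW_RADII[atoms$element])
  if (anyNA(r)) {
    bad <- atoms[is.na(r), ][1, ]
    rlang::abort(paste0("no van der Waals radius for element '", bad$element,
                        "' (atom ", bad$atom, " in ", bad$resid, " ",
                        bad$chain, bad$resno, ")"))
  }
  r
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice); no randomness, so SASA values are reproducible.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa_engine <- function(xyz, radii, probe, pts) {
  n <- nrow(xyz)
  n_points <- nrow(pts)
  rp <- radii + probe
  area <- numeric(n)
  # neighbour lists from the pairwise distance matrix; fine up to ~10k atoms
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rp[i] + rp)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0) { area[i] <- 4 * pi * rp[i]^2; next }
    sp <- pts * rp[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- sp[exposed, 1] - xyz[j, 1]
      dy <- sp[exposed, 2] - xyz[j, 2]
      dz <- sp[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- (dx * dx + dy * dy + dz * dz) >= rp[j]^2
    }
    area[i] <- sum(exposed) / n_points * 4 * pi * rp[i]^2
  }
  area
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic golden-spiral point set on each atom's expanded sphere
#' against all neighbouring expanded spheres. Per-atom area is
#' `exposed_points / n_points * 4 * pi * (r + probe)^2`.
#'
#' @param model A `structure_model` (or atom tibble).
#' @param probe_radius Probe radius in angstrom (water: 1.4).
#' @param n_points Sphere sample count (>= 92; default 960).
#' @return A `sasa_map`: list with `per_atom` (atom tibble plus `area`),
#'   `per_residue` (summed over atoms), `probe_radius`, `n_points`,
#'   `radii_set`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  a <- if (is_structure_model(model)) model$atoms else as_tibble(model)
  if (nrow(a) < 1) rlang::abort("model has no atoms")
  if (n_points < 92) rlang::abort("n_points must be >= 92")
  radii <- atom_radii(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  a$area <- sasa_engine(xyz, radii, probe_radius, golden_spiral_points(n_points))
  per_res <- a |>
    group_by(.data$chain, .data$resno, .data$ins, .data$orf, .data$resid,
             .data$resid1) |>
    summarise(area = sum(.data$area), n_atoms = dplyr::n(), .groups = "drop")
  structure(list(per_atom = a, per_residue = per_res,
                 probe_radius = probe_radius, n_points = n_points,
                 radii_set = "protein-vdw-1.70/1.55/1.52/1.80"),
            class = "sasa_map")
}

# Independent Monte-Carlo SASA oracle: random (seeded) directions instead of
# the golden-spiral lattice, brute-force all-pairs burial test. Used only for
# cross-checks and for the planted buried-area truth of synthetic complexes.
sasa_monte_carlo <- function(model, probe_radius = 1.4, n_points = 10000,
                             seed = 1) {
  a <- if (is_structure_model(model)) model$atoms else as_tibble(model)
  radii <- atom_radii(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  withr::with_seed(seed, {
    z <- stats::runif(n_points, -1, 1)
    th <- stats::runif(n_points, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pts <- cbind(s * cos(th), s * sin(th), z)
  })
  area <- sasa_engine(xyz, radii, probe_radius, pts)
  a$area <- area
  a
}

#' Buried-interface analysis of a two-group chain partition
#'
#' Computes SASA three times (group A alone, group B alone, complex) and
#' reports the per-residue buried area `dSASA = SASA(isolated) -
#' SASA(complex)`, clamped at zero. Interface residues are those with
#' `dSASA >= min_delta`. The headline buried surface area is the two-side
#' average `(sum_A + sum_B) / 2` (PISA convention); both one-sided sums are
#' also reported.
#'
#' @param model A `structure_model` containing all chains.
#' @param group_a,group_b Disjoint chain-id sets.
#' @param min_delta Interface membership threshold in square angstrom. Any
#'   positive buried area counts; the default 0.1 guards float noise.
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return An `interface_report`: list with `residues` (per-residue tibble:
#'   `side`, `chain`, `resno`, `ins`, `orf`, `resid`, `dsasa`,
#'   `is_interface`), `bsa_total`, `bsa_a`, `bsa_b`, `contribution`
#'   (per-chain share of each side's buried area), and the parameters used.
#' @export
interface_report <- function(model, group_a, group_b, min_delta = 0.1,
                             probe_radius = 1.4, n_points = 960) {
  stopifnot(is_structure_model(model))
  if (length(intersect(group_a, group_b)) > 0)
    rlang::abort("group_a and group_b must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0)
    rlang::abort("both chain groups must be non-empty")

  iso_a <- compute_sasa(subset_chains(model, group_a), probe_radius, n_points)
  iso_b <- compute_sasa(subset_chains(model, group_b), probe_radius, n_points)
  cplx <- compute_sasa(subset_chains(model, c(group_a, group_b)),
                       probe_radius, n_points)

  delta_side <- function(iso, side) {
    iso$per_residue |>
      left_join(cplx$per_residue |>
                  select("chain", "resno", "ins", area_complex = "area"),
                by = c("chain", "resno", "ins")) |>
      mutate(dsasa = pmax(.data$area - .data$area_complex, 0),
             side = side,
             is_interface = .data$dsasa >= min_delta) |>
      select("side", "chain", "resno", "ins", "orf", "resid", "resid1",
             area_isolated = "area", "area_complex", "dsasa", "is_interface")
  }
  res <- bind_rows(delta_side(iso_a, "a"), delta_side(iso_b, "b"))
  bsa_a <- sum(res$dsasa[res$side == "a"])
  bsa_b <- sum(res$dsasa[res$side == "b"])
  contrib <- res |>
    group_by(.data$side, .data$chain) |>
    summarise(dsasa = sum(.data$dsasa), .groups = "drop_last") |>
    mutate(share = ifelse(sum(.data$dsasa) > 0,
                          .data$dsasa / sum(.data$dsasa), NA_real_)) |>
    ungroup()
  structure(list(residues = res, group_a = group_a, group_b = group_b,
                 bsa_total = (bsa_a + bsa_b) / 2, bsa_a = bsa_a, bsa_b = bsa_b,
                 contribution = contrib, min_delta = min_delta,
                 probe_radius = probe_radius, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report> ", paste(x$group_a, collapse = ","), " | ",
      paste(x$group_b, collapse = ","), "\n", sep = "")
  cat(sprintf("  BSA (two-side average): %.1f A^2 (A: %.1f, B: %.1f)\n",
              x$bsa_total, x$bsa_a, x$bsa_b))
  cat("  interface residues: ",
      sum(x$residues$is_interface & x$residues$side == "a"), " (side A), ",
      sum(x$residues$is_interface & x$residues$side == "b"), " (side B)\n",
      sep = "")
  invisible(x)
}

#' Interface residues of one side of an interface report
#' @param report An [interface_report()] result.
#' @param side `"a"` or `"b"`.
#' @export
interface_residues <- function(report, side = c("a", "b")) {
  side <- match.arg(side)
  filter(report$residues, .data$side == !!side, .data$is_interface)
}

#' Per-monomer breakdown of one side's buried surface area
#'
#' Splits side A's buried area over a partition of its chains (e.g. the two
#' monomers of a growth-factor dimer facing one receptor chain).
#'
#' @param report An [interface_report()] result.
#' @param monomer_chains List of chain-id vectors partitioning `group_a`.
#' @return Tibble with `monomer`, `chains`, `bsa`, `share`; shares sum to 1.
#' @export
per_monomer_breakdown <- function(report, monomer_chains) {
  stopifnot(inherits(report, "interface_report"))
  all_ch <- unlist(monomer_chains)
  if (!setequal(all_ch, report$group_a) || anyDuplicated(all_ch) > 0)
    rlang::abort("monomer_chains must partition group_a")
  resa <- filter(report$residues, .data$side == "a")
  out <- purrr::imap_dfr(monomer_chains, function(ch, nm) {
    tibble(monomer = if (is.character(nm) && nzchar(nm)) nm else paste(ch, collapse = ""),
           chains = paste(ch, collapse = ","),
           bsa = sum(resa$dsasa[resa$chain %in% ch]))
  })
  out$share <- if (sum(out$bsa) > 0) out$bsa / sum(out$bsa) else NA_real_
  out
}

#' Plot per-residue buried area of an interface
#' @param object An [interface_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interface_report
#' @export
autoplot.interface_report <- function(object, ...) {
  d <- filter(object$residues, .data$is_interface) |>
    mutate(label = paste0(.data$chain, .data$resno))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, -.data$dsasa),
                                  y = .data$dsasa, fill = .data$side)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(Delta * SASA ~ (ring(A)^2)),
                  title = "Buried area per interface residue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
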