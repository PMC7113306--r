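# Heavy-atom hydrogen-bond chemistry tables. Proline backbone N carries no
# amide hydrogen, so it is never a donor. Ser/Thr/Tyr hydroxyls act as both
# donor and acceptor; His ring nitrogens are treated as both (protonation
# unknown in crystal structures).
HB_DONORS <- list(
  backbone = "N",  # except PRO
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH"
)
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)
SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SB_BASIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))

flag_role <- function(atoms, table) {
  bb <- atoms$is_mainchain & atoms$atom %in% table$backbone &
    !(atoms$resid == "PRO" & atoms$atom == "N")
  sc <- mapply(function(res, at) at %in% (table[[res]] %||% character(0)),
               atoms$resid, atoms$atom)
  bb | sc
}

res_key <- function(d) paste0(d$chain, ":", d$resno, d$ins)

vec_angle <- function(a, b, c) {
  # angle at b (degrees) for rows of 3-col matrices
  u <- a - b; v <- c - b
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# antecedent of a donor atom: nearest heavy atom of the same residue within
# bonding distance (covers backbone N -> CA and all sidechain donors without
# a per-atom topology table)
antecedent_coords <- function(atoms, idx) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  keys <- res_key(atoms)
  out <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) {
    i <- idx[k]
    same <- which(keys == keys[i] & seq_len(nrow(atoms)) != i)
    if (length(same) == 0) next
    d2 <- rowSums((xyz[same, , drop = FALSE] -
                     matrix(xyz[i, ], length(same), 3, byrow = TRUE))^2)
    cand <- same[d2 < 1.9^2]
    if (length(cand) == 0) cand <- same[which.min(d2)]
    out[k, ] <- xyz[cand[which.min(d2[match(cand, same)])], ]
  }
  out
}

#' Detect hydrogen bonds between two chain sets
#'
#' Heavy-atom criteria suitable for mid-resolution crystal structures
#' without hydrogens: donor-acceptor distance `<= max_dist` and
#' antecedent-donor-acceptor angle `>= min_angle`, where the antecedent is
#' the donor's bonded heavy atom. Donors and acceptors are N/O atoms per a
#' standard chemistry table (Pro backbone N excluded as donor; Ser/Thr/Tyr
#' hydroxyls both roles). Each qualifying pair is reported once per
#' donor -> acceptor direction.
#'
#' @param model A `structure_model`.
#' @param chains_a,chains_b Disjoint chain-id sets; bonds are reported
#'   between the sets (both directions).
#' @param max_dist Donor-acceptor heavy-atom distance cutoff (angstrom).
#' @param min_angle Antecedent-donor-acceptor angle cutoff (degrees).
#' @param mainchain_only Keep only bonds where both partners are backbone
#'   atoms.
#' @return Tibble of bonds: donor/acceptor chain, resno, ins, orf, resid,
#'   atom, `distance`, `angle`, `donor_is_mainchain`, `acceptor_is_mainchain`.
#' @export
find_hbonds <- function(model, chains_a, chains_b, max_dist = 3.5,
                        min_angle = 90, mainchain_only = FALSE) {
  stopifnot(is_structure_model(model))
  if (length(intersect(chains_a, chains_b)) > 0)
    rlang::abort("chain sets must be disjoint")
  a <- filter(model$atoms, .data$is_polymer,
              .data$chain %in% c(chains_a, chains_b))
  a$don <- flag_role(a, HB_DONORS) & a$element == "N" |
    (flag_role(a, HB_DONORS) & a$element == "O")
  a$acc <- flag_role(a, HB_ACCEPTORS) & a$element %in% c("N", "O")
  a$set <- ifelse(a$chain %in% chains_a, "a", "b")
  xyz <- as.matrix(a[, c("x", "y", "z")])

  one_direction <- function(dset, aset) {
    di <- which(a$don & a$set == dset)
    ai <- which(a$acc & a$set == aset)
    if (length(di) == 0 || length(ai) == 0) return(NULL)
    pairs <- expand.grid(d = di, ac = ai)
    dd <- sqrt(rowSums((xyz[pairs$d, , drop = FALSE] -
                          xyz[pairs$ac, , drop = FALSE])^2))
    keep <- dd <= max_dist
    if (!any(keep)) return(NULL)
    pairs <- pairs[keep, ]; dd <- dd[keep]
    ante <- antecedent_coords(a, pairs$d)
    ok_ante <- !is.na(ante[, 1])
    ang <- rep(180, nrow(pairs))  # donor with no antecedent: accept
    if (any(ok_ante))
      ang[ok_ante] <- vec_angle(ante[ok_ante, , drop = FALSE],
                                xyz[pairs$d[ok_ante], , drop = FALSE],
                                xyz[pairs$ac[ok_ante], , drop = FALSE])
    keep <- ang >= min_angle
    if (!any(keep)) return(NULL)
    pairs <- pairs[keep, ]; dd <- dd[keep]; ang <- ang[keep]
    tibble(
      donor_chain = a$chain[pairs$d], donor_resno = a$resno[pairs$d],
      donor_ins = a$ins[pairs$d], donor_orf = a$orf[pairs$d],
      donor_resid = a$resid[pairs$d], donor_atom = a$atom[pairs$d],
      acceptor_chain = a$chain[pairs$ac], acceptor_resno = a$resno[pairs$ac],
      acceptor_ins = a$ins[pairs$ac], acceptor_orf = a$orf[pairs$ac],
      acceptor_resid = a$resid[pairs$ac], acceptor_atom = a$atom[pairs$ac],
      distance = dd, angle = ang,
      donor_is_mainchain = a$is_mainchain[pairs$d],
      acceptor_is_mainchain = a$is_mainchain[pairs$ac]
    )
  }
  out <- bind_rows(one_direction("a", "b"), one_direction("b", "a"))
  if (nrow(out) == 0) return(out)
  out <- arrange(out, .data$donor_chain, .data$donor_resno, .data$distance)
  if (mainchain_only)
    out <- filter(out, .data$donor_is_mainchain, .data$acceptor_is_mainchain)
  out
}

#' Detect salt bridges between two chain sets
#'
#' One record per acidic/basic residue pair whose closest carboxylate
#' oxygen to basic nitrogen distance is within `max_dist`. Histidine is
#' treated as a potential base (protonation unknown) and flagged
#' `ambiguous`.
#'
#' @inheritParams find_hbonds
#' @param max_dist Maximum O-N distance in angstrom (default 4.0).
#' @return Tibble with acidic/basic residue identifiers, closest atom pair,
#'   `distance`, `ambiguous`.
#' @export
find_salt_bridges <- function(model, chains_a, chains_b, max_dist = 4.0) {
  stopifnot(is_structure_model(model))
  a <- filter(model$atoms, .data$is_polymer,
              .data$chain %in% c(chains_a, chains_b))
  a$acid <- flag_role(a, c(SB_ACIDIC, backbone = "OXT")) |
    (a$atom == "OXT")
  a$base <- flag_role(a, c(SB_BASIC, backbone = list(character(0))))
  a$set <- ifelse(a$chain %in% chains_a, "a", "b")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ai <- which(a$acid); bi <- which(a$base)
  if (length(ai) == 0 || length(bi) == 0) return(empty_saltbridge())
  pairs <- expand.grid(ac = ai, ba = bi)
  pairs <- pairs[a$set[pairs$ac] != a$set[pairs$ba], ]
  if (nrow(pairs) == 0) return(empty_saltbridge())
  dd <- sqrt(rowSums((xyz[pairs$ac, , drop = FALSE] -
                        xyz[pairs$ba, , drop = FALSE])^2))
  keep <- dd <= max_dist
  if (!any(keep)) return(empty_saltbridge())
  pairs <- pairs[keep, ]; dd <- dd[keep]
  out <- tibble(
    acidic_chain = a$chain[pairs$ac], acidic_resno = a$resno[pairs$ac],
    acidic_ins = a$ins[pairs$ac], acidic_orf = a$orf[pairs$ac],
    acidic_resid = a$resid[pairs$ac], acidic_atom = a$atom[pairs$ac],
    basic_chain = a$chain[pairs$ba], basic_resno = a$resno[pairs$ba],
    basic_ins = a$ins[pairs$ba], basic_orf = a$orf[pairs$ba],
    basic_resid = a$resid[pairs$ba], basic_atom = a$atom[pairs$ba],
    distance = dd,
    ambiguous = a$resid[pairs$ba] == "HIS"
  )
  # minimum inter-group atom distance per residue pair
  out |>
    group_by(.data$acidic_chain, .data$acidic_resno, .data$acidic_ins,
             .data$basic_chain, .data$basic_resno, .data$basic_ins) |>
    slice(which.min(.data$distance)) |>
    ungroup() |>
    arrange(.data$acidic_chain, .data$acidic_resno, .data$distance)
}

empty_saltbridge <- function() {
  tibble(acidic_chain = character(), acidic_resno = integer(),
         acidic_ins = character(), acidic_orf = integer(),
         acidic_resid = character(), acidic_atom = character(),
         basic_chain = character(), basic_resno = integer(),
         basic_ins = character(), basic_orf = integer(),
         basic_resid = character(), basic_atom = character(),
         distance = numeric(), ambiguous = logical())
}

#' Group backbone hydrogen bonds into beta-sheet ladders
#'
#' Mainchain-mainchain bonds are clustered into ladders when they pair
#' residues advancing in register: residue-index steps of opposite sign
#' (antiparallel, the classic `(i, j), (i+2, j-2)` narrow-pair pattern) or
#' the same sign (parallel). A ladder requires at least two backbone bonds.
#'
#' @param hbonds A [find_hbonds()] result (from one structure).
#' @return A list of `sheet_ladder` records, each a list with `strand_a`
#'   and `strand_b` residue intervals, `hbonds` (tibble), `orientation`.
#'   Unclustered backbone bonds are attached as attribute `"unclustered"`.
#' @export
group_sheet_ladders <- function(hbonds) {
  mc <- filter(hbonds, .data$donor_is_mainchain, .data$acceptor_is_mainchain)
  if (nrow(mc) == 0)
    return(structure(list(), unclustered = mc))
  # orient every bond as (chain_lo residue i, chain_hi residue j)
  swap <- mc$donor_chain > mc$acceptor_chain |
    (mc$donor_chain == mc$acceptor_chain & mc$donor_resno > mc$acceptor_resno)
  pr <- tibble(
    chain_i = ifelse(swap, mc$acceptor_chain, mc$donor_chain),
    res_i = ifelse(swap, mc$acceptor_resno, mc$donor_resno),
    chain_j = ifelse(swap, mc$donor_chain, mc$acceptor_chain),
    res_j = ifelse(swap, mc$donor_resno, mc$acceptor_resno),
    bond = seq_len(nrow(mc))
  )
  pairs <- pr |>
    group_by(.data$chain_i, .data$res_i, .data$chain_j, .data$res_j) |>
    summarise(bonds = list(.data$bond), .groups = "drop") |>
    arrange(.data$chain_i, .data$chain_j, .data$res_i)

  # step patterns between successive residue pairs of one ladder:
  # antiparallel advances (+2, -2); parallel alternates its two registers,
  # (+2, +2), (0, +2) and (+2, 0)
  step_kind <- function(di, dj) {
    if (di == 2 && dj == -2) "antiparallel"
    else if ((di == 2 && dj == 2) || (di == 0 && dj == 2) ||
               (di == 2 && dj == 0)) "parallel"
    else NA_character_
  }
  ladders <- list(); used <- rep(FALSE, nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    if (used[s]) next
    grp <- s; used[s] <- TRUE; orient <- NA_character_
    repeat {
      last <- pairs[grp[length(grp)], ]
      cand <- which(!used & pairs$chain_i == last$chain_i &
                      pairs$chain_j == last$chain_j &
                      pairs$res_i >= last$res_i & pairs$res_i <= last$res_i + 2)
      step <- NA_integer_
      for (k in cand) {
        o <- step_kind(pairs$res_i[k] - last$res_i,
                       pairs$res_j[k] - last$res_j)
        if (!is.na(o) && (is.na(orient) || o == orient)) { step <- k; break }
      }
      if (is.na(step)) break
      if (is.na(orient)) orient <- o
      grp <- c(grp, step); used[step] <- TRUE
    }
    bond_ids <- unlist(pairs$bonds[grp])
    if (length(bond_ids) >= 2 && (length(grp) >= 2 || length(bond_ids) >= 2)) {
      if (is.na(orient)) {
        # single residue pair carrying >= 2 bonds: antiparallel narrow pair
        orient <- "antiparallel"
      }
      ladders[[length(ladders) + 1]] <- structure(list(
        strand_a = range(pairs$res_i[grp]),
        strand_b = range(pairs$res_j[grp]),
        chain_a = pairs$chain_i[grp][1], chain_b = pairs$chain_j[grp][1],
        hbonds = mc[bond_ids, ], orientation = orient
      ), class = "sheet_ladder")
    } else {
      used[grp] <- TRUE  # leave as unclustered
      for (g in grp) pairs$bonds[[g]] <- -abs(unlist(pairs$bonds[[g]]))
    }
  }
  in_ladder <- unlist(lapply(ladders, function(l) {
    which(seq_len(nrow(mc)) %in% match(
      do.call(paste, mc[, c("donor_chain", "donor_resno", "acceptor_chain",
                            "acceptor_resno", "donor_atom", "acceptor_atom")]),
      do.call(paste, l$hbonds[, c("donor_chain", "donor_resno", "acceptor_chain",
                                  "acceptor_resno", "donor_atom", "acceptor_atom")])
    ) & !is.na(match(
      do.call(paste, mc[, c("donor_chain", "donor_resno", "acceptor_chain",
                            "acceptor_resno", "donor_atom", "acceptor_atom")]),
      do.call(paste, l$hbonds[, c("donor_chain", "donor_resno", "acceptor_chain",
                                  "acceptor_resno", "donor_atom", "acceptor_atom")])
    )))
  }))
  lad_keys <- unlist(lapply(ladders, function(l)
    do.call(paste, l$hbonds[, c("donor_chain", "donor_resno", "acceptor_chain",
                                "acceptor_resno", "donor_atom", "acceptor_atom")])))
  mc_keys <- do.call(paste, mc[, c("donor_chain", "donor_resno", "acceptor_chain",
                                   "acceptor_resno", "donor_atom", "acceptor_atom")])
  structure(ladders, unclustered = mc[!(mc_keys %in% lad_keys), ])
}

#' @export
print.sheet_ladder <- function(x, ...) {
  cat("<sheet_ladder> ", x$orientation, ": ", x$chain_a, x$strand_a[1], "-",
      x$strand_a[2], " | ", x$chain_b, x$strand_b[1], "-", x$strand_b[2],
      " (", nrow(x$hbonds), " backbone H-bonds)\n", sep = "")
  invisible(x)
}
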