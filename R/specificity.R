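#' Detect a subfamily-specific insertion and its structural kink
#'
#' Locates alignment columns within a strand interval that are gapped in
#' every non-subfamily row but occupied in the subfamily (the hallmark of
#' a subfamily-specific one-residue insertion, e.g. the extra aromatic in
#' the finger-1 top strand of BMP9/BMP10), and quantifies the resulting
#' kink: after a local superposition on the flanking mainchain atoms, the
#' maximum mainchain deviation of the host strand from the reference
#' family member's strand.
#'
#' @param aln A `family_alignment`.
#' @param subfamily Subfamily row names.
#' @param member_model,member_chain Structure and chain of a subfamily
#'   member (ORF numbering assigned).
#' @param reference_model,reference_chain Structure and chain of a
#'   non-subfamily reference (ORF numbering assigned).
#' @param member_row,reference_row Alignment rows for the two structures.
#' @param strand_interval ORF interval `c(lo, hi)` in the member's
#'   numbering covering the strand.
#' @param flank Number of paired residues at each end of the interval used
#'   as the superposition anchor (default 2).
#' @return An `insertion_call`: list with `columns` (insertion columns;
#'   empty if none), `inserted_residues` (per subfamily member),
#'   `host_interval`, `kink_metric` (angstrom, max mainchain deviation —
#'   computed whether or not an insertion is present).
#' @export
detect_insertion <- function(aln, subfamily, member_model, member_chain,
                             reference_model, reference_chain,
                             member_row, reference_row,
                             strand_interval, flank = 2) {
  stopifnot(inherits(aln, "family_alignment"))
  others <- setdiff(rownames(aln$mat), subfamily)
  memb_map <- filter(aln$orf_map, .data$row == member_row,
                     .data$orf >= strand_interval[1],
                     .data$orf <= strand_interval[2])
  if (nrow(memb_map) == 0) rlang::abort("strand interval not covered by alignment row")
  cols <- memb_map$column
  ins_cols <- cols[vapply(cols, function(j) {
    all(aln$mat[others, j] == "-") && all(aln$mat[subfamily, j] != "-")
  }, logical(1))]
  inserted <- if (length(ins_cols) > 0)
    purrr::map_dfr(ins_cols, function(j) {
      filter(aln$orf_map, .data$column == j, .data$row %in% subfamily) |>
        select("row", "residue", "orf") |> mutate(column = j)
    })
  else tibble(row = character(), residue = character(), orf = integer(),
              column = integer())

  # paired (non-gap in both rows) columns in the interval -> orf pairs
  ref_map <- filter(aln$orf_map, .data$row == reference_row)
  paired <- memb_map |>
    dplyr::inner_join(ref_map |> select("column", ref_orf = "orf"),
                      by = "column")
  kink <- NA_real_
  if (nrow(paired) >= 2 * flank + 1) {
    mem_atoms <- purrr::map(paired$orf, function(o)
      filter(member_model$atoms, .data$chain == member_chain, .data$orf == o,
             .data$is_mainchain, .data$atom %in% c("N", "CA", "C", "O")))
    ref_atoms <- purrr::map(paired$ref_orf, function(o)
      filter(reference_model$atoms, .data$chain == reference_chain,
             .data$orf == o, .data$is_mainchain,
             .data$atom %in% c("N", "CA", "C", "O")))
    keep <- vapply(seq_along(mem_atoms), function(i)
      nrow(mem_atoms[[i]]) > 0 && nrow(ref_atoms[[i]]) > 0, logical(1))
    mem_atoms <- mem_atoms[keep]; ref_atoms <- ref_atoms[keep]
    n <- length(mem_atoms)
    if (n >= 2 * flank + 1) {
      anchor <- c(seq_len(flank), seq(n - flank + 1, n))
      pair_xyz <- function(ma, ra) {
        common <- intersect(ma$atom, ra$atom)
        list(m = as.matrix(ma[match(common, ma$atom), c("x", "y", "z")]),
             r = as.matrix(ra[match(common, ra$atom), c("x", "y", "z")]))
      }
      anc <- purrr::map(anchor, ~pair_xyz(mem_atoms[[.x]], ref_atoms[[.x]]))
      sp <- kabsch(list(xyz_moving = do.call(rbind, purrr::map(anc, "m")),
                        xyz_fixed = do.call(rbind, purrr::map(anc, "r"))))
      devs <- vapply(seq_len(n), function(i) {
        pq <- pair_xyz(mem_atoms[[i]], ref_atoms[[i]])
        moved <- pq$m %*% t(sp$rotation) +
          matrix(sp$translation, nrow(pq$m), 3, byrow = TRUE)
        max(sqrt(rowSums((moved - pq$r)^2)))
      }, numeric(1))
      kink <- max(devs)
    }
  }
  structure(list(columns = ins_cols, inserted_residues = inserted,
                 host_interval = strand_interval, kink_metric = kink),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat("<insertion_call> ",
      if (length(x$columns) == 0) "no insertion"
      else paste0("insertion at column(s) ", paste(x$columns, collapse = ",")),
      sprintf("; kink metric %.2f A\n", x$kink_metric), sep = "")
  invisible(x)
}

#' Predict whether a beta-augmentation binding mode is preserved
#'
#' Tests whether an antagonist that engages a template ligand through a
#' backbone hydrogen-bond ladder (beta-augmentation) could engage a target
#' ligand the same way. The target ligand is superposed onto the template
#' ligand over whole-domain mainchain atoms; each template ladder bond is
#' preserved if the corresponding target backbone atom sits within
#' `max_disp` of the template atom position and the implied bond to the
#' (fixed) antagonist atom still meets the hydrogen-bond distance
#' criterion. A kinked/bulged strand displaces the backbone and breaks the
#' ladder.
#'
#' @param template_model Structure of the antagonist:ligand complex.
#' @param template_ladder A `sheet_ladder` from [group_sheet_ladders()]
#'   whose bonds span the antagonist and the template ligand.
#' @param ligand_chains Template ligand chain ids.
#' @param target_model Structure containing the target ligand.
#' @param target_chains Target ligand chain ids.
#' @param min_required Minimum preserved bonds for a `compatible` verdict.
#' @param max_disp Maximum tolerated backbone displacement (angstrom) at a
#'   bond position.
#' @param max_hbond_dist Hydrogen-bond distance criterion for the implied
#'   bond (angstrom).
#' @return A `compatibility_verdict`: list with `verdict`
#'   (`"compatible"`/`"incompatible"`), `preserved_hbond_count`,
#'   `ladder_size`, `max_backbone_displacement`, `bonds` (per-bond tibble).
#' @export
predict_beta_augmentation <- function(template_model, template_ladder,
                                      ligand_chains, target_model,
                                      target_chains, min_required = 3,
                                      max_disp = 2.0, max_hbond_dist = 3.5) {
  stopifnot(inherits(template_ladder, "sheet_ladder"))
  sp <- superpose_models(target_model, template_model, target_chains,
                         ligand_chains, mainchain_only = TRUE)
  moved <- transform_model(target_model, sp$rotation, sp$translation)
  rp <- sp$correspondence$residue_pairs

  hb <- template_ladder$hbonds
  bonds <- purrr::map_dfr(seq_len(nrow(hb)), function(k) {
    b <- hb[k, ]
    lig_side <- if (b$donor_chain %in% ligand_chains) "donor" else "acceptor"
    lig_chain <- b[[paste0(lig_side, "_chain")]]
    lig_resno <- b[[paste0(lig_side, "_resno")]]
    lig_atom <- b[[paste0(lig_side, "_atom")]]
    other_side <- setdiff(c("donor", "acceptor"), lig_side)
    partner <- filter(template_model$atoms,
                      .data$chain == b[[paste0(other_side, "_chain")]],
                      .data$resno == b[[paste0(other_side, "_resno")]],
                      .data$atom == b[[paste0(other_side, "_atom")]])
    tmpl_atom <- filter(template_model$atoms, .data$chain == lig_chain,
                        .data$resno == lig_resno, .data$atom == lig_atom)
    # equivalent target residue via the alignment-derived residue pairing
    hit <- which(rp$fixed_chain == lig_chain & rp$fixed_resno == lig_resno)
    if (length(hit) == 0 || nrow(tmpl_atom) == 0 || nrow(partner) == 0)
      return(tibble(bond = k, paired = FALSE, displacement = NA_real_,
                    implied_dist = NA_real_, preserved = FALSE))
    tgt_atom <- filter(moved$atoms, .data$chain == rp$moving_chain[hit[1]],
                       .data$resno == rp$moving_resno[hit[1]],
                       .data$atom == lig_atom)
    if (nrow(tgt_atom) == 0)
      return(tibble(bond = k, paired = FALSE, displacement = NA_real_,
                    implied_dist = NA_real_, preserved = FALSE))
    disp <- sqrt(sum((c(tgt_atom$x, tgt_atom$y, tgt_atom$z) -
                        c(tmpl_atom$x, tmpl_atom$y, tmpl_atom$z))^2))
    impd <- sqrt(sum((c(tgt_atom$x, tgt_atom$y, tgt_atom$z) -
                        c(partner$x, partner$y, partner$z))^2))
    tibble(bond = k, paired = TRUE, displacement = disp, implied_dist = impd,
           preserved = disp <= max_disp && impd <= max_hbond_dist)
  })
  n_pres <- sum(bonds$preserved)
  structure(list(
    verdict = if (n_pres >= min_required) "compatible" else "incompatible",
    preserved_hbond_count = n_pres, ladder_size = nrow(hb),
    max_backbone_displacement = suppressWarnings(max(bonds$displacement,
                                                     na.rm = TRUE)),
    min_required = min_required, max_disp = max_disp,
    superposition_rmsd = sp$rmsd, bonds = bonds
  ), class = "compatibility_verdict")
}

#' @export
print.compatibility_verdict <- function(x, ...) {
  cat("<compatibility_verdict> ", x$verdict, ": ", x$preserved_hbond_count,
      "/", x$ladder_size, " ladder bonds preserved (max backbone displacement ",
      sprintf("%.2f", x$max_backbone_displacement), " A)\n", sep = "")
  invisible(x)
}

#' Design interface swap mutants between two subfamily members
#'
#' For every variable (non-conserved, non-override) interface position
#' where the aligned residues of the source and target rows differ, emits
#' the substitution that converts the source residue into its equivalent
#' in the target — the classic specificity-swap mutant panel. Structurally
#' promoted override residues are excluded: they are conserved in
#' function if not in identity.
#'
#' @param partition A [tripartite_partition()] result for the source
#'   ligand's interface.
#' @param aln The `family_alignment`.
#' @param source_row,target_row Alignment rows (e.g. `"BMP9"`, `"BMP10"`).
#' @param site Optional site label recorded on every mutant.
#' @return Tibble of `swap_mutant`s: `position` (source ORF), `from`,
#'   `to`, `site`, sorted by position.
#' @export
design_swap_mutants <- function(partition, aln, source_row, target_row,
                                site = NA_character_) {
  src_map <- filter(aln$orf_map, .data$row == source_row)
  tgt_map <- filter(aln$orf_map, .data$row == target_row)
  cand <- partition |>
    filter(.data$partition == "variable", !.data$override)
  out <- cand |>
    left_join(src_map |> select(orf = "orf", column = "column", from = "residue"),
              by = "orf") |>
    left_join(tgt_map |> select(column = "column", to = "residue"),
              by = "column") |>
    filter(!is.na(.data$from), !is.na(.data$to), .data$from != .data$to) |>
    mutate(position = .data$orf, site = !!site,
           label = paste0(.data$from, .data$position, .data$to)) |>
    select("position", "from", "to", "site", "label") |>
    arrange(.data$position)
  out
}
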